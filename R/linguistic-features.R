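# Transcript-derived features: POS ratios, lexical diversity, propositional
# and content density, psycholinguistic noun norms, and TF-IDF-based
# inter-sentence semantic distances. Denominator conventions: "all words"
# means all word tokens (punctuation is never a token, interjections count
# as words).

#' Fixed order of the linguistic feature names
#' @return character vector of feature names.
#' @export
linguistic_feature_names <- function() {
  c(
    "n_words", "verb_noun_ratio", "subordinate_coordinate_conjunction_ratio",
    "adverb_ratio", "noun_ratio", "verb_ratio", "pronoun_ratio",
    "personal_pronoun_ratio", "determiner_ratio", "preposition_ratio",
    "verb_present_participle_ratio", "verb_modal_ratio",
    "verb_third_person_singular_ratio", "interjection_ratio",
    "avg_word_length", "words_not_in_dict_ratio", "brunets_index",
    "honores_statistic", "moving_average_type_token_ratio", "n_unique_in_50",
    "propositional_density", "content_density", "frequency_noun",
    "age_of_acquisition_noun", "familiarity_noun", "ambiguity_noun",
    "noun_concreteness",
    "production_NP_PRP", "production_ROOT_FRAG", "production_VP_VBG",
    "production_VP_VBG_PP", "production_VP_VBD_NP", "production_INTJ_UH",
    "NP_ratio", "VP_ratio", "avg_n_words_in_NP", "flesch_kincaid",
    "avg_distance_between_utterances", "prop_utterance_dist_below_05"
  )
}

#' Part-of-speech ratio features
#'
#' Computes the POS-based ratios plus `n_words`, `avg_word_length` and
#' `words_not_in_dict_ratio`. All ratios use the count of word tokens as
#' denominator except `verb_noun_ratio` (verbs over nouns) and the
#' subordinate/coordinate conjunction ratio.
#'
#' @param tokens a `cogspeech_tokens` object from [tokenize_and_tag()].
#' @param dictionary character vector of dictionary words; defaults to the
#'   bundled list.
#' @return a `cogspeech_features` with 17 features. Ratios with a zero
#'   denominator (e.g. `verb_noun_ratio` in a noun-free transcript) are
#'   flagged invalid rather than silently set to 0.
#' @export
pos_ratio_features <- function(tokens, dictionary = english_dictionary()) {
  stopifnot(inherits(tokens, "cogspeech_tokens"))
  cls <- .coarse_class(tokens)
  n <- nrow(tokens)
  nouns <- sum(cls == "NOUN")
  verbs <- sum(cls == "VERB")
  cc <- sum(cls == "CCONJ")
  sc <- sum(cls == "SCONJ")
  vals <- c(
    n_words = n,
    verb_noun_ratio = if (nouns > 0) verbs / nouns else NA_real_,
    subordinate_coordinate_conjunction_ratio =
      if (cc > 0) sc / cc else NA_real_,
    adverb_ratio = sum(cls == "ADV") / n,
    noun_ratio = nouns / n,
    verb_ratio = verbs / n,
    pronoun_ratio = sum(cls == "PRON") / n,
    personal_pronoun_ratio = sum(tokens$tag == "PRP") / n,
    determiner_ratio = sum(cls == "DET") / n,
    preposition_ratio = sum(cls == "ADP") / n,
    verb_present_participle_ratio = sum(tokens$tag == "VBG") / n,
    verb_modal_ratio = sum(tokens$tag == "MD") / n,
    verb_third_person_singular_ratio = sum(tokens$tag == "VBZ") / n,
    interjection_ratio = sum(cls == "INTJ") / n,
    avg_word_length = mean(nchar(gsub("[^a-z]", "", tokens$token))),
    words_not_in_dict_ratio =
      sum(!(tokens$token %in% dictionary | tokens$lemma %in% dictionary)) / n
  )
  feature_vector(vals)
}

#' Lexical diversity features
#'
#' Moving-average type-token ratio (mean TTR over all contiguous windows of
#' `window` tokens), mean number of unique words per `sample_size`-token
#' sliding window, Brunet's index \eqn{W = N^{V^{-0.165}}} and Honore's
#' statistic \eqn{R = 100 \ln(N) / (1 - V_1/V)} with N tokens, V types and
#' V1 hapax legomena. Texts shorter than a window are scored on the whole
#' text as a single window.
#'
#' @param tokens a `cogspeech_tokens` object.
#' @param window MATTR window length in tokens (default 20).
#' @param sample_size window length for the unique-word count (default 50).
#' @return a `cogspeech_features` with 4 features. Honore's statistic is
#'   flagged invalid when every type is a hapax (V1 = V).
#' @export
lexical_diversity_features <- function(tokens, window = 20L, sample_size = 50L) {
  stopifnot(inherits(tokens, "cogspeech_tokens"), nrow(tokens) >= 1)
  toks <- tokens$token
  N <- length(toks)
  tab <- table(toks)
  V <- length(tab)
  V1 <- sum(tab == 1L)
  brunet <- N^(V^-0.165)
  honore <- if (V1 < V) 100 * log(N) / (1 - V1 / V) else NA_real_
  win_stat <- function(w, f) {
    if (N <= w) return(f(toks))
    mean(vapply(seq_len(N - w + 1L), function(i) f(toks[i:(i + w - 1L)]), 0))
  }
  mattr <- win_stat(as.integer(window),
                    function(x) length(unique(x)) / length(x))
  uniq50 <- win_stat(as.integer(sample_size),
                     function(x) as.numeric(length(unique(x))))
  feature_vector(c(
    brunets_index = brunet,
    honores_statistic = honore,
    moving_average_type_token_ratio = mattr,
    n_unique_in_50 = uniq50
  ))
}

#' Density and psycholinguistic norm features
#'
#' Propositional density is the ratio of verbs, adjectives, adverbs,
#' prepositions and conjunctions to all words; content density the ratio of
#' nouns, verbs, adjectives and adverbs to all words. The five noun norm
#' features are means of lexicon values over noun tokens covered by the
#' norm lexicon (lookup by lemma, then surface form, case-insensitive).
#'
#' @param tokens a `cogspeech_tokens` object.
#' @param lexicon a `cogspeech_norm_lexicon` from [make_norm_lexicon()] or a
#'   data.frame with columns word, frequency, aoa, familiarity, ambiguity,
#'   concreteness.
#' @return a `cogspeech_features` with 7 features; norm features are flagged
#'   invalid when no noun is covered. Coverage fraction is reported in
#'   `$meta$norm_coverage`.
#' @export
density_and_norm_features <- function(tokens, lexicon) {
  stopifnot(inherits(tokens, "cogspeech_tokens"))
  lex <- as.data.frame(lexicon)
  stopifnot(all(c("word", "frequency", "aoa", "familiarity", "ambiguity",
                  "concreteness") %in% names(lex)))
  cls <- .coarse_class(tokens)
  n <- nrow(tokens)
  prop_density <- sum(cls %in% c("VERB", "ADJ", "ADV", "ADP", "CCONJ", "SCONJ")) / n
  content_density <- sum(cls %in% c("NOUN", "VERB", "ADJ", "ADV")) / n

  noun_idx <- which(cls == "NOUN")
  key <- tolower(lex$word)
  hit <- function(w) match(w, key)
  rows <- rep(NA_integer_, length(noun_idx))
  if (length(noun_idx) > 0) {
    rows <- hit(tokens$lemma[noun_idx])
    miss <- is.na(rows)
    rows[miss] <- hit(tokens$token[noun_idx][miss])
  }
  covered <- !is.na(rows)
  coverage <- if (length(noun_idx) > 0) mean(covered) else 0
  norm_mean <- function(col) {
    if (!any(covered)) return(NA_real_)
    mean(lex[[col]][rows[covered]])
  }
  vals <- c(
    propositional_density = prop_density,
    content_density = content_density,
    frequency_noun = norm_mean("frequency"),
    age_of_acquisition_noun = norm_mean("aoa"),
    familiarity_noun = norm_mean("familiarity"),
    ambiguity_noun = norm_mean("ambiguity"),
    noun_concreteness = norm_mean("concreteness")
  )
  feature_vector(vals, meta = list(norm_coverage = coverage))
}

#' Inter-sentence semantic distance features
#'
#' Builds TF-IDF vectors over the transcript's own sentences (raw term
#' frequency times smoothed idf \eqn{\ln((1+N)/(1+df)) + 1}) and computes
#' the average pairwise cosine distance over all unordered sentence pairs
#' and the proportion of pairs with distance at most 0.5.
#'
#' @param tokens a `cogspeech_tokens` object.
#' @return a `cogspeech_features` with 2 features, flagged invalid for
#'   transcripts with fewer than two sentences.
#' @export
semantic_distance_features <- function(tokens) {
  stopifnot(inherits(tokens, "cogspeech_tokens"))
  ns <- attr(tokens, "n_sentences")
  if (is.null(ns)) ns <- max(tokens$sentence) + 1L
  if (ns < 2L) {
    return(feature_vector(
      c(avg_distance_between_utterances = NA_real_,
        prop_utterance_dist_below_05 = NA_real_),
      valid = c(avg_distance_between_utterances = FALSE,
                prop_utterance_dist_below_05 = FALSE)
    ))
  }
  vocab <- sort(unique(tokens$token))
  tf <- matrix(0, nrow = ns, ncol = length(vocab),
               dimnames = list(NULL, vocab))
  for (s in seq_len(ns)) {
    tab <- table(tokens$token[tokens$sentence == s - 1L])
    tf[s, names(tab)] <- as.numeric(tab)
  }
  df <- colSums(tf > 0)
  idf <- log((1 + ns) / (1 + df)) + 1
  w <- sweep(tf, 2, idf, `*`)
  norms <- sqrt(rowSums(w^2))
  dists <- c()
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      sim <- sum(w[i, ] * w[j, ]) / (norms[i] * norms[j])
      dists <- c(dists, 1 - sim)
    }
  }
  feature_vector(c(
    avg_distance_between_utterances = mean(dists),
    prop_utterance_dist_below_05 = mean(dists <= 0.5)
  ))
}

#' Extract the full linguistic feature vector from raw text
#'
#' Orchestrates tokenization/tagging, POS ratios, lexical diversity,
#' density/norm features, syntactic chunk-parse features and semantic
#' distance features into one fixed-order named vector (see
#' [linguistic_feature_names()]).
#'
#' @param text transcript text (non-empty string).
#' @param lexicon a norm lexicon (see [make_norm_lexicon()]).
#' @param mattr_window,unique_sample window sizes for the diversity features.
#' @param extra_dictionary_words extra words accepted by
#'   `words_not_in_dict_ratio`.
#' @return a `cogspeech_features` with the features of
#'   [linguistic_feature_names()], in that order.
#' @export
extract_linguistic_features <- function(text, lexicon,
                                        mattr_window = 20L,
                                        unique_sample = 50L,
                                        extra_dictionary_words = character()) {
  tokens <- tokenize_and_tag(text)
  dict <- c(english_dictionary(), tolower(extra_dictionary_words))
  merged <- merge_features(
    pos_ratio_features(tokens, dictionary = dict),
    lexical_diversity_features(tokens, mattr_window, unique_sample),
    density_and_norm_features(tokens, lexicon),
    syntactic_parse_features(text),
    semantic_distance_features(tokens)
  )
  ord <- linguistic_feature_names()
  feature_vector(merged$values[ord], merged$valid[ord], merged$meta)
}
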