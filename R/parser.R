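# Deterministic POS-driven chunk parsing. A lightweight stand-in for full
# constituency parsing: noun phrases, prepositional phrases, verb phrases
# and interjection chunks are built by a single left-to-right pass over the
# tagged tokens of each sentence. The six contracted production-rule counts
# are defined on these chunks:
#   NP -> PRP     a noun phrase consisting of a single personal pronoun
#   ROOT -> FRAG  a sentence containing no verb or modal (fragment)
#   VP -> VBG     a VP headed by a present participle with no PP complement
#   VP -> VBG_PP  a VP with a present participle followed by a PP
#   VP -> VBD_NP  a past-tense verb directly followed by an NP complement
#   INTJ -> UH    an interjection token

.chunk_sentence <- function(tok, tag) {
  n <- length(tok)
  chunks <- list()
  i <- 1L
  add <- function(type, span, head = NA_character_) {
    chunks[[length(chunks) + 1L]] <<- list(type = type, span = span, head = head)
  }
  while (i <= n) {
    t <- tag[i]
    if (t == "UH") {
      add("INTJ", i, "UH"); i <- i + 1L
    } else if (t == "PRP" || t == "WP") {
      add("NP", i, t); i <- i + 1L
    } else if (t %in% c("DT", "PRP$", "JJ", "JJR", "JJS", "CD") ||
               t %in% c("NN", "NNS", "NNP", "NNPS")) {
      # NP: (DT|PRP$)? (JJ|CD)* NN+  -- require at least one noun
      j <- i
      if (tag[j] %in% c("DT", "PRP$")) j <- j + 1L
      while (j <= n && tag[j] %in% c("JJ", "JJR", "JJS", "CD")) j <- j + 1L
      k <- j
      while (k <= n && tag[k] %in% c("NN", "NNS", "NNP", "NNPS")) k <- k + 1L
      if (k > j) {
        add("NP", i:(k - 1L), "NN"); i <- k
      } else i <- i + 1L
    } else i <- i + 1L
  }
  # PPs: IN/TO immediately preceding an NP chunk
  np_starts <- vapply(chunks, function(c) if (c$type == "NP") c$span[1] else NA_integer_, 1L)
  for (s in np_starts[!is.na(np_starts)]) {
    if (s > 1L && tag[s - 1L] %in% c("IN", "TO")) {
      chunks[[length(chunks) + 1L]] <- list(
        type = "PP", span = (s - 1L):max(which(np_starts == s)), head = "IN")
    }
  }
  # VPs: maximal runs of MD/VB* plus an immediate NP or PP complement
  verb_tags <- c("MD", "VB", "VBD", "VBG", "VBN", "VBP", "VBZ")
  vps <- list()
  i <- 1L
  while (i <= n) {
    if (tag[i] %in% verb_tags) {
      j <- i
      while (j <= n && tag[j] %in% verb_tags) j <- j + 1L
      vp <- list(type = "VP", verb_span = i:(j - 1L),
                 verb_tags = tag[i:(j - 1L)], complement = "none")
      if (j <= n) {
        ch_here <- Filter(function(c) c$span[1] == j, chunks)
        pp_here <- any(vapply(ch_here, function(c) c$type == "PP", TRUE))
        np_here <- any(vapply(ch_here, function(c) c$type == "NP", TRUE))
        if (pp_here) vp$complement <- "PP"
        else if (np_here || tag[j] %in% c("IN", "TO")) {
          # allow PP complement whose preposition starts right after the verb
          pp_after <- tag[j] %in% c("IN", "TO") &&
            any(vapply(chunks, function(c) c$type == "PP" && c$span[1] == j, TRUE))
          vp$complement <- if (np_here) "NP" else if (pp_after) "PP" else "none"
        }
      }
      vps[[length(vps) + 1L]] <- vp
      i <- j
    } else i <- i + 1L
  }
  list(chunks = chunks, vps = vps,
       has_verb = any(tag %in% verb_tags))
}

# Syllable counting: vowel-group counting with a silent-e rule.
# Count maximal groups of [aeiouy]; subtract a final silent 'e' (not 'le'
# after a consonant) when more than one group remains; minimum 1.
count_syllables <- function(word) {
  w <- tolower(gsub("[^a-z]", "", word))
  if (!nzchar(w)) return(0L)
  groups <- length(gregexpr("[aeiouy]+", w)[[1]])
  if (identical(gregexpr("[aeiouy]+", w)[[1]][1], -1L)) return(1L)
  if (groups > 1L && grepl("e$", w) && !grepl("le$", w)) groups <- groups - 1L
  max(1L, groups)
}

#' Syntactic features from chunk parsing
#'
#' Counts the six contracted production rules, the NP and VP constituent
#' ratios, the average noun-phrase length in words, and the Flesch-Kincaid
#' grade level \eqn{0.39 (words/sentences) + 11.8 (syllables/word) - 15.59}.
#'
#' @param text transcript text.
#' @return a `cogspeech_features` with 10 features. `NP_ratio`/`VP_ratio`
#'   are computed over all chunked constituents (NP, VP, PP, INTJ);
#'   `avg_n_words_in_NP` is flagged invalid when there is no noun phrase.
#' @export
syntactic_parse_features <- function(text) {
  tokens <- tokenize_and_tag(text)
  ns <- attr(tokens, "n_sentences")
  counts <- c(NP_PRP = 0, ROOT_FRAG = 0, VP_VBG = 0, VP_VBG_PP = 0,
              VP_VBD_NP = 0, INTJ_UH = 0)
  n_np <- 0; n_vp <- 0; n_const <- 0
  np_lens <- c()
  for (s in seq_len(ns)) {
    sel <- tokens$sentence == s - 1L
    parsed <- .chunk_sentence(tokens$token[sel], tokens$tag[sel])
    for (ch in parsed$chunks) {
      n_const <- n_const + 1L
      if (ch$type == "NP") {
        n_np <- n_np + 1L
        np_lens <- c(np_lens, length(ch$span))
        if (identical(ch$head, "PRP")) counts["NP_PRP"] <- counts["NP_PRP"] + 1
      }
      if (ch$type == "INTJ") counts["INTJ_UH"] <- counts["INTJ_UH"] + 1
    }
    for (vp in parsed$vps) {
      n_vp <- n_vp + 1L
      n_const <- n_const + 1L
      has_vbg <- "VBG" %in% vp$verb_tags
      if (has_vbg && vp$complement == "PP") {
        counts["VP_VBG_PP"] <- counts["VP_VBG_PP"] + 1
      } else if (has_vbg) {
        counts["VP_VBG"] <- counts["VP_VBG"] + 1
      }
      if (vp$verb_tags[length(vp$verb_tags)] == "VBD" && vp$complement == "NP") {
        counts["VP_VBD_NP"] <- counts["VP_VBD_NP"] + 1
      }
    }
    if (!parsed$has_verb) counts["ROOT_FRAG"] <- counts["ROOT_FRAG"] + 1
  }
  syl <- sum(vapply(tokens$token, count_syllables, 0L))
  fk <- 0.39 * (nrow(tokens) / ns) + 11.8 * (syl / nrow(tokens)) - 15.59
  vals <- c(
    production_NP_PRP = unname(counts["NP_PRP"]),
    production_ROOT_FRAG = unname(counts["ROOT_FRAG"]),
    production_VP_VBG = unname(counts["VP_VBG"]),
    production_VP_VBG_PP = unname(counts["VP_VBG_PP"]),
    production_VP_VBD_NP = unname(counts["VP_VBD_NP"]),
    production_INTJ_UH = unname(counts["INTJ_UH"]),
    NP_ratio = if (n_const > 0) n_np / n_const else 0,
    VP_ratio = if (n_const > 0) n_vp / n_const else 0,
    avg_n_words_in_NP = if (n_np > 0) mean(np_lens) else NA_real_,
    flesch_kincaid = fk
  )
  feature_vector(vals)
}
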