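# Tokenization, POS tagging and lemmatization.
#
# Tokenization rules (stable, documented):
#   * sentences are split on runs of . ! ? (a transcript without terminal
#     punctuation is a single sentence);
#   * word tokens match [A-Za-z][A-Za-z'-]* after lowercasing; punctuation
#     and digits are never tokens;
#   * tags are Penn Treebank; unknown words fall back to suffix rules
#     (-ly -> RB, -ing -> VBG, -ed -> VBD, -s -> NNS, adjectival suffixes ->
#     JJ, else NN).

.suffix_tag <- function(word) {
  if (grepl("ly$", word) && nchar(word) > 3) return("RB")
  if (grepl("ing$", word) && nchar(word) > 4) return("VBG")
  if (grepl("ed$", word) && nchar(word) > 3) return("VBD")
  if (grepl("(ful|ous|ive|able|ible|al|ish)$", word) && nchar(word) > 4) return("JJ")
  if (grepl("(tion|ness|ment|ity|ship|hood)$", word)) return("NN")
  if (grepl("[^su]s$", word) && nchar(word) > 3) return("NNS")
  "NN"
}

.lemma_of <- function(word, tag) {
  if (word %in% names(.irregular_lemmas)) return(unname(.irregular_lemmas[word]))
  if (tag %in% c("NNS", "NNPS")) {
    plain <- sub("s$", "", word)
    if (plain %in% names(.tag_lexicon())) return(plain)
    if (grepl("ies$", word)) return(sub("ies$", "y", word))
    if (grepl("(ches|shes|sses|xes|zes)$", word)) return(sub("es$", "", word))
    if (grepl("s$", word) && !grepl("ss$", word)) return(plain)
  }
  if (tag == "VBG" && grepl("ing$", word)) {
    stem <- sub("ing$", "", word)
    if (grepl("([a-z])\\1$", stem)) stem <- sub(".$", "", stem)   # tipping -> tip
    if (stem %in% names(.tag_lexicon())) return(stem)
    if (paste0(stem, "e") %in% names(.tag_lexicon())) return(paste0(stem, "e"))
    return(stem)
  }
  if (tag %in% c("VBD", "VBN") && grepl("ed$", word)) {
    stem <- sub("ed$", "", word)
    if (grepl("([a-z])\\1$", stem)) stem <- sub(".$", "", stem)
    if (stem %in% names(.tag_lexicon())) return(stem)
    if (paste0(stem, "e") %in% names(.tag_lexicon())) return(paste0(stem, "e"))
    return(stem)
  }
  if (tag == "VBZ" && grepl("s$", word)) {
    if (grepl("(ches|shes|sses|xes|zes)$", word)) return(sub("es$", "", word))
    if (grepl("ies$", word)) return(sub("ies$", "y", word))
    return(sub("s$", "", word))
  }
  word
}

#' Tokenize and POS-tag a transcript
#'
#' Splits the text into sentences and word tokens, assigns Penn Treebank POS
#' tags from the bundled lexicon (suffix-rule fallback for unknown words) and
#' rule-based lemmas.
#'
#' @param text a non-empty UTF-8 string.
#' @return a `cogspeech_tokens` object: a data.frame with columns `token`
#'   (lowercased surface form), `lemma`, `tag` (Penn Treebank), `sentence`
#'   (0-based sentence index), plus attributes `n_sentences` and
#'   `known` (logical, whether the tag came from the lexicon).
#' @export
tokenize_and_tag <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    cs_stop("text must be a non-empty string", "cogspeech_empty_input")
  }
  sents <- strsplit(text, "[.!?]+")[[1]]
  sents <- sents[nzchar(trimws(sents))]
  if (length(sents) == 0L) {
    cs_stop("text contains no words", "cogspeech_empty_input")
  }
  lex <- .tag_lexicon()
  rows <- lapply(seq_along(sents), function(si) {
    m <- regmatches(sents[si], gregexpr("[A-Za-z][A-Za-z'-]*", sents[si]))[[1]]
    if (length(m) == 0L) return(NULL)
    tok <- tolower(m)
    known <- tok %in% names(lex)
    tag <- ifelse(known, unname(lex[tok]), vapply(tok, .suffix_tag, ""))
    data.frame(token = tok, tag = tag, sentence = si - 1L, known = known,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L) {
    cs_stop("text contains no words", "cogspeech_empty_input")
  }
  # renumber sentences that actually contained words, keeping 0-based indices
  out$sentence <- as.integer(match(out$sentence, sort(unique(out$sentence))) - 1L)
  out$lemma <- mapply(.lemma_of, out$token, out$tag, USE.NAMES = FALSE)
  out <- out[, c("token", "lemma", "tag", "sentence", "known")]
  attr(out, "n_sentences") <- max(out$sentence) + 1L
  class(out) <- c("cogspeech_tokens", "data.frame")
  out
}

# Penn Treebank -> coarse class mapping used by the ratio features.
# "Verbs" are the VB* tags; modals (MD) are counted only by the modal
# feature; TO is counted with prepositions; subordinating conjunctions are
# the IN-tagged members of the bundled subordinator list.
.coarse_class <- function(tokens) {
  tag <- tokens$tag
  cls <- rep("OTHER", length(tag))
  cls[tag %in% c("NN", "NNS", "NNP", "NNPS")] <- "NOUN"
  cls[tag %in% c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ")] <- "VERB"
  cls[tag %in% c("JJ", "JJR", "JJS")] <- "ADJ"
  cls[tag %in% c("RB", "RBR", "RBS")] <- "ADV"
  cls[tag %in% c("PRP", "PRP$", "WP", "WP$")] <- "PRON"
  cls[tag %in% c("DT", "PDT", "WDT")] <- "DET"
  cls[tag == "MD"] <- "MODAL"
  cls[tag == "UH"] <- "INTJ"
  cls[tag == "CD"] <- "NUM"
  cls[tag == "CC"] <- "CCONJ"
  is_in <- tag %in% c("IN", "TO")
  cls[is_in] <- ifelse(tokens$token[is_in] %in% .sconj_words, "SCONJ", "ADP")
  cls
}
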