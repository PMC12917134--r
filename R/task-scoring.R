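# Automated scoring of the three standardized language tasks (semantic
# fluency, phonemic fluency, confrontation naming) plus transcription and
# agreement metrics.

#' Build an answer key for the language tasks
#'
#' @param animals character vector of valid animal lemmas (may contain
#'   multiword entries such as "polar bear").
#' @param phonemic_letter target initial letter for the letter-fluency task.
#' @param phonemic_exclusions words never credited (number words and proper
#'   nouns by default rule; see [score_phonemic_fluency()]).
#' @param naming_key named list: item -> character vector of acceptable
#'   labels.
#' @return a `cogspeech_answer_key`.
#' @export
answer_key <- function(animals, phonemic_letter = "f",
                       phonemic_exclusions = character(),
                       naming_key = list()) {
  if (length(animals) == 0L) {
    cs_stop("animal key must be non-empty", "cogspeech_validation_error")
  }
  structure(list(animals = tolower(animals),
                 phonemic_letter = tolower(phonemic_letter),
                 phonemic_exclusions = tolower(phonemic_exclusions),
                 naming_key = lapply(naming_key, tolower)),
            class = "cogspeech_answer_key")
}

.norm_response <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("^(a|an|the)\\s+", "", x)
  gsub("\\s+", " ", x)
}

#' Score a semantic (animal) fluency transcript
#'
#' Counts distinct key entries found in the token stream. Matching is
#' case-insensitive on lemmas; multiword key entries are matched greedily
#' (longest first) against consecutive tokens, and repetitions of an entry
#' count once.
#'
#' @param tokens a `cogspeech_tokens`, or a character vector of words.
#' @param key a `cogspeech_answer_key`.
#' @return integer count.
#' @export
score_semantic_fluency <- function(tokens, key) {
  words <- if (inherits(tokens, "cogspeech_tokens")) tokens$lemma
           else tolower(as.character(tokens))
  if (length(words) == 0L) return(0L)
  surface <- if (inherits(tokens, "cogspeech_tokens")) tokens$token else words
  entries <- key$animals[order(-lengths(strsplit(key$animals, " ")))]
  matched <- character(0)
  used <- rep(FALSE, length(words))
  for (e in entries) {
    parts <- strsplit(e, " ")[[1]]
    k <- length(parts)
    if (k > length(words)) next
    for (i in seq_len(length(words) - k + 1L)) {
      if (any(used[i:(i + k - 1L)])) next
      span_l <- words[i:(i + k - 1L)]
      span_s <- surface[i:(i + k - 1L)]
      if (identical(span_l, parts) || identical(span_s, parts)) {
        if (!(e %in% matched)) matched <- c(matched, e)
        used[i:(i + k - 1L)] <- TRUE
      }
    }
  }
  length(matched)
}

#' Score a phonemic (letter) fluency transcript
#'
#' Counts distinct words starting with the target letter, after removing
#' excluded entries. The documented exclusion rule removes number words and
#' any word in the key's exclusion list (proper nouns); morphological
#' variants sharing a lemma with an already-counted word count once.
#'
#' @param tokens a `cogspeech_tokens` or character vector.
#' @param key a `cogspeech_answer_key`.
#' @return integer count.
#' @export
score_phonemic_fluency <- function(tokens, key) {
  number_words <- c("one", "two", "three", "four", "five", "six", "seven",
                    "eight", "nine", "ten", "eleven", "twelve", "fifteen",
                    "twenty", "forty", "fifty", "hundred", "thousand",
                    "four", "fourteen", "forty")
  if (inherits(tokens, "cogspeech_tokens")) {
    lemmas <- tokens$lemma
  } else {
    lemmas <- tolower(as.character(tokens))
  }
  if (length(lemmas) == 0L) return(0L)
  ok <- startsWith(lemmas, key$phonemic_letter) &
    !(lemmas %in% number_words) &
    !(lemmas %in% key$phonemic_exclusions)
  length(unique(lemmas[ok]))
}

#' Score a confrontation-naming task
#'
#' @param responses character vector, one response per item (in key order).
#' @param key a `cogspeech_answer_key` with a non-empty `naming_key`.
#' @return integer count of items whose normalized response (lowercased,
#'   leading article stripped) is in that item's acceptable set.
#' @export
score_boston_naming <- function(responses, key) {
  if (length(responses) != length(key$naming_key)) {
    cs_stop(sprintf("expected %d responses, got %d",
                    length(key$naming_key), length(responses)),
            "cogspeech_validation_error")
  }
  sum(vapply(seq_along(responses), function(i) {
    .norm_response(responses[i]) %in% key$naming_key[[i]]
  }, TRUE))
}

#' Word error rate between a reference and hypothesis token sequence
#'
#' Minimum edit distance (substitutions + insertions + deletions) divided
#' by the reference length.
#'
#' @param reference,hypothesis character vectors of tokens (or strings,
#'   split on whitespace).
#' @return non-negative rate (can exceed 1 for long hypotheses).
#' @export
word_error_rate <- function(reference, hypothesis) {
  split1 <- function(x) {
    if (length(x) == 1L && grepl("\\s", x)) strsplit(trimws(x), "\\s+")[[1]]
    else as.character(x)
  }
  ref <- split1(reference); hyp <- split1(hypothesis)
  if (length(ref) == 0L) {
    cs_stop("reference must be non-empty", "cogspeech_validation_error")
  }
  n <- length(ref); m <- length(hyp)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ref[i] == hyp[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[n + 1L, m + 1L] / n
}

#' Agreement between automated and manual scores
#'
#' Mean absolute error and two-way random-effects intra-class correlation
#' for absolute agreement of single ratings, ICC(2,1):
#' \deqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n)}
#' with subjects-by-raters mean squares.
#'
#' @param auto,manual paired numeric vectors (n >= 3).
#' @return list with `mae`, `icc`, `n`.
#' @export
agreement_stats <- function(auto, manual) {
  if (length(auto) != length(manual)) {
    cs_stop("auto and manual scores must be paired", "cogspeech_validation_error")
  }
  n <- length(auto)
  if (n < 3L) cs_stop("need at least 3 pairs", "cogspeech_validation_error")
  Y <- cbind(auto, manual)
  k <- 2L
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(mae = mean(abs(auto - manual)), icc = icc, n = n)
}
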