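# Voice activity detection, pause/rate features and SNR.
#
# The detector is a deterministic frame-energy VAD: 30 ms frames at a 10 ms
# hop, a frame is voiced when its energy exceeds
# max(noise floor + threshold, absolute floor), where the noise floor is the
# 5th percentile of frame energies (dB). Isolated unvoiced gaps of up to
# `hangover` frames inside a voiced run are bridged, and voiced segments
# separated by less than `min_gap_s` are merged.

.frame_db <- function(samples, sr, frame_ms, hop_ms) {
  frame <- max(1L, round(sr * frame_ms / 1000))
  hop <- max(1L, round(sr * hop_ms / 1000))
  n <- length(samples)
  if (n < frame) return(list(db = numeric(0), frame = frame, hop = hop))
  starts <- seq(1L, n - frame + 1L, by = hop)
  rms <- vapply(starts, function(s) {
    sqrt(mean(samples[s:(s + frame - 1L)]^2))
  }, 0)
  list(db = 20 * log10(pmax(rms, 1e-10)), frame = frame, hop = hop,
       starts = starts)
}

#' Detect voiced segments with a frame-energy detector
#'
#' @param w a `cogspeech_waveform`.
#' @param frame_ms,hop_ms analysis frame length and hop in milliseconds.
#' @param energy_threshold_db margin above the estimated noise floor for a
#'   frame to count as voiced.
#' @param abs_floor_db absolute level (dBFS) below which a frame is never
#'   voiced; makes the detector well-defined on homogeneous audio (all
#'   silence or all tone), where the adaptive floor is uninformative.
#' @param hangover unvoiced gaps of up to this many frames inside speech are
#'   bridged.
#' @param min_gap_s voiced segments closer than this are merged.
#' @return a `cogspeech_segments` object: data.frame with columns `start`,
#'   `end` (seconds, half-open intervals), attribute `total_duration`.
#' @export
detect_voice_segments <- function(w, frame_ms = 30, hop_ms = 10,
                                  energy_threshold_db = 10,
                                  abs_floor_db = -50,
                                  hangover = 3L, min_gap_s = 0.1) {
  stopifnot(inherits(w, "cogspeech_waveform"))
  if (length(w$samples) == 0L) {
    cs_stop("waveform is empty", "cogspeech_validation_error")
  }
  if (w$sample_rate * frame_ms / 1000 < 2) {
    cs_stop("sample rate too low for the requested framing",
            "cogspeech_validation_error")
  }
  fr <- .frame_db(w$samples, w$sample_rate, frame_ms, hop_ms)
  total <- wav_duration(w)
  empty <- structure(
    data.frame(start = numeric(0), end = numeric(0)),
    total_duration = total, class = c("cogspeech_segments", "data.frame"))
  if (length(fr$db) == 0L) return(empty)
  floor_db <- as.numeric(stats::quantile(fr$db, 0.05, names = FALSE))
  dyn_range <- as.numeric(stats::quantile(fr$db, 0.95, names = FALSE)) - floor_db
  # homogeneous audio (all silence or all tone) has no usable noise floor;
  # fall back to the absolute threshold alone
  thr <- if (dyn_range < energy_threshold_db) abs_floor_db
         else max(floor_db + energy_threshold_db, abs_floor_db)
  voiced <- fr$db > thr
  if (!any(voiced)) return(empty)
  # bridge short unvoiced gaps (hangover smoothing)
  r <- rle(voiced)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    fill <- inner[!r$values[inner] & r$lengths[inner] <= hangover]
    r$values[fill] <- TRUE
  }
  voiced <- inverse.rle(r)
  r <- rle(voiced)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  hop_s <- fr$hop / w$sample_rate
  frame_s <- fr$frame / w$sample_rate
  seg <- data.frame(
    start = (starts_i[keep] - 1L) * hop_s,
    end = pmin((ends_i[keep] - 1L) * hop_s + frame_s, total)
  )
  # merge segments separated by < min_gap_s
  if (nrow(seg) > 1L) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg$start[i] - merged$end[nrow(merged)] < min_gap_s) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  structure(seg, total_duration = total,
            class = c("cogspeech_segments", "data.frame"))
}

#' Construct a segment list directly (e.g. from a ground-truth plan)
#' @param start,end numeric vectors of interval bounds in seconds.
#' @param total_duration total audio duration in seconds.
#' @return a `cogspeech_segments`.
#' @export
voice_segments <- function(start, end, total_duration) {
  stopifnot(length(start) == length(end))
  if (length(start) > 0) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (any(end <= start) || any(start < 0) || any(end > total_duration + 1e-9)) {
      cs_stop("segments must be within [0, total_duration] with end > start",
              "cogspeech_validation_error")
    }
    if (length(start) > 1 && any(start[-1] < end[-length(end)])) {
      cs_stop("segments must be non-overlapping", "cogspeech_validation_error")
    }
  }
  structure(data.frame(start = start, end = end),
            total_duration = total_duration,
            class = c("cogspeech_segments", "data.frame"))
}

#' Pause features from voiced segments
#'
#' Leading and trailing pauses are excluded: pauses are the gaps between
#' consecutive voiced segments inside the span from the first voiced start
#' to the last voiced end. The pause fraction uses that trimmed span as
#' denominator; the standard deviation is the population form (a single
#' pause has sd 0). With no internal pause, mean and sd are 0.
#'
#' @param seg a `cogspeech_segments`.
#' @return a `cogspeech_features` with `fraction_of_pause`, `mean_duration`,
#'   `std_duration`; all three flagged invalid when no voiced segment exists.
#' @export
pause_features <- function(seg) {
  stopifnot(inherits(seg, "cogspeech_segments"))
  if (nrow(seg) == 0L) {
    return(feature_vector(
      c(fraction_of_pause = NA_real_, mean_duration = NA_real_,
        std_duration = NA_real_),
      valid = c(fraction_of_pause = FALSE, mean_duration = FALSE,
                std_duration = FALSE)))
  }
  span <- seg$end[nrow(seg)] - seg$start[1]
  pauses <- if (nrow(seg) > 1L) seg$start[-1] - seg$end[-nrow(seg)] else numeric(0)
  feature_vector(c(
    fraction_of_pause = if (span > 0) sum(pauses) / span else 0,
    mean_duration = if (length(pauses)) mean(pauses) else 0,
    std_duration = if (length(pauses)) pop_sd(pauses) else 0
  ))
}

# Per-word phoneme counts: a small bundled grapheme-to-phoneme table for
# common words; out-of-table words use a documented letter-based fallback
# (collapsed consonant letters + vowel groups, silent final e removed).
.g2p_table <- c(
  cat = 3, dog = 3, the = 2, a = 1, an = 2, boy = 2, girl = 3, cookie = 4,
  jar = 2, stool = 4, water = 4, mother = 4, kitchen = 5, window = 5,
  sink = 4, floor = 3, tree = 3, house = 3, fish = 3, bird = 3, uh = 1,
  um = 2, and = 3, is = 2, are = 2, was = 3, running = 5, falling = 5,
  washing = 5, picnic = 6, basket = 6, blanket = 7, sandwich = 7, lake = 3,
  boat = 3, kite = 3, one = 3, two = 2, three = 3
)

.fallback_phonemes <- function(word) {
  w <- tolower(gsub("[^a-z]", "", word))
  if (!nzchar(w)) return(0L)
  w2 <- gsub("([a-z])\\1+", "\\1", w)              # collapse doubled letters
  vg <- gregexpr("[aeiouy]+", w2)[[1]]
  n_v <- if (identical(vg[1], -1L)) 0L else length(vg)
  n_c <- nchar(gsub("[aeiouy]", "", w2))
  if (grepl("e$", w2) && n_v > 1L) n_v <- n_v - 1L   # silent final e
  max(1L, n_v + n_c)
}

#' Count spoken phonemes in a transcript
#'
#' @param text transcript text (or a `cogspeech_tokens` object).
#' @param g2p named numeric vector word -> phoneme count; defaults to the
#'   bundled table.
#' @return integer phoneme count, with attribute `fallback_fraction` (share
#'   of tokens scored by the letter-based fallback).
#' @export
count_phonemes <- function(text, g2p = .g2p_table) {
  tokens <- if (inherits(text, "cogspeech_tokens")) text else tokenize_and_tag(text)
  toks <- tokens$token[nzchar(tokens$token)]
  known <- toks %in% names(g2p)
  n <- sum(g2p[toks[known]]) +
    sum(vapply(toks[!known], .fallback_phonemes, 0L))
  structure(as.integer(n),
            fallback_fraction = if (length(toks)) mean(!known) else 0)
}

#' Speech and articulation rate
#'
#' @param phonemes phoneme count (numerator for both rates).
#' @param audio_length_s total audio length in seconds.
#' @param voiced_length_s total duration of voiced segments in seconds.
#' @return a `cogspeech_features` with `speech_rate` (phonemes per second of
#'   audio) and `articulation_rate` (phonemes per second of voiced speech,
#'   invalid when `voiced_length_s` is 0).
#' @export
rate_features <- function(phonemes, audio_length_s, voiced_length_s) {
  if (audio_length_s <= 0) {
    cs_stop("audio_length_s must be positive", "cogspeech_validation_error")
  }
  art <- if (voiced_length_s > 0) phonemes / voiced_length_s else NA_real_
  feature_vector(c(speech_rate = phonemes / audio_length_s,
                   articulation_rate = art))
}

#' Signal-to-noise ratio from a voiced/pause segmentation
#'
#' @param w a `cogspeech_waveform`.
#' @param seg a `cogspeech_segments` (voiced intervals = signal; all other
#'   samples = noise).
#' @return SNR in dB (`10 log10(mean voiced power / mean pause power)`), or
#'   `NA` with attribute `valid = FALSE` when either class has no samples.
#' @export
estimate_snr <- function(w, seg) {
  stopifnot(inherits(w, "cogspeech_waveform"), inherits(seg, "cogspeech_segments"))
  n <- length(w$samples)
  idx <- rep(FALSE, n)
  for (i in seq_len(nrow(seg))) {
    a <- max(1L, floor(seg$start[i] * w$sample_rate) + 1L)
    b <- min(n, ceiling(seg$end[i] * w$sample_rate))
    if (b >= a) idx[a:b] <- TRUE
  }
  if (!any(idx) || all(idx)) {
    return(structure(NA_real_, valid = FALSE))
  }
  structure(10 * log10(mean(w$samples[idx]^2) / mean(w$samples[!idx]^2)),
            valid = TRUE)
}

#' Names of the acoustic feature vector (6 hand-crafted + 21 descriptors)
#' @return character vector of length 27.
#' @export
acoustic_feature_names <- function() {
  c("audio_length", "fraction_of_pause", "mean_duration", "std_duration",
    "speech_rate", "articulation_rate", egemaps_descriptor_names())
}

#' Extract the full acoustic feature vector
#'
#' @param w a `cogspeech_waveform`.
#' @param transcript transcript text for the same recording (used for the
#'   phoneme-based rate features).
#' @param vad list of VAD parameter overrides passed to
#'   [detect_voice_segments()].
#' @return a `cogspeech_features` with the 27 features of
#'   [acoustic_feature_names()], in that order.
#' @export
extract_all_acoustic <- function(w, transcript, vad = list()) {
  seg <- do.call(detect_voice_segments, c(list(w), vad))
  pf <- pause_features(seg)
  ph <- count_phonemes(transcript)
  voiced_len <- if (nrow(seg)) sum(seg$end - seg$start) else 0
  rf <- rate_features(as.integer(ph), wav_duration(w), voiced_len)
  eg <- egemaps_subset(w, seg = seg)
  merged <- merge_features(
    feature_vector(c(audio_length = wav_duration(w))), pf, rf, eg)
  ord <- acoustic_feature_names()
  feature_vector(merged$values[ord], merged$valid[ord],
                 list(fallback_fraction = attr(ph, "fallback_fraction")))
}

#' Rank and prune acoustic descriptors on the development set
#'
#' Ranks candidate descriptors by their maximum absolute Pearson correlation
#' to any of the composite scores, keeps the `top_k` best, then greedily
#' drops the lower-ranked member of any pair whose absolute inter-feature
#' correlation exceeds `corr_cap`. Ties in ranking are broken by the input
#' column order.
#'
#' @param candidates data.frame/matrix of candidate descriptor columns over
#'   development-set participants.
#' @param targets data.frame/matrix of composite scores on the same rows.
#' @param top_k number of descriptors kept before the redundancy pass.
#' @param corr_cap maximum allowed absolute pairwise correlation.
#' @return a list with `kept` (character), `ranking` (data.frame of name and
#'   effect size), `dropped_redundant`, `dropped_constant`, and parameters.
#' @export
select_descriptors <- function(candidates, targets, top_k = 30, corr_cap = 0.85) {
  X <- as.matrix(as.data.frame(candidates))
  Y <- as.matrix(as.data.frame(targets))
  if (nrow(X) != nrow(Y)) {
    cs_stop("candidates and targets must cover the same participants",
            "cogspeech_validation_error")
  }
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  constant <- colnames(X)[!is.finite(sds) | sds == 0]
  if (length(constant)) {
    cs_warn(sprintf("excluding constant candidate column(s): %s",
                    paste(constant, collapse = ", ")))
    X <- X[, setdiff(colnames(X), constant), drop = FALSE]
  }
  eff <- apply(X, 2, function(x) max(abs(stats::cor(x, Y, use = "complete.obs"))))
  ord <- order(-eff)   # stable: ties keep input order
  ranking <- data.frame(name = colnames(X)[ord], effect_size = eff[ord],
                        row.names = NULL)
  # greedy walk down the ranking: keep a descriptor when it is below the
  # correlation cap against everything already kept, until top_k are kept
  final <- character(0)
  dropped <- character(0)
  for (nm in ranking$name) {
    if (length(final) >= top_k) break
    if (length(final) == 0L) { final <- nm; next }
    r <- abs(stats::cor(X[, nm], X[, final, drop = FALSE], use = "complete.obs"))
    if (all(r <= corr_cap)) final <- c(final, nm) else dropped <- c(dropped, nm)
  }
  list(kept = final, ranking = ranking, dropped_redundant = dropped,
       dropped_constant = constant,
       params = list(top_k = top_k, corr_cap = corr_cap))
}
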