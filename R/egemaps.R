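# Documented approximations of the contracted 21-descriptor subset of the
# extended Geneva minimalistic acoustic parameter set. The contract is the
# named vector of descriptors, not bit-compatibility with any external
# toolkit; each descriptor is computed from short-time analysis frames
# (25 ms window, 10 ms hop) as documented below:
#   * loudness: Stevens-law proxy (frame RMS)^0.3;
#   * spectral flux: L2 difference of successive L1-normalized magnitude
#     spectra;
#   * MFCCs: 26 triangular mel filters up to Nyquist, log energies, DCT-II;
#   * F0: autocorrelation peak in 55-400 Hz on voiced frames, expressed in
#     semitones above 27.5 Hz;
#   * F1: lowest root of an order-10 LPC polynomial (autocorrelation
#     method) between 150 and 1200 Hz; bandwidth from the root radius;
#   * alpha ratio: dB ratio of energy in 50-1000 Hz vs 1-5 kHz;
#   * stddevNorm descriptors are coefficients of variation (sd / |mean|).
# Voiced/unvoiced frame labels come from the package VAD segmentation.

egemaps_descriptor_names <- function() {
  c("F0semitoneFrom27.5Hz_sma3nz_meanRisingSlope",
    "loudness_sma3_percentile20.0", "loudness_sma3_percentile50.0",
    "loudness_sma3_percentile80.0", "loudness_sma3_meanRisingSlope",
    "spectralFlux_sma3_amean", "spectralFlux_sma3_stddevNorm",
    "mfcc1_sma3_stddevNorm", "mfcc3_sma3_amean", "mfcc3_sma3_stddevNorm",
    "F1bandwidth_sma3nz_stddevNorm", "F1amplitudeLogRelF0_sma3nz_amean",
    "alphaRatioV_sma3nz_stddevNorm", "spectralFluxV_sma3nz_stddevNorm",
    "mfcc1V_sma3nz_stddevNorm", "alphaRatioUV_sma3nz_amean",
    "spectralFluxUV_sma3nz_amean", "loudnessPeaksPerSec",
    "VoicedSegmentsPerSec", "MeanUnvoicedSegmentLength",
    "equivalentSoundLevel_dBp")
}

.mel <- function(f) 2595 * log10(1 + f / 700)
.mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

.mel_filterbank <- function(nfft, sr, n_filters = 26L) {
  pts <- .mel_inv(seq(.mel(0), .mel(sr / 2), length.out = n_filters + 2L))
  bins <- floor((nfft + 1) * pts / sr) + 1
  fb <- matrix(0, n_filters, nfft %/% 2L + 1L)
  for (m in seq_len(n_filters)) {
    a <- bins[m]; b <- bins[m + 1]; c <- bins[m + 2]
    if (b > a) fb[m, a:b] <- (seq(a, b) - a) / (b - a)
    if (c > b) fb[m, b:c] <- (c - seq(b, c)) / (c - b)
  }
  fb
}

.dct2 <- function(x, k_max) {
  n <- length(x)
  vapply(seq_len(k_max), function(k) {
    sum(x * cos(pi * k * (seq_len(n) - 0.5) / n))
  }, 0)
}

.autocorr_f0 <- function(frame, sr, f0_min = 55, f0_max = 400) {
  frame <- frame - mean(frame)
  if (sum(frame^2) < 1e-12) return(NA_real_)
  ac <- stats::acf(frame, lag.max = floor(sr / f0_min), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lo <- max(2L, floor(sr / f0_max))
  hi <- length(ac) - 1L
  if (hi <= lo) return(NA_real_)
  lags <- lo:hi
  peak <- lags[which.max(ac[lags + 1L])]
  if (ac[peak + 1L] / ac[1L] < 0.3) return(NA_real_)
  sr / peak
}

.lpc_f1 <- function(frame, sr, order = 10L) {
  frame <- frame - mean(frame)
  if (sum(frame^2) < 1e-12 || length(frame) <= order + 1L) return(NULL)
  # pre-emphasis
  frame <- c(frame[1], frame[-1] - 0.97 * frame[-length(frame)])
  a <- tryCatch(stats::ar.yw(frame, aic = FALSE, order.max = order,
                             demean = FALSE)$ar,
                error = function(e) NULL)
  if (is.null(a) || length(a) == 0L) return(NULL)
  # poles of 1/A(z): reciprocals of the zeros of the AR characteristic
  # polynomial in z
  r <- 1 / polyroot(c(1, -a))
  ang <- Arg(r); mod <- Mod(r)
  keep <- ang > 0 & mod < 1
  if (!any(keep)) return(NULL)
  f <- ang[keep] * sr / (2 * pi)
  bw <- -(sr / pi) * log(mod[keep])
  sel <- which(f >= 150 & f <= 1200)
  if (!length(sel)) return(NULL)
  i <- sel[which.min(f[sel])]
  list(f1 = f[i], bw = bw[i])
}

.cov_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(c(amean = NA_real_, stddevNorm = NA_real_))
  m <- mean(x)
  c(amean = m, stddevNorm = if (abs(m) > 1e-12) stats::sd(x) / abs(m) else NA_real_)
}

.mean_rising_slope <- function(x, hop_s) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) return(NA_real_)
  d <- diff(x)
  r <- rle(d > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  slopes <- c()
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= 1L) {
      rise <- x[ends[i] + 1L] - x[starts[i]]
      slopes <- c(slopes, rise / (r$lengths[i] * hop_s))
    }
  }
  if (length(slopes)) mean(slopes) else 0
}

#' Extract the 21-descriptor acoustic parameter subset
#'
#' See the header of this file's source for the documented approximation of
#' each descriptor. Requires at least one second of audio; shorter input
#' yields an all-invalid vector.
#'
#' @param w a `cogspeech_waveform`.
#' @param seg optional precomputed `cogspeech_segments` (detected with
#'   defaults otherwise).
#' @param frame_ms,hop_ms analysis framing in milliseconds.
#' @return a `cogspeech_features` with the descriptors of
#'   `egemaps_descriptor_names()`.
#' @export
egemaps_subset <- function(w, seg = NULL, frame_ms = 25, hop_ms = 10) {
  stopifnot(inherits(w, "cogspeech_waveform"))
  nm <- egemaps_descriptor_names()
  if (wav_duration(w) < 1) {
    return(feature_vector(stats::setNames(rep(NA_real_, length(nm)), nm),
                          valid = stats::setNames(rep(FALSE, length(nm)), nm)))
  }
  if (is.null(seg)) seg <- detect_voice_segments(w)
  sr <- w$sample_rate
  frame <- round(sr * frame_ms / 1000)
  hop <- round(sr * hop_ms / 1000)
  starts <- seq(1L, length(w$samples) - frame + 1L, by = hop)
  nfr <- length(starts)
  fm <- matrix(0, frame, nfr)
  for (i in seq_len(nfr)) fm[, i] <- w$samples[starts[i]:(starts[i] + frame - 1L)]
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(frame) / (frame + 1))  # Hamming
  nfft <- 2^ceiling(log2(frame))
  fmw <- rbind(fm * win, matrix(0, nfft - frame, nfr))
  spec <- Mod(stats::mvfft(fmw))[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  freqs <- (seq_len(nfft %/% 2L + 1L) - 1L) * sr / nfft
  hop_s <- hop / sr

  # frame times and voiced labels from the segmentation
  t_mid <- (starts - 1L + frame / 2) / sr
  voiced <- rep(FALSE, nfr)
  for (i in seq_len(nrow(seg))) {
    voiced <- voiced | (t_mid >= seg$start[i] & t_mid < seg$end[i])
  }

  loud <- (sqrt(colMeans(fm^2)))^0.3
  sn <- sweep(spec, 2, pmax(colSums(spec), 1e-12), `/`)
  flux <- c(NA, sqrt(colSums((sn[, -1, drop = FALSE] - sn[, -nfr, drop = FALSE])^2)))

  fb <- .mel_filterbank(nfft, sr)
  logmel <- log(pmax(fb %*% spec^2, 1e-12))
  mfcc <- apply(logmel, 2, .dct2, k_max = 4L)   # rows: coefficients 1..4

  lo_band <- freqs >= 50 & freqs < 1000
  hi_band <- freqs >= 1000 & freqs < 5000
  pow <- spec^2
  alpha <- 10 * log10(pmax(colSums(pow[hi_band, , drop = FALSE]), 1e-15) /
                      pmax(colSums(pow[lo_band, , drop = FALSE]), 1e-15))

  vi <- which(voiced); ui <- which(!voiced)
  f0 <- rep(NA_real_, nfr)
  f1f <- rep(NA_real_, nfr); f1bw <- rep(NA_real_, nfr); f1rel <- rep(NA_real_, nfr)
  for (i in vi) {
    fr_i <- fm[, i]
    f0[i] <- .autocorr_f0(fr_i, sr)
    lp <- .lpc_f1(fr_i, sr)
    if (!is.null(lp)) { f1f[i] <- lp$f1; f1bw[i] <- lp$bw }
    if (is.finite(f0[i]) && !is.null(lp)) {
      b0 <- which.min(abs(freqs - f0[i]))
      b1 <- which.min(abs(freqs - lp$f1))
      f1rel[i] <- 20 * log10(pmax(spec[b1, i], 1e-12) / pmax(spec[b0, i], 1e-12))
    }
  }
  f0_st <- 12 * log2(f0 / 27.5)

  # loudness peaks: strict local maxima above the 25th percentile of loudness
  peaks <- 0L
  if (nfr >= 3L) {
    thr <- stats::quantile(loud, 0.25, names = FALSE)
    core <- 2:(nfr - 1L)
    peaks <- sum(loud[core] > loud[core - 1L] & loud[core] >= loud[core + 1L] &
                 loud[core] > thr)
  }
  dur <- wav_duration(w)
  gaps <- if (nrow(seg) > 1L) seg$start[-1] - seg$end[-nrow(seg)] else numeric(0)

  mf1 <- .cov_stats(mfcc[1, ]); mf3 <- .cov_stats(mfcc[3, ])
  mf1v <- .cov_stats(mfcc[1, vi])
  flux_all <- .cov_stats(flux)
  flux_v <- .cov_stats(flux[vi]); flux_uv <- .cov_stats(flux[ui])
  alpha_v <- .cov_stats(alpha[vi]); alpha_uv <- .cov_stats(alpha[ui])
  f1bw_s <- .cov_stats(f1bw)

  vals <- c(
    "F0semitoneFrom27.5Hz_sma3nz_meanRisingSlope" =
      .mean_rising_slope(f0_st[vi], hop_s),
    "loudness_sma3_percentile20.0" = stats::quantile(loud, 0.2, names = FALSE),
    "loudness_sma3_percentile50.0" = stats::quantile(loud, 0.5, names = FALSE),
    "loudness_sma3_percentile80.0" = stats::quantile(loud, 0.8, names = FALSE),
    "loudness_sma3_meanRisingSlope" = .mean_rising_slope(loud, hop_s),
    "spectralFlux_sma3_amean" = unname(flux_all["amean"]),
    "spectralFlux_sma3_stddevNorm" = unname(flux_all["stddevNorm"]),
    "mfcc1_sma3_stddevNorm" = unname(mf1["stddevNorm"]),
    "mfcc3_sma3_amean" = unname(mf3["amean"]),
    "mfcc3_sma3_stddevNorm" = unname(mf3["stddevNorm"]),
    "F1bandwidth_sma3nz_stddevNorm" = unname(f1bw_s["stddevNorm"]),
    "F1amplitudeLogRelF0_sma3nz_amean" = mean(f1rel[is.finite(f1rel)]),
    "alphaRatioV_sma3nz_stddevNorm" = unname(alpha_v["stddevNorm"]),
    "spectralFluxV_sma3nz_stddevNorm" = unname(flux_v["stddevNorm"]),
    "mfcc1V_sma3nz_stddevNorm" = unname(mf1v["stddevNorm"]),
    "alphaRatioUV_sma3nz_amean" = unname(alpha_uv["amean"]),
    "spectralFluxUV_sma3nz_amean" = unname(flux_uv["amean"]),
    "loudnessPeaksPerSec" = peaks / dur,
    "VoicedSegmentsPerSec" = nrow(seg) / dur,
    "MeanUnvoicedSegmentLength" = if (length(gaps)) mean(gaps) else 0,
    "equivalentSoundLevel_dBp" = 10 * log10(pmax(mean(w$samples^2), 1e-15))
  )
  feature_vector(vals)
}
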