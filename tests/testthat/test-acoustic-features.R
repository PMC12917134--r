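test_that("VAD recovers planted voiced bursts within two frames", {
  iv <- data.frame(start = c(0.3, 1.0, 1.8), end = c(0.7, 1.5, 2.4))
  w <- synthesize_waveform(list(intervals = iv, duration_s = 3, f0 = 160,
                                seed = 4))
  seg <- detect_voice_segments(w)
  expect_equal(nrow(seg), 3L)
  tol <- 2 * 0.03   # two frame lengths
  expect_true(all(abs(seg$start - iv$start) < tol))
  expect_true(all(abs(seg$end - iv$end) < tol))
})

test_that("VAD handles homogeneous audio (silence and continuous tone)", {
  silence <- synthesize_waveform(
    list(intervals = data.frame(start = numeric(0), end = numeric(0)),
         duration_s = 2, f0 = 150, seed = 1))
  expect_equal(nrow(detect_voice_segments(silence)), 0L)

  tone <- synthesize_waveform(
    list(intervals = data.frame(start = 0, end = 2), duration_s = 2,
         f0 = 150, seed = 1))
  seg <- detect_voice_segments(tone)
  expect_equal(nrow(seg), 1L)
  expect_gt(seg$end[1] - seg$start[1], 1.9)
})

test_that("VAD segmentation overlaps truth plans with Jaccard >= 0.9", {
  set.seed(77)
  for (s in 1:5) {
    plan <- plan_waveform(rnorm(1), duration_s = 8, seed = s)
    w <- synthesize_waveform(plan)
    seg <- detect_voice_segments(w)
    grid <- seq(0, 8, by = 0.005)
    in_iv <- function(iv) {
      out <- rep(FALSE, length(grid))
      for (i in seq_len(nrow(iv))) {
        out <- out | (grid >= iv$start[i] & grid < iv$end[i])
      }
      out
    }
    a <- in_iv(plan$intervals); b <- in_iv(seg)
    expect_gt(sum(a & b) / sum(a | b), 0.9)
  }
})

test_that("pause features match the hand-computed worked examples", {
  seg <- voice_segments(c(1, 5), c(3, 8), total_duration = 10)
  pf <- pause_features(seg)
  expect_equal(pf$values[["fraction_of_pause"]], 2 / 7)
  expect_equal(pf$values[["mean_duration"]], 2)
  expect_equal(pf$values[["std_duration"]], 0)

  seg2 <- voice_segments(c(0, 2, 6), c(1, 3, 7), total_duration = 8)
  pf2 <- pause_features(seg2)  # pauses 1 s and 3 s
  expect_equal(pf2$values[["mean_duration"]], 2)
  expect_equal(pf2$values[["std_duration"]], 1)   # population sd

  single <- voice_segments(1, 4, total_duration = 5)
  expect_equal(pause_features(single)$values[["fraction_of_pause"]], 0)

  none <- voice_segments(numeric(0), numeric(0), total_duration = 5)
  expect_false(any(pause_features(none)$valid))
})

test_that("phoneme counts are additive and fall back for unknown words", {
  n1 <- count_phonemes("cat")
  expect_equal(as.integer(n1), 3L)
  expect_equal(as.integer(count_phonemes("cat cat")), 6L)
  nf <- count_phonemes("zorb")
  expect_gt(attr(nf, "fallback_fraction"), 0)
  expect_gt(as.integer(nf), 0L)
})

test_that("speech and articulation rates follow their definitions", {
  rf <- rate_features(120, 60, 40)
  expect_equal(rf$values[["speech_rate"]], 2)
  expect_equal(rf$values[["articulation_rate"]], 3)
  eq <- rate_features(120, 60, 60)
  expect_equal(eq$values[["speech_rate"]], eq$values[["articulation_rate"]])
  inv <- rate_features(120, 60, 0)
  expect_false(inv$valid[["articulation_rate"]])
  # articulation >= speech whenever a pause exists
  expect_gte(rf$values[["articulation_rate"]], rf$values[["speech_rate"]])
})

test_that("SNR matches the closed form and is scale invariant", {
  sr <- 16000
  voiced <- rep(c(rep(10, sr), rep(1, sr)), 1)  # power ratio 100
  w <- waveform(voiced / 20, sr)
  seg <- voice_segments(0, 1, total_duration = 2)
  expect_equal(as.numeric(estimate_snr(w, seg)), 20, tolerance = 1e-10)
  w2 <- waveform(voiced / 40, sr)
  expect_equal(as.numeric(estimate_snr(w2, seg)), 20, tolerance = 1e-10)
  all_voiced <- voice_segments(0, 2, total_duration = 2)
  expect_true(is.na(estimate_snr(w, all_voiced)))
})

test_that("descriptor subset honours its contract on synthetic audio", {
  iv <- data.frame(start = c(0.1, 0.6, 1.1, 1.6), end = c(0.4, 0.9, 1.4, 1.9))
  w <- synthesize_waveform(list(intervals = iv, duration_s = 2, f0 = 150,
                                seed = 2))
  eg <- egemaps_subset(w)
  expect_identical(names(eg$values), cogspeech:::egemaps_descriptor_names())
  expect_equal(eg$values[["VoicedSegmentsPerSec"]], 2)

  w2 <- w; w2$samples <- w$samples * 2
  eg2 <- egemaps_subset(w2)
  expect_equal(eg2$values[["equivalentSoundLevel_dBp"]] -
               eg$values[["equivalentSoundLevel_dBp"]], 20 * log10(2),
               tolerance = 1e-6)

  short <- waveform(rnorm(4000, 0, 0.01), 16000)
  expect_false(any(egemaps_subset(short)$valid))
})

test_that("the acoustic orchestrator emits the fixed 27-feature vector", {
  plan <- plan_waveform(0.5, duration_s = 6, seed = 9)
  w <- synthesize_waveform(plan)
  fv <- extract_all_acoustic(w, "the boy is washing a dish. the water falls.")
  expect_identical(names(fv$values), acoustic_feature_names())
  expect_equal(length(fv$values), 27L)
  expect_equal(fv$values[["audio_length"]], wav_duration(w))
  fv2 <- extract_all_acoustic(w, "the boy is washing a dish. the water falls.")
  expect_identical(fv$values, fv2$values)
  expect_gte(fv$values[["articulation_rate"]], fv$values[["speech_rate"]])
})

test_that("descriptor selection ranks, prunes duplicates and is order-stable", {
  set.seed(5)
  n <- 120
  y <- rnorm(n)
  f1 <- y + rnorm(n, 0, 0.5)
  f2 <- f1                           # exact duplicate of f1
  f3 <- rnorm(n)
  cand <- data.frame(f1 = f1, f2 = f2, f3 = f3)
  sel <- select_descriptors(cand, data.frame(language = y), top_k = 2)
  expect_identical(sel$kept, c("f1", "f3"))

  # top_k >= |candidates| and low correlations: everything kept
  cand2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sel2 <- select_descriptors(cand2, data.frame(language = y), top_k = 10)
  expect_setequal(sel2$kept, c("a", "b", "c"))

  # a candidate equal to a target ranks first
  cand3 <- data.frame(x = rnorm(n), exact = y)
  sel3 <- select_descriptors(cand3, data.frame(language = y))
  expect_identical(sel3$ranking$name[1], "exact")

  # constant column excluded with a warning
  expect_warning(
    sel4 <- select_descriptors(data.frame(k = rep(1, n), x = rnorm(n)),
                               data.frame(language = y)),
    "constant")
  expect_false("k" %in% sel4$kept)

  # permuting candidate order leaves the kept set unchanged
  sel5 <- select_descriptors(cand[, c(3, 1, 2)], data.frame(language = y),
                             top_k = 2)
  expect_setequal(sel5$kept, sel$kept)
})
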