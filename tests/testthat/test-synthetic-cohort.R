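test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_participants = 12, audio_duration_s = 4, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$test_scores, b$test_scores)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$latent_domains, b$latent_domains)
  expect_identical(cohort_waveform(a, "P0001")$samples,
                   cohort_waveform(b, "P0001")$samples)
})

test_that("invalid configurations are rejected", {
  bad_corr <- matrix(c(1, 2, 2, 1), 2)
  expect_error(cohort_config(domain_corr = bad_corr),
               class = "cogspeech_validation_error")
  nonpd <- matrix(0.99, 4, 4); diag(nonpd) <- 1; nonpd[1, 2] <- nonpd[2, 1] <- -0.99
  expect_error(cohort_config(domain_corr = nonpd),
               class = "cogspeech_validation_error")
  expect_error(cohort_config(missing_rate = 1.5),
               class = "cogspeech_validation_error")
})

test_that("latent correlations converge to the configured matrix", {
  cfg <- null_demo_config(n_participants = 3000, seed = 2)
  co <- generate_cohort(cfg)
  expect_lt(max(abs(cor(co$latent_domains) - cfg$domain_corr)), 0.06)
})

test_that("test-latent correlation follows the closed-form attenuation", {
  # single loading 0.8, residual sd 0.6: corr = 0.8 / sqrt(0.64 + 0.36) = 0.8
  cfg <- null_demo_config(n_participants = 5000, seed = 8,
                          loading_matrix = default_loading_matrix(primary = 0.8),
                          noise_sd = 0.6, missing_rate = 0, outlier_rate = 0)
  co <- generate_cohort(cfg)
  expected <- 0.8 / sqrt(0.8^2 + 0.6^2)
  got <- cor(harmonize_test_scores(co$test_scores)[, "semantic_fluency"],
             co$latent_domains[, "language"])
  expect_equal(got, expected, tolerance = 0.025)
})

test_that("zero speech effect decouples transcripts from the latent", {
  cfg <- null_demo_config(n_participants = 2000, speech_effect_size = 0,
                          transcript_length = c(60L, 120L), seed = 3)
  co <- generate_cohort(cfg)
  mattr <- vapply(co$demographics$participant_id, function(id) {
    lexical_diversity_features(
      tokenize_and_tag(co$transcripts[[id]]$cookie_theft))$values[["moving_average_type_token_ratio"]]
  }, 0)
  expect_lt(abs(cor(mattr, co$latent_domains[, "language"])), 0.05)
})

test_that("transcript synthesis is monotone in the latent and length-exact", {
  set.seed(0)
  m_low <- m_high <- h_low <- h_high <- numeric(60)
  for (s in 1:60) {
    lo <- synthesize_transcript(-3, c(200L, 200L), seed = s)
    hi <- synthesize_transcript(3, c(200L, 200L), seed = s + 5000)
    tl <- tokenize_and_tag(lo$text); th <- tokenize_and_tag(hi$text)
    expect_equal(nrow(tl), 200L)
    expect_equal(nrow(th), 200L)
    m_low[s] <- lexical_diversity_features(tl)$values[["moving_average_type_token_ratio"]]
    m_high[s] <- lexical_diversity_features(th)$values[["moving_average_type_token_ratio"]]
    h_low[s] <- mean(tl$tag == "UH"); h_high[s] <- mean(th$tag == "UH")
  }
  expect_gt(mean(m_high), mean(m_low))
  expect_lt(mean(h_high), mean(h_low))
  # determinism
  expect_identical(synthesize_transcript(1, c(50L, 80L), seed = 7)$text,
                   synthesize_transcript(1, c(50L, 80L), seed = 7)$text)
})

test_that("waveform plans respect their invariants and plant recoverable pauses", {
  plan <- plan_waveform(0.4, duration_s = 10, seed = 6)
  iv <- plan$intervals
  expect_true(all(iv$end > iv$start))
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  w <- synthesize_waveform(plan)
  seg <- detect_voice_segments(w)
  detected <- pause_features(seg)$values[["fraction_of_pause"]]
  span <- iv$end[nrow(iv)] - iv$start[1]
  planted <- sum(iv$start[-1] - iv$end[-nrow(iv)]) / span
  expect_lt(abs(detected - planted), 0.05)

  overlapping <- list(intervals = data.frame(start = c(0, 1), end = c(2, 3)),
                      duration_s = 5)
  expect_error(synthesize_waveform(overlapping, f0 = 150, seed = 1),
               class = "cogspeech_validation_error")
})

test_that("norm lexicon is deterministic, complete and within ranges", {
  lex1 <- make_norm_lexicon(c("dog", "cat", "jar"), seed = 4)
  lex2 <- make_norm_lexicon(c("dog", "cat", "jar"), seed = 4)
  expect_identical(lex1, lex2)
  expect_true(all(c("frequency", "aoa", "familiarity", "ambiguity",
                    "concreteness") %in% names(lex1)))
  expect_false(anyNA(lex1))
  expect_true(all(lex1$frequency >= 1 & lex1$frequency <= 7))
  expect_true(all(lex1$aoa >= 2 & lex1$aoa <= 18))
  expect_true(all(lex1$concreteness >= 1 & lex1$concreteness <= 5))
  expect_error(make_norm_lexicon(character(0)),
               class = "cogspeech_validation_error")
})

test_that("corruption injection matches its masks and rates", {
  set.seed(10)
  X <- matrix(rnorm(10000), 1000, 10,
              dimnames = list(NULL, paste0("t", 1:10)))
  none <- inject_missing_and_outliers(X, 0, 0, seed = 1)
  expect_identical(none$scores, X)

  corr <- inject_missing_and_outliers(X, missing_rate = 0.05,
                                      outlier_rate = 0.01,
                                      outlier_magnitude_sd = 10, seed = 2)
  n_missing <- sum(corr$missing_mask)
  # binomial 99% interval around 0.05 * 10000
  expect_gt(n_missing, 500 - 2.58 * sqrt(10000 * 0.05 * 0.95))
  expect_lt(n_missing, 500 + 2.58 * sqrt(10000 * 0.05 * 0.95))
  expect_true(all(is.na(corr$scores[corr$missing_mask])))
  untouched <- !corr$missing_mask & !corr$outlier_mask
  expect_identical(corr$scores[untouched], X[untouched])
})

test_that("magnitude-10 outliers are all caught by the |z| > 4 rule", {
  set.seed(11)
  n <- 800
  demo <- data.frame(participant_id = sprintf("P%03d", 1:n),
                     age = rnorm(n, 65, 5),
                     gender = sample(c("female", "male"), n, TRUE),
                     country = sample(c("UK", "USA"), n, TRUE),
                     education = sample(c("high", "low"), n, TRUE))
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("t", 1:5)))
  corr <- inject_missing_and_outliers(X, 0, 0.01, outlier_magnitude_sd = 10,
                                      demographics = demo, seed = 3)
  fl <- flag_outliers_by_demographic_regression(corr$scores, demo)
  expect_true(all(fl$flags[corr$outlier_mask]))
})
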