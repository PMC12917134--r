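# Synthetic cohort generation. Emulates the statistical structure the
# analysis assumes: four correlated latent cognitive domains with linear
# demographic effects, test scores from a sparse factor-loading pattern plus
# Gaussian noise, template-sentence transcripts whose lexical diversity and
# hesitation rate are monotone in the latent language score, and
# additive-synthesis waveforms whose voiced/pause plan depends on the latent
# speed score. All ground truth is retained for recovery tests.

.domain_names <- c("language", "executive_function", "memory", "speed")

#' Names of the synthetic cognitive test battery
#' @return character vector of 14 test names. Columns ending in `_time` and
#'   `tol_extra_moves` are emitted on a "higher = worse" scale and must be
#'   sign-flipped before factor analysis (see [harmonize_test_scores()]).
#' @export
test_battery_names <- function() {
  c("semantic_fluency", "phonemic_fluency", "boston_naming",
    "ravlt_learning", "ravlt_recall",
    "tmt_b_time", "tol_extra_moves", "digit_span", "corsi_span",
    "reaction_time", "pegboard_time", "clicking_time", "dragging_time",
    "tmt_a_time")
}

#' Columns of the test battery that are reverse-scored (higher = worse)
#' @return character vector.
#' @export
negative_test_columns <- function() {
  c(grep("_time$", test_battery_names(), value = TRUE), "tol_extra_moves")
}

#' Default factor-loading pattern of the test battery
#'
#' Each test loads on a single domain except Trail Making Test A, which
#' cross-loads on speed and executive function.
#'
#' @param primary loading value for single-loading tests.
#' @param tmt_a loadings (speed, executive) for the cross-loading test.
#' @return a 14 x 4 numeric matrix (tests x domains).
#' @export
default_loading_matrix <- function(primary = 0.75, tmt_a = c(0.55, 0.3)) {
  L <- matrix(0, length(test_battery_names()), 4,
              dimnames = list(test_battery_names(), .domain_names))
  assign_l <- function(tests, dom) L[tests, dom] <<- primary
  assign_l(c("semantic_fluency", "phonemic_fluency", "boston_naming"), "language")
  assign_l(c("ravlt_learning", "ravlt_recall"), "memory")
  assign_l(c("tmt_b_time", "tol_extra_moves", "digit_span", "corsi_span"),
           "executive_function")
  assign_l(c("reaction_time", "pegboard_time", "clicking_time",
             "dragging_time"), "speed")
  L["tmt_a_time", "speed"] <- tmt_a[1]
  L["tmt_a_time", "executive_function"] <- tmt_a[2]
  L
}

#' Default inter-domain correlation matrix
#' @return a 4 x 4 correlation matrix.
#' @export
default_domain_corr <- function() {
  m <- diag(4)
  dimnames(m) <- list(.domain_names, .domain_names)
  m["language", "executive_function"] <- m["executive_function", "language"] <- 0.5
  m["language", "memory"] <- m["memory", "language"] <- 0.4
  m["language", "speed"] <- m["speed", "language"] <- 0.3
  m["executive_function", "memory"] <- m["memory", "executive_function"] <- 0.4
  m["executive_function", "speed"] <- m["speed", "executive_function"] <- 0.5
  m["memory", "speed"] <- m["speed", "memory"] <- 0.3
  m
}

#' Cohort generation configuration
#'
#' Defaults reflect the cohort the analysis harness expects: age normal
#' (65.5, 4.8) truncated at 60, 60/40 female/male, 50/50 UK/USA, 60/40
#' high/low education; test-score residual sd 0.6 against loadings of 0.75;
#' about 30% of latent-language variance expressed in transcript properties
#' and 25% of latent-speed variance in the waveform plan.
#'
#' @param n_participants cohort size.
#' @param domain_corr 4x4 correlation matrix of the latent domains.
#' @param loading_matrix tests x domains loading matrix respecting the
#'   sparsity pattern (one domain per test, Trail Making A on two).
#' @param demographic_effects 4x4 numeric matrix (domain x covariate) of
#'   coefficients for centered age, male gender, high education, UK country.
#' @param speech_effect_size fraction of latent-language variance expressed
#'   in transcript properties, in [0, 1].
#' @param audio_effect_size same for latent speed in the waveform plan.
#' @param noise_sd residual sd of the test scores.
#' @param missing_rate,outlier_rate corruption rates applied to test scores.
#' @param transcript_length c(min, max) token counts per task.
#' @param audio_duration_s nominal duration of each synthetic recording.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return a `cogspeech_cohort_config` list.
#' @export
cohort_config <- function(n_participants = 200L,
                          domain_corr = default_domain_corr(),
                          loading_matrix = default_loading_matrix(),
                          demographic_effects = NULL,
                          speech_effect_size = 0.3,
                          audio_effect_size = 0.25,
                          noise_sd = 0.6,
                          missing_rate = 0.01,
                          outlier_rate = 0.005,
                          transcript_length = c(100L, 250L),
                          audio_duration_s = 60,
                          seed = 1L) {
  if (n_participants < 1) {
    cs_stop("n_participants must be positive", "cogspeech_validation_error")
  }
  check_corr_matrix(domain_corr, "domain_corr")
  check_rate(speech_effect_size, "speech_effect_size")
  check_rate(audio_effect_size, "audio_effect_size")
  check_rate(missing_rate, "missing_rate")
  check_rate(outlier_rate, "outlier_rate")
  L <- as.matrix(loading_matrix)
  n_load <- rowSums(L != 0)
  cross <- rownames(L)[n_load > 1]
  if (any(n_load == 0) || length(cross) > 1 ||
      (length(cross) == 1 && !identical(cross, "tmt_a_time"))) {
    cs_stop("loading_matrix must load every test on one domain (tmt_a_time on two)",
            "cogspeech_validation_error")
  }
  if (is.null(demographic_effects)) {
    demographic_effects <- matrix(
      c(-0.03, 0.00, 0.40, 0.20,
        -0.03, 0.00, 0.35, 0.15,
        -0.04, 0.00, 0.30, 0.10,
        -0.05, 0.00, 0.25, 0.10),
      nrow = 4, byrow = TRUE,
      dimnames = list(.domain_names, c("age", "gender_male", "education_high",
                                       "country_uk")))
  }
  structure(list(
    n_participants = as.integer(n_participants), domain_corr = domain_corr,
    loading_matrix = L, demographic_effects = demographic_effects,
    speech_effect_size = speech_effect_size,
    audio_effect_size = audio_effect_size, noise_sd = noise_sd,
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    transcript_length = as.integer(transcript_length),
    audio_duration_s = audio_duration_s, seed = as.integer(seed)
  ), class = "cogspeech_cohort_config")
}

# --- transcript synthesis ---------------------------------------------------

.template_pools <- function() {
  lex <- .tag_lexicon()
  list(
    nouns = names(lex)[lex == "NN"],
    verbs_z = names(lex)[lex == "VBZ"],
    verbs_g = setdiff(names(lex)[lex == "VBG"],
                      c("being", "having", "doing")),
    adjs = names(lex)[lex == "JJ"],
    advs = names(lex)[lex == "RB"],
    preps = c("in", "on", "near", "beside", "behind", "under", "over", "at")
  )
}

#' Synthesize a transcript whose lexical properties track a latent score
#'
#' Template sentences are drawn from the bundled lexicon. A higher latent
#' value monotonically widens the content-word vocabulary in use (raising
#' the type-token ratio) and lowers the hesitation-interjection rate via
#' `plogis(-2.2 - 0.6 * latent)`.
#'
#' @param latent_language latent score on the standard-normal scale.
#' @param length_params c(min, max) token count; the transcript has exactly
#'   a uniformly drawn count in that range.
#' @param seed integer seed.
#' @param lexicon optional template pools (see source); defaults bundled.
#' @return a list with `text`, `target_tokens`, `hesitation_rate`,
#'   `vocab_size` (the planted ground truth).
#' @export
synthesize_transcript <- function(latent_language, length_params = c(100L, 250L),
                                  seed = 1L, lexicon = .template_pools()) {
  if (length(lexicon$nouns) == 0L || length(lexicon$verbs_z) == 0L) {
    cs_stop("lexicon must cover nouns and verbs", "cogspeech_validation_error")
  }
  with_seed(seed, {
    n_target <- if (length_params[1] >= length_params[2]) length_params[1] else
      sample(length_params[1]:length_params[2], 1L)
    frac <- stats::plogis(0.9 * latent_language)
    pool_n <- pmax(5L, round(length(lexicon$nouns) * frac))
    pool_v <- pmax(4L, round(length(lexicon$verbs_z) * frac))
    pool_a <- pmax(3L, round(length(lexicon$adjs) * frac))
    hes_rate <- stats::plogis(-2.2 - 0.6 * latent_language)
    nouns <- lexicon$nouns[seq_len(pool_n)]
    verbs <- lexicon$verbs_z[seq_len(pool_v)]
    verbg <- lexicon$verbs_g[seq_len(pmax(3L, min(pool_v, length(lexicon$verbs_g))))]
    adjs <- lexicon$adjs[seq_len(pool_a)]
    advs <- lexicon$advs
    preps <- lexicon$preps
    pick <- function(x) x[sample.int(length(x), 1L)]
    sentences <- list()
    n_tok <- 0L
    while (n_tok < n_target) {
      s <- switch(sample.int(5L, 1L),
        c("the", pick(nouns), pick(verbs), "the", pick(nouns)),
        c("a", pick(adjs), pick(nouns), "is", pick(verbg), pick(preps),
          "the", pick(nouns)),
        c("the", pick(nouns), "is", pick(verbg), pick(advs)),
        c("there", "is", "a", pick(nouns), pick(preps), "the", pick(nouns)),
        c("the", pick(adjs), pick(nouns), pick(verbs), pick(preps), "the",
          pick(nouns))
      )
      hes <- stats::runif(1) < hes_rate * length(s) / 2
      if (hes) s <- append(s, "uh", after = sample.int(length(s), 1L) - 1L)
      sentences[[length(sentences) + 1L]] <- s
      n_tok <- n_tok + length(s)
    }
    toks <- unlist(sentences)
    lens <- lengths(sentences)
    if (length(toks) > n_target) {
      toks <- toks[seq_len(n_target)]
      keep <- cumsum(lens) <= n_target
      lens <- c(lens[keep], n_target - sum(lens[keep]))
      lens <- lens[lens > 0L]
    }
    # re-render with sentence-final periods
    idx <- cumsum(lens)
    out <- character(0)
    prev <- 0L
    for (i in idx) {
      out <- c(out, paste(toks[(prev + 1L):i], collapse = " "), ". ")
      prev <- i
    }
    list(text = trimws(paste(out, collapse = "")),
         target_tokens = n_target, hesitation_rate = hes_rate,
         vocab_size = pool_n + pool_v + pool_a)
  })
}

# --- waveform synthesis -----------------------------------------------------

#' Plan voiced/pause intervals for a synthetic recording
#'
#' Alternating voiced runs and pauses; the pause fraction and voiced-run
#' rate are monotone in the latent speed score.
#'
#' @param latent_speed latent score (standard-normal scale).
#' @param duration_s total duration.
#' @param seed integer seed.
#' @return list with `intervals` (data.frame start/end of voiced intervals),
#'   `duration_s`, `f0`, `pause_fraction_target`, `seed`.
#' @export
plan_waveform <- function(latent_speed, duration_s = 60, seed = 1L) {
  with_seed(seed, {
    pause_target <- stats::plogis(-1.1 - 0.35 * latent_speed)
    f0 <- stats::runif(1, 110, 220)
    t <- 0.2     # lead-in pause
    starts <- c(); ends <- c()
    while (t < duration_s - 0.5) {
      v <- min(stats::rlnorm(1, log(1.2), 0.3), duration_s - 0.3 - t)
      if (v < 0.2) break
      starts <- c(starts, t); ends <- c(ends, t + v)
      p <- v * pause_target / (1 - pause_target)
      t <- t + v + max(p, 0.12)
    }
    list(intervals = data.frame(start = starts, end = ends),
         duration_s = duration_s, f0 = f0,
         pause_fraction_target = pause_target, seed = as.integer(seed))
  })
}

#' Synthesize a waveform from a voiced/pause plan
#'
#' Voiced intervals contain a three-harmonic tone at `f0` with 10 ms onset
#' and offset ramps at amplitude 0.3; everything else is low-level Gaussian
#' noise (sd 1e-3). Deterministic given the seed.
#'
#' @param plan a plan from [plan_waveform()], or a list with `intervals`
#'   (non-overlapping, inside the total duration) and `duration_s`.
#' @param f0 fundamental frequency in Hz (defaults to the plan's).
#' @param sample_rate sampling rate, at least 8000 Hz.
#' @param seed integer seed for the noise floor.
#' @return a `cogspeech_waveform` with the plan attached as attribute
#'   `truth`.
#' @export
synthesize_waveform <- function(plan, f0 = plan$f0 %||% 150,
                                sample_rate = 16000, seed = plan$seed %||% 1L) {
  if (sample_rate < 8000) {
    cs_stop("sample_rate must be at least 8000 Hz", "cogspeech_validation_error")
  }
  iv <- plan$intervals
  if (nrow(iv) > 0) {
    o <- order(iv$start); iv <- iv[o, ]
    if (any(iv$end <= iv$start) || any(iv$start < 0) ||
        any(iv$end > plan$duration_s + 1e-9)) {
      cs_stop("plan intervals must lie within the total duration",
              "cogspeech_validation_error")
    }
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-12)) {
      cs_stop("plan intervals must be non-overlapping",
              "cogspeech_validation_error")
    }
  }
  n <- round(plan$duration_s * sample_rate)
  x <- with_seed(child_seed(seed, "noise"), stats::rnorm(n, 0, 1e-3))
  ramp_n <- round(0.01 * sample_rate)
  for (i in seq_len(nrow(iv))) {
    a <- floor(iv$start[i] * sample_rate) + 1L
    b <- min(n, ceiling(iv$end[i] * sample_rate))
    if (b <= a) next
    tt <- (a:b) / sample_rate
    tone <- 0.3 * (sin(2 * pi * f0 * tt) + 0.5 * sin(4 * pi * f0 * tt) +
                   0.25 * sin(6 * pi * f0 * tt)) / 1.75
    len <- length(tone)
    env <- rep(1, len)
    r <- min(ramp_n, len %/% 2L)
    if (r > 1) {
      env[seq_len(r)] <- seq(0, 1, length.out = r)
      env[(len - r + 1L):len] <- seq(1, 0, length.out = r)
    }
    x[a:b] <- x[a:b] + tone * env
  }
  w <- waveform(x, sample_rate)
  attr(w, "truth") <- plan
  w
}

# --- norm lexicon -----------------------------------------------------------

#' Generate a synthetic psycholinguistic norm lexicon
#'
#' Stands in for published word-norm databases. Declared ranges: frequency
#' (Zipf scale 1-7, lognormal rank profile), age of acquisition 2-18 years,
#' familiarity 100-700, ambiguity (number of senses) 1-10, concreteness 1-5.
#'
#' @param vocabulary character vector of words.
#' @param seed integer seed.
#' @return a `cogspeech_norm_lexicon` data.frame with columns word,
#'   frequency, aoa, familiarity, ambiguity, concreteness.
#' @export
make_norm_lexicon <- function(vocabulary = english_dictionary(), seed = 1L) {
  if (length(vocabulary) == 0L) {
    cs_stop("vocabulary must be non-empty", "cogspeech_validation_error")
  }
  vocabulary <- unique(tolower(vocabulary))
  with_seed(seed, {
    n <- length(vocabulary)
    data.frame(
      word = vocabulary,
      frequency = pmin(7, pmax(1, stats::rnorm(n, 4.0, 1.0))),
      aoa = pmin(18, pmax(2, stats::rnorm(n, 8, 3))),
      familiarity = pmin(700, pmax(100, stats::rnorm(n, 480, 90))),
      ambiguity = pmin(10, 1 + stats::rpois(n, 1.2)),
      concreteness = pmin(5, pmax(1, stats::rnorm(n, 3.3, 0.9))),
      stringsAsFactors = FALSE
    ) -> lex
    class(lex) <- c("cogspeech_norm_lexicon", "data.frame")
    lex
  })
}

# --- corruption -------------------------------------------------------------

#' Inject missing values and outliers into a test-score table
#'
#' Outliers are displaced by `outlier_magnitude_sd` residual standard
#' deviations from the per-column demographic regression line (or the
#' column mean when no demographics are given); missing cells are set NA
#' uniformly at random. Both are recorded in the returned masks.
#'
#' @param test_scores numeric matrix/data.frame (participants x tests).
#' @param missing_rate,outlier_rate cell-level corruption probabilities.
#' @param outlier_magnitude_sd displacement in residual sds.
#' @param demographics optional data.frame for the regression line.
#' @param seed integer seed.
#' @return list with `scores`, `missing_mask`, `outlier_mask`.
#' @export
inject_missing_and_outliers <- function(test_scores, missing_rate = 0.01,
                                        outlier_rate = 0.005,
                                        outlier_magnitude_sd = 8,
                                        demographics = NULL, seed = 1L) {
  check_rate(missing_rate, "missing_rate")
  check_rate(outlier_rate, "outlier_rate")
  X <- as.matrix(test_scores)
  with_seed(seed, {
    out_mask <- matrix(stats::runif(length(X)) < outlier_rate, nrow(X))
    out_mask[is.na(X)] <- FALSE
    for (j in seq_len(ncol(X))) {
      rows <- which(out_mask[, j])
      if (!length(rows)) next
      if (!is.null(demographics)) {
        D <- .demographic_design(demographics)
        fit <- stats::lm.fit(D, X[, j])
        rsd <- stats::sd(fit$residuals)
        base <- D[rows, , drop = FALSE] %*% fit$coefficients
      } else {
        rsd <- stats::sd(X[, j], na.rm = TRUE)
        base <- rep(mean(X[, j], na.rm = TRUE), length(rows))
      }
      sign <- ifelse(stats::runif(length(rows)) < 0.5, -1, 1)
      X[rows, j] <- as.numeric(base) + sign * outlier_magnitude_sd * rsd
    }
    miss_mask <- matrix(stats::runif(length(X)) < missing_rate, nrow(X))
    miss_mask[out_mask] <- FALSE
    X[miss_mask] <- NA_real_
    list(scores = X, missing_mask = miss_mask, outlier_mask = out_mask)
  })
}

# --- cohort -----------------------------------------------------------------

.demographic_design <- function(demographics) {
  cbind(intercept = 1,
        age = demographics$age - mean(demographics$age),
        gender_male = as.numeric(demographics$gender == "male"),
        education_high = as.numeric(demographics$education == "high"),
        country_uk = as.numeric(demographics$country == "UK"))
}

#' Generate a full synthetic cohort
#'
#' @param config a `cogspeech_cohort_config`.
#' @return a `cogspeech_cohort`: list with `demographics`, `latent_domains`,
#'   `test_scores` (corrupted, raw orientation), `test_scores_clean`,
#'   `transcripts` (per participant, tasks cookie_theft and picnic),
#'   `audio_plans`, `truth` (planted parameters and masks), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cogspeech_cohort_config"))
  n <- config$n_participants
  with_seed(config$seed, {
    ids <- sprintf("P%04d", seq_len(n))
    demographics <- data.frame(
      participant_id = ids,
      age = pmax(60, stats::rnorm(n, 65.5, 4.8)),
      gender = sample(c("female", "male"), n, TRUE, c(0.6, 0.4)),
      country = sample(c("UK", "USA"), n, TRUE, c(0.5, 0.5)),
      education = sample(c("high", "low"), n, TRUE, c(0.6, 0.4)),
      ses = pmin(10, pmax(1, round(stats::rnorm(n, 5.6, 1.6)))),
      stringsAsFactors = FALSE
    )
    Z <- MASS::mvrnorm(n, rep(0, 4), config$domain_corr)
    colnames(Z) <- .domain_names
    D <- .demographic_design(demographics)[, -1, drop = FALSE]
    shift <- D %*% t(config$demographic_effects)
    latents <- Z + shift

    L <- config$loading_matrix
    scores_h <- latents %*% t(L) +
      matrix(stats::rnorm(n * nrow(L), 0, config$noise_sd), n)
    colnames(scores_h) <- rownames(L)
    # emit reverse-scored columns on their natural (higher = worse) scale
    raw <- scores_h
    neg <- negative_test_columns()
    raw[, neg] <- -raw[, neg]
    rownames(raw) <- ids

    se <- config$speech_effect_size
    ae <- config$audio_effect_size
    z_speech <- sqrt(se) * latents[, "language"] +
      sqrt(1 - se) * stats::rnorm(n)
    z_audio <- sqrt(ae) * latents[, "speed"] +
      sqrt(1 - ae) * stats::rnorm(n)

    transcripts <- vector("list", n)
    plans <- vector("list", n)
    truth_tr <- vector("list", n)
    for (i in seq_len(n)) {
      tr <- list(
        cookie_theft = synthesize_transcript(
          z_speech[i], config$transcript_length,
          seed = child_seed(config$seed, paste0("tr1-", i))),
        picnic = synthesize_transcript(
          z_speech[i], config$transcript_length,
          seed = child_seed(config$seed, paste0("tr2-", i)))
      )
      transcripts[[i]] <- lapply(tr, `[[`, "text")
      truth_tr[[i]] <- lapply(tr, function(x) x[setdiff(names(x), "text")])
      plans[[i]] <- plan_waveform(z_audio[i], config$audio_duration_s,
                                  seed = child_seed(config$seed, paste0("wav-", i)))
    }
    names(transcripts) <- names(plans) <- names(truth_tr) <- ids

    corr <- inject_missing_and_outliers(
      raw, config$missing_rate, config$outlier_rate,
      demographics = demographics,
      seed = child_seed(config$seed, "corrupt"))

    structure(list(
      demographics = demographics,
      latent_domains = latents,
      test_scores = corr$scores,
      test_scores_clean = raw,
      transcripts = transcripts,
      audio_plans = plans,
      truth = list(z_speech = z_speech, z_audio = z_audio,
                   transcripts = truth_tr,
                   missing_mask = corr$missing_mask,
                   outlier_mask = corr$outlier_mask),
      config = config
    ), class = "cogspeech_cohort")
  })
}

#' @export
print.cogspeech_cohort <- function(x, ...) {
  cat(sprintf("<cogspeech_cohort: %d participants, %d tests>\n",
              nrow(x$demographics), ncol(x$test_scores)))
  invisible(x)
}

#' Materialize the synthetic waveform for one participant
#' @param cohort a `cogspeech_cohort`.
#' @param id participant id.
#' @param sample_rate sampling rate in Hz.
#' @return a `cogspeech_waveform`.
#' @export
cohort_waveform <- function(cohort, id, sample_rate = 16000) {
  plan <- cohort$audio_plans[[id]]
  if (is.null(plan)) cs_stop(sprintf("unknown participant '%s'", id))
  w <- synthesize_waveform(plan, sample_rate = sample_rate)
  w$participant_id <- id
  w
}

#' Concatenated picture-description transcript for one participant
#' @param cohort a `cogspeech_cohort`.
#' @param id participant id.
#' @return single string (tasks joined with a space).
#' @export
cohort_transcript <- function(cohort, id) {
  tr <- cohort$transcripts[[id]]
  if (is.null(tr)) cs_stop(sprintf("unknown participant '%s'", id))
  paste(unlist(tr), collapse = " ")
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes demographics and test scores as CSV, transcripts as JSON records
#' ({id, task, text}), waveforms as 16-bit PCM WAV, and the planted ground
#' truth as truth.json.
#'
#' @param cohort a `cogspeech_cohort`.
#' @param dir output directory (created if needed).
#' @param write_audio whether to synthesize and write WAV files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_audio = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$demographics,
                   file.path(dir, "demographics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(participant_id = rownames(cohort$test_scores),
                              cohort$test_scores, check.names = FALSE),
                   file.path(dir, "test_scores.csv"), row.names = FALSE)
  recs <- list()
  for (id in names(cohort$transcripts)) {
    for (task in names(cohort$transcripts[[id]])) {
      recs[[length(recs) + 1L]] <- list(
        id = id, task = task, text = cohort$transcripts[[id]][[task]])
    }
  }
  jsonlite::write_json(recs, file.path(dir, "transcripts.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(
    list(z_speech = unname(cohort$truth$z_speech),
         z_audio = unname(cohort$truth$z_audio),
         pause_fraction_target = vapply(cohort$audio_plans,
                                        `[[`, 0, "pause_fraction_target")),
    file.path(dir, "truth.json"), digits = NA)
  if (write_audio) {
    adir <- file.path(dir, "audio")
    dir.create(adir, showWarnings = FALSE)
    for (id in names(cohort$audio_plans)) {
      write_wav(cohort_waveform(cohort, id),
                file.path(adir, paste0(id, ".wav")))
    }
  }
  invisible(dir)
}

# --- calibrated feature-space signal ---------------------------------------

#' Simulate a feature matrix carrying an exact theoretical signal
#'
#' One standard-normal latent score per participant (optionally mean-shifted
#' for clinical-cohort emulation); each feature is
#' \eqn{x_j = a t + \sqrt{1-a^2}\, e_j} with `a` solved so that the
#' population R-squared of the best linear predictor of the latent from all
#' `p` features equals `r2` exactly: \eqn{a^2 = r2 / (p - r2 (p - 1))}.
#' The target is the latent itself.
#'
#' @param n participants.
#' @param p number of features.
#' @param r2 theoretical R-squared of the feature signal, in [0, 1).
#' @param latent_shift mean shift of the latent (e.g. a clinical deficit).
#' @param seed integer seed.
#' @return list with `X` (n x p matrix), `y` (latent), `loading` (a).
#' @export
simulate_feature_signal <- function(n, p = 5L, r2 = 0.3, latent_shift = 0,
                                    seed = 1L) {
  stopifnot(r2 >= 0, r2 < 1, p >= 1)
  a <- sqrt(r2 / (p - r2 * (p - 1)))
  with_seed(seed, {
    t <- stats::rnorm(n, latent_shift, 1)
    E <- matrix(stats::rnorm(n * p), n, p)
    X <- a * t + sqrt(1 - a^2) * E
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = t, loading = a)
  })
}
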