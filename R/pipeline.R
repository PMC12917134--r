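# End-to-end study orchestration: synthetic cohort (or supplied cohort) ->
# feature extraction -> composite scores -> stratified split -> CV
# regression over feature sets -> holdout evaluation -> low-performer
# screening -> optional clinical transfer. Every run writes its resolved
# configuration and seeds next to the outputs.

#' Study configuration
#'
#' @param output_dir run directory (created).
#' @param cohort a `cogspeech_cohort_config` for synthetic generation, or a
#'   ready `cogspeech_cohort`.
#' @param feature_sets named list: set label -> character vector drawn from
#'   "demographic", "linguistic", "acoustic".
#' @param domains composite domains to model.
#' @param model a `cogspeech_model_config`.
#' @param include_acoustic whether to synthesize audio and extract acoustic
#'   features (the expensive stage).
#' @param screen_threshold normative z threshold for low performers.
#' @param seed global seed (overrides the member configs' seeds).
#' @return a `cogspeech_study_config`.
#' @export
study_config <- function(output_dir = tempfile("cogspeech_run_"),
                         cohort = cohort_config(),
                         feature_sets = list(
                           demographic = "demographic",
                           linguistic_demographic = c("linguistic", "demographic"),
                           acoustic_demographic = c("acoustic", "demographic"),
                           all = c("linguistic", "acoustic", "demographic")),
                         domains = c("language", "executive_function",
                                     "memory", "speed"),
                         model = model_config(),
                         include_acoustic = TRUE,
                         screen_threshold = -1.96,
                         seed = 1L) {
  if (!include_acoustic) {
    feature_sets <- Filter(function(fs) !("acoustic" %in% fs), feature_sets)
  }
  structure(list(output_dir = output_dir, cohort = cohort,
                 feature_sets = feature_sets, domains = domains,
                 model = model, include_acoustic = include_acoustic,
                 screen_threshold = screen_threshold,
                 seed = as.integer(seed)),
            class = "cogspeech_study_config")
}

#' Demographic feature matrix used by the predictive models
#' @param demographics cohort demographics data.frame.
#' @return numeric matrix (age, gender_male, education_high, country_uk)
#'   with participant ids as rownames.
#' @export
demographic_features <- function(demographics) {
  D <- .demographic_design(demographics)[, -1, drop = FALSE]
  rownames(D) <- demographics$participant_id
  D
}

.extract_cohort_features <- function(cohort, include_acoustic, lexicon) {
  ids <- cohort$demographics$participant_id
  ling <- vector("list", length(ids)); names(ling) <- ids
  acou <- if (include_acoustic) ling else NULL
  for (id in ids) {
    text <- cohort_transcript(cohort, id)
    ling[[id]] <- extract_linguistic_features(text, lexicon)
    if (include_acoustic) {
      w <- cohort_waveform(cohort, id)
      acou[[id]] <- extract_all_acoustic(w, text)
    }
  }
  lt <- feature_table(ling)
  out <- list(linguistic = as.matrix(lt[, -1]))
  rownames(out$linguistic) <- lt$participant_id
  if (include_acoustic) {
    at <- feature_table(acou)
    out$acoustic <- as.matrix(at[, -1])
    rownames(out$acoustic) <- at$participant_id
  }
  out
}

.assemble_features <- function(blocks, set) {
  do.call(cbind, blocks[set])
}

#' Run the full study end-to-end
#'
#' @param config a `cogspeech_study_config`.
#' @return (invisibly) a list with `cohort`, `features`, `composites`,
#'   `split`, `regression` (per feature set x domain: CV and holdout
#'   metrics), `screening` (per domain), and `output_dir`. All tables are
#'   also written to the run directory as CSV/JSON.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "cogspeech_study_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (inherits(config$cohort, "cogspeech_cohort")) config$cohort
            else {
              cc <- config$cohort
              cc$seed <- child_seed(config$seed, "cohort")
              generate_cohort(cc)
            }
  ids <- cohort$demographics$participant_id
  lexicon <- make_norm_lexicon(seed = child_seed(config$seed, "lexicon"))

  blocks <- .extract_cohort_features(cohort, config$include_acoustic, lexicon)
  blocks$demographic <- demographic_features(cohort$demographics)

  comp <- compute_composite_scores(cohort$test_scores, cohort$demographics)
  composites <- comp$composites
  rownames(composites) <- ids

  strat <- cohort$demographics
  strat$mean_composite <- rowMeans(composites)
  split <- make_holdout_split(
    strat, frac = 0.8,
    strat_vars = c("age", "country", "gender", "education", "mean_composite"),
    seed = child_seed(config$seed, "split"))
  dev <- strat[strat$participant_id %in% split$development, ]
  folds <- make_cv_folds(dev, k = config$model$folds,
                         seed = child_seed(config$seed, "folds"))

  regression <- list()
  predictions <- list()
  for (set_name in names(config$feature_sets)) {
    X <- .assemble_features(blocks, config$feature_sets[[set_name]])
    for (domain in config$domains) {
      y <- stats::setNames(composites[, domain], ids)
      cfg <- config$model
      cfg$seed <- child_seed(config$seed, paste(set_name, domain))
      cv <- cross_validate(X[split$development, , drop = FALSE],
                           y[split$development], folds, cfg)
      cv_m <- evaluate_predictions(cv$truth, cv$prediction)
      cv_ci <- bootstrap_metric_ci(cv$truth, cv$prediction, "r_squared",
                                   n_boot = cfg$n_boot, level = cfg$level,
                                   seed = child_seed(cfg$seed, "ci"))
      pp <- preprocess_fold_features(X[split$development, , drop = FALSE],
                                     X[split$holdout, , drop = FALSE])
      fp <- fit_predict(cfg, pp$train, y[split$development], pp$apply)
      ho_m <- evaluate_predictions(y[split$holdout], fp$predictions)
      key <- paste(set_name, domain, sep = ".")
      regression[[key]] <- list(
        feature_set = set_name, domain = domain,
        cv = c(cv_m[c("r_squared", "spearman_rho", "mae")],
               list(r_squared_ci = c(cv_ci$lower, cv_ci$upper))),
        holdout = ho_m[c("r_squared", "spearman_rho", "mae")])
      predictions[[key]] <- data.frame(cv, feature_set = set_name,
                                       domain = domain)
    }
  }

  # dummy baselines on the largest feature set
  main_set <- names(config$feature_sets)[length(config$feature_sets)]
  X <- .assemble_features(blocks, config$feature_sets[[main_set]])
  for (dummy in c("dummy_mean", "dummy_random")) {
    for (domain in config$domains) {
      y <- stats::setNames(composites[, domain], ids)
      cfg <- config$model
      cfg$model <- dummy
      cfg$seed <- child_seed(config$seed, paste(dummy, domain))
      cv <- cross_validate(X[split$development, , drop = FALSE],
                           y[split$development], folds, cfg)
      m <- evaluate_predictions(cv$truth, cv$prediction)
      regression[[paste(dummy, domain, sep = ".")]] <- list(
        feature_set = dummy, domain = domain,
        cv = m[c("r_squared", "spearman_rho", "mae")])
    }
  }

  # normative screening on the full cohort, classified from the main set
  norm <- fit_normative_model(composites, cohort$demographics)
  screening <- list()
  for (domain in config$domains) {
    labels <- stats::setNames(
      label_low_performers(norm$z[, domain], config$screen_threshold), ids)
    dev_lab <- labels[split$development]
    if (length(unique(dev_lab)) < 2L || min(table(dev_lab)) < config$model$folds) {
      screening[[domain]] <- list(domain = domain, skipped = "class too rare")
      next
    }
    cfg <- config$model
    cfg$seed <- child_seed(config$seed, paste("screen", domain))
    scores <- rep(NA_real_, length(split$development))
    names(scores) <- split$development
    for (f in sort(unique(folds))) {
      test_ids <- names(folds)[folds == f]
      train_ids <- setdiff(split$development, test_ids)
      pp <- preprocess_fold_features(X[train_ids, , drop = FALSE],
                                     X[test_ids, , drop = FALSE])
      fc <- fit_predict_classifier(cfg, pp$train, labels[train_ids], pp$apply)
      scores[test_ids] <- fc$scores
    }
    curves <- classification_curves(scores, dev_lab,
                                    n_boot = min(cfg$n_boot, 200L),
                                    seed = child_seed(cfg$seed, "curves"))
    screening[[domain]] <- list(
      domain = domain, prevalence = curves$prevalence,
      roc_auc = curves$roc_auc, pr_auc = curves$pr_auc,
      roc_auc_ci = curves$roc_auc_ci, pr_auc_ci = curves$pr_auc_ci)
  }

  # persist artifacts
  metrics <- list(regression = regression, screening = screening,
                  split = list(development = length(split$development),
                               holdout = length(split$holdout),
                               excluded = length(split$excluded)),
                  cfa_fit = as.list(comp$fit$fit_indices))
  jsonlite::write_json(metrics, file.path(config$output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(do.call(rbind, predictions),
                   file.path(config$output_dir, "predictions.csv"),
                   row.names = FALSE)
  resolved <- config
  resolved$cohort <- NULL
  jsonlite::write_json(resolved, file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, force = TRUE)

  invisible(list(cohort = cohort, features = blocks, composites = composites,
                 split = split, regression = regression,
                 screening = screening, metrics = metrics,
                 output_dir = config$output_dir))
}
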