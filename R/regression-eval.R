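# The prediction harness: stratified development/holdout split, stratified
# k-fold cross-validation, leakage-safe per-fold feature preprocessing,
# SVR / random-forest / dummy regressors, metrics with bootstrap confidence
# intervals and a paired bootstrap superiority test.

.bin_continuous <- function(x, n_bins = 5L) {
  if (is.numeric(x) && length(unique(x)) > n_bins) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                 na.rm = TRUE))
    if (length(br) < 2L) return(factor(rep("b1", length(x))))
    cut(x, breaks = br, include.lowest = TRUE)
  } else factor(x)
}

.stratum_labels <- function(data, strat_vars) {
  cols <- lapply(strat_vars, function(v) .bin_continuous(data[[v]]))
  interaction(cols, drop = TRUE)
}

#' Stratified development/holdout split
#'
#' Participants missing any stratification variable are excluded and
#' listed. Continuous variables are binned into quintiles. Development
#' counts are allocated per stratum by largest remainder so the global
#' development size is exactly `round(frac * n)`; strata with fewer than 2
#' members are pooled into a joint stratum (with a warning).
#'
#' @param data data.frame with a `participant_id` column and the
#'   stratification variables.
#' @param frac development fraction (default 0.8).
#' @param strat_vars variable names to stratify on.
#' @param seed integer seed.
#' @return a `cogspeech_split`: list with `development`, `holdout`,
#'   `excluded` (ids), `strat_vars`, `seed`.
#' @export
make_holdout_split <- function(data, frac = 0.8,
                               strat_vars = c("age", "country", "gender",
                                              "education"),
                               seed = 1L) {
  stopifnot("participant_id" %in% names(data))
  missing_vars <- setdiff(strat_vars, names(data))
  if (length(missing_vars)) {
    cs_stop(sprintf("missing stratification variable(s): %s",
                    paste(missing_vars, collapse = ", ")),
            "cogspeech_validation_error")
  }
  ok <- stats::complete.cases(data[, strat_vars, drop = FALSE])
  excluded <- data$participant_id[!ok]
  d <- data[ok, , drop = FALSE]
  n <- nrow(d)
  n_dev <- round(frac * n)
  strata <- .stratum_labels(d, strat_vars)
  tab <- table(strata)
  if (any(tab < 2L)) {
    cs_warn(sprintf("%d stratum(s) with < 2 members pooled", sum(tab < 2L)))
    small <- names(tab)[tab < 2L]
    strata <- as.character(strata)
    strata[strata %in% small] <- "__pooled__"
    strata <- factor(strata)
  }
  with_seed(seed, {
    levs <- levels(strata)
    sizes <- as.integer(table(strata)[levs])
    ideal <- frac * sizes
    base <- floor(ideal)
    rem <- n_dev - sum(base)
    if (rem > 0) {
      ord <- order(-(ideal - base))
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      ord <- order(ideal - base)
      take <- ord[base[ord] > 0][seq_len(-rem)]
      base[take] <- base[take] - 1L
    }
    dev_ids <- character(0)
    for (i in seq_along(levs)) {
      members <- d$participant_id[strata == levs[i]]
      pick <- sample(members, min(base[i], length(members)))
      dev_ids <- c(dev_ids, pick)
    }
    structure(list(
      development = sort(dev_ids),
      holdout = sort(setdiff(d$participant_id, dev_ids)),
      excluded = excluded, strat_vars = strat_vars, seed = as.integer(seed)
    ), class = "cogspeech_split")
  })
}

#' Stratified k-fold assignment
#'
#' Members are shuffled within strata and dealt round-robin across the
#' concatenated strata, so global fold sizes differ by at most one and each
#' stratum is spread across folds.
#'
#' @param data data.frame of development participants (with
#'   `participant_id` and the stratification variables), or a character
#'   vector of ids (unstratified).
#' @param k number of folds.
#' @param strat_vars stratification variables (ignored for id vectors).
#' @param seed integer seed.
#' @return named integer vector: participant id -> fold (1..k).
#' @export
make_cv_folds <- function(data, k = 10L,
                          strat_vars = c("age", "country", "gender",
                                         "education"),
                          seed = 1L) {
  if (is.character(data)) {
    ids <- data
    strata <- factor(rep("all", length(ids)))
  } else {
    ids <- data$participant_id
    strata <- .stratum_labels(data, intersect(strat_vars, names(data)))
  }
  if (length(ids) < k) {
    cs_stop("fewer participants than folds", "cogspeech_validation_error")
  }
  with_seed(seed, {
    ordered <- unlist(lapply(levels(strata), function(l) {
      m <- ids[strata == l]
      if (length(m) > 1) sample(m) else m
    }), use.names = FALSE)
    folds <- rep(seq_len(k), length.out = length(ordered))
    stats::setNames(folds[match(ids, ordered)], ids)
  })
}

# --- leakage-safe feature preprocessing ------------------------------------

#' Fit a train-only feature transform
#'
#' Per feature: cells beyond `z_cap` train standard deviations from the
#' train mean are set missing; missing cells are completed by round-robin
#' ridge imputation on the training matrix; the per-column ridge
#' regressions refitted on the completed training matrix are stored so the
#' same (frozen) imputation applies to new data; finally columns are
#' standardized by the completed-train mean and standard deviation.
#' Constant training columns are dropped with a warning.
#'
#' @param train numeric matrix/data.frame of training features.
#' @param z_cap outlier threshold in train sds.
#' @return a `cogspeech_feature_transform`.
#' @export
fit_feature_transform <- function(train, z_cap = 4) {
  X <- as.matrix(train)
  sds0 <- apply(X, 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(sds0) & sds0 > 1e-12
  if (!all(keep)) {
    cs_warn(sprintf("dropping constant feature(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  mu0 <- colMeans(X, na.rm = TRUE)
  sd0 <- apply(X, 2, stats::sd, na.rm = TRUE)
  Z <- sweep(sweep(X, 2, mu0), 2, sd0, `/`)
  X[abs(Z) > z_cap] <- NA_real_
  Xc <- impute_round_robin(X)
  # frozen per-column ridge imputers from the completed training matrix
  betas <- lapply(seq_len(ncol(Xc)), function(j) {
    A <- cbind(1, Xc[, -j, drop = FALSE])
    P <- diag(c(0, rep(1e-3, ncol(A) - 1L)), nrow = ncol(A))
    drop(solve(crossprod(A) + P, crossprod(A, Xc[, j])))
  })
  structure(list(
    columns = colnames(Xc),
    outlier_mu = mu0, outlier_sd = sd0, z_cap = z_cap,
    center = colMeans(Xc), scale = apply(Xc, 2, stats::sd),
    betas = betas, train_completed = Xc
  ), class = "cogspeech_feature_transform")
}

#' Apply a fitted feature transform to new data
#'
#' No statistic of the new data enters the transform: outlier thresholds,
#' imputation regressions and standardization constants all come from the
#' training fit.
#'
#' @param transform a `cogspeech_feature_transform`.
#' @param newdata matrix/data.frame sharing the training feature schema.
#' @param max_sweeps fixed-point sweeps of the frozen imputers for rows
#'   with several missing cells.
#' @return standardized numeric matrix.
#' @export
apply_feature_transform <- function(transform, newdata, max_sweeps = 5L) {
  X <- as.matrix(newdata)
  missing_cols <- setdiff(transform$columns, colnames(X))
  if (length(missing_cols)) {
    cs_stop(sprintf("newdata is missing feature(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "cogspeech_validation_error")
  }
  X <- X[, transform$columns, drop = FALSE]
  Z <- sweep(sweep(X, 2, transform$outlier_mu), 2, transform$outlier_sd, `/`)
  X[abs(Z) > transform$z_cap] <- NA_real_
  miss <- is.na(X)
  if (any(miss)) {
    for (j in seq_len(ncol(X))) X[miss[, j], j] <- transform$center[j]
    for (s in seq_len(max_sweeps)) {
      for (j in seq_len(ncol(X))) {
        rows <- which(miss[, j])
        if (!length(rows)) next
        X[rows, j] <- cbind(1, X[rows, -j, drop = FALSE]) %*% transform$betas[[j]]
      }
    }
  }
  sweep(sweep(X, 2, transform$center), 2, transform$scale, `/`)
}

#' Preprocess features for one fold
#'
#' @param train,apply feature matrices with identical columns.
#' @param z_cap outlier threshold.
#' @return list with `train`, `apply` (standardized matrices) and
#'   `transform`.
#' @export
preprocess_fold_features <- function(train, apply, z_cap = 4) {
  tr <- fit_feature_transform(train, z_cap = z_cap)
  list(train = apply_feature_transform(tr, train),
       apply = apply_feature_transform(tr, apply),
       transform = tr)
}

# --- models -----------------------------------------------------------------

#' Model configuration for the prediction harness
#'
#' @param model one of "svr", "random_forest", "dummy_mean", "dummy_random".
#' @param kernel SVR kernel family.
#' @param C SVR regularization parameter (default 0.5).
#' @param epsilon SVR epsilon-tube width.
#' @param folds cross-validation folds.
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param level confidence level.
#' @param ntree random-forest tree count.
#' @param seed integer seed.
#' @return a `cogspeech_model_config`.
#' @export
model_config <- function(model = c("svr", "random_forest", "dummy_mean",
                                   "dummy_random"),
                         kernel = "radial", C = 0.5, epsilon = 0.1,
                         folds = 10L, n_boot = 1000L, level = 0.95,
                         ntree = 500L, seed = 1L) {
  model <- match.arg(model)
  if (C <= 0) cs_stop("C must be positive", "cogspeech_validation_error")
  if (folds < 2) cs_stop("folds must be >= 2", "cogspeech_validation_error")
  structure(list(model = model, kernel = kernel, C = C, epsilon = epsilon,
                 folds = as.integer(folds), n_boot = as.integer(n_boot),
                 level = level, ntree = as.integer(ntree),
                 seed = as.integer(seed)),
            class = "cogspeech_model_config")
}

#' Fit a regressor and predict on test rows
#'
#' @param config a `cogspeech_model_config`.
#' @param train_x,train_y training features and targets.
#' @param test_x test features (no overlap with training rows).
#' @return list with `predictions` (numeric) and `model` (fitted object or
#'   NULL for dummies).
#' @export
fit_predict <- function(config, train_x, train_y, test_x) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (any(is.na(train_x)) || any(is.na(test_x))) {
    cs_stop("feature matrices must not contain NA (preprocess first)",
            "cogspeech_validation_error")
  }
  switch(config$model,
    dummy_mean = list(predictions = rep(mean(train_y), nrow(test_x)),
                      model = NULL),
    dummy_random = list(
      predictions = with_seed(config$seed,
        sample(train_y, nrow(test_x), replace = TRUE)),
      model = NULL),
    svr = {
      fit <- with_seed(config$seed,
        e1071::svm(x = train_x, y = train_y, type = "eps-regression",
                   kernel = config$kernel, cost = config$C,
                   epsilon = config$epsilon, scale = FALSE))
      list(predictions = as.numeric(stats::predict(fit, test_x)), model = fit)
    },
    random_forest = {
      fit <- with_seed(config$seed,
        randomForest::randomForest(x = train_x, y = train_y,
                                   ntree = config$ntree))
      list(predictions = as.numeric(stats::predict(fit, test_x)), model = fit)
    })
}

# --- metrics ----------------------------------------------------------------

.r_squared <- function(truth, pred) {
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  1 - ss_res / ss_tot
}

#' Regression metric set
#'
#' Coefficient of determination (1 minus the ratio of squared residual to
#' squared total deviation), Spearman rank correlation with average-rank
#' ties, and mean absolute error.
#'
#' @param truth,pred numeric vectors (at least 2 values).
#' @return list with `r_squared`, `spearman_rho`, `mae`, `n`, and
#'   `valid` (FALSE when the truth is constant, in which case `r_squared`
#'   and `spearman_rho` are NA).
#' @export
evaluate_predictions <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 2)
  constant <- stats::sd(truth) < 1e-14
  list(
    r_squared = if (constant) NA_real_ else .r_squared(truth, pred),
    spearman_rho = if (constant || stats::sd(pred) < 1e-14) NA_real_ else
      stats::cor(truth, pred, method = "spearman"),
    mae = mean(abs(truth - pred)),
    n = length(truth),
    valid = !constant
  )
}

#' Percentile bootstrap confidence interval for a prediction metric
#'
#' Participant-level resampling with replacement; resamples with constant
#' truth are redrawn (counted, capped at 10 times `n_boot`).
#'
#' @param truth,pred paired vectors (>= 10 predictions).
#' @param metric which metric to bootstrap.
#' @param n_boot resample count.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `level`, `point`, `n_redrawn`.
#' @export
bootstrap_metric_ci <- function(truth, pred,
                                metric = c("r_squared", "spearman_rho", "mae"),
                                n_boot = 1000L, level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  n <- length(truth)
  if (n < 10L) cs_stop("need at least 10 predictions", "cogspeech_validation_error")
  point <- evaluate_predictions(truth, pred)[[metric]]
  with_seed(seed, {
    vals <- numeric(n_boot)
    redrawn <- 0L
    cap <- 10L * n_boot
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(truth[idx]) < 1e-14) {
        redrawn <- redrawn + 1L
        if (redrawn > cap) cs_stop("too many degenerate resamples",
                                   "cogspeech_validation_error")
        next
      }
      vals[b] <- evaluate_predictions(truth[idx], pred[idx])[[metric]]
      b <- b + 1L
    }
    alpha <- (1 - level) / 2
    q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
    list(lower = q[1], upper = q[2], level = level, point = point,
         n_redrawn = redrawn)
  })
}

#' Paired bootstrap superiority test
#'
#' Resamples participants with replacement and computes the metric
#' difference (A minus B) per resample; the improvement is significant when
#' at least `prop` of the differences are greater than zero.
#'
#' @param truth shared true scores.
#' @param pred_a,pred_b paired predictions on the same participants.
#' @param metric metric to compare.
#' @param n_boot resample count.
#' @param prop significance proportion (default 0.95).
#' @param seed integer seed.
#' @return list with `fraction_positive`, `significant`, `mean_difference`.
#' @export
bootstrap_superiority_test <- function(truth, pred_a, pred_b,
                                       metric = "r_squared",
                                       n_boot = 1000L, prop = 0.95, seed = 1L) {
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth)) {
    cs_stop("predictions must be paired on identical participants",
            "cogspeech_validation_error")
  }
  n <- length(truth)
  with_seed(seed, {
    diffs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      while (stats::sd(truth[idx]) < 1e-14) idx <- sample.int(n, n, TRUE)
      ma <- evaluate_predictions(truth[idx], pred_a[idx])[[metric]]
      mb <- evaluate_predictions(truth[idx], pred_b[idx])[[metric]]
      diffs[b] <- ma - mb
    }
    list(fraction_positive = mean(diffs > 0),
         significant = mean(diffs > 0) >= prop,
         mean_difference = mean(diffs))
  })
}

#' Metrics within demographic subgroups
#'
#' @param truth,pred paired vectors.
#' @param groups factor/character vector of group labels.
#' @param low_n groups smaller than this are flagged.
#' @return data.frame with one row per group: n, r_squared, spearman_rho,
#'   mae, low_n flag.
#' @export
subgroup_metrics <- function(truth, pred, groups, low_n = 20L) {
  stopifnot(length(groups) == length(truth))
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    sel <- groups == g
    m <- evaluate_predictions(truth[sel], pred[sel])
    data.frame(group = g, n = sum(sel), r_squared = m$r_squared,
               spearman_rho = m$spearman_rho, mae = m$mae,
               low_n = sum(sel) < low_n)
  })
  do.call(rbind, out)
}

# --- cross-validation driver ------------------------------------------------

#' Cross-validated predictions with leakage-safe preprocessing
#'
#' For each fold, the feature transform and the model are fitted on the
#' training folds only; predictions are pooled over the union of the fold
#' test sets.
#'
#' @param X feature matrix with rownames = participant ids.
#' @param y named target vector.
#' @param folds named fold assignment from [make_cv_folds()].
#' @param config a `cogspeech_model_config`.
#' @return data.frame (participant_id, truth, prediction, fold).
#' @export
cross_validate <- function(X, y, folds, config = model_config()) {
  X <- as.matrix(X)
  ids <- rownames(X)
  stopifnot(!is.null(ids), !is.null(names(folds)), !is.null(names(y)))
  out <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    test_ids <- names(folds)[folds == f]
    train_ids <- setdiff(ids, test_ids)
    pp <- preprocess_fold_features(X[train_ids, , drop = FALSE],
                                   X[test_ids, , drop = FALSE])
    cfg_f <- config
    cfg_f$seed <- child_seed(config$seed, paste0("fold", f))
    fp <- fit_predict(cfg_f, pp$train, y[train_ids], pp$apply)
    out[[f]] <- data.frame(participant_id = test_ids, truth = y[test_ids],
                           prediction = fp$predictions, fold = f,
                           row.names = NULL)
  }
  do.call(rbind, out)
}
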