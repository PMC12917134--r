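make_demo_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             age = rnorm(n, 65, 5),
             country = sample(c("UK", "USA"), n, TRUE),
             gender = sample(c("female", "male"), n, TRUE),
             education = sample(c("high", "low"), n, TRUE),
             mean_composite = rnorm(n))
}

test_that("the stratified holdout split has exact sizes and balance", {
  d <- make_demo_frame(985, seed = 2)
  sp <- suppressWarnings(
    make_holdout_split(d, strat_vars = c("age", "country", "gender",
                                         "education", "mean_composite"),
                       seed = 4))
  expect_length(sp$development, 788)
  expect_length(sp$holdout, 197)
  expect_length(intersect(sp$development, sp$holdout), 0)
  # per-stratum development fraction within 5 points of 80% (large strata)
  strata <- cogspeech:::.stratum_labels(d, c("country", "gender", "education"))
  for (l in levels(strata)) {
    ids <- d$participant_id[strata == l]
    if (length(ids) < 50) next
    frac <- mean(ids %in% sp$development)
    expect_lt(abs(frac - 0.8), 0.05)
  }
  # determinism
  sp2 <- suppressWarnings(
    make_holdout_split(d, strat_vars = c("age", "country", "gender",
                                         "education", "mean_composite"),
                       seed = 4))
  expect_identical(sp, sp2)
})

test_that("participants missing stratification data are excluded and listed", {
  d <- make_demo_frame(100, seed = 3)
  d$age[c(4, 9)] <- NA
  sp <- suppressWarnings(make_holdout_split(d, seed = 1))
  expect_setequal(sp$excluded, d$participant_id[c(4, 9)])
  expect_length(c(sp$development, sp$holdout), 98)
})

test_that("cv folds partition the development set with balanced sizes", {
  d <- make_demo_frame(788, seed = 5)
  f <- make_cv_folds(d, k = 10, seed = 2)
  expect_setequal(names(f), d$participant_id)
  expect_true(all(table(f) %in% c(78, 79)))
  expect_identical(f, make_cv_folds(d, k = 10, seed = 2))
  expect_error(make_cv_folds(d$participant_id[1:5], k = 10),
               class = "cogspeech_validation_error")
})

test_that("fold preprocessing standardizes by train statistics only", {
  set.seed(6)
  train <- matrix(rnorm(200 * 3, 10, 2), 200, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  apply_m <- matrix(14, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  pp <- preprocess_fold_features(train, apply_m)
  # (14 - train mean) / train sd, per column
  expect_equal(as.numeric(pp$apply),
               (14 - pp$transform$center) / pp$transform$scale,
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(pp$train)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(pp$train, 2, sd)), rep(1, 3), tolerance = 1e-10)
})

test_that("no statistic of the apply set influences the fitted transform", {
  set.seed(7)
  train <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  apply1 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  apply2 <- apply1[sample(10), ] * 100
  colnames(apply2) <- colnames(apply1)
  pp1 <- preprocess_fold_features(train, apply1)
  pp2 <- preprocess_fold_features(train, apply2)
  expect_identical(pp1$transform, pp2$transform)
  expect_identical(pp1$train, pp2$train)
})

test_that("constant training features are dropped with a warning", {
  train <- cbind(a = rnorm(50), k = rep(2, 50))
  expect_warning(tr <- fit_feature_transform(train), "constant")
  expect_identical(tr$columns, "a")
})

test_that("dummy and SVR regressors honour their contracts", {
  cfg_mean <- model_config("dummy_mean")
  X <- matrix(0, 3, 1); Xt <- matrix(0, 4, 1)
  expect_equal(fit_predict(cfg_mean, X, c(1, 2, 3), Xt)$predictions,
               rep(2, 4))
  cfg_rand <- model_config("dummy_random", seed = 3)
  pr <- fit_predict(cfg_rand, X, c(1, 2, 3), Xt)$predictions
  expect_true(all(pr %in% c(1, 2, 3)))
  expect_identical(pr, fit_predict(cfg_rand, X, c(1, 2, 3), Xt)$predictions)

  # SVR learns a noiseless function
  set.seed(8)
  x <- matrix(sort(runif(200, -2, 2)), ncol = 1, dimnames = list(NULL, "x"))
  y <- x[, 1]
  test_x <- matrix(runif(50, -1.8, 1.8), ncol = 1, dimnames = list(NULL, "x"))
  p <- fit_predict(model_config("svr", C = 10), x, y, test_x)$predictions
  expect_gt(evaluate_predictions(test_x[, 1], p)$r_squared, 0.95)

  expect_error(fit_predict(cfg_mean, matrix(NA_real_, 2, 1), 1:2, Xt),
               class = "cogspeech_validation_error")
})

test_that("metrics match hand values and brute-force oracles", {
  m <- evaluate_predictions(c(1, 2, 3, 4), c(2, 2, 3, 3))
  expect_equal(m$r_squared, 0.6)
  expect_equal(m$mae, 0.5)
  ident <- evaluate_predictions(1:5, 1:5)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$spearman_rho, 1)
  expect_equal(ident$mae, 0)
  mean_pred <- evaluate_predictions(c(1, 2, 3, 6), rep(3, 4))
  expect_equal(mean_pred$r_squared, 0)
  const <- evaluate_predictions(rep(1, 4), c(1, 2, 1, 2))
  expect_false(const$valid)
  expect_true(is.na(const$r_squared))

  set.seed(9)
  for (r in 1:10) {
    n <- sample(10:200, 1)
    truth <- rnorm(n); pred <- truth * 0.5 + rnorm(n)
    m <- evaluate_predictions(truth, pred)
    expect_equal(m$r_squared, oracle_r_squared(truth, pred), tolerance = 1e-10)
    expect_equal(m$mae, oracle_mae(truth, pred), tolerance = 1e-10)
    expect_equal(m$spearman_rho, oracle_spearman(truth, pred), tolerance = 1e-10)
    # ties: average-rank convention
    tied <- round(pred)
    expect_equal(evaluate_predictions(truth, tied)$spearman_rho,
                 oracle_spearman(truth, tied), tolerance = 1e-10)
  }
})

test_that("bootstrap confidence intervals are ordered, seeded and calibrated", {
  set.seed(10)
  truth <- rnorm(200); pred <- truth + rnorm(200, 0, 0.5)
  ci <- bootstrap_metric_ci(truth, pred, "r_squared", n_boot = 300, seed = 5)
  expect_lte(ci$lower, ci$upper)
  expect_identical(ci,
                   bootstrap_metric_ci(truth, pred, "r_squared",
                                       n_boot = 300, seed = 5))
  perfect <- bootstrap_metric_ci(truth, truth, "r_squared", n_boot = 100,
                                 seed = 1)
  expect_equal(c(perfect$lower, perfect$upper), c(1, 1))

  # coverage of the true MAE at nominal 95%
  true_mae <- 0.5 * sqrt(2 / pi)
  hits <- 0
  for (s in 1:60) {
    set.seed(400 + s)
    tr <- rnorm(200); pr <- tr + rnorm(200, 0, 0.5)
    ci <- bootstrap_metric_ci(tr, pr, "mae", n_boot = 200, seed = s)
    if (ci$lower <= true_mae && true_mae <= ci$upper) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.85)
})

test_that("the paired superiority test detects planted improvements", {
  set.seed(11)
  n <- 500
  truth <- rnorm(n)
  good <- truth * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))   # R2 ~ 0.5
  flat <- rep(mean(truth), n)                          # R2 ~ 0
  res <- bootstrap_superiority_test(truth, good, flat, n_boot = 500, seed = 2)
  expect_true(res$significant)
  same <- bootstrap_superiority_test(truth, good, good, n_boot = 200, seed = 3)
  expect_false(same$significant)
  expect_error(bootstrap_superiority_test(truth, good[-1], flat),
               class = "cogspeech_validation_error")
})

test_that("subgroup metrics partition cleanly", {
  set.seed(12)
  truth <- rnorm(120); pred <- truth + rnorm(120, 0, 0.6)
  g <- rep(c("UK", "USA"), each = 60)
  sm <- subgroup_metrics(truth, pred, g)
  expect_equal(sum(sm$n), 120)
  one <- subgroup_metrics(truth, pred, rep("all", 120))
  expect_equal(one$r_squared, evaluate_predictions(truth, pred)$r_squared)
  small <- subgroup_metrics(truth, pred, c(rep("a", 110), rep("b", 10)))
  expect_true(small$low_n[small$group == "b"])
})

test_that("exact Shapley satisfies local accuracy, linearity and null players", {
  set.seed(13)
  X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  f <- function(M) 2 * M[, 1] + 0.5 * M[, 4]
  inst <- X[1:4, , drop = FALSE]
  sh <- shapley_attributions(f, X, inst)
  expect_true(sh$exact)
  expect_equal(sh$base_value + rowSums(sh$attributions), f(inst),
               tolerance = 1e-6, ignore_attr = TRUE)
  # closed form for linear models: phi_j = beta_j (x_j - mean background_j)
  expect_equal(sh$attributions[, 1], 2 * (inst[, 1] - mean(X[, 1])),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(max(abs(sh$attributions[, 2])), 0, tolerance = 1e-12)
  # global importance reflects the coefficients
  expect_gt(sh$global_importance[["f1"]], sh$global_importance[["f4"]])
})

test_that("cross-validation pools out-of-fold predictions only", {
  sim <- simulate_feature_signal(120, p = 3, r2 = 0.4, seed = 14)
  ids <- sprintf("P%04d", 1:120)
  rownames(sim$X) <- ids; names(sim$y) <- ids
  folds <- make_cv_folds(ids, k = 4, seed = 1)
  cv <- cross_validate(sim$X, sim$y, folds, model_config("svr", folds = 4))
  expect_setequal(cv$participant_id, ids)
  expect_equal(nrow(cv), 120)
  expect_equal(sort(unique(cv$fold)), 1:4)
  # each participant predicted exactly once, in their own fold
  expect_equal(unname(folds[cv$participant_id]), cv$fold)
})
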