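test_that("sign harmonization flips exactly the reverse-scored columns", {
  X <- matrix(1, 2, 3,
              dimnames = list(NULL, c("semantic_fluency", "tmt_a_time",
                                      "tol_extra_moves")))
  H <- harmonize_test_scores(X)
  expect_equal(H[, "semantic_fluency"], c(1, 1))
  expect_equal(H[, "tmt_a_time"], c(-1, -1))
  expect_equal(H[, "tol_extra_moves"], c(-1, -1))
})

test_that("demographic-regression outliers are flagged and clean data is not", {
  set.seed(5)
  n <- 1000
  demo <- data.frame(age = rnorm(n, 65, 5),
                     gender = sample(c("female", "male"), n, TRUE),
                     country = sample(c("UK", "USA"), n, TRUE),
                     education = sample(c("high", "low"), n, TRUE))
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("t", 1:3)))
  X[5, 1] <- 10 * sd(X[, 1])
  fl <- flag_outliers_by_demographic_regression(X, demo)
  expect_true(fl$flags[5, 1])
  # Gaussian columns: expected flags ~ n * 2 * pnorm(-4) ~ 0.06 per column
  expect_lte(sum(fl$n_flagged) - 1, 2)
  # constant column produces no flags
  Xc <- cbind(X[, 1, drop = FALSE], const = rep(3, n))
  flc <- flag_outliers_by_demographic_regression(Xc, demo)
  expect_equal(unname(flc$n_flagged[["const"]]), 0)
})

test_that("round-robin imputation recovers exact linear structure", {
  A <- seq(0, 5, length.out = 60)
  B <- 2 * A
  X <- cbind(A = A, B = B)
  X[13, "B"] <- NA  # A = ~1.02 there
  done <- impute_round_robin(X)
  expect_equal(unname(done[13, "B"]), 2 * A[13], tolerance = 1e-2)
  # observed cells never altered
  expect_identical(done[-13, ], X[-13, ])
  # no missing: unchanged
  expect_identical(impute_round_robin(cbind(A, B)), cbind(A, B))
  # all-missing column rejected
  bad <- cbind(A, C = rep(NA_real_, 60))
  expect_error(impute_round_robin(bad), class = "cogspeech_validation_error")
})

test_that("MCAR imputation beats mean imputation and nears the optimum", {
  set.seed(9)
  n <- 400
  f <- rnorm(n)
  X <- sapply(1:5, function(j) 0.8 * f + rnorm(n, 0, 0.6))
  colnames(X) <- paste0("t", 1:5)
  mask <- matrix(runif(n * 5) < 0.05, n, 5)
  Xm <- X; Xm[mask] <- NA
  done <- impute_round_robin(Xm)
  rmse <- sqrt(mean((done[mask] - X[mask])^2))
  # mean imputation would err at the marginal sd, sqrt(0.8^2 + 0.6^2) = 1;
  # the best linear predictor from the other four indicators has rmse
  # sqrt(1 - 4 c^2 / (1 + 3 c)) with inter-item correlation c = 0.64
  expect_lt(rmse, 1)
  optimum <- sqrt(1 - 4 * 0.64^2 / (1 + 3 * 0.64))
  expect_lt(rmse, optimum * 1.1)
})

test_that("CFA recovers loadings and factor correlations from simulated data", {
  cfg <- null_demo_config(n_participants = 4000, seed = 13, missing_rate = 0,
                          outlier_rate = 0)
  co <- generate_cohort(cfg)
  fit <- fit_factor_model(harmonize_test_scores(co$test_scores),
                          factor_model_spec())
  expect_true(fit$converged)
  L <- cfg$loading_matrix
  true_sd <- sqrt(diag(L %*% cfg$domain_corr %*% t(L)) + cfg$noise_sd^2)
  expect_lt(max(abs(fit$loadings - L / true_sd)), 0.05)
  expect_lt(max(abs(fit$factor_corr - cfg$domain_corr)), 0.06)
  # factor scores track the generating latents
  expect_true(all(diag(cor(fit$factor_scores, co$latent_domains)) > 0.8))
  # the true model fits: CFI near 1, RMSEA near 0
  expect_gt(fit$fit_indices[["cfi"]], 0.99)
  expect_lt(fit$fit_indices[["rmsea"]], 0.02)
})

test_that("a just-identified single-factor model reaches CFI 1", {
  set.seed(14)
  f <- rnorm(800)
  X <- sapply(1:3, function(j) 0.7 * f + rnorm(800, 0, 0.7))
  colnames(X) <- paste0("y", 1:3)
  pat <- matrix(0.7, 3, 1, dimnames = list(colnames(X), "g"))
  fit <- fit_factor_model(X, factor_model_spec(pat))
  expect_equal(fit$fit_indices[["cfi"]], 1, tolerance = 1e-6)
  expect_lt(abs(fit$fit_indices[["chisq"]]), 1e-4)
})

test_that("standardization is exact, idempotent and affine invariant", {
  x <- matrix(c(1, 2, 3, 10, 20, 33), 3, 2, dimnames = list(NULL, c("a", "b")))
  s <- standardize_columns(x)
  expect_equal(unname(colMeans(s)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(standardize_columns(s), s, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(standardize_columns(3 * x + 7), s, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize_columns(cbind(x, k = c(1, 1, 1))),
               class = "cogspeech_validation_error")
})

test_that("the composite pipeline is deterministic and leaves observed cells alone", {
  cfg <- cohort_config(n_participants = 300, seed = 17)
  co <- generate_cohort(cfg)
  a <- compute_composite_scores(co$test_scores, co$demographics)
  b <- compute_composite_scores(co$test_scores, co$demographics)
  expect_identical(a$composites, b$composites)
  expect_equal(unname(colMeans(a$composites)), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(apply(a$composites, 2, sd)), rep(1, 4), tolerance = 1e-8)
})
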