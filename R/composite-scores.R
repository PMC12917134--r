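# From individual test scores to the four standardized cognitive
# composites: sign harmonization, demographic-regression outlier removal,
# round-robin ridge imputation, confirmatory factor analysis (maximum
# likelihood, fixed loading pattern), regression-method factor scores, and
# column standardization.

#' Sign-harmonize a test-score table (higher = better)
#'
#' @param scores matrix/data.frame of raw test scores.
#' @param negative_columns columns to flip (defaults to the battery's
#'   completion-time columns and the extra-moves count).
#' @return numeric matrix with flipped columns.
#' @export
harmonize_test_scores <- function(scores,
                                  negative_columns = negative_test_columns()) {
  X <- as.matrix(scores)
  flip <- intersect(negative_columns, colnames(X))
  X[, flip] <- -X[, flip]
  X
}

#' Flag outliers by demographic regression
#'
#' Per test column, fits ordinary least squares on age, gender, education
#' and country, standardizes residuals, and replaces cells with
#' `|z| > z_cap` by missing values. Columns with zero residual variance
#' produce no flags; columns with fewer than `min_obs` observed values are
#' skipped with a warning.
#'
#' @param scores participants x tests matrix (harmonized orientation).
#' @param demographics data.frame with age, gender, country, education.
#' @param z_cap absolute standardized-residual threshold (default 4).
#' @param min_obs minimum observed values per column.
#' @return list with `scores` (flagged cells set NA), `flags` (logical
#'   matrix), `n_flagged` (per-test counts).
#' @export
flag_outliers_by_demographic_regression <- function(scores, demographics,
                                                    z_cap = 4, min_obs = 10L) {
  X <- as.matrix(scores)
  D <- .demographic_design(demographics)
  if (any(is.na(D))) {
    cs_stop("demographics must be complete for outlier regression",
            "cogspeech_validation_error")
  }
  flags <- matrix(FALSE, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    obs <- which(!is.na(X[, j]))
    if (length(obs) < min_obs) {
      cs_warn(sprintf("column '%s' has < %d observed values; skipped",
                      colnames(X)[j], min_obs))
      next
    }
    fit <- stats::lm.fit(D[obs, , drop = FALSE], X[obs, j])
    rsd <- stats::sd(fit$residuals)
    if (!is.finite(rsd) || rsd < 1e-12) next
    z <- fit$residuals / rsd
    flags[obs[abs(z) > z_cap], j] <- TRUE
  }
  X[flags] <- NA_real_
  list(scores = X, flags = flags, n_flagged = colSums(flags))
}

#' Round-robin ridge imputation
#'
#' Iteratively regresses each column with missing values on all other score
#' columns (ridge penalty `lambda`), visiting columns in fixed left-to-right
#' order, starting from column-mean initialization, until the largest change
#' of any imputed cell is below `tol` or `max_iter` sweeps.
#'
#' @param scores participants x tests matrix with missing cells.
#' @param max_iter maximum sweeps.
#' @param tol convergence tolerance on imputed values.
#' @param lambda ridge penalty (small, for numerical stability).
#' @return completed numeric matrix; observed cells are never altered.
#' @export
impute_round_robin <- function(scores, max_iter = 20L, tol = 1e-4,
                               lambda = 1e-3) {
  X <- as.matrix(scores)
  miss <- is.na(X)
  if (!any(miss)) return(X)
  if (any(colSums(!miss) < 2L)) {
    cs_stop("every column needs at least 2 observed values",
            "cogspeech_validation_error")
  }
  if (any(rowSums(!miss) < 1L)) {
    cs_stop("every row needs at least 1 observed value",
            "cogspeech_validation_error")
  }
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- mu[j]
  for (it in seq_len(max_iter)) {
    max_change <- 0
    for (j in seq_len(ncol(X))) {
      rows <- which(miss[, j])
      if (!length(rows)) next
      obs <- which(!miss[, j])
      A <- cbind(1, X[obs, -j, drop = FALSE])
      y <- X[obs, j]
      P <- diag(c(0, rep(lambda, ncol(A) - 1L)), nrow = ncol(A))
      beta <- solve(crossprod(A) + P, crossprod(A, y))
      pred <- cbind(1, X[rows, -j, drop = FALSE]) %*% beta
      max_change <- max(max_change, max(abs(pred - X[rows, j])))
      X[rows, j] <- pred
    }
    if (max_change < tol) break
  }
  X
}

#' Factor model specification
#'
#' @param loading_pattern tests x factors matrix of 0/1 (or starting
#'   values); nonzero entries are free loadings.
#' @return a `cogspeech_factor_spec`.
#' @export
factor_model_spec <- function(loading_pattern = default_loading_matrix()) {
  P <- as.matrix(loading_pattern)
  if (any(rowSums(P != 0) == 0)) {
    cs_stop("every test must load on at least one factor",
            "cogspeech_validation_error")
  }
  structure(list(pattern = P != 0, start = ifelse(P != 0, pmax(abs(P), 0.3), 0),
                 tests = rownames(P), factors = colnames(P)),
            class = "cogspeech_factor_spec")
}

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p
.cfa_objective <- function(par, S, pattern, n_load, p, q) {
  est <- .cfa_unpack(par, pattern, p, q)
  Sigma <- est$L %*% est$Phi %*% t(est$L) + diag(est$theta, p)
  ev <- determinant(Sigma, logarithm = TRUE)
  if (ev$sign <= 0) return(1e10)
  val <- as.numeric(ev$modulus) + sum(diag(solve(Sigma, S))) -
    as.numeric(determinant(S, logarithm = TRUE)$modulus) - p
  if (!is.finite(val)) 1e10 else val
}

.cfa_unpack <- function(par, pattern, p, q) {
  n_load <- sum(pattern)
  n_corr <- q * (q - 1L) / 2L
  L <- matrix(0, p, q)
  L[pattern] <- par[seq_len(n_load)]
  lt <- par[n_load + seq_len(n_corr)]
  theta <- exp(par[n_load + n_corr + seq_len(p)])
  # factor correlation via row-normalized Cholesky factor
  C <- diag(q)
  if (n_corr > 0) C[lower.tri(C)] <- lt
  C <- C / sqrt(rowSums(C^2))
  list(L = L, Phi = C %*% t(C), theta = theta)
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Standardizes the indicators, minimizes the ML discrepancy function over
#' the free loadings, factor correlations (unit factor variances) and
#' residual variances under the fixed loading pattern, and returns fit
#' indices (CFI, TLI, RMSEA against the independence baseline) and
#' regression-method factor scores
#' \eqn{\hat F = (X - \bar X) \Sigma^{-1} \Lambda \Phi}.
#'
#' @param scores complete participants x tests matrix (harmonized).
#' @param spec a `cogspeech_factor_spec`.
#' @param max_restarts extra random restarts if the first fit does not
#'   converge.
#' @return a `cogspeech_factor_fit`: list with `loadings`, `factor_corr`,
#'   `residual_var`, `fit_indices` (chisq, df, cfi, tli, rmsea),
#'   `factor_scores`, `heywood` (logical), `converged`.
#' @export
fit_factor_model <- function(scores, spec, max_restarts = 3L) {
  stopifnot(inherits(spec, "cogspeech_factor_spec"))
  X <- as.matrix(scores)[, spec$tests, drop = FALSE]
  if (any(is.na(X))) {
    cs_stop("scores must be complete (impute first)", "cogspeech_validation_error")
  }
  n <- nrow(X); p <- ncol(X); q <- length(spec$factors)
  Xs <- scale(X)
  S <- stats::cov(Xs)
  pattern <- spec$pattern
  n_load <- sum(pattern)
  n_par_total <- n_load + q * (q - 1L) / 2L + p
  if (n <= n_par_total) {
    cs_stop("more free parameters than participants", "cogspeech_validation_error")
  }
  start <- c(spec$start[pattern], rep(0.3, q * (q - 1L) / 2L),
             rep(log(0.5), p))
  best <- NULL
  for (r in 0:max_restarts) {
    par0 <- if (r == 0) start else
      with_seed(1000 + r, start + stats::rnorm(length(start), 0, 0.1))
    obj <- function(par) .cfa_objective(par, S, pattern, n_load, p, q)
    opt <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$value < 1e9 && best$convergence == 0) break
  }
  if (best$value >= 1e9) {
    cs_stop("factor model did not converge (non-PD implied covariance)",
            "cogspeech_convergence_error")
  }
  est <- .cfa_unpack(best$par, pattern, p, q)
  # orient factors so the largest loading of each is positive
  for (k in seq_len(q)) {
    if (sum(est$L[, k]) < 0) {
      est$L[, k] <- -est$L[, k]
      est$Phi[k, ] <- -est$Phi[k, ]
      est$Phi[, k] <- -est$Phi[, k]
      diag(est$Phi) <- 1
    }
  }
  heywood <- any(est$theta < 1e-6) || any(abs(est$L) > 1)
  if (heywood) cs_warn("Heywood case: residual variance near zero or |loading| > 1")
  Sigma <- est$L %*% est$Phi %*% t(est$L) + diag(est$theta, p)
  chisq <- (n - 1) * best$value
  df <- p * (p + 1) / 2 - n_par_total
  # independence baseline
  f_base <- sum(log(diag(S))) - as.numeric(determinant(S, TRUE)$modulus) +
    sum(diag(solve(diag(diag(S)), S))) - p
  chisq_b <- (n - 1) * f_base
  df_b <- p * (p - 1) / 2
  cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, .Machine$double.eps)
  tli <- (chisq_b / df_b - chisq / df) / (chisq_b / df_b - 1)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  fscores <- Xs %*% solve(Sigma, est$L %*% est$Phi)
  colnames(fscores) <- spec$factors
  dimnames(est$L) <- list(spec$tests, spec$factors)
  dimnames(est$Phi) <- list(spec$factors, spec$factors)
  structure(list(
    loadings = est$L, factor_corr = est$Phi,
    residual_var = stats::setNames(est$theta, spec$tests),
    fit_indices = c(chisq = chisq, df = df, cfi = cfi, tli = tli,
                    rmsea = rmsea),
    factor_scores = fscores, heywood = heywood,
    converged = best$convergence == 0
  ), class = "cogspeech_factor_fit")
}

#' Standardize composite-score columns
#'
#' @param scores numeric matrix/data.frame with non-constant columns.
#' @return matrix with column mean 0 and sd 1.
#' @export
standardize_columns <- function(scores) {
  X <- as.matrix(scores)
  sds <- apply(X, 2, stats::sd)
  if (any(!is.finite(sds) | sds < 1e-12)) {
    cs_stop("cannot standardize a constant column", "cogspeech_validation_error")
  }
  scale(X)[, , drop = FALSE]
}

#' Compute the four standardized cognitive composites from raw test scores
#'
#' Convenience orchestrator: harmonize, flag outliers against demographic
#' regressions, impute round-robin, fit the factor model, standardize the
#' factor scores.
#'
#' @param scores raw participants x tests matrix.
#' @param demographics demographics data.frame.
#' @param spec a `cogspeech_factor_spec`.
#' @param z_cap outlier threshold.
#' @return list with `composites` (n x 4 standardized matrix), `fit`,
#'   `outliers` (flag report).
#' @export
compute_composite_scores <- function(scores, demographics,
                                     spec = factor_model_spec(), z_cap = 4) {
  H <- harmonize_test_scores(scores)
  fl <- flag_outliers_by_demographic_regression(H, demographics, z_cap = z_cap)
  Xc <- impute_round_robin(fl$scores)
  fit <- fit_factor_model(Xc, spec)
  comp <- standardize_columns(fit$factor_scores)
  list(composites = comp, fit = fit, outliers = fl)
}
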