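# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed validation error
#' @noRd
cs_stop <- function(msg, class = "cogspeech_error", ...) {
  stop(structure(
    class = c(class, "cogspeech_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

cs_warn <- function(msg) warning(msg, call. = FALSE)

#' Population standard deviation (denominator n)
#' @noRd
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Check a square matrix is a valid correlation matrix (symmetric PD, unit diag)
#' @noRd
check_corr_matrix <- function(m, name = "correlation matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    cs_stop(sprintf("%s must be a square matrix", name), "cogspeech_validation_error")
  }
  if (max(abs(m - t(m))) > tol) {
    cs_stop(sprintf("%s must be symmetric", name), "cogspeech_validation_error")
  }
  if (max(abs(diag(m) - 1)) > tol) {
    cs_stop(sprintf("%s must have unit diagonal", name), "cogspeech_validation_error")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol) {
    cs_stop(sprintf("%s must be positive definite (min eigenvalue %.3g)", name, min(ev)),
            "cogspeech_validation_error")
  }
  invisible(TRUE)
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    cs_stop(sprintf("%s must be a single number in [0, 1]", name),
            "cogspeech_validation_error")
  }
  invisible(TRUE)
}

#' Derive a reproducible child seed from a base seed and a stream label
#'
#' Keeps derived seeds in the 32-bit integer range.
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Evaluate an expression under a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
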