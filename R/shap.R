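# Shapley additive attributions with background-marginal value functions.
# For p <= max_exact features the estimator enumerates all feature
# coalitions, so local accuracy (base value plus attributions equals the
# model prediction) holds to numerical precision; larger p falls back to a
# seeded permutation-sampling estimator.

.predict_fun <- function(model) {
  if (is.function(model)) return(model)
  function(X) as.numeric(stats::predict(model, as.matrix(X)))
}

#' Shapley attributions for model predictions
#'
#' The value of a coalition S is the mean model output over the background
#' rows with the instance's values substituted on S. Attributions use the
#' exact Shapley weights for `p <= max_exact` features, otherwise a
#' permutation-sampling estimate with `n_perm` seeded permutations.
#'
#' @param model fitted model accepted by `predict`, or a function
#'   `X -> numeric`.
#' @param background matrix/data.frame of background rows (non-empty).
#' @param instances matrix/data.frame of rows to explain (same columns).
#' @param max_exact largest p for exact enumeration.
#' @param n_perm permutations for the sampling fallback.
#' @param seed integer seed (sampling fallback only).
#' @return list with `attributions` (instances x features), `base_value`
#'   (mean background prediction), `global_importance` (mean |value| per
#'   feature), `exact` (logical).
#' @export
shapley_attributions <- function(model, background, instances,
                                 max_exact = 12L, n_perm = 64L, seed = 1L) {
  f <- .predict_fun(model)
  B <- as.matrix(background)
  Xi <- as.matrix(instances)
  if (nrow(B) == 0L) cs_stop("background must be non-empty",
                             "cogspeech_validation_error")
  if (!identical(colnames(B), colnames(Xi))) {
    cs_stop("instances and background must share the feature schema",
            "cogspeech_validation_error")
  }
  p <- ncol(B)
  nb <- nrow(B)
  base_value <- mean(f(B))
  phi <- matrix(0, nrow(Xi), p, dimnames = list(rownames(Xi), colnames(Xi)))
  if (p <= max_exact) {
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
    sizes <- rowSums(subsets)
    fact <- factorial(0:p)
    for (i in seq_len(nrow(Xi))) {
      # v(S) for every coalition: substitute instance values on S in all
      # background rows, average the prediction
      v <- numeric(nrow(subsets))
      for (s in seq_len(nrow(subsets))) {
        M <- B
        on <- which(subsets[s, ])
        if (length(on)) M[, on] <- matrix(Xi[i, on], nb, length(on), byrow = TRUE)
        v[s] <- mean(f(M))
      }
      key <- as.integer(subsets %*% 2^(seq_len(p) - 1L))
      vmap <- numeric(2^p); vmap[key + 1L] <- v
      for (j in seq_len(p)) {
        without_j <- which(!subsets[, j])
        s_sizes <- sizes[without_j]
        w <- fact[s_sizes + 1L] * fact[p - s_sizes] / fact[p + 1L]
        k0 <- key[without_j]
        phi[i, j] <- sum(w * (vmap[k0 + 2^(j - 1L) + 1L] - vmap[k0 + 1L]))
      }
    }
  } else {
    with_seed(seed, {
      for (i in seq_len(nrow(Xi))) {
        acc <- numeric(p)
        for (r in seq_len(n_perm)) {
          perm <- sample.int(p)
          M <- B
          v_prev <- base_value
          for (j in perm) {
            M[, j] <- Xi[i, j]
            v_new <- mean(f(M))
            acc[j] <- acc[j] + (v_new - v_prev)
            v_prev <- v_new
          }
        }
        phi[i, ] <- acc / n_perm
      }
    })
  }
  list(attributions = phi, base_value = base_value,
       global_importance = colMeans(abs(phi)), exact = p <= max_exact)
}
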