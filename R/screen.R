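# Normative screening: linear norms of the composite scores given
# demographics, z-score thresholding of low performers, SVM classification
# and ROC / precision-recall evaluation.

#' Fit linear normative models for the composite scores
#'
#' One ordinary-least-squares regression per domain on age, gender,
#' education and country over the full cohort; a participant's z is the
#' residual divided by the residual standard deviation.
#'
#' @param composites n x domains matrix of standardized composite scores.
#' @param demographics data.frame with age, gender, education, country.
#' @return a `cogspeech_normative_model`: list with `coefficients` (per
#'   domain), `residual_sd`, `z` (n x domains matrix).
#' @export
fit_normative_model <- function(composites, demographics) {
  C <- as.matrix(composites)
  D <- .demographic_design(demographics)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) {
    cs_stop(sprintf("singular demographic design (rank %d of %d); check for collinear covariates",
                    qr_d$rank, ncol(D)),
            "cogspeech_validation_error")
  }
  coefs <- qr.coef(qr_d, C)
  res <- C - D %*% coefs
  rsd <- apply(res, 2, stats::sd)
  if (any(rsd <= 0)) cs_stop("zero residual variance", "cogspeech_validation_error")
  z <- sweep(res, 2, rsd, `/`)
  structure(list(coefficients = coefs, residual_sd = rsd, z = z),
            class = "cogspeech_normative_model")
}

#' Label cognitive low performers
#'
#' @param z numeric vector/matrix of normative z-scores.
#' @param threshold z below this is a low performer (default -1.96).
#' @return integer labels (1 = low performer) with the shape of `z`.
#' @export
label_low_performers <- function(z, threshold = -1.96) {
  if (any(!is.finite(z))) cs_stop("z must be finite", "cogspeech_validation_error")
  lab <- (z < threshold) * 1L
  lab
}

#' Fit a binary SVM classifier and score test rows
#'
#' Same preprocessing/fold discipline as the regression harness; returns
#' continuous decision scores (signed margins), oriented so larger means
#' more likely positive.
#'
#' @param config a `cogspeech_model_config` (the SVM mirrors the SVR
#'   kernel/C choices).
#' @param train_x,train_y training features and 0/1 labels (both classes
#'   must be present).
#' @param test_x test features.
#' @return list with `scores` (numeric) and `model`.
#' @export
fit_predict_classifier <- function(config, train_x, train_y, test_x) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (length(unique(train_y)) < 2L) {
    cs_stop(sprintf("training fold has a single class (n=%d, positives=%d)",
                    length(train_y), sum(train_y == 1)),
            "cogspeech_validation_error")
  }
  y <- factor(train_y, levels = c(0, 1))
  fit <- with_seed(config$seed,
    e1071::svm(x = train_x, y = y, type = "C-classification",
               kernel = config$kernel, cost = config$C, scale = FALSE))
  dvm <- attr(stats::predict(fit, test_x, decision.values = TRUE),
              "decision.values")
  dv <- dvm[, 1]
  # decision values are positive toward the first class of the "a/b" label;
  # orient them so larger means more likely positive (class 1)
  if (startsWith(colnames(dvm)[1], "0/")) dv <- -dv
  list(scores = as.numeric(dv), model = fit)
}

#' ROC curve, PR curve and their areas
#'
#' ROC by threshold sweep with trapezoidal area; PR area by average
#' precision (step-wise sum of precision times recall increments).
#' Bootstrap confidence intervals by participant-level resampling.
#'
#' @param scores continuous classifier scores (larger = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @param n_boot bootstrap resamples for the AUC confidence intervals
#'   (0 to skip).
#' @param level confidence level.
#' @param seed integer seed.
#' @return a `cogspeech_screen_result`: list with `roc` (data.frame fpr,
#'   tpr), `pr` (data.frame recall, precision), `roc_auc`, `pr_auc`,
#'   `prevalence`, and optional `roc_auc_ci`, `pr_auc_ci`.
#' @export
classification_curves <- function(scores, labels, n_boot = 1000L,
                                  level = 0.95, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    cs_stop("both classes must be present", "cogspeech_validation_error")
  }
  auc_pair <- function(s, l) {
    o <- order(s, decreasing = TRUE)
    l <- l[o]; s <- s[o]
    P <- sum(l == 1); N <- sum(l == 0)
    # threshold sweep (ties grouped)
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(l == 1); fp <- cumsum(l == 0)
    last <- !duplicated(grp, fromLast = TRUE)
    tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
    roc_auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    prec <- tp[last] / (tp[last] + fp[last])
    rec <- tp[last] / P
    ap <- sum(diff(c(0, rec)) * prec)
    list(roc = data.frame(fpr = fpr, tpr = tpr),
         pr = data.frame(recall = c(0, rec), precision = c(1, prec)),
         roc_auc = roc_auc, pr_auc = ap)
  }
  full <- auc_pair(scores, labels)
  out <- list(roc = full$roc, pr = full$pr, roc_auc = full$roc_auc,
              pr_auc = full$pr_auc, prevalence = mean(labels == 1))
  if (n_boot > 0) {
    n <- length(labels)
    cis <- with_seed(seed, {
      ra <- numeric(n_boot); pa <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        while (length(unique(labels[idx])) < 2L) idx <- sample.int(n, n, TRUE)
        a <- auc_pair(scores[idx], labels[idx])
        ra[b] <- a$roc_auc; pa[b] <- a$pr_auc
      }
      alpha <- (1 - level) / 2
      list(roc = stats::quantile(ra, c(alpha, 1 - alpha), names = FALSE),
           pr = stats::quantile(pa, c(alpha, 1 - alpha), names = FALSE))
    })
    out$roc_auc_ci <- cis$roc
    out$pr_auc_ci <- cis$pr
  }
  structure(out, class = "cogspeech_screen_result")
}
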