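# Frozen-pipeline transfer to an external cohort and group separation
# statistics.

#' Freeze a trained feature transform and regressor per domain
#'
#' @param transforms named list of `cogspeech_feature_transform` (one per
#'   domain, or a single shared transform).
#' @param models named list of fitted regressors (per domain).
#' @param config the `cogspeech_model_config` used for training.
#' @return a `cogspeech_frozen_pipeline`.
#' @export
freeze_pipeline <- function(transforms, models, config) {
  if (inherits(transforms, "cogspeech_feature_transform")) {
    transforms <- stats::setNames(rep(list(transforms), length(models)),
                                  names(models))
  }
  stopifnot(identical(sort(names(transforms)), sort(names(models))))
  structure(list(transforms = transforms, models = models, config = config),
            class = "cogspeech_frozen_pipeline")
}

#' Apply a frozen pipeline to external features
#'
#' No statistic of the external rows enters any fitted component: the
#' frozen transform standardizes and imputes with training constants, and
#' the frozen model predicts. Missing schema columns are an error; extra
#' columns are ignored with a warning.
#'
#' @param pipeline a `cogspeech_frozen_pipeline`.
#' @param features external feature matrix/data.frame.
#' @return matrix of predicted composite scores (rows = external
#'   participants, columns = domains).
#' @export
apply_pretrained <- function(pipeline, features) {
  stopifnot(inherits(pipeline, "cogspeech_frozen_pipeline"))
  X <- as.matrix(features)
  domains <- names(pipeline$models)
  preds <- matrix(NA_real_, nrow(X), length(domains),
                  dimnames = list(rownames(X), domains))
  for (d in domains) {
    tr <- pipeline$transforms[[d]]
    extra <- setdiff(colnames(X), tr$columns)
    if (length(extra)) {
      cs_warn(sprintf("ignoring column(s) not in the training schema: %s",
                      paste(extra, collapse = ", ")))
    }
    Z <- apply_feature_transform(tr, X)
    model <- pipeline$models[[d]]
    preds[, d] <- if (is.function(model)) model(Z) else
      as.numeric(stats::predict(model, Z))
  }
  preds
}

#' Two-group comparison of predicted scores
#'
#' Pooled-variance two-sample t-test and pooled-SD Cohen's d, with the
#' documented sign convention d = (mean control - mean patient) / pooled sd
#' (positive when patients score lower).
#'
#' @param predictions numeric vector of predicted scores.
#' @param groups factor/character with two levels; the first level after
#'   `control_level` ordering is treated as control.
#' @param control_level which group label is the control group.
#' @return list with `d`, `t`, `p_value`, `means`, `n`.
#' @export
group_difference <- function(predictions, groups,
                             control_level = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    cs_stop("exactly two groups required", "cogspeech_validation_error")
  }
  if (!is.null(control_level)) {
    groups <- stats::relevel(groups, ref = control_level)
  }
  g1 <- predictions[groups == levels(groups)[1]]   # control
  g2 <- predictions[groups == levels(groups)[2]]   # patient
  if (length(g1) < 2L || length(g2) < 2L) {
    cs_stop("each group needs at least 2 members", "cogspeech_validation_error")
  }
  n1 <- length(g1); n2 <- length(g2)
  sp <- sqrt(((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
             (n1 + n2 - 2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  list(
    d = (mean(g1) - mean(g2)) / sp,
    t = unname(tt$statistic),
    p_value = tt$p.value,
    means = stats::setNames(c(mean(g1), mean(g2)), levels(groups)),
    n = stats::setNames(c(n1, n2), levels(groups))
  )
}
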