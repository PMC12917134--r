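# Shared fixtures and independent oracles, all built in code.

# Build a cogspeech_tokens object directly from token/tag vectors, bypassing
# the tagger (for worked examples defined on tags).
make_tokens <- function(tokens, tags = rep("NN", length(tokens)),
                        sentence = rep(0L, length(tokens))) {
  out <- data.frame(token = tolower(tokens), lemma = tolower(tokens),
                    tag = tags, sentence = as.integer(sentence),
                    known = TRUE, stringsAsFactors = FALSE)
  attr(out, "n_sentences") <- max(out$sentence) + 1L
  class(out) <- c("cogspeech_tokens", "data.frame")
  out
}

# A cohort configuration with no demographic effects on the latents
# (latent correlations then equal the configured domain correlations).
null_demo_config <- function(...) {
  cohort_config(
    demographic_effects = matrix(
      0, 4, 4,
      dimnames = list(c("language", "executive_function", "memory", "speed"),
                      c("age", "gender_male", "education_high", "country_uk"))),
    ...)
}

# --- independent metric oracles (loop/formula based, no shared code paths) --

oracle_r_squared <- function(truth, pred) {
  m <- sum(truth) / length(truth)
  num <- 0; den <- 0
  for (i in seq_along(truth)) {
    num <- num + (truth[i] - pred[i])^2
    den <- den + (truth[i] - m)^2
  }
  1 - num / den
}

oracle_mae <- function(truth, pred) {
  s <- 0
  for (i in seq_along(truth)) s <- s + abs(truth[i] - pred[i])
  s / length(truth)
}

oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# ROC-AUC as the normalized Mann-Whitney pairwise statistic
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# average precision over ranked items (distinct scores assumed)
oracle_pr_auc <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]
  P <- sum(l == 1)
  ap <- 0
  for (k in seq_along(l)) {
    if (l[k] == 1) ap <- ap + sum(l[seq_len(k)] == 1) / k
  }
  ap / P
}

# WER via character edit distance on a token-to-character encoding
oracle_wer <- function(ref, hyp) {
  alphabet <- unique(c(ref, hyp))
  stopifnot(length(alphabet) <= 500)
  enc <- function(x) intToUtf8(match(x, alphabet) + 96L)
  drop(utils::adist(enc(ref), enc(hyp))) / length(ref)
}

# ICC(2,1) from two-way ANOVA mean squares (independent route via lm/anova)
oracle_icc21 <- function(auto, manual) {
  n <- length(auto)
  d <- data.frame(y = c(auto, manual),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(c("a", "m"), each = n)))
  a <- stats::anova(stats::lm(y ~ subject + rater, data = d))
  msr <- a["subject", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# brute-force sliding-window statistic
oracle_window_mean <- function(tokens, w, f) {
  n <- length(tokens)
  if (n <= w) return(f(tokens))
  vals <- numeric(n - w + 1)
  for (i in seq_len(n - w + 1)) vals[i] <- f(tokens[i:(i + w - 1)])
  mean(vals)
}
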