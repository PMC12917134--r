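lex <- make_norm_lexicon(seed = 42)

test_that("POS ratios match hand counts on a tagged fixture", {
  tk <- make_tokens(c("the", "boy", "runs", "to", "the", "store"),
                    c("DT", "NN", "VBZ", "TO", "DT", "NN"))
  fv <- pos_ratio_features(tk)
  expect_equal(fv$values[["noun_ratio"]], 2 / 6)
  expect_equal(fv$values[["verb_ratio"]], 1 / 6)
  expect_equal(fv$values[["determiner_ratio"]], 2 / 6)
  expect_equal(fv$values[["preposition_ratio"]], 1 / 6)
  expect_equal(fv$values[["n_words"]], 6)

  all_nouns <- make_tokens(c("cat", "dog", "jar"), rep("NN", 3))
  expect_equal(pos_ratio_features(all_nouns)$values[["noun_ratio"]], 1)
  expect_equal(pos_ratio_features(make_tokens(c("cat", "cat")))$values[["avg_word_length"]], 3)
})

test_that("zero-noun transcripts flag the verb/noun ratio invalid", {
  tk <- make_tokens(c("run", "quickly"), c("VB", "RB"))
  fv <- pos_ratio_features(tk)
  expect_false(fv$valid[["verb_noun_ratio"]])
  expect_true(is.na(fv$values[["verb_noun_ratio"]]))
})

test_that("lexical diversity formulas match hand/brute-force values", {
  tk <- make_tokens(c("a", "a", "b", "b"))
  fv <- lexical_diversity_features(tk, window = 2)
  expect_equal(fv$values[["moving_average_type_token_ratio"]], (0.5 + 1 + 0.5) / 3)

  # Brunet on N=100, V=20; Honore on N=10, V=5, V1=2
  toks100 <- make_tokens(rep(letters[1:20], 5))
  expect_equal(lexical_diversity_features(toks100)$values[["brunets_index"]],
               100^(20^-0.165))
  toks10 <- make_tokens(c("a", "a", "a", "b", "b", "b", "c", "c", "d", "e"))
  expect_equal(lexical_diversity_features(toks10)$values[["honores_statistic"]],
               100 * log(10) / (1 - 2 / 5))

  fifty <- make_tokens(rep("same", 50))
  expect_equal(lexical_diversity_features(fifty)$values[["n_unique_in_50"]], 1)

  # all-hapax text: Honore flagged invalid, MATTR = 1 regardless of window
  uniq <- make_tokens(letters[1:10])
  fu <- lexical_diversity_features(uniq, window = 4)
  expect_false(fu$valid[["honores_statistic"]])
  expect_equal(fu$values[["moving_average_type_token_ratio"]], 1)
})

test_that("windowed statistics equal naive brute-force enumeration", {
  set.seed(31)
  for (n in c(15, 60, 180)) {
    toks <- sample(letters[1:8], n, replace = TRUE)
    fv <- lexical_diversity_features(make_tokens(toks), window = 20,
                                     sample_size = 50)
    expect_equal(fv$values[["moving_average_type_token_ratio"]],
                 oracle_window_mean(toks, 20,
                                    function(x) length(unique(x)) / length(x)))
    expect_equal(fv$values[["n_unique_in_50"]],
                 oracle_window_mean(toks, 50,
                                    function(x) length(unique(x))))
  }
})

test_that("densities follow the documented POS unions", {
  tk <- make_tokens(c("the", "boy", "runs", "to", "the", "store"),
                    c("DT", "NN", "VBZ", "TO", "DT", "NN"))
  fv <- density_and_norm_features(tk, lex)
  expect_equal(fv$values[["propositional_density"]], 2 / 6)
  expect_equal(fv$values[["content_density"]], 3 / 6)
})

test_that("noun norm features average lexicon values over covered nouns", {
  toy_lex <- data.frame(word = c("boy", "store"), frequency = c(5, 5),
                        aoa = c(4, 6), familiarity = c(500, 520),
                        ambiguity = c(2, 2), concreteness = c(4.5, 4.0))
  tk <- make_tokens(c("the", "boy", "runs", "to", "the", "store"),
                    c("DT", "NN", "VBZ", "TO", "DT", "NN"))
  fv <- density_and_norm_features(tk, toy_lex)
  expect_equal(fv$values[["frequency_noun"]], 5)
  expect_equal(fv$values[["age_of_acquisition_noun"]], 5)
  expect_equal(fv$meta$norm_coverage, 1)

  no_nouns <- make_tokens(c("run", "quickly"), c("VB", "RB"))
  fv2 <- density_and_norm_features(no_nouns, toy_lex)
  expect_false(any(fv2$valid[c("frequency_noun", "age_of_acquisition_noun",
                               "familiarity_noun", "ambiguity_noun",
                               "noun_concreteness")]))
})

test_that("semantic distances behave on identical / disjoint sentence pairs", {
  same <- tokenize_and_tag("the boy runs. the boy runs.")
  fv <- semantic_distance_features(same)
  expect_equal(fv$values[["avg_distance_between_utterances"]], 0, tolerance = 1e-12)
  expect_equal(fv$values[["prop_utterance_dist_below_05"]], 1)

  disjoint <- tokenize_and_tag("the boy runs. a girl sat.")
  fv2 <- semantic_distance_features(disjoint)
  expect_equal(fv2$values[["avg_distance_between_utterances"]], 1)
  expect_equal(fv2$values[["prop_utterance_dist_below_05"]], 0)

  single <- tokenize_and_tag("the boy runs")
  fv3 <- semantic_distance_features(single)
  expect_false(any(fv3$valid))
})

test_that("pairwise TF-IDF distances match a brute-force computation", {
  tk <- tokenize_and_tag("the boy runs. the girl runs. a cat sat.")
  fv <- semantic_distance_features(tk)
  # brute force: rebuild tf-idf and average over the 3 pairs
  sents <- list(c("the", "boy", "runs"), c("the", "girl", "runs"),
                c("a", "cat", "sat"))
  vocab <- sort(unique(unlist(sents)))
  tf <- t(vapply(sents, function(s) {
    vapply(vocab, function(v) sum(s == v), 0)
  }, numeric(length(vocab))))
  idf <- log((1 + 3) / (1 + colSums(tf > 0))) + 1
  W <- sweep(tf, 2, idf, `*`)
  cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  d <- c(cosd(W[1, ], W[2, ]), cosd(W[1, ], W[3, ]), cosd(W[2, ], W[3, ]))
  expect_equal(fv$values[["avg_distance_between_utterances"]], mean(d),
               tolerance = 1e-12)
  expect_equal(fv$values[["prop_utterance_dist_below_05"]], mean(d <= 0.5))
})

test_that("the orchestrator returns the full named vector deterministically", {
  text <- "the boy is washing a dish. uh the water is falling on the floor. the mother looks at the window."
  fv <- extract_linguistic_features(text, lex)
  expect_identical(names(fv$values), linguistic_feature_names())
  expect_equal(length(fv$values), 39L)
  fv2 <- extract_linguistic_features(text, lex)
  expect_identical(fv$values, fv2$values)
  # concatenation adds token counts
  both <- extract_linguistic_features(paste(text, text), lex)
  expect_equal(both$values[["n_words"]], 2 * fv$values[["n_words"]])
  # proportions stay in [0, 1]
  props <- grep("_ratio$|_density$", names(fv$values), value = TRUE)
  props <- setdiff(props, "verb_noun_ratio")
  expect_true(all(fv$values[props] >= 0 & fv$values[props] <= 1, na.rm = TRUE))
})

test_that("features are invariant to trailing whitespace and case", {
  a <- extract_linguistic_features("The boy runs. The girl sat.", lex)
  b <- extract_linguistic_features("the boy runs. the girl sat.   ", lex)
  expect_identical(a$values, b$values)
})
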