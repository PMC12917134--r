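---
title: "Methods: speech features, cognitive composites, and the prediction harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech features, cognitive composites, and the prediction harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogspeech)
```

`cogspeech` models the relationship between spontaneous speech and
cognitive performance in older adults. This vignette is the package's own
account of the science it implements: the models, the tunable parameters,
the numerical choices, and what the synthetic tests do and do not show.

## The measurement model: four cognitive composites

The package assumes a test battery of 14 measures (verbal fluency,
confrontation naming, verbal learning and recall, trail making, planning,
span tasks, and several psychomotor speed tasks). Completion times and
error counts are reverse-scored (`harmonize_test_scores()`), so higher
always means better.

The battery is summarized by a confirmatory factor model with four
correlated latent domains — language, executive function, memory, speed —
in which each test loads on exactly one domain, except Trail Making Test A,
which cross-loads on speed and executive function (it taxes both
psychomotor speed and attention switching). `fit_factor_model()` estimates
the free loadings, factor correlations (unit factor variances), and
residual variances by minimizing the maximum-likelihood discrepancy
\(F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p\)
with BFGS; the factor correlation matrix is parameterized through a
row-normalized Cholesky factor, which keeps it positive definite without
constraints, and residual variances through their logarithm. Fit is
reported as \(\chi^2\), CFI, TLI and RMSEA against the independence
baseline. These are the standard ML indices; robust (mean-scaled)
corrections are not implemented, so indices on heavy-tailed data will
differ slightly from robust variants. Factor scores use the regression
method \(\hat F = (X-\bar X)\,\Sigma^{-1}\Lambda\Phi\) — chosen over
Bartlett scores because downstream models care about prediction, not
unbiasedness per indicator — and are standardized to mean 0, sd 1.

Before the CFA, raw scores pass two cleaning steps that mirror common
practice with unsupervised online testing:

* **Outlier removal** (`flag_outliers_by_demographic_regression()`): per
  test, an OLS regression on age, gender, education and country;
  observations with standardized residuals |z| > 4 become missing. The
  threshold of 4 keeps the false-flag rate of clean Gaussian data near
  \(2n\Phi(-4) \approx 0.06\) per 1000 observations. Columns with zero
  residual variance produce no flags (z is undefined there).
* **Round-robin imputation** (`impute_round_robin()`): each incomplete
  column is regressed on all other score columns with a small ridge
  penalty (1e-3), visiting columns left-to-right from column-mean starts
  until the largest imputed-cell change falls below 1e-4. The fixed visit
  order and deterministic ridge solution make the pipeline reproducible
  without a random seed.

## Speech features

**Linguistic features** (39 named features, `extract_linguistic_features()`)
are computed from a lexicon-driven Penn Treebank tagger with documented
suffix fallback rules and a deterministic POS-chunk parser. Tokenization,
tagging and parsing conventions are documented in the source headers;
feature values are tagger-dependent in any pipeline, and the frozen test
fixtures document this package's choices. Key definitions:

* MATTR: mean type-token ratio over all contiguous windows of 20 tokens
  (texts shorter than the window are scored as one window, which makes the
  statistic defined everywhere and continuous at the boundary).
* `n_unique_in_50`: mean count of unique words over sliding 50-token
  windows (sliding rather than random samples, for determinism).
* Brunét \(W = N^{V^{-0.165}}\); Honoré \(R = 100\ln N/(1 - V_1/V)\)
  with natural log. When every type is a hapax (\(V_1 = V\)) Honoré is
  flagged invalid instead of returning infinity, so it cannot poison
  downstream standardization.
* Propositional density: verbs, adjectives, adverbs, prepositions and
  conjunctions over all words; content density: nouns, verbs, adjectives,
  adverbs over all words. Punctuation is never a token; interjections
  (hesitations like *uh*) count as words.
* Flesch–Kincaid grade \(0.39\,(w/s) + 11.8\,(syl/w) - 15.59\) with a
  vowel-group syllable counter (silent-e rule) — reproducible, if crude.
* TF-IDF inter-sentence distances use raw term frequency times smoothed
  idf \(\ln((1+N)/(1+df)) + 1\), so identical sentences get distance 0 and
  disjoint ones distance 1.

**Acoustic features** (27 named features, `extract_all_acoustic()`): a
frame-energy voice-activity detector (30 ms frames, 10 ms hop, threshold =
5th-percentile frame energy + 10 dB, absolute floor −50 dBFS, 3-frame gap
bridging, 100 ms merge) segments audio into voiced and pause intervals.
On homogeneous audio (all silence, or one continuous tone) the adaptive
floor is uninformative and the absolute threshold alone decides. Pause
features exclude leading and trailing silence: the pause fraction is total
internal gap over the trimmed span — a deliberate reading of "fraction of
pause over audio length", configurable by computing on untrimmed
durations if wanted. Speech rate divides transcript-derived phoneme counts
(bundled grapheme-to-phoneme table, letter-based fallback) by total audio
length; articulation rate divides by voiced time only, so articulation
rate ≥ speech rate whenever any pause exists. The 21 eGeMAPS-style
descriptors are documented approximations (Stevens-law loudness proxy,
L2 spectral flux on L1-normalized spectra, 26-filter mel cepstra,
autocorrelation F0 in 55–400 Hz, order-10 LPC formant F1): the contract is
the named descriptor vector, not bit-compatibility with any external
toolkit. `select_descriptors()` ranks candidates by their maximum absolute
Pearson correlation against any of the four composites on the development
set only (the maximum over domains, since a single shared ranking is
needed), keeps up to 30 non-redundant descriptors while skipping any
candidate correlated above 0.85 with one already kept, and breaks ranking
ties by input order.

## The prediction harness

The evaluation design reserves a stratified 20% holdout and evaluates
models by stratified 10-fold cross-validation on the remaining 80%.
Stratification uses age, country, gender, education and the mean composite
score; continuous variables are binned into quintiles (the binning is a
package choice — any coarse binning serves). Development counts are
allocated per stratum by largest remainder, so global sizes are exact
(985 participants split exactly 788/197); strata smaller than two members
are pooled. CV metrics are computed on the union of the fold test sets,
not averaged per fold, so every development participant contributes one
out-of-fold prediction.

All feature preprocessing is fitted on training rows only: train-statistic
|z| > 4 outlier removal, round-robin imputation whose per-column ridge
regressions are refitted on the completed training matrix and then frozen,
and train-mean/sd standardization. Unlike the cognitive-score cleaning,
feature outliers are judged against plain train mean/sd rather than a
demographic regression — the simplest leakage-safe reading of "the same
approach, but with training statistics only". The leakage tests assert
that perturbing apply-set rows leaves every fitted component bit-identical.

The main regressor is epsilon-SVR with an RBF kernel, C = 0.5 and the
default epsilon of 0.1 (only kernel and C are treated as fixed design
choices; epsilon is exposed). Baselines: a random forest, a train-mean
predictor (expected R² = 0), and a random predictor drawing a training
target with replacement per test case (expected R² = −1, since the
expected squared error of an independent draw is twice the target
variance). R² is the standard squared-residual form
\(1-\sum(c_i-\hat c_i)^2/\sum(c_i-\bar c)^2\); Spearman uses average
ranks; MAE is the mean absolute error. Uncertainty comes from 1000
participant-level bootstrap resamples (percentile intervals, degenerate
constant-truth resamples redrawn); the superiority test resamples pairs
and declares an improvement significant when ≥ 95% of resampled metric
differences exceed zero. Shapley attributions enumerate all feature
coalitions (background-marginal value function) for up to 12 features, so
local accuracy holds to numerical precision; beyond that a seeded
permutation estimator is used.

## Screening and clinical transfer

Normative models regress each composite on age, gender, education and
country over the full cohort — deliberately including the holdout, because
the norms define the screening labels rather than a predictive model; a
dev-only variant is available by restricting the input rows. Participants
more than 1.96 residual standard deviations below their expected score
(z < −1.96) are labeled low performers, which under well-specified
Gaussian norms yields a prevalence of Φ(−1.96) ≈ 2.5% per domain. The SVM
classifier reuses the regression kernel/C (the classification-specific
values being an open choice) and is evaluated by ROC (threshold sweep,
trapezoidal area) and PR (step-wise average precision, the conservative
non-interpolated estimator) on signed decision margins — AUCs are
invariant to monotone transforms, so no calibration step is needed.

Transfer freezes the fitted transform and regressor and applies them
unchanged to an external cohort (`apply_pretrained()`); group separation
is quantified by an equal-variance t-test and pooled-SD Cohen's d with the
convention d = (control − patient)/pooled sd, positive when patients score
lower. The pooled t-test matches the pooled-SD d; a Welch variant would
mismatch the effect-size denominator.

## The synthetic cohort generator

`generate_cohort()` produces the study conditions the harness expects:
age ~ N(65.5, 4.8) truncated at 60, 60/40 female/male, 50/50 UK/USA,
60/40 high/low education; four latent domains drawn from a correlation
matrix (defaults 0.3–0.5, reflecting that cognitive domains correlate);
test scores = loadings × latents + N(0, 0.6) with primary loadings 0.75
(cross-loading 0.55/0.30 for Trail Making A); linear demographic shifts on
the latents. Transcripts are template sentences from a bundled lexicon: a
higher latent language score monotonically widens the content vocabulary
in use (raising the type-token ratio) and lowers the hesitation rate via
plogis(−2.2 − 0.6·latent). Waveforms are three-harmonic tones with 10 ms
ramps over a planned voiced/pause alternation whose pause fraction is
monotone in the latent speed score, over a 1e-3 noise floor. The speech
and audio effect sizes default to 0.30 and 0.25 of latent variance —
chosen once as a realistic mid-range coupling consistent with speech
explaining roughly a quarter to a third of language-domain variance.

The linear-with-Gaussian-noise latent-to-observable links are the simplest
structure supporting recovery tests; the generator does **not** emulate
natural language, prosody, disfluency structure beyond a hesitation rate,
reverberation or microphone variation. Green tests therefore demonstrate
that the *pipeline machinery* is correct and calibrated — not that the
features capture cognition in real speech, which only human data can show.

For harness calibration, `simulate_feature_signal()` plants a linear
signal directly in feature space: one latent t per participant, features
\(x_j = a\,t + \sqrt{1-a^2}\,e_j\) with \(a\) solved so the population R²
of the best linear predictor from all p features equals the requested
value exactly (\(a^2 = R^2/(p - R^2(p-1))\)). A text-level planting cannot
fix a theoretical R² because lexical estimators add estimation noise with
no closed form; the feature-space construction makes "planted R² = 0.3"
well-defined, and a shifted latent mean emulates a clinical deficit for
transfer tests.

## Problem sizes, determinism, degenerate inputs

The test suite uses cohorts of 40–5000 participants, transcripts of
30–250 tokens, and recordings of 2–10 s; simulation counts (200 seeds for
dummy calibration, 500 repetitions for no-skill baselines, 200 null
simulations for type-I control) are the package's chosen Monte-Carlo
sizes, balancing tightness of the checks against runtime. Every stochastic
component takes an explicit integer seed; child seeds are derived
deterministically per stream and kept within 32-bit range. Degenerate
inputs are flagged, never silently coerced: empty transcripts raise
errors; noun-free transcripts invalidate noun-dependent features;
constant truth invalidates R²; single-class folds are an error with fold
diagnostics; Heywood cases in the CFA are reported.

## Known limitations

* The tagger, chunk parser, syllable counter and G2P table are compact
  rule systems: adequate for the template-based synthetic language and for
  well-behaved English text, but not competitive with statistical parsers
  on free-form speech transcripts.
* The acoustic descriptors are approximations of the published parameter
  set; absolute values are not comparable across toolkits (their use here
  is within-cohort, after train-standardization, where only relative
  variation matters).
* Fit indices are non-robust ML versions.
* English only; cross-sectional design assumptions throughout.
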