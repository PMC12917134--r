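# cogspeech

Speech-derived digital biomarkers of cognitive performance in older adults.

Spontaneous speech — e.g. a one-minute description of a line drawing — is
cheap to collect, non-intrusive, and repeatable, which makes it attractive
as a screening signal for early cognitive decline. `cogspeech` implements a
complete, testable analysis pipeline around that idea:

1. **Feature extraction.** From transcripts: part-of-speech ratios, lexical
   diversity (moving-average type-token ratio, Brunét's index
   *W = N^(V^-0.165)*, Honoré's statistic *R = 100·ln N / (1 − V₁/V)*),
   propositional/content density, psycholinguistic noun norms, chunk-parse
   production rules, Flesch–Kincaid grade, TF-IDF inter-sentence distances.
   From audio: voice-activity segmentation, pause fraction/durations,
   phoneme-based speech and articulation rates, and a 21-descriptor subset
   of eGeMAPS-style acoustic parameters (loudness percentiles, spectral
   flux, MFCC statistics, F0/F1 descriptors, equivalent sound level).
2. **Composite cognitive scores.** Individual test scores from a
   14-test battery are sign-harmonized, cleaned of outliers by
   demographic-regression z-scores (|z| > 4), completed by round-robin
   ridge imputation, and reduced to four standardized domain composites —
   *language*, *executive function*, *memory*, *speed* — by confirmatory
   factor analysis (maximum likelihood, fixed loading pattern with one
   cross-loading, regression-method factor scores).
3. **Prediction harness.** Stratified 80/20 development/holdout split,
   stratified 10-fold cross-validation, leakage-safe train-only feature
   preprocessing, SVR (RBF kernel, C = 0.5) with random-forest and dummy
   baselines, the R², Spearman and MAE metrics with 1000-resample
   bootstrap confidence intervals, a paired bootstrap superiority test,
   and exact Shapley feature attributions.
4. **Screening and transfer.** Normative regression of each composite on
   demographics defines *cognitive low performers* (z < −1.96); an SVM
   classifier is evaluated with ROC/PR curves. A frozen trained pipeline
   can be applied unchanged to an external clinical cohort and group
   separation quantified by pooled t-tests and Cohen's d.
5. **Synthetic cohorts.** A first-class generator produces cohorts with
   four correlated latent domains, demographic effects, factor-structured
   test scores, template transcripts whose lexical diversity and
   hesitation rate track the latent language score, and synthetic
   waveforms with planted voiced/pause structure — with all ground truth
   retained, so every stage above is testable without human data.

## Worked example

```r
library(cogspeech)

cohort <- generate_cohort(cohort_config(n_participants = 200, seed = 1))
comp <- compute_composite_scores(cohort$test_scores, cohort$demographics)
round(comp$fit$fit_indices, 3)
#>  chisq     df    cfi    tli  rmsea
#> 54.737 70.000  1.000  1.014  0.000

lex <- make_norm_lexicon(seed = 1)
fv <- extract_linguistic_features(cohort_transcript(cohort, "P0001"), lex)
round(fv$values[c("moving_average_type_token_ratio", "brunets_index",
                  "interjection_ratio")], 3)
#> moving_average_type_token_ratio    brunets_index interjection_ratio
#>                           0.737           15.139              0.052
```

The CFA fit indices say the configured four-domain factor model reproduces
the synthetic test-score covariances almost exactly (CFI/TLI near 1, RMSEA
near 0, as expected when the generating model matches the fitted pattern).
The feature values are the per-transcript lexical diversity and hesitation
measures that the regression harness consumes. A full study — features,
composites, split, cross-validated SVR against dummy baselines, screening —
runs via `run_study(study_config(...))` and writes metrics, predictions
and its resolved configuration to a run directory.

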