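# infotrans

Tools for quantifying **information transmission** from text stimuli to
individual raters — for quantitative psychophysics and computational
psychiatry work that asks *how much of a stimulus's objective information
content actually reaches a given person*, and how that relates to boredom
and to clinical status (e.g. healthy controls vs ADHD outpatients).

## What it computes

**Objective information content.** A text's cumulated empirical entropy

&nbsp;&nbsp;&nbsp;&nbsp;H<sub>cum</sub> = Σ<sub>i</sub> H<sub>i</sub>,&nbsp;&nbsp;H<sub>i</sub> = −Σ<sub>w</sub> f<sub>w</sub> log f<sub>w</sub>

where H<sub>i</sub> is the Shannon entropy of the word-frequency
distribution of the prefix ending at token *i*. A constant text scores 0; a
text of *n* distinct words scores log(*n*!). Semantic diversity (mean
pairwise 1 − cosine over word-type embeddings) complements entropy via a
pluggable embedding backend.

**The transmission model.** Each participant's five information ratings
*y<sub>t</sub>* (1–7 scale) are fitted **without intercept** as

&nbsp;&nbsp;&nbsp;&nbsp;ŷ<sub>t</sub> = β<sub>H</sub> H<sub>t</sub> + Σ<sub>k</sub> β<sub>k</sub> T<sub>k</sub>

with stimulus entropy (*external* factor) and the participant's Big Five
trait scores (*internal* factors) as regressors, ridge-penalized
(λ = 0.2 by default; the 5-row, 6-column per-person design is
rank-deficient). Per text, each regressor's contribution |x β| is
normalized so the six relative contributions sum to 1; the mean entropy
share over texts is the participant's **information sensitivity** ∈ [0, 1].
A shuffled-regressor null (capacity-preserving permutation) verifies the
fit captures real stimulus–rating pairing.

**Cohort analyses.** Rating summaries with Kruskal-Wallis tests across
texts; all pairwise sentiment correlations with Fisher-z CIs and a
Bonferroni threshold; the sensitivity–boredom correlation; and full
control-vs-clinical contrasts (rank-sum + Cohen's d per text × sentiment,
effect-size profiles, and an exact signed-rank test on per-text mean
entropy contributions).

**Synthetic data.** A seeded generator produces 100-word stimulus sets
with a controlled, strictly increasing entropy gradient and rating cohorts
with known ground-truth sensitivities, inverse-U or linear response
shapes, negative boredom coupling, and clinical cohort presets — so the
entire pipeline is testable end-to-end without any participant data.

## Worked example

```r
library(infotrans)

ds <- generate_two_cohorts()        # 5 texts, 142 controls + 19 clinical
profiles_table(ds$profiles)
#>   stimulus_id token_count unique_count H_cum semantic_diversity
#> 1 text_1              100            2  67.2              0.996
#> 2 text_2              100            6 167.               1.01
#> 3 text_3              100           18 253.               1.01
#> 4 text_4              100           45 314.               1.01
#> 5 text_5              100           63 337.               1.01

ctrl   <- subset(ds$participants, cohort == "control")
r      <- subset(ds$ratings, participant_id %in% ctrl$participant_id)
design <- build_design(ctrl, r, ds$profiles)

fit <- fit_cohort(design, lambda = 0.2)
fit
#> <cohort_fit> 142 participants, lambda = 0.2
#>   pooled R^2 = 0.999 (no-intercept (SST about zero)); 0 degenerate
#>   mean sensitivity = 0.563

shuffled_null(design, seed = 1)
#> <null_comparison> scheme = pooled: real MSE 0.025 vs shuffled 0.892 (means), p = 6.81e-44

sensitivity_boredom_link(fit, r)
#> R_P = -0.695, n = 142, p = 9.006e-22, 95%-CI = [-0.771 -0.598]
```

Reading: the five texts share the 100-word format but span a five-fold
entropy range; the transmission fits explain the ratings far better than
capacity-matched shuffled controls; and participants whose ratings track
stimulus entropy less (lower information sensitivity) report more boredom
— the negative correlation above.

The full pipeline (simulate/load → validate → fit → null → cohort
analyses → CSV/JSON outputs) runs via

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

or from a shell through the thin wrapper
`Rscript inst/scripts/infotrans.R run --out run1 --seed 1`.

## Documentation

The methods vignette
(`vignettes/information-transmission.Rmd`) documents the model and its
assumptions, every tunable parameter with units and defaults, the
synthetic generator's design rationale and its limits, and the numerical
conventions (ridge solver, exact-test thresholds, degenerate-case
handling).
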