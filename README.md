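# hemidiff

Paired-hemisphere differential expression and asymmetry analysis for bulk
RNA-seq cohorts, motivated by hemispheric asymmetry in Parkinson's disease
(PD).

PD motor symptoms typically begin unilaterally, and degeneration is more
pronounced in the hemisphere contralateral to onset. Given a gene-by-sample
count matrix with one library per hemisphere per subject and a clinical
sample sheet, `hemidiff` labels each PD hemisphere *severe* or *moderate*
from the recorded side of symptom onset, and asks how within-subject
hemispheric asymmetry relates to between-subject disease effects. It is
aimed at analysts working with paired brain (or other bilateral-organ)
expression cohorts who want the full path from counts to stratified,
gene-set-level results in one reproducible, seedable pipeline.

## The model

Counts are TMM-normalized and modelled on the log-CPM scale
`log2((y + 0.5) / (f·N + 1) · 1e6)`. Every gene is fitted by weighted least
squares on a means model over a combined category — `status.sex.onset.hemisphere`
for PD, `status.sex.hemisphere` for controls — plus centered clinical
covariates (duration, age, RIN, log library size, nuclei yield, PMI), with
mean–variance-trend precision weights. Two contrasts are tested with
empirical-Bayes moderated t-statistics
(`t̃ = c'β̂ / sqrt(s̃² · c'(X'WX)⁻¹c)`, `s̃² = (d₀s₀² + d s²)/(d₀ + d)`) and
per-contrast Benjamini–Hochberg FDR:

* **disease** — mean of PD levels − mean of control levels (equal weight
  per level);
* **asymmetry** — mean of severe levels − mean of moderate levels within PD.

The fit is two-stage: the 2,000 genes least different between PD and
control serve as negative controls from whose reduced-model residuals the
first k = 5 sample-space singular vectors are estimated and added to the
final design as correcting variables. Around this core the package
provides rank-correlation clustering to select the most homogeneous paired
PD subset, per-subject directional gene-set z-score asymmetry
(mean ± SD of `z_severe − z_moderate` over a module such as the CCT/TRiC
chaperonin subunits) with sign-based patient stratification, cross-contrast
gene classification (same/opposite direction, asymmetry-only by a 0.5 log2
effect-size difference, disease-only), preranked running-sum enrichment
with gene-label permutation, and a negative-binomial cohort simulator with
planted truth for calibration and recovery testing.

## Worked example

```r
library(hemidiff)

spec <- cohort_spec(n_pd_subjects = 16, n_ctrl_subjects = 8, n_genes = 800,
                    disease_lfc = 1, asym_lfc = 1,
                    frac_sign_flip_subjects = 0.3, seed = 42)
sim <- simulate_cohort(spec)
res <- run_two_stage(sim$counts, sim$samples, de_config(n_control_genes = 300))
#> expression filter: 800 of 800 genes kept (CPM > 1 in >= 16 samples)
#> stage 2: 5 correcting variable(s) from 300 control genes

head(res$de_asymmetry[order(res$de_asymmetry$p), ], 5)
#>    gene_id  contrast log2fc t_mod        p      fdr ave_expr
#> 89  G00080 asymmetry   1.57  7.81 1.56e-13 6.53e-11    10.69
#> 20  G00011 asymmetry   1.56  7.75 2.22e-13 6.53e-11    12.10
#> 44  G00035 asymmetry   1.55  7.74 2.45e-13 6.53e-11     7.93
#> 50  G00041 asymmetry  -1.47 -7.47 1.32e-12 2.65e-10     9.92
#> 66  G00057 asymmetry  -1.31 -6.68 1.53e-10 2.45e-08    11.10
```

The top asymmetry genes recover the planted one-log2-unit severe-vs-moderate
effects (their estimates sit above 1 because ranking by p selects upward
noise; the mean signed estimate across all planted genes is unbiased to
within a few hundredths). 99 of 800 genes reach FDR < 0.05, against 40
planted asymmetry genes plus the module — the extra calls are disease genes
whose asymmetry is dragged along by the sign-flipped module subjects.

Per-subject module asymmetry and stratification:

```r
y <- log_cpm(sim$counts, tmm_factors(sim$counts))
z <- zscore_genes(y, sim$samples, "PD_only")
sc <- subject_asymmetry(z, sim$samples, module_genes(spec)$primary,
                        set_name = "cct_like")
head(sc, 4)
#>   subject_id score_mean score_sd n_genes gene_set            stratum
#> 1       pd01       0.68     0.30       8 cct_like   higher_in_severe
#> 2       pd02       1.11     0.83       8 cct_like   higher_in_severe
#> 3       pd03       0.39     1.57       8 cct_like   higher_in_severe
#> 4       pd04      -1.68     1.45       8 cct_like higher_in_moderate

table(sc$stratum)
#> higher_in_moderate   higher_in_severe
#>                  5                 11
```

Each row is one subject's mean ± SD of severe-minus-moderate z-differences
over the 8 module genes; the sign splits the cohort into the two asymmetry
strata (here 11 vs 5, with 30% of subjects simulated with inverted module
direction). `run_all(run_config(...))` chains every stage — full-cohort DE,
subset selection, subset DE, stratified DE, classification, module
correlations on both expression scales, enrichment — into a run directory
of TSV tables plus a checksummed `manifest.json`; a thin CLI wrapper lives
at `inst/cli/hemidiff.R`.

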