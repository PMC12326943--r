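# p53eff

Infer per-sample p53 transcriptional effectiveness from bulk log2 expression
matrices, and measure how correlations between p53-dependent genes recover
once p53-impaired samples are removed.

## The problem

Tumor cohorts mix samples with an intact p53 program and samples in which the
program is blunted (TP53 mutation or downstream defects). This mixture
dilutes correlations between p53 and its transcriptional targets, and between
gene pairs whose coupling depends on p53 — for example ZNF224 and p21
(CDKN1A) in melanoma. `p53eff` is for analysts of bulk transcriptomic cohorts
(microarray or RNA-seq, already normalized to log2 scale) who want to
stratify tumor samples by inferred p53 functionality before interpreting such
correlations.

## The method

Nontumor samples of the cohort are assumed to carry functional p53 and serve
as the calibration set. For each gene *g* of a panel of known p53
transcriptional targets (59 by default), the response

  y_g = a_g + b_g · p,   p = log2 TP53 expression

is fit on nontumor samples by least squares. Each tumor sample *s* then gets
an expected value â_g + b̂_g·p_s for every target, and the straight line
relating its measured to expected values (response components, fit with a
free intercept) yields a slope β_s:

* 0.9 ≤ β_s ≤ 1.1 → `normal_like` (fully functioning p53),
* β_s < 0.9 → `impaired` (targets expressed lower than expected),
* β_s > 1.1 → `above_range` (flagged, but retained by the filter).

Correlations use the biweight midcorrelation (bicor), a robust correlation
with Tukey biweights w_i = (1 − u_i²)² I(|u_i| < 1), u_i = (x_i −
med x)/(9·MAD x) with unscaled MAD, implemented from first principles with a
Student-t significance transform (t = r·√(n−2)/√(1−r²), n−2 df). A
synthetic-data generator draws cohorts with a known impaired fraction and
attenuation factors, so the whole inference is testable against ground truth.
See the vignette (`vignettes/p53-effectiveness.Rmd`) for the model details
and design choices.

## Worked example

```r
library(p53eff)

sim    <- simulate_dataset(sim_config(seed = 42))   # 40 nontumor + 100 tumor
models <- fit_target_responses(sim$matrix, sim$panel)
slopes <- classify_samples(sim$matrix, sim$panel, models)
#> classified 100 sample(s): 80 normal_like, 20 impaired (20.0%), 0 above_range

head(slopes, 3)
#>   sample_id     slope   intercept n_targets       class
#> 1     TU001 1.0226434 -0.14681650        59 normal_like
#> 2     TU002 0.9882996  0.13312433        59 normal_like
#> 3     TU003 0.9946626  0.04067588        59 normal_like

recovery_metrics(sim$truth, slopes)[c("sensitivity", "specificity")]
#> $sensitivity
#> [1] 1
#> $specificity
#> [1] 1

restoration_analysis(sim$matrix, slopes,
                     list(c("ZNF224", "CDKN1A"), c("TP53", "CDKN1A")))
#>   anchor partner bicor_all        p_all n_all bicor_filtered   p_filtered n_filtered n_removed
#> 1 ZNF224  CDKN1A 0.4510361 2.484653e-06   100      0.8694125 1.349602e-25         80        20
#> 2   TP53  CDKN1A 0.4394109 4.790754e-06   100      0.9017916 3.795853e-30         80        20
```

The simulated cohort contains 20 impaired tumor samples (attenuation λ drawn
from U(0.3, 0.7)); all 20 are recovered with no false positives, the
per-sample slopes track λ to within ~0.015 on average, and removing them
raises the ZNF224/CDKN1A bicor from 0.45 to 0.87 — the diluted correlation
was an artifact of the impaired subset, not a weak coupling.

Real data enters through `read_expression_tsv()` (genes × samples TSV plus a
sample→group mapping) or `read_series_matrix()` (GEO series-matrix text
format with substring rules such as `c(normal = "nontumor", melanoma =
"tumor")` applied to a metadata field, and optional probe→gene collapsing).
`run_pipeline(run_config(...))` — or a YAML config — runs
ingest → calibrate → classify → filter → correlate → restore end to end,
writing deterministic TSV outputs, a summary, and a JSON manifest.

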