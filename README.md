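# semenmeth

Cell-type deconvolution and multifactor modelling of targeted bisulfite
methylomes.

Bulk methylomes of heterogeneous tissues such as semen or buccal swabs mix
the signals of several cell types — in semen, haploid sperm alongside
prostate epithelial cells, lymphocytes and granulocytes. Any apparent
association between methylation and a phenotype like age is confounded by
shifts in this composition, so the two must be modelled jointly. `semenmeth`
implements that joint analysis for targeted bisulfite sequencing panels,
from raw CGmap methylation calls through to per-factor lists of associated
CpG sites, for researchers studying epigenetic aging and male reproductive
health.

## The model

Three stages sit at the core:

1. **Reference-based deconvolution.** Each sample's methylation vector *m*
   over the panel is decomposed against a reference methylome *R* (CpG
   sites × cell types) by non-negative least squares,
   min<sub>w ≥ 0</sub> ‖R·w − m‖₂, and the weights are renormalised to
   per-sample DNA proportions. (Because sperm are haploid, these are DNA
   proportions, not cell-count fractions.)

2. **The multifactor model.** The observed methylation matrix
   *M*<sub>obs</sub> (samples × sites) is modelled as a linear combination
   of phenotypic factors, *M*<sub>obs</sub> = *X*·*β*, where *X* holds a
   constant column, a 0/1 batch indicator and the min–max-scaled factors
   (age, cell compositions). The coefficients are the Moore–Penrose
   solution *β* = *X*<sup>†</sup>·*M*<sub>obs</sub>; methylation is fitted
   as *M*<sub>pred</sub> = *X*·*β* and the factors are predicted back from
   methylation as *X*<sub>pred</sub> = *M*<sub>obs</sub>·*β*<sup>†</sup>.
   Performance is assessed by leave-one-out cross-validation (Pearson *r*,
   two-sided *p*, and mean absolute error in original units). Collinear
   factors are pruned from *X* before fitting (immune-cell fractions track
   sperm abundance almost perfectly and would otherwise destabilise *β*).

3. **Three-filter site selection.** Per factor, a CpG site is selected when
   (i) its observed column correlates with the fitted column at
   |r| ≥ 0.5, (ii) its per-site OLS t-test p-value, Benjamini–Hochberg
   adjusted across all sites for that factor, is ≤ 0.05, and (iii) its
   largest absolute coefficient across the non-nuisance factors belongs to
   that factor. The top 200 sites by adjusted p are kept and split by
   coefficient sign — negative meaning demethylation as the factor
   increases.

A fully seeded synthetic-cohort generator (reference methylomes, DNA
mixtures, planted age/batch effects, Poisson coverage with binomial read
sampling) makes every stage testable without external data.

## Worked example

A full in-memory analysis of a simulated 40-sample semen-like cohort
(2,000-site panel, ~74× coverage with a 40× retention floor, ages 27–62):

```r
library(semenmeth)

cfg    <- simulation_config(n_samples = 40, n_sites = 2000, seed = 7)
cohort <- simulate_cohort(cfg)
mat    <- knn_impute(cohort$matrix, k = 5)

composition <- deconvolve_all(mat, cohort$reference)
fm  <- build_factor_matrix(cohort$truth$phenotypes[, c("sample_id", "age", "batch")],
                           composition, pinned = c("age", "sperm"))
fm
#> <factor_matrix> 40 samples x 5 columns: constant, age, sperm, prostate_epithelium, batch
#> pruned for collinearity: granulocyte (r=0.95 with T_lymphocyte); T_lymphocyte (r=-0.91 with sperm)

cv <- loocv(mat, fm)
cv$stats
#> # A tibble: 3 × 5
#>   factor                  r  p_value     mae     n
#>   <chr>               <dbl>    <dbl>   <dbl> <int>
#> 1 age                 0.979 8.59e-28 4.27       40
#> 2 sperm               1.000 4.59e-70 0.00303    40
#> 3 prostate_epithelium 1.000 1.88e-68 0.00298    40

sel <- select_sites(score_sites(mf_fit(mat, fm)), "age")
sel
#> <selection_result> factor 'age': 106 site(s) selected (106 passed filters pre-cap); 85 negative, 21 positive
```

The pruning report shows the lymphoid and granulocyte fractions being
dropped for collinearity with sperm abundance, leaving a design of
constant, batch, age, sperm and prostate-epithelial factors. The LOOCV
table reads: held-out age predictions correlate with true age at r = 0.98
with a mean absolute error of 4.3 years, and the cell-composition factors
are recovered almost exactly. Of the 106 age-associated CpG sites passing
all three filters, 85 lose methylation with age — the planted effects are
predominantly demethylating, and the selection recovers that asymmetry.

`tidy()`, `glance()` and `autoplot()` methods are available on the fitted
objects, and `run_pipeline()` / `inst/cli/semenmeth.R` run the same stages
from files on disk (CGmap directory, phenotype TSV, reference TSV) into a
directory of statistics tables, BED exports and a run log.

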