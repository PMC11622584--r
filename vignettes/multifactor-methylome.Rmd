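---
title: "Methods: deconvolution, the multifactor model, and site selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolution, the multifactor model, and site selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semenmeth)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where more
than one defensible option existed.

## From CGmap calls to a methylation matrix

The unit of data is a per-cytosine methylation call in CGmap format. Only
CpG-context calls are used. Calls on the G strand are folded onto the
C-strand coordinate of the dinucleotide (position − 1) and read counts are
summed per CpG before any filtering: CpG methylation is symmetric, so the
merged counts estimate one underlying level with the combined depth. The
methylation level is always recomputed as `meth_reads / total_reads`; the
file's ratio column is only cross-checked (a mismatch beyond 10⁻³ warns).

A call enters the matrix when its merged depth reaches `min_coverage`
(default 40×, the conventional floor for targeted bisulfite panels, where
mean depths of ~74× make a 40× floor retain the overwhelming majority of
calls). Below-floor calls become *missing*, not zero — coding them as zero
would bias the matrix toward hypomethylation. Sites missing in every
sample are dropped; rows and columns are sorted (samples by id, sites by
natural chromosome order then position) so every downstream fit is
deterministic. Note the corollary: a site below the floor in *all* samples
leaves the matrix entirely rather than remaining as an all-missing column.

Missing entries are then imputed by k nearest neighbours **across
samples**: the distance between two samples is the Euclidean distance over
their mutually observed sites, and a missing value at site *j* is the mean
of the *k* nearest samples observed at *j* (fewer if fewer are observed
there; `k` must be below the sample count). The default `k = 5` is the
common small-cohort choice; recovery results in the test-suite cohorts are
insensitive to `k` in the 3–10 range because missingness at a 40× floor
under ~74× coverage is rare and scattered. Imputation never alters
observed entries, so it is idempotent.

## Reference-based deconvolution

Cell-type composition is estimated per sample by non-negative least
squares: with reference matrix *R* (shared sites × cell types) and sample
vector *m*,

$$\hat w = \arg\min_{w \ge 0} \lVert R\,w - m \rVert_2 ,$$

solved by the Lawson–Hanson active-set algorithm (`pracma::lsqnonneg`).
Weights are optionally (default) renormalised to sum to one; both raw
weights and the residual norm are reported. At least 50 shared sites are
required — below that the fit is meaningless for a 4-type basis.
Reference profiles are built as unweighted means of replicate profiles
restricted to sites present in all replicates; replicates per type are few
in practice, so no weighting scheme is attempted.

Two caveats are inherent to the method and deliberately not "corrected".
First, the estimates are **DNA proportions**: sperm are haploid, so equal
DNA from sperm and from a diploid type implies twice as many sperm cells.
All package tests compare against DNA-mixing ground truth for this reason.
Second, no unknown-component estimation is attempted; an additional
suspected component (e.g. a myeloid-like fraction in semen) must be
supplied as an extra reference column.

## The multifactor model

The observed methylation matrix $M_{obs}$ (samples × sites, values in
[0, 1]) is modelled as a linear combination of phenotypic factors:

$$M_{obs} = X\,\beta,$$

where the design $X$ contains a constant column, a 0/1 batch indicator,
and the requested factors (age, cell compositions) min–max scaled to
[0, 1]. The scaling serves two purposes: coefficients become comparable
across factors (which the site-selection argmax filter relies on), and the
stored (min, max) pairs allow predictions to be mapped back to original
units. The least-squares coefficients are computed with the Moore–Penrose
pseudoinverse,

$$\beta = X^{\dagger} M_{obs}, \qquad
  M_{pred} = X\,\beta, \qquad
  X_{pred} = M_{obs}\,\beta^{\dagger},$$

where $X_{pred}$ predicts each sample's factor values back from its
methylome. With a full-column-rank design, $\beta$ equals the per-site
ordinary-least-squares solution (the test suite asserts agreement to
10⁻⁸); with a rank-deficient design the minimum-norm solution is returned.
The pseudoinverse is computed by SVD with the conventional singular-value
cutoff `max(dim) * eps * max(singular value)`, configurable where a panel
with near-constant factors needs a stricter cutoff.

**Collinearity pruning.** Cell-composition factors are compositional and
can be almost perfectly correlated (in semen, immune fractions track
1 − sperm). Before fitting, while any pair of non-constant, non-batch
factors exceeds `prune_threshold` (default 0.7) in absolute Pearson
correlation, the involved factor with the largest mean absolute
correlation to the others is dropped, and the drop is reported. Pinned
factors are never dropped: age is always pinned, and the built-in tissue
profiles also pin the factor of primary interest (sperm for semen,
epithelial for buccal) so that pruning removes its correlated proxies
rather than the factor itself — the scientifically intended resolution of
a correlated cluster, which a purely mean-correlation rule cannot infer.
The 0.7 default makes "highly correlated" explicit and configurable.

**Evaluation.** Leave-one-out cross-validation refits $\beta$ on n − 1
samples and predicts the held-out factor row as
$M_{obs}[i,]\,\beta_{-i}^{\dagger}$. Per factor, the Pearson correlation
between held-out predictions and observations is reported with a
two-sided t-test p-value (n − 2 df) and the mean absolute error on
original units (years for age). The in-sample counterpart
(`evaluate_fullfit()`) is also provided; it is optimistic relative to
LOOCV and both are reported so the gap is visible. The constant and batch
columns participate in fitting but are excluded from evaluation — batch is
a nuisance term, and a zero-variance factor's correlation is reported as
undefined (`NA`) rather than silently zero.

## Three-filter site selection

Per-site statistics come from the same design: `r_site` is the correlation
between a site's observed and fitted methylation across samples, and
per-factor p-values are two-sided OLS t-tests with
$\mathrm{se}(\beta_{kj})^2 = \hat\sigma_j^2 (X^{\mathsf T}X)^{-1}_{kk}$ on
n − p degrees of freedom. P-values are Benjamini–Hochberg adjusted **per
factor across all sites** — not pooled across factors, which would couple
unrelated factors' error budgets. The factor-specific t-test (rather than
an overall F-test) is used because selection is per factor.

A site is selected for a factor when it passes all three filters:
`|r_site| >= r_min` (default 0.5), adjusted p `<= q_max` (default 0.05),
and the argmax of |coefficient| over eligible factors equals the factor.
The filters are conjunctive, so their application order cannot change the
result (asserted in tests). Nuisance columns are excluded from the argmax:
the intercept's coefficient is the site's baseline methylation and would
absorb nearly every site. Survivors are ranked by adjusted p (ties broken
by |coefficient|, then site id — determinism over elegance), truncated to
`cap` (default 200), and split by coefficient sign; a coefficient of
exactly zero goes to the positive group with a flag. Both the pre-cap and
post-cap counts are reported, since with many true effects the cap, not
the filters, binds.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. Its defaults
describe the cohort conditions it emulates: 40 samples, a 2,000-site
panel, four reference cell types at pairwise mean methylation distinctness
δ = 0.3, ages uniform on 27–62 years, two balanced collection batches,
mean coverage 74× with a 40× floor, and 200 planted age sites whose
methylation changes by 0.1 across the age range, three quarters of them
demethylating (age effects in germline-containing tissue are predominantly
negative). Larger or noisier cohorts are a constructor argument away.

*Reference*: a shared bimodal background (CpGs near 0 or 1, Beta-mixture)
with per-type jitter, plus a disjoint block of discriminating sites per
type (that type ~0.95, others ~0.05) sized so every column pair differs by
at least δ on average; infeasible δ for the panel size is a configuration
error, and the achieved distinctness is asserted, not assumed. A further
block of mid-methylation sites, identical across types, is reserved for
planted effects — placing effects on bimodal sites would clip against the
[0, 1] bounds and convolve effect recovery with saturation.

*Compositions*: stick-breaking. For the semen profile the epithelial
fraction is carved out first from a narrow Beta(3, 15) (epithelial
shedding varies independently of sperm output), sperm takes a wide
Beta(2.5, 1) share of the remainder, and the immune residue is split by a
tight symmetric Dirichlet. This reproduces the correlation regime of real
semen mixtures — immune fractions tightly inverse to sperm abundance,
epithelial only moderately coupled — which a single Dirichlet draw cannot:
compositional coupling alone ties *every* minor fraction equally to the
dominant one, and the pruning stage would then remove the epithelial
factor too. The regime (checked across hundreds of seeds during design)
is a structural property of the sampler, not of a particular seed.
Azoospermia-like samples are generated by setting the sperm share to
exactly zero; one such sample is included by default in the semen profile.

*Reads*: per-entry coverage is Poisson(74) and methylated reads are
Binomial(coverage, level) — the noise model of count-derived methylation
fractions. A Gaussian-jitter mode (level perturbed, then quantised to read
counts) exists for fixed-noise stress tests, and a "none" mode for
degenerate checks; because levels are always stored as
`meth_reads / total_reads` for file-format consistency, even the noiseless
mode carries quantisation of at most 1/(2·coverage). Entries below the
floor are missing in the exported matrix, but the CGmap files contain
every covered call, leaving floor enforcement to the aggregation step
where it belongs (and where tests verify it bit-exactly).

What the generator does **not** emulate: linkage between neighbouring
CpGs, genomic coordinate structure beyond synthetic ids, bisulfite
conversion error, strand-specific artefacts, reference-profile
misspecification (the deconvolution basis is exactly the mixing basis),
and nonlinear or interacting phenotype effects. Passing recovery tests on
this generator therefore demonstrates the correctness of the algorithms
under the stated generative model, not their field performance on real
cohorts, where reference mismatch and unmodelled cell types dominate the
error budget.

## Numerical choices and degenerate inputs

- Pseudoinverse cutoff as above; rank < 2 designs are rejected.
- Methylation means are clamped to [0, 1] after effect injection; imputed
  values are clamped likewise (a mean of in-range values is in range, so
  this is a guard, not a correction).
- kNN distance ties are broken by sample order; selection ranking ties by
  |coefficient| then site id; the argmax of filter 3 resolves exact
  coefficient ties by factor order. All three make reruns byte-identical.
- Zero-variance sites have undefined `r_site` and simply fail filter 1;
  zero-variance factors are a configuration error at design construction
  and an `NA` (never a fabricated 0) in evaluation reports.
- An all-zero NNLS solution under renormalisation is an explicit
  degenerate-fit error rather than a division by zero.
- CGmap parsing accepts the 8-column dialect and the 7-column variant
  without the sub-context column; malformed lines fail with their line
  number, and `meth_reads > total_reads` is a data error, not a warning.

## Problem sizes in the tests

The test and acceptance cohorts use 40–80 samples and 500–2,000 sites —
sizes at which every oracle (per-site OLS via normal equations, simplex
grid search at steps 0.01–0.02, brute-force Benjamini–Hochberg,
hand-computed kNN neighbourhoods) is exactly computable, chosen so the
whole suite re-verifies the algebra rather than sampling it. The grid
oracle bounds NNLS from above only because the simplex is a subset of the
non-negative orthant; the tests exploit that direction and never the
reverse.

## Known limitations

- Deconvolution quality is bounded by the reference: missing cell types
  are absorbed into the closest available columns, and no
  unknown-component discovery is attempted.
- The multifactor model is linear in scaled factors; saturating or
  threshold effects at individual CpGs will be under-detected.
- P-values assume homoscedastic Gaussian residuals per site; bisulfite
  fractions at extreme methylation violate this, so the
  Benjamini–Hochberg control should be read as approximate there.
- With fewer samples than factors plus three, LOOCV is refused rather
  than reported unstably.
- The 40× floor plus per-CpG strand merging means a panel's retained site
  count depends on both strands' depths; panels quoted per strand will
  retain different counts.
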