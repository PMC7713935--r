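---
title: "Models and methods behind bootmods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bootmods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters, the
synthetic-data generator, and the numerical and design choices made where the
procedure left genuine freedom. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` compute.

## The experimental design the package assumes

The pipeline targets a factorial bulk RNA-seq design: two populations
(`kauai`, `mangaia`) crossed with three infestation stages (`control`, `day4`,
`day7`), three pooled libraries per cell, eighteen libraries in all. Pooling
(two individuals per library) is treated implicitly: each library is one
sample, with no hierarchical individual layer, because the analysis operates
on pools as samples. All vocabulary is configurable, but default validation
enforces this design.

## Preprocessing

**Expression filter.** A gene is kept when its CPM (on raw library sizes,
pre-normalization) reaches `min_cpm = 1` in at least `min_samples = 2`
libraries, boundary inclusive. Filtering precedes normalization; TMM factors
are computed on the filtered matrix, mirroring the stated stage order.

**TMM.** The trimmed mean of M-values is re-implemented from its published
definition rather than wrapped: for sample *s* against reference *r*, over
genes positive in both, `M = log2((y_s/N_s)/(y_r/N_r))` and
`A = (log2(y_s/N_s) + log2(y_r/N_r))/2`; the upper and lower
`logratio_trim = 0.30` tails of M and `sum_trim = 0.05` tails of A are
removed; the factor is `2^(weighted mean of M)` with inverse asymptotic
(delta-method binomial) variance weights; factors are rescaled to geometric
mean 1. The `"auto"` reference is the sample whose upper-quartile CPM is
closest to the mean upper-quartile. The test suite checks the implementation
against a literal gene-by-gene evaluation of this definition and against
edgeR's implementation on the same data.

**Log-CPM.** `log2((y + prior)/(N·f + 2·prior) × 1e6)` with `prior = 0.5`.
Because the pseudocount is fixed, doubling counts and library sizes leaves
values unchanged only up to terms of order `prior/count`; the invariance is
exact in the deep-count limit. Voom-style precision weights (lowess of the
square-root residual SD against mean log-count, span 0.5) are computed and
exposed, but nothing downstream consumes them: inference runs through NB GLMs
on counts, and the network and ordination take unweighted log-CPM, which is
how the transform is used here — as input values, not as a weighting scheme.

**Variance prefilter.** Before network construction, exactly
`floor(0.40 × n)` genes with the smallest log-CPM variance across all 18
samples are dropped (ties broken by gene order). "Variance across treatments"
is read as variance across all samples — the simplest interpretation; the
fraction and the statistic are parameters.

## Differential expression

Each gene is modeled as NB(mean `mu_gs`, dispersion `phi_g`) with
`log mu_gs = beta_{g,cell(s)} + log(N_s f_s)` — a cell-means parameterization
over the six design cells. Contrasts are length-6 vectors over the cell
means; the standard set is the four within-population infested-vs-control
contrasts and the two day-specific difference-of-differences interactions.

**Dispersion.** A deliberate simplification of empirical-Bayes machinery:
a pooled within-cell method-of-moments estimate per gene (on counts scaled to
a common library), with a small-sample correction subtracting the within-cell
variance share from the squared-mean term (without it, `E[m^2] > mu^2`
biases dispersions low and inflates the LRT tail), floored at 1e-6; the
common dispersion is the median; tagwise values shrink toward the common one
with weight `prior_df/(prior_df + residual df)`, `prior_df = 10`. Validated
by parameter recovery (lognormal truth around 0.1), the Poisson limit, and
type-I calibration.

**Testing.** Full and reduced models are fitted by IRLS (tolerance 1e-8,
at most 100 iterations); the reduced design is the full one projected onto
the orthonormal null space of the contrast, so the LRT statistic is invariant
to reparameterization. `2·(ll_full − ll_reduced)` is referred to
chi-square(1). Genes with all-zero counts across the contrast's cells get
log2FC 0 and p 1; non-convergent genes are flagged and excluded from the BH
denominator. At n = 3 per cell the chi-square tail is slightly light relative
to the true LRT null distribution — a property shared by the standard NB-GLM
stacks at this sample size (the suite pins per-gene type-I error to
[0.03, 0.08] at alpha = 0.05, which holds, while any-discovery rates after BH
under a complete null remain above what independent-uniform p-values would
give; the reference count-model stack behaves the same way on identical
data).

**BH.** `stats::p.adjust(method = "BH")` applied to the non-missing entries;
missing values propagate and do not count toward the number of tests.

## The coexpression network

**Adjacency.** Signed hybrid: `a_ij = cor(x_i, x_j)^beta` when the Pearson
correlation is positive, else 0. Pearson (not biweight midcorrelation) is the
default of the framework at the stated settings. The soft threshold is the
smallest power in 1..20 whose signed scale-free fit reaches R² = 0.80
(log-log regression of binned connectivity frequencies, sign-corrected),
falling back to 6 with a warning; the source procedure does not state its
power, so the choice is made by this convention and recorded in the run
manifest.

**TOM and clustering.** Standard topological overlap; 1 − TOM is clustered
with average linkage. The dendrogram cut is a simplified adaptive height cut:
`deepSplit` in 0..4 maps linearly to a cut at {0.95, 0.90, 0.85, 0.80, 0.75}
of the merge-height range, branches under `minModuleSize = 30` genes are left
unassigned, and there is no PAM stage (consistent with
`pamRespectsHybrid = FALSE`) and no recursive branch analysis. The validated
property is planted-module recovery (adjusted Rand index against ground
truth), not label-for-label parity with any particular cutter — the consensus
layer, which is the substantive procedure, is agnostic to the cutter's
internals.

**Merging and blocks.** Modules merge while an eigengene pair correlates at
or above `1 − mergeCutHeight = 0.85` (the consensus stage's final merge is
strictly above 0.85 — "r > .85" — and the two comparisons use an epsilon
guard of 1e-9 so both boundaries are exact under floating point). Gene sets
above `maxBlockSize = 10000` are pre-partitioned by k-means on
row-standardized profiles (standardization matters: raw profiles cluster by
baseline, splitting correlated modules across blocks), the pipeline runs per
block with the block assignment seeded from the master seed, and modules
merge across blocks by eigengene correlation.

## Bootstrap consensus

250 networks (config default; tests and the acceptance script use 50 at desk
scale) are rebuilt on with-replacement resamples of the sample columns, with
identical network parameters including the original soft threshold;
duplicated samples enter the correlations with their multiplicity. A
resampled module *R* corresponds to an original module *O* when
`|R ∩ O| >= 0.10·|O|` (inclusive); the genes of `R ∩ O` then support *O* in
that replicate. One resampled module may correspond to several original
modules — its genes divide by their original labels. Support is binary per
replicate and tallied only toward a gene's own original module (the procedure
tests the reliability of original assignments; how support toward *other*
modules should be scored is unstated, and counting it would let a gene's
reliability exceed its replicate count). A gene keeps its label when
supported in at least 70% of replicates (inclusive); otherwise it joins the
unassigned bin. Originally unassigned genes never gain a label, so the final
topology is always a refinement of the full-data modules. Survivors merge at
eigengene r strictly above .85, then modules with fewer than 30 genes (29
dissolves, 30 stays) are dissolved and labels renumbered by size. Eigengene
signs are fixed (positive loading sum) before any merge correlation, since
principal-component sign indeterminacy would otherwise corrupt the r > .85
rule.

## Eigengenes, ANOVA and response categories

The eigengene is the first right-singular vector of the gene-standardized
module submatrix (unit norm, loading sum positive); variance explained is the
first squared singular value over the total. Per module, a fixed-effects
population × infestation ANOVA runs on the eigengene scores (the balanced
design makes sequential and partial sums of squares coincide); BH is applied
across modules per term — the original's module-level multiplicity handling
is unstated, and adjusting per term matches the pipeline's FDR convention
elsewhere.

Response categories are decided on day-7-minus-control eigengene deltas per
population, in pooled within-cell SD units, with `epsilon = 0.5` (a response
must exceed half a residual SD), `ratio = 2` (category I requires the larger
response to be at least twice the smaller), and `peak_frac = 0.5` (a day-7
delta only counts as a response when it is at least half the population's
peak delta across days — without this, a module that responds at day 4 and
relaxes by day 7 is misread as a day-7 response through its residue, which is
precisely the trajectory that defines the timing category). Rules: I — same
sign, both respond, ratio met; shared — same sign, both respond, ratio not
met; II — exactly one responds; III — both respond with opposite signs; IV —
neither responds at day 7 but the day-4 trajectories differ in sign pattern;
otherwise none. The category taxonomy is verbal in origin; these three
thresholds are the package's quantitative rendering, chosen once to separate
the planted effect sizes of the reference fixture and exposed as parameters.

## Ordination and PERMANOVA

Bray–Curtis consumes TMM-scaled CPM restricted to filter-passing genes:
the dissimilarity presumes non-negative abundance-like values, and the
source states only that counts were TMM-normalized before it. A config
switch substitutes log-CPM shifted to non-negative; no square-root or
Wisconsin standardization is applied by default — both left explicit rather
than inherited from wrapper defaults. nMDS minimizes Kruskal stress-1 via
vegan's monotone-regression engine in `k = 4`, best of 20 seeded random
starts plus one principal-coordinate start, coordinates centered and rotated
to principal axes. PERMANOVA (vegan's sequential partition) uses free
permutations — no blocking is stated — with the +1 permutation correction,
1,000 permutations by default.

## Enrichment

One-sided upper-tail hypergeometric ("classic" Fisher) tests per term against
the annotated universe; terms under 3 genes are skipped; BH across tested
terms is reported alongside raw p-values, and the significance convention
defaults to raw p < 0.05, matching how such enrichments are conventionally
read (GO graph structure is out of scope — the package consumes
pre-propagated gene-to-term tables).

## The synthetic-data generator

Counts are NB with `mu = 2^(baseline + shift + lambda·f) · N_s/1e6`:
per-gene baselines N(log2(1e6/n_genes)+1, 2²) log2-CPM, per-gene dispersions
lognormal around 0.1 (sdlog 0.4), library sizes uniform within ±30% of 5e6
(the source reports only a study-wide read total, so the spread is a chosen
value typical of pooled bulk libraries). Six planted modules carry the
response categories: shared up/down, I (same direction, 3× larger in kauai),
II (kauai only), III (opposed), IV (day-4-only responses of opposite sign —
chosen so the day-7 contrast is quiet and the difference is purely in
trajectory, which is what makes IV reachable after I–III are decided on
day-7 deltas). Per-gene responsiveness jitters in U(0.8, 1.2) with a common
sign, keeping planted modules positively correlated and hence recoverable by
a signed-hybrid network.

Within-module correlation is induced by one N(0,1) latent factor per module,
centered within design cells (so planted co-expression is orthogonal to the
condition structure and cannot corrupt realized group means) and standardized
to unit sample variance. Loadings are calibrated per gene against the
delta-method log2 sampling noise `v_g = (1/mu_g + phi_g)/ln(2)²` so the total
within-module correlation — shared response profile plus latent factor —
meets the target; the latent factor always carries at least `latent_frac =
0.5` of the covariance target, because modules whose response profiles are
nearly collinear (shared-up vs category I, profile correlation ≈ 0.94) are
otherwise inseparable by any correlation network, while a purely
latent-driven module would leave its eigengene with too little design signal
for the factorial ANOVA. A `de_noise_frac = 0.1` fraction of non-module
genes receives independent random DE shifts: differentially expressed but not
co-expressed, the canonical false-positive bait for module assignment.

What the generator does not emulate: read-level sampling, GC/length bias,
batch effects, annotation uncertainty, or dispersion–mean trends. Passing
tests therefore demonstrate that the procedures recover the structure they
are defined on at the study's sample sizes — not robustness to artifacts
real libraries may carry.

## Problem sizes and determinism

The reference fixture is 2,000 genes × 18 samples with six planted modules
(sizes 150–40, 60% noise genes, 10% of those DE-noise), analyzed with 50
bootstrap networks; null-calibration suites use 400–2,000 genes and 500
PERMANOVA datasets at 199 permutations. These sizes were chosen so the full
suite and the acceptance script each complete in minutes on a single CPU
while every recovery and calibration claim retains a meaningful margin.
One master seed drives everything; stage seeds derive from it by fixed
offsets so any stage can be re-run alone and reproduce the pipeline's result,
and bootstrap replicates derive per-replicate seeds the same way.

## Known limitations

- Dispersion estimation is moment-based with fixed-weight shrinkage; genes
  with strongly outlying dispersions are handled less gracefully than by
  Cox–Reid/empirical-Bayes estimators, and no dispersion–mean trend is
  fitted.
- The chi-square(1) LRT reference is slightly anticonservative in the extreme
  tail at n = 3 per cell (shared with standard stacks at this size).
- The adaptive height cut does not reproduce hybrid dynamic-tree-cut labels;
  only recovery of well-separated modules is claimed.
- The category classifier is a threshold rendering of a verbal taxonomy;
  modules near the thresholds are sensitive to `epsilon`, `ratio` and
  `peak_frac`.
- Blockwise results depend on the k-means pre-partition when genes exceed the
  block cap; the cross-block merge recovers split modules only when their
  eigengene correlation clears the merge threshold.
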