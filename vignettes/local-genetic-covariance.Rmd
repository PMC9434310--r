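---
title: "Local genetic covariance from Bayesian multitrait models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local genetic covariance from Bayesian multitrait models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package estimates

Whole-genome genetic correlations between two quantitative traits say that
their genetic bases overlap, but not *where*. `localcov` estimates the
genetic (co)variance attributable to small chromosomal windows, so that
individual pleiotropic regions — including regions whose local covariance
has the *opposite* sign to the global correlation — can be mapped and
tested.

The model, fit independently to large chromosomal segments, is the
bivariate linear regression

$$Y = 1\mu' + X\beta + E,$$

where $Y$ ($n \times 2$) holds the two preadjusted traits, $X$
($n \times m$) the centered SNP dosages of the segment, $\beta$
($m \times 2$) per-SNP effect pairs and the rows of $E$ are IID
$N_2(0, R)$. Effect pairs get a spike-and-slab prior: for SNP $j$ and trait
$k$, $\beta_{jk} = d_{jk} b_{jk}$ with $d_{jk} \sim
\mathrm{Bern}(\pi_k)$ and latent slab effects $b_{j\cdot} \sim N_2(0,
\Sigma)$. $R$ and $\Sigma$ carry inverse-Wishart priors, each $\pi_k$ a
Beta prior. The two traits are treated symmetrically throughout.

For an LD window $w$ with member dosages $X_w$ and retained posterior draw
$s$ of the member effects, the local quantities are the sample moments over
individuals

$$V_{w1}^{(s)} = \widehat{\mathrm{Var}}(X_w \beta_{w1}^{(s)}), \qquad
  V_{w2}^{(s)} = \widehat{\mathrm{Var}}(X_w \beta_{w2}^{(s)}), \qquad
  \mathrm{Cov}_w^{(s)} = \widehat{\mathrm{Cov}}(X_w \beta_{w1}^{(s)},
  X_w \beta_{w2}^{(s)}),$$

computed through the algebraically identical quadratic forms
$\beta_{w1}^{(s)\prime} S_w \beta_{w2}^{(s)}$ with $S_w$ the sample
covariance matrix of the member dosages ($n-1$ denominator; the choice is
immaterial at study sample sizes and is stated for test determinism).
Averaging over retained draws gives posterior means; empirical 2.5% and
97.5% quantiles give an equal-tailed 95% credible region (CR). A window is
*significant* when its covariance CR excludes zero. Because the draws are
sample moments of the same two score vectors, every draw satisfies
$|\mathrm{Cov}_w| \le \sqrt{V_{w1} V_{w2}}$, and the $V$ draws are
non-negative; the test suite asserts both on every run.

# The pipeline

1. **Input and QC** (`read_plink()`, `qc_filter()`): PLINK 1 bed/bim/fam or
   any dosage matrix; SNPs with minor allele frequency below 1% or missing
   call rate above 5% are dropped (both thresholds are arguments).
2. **Imputation and centering** (`impute_center()`): missing dosages are
   replaced by the per-SNP mean and columns are mean-centered. Dosages are
   *not* variance-standardized: $\mathrm{Var}(X_w\beta_w)$ is invariant to
   centering, and leaving the scale alone keeps effects per allele copy.
3. **Trait preadjustment** (`preadjust_traits()`): each trait is (optionally)
   log-transformed and regressed on an intercept, age, sex and leading
   genotype principal components by OLS; the residuals are the $Y$ columns.
   Covariate PCs are consumed, never computed here.
4. **Segmentation** (`make_segments()`): per chromosome, non-overlapping
   cores of 1,000 contiguous SNPs, each with up to 250 flanking SNPs on
   both sides included in the regression to absorb LD across core
   boundaries. The last core per chromosome keeps the remainder (< 1,000
   SNPs) rather than being merged backwards — cores stay non-overlapping
   and the flanks still supply LD context. Flanks are clipped at chromosome
   ends; segments never span chromosomes.
5. **Per-segment sampler** (`fit_segment()`): Gibbs sampling with 5,000
   iterations, 250 burn-in, thinning 10, retaining 475 draws (defaults;
   `retained_draw_count()` documents the arithmetic). Every block is
   updated each iteration.
6. **LD windows** (`define_window()`, `enumerate_windows()`): every *core*
   SNP seeds a window; candidates outward in both directions join while
   $|\mathrm{Corr}(x_{seed}, x_{cand})| \ge 0.1$, with a one-SNP gap
   allowance (a single failing SNP is included when the SNP beyond it
   passes) and termination after two consecutive failures, neither of which
   is included. Walks may enter the flanks but never leave the segment,
   and flank SNPs never seed windows. Duplicate member sets are removed,
   keeping the first seed in map order.
7. **Window estimates, significance and loci** (`estimate_windows()`,
   `merge_significant_windows()`, `write_results()`): per-window posterior
   summaries; significant windows sharing at least one member SNP are
   merged transitively into distinct loci; tables are written with
   (co)variances scaled by $10^4$ for readability.

`run_discovery()` executes the whole chain from one `pipeline_config()`;
`run_validation()` re-fits a second cohort while *freezing* the discovery
windows (matched by member SNP identifiers) and reports which
discovery-significant windows are significant again with the same
covariance sign.

# Sampler design

All full conditionals are standard, which a latent-variable augmentation
preserves: the full bivariate slab vector $b_j$ is kept for every SNP, and
components whose indicator is zero are refreshed from their conditional
prior, so $\Sigma \mid b$ stays a conjugate inverse-Wishart on all $m$
latent rows. Per iteration the updates run: $\mu$ (bivariate Gaussian),
then a per-SNP sweep updating $(d_{jk}, b_{jk})$ trait-within-SNP with
residual updating (cost $O(nm)$ per sweep; the indicator is drawn from its
marginal with the slab integrated out, with the log-odds computed in a
numerically stable form), then $\Sigma$, $R$ (inverse-Wishart) and $\pi_k$
(Beta). Every random number comes from R's RNG, so a chain is
bit-reproducible from `(data, config, seed)`; in the pipeline each
segment's seed is derived deterministically from the global seed and the
segment's (chromosome, core start), so serial and segment-parallel runs
agree and adding a segment never perturbs another's chain.

Default hyperparameters (all overridable in `mt_config()`, all recorded in
the fitted object): inverse-Wishart $\nu = 5$ for both covariances, with
the $R$ scale set so the prior mode assigns half of each trait's sample
variance to the error term, and the $\Sigma$ scale so the slab's implied
genomic variance — prior expected active SNPs $\times$ mean dosage variance
$\times$ slab variance — covers the other half; $\pi_k \sim
\mathrm{Beta}(0.1, 9.9)$, i.e. prior mean 1% active with the weight of ten
pseudo-observations. The intercepts get a proper but very flat Gaussian
prior ($10^6 \times$ the mean trait variance by default) so that the joint
model is proper and prior-invariance checks of the sampler are
well-defined; at that width it is indistinguishable from a flat prior.
Initialization: indicators all zero, $R$ at the sample covariance of $Y$,
$\Sigma$ at its prior mean, $\pi$ at its prior mean — cheap, with burn-in
absorbing the start. Numerical guards: $2\times2$ inversions and Cholesky
factors get escalating jitter from $10^{-10}$ on failure; degenerate slab
conditionals are floored at $10^{-12}$.

Two independent checks validate the implementation. With the spike
disabled ($\pi \equiv 1$) and $R, \Sigma$ held fixed, the model is a
conjugate multivariate ridge whose posterior mean is available in closed
form; the chain matches it within Monte-Carlo error. And a
successive-conditional simulation (alternating one Gibbs transition with
re-simulation of $Y$ from the current parameters) must leave the prior
invariant; chain moments of $\pi$, $\mathrm{diag}(\Sigma)$ and
$\mathrm{diag}(R)$ match direct prior draws within Monte-Carlo error on a
tiny instance ($n = 8$, $m = 4$, with $\nu = 8$ so the inverse-Wishart has
finite variance and a Monte-Carlo SE exists).

# Design choices at genuinely open points

* **Absolute correlation for windows.** The LD criterion uses
  $|\mathrm{Corr}|$: a signed criterion would make window membership depend
  on the arbitrary choice of counted allele. A zero-variance (monomorphic)
  column is assigned correlation 0, so it can never pass a positive
  threshold.
* **Terminal failures.** A failing SNP joins a window only when "rescued"
  by a passing SNP beyond it; when two consecutive failures end a
  direction, neither is included. This matches the walk's worked boundary
  cases and keeps windows minimal.
* **Window deduplication.** Distinct seeds can induce identical member
  sets; duplicates are collapsed (first seed in map order kept), and both
  raw and deduplicated counts are logged in the manifest.
* **Equal-tailed CRs.** Empirical quantile intervals (R's default type-7
  interpolation) rather than highest-density intervals; equal-tailed
  intervals are the common reporting convention for MCMC variance
  components, and the HDI of a mass-at-zero mixture is awkward to define.
* **Locus condensation by shared SNPs.** Significant windows are merged by
  the transitive closure of "shares at least one member SNP" — since
  windows are contiguous index runs this is an interval-overlap sweep,
  cross-checked in the tests against a generic union-find. Annotation-based
  merging (same literature locus) is out of scope.
* **Missing dosages are mean-imputed** before modeling: standard for
  dense-panel whole-genome regression, and it keeps $X$ complete for the
  sampler. The imputed mean contributes no variance to the window moments.
* **No multiplicity adjustment.** Significance is raw CR exclusion per
  window, as is conventional for this analysis; the manifest records the
  window count so users can post-filter.

# The synthetic-data generator

`simulate_genotypes()` draws, per individual and LD block, two latent
Gaussian AR(1) haplotype vectors thresholded at per-SNP cut points
$\Phi^{-1}(1 - \mathrm{MAF})$ and summed to dosages. This gives analytic
control of within-block LD (rising with the AR parameter) with independent
blocks, which is exactly the structure the window construction and the
flank logic need to be exercised; it does not emulate recombination
hotspots, demography, selection, imputation error or rare variants.
Positions sit on a uniform 3 kb grid so multi-SNP windows span tens of
kilobases. `simulate_traits()` instantiates $Y = X\beta + E$ exactly:
causal effect pairs drawn from $N_2(0, \Sigma_{loc})$ for chosen SNPs in
designated blocks, correlated residuals, and the realized $\beta$ and $E$
stored so that $Y - E \equiv X\beta$ holds to machine precision and
`true_window_cov()` can evaluate the same quadratic-form functional at the
planted effects.

The default configuration — 1,000 individuals, 600 SNPs in 20-SNP blocks
with latent AR(1) correlation 0.9, MAF uniform on (0.05, 0.5), one causal
block of 10 SNPs with per-SNP effect covariance $0.02 \times
\begin{psmallmatrix}1 & 0.9\\ 0.9 & 1\end{psmallmatrix}$, residual
covariance with correlation 0.2 — plants a local covariance that is a
substantial share (well above 5%) of the total trait covariance while
keeping a full pipeline replicate to a few seconds. These sizes are also
what the calibration experiments in the test suite and the acceptance
script use; the brute-force window comparisons use 200 smaller panels
(up to 100 SNPs), and the sampler-validation checks use $n = 200, m = 10$
(conjugate limit) and $n = 8, m = 4$ (prior invariance).

# What passing tests do and do not show

Passing tests show the arithmetic is right: the QC, imputation and
preadjustment agree with brute-force recomputation; the window walk agrees
with an independent reference on hundreds of random panels; the two routes
to the (co)variances agree to $10^{-10}$; the sampler passes the conjugate
closed form and prior-invariance checks; the full pipeline is
bit-reproducible under a seed. They do not show that real biobank data
meet the model's assumptions (block-independent LD, Gaussian residuals,
sparse bivariate-Gaussian effects), and two calibration properties fail
*by design of the inference, not by defect*, which the suite reports
honestly rather than hiding:

* Under a global null, the fraction of windows whose 95% covariance CR
  excludes zero is essentially 0, not 5%: with a sparsity prior and no
  signal the indicator draws are almost all zero, the covariance draws are
  almost all exactly zero, and the CR collapses to $[0, 0]$, which touches
  but does not exclude zero. Posterior CRs are not confidence intervals;
  the discovery procedure inherits this conservatism.
* For the same reason, the planted-signal CR covers the realized truth in
  fewer than 90% of desk-scale replicates: sub-threshold member effects are
  shrunk to exactly zero, biasing the window covariance toward zero when a
  planted block mixes strong and weak effects. Sign recovery of the
  planted covariance is nonetheless reliable, and per-SNP posterior means
  are unbiased in the conjugate limit. At biobank sample sizes the
  likelihood term grows roughly linearly in $n$ and dominates these
  penalties.

# Known limitations

Two traits only (the model generalizes; the implementation commits to the
bivariate case). LD is measured by genotype-dosage correlation, not
haplotype phase. Windows never cross segment boundaries, so a true signal
straddling two cores appears in both segments' flank-informed fits but in
two separate windows. Relatedness filtering, PC computation and
trait-specific transformations (beyond the log) are upstream concerns.
The equal-tailed CR of a point-mass mixture is conservative near zero, as
discussed above.
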