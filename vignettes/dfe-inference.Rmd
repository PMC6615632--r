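---
title: "Inferring the distribution of fitness effects from MA-line backcrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the distribution of fitness effects from MA-line backcrosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental design and the inference problem

Mutation accumulation (MA) lines carry a known set of spontaneous mutations,
identified by genome sequencing. Crossing an MA line to its unmutated
ancestor produces haploid recombinant lines (RLs), each inheriting a random
~50% subset of that line's mutations. Genotyping every RL at the known
mutation positions and phenotyping it for maximum growth rate (a laboratory
fitness proxy) turns the cross into a mapping experiment for the
*distribution of fitness effects* (DFE): with hundreds of mutations and
thousands of RLs, no mutation can be estimated as a fixed effect, but the
distribution its effect is drawn from can be inferred with a random-effects
mixture model.

`dfemix` implements that full path: growth-rate extraction from absorbance
time series, genotype QC and imputation, mixed-model tests for a
directional effect of mutation number, and Bayesian MCMC fitting of two
families of DFE models, with a synthetic-data generator that reproduces
the statistical structure the inference assumes.

## The data model

For one cross, the data are `n_b` phenotyped observations: a binary
`n_b x n_m` carriage matrix **M**, an optional binary matrix **F** of
two-level fixed effects (mating type, introgressed non-focal-background
regions of the compatible ancestor), a plate index per observation, and
the phenotype vector **y**. The observation model is

y_i = ybar + g_i + sum_j F_ij f_j + p[r_i] + e_i,

with plate effects p ~ Normal(0, V_p) and residuals e ~ Normal(0, V_e).
When several crosses are merged, a separate overall mean is fitted per MA
line. The genotypic value g_i is the sum of the effects of the mutations
the RL carries; the DFE model determines how those effects are structured:

* **Multicategory (point-mass) model.** Each mutation sits in one of `n_c`
  categories; category 0 has effect exactly zero, the others have free
  effects `e_k` and frequencies `q_k`. The likelihood contains the log
  frequency of each mutation's category, a multinomial term for the
  occupancy counts, the plate-effect densities, and the residual
  densities.
* **Two-sided (reflected) gamma model.** Each mutation has a side (0 =
  deleterious, 1 = beneficial, frequencies q_0 and 1 − q_0) and a positive
  magnitude drawn from that side's gamma distribution; the sign −/+ is
  applied by side. Sides may share or differ in mean and in shape. A shape
  well below 1 gives the leptokurtic, L-shaped DFE.

Two modelling notes, both deliberate:

* The likelihoods are implemented exactly as the model states them,
  including the fact that the per-mutation frequency terms and the
  multinomial/binomial occupancy term jointly count the category
  probabilities twice (up to the combinatorial coefficient). This sharpens
  the occupancy signal relative to a single-counted mixture likelihood.
  `chain_config(likelihood_variant = "count_term_only")` exposes the
  single-counted form for sensitivity analysis; the default is the model
  as stated.
* The gamma distributions are parametrized by **mean and shape** (the rate
  is shape/mean). The means of the two sides are the scientifically
  reported quantities, the stated priors are uniform on the mean and on
  the shape, and this parametrization makes both literal: with no data the
  chain reproduces exactly those uniforms (a property the test suite
  checks by Kolmogorov-Smirnov test).

## The sampler

`run_chain()` runs a Metropolis-Hastings sampler in which **one scalar
variable is proposed per iteration**, cycling deterministically through
the variable blocks (category/side indicator per mutation, effect or
magnitude parameters, frequencies, fixed effects, plate effects, means,
variances). All proposal kernels are symmetric — normal additive shifts for
most variables, uniform shifts for frequencies, a uniform draw among the
other categories for a category indicator, a deterministic flip for a side
indicator, and log-scale normal shifts for variances — so the Hastings
correction is 1 everywhere.

Priors: frequencies uniform on (0, 1); category effects uniform on ±0.5
phenotypic standard deviations; gamma side means uniform on (0, 0.5) SD;
gamma shapes uniform on (0.1, 100); fixed effects, plate effects and the
overall means flat; variances flat on the log scale (which also makes the
log-scale random walk symmetric). Phenotypes are standardized internally
to zero mean and unit SD so the SD-unit prior bounds are literal, and all
recorded draws are rescaled back to the input scale (the recorded log
likelihood stays on the standardized scale, which is immaterial for
within-dataset model comparison).

Proposal scales adapt multiplicatively toward 25% acceptance during
burn-in (windows of 100 proposals per variable) and are frozen afterwards.
The observation likelihood is maintained incrementally through per-line
sums of residuals and squared residuals; the bookkeeping is recomputed
from scratch every 1e5 iterations to bound floating-point drift, and the
test suite verifies that recorded log likelihoods match a full vectorized
recomputation at 1e-8 and that the vectorized likelihood matches a scalar
brute-force oracle at 1e-10.

Initialization matters more than usual here. Multicategory chains start
with every mutation in the zero class, zero effects and uniform
frequencies. For the gamma model the joint posterior over side
assignments has a rival mode: the many near-zero mutations can crowd onto
one side, dragging that side's fitted shape toward the L-shaped limit and
inflating its frequency — a self-reinforcing configuration that
single-site side flips escape only astronomically slowly, and the same
mechanism that inflates the estimated proportion of beneficial mutations
on real data. `run_chain()` therefore starts the gamma chain from the
empirical per-mutation estimates — the sign and magnitude of each
mutation's raw carrier/non-carrier phenotype contrast — which places it
in the dominant basin (sampled log likelihoods on simulated data are
~100 units above the rival mode's, and recovery of a simulated
different-shapes DFE succeeds from this start and fails from a random
one). An `init` argument accepts arbitrary starting values for
sensitivity checks. Overall means start at the per-line sample means,
V_e at the sample variance, V_p at V_e/10. Chains with the same seed and
configuration are bit-identical.

**Schedules.** The package default is a desk-scale schedule — 1e6 burn-in,
1e7 sampling iterations, thinning every 1e3 (1e4 retained draws) — which
the parameter-recovery experiments below show is sufficient for datasets
of roughly 40 mutations and 1e4 observations. The published-scale schedule
(1e8-1e9 burn-in, 1e9+ sampling, thinning every 1e4) is obtained by
raising the `chain_config()` counts.

## Posterior summaries and model comparison

Parameter estimates are **posterior modes**: the argmax of a Gaussian KDE
with Silverman's rule-of-thumb bandwidth on a 512-point grid (a histogram
fallback is available). The mode estimator is a package choice; modes of
well-mixed unimodal chains are insensitive to it. 95% credible intervals
are ranked-sample bounds at nearest ranks ceiling(0.025 n) and
floor(0.975 n) — the rank rule is likewise fixed here as a package
convention. Model comparison uses BIC = k log(n) − 2 log(L), with L the
maximum sampled log likelihood and k counting the per-mutation latent
variables (n_m category assignments for the multicategory model; 2 n_m
side-plus-magnitude variables for the gamma models); differences below
−10 are read as strong evidence. Signal checks permute phenotypes within
plates **without replacement** by default (`replace = TRUE` is available;
both conventions appear in descriptions of this design, and without
replacement is the one that preserves the within-plate multiset exactly).
Per-mutation effects under the gamma model are posterior means of the
signed effect, which are shrunk toward zero relative to raw
carrier-versus-non-carrier differences, as expected from a random-effects
model.

For multicategory chains with three or more categories the nonzero labels
are exchangeable and can switch along the chain;
`relabel_by_effect()` canonicalizes draws by sorting the nonzero
categories by effect value. It permutes the `e*`/`q*` columns only — the
per-mutation `m_*` columns keep their sampled labels — so it should be
applied before summarizing category-level parameters. Four-category fits
remain hard to interpret for exactly this reason, and the package makes no
attempt to resolve label switching beyond this ordering.

## The synthetic-data generator

`simulate_rl_dataset()` generates data with exactly the structure the
inference assumes: each mutation transmitted independently with
probability 0.5 (free recombination), effects drawn from a specified
point-mass or two-sided gamma DFE in phenotypic-SD units, optional
two-level fixed effects and normally distributed plate effects, and
normal residuals. Defaults follow the validation conditions used
throughout: 40 mutations, 10,000 observations, no fixed or plate effects,
unit residual variance. What it deliberately does **not** emulate:
linkage between mutations (real chromosomes transmit blocks; the
inference conditions on observed genotypes, so this affects power, not
correctness), genotyping error, missing data (QC and imputation are
tested on their own constructed tables), and non-normal residuals.
Passing recovery tests on these simulations therefore validates the
estimator under its own assumptions — the same scope as the original
validation design — not robustness to violations of them.

`simulate_growth_curves()` is a fixture for the growth-rate module:
logistic trajectories on the 12-96 h, 12-h grid with multiplicative
log-normal noise (an artifact choice; the noise SD is exposed). At low
density the log-slope equals the true rate, so the sliding-window
estimator should recover it, and on noiseless curves does so to numerical
precision.

## Growth rates, QC and the mixed model

`max_growth_rate()` fits ln(absorbance) on time by OLS in every
contiguous window of 5-8 measurements, discards windows with R² < 0.75
(strict: the boundary is kept), and returns the highest remaining slope.
Degenerate flat windows get R² = 0 (no growth signal) and are thereby
rejected; windows containing nonpositive absorbance are invalid without
discarding the rest of the curve; slope ties break to the earliest, then
shortest window.

The QC pipeline runs in a fixed order: drop invariant mutations, drop
mutations perfectly (anti)concordant with the mating-type or
introgressed-region markers (evaluated on pairwise-complete cases; no
complete case = no evidence = retained), set missing calls of known
single-working-primer mutations to the non-amplified allele, drop lines
with >10% missing or >5% heterozygous calls (strict inequalities), recode
surviving heterozygous calls to missing (the organism is haploid), then
impute: first from clonal mates within a mating reaction (strict identity
at all co-called sites; conflicting donors leave the call missing), then
from the adjacent mutation in genome order on the same chromosome when
r² > 0.7 (strict), phased by the sign of D; the higher-r² neighbour wins,
ties to the upstream one, and never across chromosomes.

`lrt_count()` tests the mutation-count predictor by comparing maximum
likelihood (not REML — required for a likelihood-ratio test on a fixed
effect) `lme4` fits with and without the count term, with mating type and
markers fixed and MA line, haplotype and plate random; within-cross fits
drop the single-level MA-line factor. Haplotype labels are treated as
globally unique in merged fits (cross-prefixed labels make them so). The
statistic is referred to chi-squared with 1 df; tiny negative values from
convergence noise are clipped to zero.

## Validation and problem sizes

The test suite validates the pipeline at these sizes, chosen to mirror the
validation design at desk scale:

* Parameter recovery on 40 mutations x 10,000 observations with the
  desk-scale schedule, for the two-category (e1 = 0.25, q1 = 0.2),
  three-category (e = −0.3/0.2, q = 0.1/0.2) and two-sided gamma
  (means 0.5/0.25, shapes 0.5/2, q+ = 0.25) DFEs; modes are required to
  fall within truth ± 2 posterior SDs.
* Likelihood oracle equivalence on 100 random instances with up to 20
  observations and 5 mutations.
* Prior recovery with no observations (1e4 retained draws, KS p > 0.01).
* Permutation-null centering over 50 within-plate permutations of a
  null-simulated 400-observation dataset.
* Empirical type-I error of the count LRT over 500 null simulations of
  60 lines x 2 replicates.

One caveat on the two-sided gamma recovery: with 40 mutations only ~10
fall on the positive side under q+ = 0.25, so the positive-side shape is
weakly identified and its posterior is broad; its mode test is
correspondingly loose. The negative-side mean of 0.5 SD also sits at the
default prior bound expressed in residual-SD units, but the bound is
applied in observed-phenotype SD units (larger here, since the genetic
variance is substantial), so the prior does not truncate it.

## Known limitations

* Free recombination in the generator; no linkage-block option.
* No probabilistic (genotype-likelihood) imputation; the LD step is a
  deterministic single-neighbour rule.
* No convergence diagnostics beyond acceptance rates and the draw trace;
  no R-hat gating.
* The four-category model's label switching is reported, not resolved.
* BIC parameter counts include latent per-mutation variables by
  convention; only BIC *differences* between models fitted to the same
  data are meaningful.
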