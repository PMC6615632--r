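# dfemix

Inference of the distribution of fitness effects (DFE) of spontaneous
mutations from mutation-accumulation (MA) backcross experiments.

## The problem

MA lines accumulate spontaneous mutations nearly neutrally; sequencing
tells us *which* mutations each line carries, but classical MA analyses
only see their cumulative effect. Crossing an MA line to its unmutated
ancestor yields haploid recombinant lines (RLs), each carrying a random
~50% subset of the mutations. Genotyping RLs at the known mutation
positions and measuring their maximum growth rate (a fitness proxy) gives
thousands of genotype-phenotype observations from which the *distribution*
of individual mutation effects can be inferred — even though no single
mutation's effect is estimable as a fixed effect.

`dfemix` is for researchers analysing such crosses (or designing them): it
covers growth-rate extraction, genotype QC, mixed-model tests, Bayesian
DFE fitting, and a synthetic-data generator for validation and power
exploration.

## The model

For observation *i* with carriage matrix **M**, fixed effects **F** (mating
type, introgressed-region markers), plate *r_i* and phenotype *y_i*:

    y_i = ybar + g_i + Σ_j F_ij f_j + p[r_i] + ε_i,
    p ~ N(0, V_p),  ε ~ N(0, V_e),
    g_i = Σ_j (effect of mutation j) · M_ij

Mutation effects follow one of two DFE families, fitted by
Metropolis-Hastings MCMC (one scalar variable proposed per iteration,
symmetric kernels, scales adapted to ~25% acceptance during burn-in):

* **Multicategory (point-mass)**: each mutation falls in one of n_c
  categories — category 0 has effect exactly 0, the others have free
  effects e_k and frequencies q_k.
* **Two-sided (reflected) gamma**: each mutation has a side (deleterious /
  beneficial, mixing proportion q⁺) and a gamma-distributed magnitude;
  sides can share or differ in mean and shape. Shape « 1 gives the
  leptokurtic, L-shaped DFE.

Estimates are posterior modes (KDE) with ranked-sample 95% credible
intervals; models are compared by BIC (parameter counts include the
per-mutation latent variables); signals are checked against within-plate
phenotype permutations.

## Worked example

Simulate the standard validation scenario — 40 mutations, 10,000
observations, a two-category DFE where 20% of mutations increase the trait
by 0.25 phenotypic SD — and refit it:

```r
library(dfemix)

dfe <- multicategory_dfe(effects = c(0, 0.25), freqs = c(0.8, 0.2))
sc  <- sim_scenario(n_m = 40, n_b = 10000, seed = 101)
d   <- simulate_rl_dataset(dfe, sc)

ch <- run_chain(d, multicat_model(2),
                chain_config(burnin = 1e6, sampling = 1e7, thin = 1e3,
                             seed = 102))
summary(ch)
#>   parameter      mode     ci_lo     ci_hi
#> 1        e1 0.2494642 0.2381945 0.2627952
#> 2        q1 0.2481880 0.1677133 0.3563635
```

The nonzero-category effect is recovered at 0.249 (truth 0.25). The
frequency mode 0.248 tracks the *realized* composition of this dataset
(the 40 simulated mutations are themselves a binomial draw from the DFE),
with a credible interval wide enough to reflect that only 40 mutations
inform it. Runtime is ~2.5 minutes on one core.

Growth rates from raw absorbance curves, and the mutation-count test:

```r
curves <- simulate_growth_curves(runif(58, 0.05, 0.15), noise_sd = 0.02)
rates  <- growth_rates(curves, r2_min = 0.75)  # one row per well, NA = no
                                               # window with adequate fit

lrt_count(my_analysis_table)   # chi-squared LRT for the count predictor
```

A thin command-line wrapper over these functions is installed at
`inst/scripts/dfemix-cli.R` (subcommands `growth`, `qc`, `lmm`, `fit`,
`summarize`).

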