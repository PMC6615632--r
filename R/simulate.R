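#' Define a simulation scenario for recombinant-line data
#'
#' Describes the experimental design the generator emulates: haploid
#' recombinant lines genotyped at `n_m` mutation sites, each mutation
#' transmitted independently with probability `transmission_prob` (free
#' recombination, matching the ~50% transmission of a backcross), optional
#' two-level fixed effects and normally distributed plate effects, and
#' normal residual noise.
#'
#' The defaults are the validation conditions used throughout: 40 mutations,
#' 10,000 observations, no fixed or plate effects, unit residual variance
#' (so effects are in phenotypic-SD units), and 50% transmission.
#'
#' @param n_m Number of mutations.
#' @param n_b Number of observations.
#' @param n_f Number of two-level fixed effects (default 0).
#' @param n_p Number of plates (default 0 = no plate effects).
#' @param V_p Plate-effect variance.
#' @param V_e Residual variance.
#' @param ybar Overall phenotype mean.
#' @param transmission_prob Probability an observation carries a mutation.
#' @param f_effects Fixed-effect values, length `n_f`.
#' @param od_noise_sd Log-scale multiplicative noise SD for simulated growth
#'   curves (an artifact of the growth-curve fixture, not of the DFE model).
#' @param seed Integer seed consumed by [simulate_rl_dataset()]; `NULL`
#'   leaves the RNG state alone.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_m = 40L, n_b = 10000L, n_f = 0L, n_p = 0L,
                         V_p = 0, V_e = 1, ybar = 0,
                         transmission_prob = 0.5,
                         f_effects = numeric(n_f),
                         od_noise_sd = 0.05, seed = NULL) {
  if (n_m < 0 || n_b < 0 || n_f < 0 || n_p < 0) stop("counts must be >= 0")
  if (V_p < 0 || V_e < 0) stop("variances must be >= 0")
  if (transmission_prob < 0 || transmission_prob > 1)
    stop("transmission_prob must lie in [0, 1]")
  if (length(f_effects) != n_f) stop("length(f_effects) must equal n_f")
  structure(
    list(n_m = as.integer(n_m), n_b = as.integer(n_b), n_f = as.integer(n_f),
         n_p = as.integer(n_p), V_p = V_p, V_e = V_e, ybar = ybar,
         transmission_prob = transmission_prob,
         f_effects = as.numeric(f_effects),
         od_noise_sd = od_noise_sd, seed = seed),
    class = "sim_scenario")
}

#' Simulate a binary mutation-carriage matrix
#'
#' Each entry is independently 1 with probability
#' `scenario$transmission_prob`, emulating free recombination in a haploid
#' backcross where each recombinant line inherits each mutation with
#' probability ~1/2.
#'
#' Uses the current RNG state; seed handling belongs to
#' [simulate_rl_dataset()].
#'
#' @param scenario A [sim_scenario()].
#' @return `n_b x n_m` integer matrix of 0/1.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  matrix(rbinom(scenario$n_b * scenario$n_m, 1L, scenario$transmission_prob),
         nrow = scenario$n_b, ncol = scenario$n_m)
}

#' Simulate per-mutation effects from a DFE
#'
#' For a multicategory DFE, each mutation's category is drawn from the
#' category frequencies and its effect is the category effect. For a
#' two-sided gamma DFE, the side is drawn (positive with probability
#' `q_pos`), the magnitude from that side's gamma distribution, and the sign
#' applied (-1 negative side, +1 positive side).
#'
#' @param dfe A [multicategory_dfe()] or [two_sided_gamma_dfe()].
#' @param n_m Number of mutations.
#' @return A data frame with columns `effect` (signed) and `label`
#'   (0-based category index for multicategory; 0 = negative / 1 = positive
#'   side for gamma).
#' @export
simulate_effects <- function(dfe, n_m) {
  stopifnot(inherits(dfe, "dfe_spec"))
  n_m <- as.integer(n_m)
  if (dfe$model == "multicategory") {
    lab <- sample.int(dfe$n_c, n_m, replace = TRUE, prob = dfe$freqs) - 1L
    data.frame(effect = dfe$effects[lab + 1L], label = lab)
  } else {
    side <- rbinom(n_m, 1L, dfe$q_pos)
    mag <- numeric(n_m)
    neg <- side == 0L
    # gamma parametrized by (mean, shape): rate = shape / mean
    if (any(neg))
      mag[neg] <- rgamma(sum(neg), shape = dfe$shape_neg,
                         rate = dfe$shape_neg / dfe$mean_neg)
    if (any(!neg))
      mag[!neg] <- rgamma(sum(!neg), shape = dfe$shape_pos,
                          rate = dfe$shape_pos / dfe$mean_pos)
    data.frame(effect = ifelse(neg, -mag, mag), label = side)
  }
}

#' Simulate phenotypes given genotypes and mutation effects
#'
#' Builds `y_i = ybar + g_i + sum_j F_ij f_j + p[r_i] + eps_i` with genotypic
#' value `g_i` the sum of effects of the mutations carried, plate effects
#' `p ~ Normal(0, V_p)`, and residuals `eps ~ Normal(0, V_e)`. Fixed-effect
#' columns are drawn as independent Bernoulli(1/2) levels.
#'
#' @param M Binary carriage matrix from [simulate_genotypes()].
#' @param effects Signed per-mutation effect vector (or the data frame from
#'   [simulate_effects()]).
#' @param scenario A [sim_scenario()].
#' @return An [rl_dataset()].
#' @export
simulate_phenotypes <- function(M, effects, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.data.frame(effects)) effects <- effects$effect
  if (ncol(M) != length(effects))
    stop("ncol(M) must equal length(effects)")
  if (nrow(M) != scenario$n_b)
    stop("nrow(M) must equal scenario$n_b")
  n_b <- scenario$n_b
  g <- as.numeric(M %*% effects)
  F <- NULL
  fx <- 0
  if (scenario$n_f > 0) {
    F <- matrix(rbinom(n_b * scenario$n_f, 1L, 0.5), n_b, scenario$n_f)
    fx <- as.numeric(F %*% scenario$f_effects)
  }
  plate <- NULL
  px <- 0
  if (scenario$n_p > 0) {
    plate <- rep_len(seq_len(scenario$n_p), n_b)
    p <- rnorm(scenario$n_p, 0, sqrt(scenario$V_p))
    px <- p[plate]
  }
  y <- scenario$ybar + g + fx + px + rnorm(n_b, 0, sqrt(scenario$V_e))
  rl_dataset(y = y, M = M, F = F, plate = plate)
}

#' Simulate a complete RL dataset from a DFE and scenario
#'
#' Convenience wrapper: sets the scenario seed (when given), simulates
#' genotypes, effects and phenotypes, and attaches the simulation truth.
#'
#' @param dfe A `dfe_spec`.
#' @param scenario A [sim_scenario()].
#' @return An [rl_dataset()] with attribute `truth`, a data frame of the
#'   signed per-mutation effects and labels actually simulated.
#' @export
simulate_rl_dataset <- function(dfe, scenario) {
  stopifnot(inherits(dfe, "dfe_spec"), inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  M <- simulate_genotypes(scenario)
  eff <- simulate_effects(dfe, scenario$n_m)
  data <- simulate_phenotypes(M, eff$effect, scenario)
  attr(data, "truth") <- eff
  data
}

#' Simulate absorbance growth curves for known growth rates
#'
#' Fixture generator for the growth-rate module: logistic curves
#' `A(t) = K A0 e^{rt} / (K + A0 (e^{rt} - 1))` sampled on the 12-h grid
#' from 12 to 96 h, with multiplicative log-normal measurement noise. At low
#' density the log-slope equals the true rate, so a sliding-window log-linear
#' fit recovers `r` up to noise.
#'
#' @param true_rates Numeric vector of true maximum growth rates (per hour,
#'   >= 0), one per well.
#' @param design Optional data frame with one row per well and columns
#'   `plate`, `well`, `line`, `replicate`; defaults to plates of 58 wells
#'   (the layout of the growth assay, 58 recombinant lines per plate).
#' @param A0 Initial absorbance.
#' @param K Carrying-capacity absorbance.
#' @param noise_sd SD of the log-scale multiplicative noise (0 = noiseless).
#' @param times Measurement grid in hours.
#' @return A long-format data frame with columns `plate`, `well`, `line`,
#'   `replicate`, `time_h`, `od650`.
#' @export
simulate_growth_curves <- function(true_rates, design = NULL, A0 = 0.01,
                                   K = 1.0, noise_sd = 0.05,
                                   times = seq(12, 96, by = 12)) {
  if (any(true_rates < 0)) stop("rates must be >= 0")
  n <- length(true_rates)
  if (is.null(design)) {
    plate <- (seq_len(n) - 1L) %/% 58L + 1L
    well <- (seq_len(n) - 1L) %% 58L + 1L
    design <- data.frame(plate = plate, well = well,
                         line = paste0("RL", seq_len(n)), replicate = 1L)
  }
  if (nrow(design) != n) stop("design must have one row per rate")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- true_rates[i]
    A <- K * A0 * exp(r * times) / (K + A0 * (exp(r * times) - 1))
    if (noise_sd > 0) A <- A * exp(rnorm(length(times), 0, noise_sd))
    out[[i]] <- data.frame(design[i, , drop = FALSE], time_h = times,
                           od650 = A, row.names = NULL)
  }
  do.call(rbind, out)
}
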