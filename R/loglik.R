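#' Genotypic value of one observation under the multicategory model
#'
#' Sum of the effects of the carried mutations: each mutation `j` sits in
#' category `m[j]` with effect `e[m[j]]`, and a non-carried mutation indexes
#' the zero-effect category (category 0), so carriage alone switches the
#' effect on. Categories are 0-based; `e[1]` (R indexing) is the zero-effect
#' category and equals 0.
#'
#' @param M_row 0/1 carriage vector for the observation, length `n_m`.
#' @param m Integer category per mutation, 0-based (`0 .. n_c - 1`).
#' @param e Effect per category, length `n_c`, `e[1] == 0`.
#' @return The genotypic value, a scalar.
#' @examples
#' genotypic_value_multicat(c(1, 0, 1), c(1, 0, 2), c(0, -0.03, 0.02))
#' @export
genotypic_value_multicat <- function(M_row, m, e) {
  sum(e[M_row * m + 1L])
}

#' Genotypic value of one observation under the two-sided gamma model
#'
#' Each mutation `j` has a positive magnitude on each side stored in the
#' 2 x n_m matrix `E`; its current side `mu[j]` (0 = negative, 1 = positive)
#' selects the magnitude, and the sign `delta_j` (-1 for side 0, +1 for side
#' 1) is applied. Only carried mutations contribute.
#'
#' @param M_row 0/1 carriage vector, length `n_m`.
#' @param mu Integer side per mutation (0/1).
#' @param E 2 x n_m matrix of positive magnitudes; row 1 = negative side,
#'   row 2 = positive side (0-based sides 0/1).
#' @return The genotypic value, a scalar.
#' @export
genotypic_value_gamma <- function(M_row, mu, E) {
  n_m <- length(M_row)
  sel <- E[cbind(mu + 1L, seq_len(n_m))]
  delta <- ifelse(mu == 0L, -1, 1)
  sum(sel * delta * M_row)
}

# shared normal terms: plate effects and per-observation residuals
shared_loglik_terms <- function(data, state, shared) {
  ll <- 0
  if (data$n_p > 0) {
    if (shared$V_p <= 0) return(-Inf)
    ll <- ll + sum(dnorm(shared$p, 0, sqrt(shared$V_p), log = TRUE))
  }
  if (data$n_b > 0) {
    if (shared$V_e <= 0) return(-Inf)
    g <- state$g
    fx <- if (data$n_f > 0) as.numeric(data$F %*% shared$f) else 0
    px <- if (data$n_p > 0) shared$p[data$plate] else 0
    resid <- data$y - g - fx - px
    ll <- ll + sum(dnorm(resid, shared$ybar[data$line], sqrt(shared$V_e),
                         log = TRUE))
  }
  ll
}

#' Log likelihood of an RL dataset under the multicategory model
#'
#' As printed, the likelihood is the sum of (a) the log category frequency
#' of every mutation, (b) the log multinomial probability of the category
#' occupancy counts, (c) the normal log density of each plate effect, and
#' (d) the normal log density of each observation's residual about the
#' overall mean. Terms (a) and (b) jointly count the category probabilities
#' twice (up to the multinomial coefficient); `variant =
#' "count_term_only"` keeps only (b) for sensitivity analysis.
#'
#' @param data An [rl_dataset()].
#' @param state List with `m` (0-based category per mutation), `e` (effects
#'   per category, `e[1] == 0`), `q` (frequencies per category, summing
#'   to 1).
#' @param shared List with `f` (fixed effects), `p` (plate effects), `V_p`,
#'   `ybar` (one per MA line), `V_e`.
#' @param variant `"as_printed"` (default) or `"count_term_only"`.
#' @return Log likelihood (may be `-Inf`, e.g. an occupied category with
#'   zero frequency).
#' @export
loglik_multicat <- function(data, state, shared,
                            variant = c("as_printed", "count_term_only")) {
  variant <- match.arg(variant)
  n_c <- length(state$e)
  stopifnot(length(state$q) == n_c, state$e[1] == 0,
            length(state$m) == data$n_m)
  v <- tabulate(state$m + 1L, nbins = n_c)
  if (any(state$q < 0) || sum(state$q[-1]) >= 1 + 1e-12) return(-Inf)
  if (any(v > 0 & state$q == 0)) return(-Inf)
  lq <- ifelse(v > 0, v * log(state$q), 0)
  count_term <- lgamma(data$n_m + 1) - sum(lgamma(v + 1)) + sum(lq)
  cat_ll <- if (variant == "as_printed") sum(lq) + count_term else count_term
  per_mut <- state$e[state$m + 1L]
  state$g <- if (data$n_b > 0) as.numeric(data$M %*% per_mut) else numeric(0)
  cat_ll + shared_loglik_terms(data, state, shared)
}

#' Log likelihood of an RL dataset under the two-sided gamma model
#'
#' As printed: for each mutation, the log gamma density of its selected
#' magnitude under its side's distribution plus the log frequency of that
#' side; the log binomial probability of the negative-side count; and the
#' shared plate and residual normal terms. The per-mutation side
#' frequencies and the binomial term jointly count the side probabilities
#' twice (up to the binomial coefficient); `variant = "count_term_only"`
#' keeps only the binomial term.
#'
#' The gamma distributions are parametrized by mean and shape; the rate is
#' `shape / mean` (mean = shape / rate), so the printed means of the
#' distributions are the means of the sampled magnitudes.
#'
#' @param data An [rl_dataset()].
#' @param state List with `mu` (side per mutation, 0 = negative, 1 =
#'   positive), `E` (2 x n_m positive magnitudes), `q_neg` (frequency of
#'   negative-effect mutations), `mean` (length-2 vector of side means),
#'   `shape` (length-2 vector of side shapes).
#' @param shared As in [loglik_multicat()].
#' @inheritParams loglik_multicat
#' @return Log likelihood (`-Inf` for nonpositive magnitudes or a frequency
#'   outside (0, 1)).
#' @export
loglik_gamma <- function(data, state, shared,
                         variant = c("as_printed", "count_term_only")) {
  variant <- match.arg(variant)
  n_m <- data$n_m
  stopifnot(length(state$mu) == n_m)
  if (state$q_neg <= 0 || state$q_neg >= 1) return(-Inf)
  if (any(state$mean <= 0) || any(state$shape <= 0)) return(-Inf)
  q <- c(state$q_neg, 1 - state$q_neg)
  v0 <- sum(state$mu == 0L)
  mut_ll <- 0
  if (n_m > 0) {
    sel <- state$E[cbind(state$mu + 1L, seq_len(n_m))]
    if (any(sel <= 0)) return(-Inf)
    sh <- state$shape[state$mu + 1L]
    mn <- state$mean[state$mu + 1L]
    mut_ll <- sum(dgamma(sel, shape = sh, rate = sh / mn, log = TRUE)) +
      if (variant == "as_printed") sum(log(q[state$mu + 1L])) else 0
  }
  count_term <- dbinom(v0, n_m, state$q_neg, log = TRUE)
  delta <- ifelse(state$mu == 0L, -1, 1)
  state$g <- if (data$n_b > 0) {
    sel <- if (n_m > 0) state$E[cbind(state$mu + 1L, seq_len(n_m))] else numeric(0)
    as.numeric(data$M %*% (sel * delta))
  } else numeric(0)
  mut_ll + count_term + shared_loglik_terms(data, state, shared)
}
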