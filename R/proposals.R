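#' Proposal kernels used by the samplers
#'
#' Three symmetric proposal kernels: an additive shift (normal deviates for
#' most variables, uniform deviates for category/side frequencies), a
#' uniform draw among the other categories for a mutation's category index,
#' and a deterministic flip for a mutation's side indicator. All are
#' symmetric, so the Hastings correction is 1 and the acceptance rule
#' reduces to the Metropolis ratio.
#'
#' @param current Current value.
#' @param scale Proposal scale (SD for `"normal"`, half-width for
#'   `"uniform"`).
#' @param kind `"normal"` or `"uniform"`.
#' @return The proposed value.
#' @export
propose_shift <- function(current, scale, kind = c("normal", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "normal") current + rnorm(1, 0, scale)
  else current + runif(1, -scale, scale)
}

#' @rdname propose_shift
#' @param n_c Number of categories.
#' @return `propose_category`: an integer in `0 .. n_c - 1` different from
#'   `current`, uniformly chosen.
#' @export
propose_category <- function(current, n_c) {
  others <- setdiff(seq_len(n_c) - 1L, current)
  if (!length(others)) stop("need at least 2 categories to propose a move")
  others[sample.int(length(others), 1L)]
}

#' @rdname propose_shift
#' @return `propose_flip`: `1 - current` (side indicators flip
#'   deterministically).
#' @export
propose_flip <- function(current) {
  1L - as.integer(current)
}

#' Metropolis-Hastings accept/reject decision
#'
#' Accept with probability `min(1, exp(delta))` where `delta` is the change
#' in log posterior under a symmetric proposal. A non-finite proposed state
#' (`delta = -Inf` or `NaN`) is always rejected.
#'
#' @param delta Change in log posterior (proposed minus current).
#' @param u Uniform(0,1) draw; supplied for reproducible testing, drawn
#'   internally by default.
#' @return Logical: accept?
#' @export
mh_accept <- function(delta, u = runif(1)) {
  if (!is.finite(delta)) return(is.nan(delta) == FALSE && delta > 0)
  if (delta >= 0) TRUE else u < exp(delta)
}

#' Adapt a proposal scale toward a target acceptance rate
#'
#' Multiplicative update used during burn-in: the scale grows when the
#' observed acceptance rate is above target (proposals too timid) and
#' shrinks when below (too bold). After burn-in the scales are frozen.
#'
#' @param scale Current proposal scale.
#' @param rate Observed acceptance rate over the last adaptation window.
#' @param target Target acceptance rate (default 0.25).
#' @return Updated scale, clamped to `[1e-8, 1e8]`.
#' @export
tune_scale <- function(scale, rate, target = 0.25) {
  min(1e8, max(1e-8, scale * exp(rate - target)))
}
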