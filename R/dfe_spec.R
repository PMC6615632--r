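#' Specify a multicategory (point-mass mixture) DFE
#'
#' The multicategory model assumes every mutation's effect falls into one of
#' `n_c` discrete categories. Category 0 always has effect zero (mutations
#' with no detectable effect on the trait); the remaining categories have
#' free effects. Each category has a frequency, and the frequencies sum to 1.
#'
#' Effects are expressed in phenotypic standard deviation units unless the
#' surrounding code states otherwise.
#'
#' @param effects Numeric vector of per-category effects, `effects[1]` is the
#'   zero-effect category and must equal 0.
#' @param freqs Numeric vector of category frequencies, same length as
#'   `effects`, each in `[0, 1]`, summing to 1.
#' @return An object of class `dfe_spec` (model `"multicategory"`).
#' @examples
#' multicategory_dfe(effects = c(0, 0.25), freqs = c(0.8, 0.2))
#' @export
multicategory_dfe <- function(effects, freqs) {
  if (length(effects) != length(freqs))
    stop("`effects` and `freqs` must have the same length")
  if (length(effects) < 1L)
    stop("need at least one category")
  if (effects[1] != 0)
    stop("the first category is the zero-effect class; effects[1] must be 0")
  if (any(freqs < 0) || any(freqs > 1))
    stop("frequencies must lie in [0, 1]")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("frequencies must sum to 1")
  structure(
    list(model = "multicategory", effects = as.numeric(effects),
         freqs = as.numeric(freqs), n_c = length(effects)),
    class = "dfe_spec")
}

#' Specify a two-sided (reflected) gamma DFE
#'
#' Mutation effect magnitudes are gamma-distributed separately for
#' fitness-decreasing (negative side) and fitness-increasing (positive side)
#' mutations; a mutation is positive with probability `q_pos`. The negative
#' side is the gamma distribution reflected to the negative axis.
#'
#' Means are magnitudes (>= 0); the sign is applied by side. Shapes are
#' dimensionless; shape << 1 gives a leptokurtic (L-shaped) side.
#'
#' @param mean_neg,mean_pos Mean magnitude of each side (phenotypic-SD units).
#' @param shape_neg,shape_pos Gamma shape parameter of each side (> 0).
#' @param q_pos Proportion of positive-effect mutations, in `[0, 1]`.
#' @return An object of class `dfe_spec` (model `"two_sided_gamma"`).
#' @examples
#' two_sided_gamma_dfe(mean_neg = 0.5, mean_pos = 0.25,
#'                     shape_neg = 0.5, shape_pos = 2, q_pos = 0.25)
#' @export
two_sided_gamma_dfe <- function(mean_neg, mean_pos, shape_neg, shape_pos,
                                q_pos) {
  if (mean_neg < 0 || mean_pos < 0) stop("means must be >= 0")
  if (shape_neg <= 0 || shape_pos <= 0) stop("shapes must be > 0")
  if (q_pos < 0 || q_pos > 1) stop("q_pos must lie in [0, 1]")
  structure(
    list(model = "two_sided_gamma", mean_neg = mean_neg, mean_pos = mean_pos,
         shape_neg = shape_neg, shape_pos = shape_pos, q_pos = q_pos),
    class = "dfe_spec")
}

#' @export
print.dfe_spec <- function(x, ...) {
  if (x$model == "multicategory") {
    cat("Multicategory DFE with", x$n_c, "categories\n")
    cat("  effects:", paste(signif(x$effects, 4), collapse = ", "), "\n")
    cat("  freqs:  ", paste(signif(x$freqs, 4), collapse = ", "), "\n")
  } else {
    cat("Two-sided gamma DFE\n")
    cat(sprintf("  negative side: mean %g, shape %g (freq %g)\n",
                x$mean_neg, x$shape_neg, 1 - x$q_pos))
    cat(sprintf("  positive side: mean %g, shape %g (freq %g)\n",
                x$mean_pos, x$shape_pos, x$q_pos))
  }
  invisible(x)
}
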