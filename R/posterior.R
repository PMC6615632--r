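#' Posterior mode of a set of draws
#'
#' The parameter estimate is the mode of the posterior: the argmax of a
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth,
#' evaluated on a 512-point grid over the draw range). `method =
#' "histogram"` is a fallback using the midpoint of the fullest of
#' `ceiling(sqrt(n))` equal-width bins.
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @param method `"kde"` (default) or `"histogram"`.
#' @return The estimated mode.
#' @export
posterior_mode <- function(draws, method = c("kde", "histogram")) {
  method <- match.arg(method)
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) stop("too few draws (need >= 100)")
  if (diff(range(draws)) == 0) return(draws[1])
  if (method == "kde") {
    den <- density(draws, bw = "nrd0", n = 512)
    den$x[which.max(den$y)]
  } else {
    breaks <- seq(min(draws), max(draws),
                  length.out = ceiling(sqrt(length(draws))) + 1L)
    h <- hist(draws, breaks = breaks, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}

#' Ranked-sample credible interval
#'
#' Bounds are taken from the ranked draws at nearest ranks:
#' `ceiling(a n)` for the lower bound and `floor((1 - a) n)` for the upper,
#' with `a = (1 - level)/2` (clamped to valid ranks).
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @param level Credible level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100) stop("too few draws (need >= 100)")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  s <- sort(draws)
  eps <- 1e-9  # guard against floating-point spill across integer ranks
  lo <- min(n, max(1L, ceiling(a * n - eps)))
  hi <- min(n, max(lo, floor((1 - a) * n + eps)))
  c(s[lo], s[hi])
}

#' Bayesian information criterion
#'
#' `BIC = k log(n) - 2 log(Lhat)`. For chains, `Lhat` is taken as the
#' maximum log likelihood over the sampled (post-burn-in) draws. Parameter
#' counts for the DFE models include the per-mutation latent variables:
#' the category assignment for the multicategory model and, for the
#' two-sided gamma models, twice the number of mutations (side indicator
#' and magnitude).
#'
#' @param max_loglik Maximum log likelihood.
#' @param k Number of parameters.
#' @param n Number of observations.
#' @return The BIC value.
#' @export
bic <- function(max_loglik, k, n) {
  if (k <= 0 || n <= 0) stop("k and n must be positive")
  k * log(n) - 2 * max_loglik
}

#' @rdname bic
#' @param chain A `chain_samples` object.
#' @return `bic_chain`: the BIC of a fitted chain, using the maximum
#'   sampled log likelihood and the model's parameter count.
#' @export
bic_chain <- function(chain) {
  stopifnot(inherits(chain, "chain_samples"))
  dims <- chain$data_dims
  nuisance <- dims$n_f + dims$n_p + (dims$n_p > 0) + dims$n_lines + 1
  k <- if (chain$model$kind == "multicategory") {
    n_c <- chain$model$n_c
    dims$n_m + 2 * (n_c - 1) + nuisance
  } else {
    2 * dims$n_m + 1 +
      (if (chain$model$means == "same") 1 else 2) +
      (if (chain$model$shapes == "same") 1 else 2) + nuisance
  }
  bic(max(chain$draws[, "loglik"]), k, dims$n_b)
}

#' @rdname bic
#' @param bic_a,bic_b BIC values of two models.
#' @param strong_threshold ΔBIC below which evidence for model A is called
#'   strong (default -10).
#' @return `bic_compare`: list with `delta` (`bic_a - bic_b`) and `verdict`.
#' @export
bic_compare <- function(bic_a, bic_b, strong_threshold = -10) {
  delta <- bic_a - bic_b
  verdict <- if (delta < strong_threshold) "strong evidence for A"
  else if (-delta < strong_threshold) "strong evidence for B"
  else "no strong evidence"
  list(delta = delta, verdict = verdict)
}

#' Permute phenotypes within plates
#'
#' Shuffles the phenotype vector among observations within each plate
#' (among all observations when the dataset has no plates). The default is
#' permutation without replacement, which preserves the within-plate
#' multiset of phenotypes exactly; `replace = TRUE` resamples within plate
#' with replacement instead.
#'
#' @param data An [rl_dataset()].
#' @param replace Resample with replacement?
#' @return A new [rl_dataset()] with permuted `y`.
#' @export
permute_phenotypes <- function(data, replace = FALSE) {
  stopifnot(inherits(data, "rl_dataset"))
  y <- data$y
  groups <- if (data$n_p > 0) split(seq_len(data$n_b), data$plate)
  else list(seq_len(data$n_b))
  for (idx in groups) {
    y[idx] <- if (replace) y[sample(idx, length(idx), replace = TRUE)]
    else y[sample(idx, length(idx))]
  }
  out <- data
  out$y <- y
  out
}

#' Null distribution of DFE estimates from permuted phenotypes
#'
#' Repeatedly permutes phenotypes within plates, refits the model, and
#' records the posterior mode of each effect parameter. Under the null of
#' no genotype-phenotype association the permuted-data effect estimates
#' centre on zero; genuine estimates from the unpermuted data are expected
#' to fall outside this distribution.
#'
#' @param data An [rl_dataset()].
#' @param model A `dfe_model`.
#' @param config A [chain_config()]; `config$seed` seeds the whole
#'   procedure and each replicate chain gets a distinct derived seed.
#' @param n_perm Number of permutation replicates.
#' @param params Draw columns to summarize (default: the model's effect
#'   parameters).
#' @param replace Permute with replacement?
#' @return Data frame with one row per replicate and one column per
#'   parameter mode.
#' @export
permutation_null <- function(data, model, config, n_perm = 50,
                             params = NULL, replace = FALSE) {
  if (is.null(params)) {
    params <- if (model$kind == "multicategory")
      paste0("e", seq_len(model$n_c - 1))
    else c("mean_neg", "mean_pos")
  }
  set.seed(config$seed)
  perm_seeds <- sample.int(2^30, n_perm)
  rows <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(perm_seeds[i])
    pdata <- permute_phenotypes(data, replace = replace)
    cfg <- config
    cfg$seed <- perm_seeds[i]
    chain <- run_chain(pdata, model, cfg)
    modes <- vapply(params, function(pp) posterior_mode(chain$draws[, pp]),
                    0)
    rows[[i]] <- as.data.frame(as.list(modes))
  }
  out <- do.call(rbind, rows)
  names(out) <- params
  rownames(out) <- NULL
  out
}

#' Per-mutation effect estimates
#'
#' For a two-sided gamma chain, each mutation's effect is estimated as the
#' posterior mean of its signed effect (side times magnitude) across
#' draws. The raw-difference estimate is the difference in mean phenotype
#' between carriers and non-carriers, computed within each MA-line cross
#' (only crosses where the mutation segregates contribute) and averaged.
#' MCMC estimates are shrunk toward zero relative to raw differences, as
#' expected under a random-effects model.
#'
#' @param chain A gamma-model `chain_samples` object.
#' @param data The [rl_dataset()] the chain was fitted to.
#' @param annotations Optional data frame of per-mutation annotation
#'   classes (one row per mutation), carried through to the output.
#' @return Data frame with one row per mutation: `mutation`,
#'   `posterior_mean`, `raw_difference`, plus any annotation columns.
#' @export
mutation_effects <- function(chain, data, annotations = NULL) {
  stopifnot(inherits(chain, "chain_samples"), inherits(data, "rl_dataset"))
  if (chain$model$kind != "gamma")
    stop("per-mutation effects are defined for the gamma model chain")
  eff_cols <- paste0("effect_", seq_len(data$n_m))
  if (!all(eff_cols %in% colnames(chain$draws)))
    stop("chain does not contain per-mutation effect draws")
  post_mean <- colMeans(chain$draws[, eff_cols, drop = FALSE])
  raw <- vapply(seq_len(data$n_m), function(j) {
    diffs <- c()
    for (l in seq_len(max(data$n_lines, 1))) {
      idx <- data$line == l
      carrier <- idx & data$M[, j] == 1
      noncar <- idx & data$M[, j] == 0
      if (any(carrier) && any(noncar))
        diffs <- c(diffs, mean(data$y[carrier]) - mean(data$y[noncar]))
    }
    if (length(diffs)) mean(diffs) else NA_real_
  }, 0)
  out <- data.frame(mutation = seq_len(data$n_m),
                    posterior_mean = as.numeric(post_mean),
                    raw_difference = raw)
  if (!is.null(annotations)) {
    if (nrow(annotations) != data$n_m)
      stop("annotations must have one row per mutation")
    out <- cbind(out, annotations)
  }
  out
}

#' Compare mean squared effects between two mutation classes
#'
#' The additive variance contributed by a mutation is proportional to its
#' squared effect, so classes are compared on the mean of squared
#' (posterior-mean) effects. The p-value is a two-sided bootstrap:
#' mutations are resampled with replacement within each class `n_boot`
#' times, and the p-value is twice the smaller tail probability of the
#' bootstrap difference distribution crossing zero, capped at 1.
#'
#' @param effects Numeric vector of per-mutation effect estimates.
#' @param class_labels Vector with exactly two distinct values splitting
#'   the mutations into classes.
#' @param n_boot Bootstrap replicates (default 1000).
#' @return List: `classes`, `mean_sq` (per class), `difference`
#'   (class 1 minus class 2), `p_value`.
#' @export
class_squared_effect_test <- function(effects, class_labels, n_boot = 1000) {
  cls <- unique(class_labels)
  if (length(cls) != 2) stop("need exactly two classes")
  x <- effects[class_labels == cls[1]]^2
  z <- effects[class_labels == cls[2]]^2
  if (!length(x) || !length(z)) stop("empty class")
  obs <- mean(x) - mean(z)
  boot <- replicate(n_boot, {
    mean(sample(x, length(x), replace = TRUE)) -
      mean(sample(z, length(z), replace = TRUE))
  })
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  list(classes = cls, mean_sq = c(mean(x), mean(z)), difference = obs,
       p_value = p)
}

#' Relabel multicategory draws by ordering effects
#'
#' Mixture models are invariant to permuting the nonzero category labels,
#' so chains can switch labels. This canonicalizes each draw by sorting the
#' nonzero categories by effect value (ascending), permuting the matching
#' `e*` and `q*` columns together. Per-mutation `m_*` columns are left
#' untouched.
#'
#' @param chain A multicategory `chain_samples` object.
#' @return The chain with relabelled `e*`/`q*` draw columns.
#' @export
relabel_by_effect <- function(chain) {
  stopifnot(inherits(chain, "chain_samples"),
            chain$model$kind == "multicategory")
  n_c <- chain$model$n_c
  if (n_c <= 2) return(chain)
  e_cols <- paste0("e", seq_len(n_c - 1))
  q_cols <- paste0("q", seq_len(n_c - 1))
  E <- chain$draws[, e_cols, drop = FALSE]
  Q <- chain$draws[, q_cols, drop = FALSE]
  ord <- t(apply(E, 1, order))
  for (r in seq_len(nrow(E))) {
    chain$draws[r, e_cols] <- E[r, ord[r, ]]
    chain$draws[r, q_cols] <- Q[r, ord[r, ]]
  }
  chain
}
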