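#' Specify a DFE model to fit
#'
#' `multicat_model(n_c)` requests the point-mass mixture with `n_c`
#' categories (category 0 has zero effect). `gamma_model()` requests the
#' two-sided (reflected) gamma model; the side means can be shared or
#' separate, as can the side shapes.
#'
#' @param n_c Number of categories (>= 1; `n_c = 1` is the null model).
#' @return An object of class `dfe_model`.
#' @export
multicat_model <- function(n_c) {
  n_c <- as.integer(n_c)
  if (n_c < 1L) stop("n_c must be >= 1")
  structure(list(kind = "multicategory", n_c = n_c), class = "dfe_model")
}

#' @rdname multicat_model
#' @param means `"different"` (one mean per side, the paper's main model) or
#'   `"same"`.
#' @param shapes `"same"` (default) or `"different"`.
#' @export
gamma_model <- function(means = c("different", "same"),
                        shapes = c("same", "different")) {
  structure(list(kind = "gamma", means = match.arg(means),
                 shapes = match.arg(shapes)), class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  if (x$kind == "multicategory")
    cat("Multicategory DFE model,", x$n_c, "categories\n")
  else
    cat(sprintf("Two-sided gamma DFE model (%s means, %s shapes)\n",
                x$means, x$shapes))
  invisible(x)
}

#' Configure an MCMC run
#'
#' The default is a desk-scale schedule (1e6 burn-in, 1e7 sampling
#' iterations thinned to every 1e3) suitable for the validation-size
#' datasets; the full published schedule (1e8-1e9 burn-in, thinning every
#' 1e4) is obtained by raising the counts. Proposal scales adapt toward 25%
#' acceptance during burn-in only.
#'
#' Prior bounds are in phenotypic-SD units and applied on the internally
#' standardized scale: category effects uniform on ±`e_max` SD, gamma side
#' means uniform on (0, `mean_max`) SD, gamma shapes uniform on
#' (`shape_min`, `shape_max`).
#'
#' @param burnin Burn-in iterations (single-variable proposals).
#' @param sampling Sampling iterations after burn-in.
#' @param thin Record every `thin`-th sampling iteration.
#' @param seed Integer seed (required; drives R's RNG).
#' @param likelihood_variant `"as_printed"` keeps both the per-mutation
#'   frequency term and the multinomial/binomial count term;
#'   `"count_term_only"` drops the duplicated per-mutation term.
#' @param standardize Standardize phenotypes to zero mean, unit SD
#'   internally (results are rescaled back)? Forced off when there are no
#'   observations.
#' @param e_max,mean_max,shape_min,shape_max Prior bounds (see above).
#' @param tune_window Proposals per variable between scale adaptations.
#' @param refresh_every Iterations between full recomputations of the
#'   incremental likelihood bookkeeping.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(burnin = 1e6, sampling = 1e7, thin = 1e3,
                         seed = 1L,
                         likelihood_variant = c("as_printed",
                                                "count_term_only"),
                         standardize = TRUE, e_max = 0.5, mean_max = 0.5,
                         shape_min = 0.1, shape_max = 100,
                         tune_window = 100L, refresh_every = 1e5) {
  if (burnin < 0 || sampling <= 0 || thin <= 0)
    stop("iteration counts must be positive")
  structure(
    list(burnin = burnin, sampling = sampling, thin = thin,
         seed = as.integer(seed),
         likelihood_variant = match.arg(likelihood_variant),
         standardize = standardize, e_max = e_max, mean_max = mean_max,
         shape_min = shape_min, shape_max = shape_max,
         tune_window = as.integer(tune_window),
         refresh_every = refresh_every),
    class = "chain_config")
}

#' Run a Metropolis-Hastings chain for a DFE model
#'
#' Fits the requested model to an RL dataset. Phenotypes are standardized
#' internally (so the prior bounds in phenotypic-SD units are literal) and
#' every recorded quantity is rescaled back to the input scale; only the
#' recorded log likelihood stays on the standardized scale. One scalar
#' variable is proposed per iteration, cycling deterministically through
#' the variable blocks; proposals are accepted by the Metropolis rule
#' (all kernels are symmetric). Chains with identical seed and
#' configuration are bit-identical.
#'
#' @param data An [rl_dataset()].
#' @param model A [multicat_model()] or [gamma_model()].
#' @param config A [chain_config()].
#' @param init Optional named list of starting values on the input
#'   phenotype scale, overriding the defaults: for the multicategory model
#'   any of `m` (0-based categories), `e` (length `n_c`, first entry
#'   forced to 0), `q` (length `n_c`); for the gamma model any of `mu`
#'   (0/1 sides), `E` (2 x n_m magnitudes), `mean` (length 2), `shape`
#'   (length 2), `q_neg`. Useful for checking sensitivity to the starting
#'   basin in multimodal posteriors.
#' @return An object of class `chain_samples`: `draws` (matrix, one row per
#'   thinned draw; per-mutation columns are `m_*` category indices for the
#'   multicategory model and `effect_*` signed effects for the gamma
#'   model; `loglik` is the last column), `acceptance` (per-block
#'   proposal/acceptance counts over the sampling phase and mean adapted
#'   scales), `model`, `config`, `scale` (centering/scaling applied), and
#'   `data_dims`.
#' @export
run_chain <- function(data, model, config = chain_config(), init = NULL) {
  stopifnot(inherits(data, "rl_dataset"), inherits(model, "dfe_model"),
            inherits(config, "chain_config"))
  set.seed(config$seed)
  y <- data$y
  standardize <- config$standardize && data$n_b > 1 && sd(y) > 0
  mu_y <- if (standardize) mean(y) else 0
  sd_y <- if (standardize) sd(y) else 1
  y_std <- if (data$n_b > 0) (y - mu_y) / sd_y else numeric(0)

  M <- matrix(as.integer(data$M), nrow = data$n_b)
  F <- matrix(as.integer(data$F), nrow = data$n_b)
  plate <- if (data$n_p > 0) as.integer(data$plate - 1L) else integer(0)
  line <- as.integer(data$line - 1L)
  as_printed <- config$likelihood_variant == "as_printed"

  # Default gamma-model start: sides and magnitudes from the raw
  # carrier/non-carrier phenotype contrasts. The gamma posterior has a
  # rival mode in which near-zero mutations crowd onto one side and drag
  # its fitted shape down; starting from the empirical estimates places
  # the chain in the dominant basin, which single-site side flips reach
  # only astronomically slowly from a random start.
  if (is.null(init) && model$kind == "gamma" && data$n_b > 0 &&
      data$n_m > 0) {
    contrast <- vapply(seq_len(data$n_m), function(j) {
      carrier <- data$M[, j] == 1
      if (!any(carrier) || all(carrier)) return(0)
      mean(y[carrier]) - mean(y[!carrier])
    }, 0)
    mag <- pmax(abs(contrast), 1e-3 * sd_y)
    init <- list(mu = as.integer(contrast > 0), E = rbind(mag, mag))
  }

  # initial values arrive on the input scale; move them to the
  # standardized scale the sampler works on
  init_std <- init
  if (!is.null(init_std) && standardize) {
    if (!is.null(init_std$e)) init_std$e <- init_std$e / sd_y
    if (!is.null(init_std$E)) init_std$E <- init_std$E / sd_y
    if (!is.null(init_std$mean)) init_std$mean <- init_std$mean / sd_y
  }

  if (model$kind == "multicategory") {
    res <- mcmc_multicat_cpp(
      y_std, M, F, plate, data$n_p, line, max(data$n_lines, 0L),
      model$n_c, config$e_max, config$burnin, config$sampling, config$thin,
      as_printed, config$tune_window, config$refresh_every, init_std)
    n_c <- model$n_c
    nm_cols <- c(
      if (n_c > 1) paste0("e", seq_len(n_c - 1)),
      if (n_c > 1) paste0("q", seq_len(n_c - 1)),
      if (data$n_lines > 0) paste0("ybar", seq_len(data$n_lines)),
      "Ve",
      if (data$n_p > 0) c("Vp", paste0("p", seq_len(data$n_p))),
      if (data$n_f > 0) paste0("f", seq_len(data$n_f)),
      if (data$n_m > 0) paste0("m_", seq_len(data$n_m)),
      "loglik")
  } else {
    res <- mcmc_gamma_cpp(
      y_std, M, F, plate, data$n_p, line, max(data$n_lines, 0L),
      model$means == "same", model$shapes == "same",
      config$mean_max, config$shape_min, config$shape_max,
      config$burnin, config$sampling, config$thin,
      as_printed, config$tune_window, config$refresh_every, init_std)
    nm_cols <- c(
      "mean_neg", "mean_pos", "shape_neg", "shape_pos", "q_pos",
      if (data$n_lines > 0) paste0("ybar", seq_len(data$n_lines)),
      "Ve",
      if (data$n_p > 0) c("Vp", paste0("p", seq_len(data$n_p))),
      if (data$n_f > 0) paste0("f", seq_len(data$n_f)),
      if (data$n_m > 0) paste0("effect_", seq_len(data$n_m)),
      "loglik")
  }
  draws <- res$draws
  # the sampler always emits ybar/Ve columns sized by its internal layout;
  # with no observations those blocks are absent and columns match nm_cols
  colnames(draws) <- nm_cols

  # rescale back to the input phenotype scale
  if (standardize) {
    scale_cols <- grep("^(e[0-9]+|mean_neg|mean_pos|effect_|f[0-9]+|p[0-9]+)",
                       nm_cols)
    draws[, scale_cols] <- draws[, scale_cols, drop = FALSE] * sd_y
    var_cols <- grep("^(Ve|Vp)$", nm_cols)
    draws[, var_cols] <- draws[, var_cols, drop = FALSE] * sd_y^2
    yb_cols <- grep("^ybar", nm_cols)
    draws[, yb_cols] <- draws[, yb_cols, drop = FALSE] * sd_y + mu_y
  }

  structure(
    list(draws = draws,
         acceptance = as.data.frame(res$acceptance),
         model = model, config = config,
         scale = list(standardized = standardize, mean_y = mu_y,
                      sd_y = sd_y),
         data_dims = list(n_b = data$n_b, n_m = data$n_m, n_f = data$n_f,
                          n_p = data$n_p, n_lines = data$n_lines),
         n_draws = nrow(draws)),
    class = "chain_samples")
}

#' @export
print.chain_samples <- function(x, ...) {
  cat(sprintf("Chain of %d thinned draws (%s model)\n", x$n_draws,
              x$model$kind))
  cat(sprintf("  schedule: burn-in %g, sampling %g, thin %g, seed %d\n",
              x$config$burnin, x$config$sampling, x$config$thin,
              x$config$seed))
  acc <- x$acceptance
  rate <- ifelse(acc$proposals > 0, acc$accepted / acc$proposals, NA)
  cat("  acceptance: ",
      paste(sprintf("%s %.2f", acc$block, rate), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary of a chain
#'
#' Posterior mode (kernel density estimate) and ranked-sample credible
#' interval for every requested parameter column.
#'
#' @param object A `chain_samples` object.
#' @param params Character vector of draw columns (default: the DFE
#'   parameters of the fitted model).
#' @param level Credible level.
#' @param ... Unused.
#' @return Data frame with columns `parameter`, `mode`, `ci_lo`, `ci_hi`.
#' @export
summary.chain_samples <- function(object, params = NULL, level = 0.95, ...) {
  if (is.null(params)) {
    params <- if (object$model$kind == "multicategory") {
      n_c <- object$model$n_c
      if (n_c > 1) c(paste0("e", seq_len(n_c - 1)),
                     paste0("q", seq_len(n_c - 1))) else character(0)
    } else {
      ps <- c("mean_neg", "mean_pos", "shape_neg", "shape_pos", "q_pos")
      if (object$model$means == "same") ps <- setdiff(ps, "mean_pos")
      if (object$model$shapes == "same") ps <- setdiff(ps, "shape_pos")
      ps
    }
  }
  rows <- lapply(params, function(pp) {
    x <- object$draws[, pp]
    ci <- credible_interval(x, level = level)
    data.frame(parameter = pp, mode = posterior_mode(x),
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write chain draws and a run manifest
#'
#' @param chain A `chain_samples` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_chain <- function(chain, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(as.data.frame(chain$draws), file.path(dir, "samples.csv"),
            row.names = FALSE)
  manifest <- list(model = unclass(chain$model),
                   config = unclass(chain$config),
                   scale = chain$scale, data_dims = chain$data_dims,
                   n_draws = chain$n_draws)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
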