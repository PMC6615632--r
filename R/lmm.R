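#' Fit the growth-rate linear mixed model
#'
#' Growth rate is modelled with the number of carried mutations as a
#' continuous fixed predictor (optionally omitted for the reduced model),
#' mating type and any introgressed-region markers as two-level fixed
#' factors, and MA line, haplotype and growth-assay plate as random
#' intercepts. Fits use maximum likelihood (not REML), the valid choice for
#' a likelihood-ratio test on a fixed effect.
#'
#' Random factors with fewer than two observed levels are dropped (the
#' MA-line factor disappears in a single-cross analysis).
#'
#' @param data Data frame with columns `growth_rate`, the count column named
#'   by `count_col`, optional `mating_type` and `marker_*` columns, and
#'   grouping columns `ma_line`, `haplotype`, `plate`.
#' @param include_count Include the mutation-count predictor?
#' @param count_col Name of the count column (e.g. `"n_mut"`,
#'   `"n_snp"`).
#' @return A list: `fit` (the `lmerMod`), `logLik`, `converged`,
#'   `singular`, `formula`.
#' @export
fit_growth_lmm <- function(data, include_count = TRUE, count_col = "n_mut") {
  if (!count_col %in% names(data))
    stop("count column `", count_col, "` not found")
  if (any(data[[count_col]] < 0) ||
      any(data[[count_col]] != round(data[[count_col]])))
    stop("mutation counts must be nonnegative integers")
  fixed <- character(0)
  if (include_count) fixed <- count_col
  if ("mating_type" %in% names(data)) fixed <- c(fixed, "mating_type")
  fixed <- c(fixed, grep("^marker_", names(data), value = TRUE))
  rand <- c("ma_line", "haplotype", "plate")
  rand <- rand[vapply(rand, function(v)
    v %in% names(data) && length(unique(data[[v]])) >= 2L, TRUE)]
  if (!length(rand))
    stop("need at least one random grouping factor with >= 2 levels")
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 paste0("(1 | ", rand, ")")), collapse = " + ")
  form <- stats::as.formula(paste("growth_rate ~", rhs))
  fit <- suppressMessages(
    lme4::lmer(form, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  list(fit = fit, logLik = as.numeric(logLik(fit)), converged = conv,
       singular = lme4::isSingular(fit), formula = form)
}

#' Likelihood-ratio test for the mutation-count predictor
#'
#' Compares maximum-likelihood fits of the mixed model with and without the
#' mutation-count term: statistic `2 (logL_full - logL_reduced)` referred to
#' a chi-squared distribution with 1 degree of freedom. Small negative
#' statistics from convergence noise are clipped to zero (giving p = 1).
#'
#' @param data Data frame as for [fit_growth_lmm()].
#' @param count_col Name of the count column to test.
#' @return A one-row data frame: `count_col`, `chisq`, `p_value`,
#'   `logLik_full`, `logLik_reduced`, `converged`.
#' @export
lrt_count <- function(data, count_col = "n_mut") {
  full <- fit_growth_lmm(data, include_count = TRUE, count_col = count_col)
  red <- fit_growth_lmm(data, include_count = FALSE, count_col = count_col)
  stat <- max(0, 2 * (full$logLik - red$logLik))
  data.frame(count_col = count_col, chisq = stat,
             p_value = pchisq(stat, df = 1, lower.tail = FALSE),
             logLik_full = full$logLik, logLik_reduced = red$logLik,
             converged = full$converged && red$converged)
}

#' Per-cross and combined likelihood-ratio tests
#'
#' Runs [lrt_count()] on the combined table and on each MA-line cross
#' separately (within-cross fits drop the single-level MA-line factor
#' automatically).
#'
#' @param data Data frame as for [fit_growth_lmm()] with an `ma_line`
#'   column.
#' @param count_col Count column to test.
#' @return Data frame with one row per cross plus a `"combined"` row.
#' @export
lrt_by_cross <- function(data, count_col = "n_mut") {
  crosses <- sort(unique(as.character(data$ma_line)))
  rows <- lapply(crosses, function(cr) {
    d <- data[data$ma_line == cr, , drop = FALSE]
    cbind(cross = cr, lrt_count(d, count_col = count_col))
  })
  rows[[length(rows) + 1L]] <-
    cbind(cross = "combined", lrt_count(data, count_col = count_col))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
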