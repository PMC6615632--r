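#' Enumerate candidate regression windows over a growth curve
#'
#' Candidate windows are all contiguous runs of 5, 6, 7 or 8 consecutive
#' measurements (48, 60, 72 and 84 hours on the 12-h grid) within the
#' observed time span. A curve with fewer than 5 points yields no windows.
#'
#' @param times Numeric vector of measurement times in hours, strictly
#'   increasing (the standard grid is 12, 24, ..., 96).
#' @return A data frame with one row per window: `start_idx`, `end_idx`,
#'   `start_h`, `end_h`, `n_points`.
#' @examples
#' nrow(enumerate_windows(seq(12, 96, by = 12)))  # 10
#' @export
enumerate_windows <- function(times) {
  n <- length(times)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  out <- list()
  for (np in 5:8) {
    if (n < np) next
    for (s in seq_len(n - np + 1L)) {
      e <- s + np - 1L
      out[[length(out) + 1L]] <- data.frame(
        start_idx = s, end_idx = e, start_h = times[s], end_h = times[e],
        n_points = np)
    }
  }
  if (!length(out))
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_h = numeric(), end_h = numeric(),
                      n_points = integer()))
  out <- do.call(rbind, out)
  # earliest start, then shortest window, for deterministic tie-breaking later
  out[order(out$start_idx, out$n_points), , drop = FALSE]
}

#' Fit one log-linear window of a growth curve
#'
#' Ordinary least-squares regression of `ln(absorbance)` on time within the
#' window. R-squared of a flat (zero regression-sum-of-squares) fit is
#' defined as 0, so flat windows never pass the adequacy filter. Windows
#' containing nonpositive or missing absorbance are invalid (`valid = FALSE`)
#' since the log transform is undefined there.
#'
#' @param times,absorbance Numeric vectors for the whole curve.
#' @param start_idx,end_idx Window bounds (indices into `times`).
#' @return A one-row data frame: `start_h`, `end_h`, `n_points`, `slope`
#'   (per hour on ln absorbance), `r_squared`, `valid`.
#' @export
fit_window <- function(times, absorbance, start_idx, end_idx) {
  idx <- start_idx:end_idx
  t <- times[idx]
  A <- absorbance[idx]
  base <- data.frame(start_h = t[1], end_h = t[length(t)],
                     n_points = length(idx))
  if (anyNA(A) || any(A <= 0))
    return(cbind(base, slope = NA_real_, r_squared = NA_real_,
                 valid = FALSE))
  z <- log(A)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * (z - mean(z))) / sxx
  sst <- sum((z - mean(z))^2)
  r2 <- if (sst <= 0) 0 else {
    ssr <- slope^2 * sxx
    max(0, min(1, ssr / sst))
  }
  cbind(base, slope = slope, r_squared = r2, valid = TRUE)
}

#' Maximum growth rate of one curve
#'
#' Fits every candidate 5-8-point window by log-linear regression, discards
#' windows with an inadequate fit (R-squared below `r2_min`; the boundary
#' value is retained), and returns the highest remaining slope as the
#' maximum growth rate. When no window qualifies the rate is missing
#' (`NA`), mirroring the exclusion of replicates with no adequate window.
#' Ties among slopes are broken by earliest window start, then fewest
#' points.
#'
#' @param times,absorbance Numeric vectors describing the curve.
#' @param r2_min Adequacy threshold on R-squared (default 0.75).
#' @return A one-row data frame: `max_growth_rate` (`NA` if no window
#'   qualifies), `best_window_start`, `best_window_n`, `r_squared`.
#' @export
max_growth_rate <- function(times, absorbance, r2_min = 0.75) {
  empty <- data.frame(max_growth_rate = NA_real_,
                      best_window_start = NA_real_,
                      best_window_n = NA_integer_, r_squared = NA_real_)
  wins <- enumerate_windows(times)
  if (!nrow(wins)) return(empty)
  fits <- do.call(rbind, lapply(seq_len(nrow(wins)), function(i)
    fit_window(times, absorbance, wins$start_idx[i], wins$end_idx[i])))
  ok <- fits$valid & !is.na(fits$r_squared) & fits$r_squared >= r2_min
  if (!any(ok)) return(empty)
  fits <- fits[ok, , drop = FALSE]
  # rows are ordered by (start, n_points); which.max keeps the first maximum
  best <- which.max(fits$slope)
  data.frame(max_growth_rate = fits$slope[best],
             best_window_start = fits$start_h[best],
             best_window_n = fits$n_points[best],
             r_squared = fits$r_squared[best])
}

#' Maximum growth rates for a table of growth curves
#'
#' Applies [max_growth_rate()] to every curve in a long-format table
#' (one row per absorbance reading).
#'
#' @param curves Data frame with columns `plate`, `well`, `line`,
#'   `replicate`, `time_h`, `od650`.
#' @param r2_min Adequacy threshold passed to [max_growth_rate()].
#' @return Data frame with one row per curve: `line`, `replicate`, `plate`,
#'   `well`, `max_growth_rate`, `best_window_start`, `best_window_n`,
#'   `r_squared`. Missing rates are `NA`.
#' @export
growth_rates <- function(curves, r2_min = 0.75) {
  need <- c("plate", "well", "line", "replicate", "time_h", "od650")
  miss <- setdiff(need, names(curves))
  if (length(miss))
    stop("curves is missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(curves$plate, curves$well, curves$line,
                     curves$replicate, drop = TRUE)
  parts <- split(curves, key)
  out <- lapply(parts, function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    cbind(data.frame(line = d$line[1], replicate = d$replicate[1],
                     plate = d$plate[1], well = d$well[1]),
          max_growth_rate(d$time_h, d$od650, r2_min = r2_min))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
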