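grid <- seq(12, 96, by = 12)

test_that("window enumeration matches the combinatorial oracle", {
  # oracle: count contiguous runs of 5..8 points directly
  oracle_count <- function(n) sum(pmax(0, n - (5:8) + 1))
  for (n in c(4, 5, 6, 8)) {
    wins <- enumerate_windows(grid[seq_len(n)])
    expect_equal(nrow(wins), oracle_count(n))
  }
  full <- enumerate_windows(grid)
  expect_equal(nrow(full), 10)                   # 4 + 3 + 2 + 1
  expect_equal(as.numeric(table(full$n_points)), c(4, 3, 2, 1))
  expect_true(all(full$start_h >= 12 & full$end_h <= 96))
})

test_that("window fits equal the least-squares oracle", {
  # exact exponential: slope recovered exactly, perfect fit
  A <- 0.02 * exp(0.1 * grid)
  f <- fit_window(grid, A, 1, 8)
  expect_equal(f$slope, 0.1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # constant absorbance: zero slope, R-squared defined as 0
  fc <- fit_window(grid, rep(0.5, 8), 1, 5)
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  # hand data against an independent lm() fit
  t5 <- c(12, 24, 36, 48, 60)
  lnA <- c(0.1, 0.9, 2.2, 2.9, 4.1)
  fit <- lm(lnA ~ t5)
  fh <- fit_window(t5, exp(lnA), 1, 5)
  expect_equal(fh$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(fh$r_squared, summary(fit)$r.squared, tolerance = 1e-10)

  # nonpositive absorbance invalidates the window
  bad <- fit_window(grid, c(A[1:3], -1, A[5:8]), 1, 5)
  expect_false(bad$valid)
})

test_that("maximum growth rate takes the best adequate window", {
  # lag then exponential: brute-force oracle over all windows
  A <- c(0.011, 0.012, 0.011, 0.013, 0.05, 0.21, 0.84, 3.2)
  res <- max_growth_rate(grid, A)
  wins <- enumerate_windows(grid)
  slopes <- r2s <- numeric(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    idx <- wins$start_idx[i]:wins$end_idx[i]
    fit <- lm(log(A[idx]) ~ grid[idx])
    slopes[i] <- coef(fit)[2]
    r2s[i] <- summary(fit)$r.squared
  }
  keep <- r2s >= 0.75
  expect_true(any(keep))
  expect_equal(res$max_growth_rate, max(slopes[keep]), tolerance = 1e-10)
  expect_true(all(res$max_growth_rate >= slopes[keep]))

  # invariance to a constant multiplicative factor
  res2 <- max_growth_rate(grid, 100 * A)
  expect_equal(res2$max_growth_rate, res$max_growth_rate, tolerance = 1e-12)

  # single qualifying window returns its slope (5-point curve)
  A5 <- 0.01 * exp(0.08 * grid[1:5])
  expect_equal(max_growth_rate(grid[1:5], A5)$max_growth_rate, 0.08,
               tolerance = 1e-12)
})

test_that("inadequate fits are excluded strictly at the R-squared boundary", {
  # flat curve: every window has zero regression signal -> missing
  expect_true(is.na(max_growth_rate(grid, rep(0.4, 8))$max_growth_rate))

  # noisy zig-zag keeps all windows below 0.75 -> missing
  set.seed(3)
  zig <- exp(rep(c(0.1, -0.1), 4) + rnorm(8, 0, 0.02))
  wins <- enumerate_windows(grid)
  r2s <- vapply(seq_len(nrow(wins)), function(i) {
    idx <- wins$start_idx[i]:wins$end_idx[i]
    summary(lm(log(zig[idx]) ~ grid[idx]))$r.squared
  }, 0)
  expect_true(all(r2s < 0.75))
  expect_true(is.na(max_growth_rate(grid, zig)$max_growth_rate))

  # boundary is inclusive: a window whose R-squared equals r2_min is kept
  A5 <- exp(c(0.1, 0.35, 0.5, 0.75, 0.8))
  r2 <- summary(lm(log(A5) ~ grid[1:5]))$r.squared
  kept <- max_growth_rate(grid[1:5], A5, r2_min = r2)
  expect_false(is.na(kept$max_growth_rate))
  dropped <- max_growth_rate(grid[1:5], A5, r2_min = r2 + 1e-12)
  expect_true(is.na(dropped$max_growth_rate))
})

test_that("simulated growth curves are recovered by the sliding-window fit", {
  # noiseless, far from carrying capacity: pure exponential at rate 0.1
  cur <- simulate_growth_curves(0.1, A0 = 1e-6, K = 1e6, noise_sd = 0)
  est <- growth_rates(cur)
  expect_equal(est$max_growth_rate, 0.1, tolerance = 1e-8)

  # zero rate gives a flat curve -> missing
  flat <- simulate_growth_curves(0, noise_sd = 0)
  expect_true(is.na(growth_rates(flat)$max_growth_rate))

  # plate layout: 58 wells per plate, one curve each; start dilute enough
  # that every rate keeps a full 5-point window in exponential phase
  set.seed(8)
  rates <- runif(58, 0.05, 0.15)
  batch <- simulate_growth_curves(rates, A0 = 1e-4, noise_sd = 0.02)
  expect_equal(length(unique(batch$well)), 58)
  est <- growth_rates(batch)
  expect_equal(nrow(est), 58)
  est <- est[order(as.integer(sub("RL", "", est$line))), ]
  ok <- !is.na(est$max_growth_rate)
  expect_gt(mean(ok), 0.9)
  expect_lt(median(abs(est$max_growth_rate[ok] - rates[ok])), 0.02)
})
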