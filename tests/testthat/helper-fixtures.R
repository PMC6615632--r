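# Small fixtures built in code for the test suite.

# toy genotype table: lines x mutations call matrix plus markers
toy_genotype_table <- function(calls, chrom = NULL, pos = NULL,
                               reaction = NULL, markers = NULL, ...) {
  calls <- as.matrix(calls)
  if (is.null(chrom)) chrom <- rep("chr1", ncol(calls))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000
  if (is.null(reaction)) reaction <- rep("r1", nrow(calls))
  genotype_table(calls, chrom = chrom, pos = pos,
                 mating_reaction = reaction, markers = markers, ...)
}

binarize_test <- function(x) ifelse(x == "D", 1, ifelse(x == "A", 0, NA))

# scalar brute-force likelihood for the multicategory model: every term
# recomputed with elementwise arithmetic, no vectorized shortcuts
brute_loglik_multicat <- function(data, state, shared, as_printed = TRUE) {
  n_c <- length(state$e)
  v <- rep(0L, n_c)
  for (j in seq_along(state$m)) v[state$m[j] + 1L] <- v[state$m[j] + 1L] + 1L
  ll <- 0
  for (j in seq_along(state$m)) ll <- ll + log(state$q[state$m[j] + 1L])
  if (!as_printed) ll <- 0
  ll <- ll + dmultinom(v, prob = state$q, log = TRUE)
  for (k in seq_len(data$n_p)) ll <- ll +
      dnorm(shared$p[k], 0, sqrt(shared$V_p), log = TRUE)
  for (i in seq_len(data$n_b)) {
    g <- 0
    for (j in seq_len(data$n_m))
      g <- g + state$e[data$M[i, j] * state$m[j] + 1L]
    fx <- 0
    for (j in seq_len(data$n_f)) fx <- fx + data$F[i, j] * shared$f[j]
    px <- if (data$n_p > 0) shared$p[data$plate[i]] else 0
    ll <- ll + dnorm(data$y[i] - g - fx - px, shared$ybar[data$line[i]],
                     sqrt(shared$V_e), log = TRUE)
  }
  ll
}

# scalar brute-force likelihood for the two-sided gamma model
brute_loglik_gamma <- function(data, state, shared, as_printed = TRUE) {
  n_m <- data$n_m
  q <- c(state$q_neg, 1 - state$q_neg)
  ll <- 0
  for (j in seq_len(n_m)) {
    x <- state$E[state$mu[j] + 1L, j]
    sh <- state$shape[state$mu[j] + 1L]
    mn <- state$mean[state$mu[j] + 1L]
    ll <- ll + dgamma(x, shape = sh, rate = sh / mn, log = TRUE)
    if (as_printed) ll <- ll + log(q[state$mu[j] + 1L])
  }
  v0 <- 0L
  for (j in seq_len(n_m)) if (state$mu[j] == 0L) v0 <- v0 + 1L
  ll <- ll + dbinom(v0, n_m, state$q_neg, log = TRUE)
  for (k in seq_len(data$n_p)) ll <- ll +
      dnorm(shared$p[k], 0, sqrt(shared$V_p), log = TRUE)
  for (i in seq_len(data$n_b)) {
    g <- 0
    for (j in seq_len(n_m)) {
      delta <- if (state$mu[j] == 0L) -1 else 1
      g <- g + state$E[state$mu[j] + 1L, j] * delta * data$M[i, j]
    }
    fx <- 0
    for (j in seq_len(data$n_f)) fx <- fx + data$F[i, j] * shared$f[j]
    px <- if (data$n_p > 0) shared$p[data$plate[i]] else 0
    ll <- ll + dnorm(data$y[i] - g - fx - px, shared$ybar[data$line[i]],
                     sqrt(shared$V_e), log = TRUE)
  }
  ll
}

# random small instance + valid random states for oracle-equivalence tests
random_multicat_instance <- function() {
  n_b <- sample(1:20, 1)
  n_m <- sample(1:5, 1)
  n_f <- sample(0:2, 1)
  n_p <- sample(0:3, 1)
  n_c <- sample(1:3, 1)
  d <- rl_dataset(
    y = rnorm(n_b),
    M = matrix(rbinom(n_b * n_m, 1, 0.5), n_b, n_m),
    F = if (n_f > 0) matrix(rbinom(n_b * n_f, 1, 0.5), n_b, n_f) else NULL,
    plate = if (n_p > 0) sample(seq_len(n_p), n_b, replace = TRUE) else NULL,
    line = sample(1:2, n_b, replace = TRUE))
  q <- as.numeric(rmultinom(1, 50, rep(1, n_c))) + 0.5
  q <- q / sum(q)
  state <- list(m = sample(0:(n_c - 1), n_m, replace = TRUE),
                e = c(0, runif(n_c - 1, -0.5, 0.5)),
                q = q)
  shared <- list(f = rnorm(max(d$n_f, 0), 0, 0.3),
                 p = rnorm(max(d$n_p, 0), 0, 0.3),
                 V_p = runif(1, 0.1, 1), ybar = rnorm(d$n_lines, 0, 0.5),
                 V_e = runif(1, 0.5, 2))
  list(data = d, state = state, shared = shared)
}

random_gamma_instance <- function() {
  inst <- random_multicat_instance()
  d <- inst$data
  n_m <- d$n_m
  state <- list(mu = sample(0:1, n_m, replace = TRUE),
                E = matrix(rgamma(2 * n_m, 2, 10) + 1e-4, 2, n_m),
                q_neg = runif(1, 0.1, 0.9),
                mean = runif(2, 0.05, 0.5),
                shape = runif(2, 0.2, 5))
  list(data = d, state = state, shared = inst$shared)
}

# null LMM dataset: haplotype, plate and residual variation, no count effect
simulate_lmm_null <- function(n_lines = 100, reps = 2, n_plate = 5,
                              v_hap = 0.5, v_plate = 0.3, v_e = 1,
                              slope = 0) {
  counts <- rbinom(n_lines, 40, 0.5)
  hap_eff <- rnorm(n_lines, 0, sqrt(v_hap))
  plate <- sample(seq_len(n_plate), n_lines * reps, replace = TRUE)
  plate_eff <- rnorm(n_plate, 0, sqrt(v_plate))
  idx <- rep(seq_len(n_lines), each = reps)
  data.frame(
    growth_rate = 1 + slope * counts[idx] + hap_eff[idx] +
      plate_eff[plate] + rnorm(n_lines * reps, 0, sqrt(v_e)),
    n_mut = counts[idx],
    ma_line = "L1",
    haplotype = paste0("h", idx),
    plate = paste0("p", plate))
}
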