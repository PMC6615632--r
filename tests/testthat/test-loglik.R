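test_that("genotypic values follow the indexing convention", {
  # multicategory: non-carried mutations index the zero-effect category
  expect_equal(genotypic_value_multicat(c(0, 0), c(1, 2), c(0, -0.3, 0.2)), 0)
  expect_equal(genotypic_value_multicat(c(1, 1), c(0, 0), c(0, -0.3)), 0)
  expect_equal(
    genotypic_value_multicat(c(1, 0, 1), c(1, 0, 2), c(0, -0.03, 0.02)),
    -0.01)

  # two-sided gamma: side selects the magnitude, sign applied by side
  E <- rbind(c(0.03, 0.05), c(0.04, 0.01))
  expect_equal(genotypic_value_gamma(c(0, 0), c(0, 1), E), 0)
  expect_equal(
    genotypic_value_gamma(c(1, 0), c(0, 1), rbind(c(0.02, 0.5),
                                                  c(0.3, 0.09))),
    -0.02)
  expect_equal(genotypic_value_gamma(c(1, 1), c(0, 1), E), -0.03 + 0.01)
})

test_that("vectorized likelihoods equal scalar brute-force recomputation", {
  set.seed(31)
  for (i in 1:100) {
    inst <- random_multicat_instance()
    for (variant in c("as_printed", "count_term_only")) {
      ll <- loglik_multicat(inst$data, inst$state, inst$shared, variant)
      oracle <- brute_loglik_multicat(inst$data, inst$state, inst$shared,
                                      variant == "as_printed")
      expect_equal(ll, oracle, tolerance = 1e-10)
    }
  }
  for (i in 1:100) {
    inst <- random_gamma_instance()
    for (variant in c("as_printed", "count_term_only")) {
      ll <- loglik_gamma(inst$data, inst$state, inst$shared, variant)
      oracle <- brute_loglik_gamma(inst$data, inst$state, inst$shared,
                                   variant == "as_printed")
      expect_equal(ll, oracle, tolerance = 1e-10)
    }
  }
})

test_that("the null multicategory model reduces to independent normals", {
  set.seed(32)
  d <- rl_dataset(y = rnorm(15, 2), M = matrix(0L, 15, 0),
                  plate = rep(1:3, 5))
  state <- list(m = integer(0), e = 0, q = 1)
  shared <- list(f = numeric(0), p = c(0.1, -0.2, 0), V_p = 0.5,
                 ybar = 2.1, V_e = 1.3)
  ll <- loglik_multicat(d, state, shared)
  oracle <- sum(dnorm(shared$p, 0, sqrt(0.5), log = TRUE)) +
    sum(dnorm(d$y - shared$p[d$plate], 2.1, sqrt(1.3), log = TRUE))
  expect_equal(ll, oracle, tolerance = 1e-12)

  # gamma with no mutations reduces to the same shared model
  stateg <- list(mu = integer(0), E = matrix(0, 2, 0), q_neg = 0.5,
                 mean = c(0.1, 0.1), shape = c(1, 1))
  expect_equal(loglik_gamma(d, stateg, shared), oracle, tolerance = 1e-12)
})

test_that("moving one mutation between categories isolates the frequency terms", {
  set.seed(33)
  d <- rl_dataset(y = rnorm(10), M = cbind(rep(0L, 10), rbinom(10, 1, 0.5)))
  shared <- list(f = numeric(0), p = numeric(0), V_p = 1, ybar = 0, V_e = 1)
  q <- c(0.5, 0.5)
  # mutation 1 is carried by nobody and category 2 has zero effect, so only
  # the occupancy terms can change
  s0 <- list(m = c(0L, 0L), e = c(0, 0), q = q)
  s1 <- list(m = c(1L, 0L), e = c(0, 0), q = q)
  delta <- loglik_multicat(d, s1, shared) - loglik_multicat(d, s0, shared)
  cat_part <- function(v) 2 * sum(v * log(q)) +
    lgamma(3) - sum(lgamma(v + 1))
  expect_equal(delta, cat_part(c(1, 1)) - cat_part(c(2, 0)),
               tolerance = 1e-12)

  # under the gamma model, flipping a side changes only the per-mutation
  # density/frequency terms, the binomial count term, and carried residuals
  inst <- random_gamma_instance()
  st <- inst$state
  st2 <- st
  st2$mu[1] <- 1L - st2$mu[1]
  d2 <- inst$data
  ll_delta <- loglik_gamma(d2, st2, inst$shared) -
    loglik_gamma(d2, st, inst$shared)
  term <- function(s) {
    x <- s$E[s$mu[1] + 1L, 1]
    sh <- s$shape[s$mu[1] + 1L]
    mn <- s$mean[s$mu[1] + 1L]
    qq <- c(s$q_neg, 1 - s$q_neg)[s$mu[1] + 1L]
    dgamma(x, shape = sh, rate = sh / mn, log = TRUE) + log(qq)
  }
  v0_old <- sum(st$mu == 0L)
  v0_new <- sum(st2$mu == 0L)
  resid_delta <- sum(vapply(seq_len(d2$n_b), function(i) {
    g_old <- genotypic_value_gamma(d2$M[i, ], st$mu, st$E)
    g_new <- genotypic_value_gamma(d2$M[i, ], st2$mu, st2$E)
    fx <- if (d2$n_f > 0) sum(d2$F[i, ] * inst$shared$f) else 0
    px <- if (d2$n_p > 0) inst$shared$p[d2$plate[i]] else 0
    dnorm(d2$y[i] - g_new - fx - px, inst$shared$ybar[d2$line[i]],
          sqrt(inst$shared$V_e), log = TRUE) -
      dnorm(d2$y[i] - g_old - fx - px, inst$shared$ybar[d2$line[i]],
            sqrt(inst$shared$V_e), log = TRUE)
  }, 0))
  expected <- term(st2) - term(st) +
    dbinom(v0_new, d2$n_m, st$q_neg, log = TRUE) -
    dbinom(v0_old, d2$n_m, st$q_neg, log = TRUE) + resid_delta
  expect_equal(ll_delta, expected, tolerance = 1e-10)
})

test_that("impossible states get zero likelihood", {
  d <- rl_dataset(y = rnorm(5), M = matrix(1L, 5, 1))
  shared <- list(f = numeric(0), p = numeric(0), V_p = 1, ybar = 0, V_e = 1)
  # occupied category with zero frequency
  s <- list(m = 1L, e = c(0, 0.1), q = c(1, 0))
  expect_identical(loglik_multicat(d, s, shared), -Inf)
  # nonpositive magnitude
  sg <- list(mu = 0L, E = matrix(c(-0.1, 0.2), 2, 1), q_neg = 0.5,
             mean = c(0.1, 0.1), shape = c(1, 1))
  expect_identical(loglik_gamma(d, sg, shared), -Inf)
})
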