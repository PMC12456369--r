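test_that("exact reference sampling matches the quadrature posterior law", {
  # tau -> 0 with a square mask: samples concentrate at the generating point
  pr <- build_prior(seed = 1)
  lik <- make_problem("inpaint_low", seed = 1, keep = 1:10)
  lik$tau <- 1e-4
  m <- drop(gmm_sample(pr, 1, seed = 2))
  y <- simulate_measurement(lik, m, seed = 3)$y
  x <- exact_reference(pr, lik, y, 500, seed = 4)
  expect_lt(max(abs(sweep(x, 2, m))), 1e-3)
  # 1-D instance: KS distance to the quadrature CDF below 0.01 at n = 1e5
  g <- gmm(c(0.45, 0.55), list(-2, 2.5), list(1.0, 0.8))
  lik1 <- make_problem("inpaint_high", seed = 1, D = 1, keep = 1)
  lik1$tau <- 2
  y1 <- 0.7
  xs <- exact_reference(g, lik1, y1, 1e5, seed = 5)
  post <- linear_gaussian_posterior(g, lik1$A, lik1$tau, y1)
  cdf <- quad_cdf_1d(post)
  ks <- max(abs(stats::ecdf(drop(xs))(cdf$xs) - cdf$cdf))
  expect_lt(ks, 0.01)
})

test_that("split-chain PSRF and ESS behave on known chain laws", {
  set.seed(6)
  # i.i.d. chains
  A <- array(stats::rnorm(4 * 10000 * 2), c(4, 10000, 2))
  p <- psrf(A)
  # the split-chain statistic can dip to sqrt((n-1)/n) below 1 for i.i.d. data
  expect_true(all(p >= 0.999 & p < 1.01))
  e <- ess(A)
  expect_true(all(e >= 0.8 * 4 * 10000))
  # AR(1) with coefficient 0.9: ESS per draw close to (1-rho)/(1+rho)
  rho <- 0.9
  n <- 40000
  ar <- array(0, c(4, n, 1))
  for (c in 1:4) ar[c, , 1] <- stats::arima.sim(list(ar = rho), n, sd = sqrt(1 - rho^2))
  ratio <- ess(ar) / (4 * n)
  expect_equal(ratio, (1 - rho) / (1 + rho), tolerance = 0.2)
  # separated chains are detected
  B <- array(stats::rnorm(2 * 2000), c(2, 2000, 1))
  B[2, , 1] <- B[2, , 1] + 10
  expect_gt(psrf(B)[1], 2)
  # degenerate zero-variance chains give the sentinel values
  Z <- array(1, c(2, 100, 1))
  expect_equal(psrf(Z)[1], 1)
  expect_equal(ess(Z)[1], 0)
})

test_that("the DE-MC engine recovers a known 10-D Gaussian posterior", {
  set.seed(7)
  S <- diag(stats::runif(10, 0.5, 2))
  g1 <- gmm(1, list(stats::rnorm(10)), list(S))
  cs <- mcmc_reference(g1, NULL, NULL, n_chains = 8, n_iter = 20000, seed = 8)
  dg <- diagnostics(cs, n_requested = 500)
  expect_lt(max(dg$psrf), 1.01)
  x <- reference_draws(cs, 1500)
  neff <- min(dg$ess)
  expect_true(all(abs(colMeans(x) - g1$means[[1]]) < 4 * sqrt(diag(S) / neff)))
  expect_true(all(abs(apply(x, 2, stats::var) - diag(S)) < 5 * diag(S) * sqrt(2 / neff)))
})

test_that("the gate blocks unconverged chains and attaches diagnostics", {
  set.seed(9)
  A <- array(stats::rnorm(2 * 2000 * 1), c(2, 2000, 1))
  A[2, , 1] <- A[2, , 1] + 5
  cs <- structure(list(chains = A, burn_frac = 0.5, seed = 1L), class = "chain_set")
  err <- tryCatch(reference_draws(cs, 100), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "convergence gate")
  expect_true(!is.null(err$diagnostics))
})

test_that("DE-MC agrees with exact sampling on a linear-Gaussian study", {
  # validates the engine against the conjugate reference before it is trusted
  pr <- build_prior(seed = 1)
  lik <- make_problem("inpaint_high", seed = 1)
  y <- simulate_measurement(lik, drop(gmm_sample(pr, 1, seed = 10)), seed = 11)$y
  cs <- mcmc_reference(pr, lik, y, n_chains = 10, n_iter = 40000, seed = 12,
                       thin = 2)
  mc <- reference_draws(cs, 3000)
  ex <- exact_reference(pr, lik, y, 10000, seed = 13)
  ex2 <- exact_reference(pr, lik, y, 10000, seed = 14)
  alpha <- estimate_alpha(ex)
  floor_me <- mean_error(ex, ex2)
  # all four metrics within a small multiple of the n-adjusted reference floor
  adj <- sqrt(10000 / min(3000, min(ess(cs))))
  expect_lt(mean_error(mc, ex), 6 * adj * floor_me + 0.05)
  expect_lt(variance_error(mc, ex), 6 * adj * variance_error(ex, ex2) + 0.1)
  expect_lt(cmd(mc, ex, alpha), 6 * adj * cmd(ex, ex2, alpha) + 0.02)
  expect_lt(mmd(mc, ex, max_pairs_n = 1000), 3 * mmd(ex, ex2, max_pairs_n = 1000) + 0.03)
})

test_that("component-wise reference reproduces closed-form posterior weights", {
  pr <- build_prior(seed = 1)
  lik <- make_problem("inpaint_high", seed = 1)
  y <- simulate_measurement(lik, drop(gmm_sample(pr, 1, seed = 15)), seed = 16)$y
  post <- linear_gaussian_posterior(pr, lik$A, lik$tau, y)
  cw <- suppressWarnings(
    componentwise_reference(pr, lik, y, n = 4000, n_chains = 10,
                            n_iter = 25000, seed = 17, n_gate = 0, thin = 2))
  expect_equal(attr(cw, "weights"), post$weights, tolerance = 0.02)
  # constant likelihood: weights revert to the prior weights
  zero <- make_problem("phase", seed = 2)
  zero$B[] <- 0
  y0 <- simulate_measurement(zero, drop(gmm_sample(pr, 1, seed = 18)), seed = 19)$y
  cw0 <- suppressWarnings(
    componentwise_reference(pr, zero, y0, n = 2000, n_chains = 8,
                            n_iter = 15000, seed = 20, n_gate = 0, thin = 2))
  expect_equal(attr(cw0, "weights"), pr$weights, tolerance = 0.02)
})
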