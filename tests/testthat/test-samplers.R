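test_that("unadjusted Langevin reaches its known biased stationary variance", {
  # For target N(0, I) the ULA fixed point has variance 1/(1 - eta/2)
  eta <- 1e-2
  o <- sample_langevin(NULL, NULL, list(mean = matrix(0, 4000, 5), cov = 1),
                       langevin_config(eta, 4000), seed = 7)
  expect_equal(mean(apply(o, 2, stats::var)), 1 / (1 - eta / 2), tolerance = 0.05)
  # compiled mask-likelihood path targets the same invariant law
  lik <- make_problem("inpaint_low", seed = 1, D = 2, keep = 1)
  y <- 0.5
  ap <- list(mean = matrix(0, 4000, 2), cov = 1)
  oc <- sample_langevin(lik, y, ap, langevin_config(5e-4, 4000), seed = 8)
  # observed coordinate: product of N(0,1) and N(y; m, tau^2)
  vpost <- 1 / (1 + 1 / lik$tau^2)
  expect_equal(mean(oc[, 1]), vpost * y / lik$tau^2, tolerance = 4 * sqrt(vpost / 4000) + 2e-3)
  expect_equal(stats::var(oc[, 2]), 1, tolerance = 0.08)
})

test_that("Metropolis-adjusted Langevin is exact for Gaussian targets", {
  o <- sample_langevin(NULL, NULL, list(mean = matrix(0, 3000, 1), cov = 1),
                       langevin_config(0.5, 1500, metropolis = TRUE), seed = 9)
  expect_lt(abs(mean(o)), 4 / sqrt(3000) * 2)
  expect_equal(stats::var(drop(o)), 1, tolerance = 0.08)
  expect_gt(attr(o, "accept_rate"), 0.3)
})

test_that("MAP solves the prediction optimization problem", {
  # equal-precision average: A = I, tau = 1, C = I, m_aprx = 0, y = 2
  lik <- make_problem("inpaint_low", seed = 1, keep = 1:10)
  lik$tau <- 1
  ap <- list(mean = matrix(0, 3, 10), cov = 1)
  out <- sample_map(lik, rep(2, 10), ap, map_config("closed_form"))
  expect_equal(out, matrix(1, 3, 10))
  # closed form vs quasi-Newton on random linear-Gaussian instances
  set.seed(10)
  lik2 <- make_problem("inpaint_high", seed = 2)
  for (k in 1:3) {
    y <- stats::rnorm(8)
    Cm <- crossprod(matrix(stats::rnorm(100), 10)) / 10 + diag(10)
    ap <- list(mean = matrix(stats::rnorm(10), 1), cov = Cm)
    cf <- sample_map(lik2, y, ap, map_config("closed_form"))
    qn <- sample_map(lik2, y, ap, map_config("quasi_newton", max_iters = 400))
    expect_equal(qn, cf, tolerance = 1e-5)
  }
  # stationarity of the smooth nonlinear solve
  xr <- make_problem("xray", seed = 3)
  y <- simulate_measurement(xr, stats::rnorm(10, sd = 0.3), seed = 4)$y
  ap <- list(mean = matrix(stats::rnorm(10), 1), cov = 0.7)
  sol <- drop(sample_map(xr, y, ap, map_config("quasi_newton", 40)))
  g <- drop(loglike_grad(xr, sol, y)) - (sol - ap$mean[1, ]) / 0.7
  expect_lt(sqrt(sum(g^2)), 1e-4)
})

test_that("randomize-then-optimize is exact in the linear-Gaussian case", {
  lik <- make_problem("inpaint_low", seed = 1)
  set.seed(11)
  y <- stats::rnorm(8)
  m0 <- stats::rnorm(10)
  C <- 0.5
  n <- 1e5
  ap <- list(mean = matrix(m0, n, 10, byrow = TRUE), cov = C)
  out <- sample_rto(lik, y, ap, map_config("closed_form"), seed = 12)
  prec <- rep(1 / C, 10); prec[lik$keep] <- prec[lik$keep] + 1 / lik$tau^2
  rhs <- m0 / C; rhs[lik$keep] <- rhs[lik$keep] + y / lik$tau^2
  mu <- rhs / prec; v <- 1 / prec
  expect_true(all(abs(colMeans(out) - mu) < 3 * sqrt(v / n)))
  expect_true(all(abs(apply(out, 2, stats::var) - v) < 3 * v * sqrt(2 / (n - 1))))
})

test_that("randomize-then-optimize limits collapse as expected", {
  lik <- make_problem("inpaint_low", seed = 1)
  set.seed(13)
  y <- stats::rnorm(8)
  m0 <- matrix(stats::rnorm(10), 200, 10, byrow = TRUE)
  # C -> 0: degenerate prior, output -> m_aprx
  out <- sample_rto(lik, y, list(mean = m0, cov = 1e-12), map_config("closed_form"),
                    seed = 14)
  expect_equal(out, m0, tolerance = 1e-4)
  # tau -> infinity: uninformative data, output law -> N(m_aprx, C)
  likw <- lik; likw$tau <- 1e6
  out2 <- sample_rto(likw, y, list(mean = matrix(0, 2e4, 10), cov = 2),
                     map_config("closed_form"), seed = 15)
  expect_lt(max(abs(colMeans(out2))), 4 * sqrt(2 / 2e4))
  expect_equal(mean(apply(out2, 2, stats::var)), 2, tolerance = 0.05)
})

test_that("Gauss-Newton preconditioning restores MALA acceptance on stiff targets", {
  # linear-Gaussian case is anchor-independent and exact
  lik <- make_problem("inpaint_high", seed = 5)
  ap <- list(mean = matrix(0, 1, 10), cov = 0.5)
  P <- gauss_newton_preconditioner(lik, ap, matrix(stats::rnorm(30), 3, 10))
  Pinv_exact <- crossprod(lik$A) / lik$tau^2 + diag(2, 10)
  expect_equal(solve(P), Pinv_exact, tolerance = 1e-6)
  # SPD for arbitrary anchors under the nonlinear forward model
  ph <- make_problem("phase", seed = 6)
  P2 <- gauss_newton_preconditioner(ph, list(mean = NULL, cov = 1.5),
                                    matrix(stats::rnorm(50, sd = 3), 5, 10))
  expect_equal(P2, t(P2), tolerance = 1e-10)
  expect_true(min(eigen(P2, symmetric = TRUE, only.values = TRUE)$values) > 0)
  # badly scaled 2-D Gaussian target: same step size, very different acceptance
  lik2 <- make_problem("inpaint_low", seed = 7, D = 2, keep = 1)
  lik2$tau <- 0.05
  ap2 <- list(mean = matrix(0, 500, 2), cov = 25)
  P3 <- gauss_newton_preconditioner(lik2, ap2, matrix(0, 1, 2))
  plain <- sample_langevin(lik2, 0.1, ap2, langevin_config(1, 400, metropolis = TRUE),
                           seed = 16)
  prec <- sample_langevin(lik2, 0.1, ap2,
                          langevin_config(1, 400, metropolis = TRUE, preconditioner = P3),
                          seed = 17)
  expect_gt(attr(prec, "accept_rate"), 0.4)
  expect_lt(attr(plain, "accept_rate"), 0.4)
})

test_that("diverging chains are flagged and excluded", {
  # absurd step size on a stiff Gaussian factor blows up the unadjusted chain
  o <- suppressWarnings(
    sample_langevin(NULL, NULL, list(mean = matrix(0, 20, 2), cov = 1e-10),
                    langevin_config(1, 50), seed = 18))
  expect_true(all(attr(o, "diverged")))
  expect_true(all(is.na(o)))
})
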