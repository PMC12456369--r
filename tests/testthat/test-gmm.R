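test_that("benchmark prior matches its specification and is seed-deterministic", {
  pr <- build_prior(seed = 7)
  expect_equal(pr$weights, c(0.4, 0.3, 0.3))
  expect_equal(pr$means[[1]], rep(-5, 10))
  expect_equal(pr$means[[2]], rep(0, 10))
  expect_equal(pr$means[[3]], rep(5, 10))
  expect_equal(pr$covariances[[1]], diag(10))
  expect_equal(diag(pr$covariances[[2]]), seq(1, 2, length.out = 10))
  expect_equal(pr$covariances[[2]], diag(seq(1, 2, length.out = 10), 10))
  # component 3 shares component 2's eigenvalue spectrum
  ev2 <- sort(eigen(pr$covariances[[2]], symmetric = TRUE, only.values = TRUE)$values)
  ev3 <- sort(eigen(pr$covariances[[3]], symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev3, ev2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pr$covariances[[3]], pr$covariances[[2]])))
  # pure function of the seed
  expect_identical(build_prior(seed = 7), pr)
  expect_false(identical(build_prior(seed = 8)$covariances[[3]], pr$covariances[[3]]))
  expect_error(build_prior(seed = "a"))
  expect_message(build_prior(D = 4, seed = 1), "benchmark configuration")
})

test_that("mixture construction validates its invariants", {
  expect_error(gmm(c(0.5, -0.5), list(0, 1), list(1, 1)), "positive")
  expect_error(gmm(1, list(c(0, 0)), list(matrix(c(1, 2, 0, 1), 2))), "symmetric")
  expect_error(gmm(1, list(c(0, 0)), list(matrix(c(1, 2, 2, 1), 2))), "positive definite")
  expect_error(gmm(c(0.5, 0.5), list(0, c(0, 0)), list(1, diag(2))), "dimension")
  # weights are normalized
  expect_equal(gmm(c(2, 2), list(-1, 1), list(1, 1))$weights, c(0.5, 0.5))
})

test_that("log-density is exact, stable, and component-order invariant", {
  std <- gmm(1, list(rep(0, 10)), list(diag(10)))
  expect_equal(gmm_logpdf(std, rep(0, 10)), -(10 / 2) * log(2 * pi))
  g <- gmm(c(0.3, 0.7), list(-1.5, 2), list(0.8, 2.5))
  gp <- gmm(c(0.7, 0.3), list(2, -1.5), list(2.5, 0.8))
  pts <- c(-4.2, -1.5, 0, 1.1, 7.7)
  expect_equal(gmm_logpdf(g, matrix(pts)), gmm_logpdf(gp, matrix(pts)))
  # direct summation oracle, 12 significant digits
  direct <- log(0.3 * stats::dnorm(pts, -1.5, sqrt(0.8)) +
                0.7 * stats::dnorm(pts, 2, sqrt(2.5)))
  expect_equal(gmm_logpdf(g, matrix(pts)), direct, tolerance = 1e-12)
  # far tail does not underflow to -Inf
  expect_true(is.finite(gmm_logpdf(g, 60)))
})

test_that("ancestral sampling has the right component frequencies and law", {
  std <- gmm(1, list(rep(0, 10)), list(diag(10)))
  x <- gmm_sample(std, 1e5, seed = 1)
  expect_lt(sqrt(sum(colMeans(x)^2)), 4 * sqrt(10 / 1e5))
  pr <- build_prior(seed = 1)
  lab <- attr(gmm_sample(pr, 1e5, seed = 2), "component")
  expect_lt(abs(mean(lab == 1) - 0.4), 0.01)
  # Kolmogorov-Smirnov against the quadrature CDF of a 1-D mixture
  g <- gmm(c(0.4, 0.6), list(-2, 1.5), list(1.2, 0.5))
  x1 <- drop(gmm_sample(g, 1e5, seed = 3))
  cdf <- quad_cdf_1d(g)
  emp <- stats::ecdf(x1)
  ks <- max(abs(emp(cdf$xs) - cdf$cdf))
  expect_lt(ks, 0.01)
})

test_that("noisy marginal is the sigma-convolution of the mixture", {
  g <- gmm(c(0.4, 0.6), list(-2, 1.5), list(1.2, 0.5))
  expect_identical(noisy_marginal(g, 0), g)
  gn <- noisy_marginal(g, 2.5)
  expect_equal(gn$weights, g$weights)
  expect_equal(gn$means, g$means)
  expect_equal(gn$covariances[[1]][1, 1], 1.2 + 2.5^2)
  expect_error(noisy_marginal(g, -1), "nonnegative")
  # quadrature convolution oracle at 7 points
  sig <- 1.3
  xs <- quad_grid()
  dens <- exp(gmm_logpdf(g, matrix(xs)))
  dx <- xs[2] - xs[1]
  pts <- c(-5, -2, -0.5, 0, 1, 2.8, 6)
  conv <- vapply(pts, function(p) sum(dens * stats::dnorm(p - xs, 0, sig)) * dx,
                 numeric(1))
  expect_equal(exp(gmm_logpdf(noisy_marginal(g, sig), matrix(pts))), conv,
               tolerance = 1e-8)
})

test_that("noisy score is the gradient of the noisy log-density", {
  # single Gaussian closed form
  D <- 4
  set.seed(5)
  S <- crossprod(matrix(stats::rnorm(D * D), D)) + diag(D)
  mu <- stats::rnorm(D)
  g1 <- gmm(1, list(mu), list(S))
  m <- stats::rnorm(D); sig <- 1.4
  expect_equal(noisy_score(g1, m, sig),
               drop(-solve(S + diag(sig^2, D), m - mu)), tolerance = 1e-10)
  # symmetric two-component 1-D mixture vanishes at the symmetry point
  gs <- gmm(c(0.5, 0.5), list(-3, 3), list(1, 1))
  expect_equal(noisy_score(gs, 0, 0.7), 0, tolerance = 1e-12)
  # finite differences of the noisy log-density at 20 random points
  pr <- build_prior(seed = 2)
  set.seed(6)
  for (k in 1:20) {
    m <- stats::rnorm(10, sd = 4)
    sig <- stats::runif(1, 0, 10)
    nm <- noisy_marginal(pr, sig)
    fd <- fd_grad(function(x) gmm_logpdf(nm, x), m)
    s <- noisy_score(pr, m, sig)
    expect_lt(max(abs(s - fd)) / max(abs(fd)), 1e-5)
  }
  # batched evaluation agrees with per-row evaluation
  M <- matrix(stats::rnorm(30, sd = 3), 3, 10)
  SB <- noisy_score(pr, M, 1.1)
  for (r in 1:3) expect_equal(SB[r, ], noisy_score(pr, M[r, ], 1.1))
})

test_that("score Jacobian is symmetric and matches finite differences", {
  D <- 4
  set.seed(7)
  S <- crossprod(matrix(stats::rnorm(D * D), D)) + diag(D)
  g1 <- gmm(1, list(stats::rnorm(D)), list(S))
  sig <- 0.9
  expect_equal(noisy_score_jacobian(g1, stats::rnorm(D), sig),
               -solve(S + diag(sig^2, D)), tolerance = 1e-10)
  pr <- build_prior(seed = 2)
  set.seed(8)
  for (k in 1:5) {
    m <- stats::rnorm(10, sd = 4)
    sig <- stats::runif(1, 0.1, 8)
    J <- noisy_score_jacobian(pr, m, sig)
    expect_lt(max(abs(J - t(J))), 1e-10)
    fdJ <- vapply(1:10, function(j) {
      e <- rep(0, 10); e[j] <- 1e-5
      (noisy_score(pr, m + e, sig) - noisy_score(pr, m - e, sig)) / 2e-5
    }, numeric(10))
    expect_lt(max(abs(J - t(fdJ))), 1e-4)
  }
})

test_that("linear-Gaussian posterior matches conjugate identities and quadrature", {
  pr <- build_prior(seed = 3)
  # A = 0: no information, posterior equals the prior
  p0 <- linear_gaussian_posterior(pr, matrix(0, 8, 10), tau = 1, y = rep(0, 8))
  expect_equal(p0$weights, pr$weights, tolerance = 1e-12)
  expect_equal(p0$means, pr$means)
  # conjugate identity: N(0, I) prior, A = I, tau = 1, y = 0 -> N(0, I/2)
  std <- gmm(1, list(rep(0, 10)), list(diag(10)))
  pc <- linear_gaussian_posterior(std, diag(10), 1, rep(0, 10))
  expect_equal(pc$covariances[[1]], diag(0.5, 10), tolerance = 1e-12)
  expect_equal(pc$means[[1]], rep(0, 10), tolerance = 1e-12)
  # 1-D two-component prior vs quadrature
  g <- gmm(c(0.35, 0.65), list(-2, 2.5), list(1.4, 0.6))
  tau <- 1.1; y <- 0.4
  q <- quad_posterior_1d(g, tau, y)
  post <- linear_gaussian_posterior(g, matrix(1, 1, 1), tau, y)
  pm <- sum(post$weights * unlist(post$means))
  pv <- sum(post$weights * (unlist(post$covariances) + unlist(post$means)^2)) - pm^2
  expect_equal(pm, q$mean, tolerance = 1e-6)
  expect_equal(pv, q$var, tolerance = 1e-6)
  expect_equal(sum(post$weights), 1)
  # tau -> infinity: posterior weights revert to prior weights
  pinf <- linear_gaussian_posterior(g, matrix(1, 1, 1), 1e8, y)
  expect_equal(pinf$weights, g$weights, tolerance = 1e-6)
})

test_that("noisy marginal sampling agrees with sample-then-perturb", {
  g <- gmm(c(0.5, 0.5), list(c(-2, 0), c(2, 1)), list(diag(2), diag(c(0.5, 2))))
  sig <- 1.5
  a <- gmm_sample(noisy_marginal(g, sig), 1e4, seed = 1)
  b <- gmm_sample(g, 1e4, seed = 2) + sig * matrix(stats::rnorm(2e4), 1e4, 2)
  ab <- mmd(a, b, max_pairs_n = 1000)
  base <- mmd(gmm_sample(noisy_marginal(g, sig), 1e4, seed = 3), a, max_pairs_n = 1000)
  expect_lt(ab, 2 * base + 0.05)
})

test_that("mixtures round-trip through JSON", {
  pr <- build_prior(seed = 4)
  f <- tempfile(fileext = ".json")
  write_gmm(pr, f)
  pr2 <- read_gmm(f)
  expect_equal(pr2$weights, pr$weights)
  expect_equal(pr2$means, pr$means)
  expect_equal(pr2$covariances, pr$covariances)
  unlink(f)
})
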