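test_that("mean and variance errors match hand arithmetic", {
  fx <- fixture_batches()
  expect_equal(mean_error(fx$S1, fx$S1), 0)
  expect_equal(variance_error(fx$S2, fx$S2), 0)
  # hand-computed: means (2, 0) vs (2, 1); variances (1, 1) vs (4, 0)
  expect_equal(colMeans(fx$S1), c(2, 0))
  expect_equal(mean_error(fx$S1, fx$S2), 1)
  expect_equal(variance_error(fx$S1, fx$S2), sqrt(9 + 1))
  # symmetry in the two batches
  expect_equal(mean_error(fx$S2, fx$S1), mean_error(fx$S1, fx$S2))
  # translating a mean-matched batch by v changes mean_error by exactly ||v||
  S1m <- sweep(fx$S1, 2, colMeans(fx$S1) - colMeans(fx$S2))  # mean-matched
  v <- c(0.3, -0.4)
  expect_equal(mean_error(sweep(S1m, 2, -v), fx$S2), sqrt(sum(v^2)))
  expect_error(mean_error(fx$S1[1, , drop = FALSE], fx$S2))
})

test_that("central moment discrepancy matches a brute-force moment oracle", {
  a <- matrix(c(-1, 0, 2, 3))
  b <- matrix(c(0, 1, 1, 4))
  # brute force with alpha = 1, K = 3
  cm <- function(x, k) mean((x - mean(x))^k)
  want <- abs(mean(a) - mean(b)) +
    abs(cm(a, 2) - cm(b, 2)) + abs(cm(a, 3) - cm(b, 3))
  expect_equal(cmd(a, b, alpha = 1, K = 3), want, tolerance = 1e-12)
  expect_equal(cmd(a, a, alpha = 2), 0)
  # strictly decreasing in alpha for a nonzero discrepancy
  expect_gt(cmd(a, b, alpha = 1), cmd(a, b, alpha = 2))
  expect_error(cmd(a, b, alpha = 1, K = 1), "K")
  # truncation: adding the K+1 term changes the value by its own bound
  alpha <- 2; K <- 5
  d6 <- abs(cm(a, 6) - cm(b, 6)) / alpha^6
  expect_equal(cmd(a, b, alpha, K = 6) - cmd(a, b, alpha, K = 5), d6,
               tolerance = 1e-12)
})

test_that("the CMD decay rate follows the 4 eta_max rule", {
  # batches with exact per-dimension standard deviations via two-point sets
  two_pt <- function(sds) {
    vapply(sds, function(s) c(-s, s) / sqrt(2), numeric(2))
  }
  b1 <- two_pt(c(1, 2))   # sds exactly (1, 2)
  b2 <- two_pt(c(3, 1))   # sds exactly (3, 1)
  expect_equal(estimate_alpha(list(b1, b2)), 4 * (2 + 3) / 2)
  # permutation of dimensions leaves alpha unchanged
  expect_equal(estimate_alpha(list(b1[, 2:1], b2[, 2:1])), 10)
  # isotropic unit-variance reference gives alpha close to 4
  x <- matrix(stats::rnorm(2e4), 1e4, 2)
  expect_equal(estimate_alpha(x), 4, tolerance = 0.1)
  expect_error(estimate_alpha(list()), "at least one")
})

test_that("maximum mean discrepancy matches a brute-force kernel oracle", {
  a <- matrix(c(0, 1, 2))
  b <- matrix(c(0.5, 1.5, 3))
  # single bandwidth eps = 1, kernel exp(-d^2/2)
  kf <- function(x, z) exp(-outer(drop(x), drop(z), function(u, v) (u - v)^2) / 2)
  want2 <- mean(kf(a, a)) + mean(kf(b, b)) - 2 * mean(kf(a, b))
  got <- mmd(a, b, eps_bar = 1, n_bandwidths = 1)
  expect_equal(got, sqrt(want2), tolerance = 1e-12)
  # biased estimator is exactly zero on identical batches
  expect_equal(mmd(a, a, eps_bar = 1), 0)
  # the bandwidth ladder spans factors 1/4..4 around eps_bar
  got5 <- mmd(a, b, eps_bar = 1, n_bandwidths = 5)
  want5 <- sqrt(sum(vapply(2^((1:5) - 3), function(f) {
    kfe <- function(x, z) exp(-outer(drop(x), drop(z), function(u, v) (u - v)^2) / (2 * f))
    mean(kfe(a, a)) + mean(kfe(b, b)) - 2 * mean(kfe(a, b))
  }, numeric(1))))
  expect_equal(got5, want5, tolerance = 1e-12)
  # separation: distinguishable distributions sit far above the null baseline
  x <- matrix(stats::rnorm(1000))
  z <- matrix(stats::rnorm(1000, mean = 5))
  x2 <- matrix(stats::rnorm(1000))
  expect_gt(mmd(x, z), 10 * mmd(x2, x))
})

test_that("the study runner aggregates trials with interdecile ranges", {
  expect_error(run_study("inpaint_low", n_trials = 0), "n_trials")
  rep <- run_study("inpaint_low", variants = "RTO-TU", n_trials = 3,
                   n_samples = 400, seed = 5, problem_seed = 100,
                   cfg_fun = function(v, s)
                     bipsda_config(v, N_A = 40, n_chains = 400, seed = s,
                                   sampler_cfg = map_config("closed_form")))
  expect_s3_class(rep, "bipsda_report")
  expect_setequal(rep$table$variant, c("Reference", "RTO-TU"))
  expect_true(all(rep$table$mean_error >= 0))
  expect_true(all(rep$table$mean_error_q10 <= rep$table$mean_error_q90))
  expect_equal(nrow(rep$per_trial), 6L)
  expect_gt(rep$alpha, 0)
  # round-trip: CSV table and JSON twin
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_report(rep, csv = fc, json = fj)
  back <- utils::read.csv(fc, stringsAsFactors = FALSE)
  expect_equal(back$variant, rep$table$variant)
  expect_equal(back$variance_error, rep$table$variance_error, tolerance = 1e-12)
  js <- jsonlite::fromJSON(fj)
  expect_equal(js$alpha, rep$alpha, tolerance = 1e-12)
  unlink(c(fc, fj))
  expect_output(print(rep), "Benchmark study")
})

test_that("the reference floor scales like one over root n", {
  pr <- build_prior(seed = 100)
  lik <- make_problem("inpaint_low", seed = 100)
  set.seed(6)
  ratios <- replicate(12, {
    y <- simulate_measurement(lik, drop(gmm_sample(pr, 1)))$y
    e1 <- mean_error(exact_reference(pr, lik, y, 1000),
                     exact_reference(pr, lik, y, 1000))
    e4 <- mean_error(exact_reference(pr, lik, y, 4000),
                     exact_reference(pr, lik, y, 4000))
    e1 / e4
  })
  expect_equal(mean(ratios), 2, tolerance = 0.35)
})
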