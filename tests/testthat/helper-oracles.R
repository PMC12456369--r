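# Independent oracles used across the suite: grid quadrature for 1-D mixture
# posteriors and conditional (denoising) moments, and central finite
# differences. These never call the code paths they check.

quad_grid <- function(lo = -30, hi = 30, n = 40001L) seq(lo, hi, length.out = n)

# Unnormalized posterior density of a 1-D prior gmm under y = m + noise(tau),
# evaluated on a grid; returns normalized moments.
quad_posterior_1d <- function(prior, tau, y, xs = quad_grid()) {
  un <- exp(gmm_logpdf(prior, matrix(xs)) + stats::dnorm(y, xs, tau, log = TRUE))
  w <- un / sum(un)
  mu <- sum(xs * w)
  list(mean = mu, var = sum((xs - mu)^2 * w), w = w, xs = xs)
}

# Conditional moments E[m0 | mt], Var[m0 | mt] of the denoising distribution
# for a 1-D prior gmm at noise level sigma, by quadrature.
quad_denoising_1d <- function(prior, mt, sigma, xs = quad_grid()) {
  un <- exp(gmm_logpdf(prior, matrix(xs)) + stats::dnorm(mt, xs, sigma, log = TRUE))
  w <- un / sum(un)
  mu <- sum(xs * w)
  list(mean = mu, var = sum((xs - mu)^2 * w))
}

# CDF of a 1-D gmm by numerical integration of the density.
quad_cdf_1d <- function(g, xs = quad_grid()) {
  d <- exp(gmm_logpdf(g, matrix(xs)))
  p <- cumsum(d)
  p <- p / p[length(p)]
  list(xs = xs, cdf = p)
}

fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Small fixed 2-D three-point batches used by the metric oracle tests.
fixture_batches <- function() {
  list(S1 = matrix(c(1, 2, 3,
                     0, 1, -1), 3, 2),
       S2 = matrix(c(0, 2, 4,
                     1, 1, 1), 3, 2))
}
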