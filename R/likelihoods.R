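#' Benchmark likelihoods
#'
#' Constructs the likelihood object for one of the four stylized benchmark
#' inverse problems, all sharing the ten-dimensional mixture prior:
#' \describe{
#'   \item{\code{inpaint_low}, \code{inpaint_high}}{linear binary-mask
#'     subsampling \eqn{y = A m + z}, \eqn{A \in R^{8 \times 10}} keeping
#'     coordinates 1-8, Gaussian noise with \eqn{\tau = 0.1} (low) or
#'     \eqn{\tau = 5} (high).}
#'   \item{\code{xray}}{Poisson counts with mean map
#'     \eqn{\lambda(m) = I_0 \exp(-C m)}, \eqn{C \in R^{15 \times 10}} with
#'     i.i.d. entries uniform on \eqn{[0.01, 0.05]}, source intensity
#'     \eqn{I_0 = 1000}.}
#'   \item{\code{phase}}{squared linear map \eqn{f(m) = (B m)^2} elementwise,
#'     \eqn{B \in R^{5 \times 10}} with i.i.d. standard normal entries,
#'     Gaussian noise with \eqn{\tau = 25}.}
#' }
#' Operator entries are a pure function of the seed.
#'
#' @param study one of \code{"inpaint_low"}, \code{"inpaint_high"},
#'   \code{"xray"}, \code{"phase"}.
#' @param seed integer seed for the random operator entries.
#' @param D parameter dimension (benchmark value 10).
#' @param keep for the inpainting studies, the observed coordinates (default
#'   \code{1:8}; the null space of the mask is the complement).
#' @return a likelihood object of class \code{c("<family>_lik", "bipsda_lik")}
#'   where family is \code{mask}, \code{poisson} or \code{phase}.
#' @examples
#' lik <- make_problem("inpaint_low", seed = 1)
#' lik$tau
#' @export
make_problem <- function(study = c("inpaint_low", "inpaint_high", "xray", "phase"),
                         seed = 1L, D = 10L, keep = NULL) {
  study <- match.arg(study)
  seed <- as.integer(seed)
  D <- as.integer(D)
  set.seed(seed)
  out <- switch(study,
    inpaint_low = ,
    inpaint_high = {
      if (is.null(keep)) keep <- seq_len(min(8L, D - 2L))
      A <- matrix(0, length(keep), D)
      A[cbind(seq_along(keep), keep)] <- 1
      structure(list(study = study, A = A, keep = as.integer(keep),
                     tau = if (study == "inpaint_low") 0.1 else 5,
                     D = D, Kdim = length(keep), seed = seed),
                class = c("mask_lik", "bipsda_lik"))
    },
    xray = {
      C <- matrix(stats::runif(15L * D, 0.01, 0.05), 15L, D)
      structure(list(study = study, C = C, I0 = 1000, D = D, Kdim = 15L,
                     seed = seed),
                class = c("poisson_lik", "bipsda_lik"))
    },
    phase = {
      B <- matrix(stats::rnorm(5L * D), 5L, D)
      structure(list(study = study, B = B, tau = 25, D = D, Kdim = 5L,
                     seed = seed),
                class = c("phase_lik", "bipsda_lik"))
    })
  out
}

#' @export
print.bipsda_lik <- function(x, ...) {
  cat(sprintf("Benchmark likelihood '%s': %d measurements, %d parameters\n",
              x$study, x$Kdim, x$D))
  if (!is.null(x$tau)) cat("  Gaussian noise, tau =", x$tau, "\n")
  if (!is.null(x$I0)) cat("  Poisson counts, source intensity I0 =", x$I0, "\n")
  invisible(x)
}

#' Forward map of a benchmark likelihood
#'
#' @param like a likelihood object from \code{\link{make_problem}}.
#' @param m a \code{D}-vector or \code{n x D} batch.
#' @return an \code{n x K} matrix of noiseless measurement means (for the
#'   Poisson family, the Poisson mean \eqn{\lambda(m)}).
#' @export
forward_map <- function(like, m) UseMethod("forward_map")

#' @export
forward_map.mask_lik <- function(like, m) {
  m <- as_batch(m, like$D)
  m[, like$keep, drop = FALSE]
}

#' @export
forward_map.phase_lik <- function(like, m) {
  m <- as_batch(m, like$D)
  (m %*% t(like$B))^2
}

#' @export
forward_map.poisson_lik <- function(like, m) {
  m <- as_batch(m, like$D)
  u <- m %*% t(like$C)
  like$I0 * exp(pmin(-u, 700))   # saturate instead of overflowing
}

#' Simulate a measurement
#'
#' Draws \eqn{y = f(m) + \tau z} (Gaussian families) or
#' \eqn{y_k \sim \mathrm{Poisson}(\lambda_k(m))}.
#'
#' @param like a likelihood object.
#' @param m the generating parameter vector.
#' @param seed optional integer seed.
#' @return a list with elements \code{y}, \code{m}, \code{seed}.
#' @export
simulate_measurement <- function(like, m, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(all(is.finite(m)))
  f <- drop(forward_map(like, m))
  y <- if (inherits(like, "poisson_lik")) {
    stats::rpois(length(f), f)
  } else {
    f + like$tau * stats::rnorm(length(f))
  }
  list(y = as.numeric(y), m = as.numeric(m), seed = seed)
}

#' Log-likelihood and gradient
#'
#' \code{loglike} evaluates the data log-density (additive constants dropped
#' consistently: for the Gaussian families the \eqn{-K/2 \log(2\pi\tau^2)}
#' term, for the Poisson family the \eqn{-\log y!} term). \code{loglike_grad}
#' is its exact gradient in \code{m}. Both are batched over rows of \code{m}.
#'
#' @param like a likelihood object.
#' @param m a \code{D}-vector or \code{n x D} batch.
#' @param y the measurement vector.
#' @return \code{loglike}: numeric vector of length \code{n};
#'   \code{loglike_grad}: \code{n x D} matrix (vector for vector input).
#' @export
loglike <- function(like, m, y) UseMethod("loglike")

#' @rdname loglike
#' @export
loglike_grad <- function(like, m, y) UseMethod("loglike_grad")

#' @export
loglike.mask_lik <- function(like, m, y) {
  r <- sweep(forward_map(like, m), 2L, y)
  -rowSums(r^2) / (2 * like$tau^2)
}

#' @export
loglike_grad.mask_lik <- function(like, m, y) {
  vec_in <- is.null(dim(m))
  m <- as_batch(m, like$D)
  g <- matrix(0, nrow(m), like$D)
  r <- sweep(m[, like$keep, drop = FALSE], 2L, y)
  g[, like$keep] <- -r / like$tau^2
  if (vec_in) drop(g) else g
}

#' @export
loglike.phase_lik <- function(like, m, y) {
  r <- sweep(forward_map(like, m), 2L, y)
  -rowSums(r^2) / (2 * like$tau^2)
}

#' @export
loglike_grad.phase_lik <- function(like, m, y) {
  vec_in <- is.null(dim(m))
  m <- as_batch(m, like$D)
  Bm <- m %*% t(like$B)
  r <- Bm^2 - matrix(y, nrow(m), length(y), byrow = TRUE)
  # J = 2 diag(Bm) B per row; grad = -J^T r / tau^2
  g <- -(2 * (r * Bm)) %*% like$B / like$tau^2
  if (vec_in) drop(g) else g
}

#' @export
loglike.poisson_lik <- function(like, m, y) {
  m <- as_batch(m, like$D)
  u <- m %*% t(like$C)
  lam <- like$I0 * exp(pmin(-u, 700))
  ym <- matrix(y, nrow(m), length(y), byrow = TRUE)
  rowSums(ym * (log(like$I0) - u) - lam)
}

#' @export
loglike_grad.poisson_lik <- function(like, m, y) {
  vec_in <- is.null(dim(m))
  m <- as_batch(m, like$D)
  lam <- forward_map(like, m)
  g <- (lam - matrix(y, nrow(m), length(y), byrow = TRUE)) %*% like$C
  if (vec_in) drop(g) else g
}

#' Monte-Carlo signal-to-noise ratio
#'
#' Reports \eqn{10 \log_{10}(\hat E \|f(m)\|^2 / \hat E \|z\|^2)} under the
#' prior, one of several possible SNR conventions; informational only.
#'
#' @param like a likelihood object.
#' @param prior the \code{\link{gmm}} prior.
#' @param n_mc Monte-Carlo sample size (at least 1000).
#' @param seed integer seed.
#' @return SNR in dB (\code{-Inf} for an identically zero forward map).
#' @export
report_snr <- function(like, prior, n_mc = 1e4, seed = 1L) {
  stopifnot(n_mc >= 1e3)
  m <- gmm_sample(prior, n_mc, seed = seed)
  f <- forward_map(like, m)
  sig <- mean(rowSums(f^2))
  noise <- if (inherits(like, "poisson_lik")) mean(rowSums(f)) else like$Kdim * like$tau^2
  if (sig == 0) return(-Inf)
  10 * log10(sig / noise)
}

#' Serialize a benchmark problem to JSON
#'
#' @param like a likelihood object.
#' @param path file path; when \code{NULL} the JSON string is returned.
#' @return \code{path} invisibly, or the JSON string.
#' @export
write_problem <- function(like, path = NULL) {
  obj <- unclass(like)
  for (nm in c("A", "C", "B"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- list(dim = dim(like[[nm]]),
                                               data = as.vector(t(like[[nm]])))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname write_problem
#' @param x a file path or JSON string produced by \code{write_problem}.
#' @export
read_problem <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyMatrix = FALSE)
  lk <- make_problem(unlist(obj$study), seed = as.integer(unlist(obj$seed)),
                     D = as.integer(unlist(obj$D)))
  for (nm in c("A", "C", "B"))
    if (!is.null(obj[[nm]])) {
      dm <- as.integer(unlist(obj[[nm]]$dim))
      lk[[nm]] <- matrix(unlist(obj[[nm]]$data), dm[1], dm[2], byrow = TRUE)
    }
  if (!is.null(obj$keep)) lk$keep <- as.integer(unlist(obj$keep))
  if (!is.null(obj$tau)) lk$tau <- as.numeric(unlist(obj$tau))
  if (!is.null(obj$I0)) lk$I0 <- as.numeric(unlist(obj$I0))
  lk
}
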