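#' Gaussian mixture distributions
#'
#' A \code{gmm} object represents a finite mixture of multivariate Gaussians
#' \deqn{\pi(m) = \sum_{i=1}^{N_m} w_i \, N(m; \mu_i, \Sigma_i),}
#' used throughout the package as the prior, as the noisy marginal of the
#' variance-exploding diffusion at level \eqn{\sigma}, and as the closed-form
#' posterior under a linear-Gaussian likelihood.
#'
#' @param weights numeric vector of strictly positive component weights
#'   (normalized internally to sum to one).
#' @param means list of mean vectors, all of common dimension \code{D}.
#' @param covariances list of \code{D x D} symmetric positive-definite
#'   covariance matrices.
#' @return An object of class \code{gmm} with elements \code{weights},
#'   \code{means}, \code{covariances}, \code{D} and \code{K} (number of
#'   components).
#' @examples
#' g <- gmm(c(0.5, 0.5), list(-2, 2), list(1, 0.5))
#' gmm_logpdf(g, 0)
#' @export
gmm <- function(weights, means, covariances) {
  if (!is.list(means)) means <- lapply(seq_along(weights), function(i) means[[i]])
  means <- lapply(means, as.numeric)
  covariances <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    storage.mode(S) <- "double"
    S
  })
  K <- length(weights)
  stopifnot(K >= 1, length(means) == K, length(covariances) == K)
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("component weights must be finite and strictly positive")
  weights <- weights / sum(weights)
  D <- length(means[[1]])
  for (i in seq_len(K)) {
    if (length(means[[i]]) != D) stop("all components must share dimension D")
    S <- covariances[[i]]
    if (!all(dim(S) == c(D, D))) stop("covariance ", i, " is not D x D")
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop("covariance ", i, " is not symmetric")
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance ", i, " is not positive definite")
    covariances[[i]] <- (S + t(S)) / 2
  }
  structure(list(weights = weights, means = means, covariances = covariances,
                 D = D, K = K),
            class = "gmm")
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d component(s) in %d dimension(s)\n", x$K, x$D))
  cat("weights:", format(x$weights, digits = 4), "\n")
  invisible(x)
}

#' Benchmark Gaussian-mixture prior
#'
#' Constructs the ten-dimensional three-component mixture prior used by all
#' benchmark studies: component 1 has mean \code{-5} in every coordinate and
#' identity covariance; component 2 has mean zero and a diagonal covariance
#' with entries linearly spaced between 1 and 2; component 3 has mean \code{+5}
#' in every coordinate and a covariance sharing component 2's eigenvalues but
#' with a random orthonormal eigenbasis (the orthogonal factor of a seeded QR
#' decomposition of a standard Gaussian matrix). Weights are (0.4, 0.3, 0.3).
#'
#' @param D problem dimension. The benchmark configuration is \code{D = 10};
#'   other values are accepted (with a message) for experimentation.
#' @param seed integer seed controlling the random eigenvectors of component 3.
#'   Construction is a pure function of the seed.
#' @return A \code{\link{gmm}} object.
#' @examples
#' pr <- build_prior(seed = 1)
#' diag(pr$covariances[[2]])
#' @export
build_prior <- function(D = 10L, seed = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  seed <- as.integer(seed)
  D <- as.integer(D)
  if (D != 10L)
    message("note: D = ", D, " differs from the benchmark configuration (D = 10)")
  eigvals <- seq(1, 2, length.out = D)
  Q <- local({
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
  })
  S3 <- Q %*% diag(eigvals, D) %*% t(Q)
  gmm(weights = c(0.4, 0.3, 0.3),
      means = list(rep(-5, D), rep(0, D), rep(5, D)),
      covariances = list(diag(1, D), diag(eigvals, D), S3))
}

# Batched helper: coerce a vector or n x D matrix to n x D matrix.
as_batch <- function(m, D) {
  if (is.null(dim(m))) {
    if (length(m) != D) stop("point has length ", length(m), ", expected ", D)
    m <- matrix(m, 1L, D)
  }
  m <- as.matrix(m)
  if (ncol(m) != D) stop("batch has ", ncol(m), " columns, expected ", D)
  storage.mode(m) <- "double"
  m
}

# Per-component Cholesky factors of (Sigma_i + sigma^2 I), cached pieces used
# by density, score and Jacobian evaluations.
gmm_factors <- function(g, sigma = 0) {
  lapply(seq_len(g$K), function(i) {
    S <- g$covariances[[i]]
    if (sigma > 0) S <- S + diag(sigma^2, g$D)
    R <- chol(S)
    list(R = R, logdet = 2 * sum(log(diag(R))))
  })
}

# log N(m; mu_i, Sigma_i + sigma^2 I) for a batch, one column per component,
# plus log weights. Returns n x K matrix of log(w_i) + log-density.
gmm_comp_logdens <- function(g, m, sigma = 0, factors = NULL) {
  m <- as_batch(m, g$D)
  if (is.null(factors)) factors <- gmm_factors(g, sigma)
  n <- nrow(m)
  out <- matrix(0, n, g$K)
  for (i in seq_len(g$K)) {
    d <- sweep(m, 2L, g$means[[i]])
    # rows of u solve R^T u = d^T  =>  quadform = rowSums(u^2)
    u <- backsolve(factors[[i]]$R, t(d), transpose = TRUE)
    q <- colSums(u^2)
    out[, i] <- log(g$weights[i]) - 0.5 * (g$D * log(2 * pi) + factors[[i]]$logdet + q)
  }
  out
}

logsumexp_rows <- function(L) {
  mx <- apply(L, 1L, max)
  mx + log(rowSums(exp(L - mx)))
}

#' Mixture log-density
#'
#' Log of the Gaussian-mixture density, evaluated stably in log space
#' (log-sum-exp over components). Accepts a single point or an \code{n x D}
#' batch, returning a vector of length \code{n}.
#'
#' @param gmm a \code{\link{gmm}} object.
#' @param m a \code{D}-vector or \code{n x D} matrix of evaluation points.
#' @return numeric vector of log-density values.
#' @export
gmm_logpdf <- function(gmm, m) {
  unname(logsumexp_rows(gmm_comp_logdens(gmm, m)))
}

#' Sample from a Gaussian mixture
#'
#' Ancestral sampling: component labels are drawn from the weight vector and
#' conditionally Gaussian draws are generated with the component Cholesky
#' factors.
#'
#' @param gmm a \code{\link{gmm}} object.
#' @param n number of draws.
#' @param seed optional integer seed (uses the current RNG state when `NULL`).
#' @return an \code{n x D} matrix with attribute \code{"component"} giving the
#'   component label of each row.
#' @export
gmm_sample <- function(gmm, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n)
  lab <- sample.int(gmm$K, n, replace = TRUE, prob = gmm$weights)
  out <- matrix(0, n, gmm$D)
  for (i in seq_len(gmm$K)) {
    idx <- which(lab == i)
    if (!length(idx)) next
    R <- chol(gmm$covariances[[i]])
    z <- matrix(stats::rnorm(length(idx) * gmm$D), length(idx), gmm$D)
    out[idx, ] <- sweep(z %*% R, 2L, gmm$means[[i]], "+")
  }
  attr(out, "component") <- lab
  out
}

#' Noisy marginal of a mixture under variance-exploding noise
#'
#' The marginal of \eqn{m + \sigma z}, \eqn{z \sim N(0, I)}, when
#' \eqn{m} follows the mixture: weights and means are unchanged and each
#' covariance becomes \eqn{\Sigma_i + \sigma^2 I}.
#'
#' @param gmm a \code{\link{gmm}} object.
#' @param sigma noise standard deviation, \code{sigma >= 0}.
#' @return a \code{\link{gmm}} object.
#' @export
noisy_marginal <- function(gmm, sigma) {
  stopifnot(length(sigma) == 1L, is.finite(sigma))
  if (sigma < 0) stop("'sigma' must be nonnegative")
  if (sigma == 0) return(gmm)
  covs <- lapply(gmm$covariances, function(S) S + diag(sigma^2, gmm$D))
  gmm(gmm$weights, gmm$means, covs)
}

#' Analytic noisy score of a Gaussian mixture
#'
#' Gradient of the log-density of the noisy marginal at level \eqn{\sigma}:
#' \deqn{s(m) = \sum_i \gamma_i(m)\,[-(\Sigma_i + \sigma^2 I)^{-1}(m - \mu_i)],}
#' with \eqn{\gamma_i} the noisy-mixture responsibilities computed in log
#' space. Batched: accepts an \code{n x D} matrix and returns one score per
#' row.
#'
#' @inheritParams gmm_logpdf
#' @param sigma noise standard deviation, \code{sigma >= 0}.
#' @return an \code{n x D} matrix of scores (a plain vector when \code{m} is a
#'   vector).
#' @export
noisy_score <- function(gmm, m, sigma = 0) {
  vec_in <- is.null(dim(m))
  m <- as_batch(m, gmm$D)
  factors <- gmm_factors(gmm, sigma)
  n <- nrow(m)
  L <- matrix(0, n, gmm$K)
  si <- vector("list", gmm$K)
  for (i in seq_len(gmm$K)) {
    R <- factors[[i]]$R
    u <- backsolve(R, t(m) - gmm$means[[i]], transpose = TRUE)
    L[, i] <- log(gmm$weights[i]) -
      0.5 * (gmm$D * log(2 * pi) + factors[[i]]$logdet + colSums(u^2))
    si[[i]] <- -t(backsolve(R, u))       # rows: -(Sigma + sigma^2 I)^{-1} d
  }
  G <- exp(L - logsumexp_rows(L))        # n x K responsibilities
  out <- matrix(0, n, gmm$D)
  for (i in seq_len(gmm$K)) out <- out + G[, i] * si[[i]]
  if (vec_in) drop(out) else out
}

#' Jacobian of the analytic noisy score
#'
#' The \code{D x D} Jacobian of \code{\link{noisy_score}} at a single point;
#' symmetric because the score is a gradient field. For a mixture,
#' \deqn{J(m) = -\sum_i \gamma_i P_i + \sum_i \gamma_i s_i s_i^T - s s^T,}
#' where \eqn{P_i = (\Sigma_i + \sigma^2 I)^{-1}}, \eqn{s_i = -P_i (m - \mu_i)}
#' and \eqn{s = \sum_i \gamma_i s_i}.
#'
#' @inheritParams noisy_score
#' @param m a single \code{D}-vector.
#' @return a symmetric \code{D x D} matrix.
#' @export
noisy_score_jacobian <- function(gmm, m, sigma = 0) {
  m <- as_batch(m, gmm$D)
  if (nrow(m) != 1L) stop("'m' must be a single point; see noisy_score_jacobians()")
  noisy_score_jacobians(gmm, m, sigma)[[1L]]
}

#' Batched score Jacobians
#'
#' @inheritParams noisy_score
#' @return a list of symmetric \code{D x D} matrices, one per row of \code{m}.
#' @export
noisy_score_jacobians <- function(gmm, m, sigma = 0) {
  m <- as_batch(m, gmm$D)
  factors <- gmm_factors(gmm, sigma)
  L <- gmm_comp_logdens(gmm, m, sigma, factors)
  G <- exp(L - logsumexp_rows(L))
  P <- lapply(factors, function(f) chol2inv(f$R))
  n <- nrow(m)
  si <- vector("list", gmm$K)
  for (i in seq_len(gmm$K)) {
    d <- sweep(m, 2L, gmm$means[[i]])
    si[[i]] <- -d %*% P[[i]]
  }
  lapply(seq_len(n), function(r) {
    s <- rep(0, gmm$D)
    for (i in seq_len(gmm$K)) s <- s + G[r, i] * si[[i]][r, ]
    J <- -Reduce(`+`, lapply(seq_len(gmm$K), function(i) G[r, i] * P[[i]]))
    for (i in seq_len(gmm$K)) J <- J + G[r, i] * tcrossprod(si[[i]][r, ])
    J <- J - tcrossprod(s)
    (J + t(J)) / 2
  })
}

#' Closed-form posterior under a linear-Gaussian likelihood
#'
#' For a mixture prior and likelihood \eqn{y = A m + z}, \eqn{z \sim N(0,
#' \tau^2 I)}, the posterior is again a Gaussian mixture with
#' \deqn{\Sigma_i' = (\Sigma_i^{-1} + A^T A/\tau^2)^{-1}, \quad
#'       \mu_i' = \Sigma_i'(\Sigma_i^{-1}\mu_i + A^T y/\tau^2),}
#' and weights proportional to \eqn{w_i N(y; A\mu_i, A\Sigma_i A^T + \tau^2 I)}.
#'
#' @param gmm the \code{\link{gmm}} prior.
#' @param A a \code{K x D} forward matrix.
#' @param tau noise standard deviation, \code{tau > 0}.
#' @param y observed \code{K}-vector.
#' @return the posterior \code{\link{gmm}}.
#' @export
linear_gaussian_posterior <- function(gmm, A, tau, y) {
  stopifnot(tau > 0)
  A <- as.matrix(A)
  y <- as.numeric(y)
  stopifnot(ncol(A) == gmm$D, nrow(A) == length(y))
  AtA <- crossprod(A) / tau^2
  Aty <- drop(crossprod(A, y)) / tau^2
  means <- covs <- vector("list", gmm$K)
  logw <- numeric(gmm$K)
  for (i in seq_len(gmm$K)) {
    Si <- gmm$covariances[[i]]
    Pi <- chol2inv(chol(Si))
    Sp <- chol2inv(chol(Pi + AtA))
    covs[[i]] <- (Sp + t(Sp)) / 2
    means[[i]] <- drop(Sp %*% (Pi %*% gmm$means[[i]] + Aty))
    Sy <- A %*% Si %*% t(A) + diag(tau^2, nrow(A))
    Ry <- chol((Sy + t(Sy)) / 2)
    r <- y - drop(A %*% gmm$means[[i]])
    u <- backsolve(Ry, r, transpose = TRUE)
    logw[i] <- log(gmm$weights[i]) -
      0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(Ry))) + sum(u^2))
  }
  w <- exp(logw - max(logw))
  gmm(w / sum(w), means, covs)
}

#' Serialize a Gaussian mixture to JSON
#'
#' Mixtures round-trip through a plain JSON representation (weights, means,
#' covariances row-major) so that problem instances are archivable as text.
#'
#' @param gmm a \code{\link{gmm}} object.
#' @param path file path; when \code{NULL} the JSON string is returned.
#' @return \code{path} invisibly, or the JSON string.
#' @export
write_gmm <- function(gmm, path = NULL) {
  obj <- list(weights = gmm$weights,
              means = gmm$means,
              covariances = lapply(gmm$covariances, function(S) as.vector(t(S))),
              D = gmm$D)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname write_gmm
#' @param x a file path or JSON string produced by \code{write_gmm}.
#' @export
read_gmm <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyMatrix = FALSE)
  D <- as.integer(obj$D)
  gmm(unlist(obj$weights),
      lapply(obj$means, unlist),
      lapply(obj$covariances, function(v) matrix(unlist(v), D, D, byrow = TRUE)))
}
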