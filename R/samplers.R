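#' Sampler configurations
#'
#' \code{langevin_config} parameterizes the (possibly Metropolis-adjusted,
#' possibly preconditioned) Langevin sampler for the prediction distribution;
#' \code{map_config} parameterizes the MAP optimizer used by the MAP and
#' randomize-then-optimize variants. Benchmark settings: inpainting Langevin
#' uses step size \code{5e-5} with 100 subiterations and no Metropolis
#' correction; the x-ray problem uses 1000 subiterations; phase retrieval uses
#' Metropolis-adjusted, preconditioned Langevin with step size 0.2 and 1000
#' subiterations; quasi-Newton MAP solves run 40 iterations with a Wolfe line
#' search.
#'
#' @param step_size Langevin step size \eqn{\eta} (drift coefficient
#'   convention: the update is \eqn{m + \eta P \nabla \log p + \sqrt{2\eta}
#'   P^{1/2} z}).
#' @param n_subiters number of Langevin subiterations.
#' @param metropolis apply a Metropolis-Hastings correction.
#' @param preconditioner a \code{D x D} SPD matrix \eqn{P}, or \code{NULL} for
#'   the identity.
#' @param gn_precondition when \code{TRUE}, the annealing loop recomputes the
#'   preconditioner at every outer iteration as the averaged Gauss-Newton
#'   Hessian approximation over a small set of anchor chains
#'   (\code{\link{gauss_newton_preconditioner}}).
#' @return a config list.
#' @export
langevin_config <- function(step_size = 5e-5, n_subiters = 100L,
                            metropolis = FALSE, preconditioner = NULL,
                            gn_precondition = FALSE) {
  stopifnot(step_size > 0, n_subiters >= 1)
  structure(list(step_size = step_size, n_subiters = as.integer(n_subiters),
                 metropolis = metropolis, preconditioner = preconditioner,
                 gn_precondition = gn_precondition),
            class = "langevin_config")
}

#' @rdname langevin_config
#' @param method \code{"closed_form"} (linear-Gaussian likelihood only) or
#'   \code{"quasi_newton"}.
#' @param max_iters optimizer iteration cap.
#' @param line_search use a Wolfe line search (always on for the built-in
#'   solvers; kept as a flag for interface completeness).
#' @export
map_config <- function(method = c("closed_form", "quasi_newton"),
                       max_iters = 40L, line_search = TRUE) {
  method <- match.arg(method)
  stopifnot(max_iters >= 1)
  structure(list(method = method, max_iters = as.integer(max_iters),
                 line_search = line_search),
            class = "map_config")
}

# --- covariance helpers: 'cov' is a scalar variance (isotropic), a shared
# D x D matrix, or a list of per-chain matrices ------------------------------

cov_kind <- function(cov) {
  if (is.list(cov)) "perchain" else if (is.matrix(cov)) "shared" else "scalar"
}

cov_inv <- function(cov) {
  switch(cov_kind(cov),
         scalar = 1 / cov,
         shared = chol2inv(chol(cov)),
         perchain = lapply(cov, function(S) chol2inv(chol(S))))
}

cov_sqrt <- function(cov) {
  switch(cov_kind(cov),
         scalar = sqrt(cov),
         shared = t(chol(cov)),
         perchain = lapply(cov, function(S) t(chol(S))))
}

# Draw n x D Gaussian increments with covariance 'cov'.
cov_rnorm <- function(cov, n, D) {
  Z <- matrix(stats::rnorm(n * D), n, D)
  switch(cov_kind(cov),
         scalar = sqrt(cov) * Z,
         shared = Z %*% chol(cov),
         perchain = t(vapply(seq_len(n),
                             function(i) drop(cov_sqrt(cov[[i]]) %*% Z[i, ]),
                             numeric(D))))
}

# log-density (up to constants) and gradient of the prediction target
# loglike(m | y) + log N(m; m0, cov); like may be NULL (Gaussian factor only).
pred_logp <- function(like, y, m, m0, cinv) {
  d <- m - m0
  quad <- switch(cov_kind_from_inv(cinv),
                 scalar = rowSums(d^2) * cinv,
                 shared = rowSums((d %*% cinv) * d),
                 perchain = vapply(seq_len(nrow(m)),
                                   function(i) drop(d[i, ] %*% cinv[[i]] %*% d[i, ]),
                                   numeric(1)))
  lp <- -0.5 * quad
  if (!is.null(like)) lp <- lp + loglike(like, m, y)
  lp
}

cov_kind_from_inv <- function(cinv) {
  if (is.list(cinv)) "perchain" else if (is.matrix(cinv)) "shared" else "scalar"
}

pred_grad <- function(like, y, m, m0, cinv) {
  d <- m0 - m
  g <- switch(cov_kind_from_inv(cinv),
              scalar = d * cinv,
              shared = d %*% cinv,
              perchain = t(vapply(seq_len(nrow(m)),
                                  function(i) drop(cinv[[i]] %*% d[i, ]),
                                  numeric(ncol(m)))))
  if (!is.null(like)) g <- g + loglike_grad(like, m, y)
  g
}

#' Langevin sampling of the prediction distribution
#'
#' Samples the prediction target \eqn{\pi(m) \propto \pi_{like}(y | m)\,
#' N(m; m_{aprx}, C_{aprx})} by (preconditioned) Langevin dynamics, batched
#' over chains. Without Metropolis adjustment the update is the unadjusted
#' Euler-Maruyama step \eqn{m \leftarrow m + \eta P \nabla \log \pi(m) +
#' \sqrt{2\eta} P^{1/2} z}; with \code{metropolis = TRUE} each proposal is
#' accepted or rejected by the Metropolis-Hastings ratio for the
#' preconditioned proposal kernel (MALA).
#'
#' @param like a likelihood object, or \code{NULL} to target the Gaussian
#'   factor alone.
#' @param y the measurement vector.
#' @param approx list with \code{mean} (\code{n x D} matrix, one row per
#'   chain) and \code{cov} (scalar variance, shared matrix, or per-chain
#'   list).
#' @param cfg a \code{\link{langevin_config}}.
#' @param init initial state (defaults to \code{approx$mean}).
#' @param seed optional integer seed.
#' @return an \code{n x D} matrix; rows that became non-finite are flagged in
#'   the \code{"diverged"} attribute (and left as \code{NA}).
#' @export
sample_langevin <- function(like, y, approx, cfg = langevin_config(),
                            init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m0 <- as.matrix(approx$mean)
  n <- nrow(m0); D <- ncol(m0)
  m <- if (is.null(init)) m0 else as.matrix(init)
  eta <- cfg$step_size
  use_cpp <- !cfg$metropolis && is.null(cfg$preconditioner) &&
    cov_kind(approx$cov) == "scalar" && !is.null(like) &&
    inherits(like, c("mask_lik", "poisson_lik"))
  if (use_cpp) {
    kseed <- stats::runif(1) * 2^31   # derived from the R RNG stream
    m <- if (inherits(like, "mask_lik")) {
      ula_mask_cpp(m, m0, like$keep - 1L, y, like$tau, approx$cov, eta,
                   cfg$n_subiters, kseed)
    } else {
      ula_poisson_cpp(m, m0, like$C, like$I0, y, approx$cov, eta,
                      cfg$n_subiters, kseed)
    }
    return(flag_diverged(m))
  }
  cinv <- cov_inv(approx$cov)
  P <- cfg$preconditioner
  Phalf <- if (!is.null(P)) t(chol(P)) else NULL
  if (!cfg$metropolis) {
    for (s in seq_len(cfg$n_subiters)) {
      g <- pred_grad(like, y, m, m0, cinv)
      z <- matrix(stats::rnorm(n * D), n, D)
      if (is.null(P)) m <- m + eta * g + sqrt(2 * eta) * z
      else m <- m + eta * g %*% P + sqrt(2 * eta) * z %*% t(Phalf)
    }
    return(flag_diverged(m))
  }
  # MALA with (optionally preconditioned) proposal N(m + eta P grad, 2 eta P)
  Pinv <- if (!is.null(P)) chol2inv(chol(P)) else NULL
  lp <- pred_logp(like, y, m, m0, cinv)
  g <- pred_grad(like, y, m, m0, cinv)
  n_acc <- 0
  qdens <- function(from, to, gfrom) {
    mu <- from + if (is.null(P)) eta * gfrom else eta * gfrom %*% P
    d <- to - mu
    q <- if (is.null(P)) rowSums(d^2) else rowSums((d %*% Pinv) * d)
    -q / (4 * eta)
  }
  for (s in seq_len(cfg$n_subiters)) {
    z <- matrix(stats::rnorm(n * D), n, D)
    noise <- if (is.null(P)) sqrt(2 * eta) * z else sqrt(2 * eta) * z %*% t(Phalf)
    prop <- m + (if (is.null(P)) eta * g else eta * g %*% P) + noise
    lp_p <- pred_logp(like, y, prop, m0, cinv)
    g_p <- pred_grad(like, y, prop, m0, cinv)
    logr <- lp_p - lp + qdens(prop, m, g_p) - qdens(m, prop, g)
    acc <- log(stats::runif(n)) < logr & is.finite(logr)
    m[acc, ] <- prop[acc, ]
    lp[acc] <- lp_p[acc]
    g[acc, ] <- g_p[acc, ]
    n_acc <- n_acc + sum(acc)
  }
  out <- flag_diverged(m)
  attr(out, "accept_rate") <- n_acc / (cfg$n_subiters * n)
  out
}

flag_diverged <- function(m) {
  bad <- !is.finite(rowSums(m))
  if (any(bad)) {
    m[bad, ] <- NA_real_
    attr(m, "diverged") <- bad
  }
  m
}

#' MAP point of the prediction distribution
#'
#' Computes \eqn{\arg\max_m \pi_{like}(y | m)\, N(m; m_{aprx}, C_{aprx})} per
#' chain. For the linear-Gaussian mask likelihood the closed form
#' \eqn{(A^T A/\tau^2 + C^{-1})^{-1}(A^T y/\tau^2 + C^{-1} m_{aprx})} is used;
#' otherwise a quasi-Newton solver (dense BFGS with Wolfe line search in
#' compiled code for the Poisson and phase families, \code{stats::optim}
#' L-BFGS-B elsewhere) is run from \code{init = approx$mean}.
#'
#' @inheritParams sample_langevin
#' @param cfg a \code{\link{map_config}}.
#' @param y the measurement; for internal use by the randomize-then-optimize
#'   sampler an \code{n x K} matrix of per-chain measurements is also
#'   accepted.
#' @return an \code{n x D} matrix of MAP points.
#' @export
sample_map <- function(like, y, approx, cfg = map_config(), init = NULL) {
  m0 <- as.matrix(approx$mean)
  n <- nrow(m0); D <- ncol(m0)
  if (cfg$method == "closed_form") {
    if (!inherits(like, "mask_lik"))
      stop("closed-form MAP requires the linear-Gaussian mask likelihood")
    return(mask_map_closed(like, y, m0, approx$cov))
  }
  Y <- if (is.null(dim(y))) matrix(y, 1L) else as.matrix(y)
  if (cov_kind(approx$cov) == "scalar" &&
      inherits(like, c("poisson_lik", "phase_lik"))) {
    type <- if (inherits(like, "poisson_lik")) 0L else 1L
    F <- if (type == 0L) like$C else like$B
    extra <- if (type == 0L) like$I0 else like$tau
    return(map_batch_cpp(type, F, extra, Y, m0, approx$cov, cfg$max_iters))
  }
  # generic per-chain path (full covariances / arbitrary likelihoods)
  cinv <- cov_inv(approx$cov)
  out <- matrix(NA_real_, n, D)
  for (i in seq_len(n)) {
    ci <- switch(cov_kind_from_inv(cinv), scalar = cinv, shared = cinv,
                 perchain = cinv[[i]])
    yi <- if (nrow(Y) == 1L) Y[1L, ] else Y[i, ]
    fn <- function(mm) {
      d <- mm - m0[i, ]
      q <- if (is.matrix(ci)) drop(d %*% ci %*% d) else sum(d^2) * ci
      ll <- if (is.null(like)) 0 else loglike(like, mm, yi)
      -(ll - 0.5 * q)
    }
    gr <- function(mm) {
      d <- m0[i, ] - mm
      g <- if (is.matrix(ci)) drop(ci %*% d) else ci * d
      if (!is.null(like)) g <- g + drop(loglike_grad(like, mm, yi))
      -g
    }
    st <- if (is.null(init)) m0[i, ] else as.matrix(init)[i, ]
    opt <- stats::optim(st, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = cfg$max_iters))
    out[i, ] <- opt$par
  }
  out
}

mask_map_closed <- function(like, y, m0, cov) {
  n <- nrow(m0); D <- ncol(m0)
  Y <- if (is.null(dim(y))) matrix(y, n, length(y), byrow = TRUE) else as.matrix(y)
  if (cov_kind(cov) == "scalar") {
    out <- m0
    a <- 1 / like$tau^2; b <- 1 / cov
    out[, like$keep] <- (a * Y + b * m0[, like$keep, drop = FALSE]) / (a + b)
    return(out)
  }
  AtA <- crossprod(like$A) / like$tau^2
  if (cov_kind(cov) == "shared") {
    cinv <- chol2inv(chol(cov))
    Pm <- AtA + cinv
    rhs <- t(m0 %*% cinv)
    rhs[like$keep, ] <- rhs[like$keep, ] + t(Y) / like$tau^2
    return(t(solve(Pm, rhs)))
  }
  out <- matrix(NA_real_, n, D)
  for (i in seq_len(n)) {
    cinv <- chol2inv(chol(cov[[i]]))
    rhs <- drop(cinv %*% m0[i, ])
    rhs[like$keep] <- rhs[like$keep] + Y[i, ] / like$tau^2
    out[i, ] <- solve(AtA + cinv, rhs)
  }
  out
}

#' Randomize-then-optimize sampling of the prediction distribution
#'
#' Draws perturbed quantities \eqn{m'_{aprx} \sim N(m_{aprx}, C_{aprx})} and
#' \eqn{y' \sim N(y, \Sigma_z)} and returns the MAP point of the perturbed
#' problem. In the linear-Gaussian case this is exact sampling from the
#' prediction distribution. For Poisson data the perturbation uses the
#' variance-matched Gaussian surrogate \eqn{y'_k \sim N(y_k, \max(y_k, 1))}
#' (the Poisson noise model has no additive-noise decomposition).
#'
#' @inheritParams sample_map
#' @param seed optional integer seed.
#' @return an \code{n x D} matrix of approximate prediction-distribution
#'   samples.
#' @export
sample_rto <- function(like, y, approx, cfg = map_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m0 <- as.matrix(approx$mean)
  n <- nrow(m0); D <- ncol(m0)
  m0p <- m0 + cov_rnorm(approx$cov, n, D)
  K <- length(y)
  Yp <- if (inherits(like, "poisson_lik")) {
    matrix(stats::rnorm(n * K, mean = rep(y, each = n),
                        sd = rep(sqrt(pmax(y, 1)), each = n)), n, K)
  } else {
    matrix(stats::rnorm(n * K, mean = rep(y, each = n), sd = like$tau), n, K)
  }
  approx_p <- list(mean = m0p, cov = approx$cov)
  sample_map(like, Yp, approx_p, cfg)
}

#' Gauss-Newton preconditioner for Langevin sampling
#'
#' Averages the Gauss-Newton Hessian approximation of the negative log
#' prediction density over a set of representative anchor points:
#' \eqn{P^{-1} = \mathrm{mean}_a [J(a)^T \Sigma_z^{-1} J(a) + C_{aprx}^{-1}]}
#' (for the Poisson family the Fisher information \eqn{C^T \Lambda(a) C} takes
#' the place of \eqn{J^T \Sigma_z^{-1} J}), then inverts and symmetrizes. A
#' small ridge guards against near-singularity.
#'
#' @param like a likelihood object.
#' @param approx list with elements \code{mean}/\code{cov} as in
#'   \code{\link{sample_langevin}} (only \code{cov} is used).
#' @param anchor_points an \code{n x D} matrix of anchor states.
#' @return a symmetric positive-definite \code{D x D} matrix \eqn{P}.
#' @export
gauss_newton_preconditioner <- function(like, approx, anchor_points) {
  X <- as.matrix(anchor_points)
  D <- ncol(X)
  cinv <- cov_inv(approx$cov)
  Cmat <- if (is.matrix(cinv)) cinv else diag(drop(cinv), D)
  acc <- matrix(0, D, D)
  for (i in seq_len(nrow(X))) {
    H <- if (inherits(like, "mask_lik")) {
      crossprod(like$A) / like$tau^2
    } else if (inherits(like, "phase_lik")) {
      J <- 2 * drop(like$B %*% X[i, ]) * like$B
      crossprod(J) / like$tau^2
    } else if (inherits(like, "poisson_lik")) {
      lam <- drop(forward_map(like, X[i, ]))
      t(like$C) %*% (lam * like$C)
    } else stop("unsupported likelihood")
    acc <- acc + H + Cmat
  }
  Pinv <- acc / nrow(X) + diag(1e-8, D)
  P <- chol2inv(chol((Pinv + t(Pinv)) / 2))
  (P + t(P)) / 2
}
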