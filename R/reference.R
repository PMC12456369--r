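#' Exact reference posterior samples (linear-Gaussian studies)
#'
#' For the mask likelihood the posterior is a Gaussian mixture in closed form,
#' so reference samples are exact: \code{gmm_sample(linear_gaussian_posterior(
#' prior, A, tau, y), n)}.
#'
#' @param prior the \code{\link{gmm}} prior.
#' @param like a mask likelihood from \code{\link{make_problem}}.
#' @param y the measurement vector.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return an \code{n x D} matrix of exact posterior draws.
#' @export
exact_reference <- function(prior, like, y, n, seed = NULL) {
  if (!inherits(like, "mask_lik"))
    stop("exact sampling requires the linear-Gaussian mask likelihood")
  post <- linear_gaussian_posterior(prior, like$A, like$tau, y)
  gmm_sample(post, n, seed = seed)
}

#' Differential-evolution MCMC reference sampler
#'
#' Multi-chain DE-MC with proposals generated from an archive of past states
#' and occasional snooker moves, targeting \eqn{\pi_{like}(y|m)\,\pi_{pr}(m)}
#' (the prior may be a full mixture or a single component). The first half of
#' each chain is discarded as burn-in when diagnostics and samples are
#' extracted. References produced by this engine must pass the convergence
#' gate (\code{max PSRF < 1.01}) before use; \code{\link{reference_draws}}
#' enforces this.
#'
#' @param prior a \code{\link{gmm}} (full prior or a single component).
#' @param like a likelihood object (or \code{NULL} to sample the prior).
#' @param y the measurement vector.
#' @param n_chains number of parallel chains (at least 4 recommended).
#' @param n_iter iterations per chain.
#' @param seed integer seed.
#' @param init optional \code{n_chains x D} initial states; by default a Latin
#'   hypercube over component mean +- 6 component standard deviations (single
#'   component) or draws from the prior (mixture).
#' @param thin storage thinning factor (diagnostics and draws use the thinned
#'   chains; choose \code{thin} well below the integrated autocorrelation
#'   time).
#' @return a \code{chain_set}: list with \code{chains} (array \code{n_chains x
#'   (n_iter/thin) x D}), \code{logpost} matrix, \code{burn_frac = 0.5},
#'   \code{thin} and \code{seed}.
#' @export
mcmc_reference <- function(prior, like, y, n_chains = 10L, n_iter = 20000L,
                           seed = 1L, init = NULL, thin = 1L) {
  set.seed(as.integer(seed))
  D <- prior$D
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  thin <- as.integer(thin)
  stopifnot(n_chains >= 2L, n_iter >= 20L * thin)
  lhs_box <- function(n) {
    mu <- prior$means[[1L]]
    sd6 <- 6 * sqrt(diag(prior$covariances[[1L]]))
    U <- lhs::randomLHS(n, D)
    sweep(sweep(U, 2L, 2 * sd6, "*"), 2L, mu - sd6, "+")
  }
  if (is.null(init)) {
    init <- if (prior$K == 1L) lhs_box(n_chains) else gmm_sample(prior, n_chains)
  }
  n_arch0 <- max(10L * D, 3L * n_chains)
  archive <- if (prior$K == 1L) lhs_box(n_arch0) else gmm_sample(prior, n_arch0)
  archive <- rbind(archive, init)
  # pack the mixture prior for the compiled engine
  means <- do.call(rbind, prior$means)
  Pinv <- array(0, c(D, D, prior$K))
  lw <- numeric(prior$K)
  for (i in seq_len(prior$K)) {
    R <- chol(prior$covariances[[i]])
    Pinv[, , i] <- chol2inv(R)
    lw[i] <- log(prior$weights[i]) -
      0.5 * (D * log(2 * pi)) - sum(log(diag(R)))
  }
  if (is.null(like)) {
    type <- 0L; F <- matrix(0, 1, D); extra <- 1; yy <- 0
  } else if (inherits(like, "mask_lik")) {
    type <- 1L; F <- like$A; extra <- like$tau; yy <- y
  } else if (inherits(like, "poisson_lik")) {
    type <- 2L; F <- like$C; extra <- like$I0; yy <- y
  } else if (inherits(like, "phase_lik")) {
    type <- 3L; F <- like$B; extra <- like$tau; yy <- y
  } else stop("unsupported likelihood for the compiled DE-MC engine")
  out <- demc_cpp(means, Pinv, lw, type, F, extra, as.numeric(yy),
                  as.matrix(init), archive, n_iter, thin,
                  stats::runif(1) * 2^31)
  structure(list(chains = out$chains, logpost = out$logpost, burn_frac = 0.5,
                 thin = thin, seed = as.integer(seed)),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  d <- dim(x$chains)
  cat(sprintf("chain_set: %d chains x %d iterations x %d dimensions (burn-in %.0f%%)\n",
              d[1], d[2], d[3], 100 * x$burn_frac))
  invisible(x)
}

post_burnin <- function(cs) {
  d <- dim(cs$chains)
  keep <- seq.int(floor(d[2] * cs$burn_frac) + 1L, d[2])
  cs$chains[, keep, , drop = FALSE]
}

#' MCMC convergence diagnostics
#'
#' \code{psrf} computes the split-chain Gelman-Rubin potential scale reduction
#' factor per dimension (each post-burn-in chain is split in half, so
#' within-chain trends inflate the statistic). \code{ess} computes the
#' effective sample size per dimension by initial-positive-sequence
#' autocorrelation summation, computed per chain and summed across chains.
#'
#' @param chains a \code{chain_set} from \code{\link{mcmc_reference}} or an
#'   array \code{n_chains x n_iter x D} (taken as already post-burn-in when an
#'   array is passed).
#' @return numeric vector of length \code{D}.
#' @export
psrf <- function(chains) {
  A <- if (inherits(chains, "chain_set")) post_burnin(chains) else chains
  d <- dim(A)
  stopifnot(d[1] >= 2L, d[2] >= 10L)
  half <- d[2] %/% 2L
  vapply(seq_len(d[3]), function(j) {
    segs <- list()
    for (c in seq_len(d[1])) {
      segs[[2 * c - 1]] <- A[c, seq_len(half), j]
      segs[[2 * c]] <- A[c, seq.int(d[2] - half + 1L, d[2]), j]
    }
    mns <- vapply(segs, mean, numeric(1))
    vrs <- vapply(segs, stats::var, numeric(1))
    W <- mean(vrs)
    B <- half * stats::var(mns)
    if (W <= 0) return(if (stats::var(mns) <= 0) 1 else Inf)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
}

#' @rdname psrf
#' @export
ess <- function(chains) {
  A <- if (inherits(chains, "chain_set")) post_burnin(chains) else chains
  d <- dim(A)
  stopifnot(d[1] >= 1L, d[2] >= 10L)
  vapply(seq_len(d[3]), function(j) {
    tot <- 0
    for (c in seq_len(d[1])) {
      x <- A[c, , j]
      v <- stats::var(x)
      if (v <= 0) { tot <- tot + 0; next }
      rho <- as.numeric(stats::acf(x, lag.max = min(d[2] - 1L, 2000L),
                                   plot = FALSE, demean = TRUE)$acf)[-1L]
      # initial positive sequence on paired sums
      npair <- length(rho) %/% 2L
      ssum <- 0
      for (k in seq_len(npair)) {
        g <- rho[2 * k - 1] + rho[2 * k]
        if (g <= 0) break
        ssum <- ssum + g
      }
      tot <- tot + d[2] / (1 + 2 * ssum)
    }
    tot
  }, numeric(1))
}

#' @rdname psrf
#' @param n_requested the number of reference draws that will be consumed; the
#'   gate requires \code{min(ess) >= n_requested}.
#' @return \code{diagnostics}: list with \code{psrf}, \code{ess} and logical
#'   \code{pass}.
#' @export
diagnostics <- function(chains, n_requested = 0L) {
  p <- psrf(chains)
  e <- ess(chains)
  list(psrf = p, ess = e,
       pass = max(p) < 1.01 && min(e) >= n_requested)
}

#' Gated extraction of reference draws from an MCMC run
#'
#' Discards burn-in, checks the convergence gate (max PSRF < 1.01 and ESS at
#' least the requested sample count) and subsamples the pooled post-burn-in
#' draws. Fails loudly (with the diagnostics attached to the condition) if the
#' gate is not passed; gated references are never silently used.
#'
#' @param cs a \code{chain_set}.
#' @param n number of draws to extract.
#' @param gate enforce the convergence gate.
#' @return an \code{n x D} matrix.
#' @export
reference_draws <- function(cs, n, gate = TRUE) {
  dg <- diagnostics(cs, n_requested = if (gate) n else 0L)
  if (gate && !dg$pass) {
    cond <- simpleError(sprintf(
      "MCMC reference failed the convergence gate (max PSRF %.4f, min ESS %.0f, requested %d)",
      max(dg$psrf), min(dg$ess), n))
    cond$diagnostics <- dg
    stop(cond)
  }
  A <- post_burnin(cs)
  d <- dim(A)
  pool <- matrix(aperm(A, c(2, 1, 3)), d[1] * d[2], d[3])
  idx <- sample.int(nrow(pool), n, replace = n > nrow(pool))
  pool[idx, , drop = FALSE]
}

# Log evidence of the unnormalized target via reverse importance sampling
# with a Gaussian fitted to posterior draws.
log_evidence_ris <- function(draws, log_unnorm) {
  mu <- colMeans(draws)
  S <- stats::cov(draws)
  S <- S + diag(1e-10, ncol(draws))
  R <- chol(S)
  dmat <- sweep(draws, 2L, mu)
  u <- backsolve(R, t(dmat), transpose = TRUE)
  logq <- -0.5 * (ncol(draws) * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(u^2))
  lr <- logq - log_unnorm
  mx <- max(lr)
  lz <- -(mx + log(mean(exp(lr - mx))))
  ratios <- exp(lr - mx)
  if (stats::sd(ratios) / mean(ratios) > 5)
    warning("high-variance evidence estimate; consider longer chains")
  lz
}

#' Component-wise reference sampling for multimodal posteriors
#'
#' Exploits the mixture structure of the posterior,
#' \eqn{\pi_{post}(m|y) \propto \sum_i w_i \pi_{like}(y|m) \pi_{pr,i}(m)}: each
#' component posterior is sampled by its own gated MCMC run, per-component
#' evidences \eqn{Z_i} are estimated by reverse importance sampling with a
#' Gaussian fitted to the post-burn-in draws, and the final batch resamples
#' components with probability proportional to \eqn{w_i Z_i}.
#'
#' @param prior the \code{\link{gmm}} mixture prior.
#' @param like a likelihood object.
#' @param y the measurement vector.
#' @param n number of draws returned.
#' @param n_chains,n_iter per-component MCMC settings; \code{n_iter} may be a
#'   vector (recycled over components) so that components with harder
#'   geometry, e.g. one straddling a sign symmetry of the forward map, can run
#'   longer chains.
#' @param seed integer seed.
#' @param gate enforce the convergence gate per component.
#' @param n_gate effective-sample-size requirement of the gate (default
#'   \code{min(n, 10000)}). Set to 0 to gate on PSRF alone, appropriate when
#'   the consumer is a self-distance between two resamples of the same pool
#'   (pool-level MCMC error cancels there).
#' @return an \code{n x D} matrix with attributes \code{"weights"} (posterior
#'   component weights) and \code{"diagnostics"} (per-component list).
#' @export
componentwise_reference <- function(prior, like, y, n = 10000L,
                                    n_chains = 40L, n_iter = 20000L,
                                    seed = 1L, gate = TRUE, n_gate = NULL,
                                    thin = 1L) {
  if (is.null(n_gate)) n_gate <- min(n, 10000L)
  comps <- seq_len(prior$K)
  n_iter <- rep_len(n_iter, prior$K)
  pools <- vector("list", prior$K)
  logz <- numeric(prior$K)
  diags <- vector("list", prior$K)
  for (i in comps) {
    comp <- gmm(1, prior$means[i], prior$covariances[i])
    cs <- mcmc_reference(comp, like, y, n_chains = n_chains,
                         n_iter = n_iter[i], seed = seed + 1000L * i,
                         thin = thin)
    dg <- diagnostics(cs, n_requested = if (gate) n_gate else 0L)
    diags[[i]] <- dg
    if (gate && !dg$pass)
      stop(sprintf("component %d failed the convergence gate (max PSRF %.4f, min ESS %.0f)",
                   i, max(dg$psrf), min(dg$ess)))
    A <- post_burnin(cs)
    d <- dim(A)
    pool <- matrix(aperm(A, c(2, 1, 3)), d[1] * d[2], d[3])
    sub <- pool[sample.int(nrow(pool), min(nrow(pool), 20000L)), , drop = FALSE]
    lu <- gmm_logpdf(comp, sub)
    if (!is.null(like)) lu <- lu + loglike(like, sub, y)
    logz[i] <- log_evidence_ris(sub, lu)
    pools[[i]] <- pool
  }
  lw <- log(prior$weights) + logz
  w <- exp(lw - max(lw)); w <- w / sum(w)
  set.seed(as.integer(seed) + 7L)
  lab <- sample.int(prior$K, n, replace = TRUE, prob = w)
  out <- matrix(NA_real_, n, prior$D)
  for (i in comps) {
    idx <- which(lab == i)
    if (!length(idx)) next
    pool <- pools[[i]]
    out[idx, ] <- pool[sample.int(nrow(pool), length(idx),
                                  replace = length(idx) > nrow(pool)), ]
  }
  attr(out, "weights") <- w
  attr(out, "diagnostics") <- diags
  out
}
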