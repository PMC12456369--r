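#' Configuration of an annealing sampler variant
#'
#' A variant couples a denoising approximation (\code{"ODE"}, \code{"TU"} or
#' \code{"TC"}) with a prediction sampler (\code{"Lang"}, \code{"MAP"} or
#' \code{"RTO"}), giving the nine algorithms of the framework. \code{"Lang-ODE"}
#' recovers the DAPS algorithm and \code{"MAP-TU"} recovers DiffPIR.
#'
#' @param variant a string \code{"<sampler>-<approx>"}, e.g. \code{"RTO-TU"}
#'   (case insensitive).
#' @param N_A number of annealing steps (benchmark value 200).
#' @param schedule a \code{\link{noise_schedule}}.
#' @param rho polynomial exponent of the annealing grid.
#' @param t_min terminal positive grid level (see \code{\link{make_time_grid}};
#'   the benchmark configuration anneals down to 0.01 before the final jump to
#'   0, which keeps the fixed-step Langevin sampler stable).
#' @param n_ode_steps Euler steps of the probability-flow-ODE denoiser
#'   (benchmark value 5).
#' @param beta_rule function mapping \eqn{\sigma(t)} to the isotropic
#'   denoising standard deviation \eqn{\beta(t)} used by the ODE and TU
#'   approximations (benchmark rule \eqn{\beta(t) = \sigma(t)}).
#' @param sampler_cfg a \code{\link{langevin_config}} or
#'   \code{\link{map_config}}; a sensible default is chosen per sampler when
#'   \code{NULL}.
#' @param n_chains number of chains run in parallel (one posterior draw each).
#' @param seed integer seed.
#' @param force_tc allow the TC approximation with a learned score (refused by
#'   default: the Jacobian of a learned score is not a reliable covariance
#'   estimate).
#' @return a \code{bipsda_config} object.
#' @export
bipsda_config <- function(variant = "RTO-TU", N_A = 200L, schedule = noise_schedule(),
                          rho = 7, t_min = 0.01, n_ode_steps = 5L,
                          beta_rule = identity, sampler_cfg = NULL,
                          n_chains = 10000L, seed = 1L, force_tc = FALSE) {
  parts <- strsplit(tolower(variant), "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1] %in% c("lang", "map", "rto") ||
      !parts[2] %in% c("ode", "tu", "tc"))
    stop("'variant' must be one of ", paste(bipsda_variants(), collapse = ", "))
  if (is.null(sampler_cfg))
    sampler_cfg <- if (parts[1] == "lang") langevin_config() else map_config("closed_form")
  structure(list(sampler = parts[1], approx = parts[2], variant = toupper(variant),
                 N_A = as.integer(N_A), schedule = schedule, rho = rho, t_min = t_min,
                 n_ode_steps = as.integer(n_ode_steps), beta_rule = beta_rule,
                 sampler_cfg = sampler_cfg, n_chains = as.integer(n_chains),
                 seed = as.integer(seed), force_tc = force_tc),
            class = "bipsda_config")
}

#' @rdname bipsda_config
#' @export
bipsda_variants <- function() {
  as.vector(outer(c("Lang", "MAP", "RTO"), c("ODE", "TU", "TC"), paste, sep = "-"))
}

#' Gaussian approximation of the denoising distribution
#'
#' Builds the per-chain Gaussian approximation \eqn{N(m_{aprx}, C_{aprx})} of
#' \eqn{\pi(m(0) | m(t))}:
#' \describe{
#'   \item{ODE}{mean from the probability-flow-ODE denoiser,
#'     \eqn{C = \beta(t)^2 I}.}
#'   \item{TU}{mean from Tweedie's formula, \eqn{C = \beta(t)^2 I}.}
#'   \item{TC}{Tweedie mean and generalized-Tweedie covariance (requires a
#'     score Jacobian provider).}
#' }
#'
#' @param approx_kind \code{"ode"}, \code{"tu"} or \code{"tc"}.
#' @param score a \code{\link{score_function}}.
#' @param m_batch \code{n x D} matrix of current iterates.
#' @param t current annealing time (\code{t > 0}).
#' @param cfg a \code{\link{bipsda_config}} (supplies schedule, beta rule and
#'   ODE sub-steps).
#' @return list with \code{mean} (\code{n x D}) and \code{cov} (scalar
#'   variance, shared matrix, or per-chain list).
#' @export
approx_denoising <- function(approx_kind, score, m_batch, t, cfg = bipsda_config()) {
  approx_kind <- tolower(approx_kind)
  sig <- cfg$schedule$sigma(t)
  beta2 <- cfg$beta_rule(sig)^2
  m_batch <- as.matrix(m_batch)
  if (approx_kind == "ode") {
    mu <- pf_ode_denoise(score, m_batch, t, n_steps = cfg$n_ode_steps,
                         schedule = cfg$schedule, rho = cfg$rho,
                         t_min = cfg$t_min)
    return(list(mean = mu, cov = beta2))
  }
  mu <- tweedie_mean(score, m_batch, sig)
  if (approx_kind == "tu") return(list(mean = mu, cov = beta2))
  if (score$kind == "learned" && !isTRUE(cfg$force_tc))
    stop("TC approximation with a learned score is refused (set force_tc = TRUE to override)")
  if (is.null(score$jacobian)) stop("TC approximation requires a score Jacobian provider")
  J <- score$jacobian(m_batch, sig)
  if (isTRUE(attr(J, "shared"))) {
    C <- sig^2 * (diag(ncol(m_batch)) + sig^2 * J[[1L]])
    list(mean = mu, cov = (C + t(C)) / 2)
  } else {
    covs <- lapply(J, function(Ji) {
      C <- sig^2 * (diag(ncol(m_batch)) + sig^2 * Ji)
      C <- (C + t(C)) / 2
      e <- eigen(C, symmetric = TRUE)
      if (min(e$values) < 1e-10) {
        e$values <- pmax(e$values, 1e-10)
        C <- e$vectors %*% (e$values * t(e$vectors))
        C <- (C + t(C)) / 2
      }
      C
    })
    list(mean = mu, cov = covs)
  }
}

#' Decoupled-noise-annealing posterior sampler
#'
#' Runs the annealing loop: chains are initialized from \eqn{N(0,
#' \sigma^2(T) I)}; at each of the \code{N_A} steps the denoising distribution
#' at the current noise level is approximated by a Gaussian
#' (\code{\link{approx_denoising}}), an approximate sample from the prediction
#' distribution \eqn{\pi_{like}(y|m)\,N(m; m_{aprx}, C_{aprx})} is drawn
#' (Langevin, MAP, or randomize-then-optimize), and the result is re-noised to
#' the next (lower) level. The final iteration performs prediction only.
#'
#' @param problem a likelihood object from \code{\link{make_problem}}.
#' @param prior_score a \code{\link{score_function}} for the prior.
#' @param y the measurement vector.
#' @param cfg a \code{\link{bipsda_config}}.
#' @return a \code{sample_batch} object: list with \code{values}
#'   (\code{n_chains x D}), logical \code{diverged} mask, \code{variant} and
#'   \code{seed}.
#' @examples
#' pr <- gmm(1, list(rep(0, 3)), list(diag(3)))
#' lik <- make_problem("inpaint_low", seed = 1, D = 3, keep = 1)
#' y <- simulate_measurement(lik, rep(0, 3), seed = 2)$y
#' cfg <- bipsda_config("RTO-TU", N_A = 20, n_chains = 50, seed = 3)
#' s <- bipsda_sample(lik, analytic_score(pr), y, cfg)
#' summary(s)
#' @export
bipsda_sample <- function(problem, prior_score, y, cfg = bipsda_config()) {
  set.seed(cfg$seed)
  D <- prior_score$D
  if (is.null(D)) stop("prior_score must carry its dimension D")
  n <- cfg$n_chains
  grid <- make_time_grid(cfg$N_A, cfg$schedule$T, cfg$rho, cfg$t_min)
  m <- cfg$schedule$sigma(grid[1L]) * matrix(stats::rnorm(n * D), n, D)
  for (i in seq_len(cfg$N_A)) {
    t_cur <- grid[i]
    ap <- approx_denoising(cfg$approx, prior_score, m, t_cur, cfg)
    scfg <- cfg$sampler_cfg
    if (cfg$sampler == "lang" && isTRUE(scfg$gn_precondition)) {
      anchors <- ap$mean[sample.int(n, min(8L, n)), , drop = FALSE]
      anchors <- anchors[is.finite(rowSums(anchors)), , drop = FALSE]
      if (nrow(anchors) > 0)
        scfg$preconditioner <- gauss_newton_preconditioner(problem, ap, anchors)
    }
    m0 <- switch(cfg$sampler,
                 lang = sample_langevin(problem, y, ap, scfg),
                 map  = sample_map(problem, y, ap, scfg),
                 rto  = sample_rto(problem, y, ap, scfg))
    sig_next <- cfg$schedule$sigma(grid[i + 1L])
    m <- if (sig_next > 0) {
      m0 + sig_next * matrix(stats::rnorm(n * D), n, D)
    } else m0
  }
  diverged <- !is.finite(rowSums(m))
  if (mean(diverged) > 0.01)
    warning(sprintf("%.1f%% of chains diverged", 100 * mean(diverged)))
  structure(list(values = m, diverged = diverged, variant = cfg$variant,
                 seed = cfg$seed),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("sample_batch: %d draws in %d dimensions (variant %s, seed %d)\n",
              nrow(x$values), ncol(x$values), x$variant, x$seed))
  if (any(x$diverged))
    cat(sprintf("  %d diverged chain(s) excluded from summaries\n", sum(x$diverged)))
  invisible(x)
}

#' @export
summary.sample_batch <- function(object, ...) {
  v <- object$values[!object$diverged, , drop = FALSE]
  out <- rbind(mean = colMeans(v), sd = apply(v, 2L, stats::sd))
  colnames(out) <- paste0("m", seq_len(ncol(v)))
  cat(sprintf("Posterior summaries from %d draws (variant %s):\n",
              nrow(v), object$variant))
  print(round(out, 4))
  invisible(out)
}

#' @export
plot.sample_batch <- function(x, dims = c(1L, 2L), ...) {
  v <- x$values[!x$diverged, dims, drop = FALSE]
  graphics::plot(v[, 1L], v[, 2L], pch = ".", cex = 2,
                 xlab = paste0("m", dims[1L]), ylab = paste0("m", dims[2L]),
                 main = paste("Posterior draws,", x$variant), ...)
  invisible(x)
}

#' @export
as.matrix.sample_batch <- function(x, ...) x$values[!x$diverged, , drop = FALSE]

# Coerce matrices / sample batches to a clean draw matrix (sample_batch
# dispatch drops diverged chains).
batch_values <- function(x) as.matrix(x)
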