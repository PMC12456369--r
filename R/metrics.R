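#' Posterior mean and pointwise-variance errors
#'
#' Two-norm discrepancies between empirical summaries of two sample batches:
#' \code{mean_error} is \eqn{\|\bar m_1 - \bar m_2\|_2}; \code{variance_error}
#' compares the vectors of per-dimension (unbiased) variances.
#'
#' @param S1,S2 sample matrices (\code{n x D}) or \code{sample_batch} objects;
#'   both need at least two rows and a common \code{D}.
#' @return a nonnegative scalar.
#' @export
mean_error <- function(S1, S2) {
  S1 <- batch_values(S1); S2 <- batch_values(S2)
  stopifnot(nrow(S1) >= 2, nrow(S2) >= 2, ncol(S1) == ncol(S2))
  sqrt(sum((colMeans(S1) - colMeans(S2))^2))
}

#' @rdname mean_error
#' @export
variance_error <- function(S1, S2) {
  S1 <- batch_values(S1); S2 <- batch_values(S2)
  stopifnot(nrow(S1) >= 2, nrow(S2) >= 2, ncol(S1) == ncol(S2))
  v1 <- apply(S1, 2L, stats::var)
  v2 <- apply(S2, 2L, stats::var)
  sqrt(sum((v1 - v2)^2))
}

#' Central moment discrepancy
#'
#' Weighted sum of two-norm differences of empirical per-coordinate central
#' moments,
#' \deqn{\mathrm{CMD} = \frac{1}{\alpha}\|\bar m_1 - \bar m_2\|_2 +
#'       \sum_{k=2}^{K} \frac{1}{\alpha^k}\|c_k(S_1) - c_k(S_2)\|_2,}
#' with \eqn{c_k} the vector of per-coordinate k-th central moments. The decay
#' rate \eqn{\alpha} scales the contribution of higher moments;
#' \code{\link{estimate_alpha}} supplies the benchmark rule
#' \eqn{\alpha = 4 \hat\eta_{max}}.
#'
#' @inheritParams mean_error
#' @param alpha decay rate, \code{alpha > 0}.
#' @param K highest moment retained (benchmark value 5), \code{K >= 2}.
#' @return a nonnegative scalar.
#' @export
cmd <- function(S1, S2, alpha, K = 5L) {
  stopifnot(alpha > 0)
  if (K < 2) stop("'K' must be at least 2")
  S1 <- batch_values(S1); S2 <- batch_values(S2)
  central <- function(S, k) colMeans(sweep(S, 2L, colMeans(S))^k)
  out <- sqrt(sum((colMeans(S1) - colMeans(S2))^2)) / alpha
  for (k in 2:K)
    out <- out + sqrt(sum((central(S1, k) - central(S2, k))^2)) / alpha^k
  out
}

#' Decay rate for the central moment discrepancy
#'
#' The benchmark rule \eqn{\alpha = 4 \hat\eta_{max}}, where
#' \eqn{\hat\eta_{max}} is the empirical mean, over trial measurements, of the
#' sup-norm of the componentwise posterior standard deviation (estimated from
#' the reference batch of each trial).
#'
#' @param reference_batches a list with one reference sample matrix per trial
#'   (a single matrix is treated as one trial).
#' @return a positive scalar.
#' @export
estimate_alpha <- function(reference_batches) {
  if (is.matrix(reference_batches)) reference_batches <- list(reference_batches)
  if (!length(reference_batches)) stop("need at least one reference batch")
  eta <- vapply(reference_batches,
                function(S) max(apply(batch_values(S), 2L, stats::sd)),
                numeric(1))
  4 * mean(eta)
}

#' Maximum mean discrepancy
#'
#' Kernel two-sample distance with the multi-bandwidth Gaussian kernel
#' \eqn{k(m_1, m_2) = \sum_{i=1}^{N_b} \exp(-\|m_1 - m_2\|_2^2 / (2\epsilon_i))},
#' \eqn{\epsilon_i = \bar\epsilon\, 2^{\,i - \lceil N_b/2 \rceil}} (factors
#' 1/4, 1/2, 1, 2, 4 at the default \eqn{N_b = 5}), where \eqn{\bar\epsilon} is
#' the average squared pairwise distance among reference samples. The default
#' estimator is the biased V-statistic, reported on the square-root scale and
#' floored at zero; the unbiased U-statistic is available.
#'
#' @inheritParams mean_error
#' @param eps_bar base bandwidth; computed from \code{S2} (the reference)
#'   when \code{NULL}, on a subsample of at most \code{max_pairs_n} rows.
#' @param n_bandwidths number of kernel bandwidths (benchmark value 5).
#' @param estimator \code{"biased"} (V-statistic) or \code{"unbiased"}
#'   (U-statistic).
#' @param kernel_scale \code{"2eps"} for \eqn{\exp(-d^2/(2\epsilon))} (the
#'   default convention) or \code{"eps"} for \eqn{\exp(-d^2/\epsilon)}.
#' @param max_pairs_n cap on rows used per batch (quadratic cost control);
#'   larger batches are subsampled deterministically (every k-th row).
#' @return a nonnegative scalar (for the unbiased estimator, possibly the
#'   signed square root of a small negative value, floored at 0).
#' @export
mmd <- function(S1, S2, eps_bar = NULL, n_bandwidths = 5L,
                estimator = c("biased", "unbiased"),
                kernel_scale = c("2eps", "eps"), max_pairs_n = 2000L) {
  estimator <- match.arg(estimator)
  kernel_scale <- match.arg(kernel_scale)
  S1 <- batch_values(S1); S2 <- batch_values(S2)
  stopifnot(nrow(S1) >= 2, nrow(S2) >= 2, ncol(S1) == ncol(S2))
  sub <- function(S) {
    if (nrow(S) <= max_pairs_n) return(S)
    S[seq(1L, nrow(S), length.out = max_pairs_n), , drop = FALSE]
  }
  S1 <- sub(S1); S2 <- sub(S2)
  sqd <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    pmax(d2, 0)
  }
  D22 <- sqd(S2, S2)
  if (is.null(eps_bar)) eps_bar <- mean(D22)
  stopifnot(eps_bar > 0)
  eps <- eps_bar * 2^(seq_len(n_bandwidths) - ceiling(n_bandwidths / 2))
  denom <- if (kernel_scale == "2eps") 2 * eps else eps
  ksum <- function(d2) Reduce(`+`, lapply(denom, function(e) exp(-d2 / e)))
  K11 <- ksum(sqd(S1, S1))
  K22 <- ksum(D22)
  K12 <- ksum(sqd(S1, S2))
  n1 <- nrow(S1); n2 <- nrow(S2)
  m2 <- if (estimator == "biased") {
    mean(K11) + mean(K22) - 2 * mean(K12)
  } else {
    (sum(K11) - sum(diag(K11))) / (n1 * (n1 - 1)) +
      (sum(K22) - sum(diag(K22))) / (n2 * (n2 - 1)) - 2 * mean(K12)
  }
  sqrt(max(m2, 0))
}

#' Run a benchmark study
#'
#' Replicates the benchmark evaluation protocol: a problem instance is fixed;
#' for each trial a ground truth \eqn{m} is drawn from the prior and a
#' measurement \eqn{y} simulated; a reference batch (exact sampling for the
#' inpainting studies, gated MCMC otherwise) and one batch per requested
#' variant are produced; the four metrics (posterior mean error,
#' pointwise-variance error, CMD, MMD) are computed against the reference and
#' aggregated as trial means with empirical interdecile (10th-90th percentile)
#' ranges. A \code{"Reference"} row compares two independent reference
#' batches, giving the Monte-Carlo floor of each metric.
#'
#' @param study one of \code{"inpaint_low"}, \code{"inpaint_high"},
#'   \code{"xray"}, \code{"phase"}.
#' @param variants character vector of variant labels (see
#'   \code{\link{bipsda_variants}}); may be empty to evaluate the reference
#'   floor only.
#' @param n_trials number of measurement trials (benchmark value 100).
#' @param n_samples draws per batch (benchmark value 10,000).
#' @param seed integer master seed.
#' @param score_mode \code{"analytic"} or \code{"learned"}; the learned mode
#'   requires \code{learned_score}.
#' @param learned_score a trained \code{\link{score_function}} (only with
#'   \code{score_mode = "learned"}).
#' @param prior the \code{\link{gmm}} prior (default: the benchmark prior).
#' @param problem_seed seed of the fixed problem instance.
#' @param cfg_fun optional function \code{(variant, trial_seed) ->
#'   \link{bipsda_config}} overriding the per-study defaults.
#' @param ref_cfg list overriding the per-study reference-sampler defaults
#'   (\code{n_chains}, \code{n_iter} — possibly per-component —, \code{thin},
#'   \code{n_gate}, \code{componentwise}) for the MCMC studies.
#' @param mmd_max_n subsample cap for the quadratic-cost MMD.
#' @param verbose print per-trial progress.
#' @return a \code{bipsda_report}: list with \code{table} (one row per variant
#'   plus the reference row: metric means and interdecile bounds),
#'   \code{per_trial} (long data frame), \code{alpha}, and divergence counts.
#' @export
run_study <- function(study, variants = character(), n_trials = 100L,
                      n_samples = 10000L, seed = 1L,
                      score_mode = c("analytic", "learned"),
                      learned_score = NULL, prior = NULL, problem_seed = 100L,
                      cfg_fun = NULL, ref_cfg = list(), mmd_max_n = 2000L,
                      verbose = FALSE) {
  score_mode <- match.arg(score_mode)
  stopifnot(n_trials >= 1L)
  if (is.null(prior)) prior <- build_prior(seed = problem_seed)
  like <- make_problem(study, seed = problem_seed, D = prior$D)
  score <- if (score_mode == "analytic") analytic_score(prior) else {
    if (is.null(learned_score)) stop("learned score mode requires 'learned_score'")
    learned_score
  }
  exact <- inherits(like, "mask_lik")
  rc_default <- if (study == "phase") {
    # the zero-mean component straddles the sign symmetry of the forward map
    # and runs longer chains; shared-pool resamples need no ESS gate
    list(n_chains = 24L, n_iter = c(120000L, 400000L, 120000L), thin = 20L,
         n_gate = 0L, componentwise = TRUE)
  } else {
    # sized so the pooled effective sample size clears a 10,000-draw request
    list(n_chains = 10L, n_iter = 100000L, thin = 5L, n_gate = NULL,
         componentwise = FALSE)
  }
  rc <- utils::modifyList(rc_default, ref_cfg)
  if (is.null(cfg_fun)) cfg_fun <- function(variant, trial_seed)
    default_study_config(study, variant, n_samples, trial_seed)
  ref_batch <- function(trial_seed, n) {
    if (exact) return(exact_reference(prior, like, y, n, seed = trial_seed))
    if (rc$componentwise) {
      componentwise_reference(prior, like, y, n = n, n_chains = rc$n_chains,
                              n_iter = rc$n_iter, seed = trial_seed,
                              n_gate = rc$n_gate, thin = rc$thin)
    } else {
      cs <- mcmc_reference(prior, like, y, n_chains = rc$n_chains,
                           n_iter = rc$n_iter, seed = trial_seed,
                           thin = rc$thin)
      reference_draws(cs, n)
    }
  }
  rows <- list()
  n_div <- stats::setNames(integer(length(variants)), variants)
  refs <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    tseed <- seed + 13L * tr
    set.seed(tseed)
    m_true <- drop(gmm_sample(prior, 1L))
    y <- simulate_measurement(like, m_true)$y
    if (exact || !rc$componentwise) {
      S_ref <- ref_batch(tseed + 1L, n_samples)
      S_ref2 <- ref_batch(tseed + 2L, n_samples)
    } else {
      # component-wise MCMC: reuse the gated chains, resample twice
      cw <- componentwise_reference(prior, like, y, n = 2L * n_samples,
                                    n_chains = rc$n_chains, n_iter = rc$n_iter,
                                    seed = tseed + 1L, n_gate = rc$n_gate,
                                    thin = rc$thin)
      S_ref <- cw[seq_len(n_samples), , drop = FALSE]
      S_ref2 <- cw[n_samples + seq_len(n_samples), , drop = FALSE]
    }
    refs[[tr]] <- S_ref
    rows[[length(rows) + 1L]] <- data.frame(
      trial = tr, variant = "Reference",
      mean_error = mean_error(S_ref2, S_ref),
      variance_error = variance_error(S_ref2, S_ref),
      S1 = I(list(S_ref2)), stringsAsFactors = FALSE)
    for (v in variants) {
      cfg <- cfg_fun(v, tseed + 3L)
      sb <- bipsda_sample(like, score, y, cfg)
      n_div[v] <- n_div[v] + sum(sb$diverged)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, variant = v,
        mean_error = mean_error(sb, S_ref),
        variance_error = variance_error(sb, S_ref),
        S1 = I(list(batch_values(sb))), stringsAsFactors = FALSE)
    }
    if (verbose) message("trial ", tr, "/", n_trials, " done")
  }
  alpha <- estimate_alpha(refs)
  per_trial <- do.call(rbind, rows)
  per_trial$cmd <- per_trial$mmd <- NA_real_
  for (r in seq_len(nrow(per_trial))) {
    S1 <- per_trial$S1[[r]]
    S_ref <- refs[[per_trial$trial[r]]]
    per_trial$cmd[r] <- cmd(S1, S_ref, alpha = alpha)
    per_trial$mmd[r] <- mmd(S1, S_ref, max_pairs_n = mmd_max_n)
  }
  per_trial$S1 <- NULL
  tab <- aggregate_report(per_trial)
  structure(list(study = study, table = tab, per_trial = per_trial,
                 alpha = alpha, n_trials = n_trials, n_samples = n_samples,
                 divergences = n_div, score_mode = score_mode),
            class = "bipsda_report")
}

# Per-study default sampler settings mirroring the benchmark protocol.
default_study_config <- function(study, variant, n_samples, trial_seed) {
  parts <- strsplit(tolower(variant), "-")[[1L]]
  scfg <- if (parts[1] == "lang") {
    if (study == "phase") langevin_config(step_size = 0.2, n_subiters = 1000L,
                                          metropolis = TRUE,
                                          gn_precondition = TRUE)
    else if (study == "xray") langevin_config(step_size = 5e-5, n_subiters = 1000L)
    else langevin_config(step_size = 5e-5, n_subiters = 100L)
  } else {
    if (study %in% c("inpaint_low", "inpaint_high")) map_config("closed_form")
    else map_config("quasi_newton", max_iters = 40L)
  }
  bipsda_config(variant, sampler_cfg = scfg, n_chains = n_samples,
                seed = trial_seed)
}

aggregate_report <- function(per_trial) {
  mets <- c("mean_error", "variance_error", "cmd", "mmd")
  vars <- unique(per_trial$variant)
  out <- do.call(rbind, lapply(vars, function(v) {
    d <- per_trial[per_trial$variant == v, ]
    row <- data.frame(variant = v, stringsAsFactors = FALSE)
    for (m in mets) {
      x <- d[[m]]
      row[[m]] <- mean(x)
      qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
      row[[paste0(m, "_q10")]] <- qs[1]
      row[[paste0(m, "_q90")]] <- qs[2]
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.bipsda_report <- function(x, digits = 3, ...) {
  cat(sprintf("Benchmark study '%s': %d trial(s) x %d samples (%s score)\n",
              x$study, x$n_trials, x$n_samples, x$score_mode))
  cat(sprintf("CMD decay rate alpha = %.3f\n", x$alpha))
  tab <- x$table
  fmt <- function(m, lo, hi) sprintf("%.*f (%.*f, %.*f)", digits, m, digits, lo, digits, hi)
  disp <- data.frame(
    variant = tab$variant,
    mean_error = fmt(tab$mean_error, tab$mean_error_q10, tab$mean_error_q90),
    variance_error = fmt(tab$variance_error, tab$variance_error_q10, tab$variance_error_q90),
    cmd = fmt(tab$cmd, tab$cmd_q10, tab$cmd_q90),
    mmd = fmt(tab$mmd, tab$mmd_q10, tab$mmd_q90))
  print(disp, row.names = FALSE)
  if (any(x$divergences > 0)) {
    cat("diverged chains discarded:\n")
    print(x$divergences[x$divergences > 0])
  }
  invisible(x)
}

#' Serialize a study report
#'
#' Round-trips the aggregate table and per-trial metrics through CSV (table)
#' and JSON (full report).
#'
#' @param report a \code{bipsda_report}.
#' @param csv,json output paths (either may be \code{NULL}).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$table, csv, row.names = FALSE)
  if (!is.null(json)) {
    obj <- list(study = report$study, alpha = report$alpha,
                n_trials = report$n_trials, n_samples = report$n_samples,
                divergences = as.list(report$divergences),
                table = report$table, per_trial = report$per_trial)
    writeLines(as.character(jsonlite::toJSON(obj, digits = NA, dataframe = "columns")),
               json)
  }
  invisible(c(csv = csv, json = json))
}
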