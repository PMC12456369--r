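#' Score-model training configuration
#'
#' Constants for denoising score-matching training of a conservative score
#' model. The loss is the standard weighted denoising objective with
#' \eqn{w(t) = \sigma^2(t)}: per triplet \eqn{(m, z, t)} drawn i.i.d. at each
#' step (with \eqn{t} uniform on \eqn{[T_{min}, T]}), the contribution is
#' \eqn{\|\sigma(t) s_\theta(m + \sigma(t) z, t) + z\|^2}. Defaults mirror the
#' benchmark training protocol (80,000 training samples, width 512, learning
#' rate \eqn{10^{-5}}, batch 8,000, 50,000 iterations); tests and examples use
#' much smaller settings.
#'
#' @param n_train number of prior samples in the training set.
#' @param width hidden-layer width of the scalar potential network.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param iters number of optimization iterations.
#' @param seed integer seed.
#' @return a \code{score_train_config} list.
#' @export
score_train_config <- function(n_train = 80000L, width = 512L, lr = 1e-5,
                               batch = 8000L, iters = 50000L, seed = 1L) {
  stopifnot(n_train > 0, width > 0, lr > 0, batch > 0, iters > 0)
  structure(list(n_train = as.integer(n_train), width = as.integer(width),
                 lr = lr, batch = as.integer(batch), iters = as.integer(iters),
                 seed = as.integer(seed)),
            class = "score_train_config")
}

# Scalar potential g(x, sigma) = w2' tanh(W1 [x; sigma] + b1) + c'x, with the
# score s = grad_x g computed analytically. theta is a flat parameter list.
score_net_init <- function(D, width, seed) {
  set.seed(seed)
  list(W1 = matrix(stats::rnorm(width * (D + 1), sd = 1 / sqrt(D + 1)), width, D + 1),
       b1 = rep(0, width),
       w2 = stats::rnorm(width, sd = 0.1 / sqrt(width)),
       cc = rep(0, D),
       D = D, H = width)
}

# Batched score of the potential network: X n x D, sig length-n (or scalar).
score_net_eval <- function(th, X, sig) {
  n <- nrow(X)
  sig <- rep_len(sig, n)
  Xt <- cbind(X, sig)
  A <- Xt %*% t(th$W1) + matrix(th$b1, n, th$H, byrow = TRUE)
  Hh <- tanh(A)
  U <- (1 - Hh^2) * matrix(th$w2, n, th$H, byrow = TRUE)
  S <- U %*% th$W1[, seq_len(th$D), drop = FALSE] +
    matrix(th$cc, n, th$D, byrow = TRUE)
  list(S = S, Hh = Hh, U = U, Xt = Xt)
}

# Gradient of mean_n || sig * S + Z ||^2 w.r.t. theta (analytic backprop
# through the input-gradient of the potential).
score_net_grad <- function(th, X, Z, sig) {
  n <- nrow(X)
  sig <- rep_len(sig, n)
  ev <- score_net_eval(th, X, sig)
  R <- sig * ev$S + Z
  G <- (2 * sig * R) / n                     # dL/dS
  W1x <- th$W1[, seq_len(th$D), drop = FALSE]
  V <- G %*% t(W1x)                          # dL/dU
  WA <- V * (-2 * ev$Hh * (1 - ev$Hh^2)) *
    matrix(th$w2, n, th$H, byrow = TRUE)     # dL/dA
  gW1 <- t(WA) %*% ev$Xt
  gW1[, seq_len(th$D)] <- gW1[, seq_len(th$D)] + t(ev$U) %*% G
  list(loss = sum(R^2) / n,
       W1 = gW1,
       b1 = colSums(WA),
       w2 = colSums(V * (1 - ev$Hh^2)),
       cc = colSums(G))
}

#' Train a conservative score model
#'
#' Fits the scalar-potential network by stochastic gradient descent (Adam) on
#' the denoising score-matching loss; the returned score is the exact input
#' gradient of the learned potential, so it is conservative by construction.
#'
#' @param prior_samples an \code{n x D} matrix of draws from the prior.
#' @param schedule a \code{\link{noise_schedule}}.
#' @param cfg a \code{\link{score_train_config}}.
#' @param verbose print the loss every 500 iterations.
#' @return a \code{\link{score_function}} of kind \code{"learned"} carrying the
#'   trained parameters in its \code{theta} element.
#' @export
train_score_model <- function(prior_samples, schedule = noise_schedule(),
                              cfg = score_train_config(), verbose = FALSE) {
  X0 <- as.matrix(prior_samples)
  if (nrow(X0) < cfg$n_train)
    stop("need at least cfg$n_train = ", cfg$n_train, " prior samples")
  X0 <- X0[seq_len(cfg$n_train), , drop = FALSE]
  D <- ncol(X0)
  th <- score_net_init(D, cfg$width, cfg$seed)
  mom <- lapply(th[c("W1", "b1", "w2", "cc")], function(p) p * 0)
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  set.seed(cfg$seed + 1L)
  for (it in seq_len(cfg$iters)) {
    idx <- sample.int(nrow(X0), min(cfg$batch, nrow(X0)))
    t <- stats::runif(length(idx), schedule$Tmin, schedule$T)
    sig <- schedule$sigma(t)
    Z <- matrix(stats::rnorm(length(idx) * D), length(idx), D)
    X <- X0[idx, , drop = FALSE] + sig * Z
    g <- score_net_grad(th, X, Z, sig)
    if (!is.finite(g$loss)) stop("non-finite training loss at iteration ", it)
    for (nm in c("W1", "b1", "w2", "cc")) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
      vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1^it)
      vhat <- vel[[nm]] / (1 - b2^it)
      th[[nm]] <- th[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
    }
    if (verbose && it %% 500 == 0)
      message(sprintf("iter %6d  loss %.5f", it, g$loss))
  }
  sf <- score_function(
    fun = function(m, sigma) {
      vec_in <- is.null(dim(m))
      M <- if (vec_in) matrix(m, 1L) else as.matrix(m)
      S <- score_net_eval(th, M, sigma)$S
      if (vec_in) drop(S) else S
    },
    jacobian = NULL, kind = "learned", D = D)
  sf$theta <- th
  sf
}

#' Serialize a learned score model
#'
#' Writes the trained potential-network parameters to a single JSON checkpoint
#' and restores a \code{\link{score_function}} from it.
#'
#' @param score a learned \code{\link{score_function}}.
#' @param path checkpoint file path.
#' @return \code{path} invisibly; \code{read_score_model} returns the restored
#'   \code{\link{score_function}}.
#' @export
write_score_model <- function(score, path) {
  th <- score$theta
  if (is.null(th)) stop("not a learned score model")
  obj <- list(W1 = as.vector(t(th$W1)), b1 = th$b1, w2 = th$w2, cc = th$cc,
              D = th$D, H = th$H)
  writeLines(as.character(jsonlite::toJSON(obj, digits = NA)), path)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  th <- list(W1 = matrix(obj$W1, obj$H, obj$D + 1, byrow = TRUE),
             b1 = obj$b1, w2 = obj$w2, cc = obj$cc, D = obj$D, H = obj$H)
  sf <- score_function(
    fun = function(m, sigma) {
      vec_in <- is.null(dim(m))
      M <- if (vec_in) matrix(m, 1L) else as.matrix(m)
      S <- score_net_eval(th, M, sigma)$S
      if (vec_in) drop(S) else S
    },
    jacobian = NULL, kind = "learned", D = obj$D)
  sf$theta <- th
  sf
}
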