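# Amplitude ansaetze over occupation number vectors.
#
# Modal-product (MP) states: Psi(n) = prod_i phi0[i, n_i + 1].
# Modal backflow (MBF): the modal matrix acquires an ONV-dependent
# correction delta(n) produced by a two-layer tanh network fed with the
# raw occupations, phi(n) = phi0 + delta(n); exactly one coefficient per
# mode (selected by that mode's occupation) enters the product.
# FNN baseline: the same two-layer tanh network with a scalar head that
# outputs the amplitude directly.
#
# Parameter vectors are packed [vec(W0); b0; vec(W1); b1; (vec(phi0))],
# column-major, phi0 appended only when it is trainable (VSCF mode).

new_net_params <- function(mode, phi0, alpha, sigma, seed) {
  L <- nrow(phi0)
  nmodal <- ncol(phi0)
  nhid <- max(1L, round(alpha * L))
  nout <- if (mode == "mbf") L * nmodal else 1L
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  draw <- function(n) if (sigma > 0) rnorm(n, 0, sigma) else numeric(n)
  structure(list(
    W0 = matrix(draw(nhid * L), nhid, L),
    b0 = draw(nhid),
    W1 = matrix(draw(nout * nhid), nout, nhid),
    b1 = draw(nout),
    phi0 = phi0,
    alpha = alpha, L = L, nmodal = nmodal, nhid = nhid,
    train_weights = TRUE, train_phi0 = FALSE
  ), class = c(paste0(mode, "_params"), "net_params"))
}

#' Initialize network parameters
#'
#' Weights and biases are drawn i.i.d. from \eqn{N(0, \sigma^2)};
#' \code{sigma = 0} reproduces the bare modal-product state exactly (for
#' the MBF head, \code{tanh(0) = 0} leaves \code{phi(n) = phi0}).
#'
#' @param mode \code{"mbf"} (modal-backflow head) or \code{"fnn"} (scalar
#'   head).
#' @param phi0 \code{L x Nmodal} fixed modal matrix. No row may vanish
#'   identically. For the FNN the matrix only fixes the input dimensions.
#' @param alpha hidden neuron density; \code{Nhidden = round(alpha * L)},
#'   at least 1.
#' @param sigma initialization scale. The default 0.01 keeps the initial
#'   MBF state close to the modal-product state defined by \code{phi0}.
#' @param seed optional integer for reproducible draws.
#' @return object of class \code{mbf_params} or \code{fnn_params}.
#' @export
init_params <- function(mode = c("mbf", "fnn"), phi0, alpha = 1,
                        sigma = 0.01, seed = NULL) {
  mode <- match.arg(mode)
  phi0 <- as.matrix(phi0)
  if (any(!is.finite(phi0))) stop("phi0 must be finite")
  if (mode == "mbf" && any(rowSums(abs(phi0)) == 0)) {
    stop("phi0 has an all-zero row: every mode needs a nonvanishing modal")
  }
  if (sigma < 0) stop("sigma must be >= 0")
  new_net_params(mode, phi0, alpha, sigma, seed)
}

#' @export
print.net_params <- function(x, ...) {
  cat("<", class(x)[1], "> L = ", x$L, ", Nmodal = ", x$nmodal,
      ", alpha = ", x$alpha, " (", x$nhid, " hidden), ",
      n_params(x), " trainable parameters\n", sep = "")
  invisible(x)
}

as_onv_matrix <- function(n, L) {
  if (!is.matrix(n)) n <- matrix(n, nrow = L)
  storage.mode(n) <- "integer"
  n
}

#' Number of trainable parameters
#' @param p a parameter object.
#' @return integer count, honouring the trainable-block flags.
#' @export
n_params <- function(p) {
  nw <- length(p$W0) + length(p$b0) + length(p$W1) + length(p$b1)
  (if (p$train_weights) nw else 0L) +
    (if (p$train_phi0) length(p$phi0) else 0L)
}

#' Pack trainable parameters into a flat vector
#' @param p a parameter object.
#' @return numeric vector (see layout note in the source).
#' @export
params_vector <- function(p) {
  out <- numeric(0)
  if (p$train_weights) out <- c(as.numeric(p$W0), p$b0, as.numeric(p$W1), p$b1)
  if (p$train_phi0) out <- c(out, as.numeric(p$phi0))
  out
}

#' Write a flat vector back into the trainable parameter blocks
#' @param p a parameter object.
#' @param theta numeric vector as produced by \code{\link{params_vector}}.
#' @return updated parameter object.
#' @export
set_params_vector <- function(p, theta) {
  stopifnot(length(theta) == n_params(p))
  off <- 0L
  take <- function(k) {
    v <- theta[off + seq_len(k)]
    off <<- off + k
    v
  }
  if (p$train_weights) {
    p$W0 <- matrix(take(length(p$W0)), nrow(p$W0), ncol(p$W0))
    p$b0 <- take(length(p$b0))
    p$W1 <- matrix(take(length(p$W1)), nrow(p$W1), ncol(p$W1))
    p$b1 <- take(length(p$b1))
  }
  if (p$train_phi0) {
    p$phi0 <- matrix(take(length(p$phi0)), nrow(p$phi0), ncol(p$phi0))
  }
  p
}

#' MBF forward pass
#'
#' Computes the hidden activations \code{h = tanh(W0 n + b0)}, the output
#' \code{o = tanh(W1 h + b1)}, and the ONV-dependent modal matrix
#' \code{phi(n) = phi0 + delta(n)} where \code{delta} is \code{o}
#' reshaped to \code{L x Nmodal}.
#'
#' @param p an \code{mbf_params} object.
#' @param n a single occupation number vector.
#' @return \code{list(h, o, delta, phi)}.
#' @export
mbf_forward <- function(p, n) {
  n <- as.numeric(n)
  if (length(n) != p$L) stop("configuration length does not match L")
  h <- tanh(as.numeric(p$W0 %*% n) + p$b0)
  o <- tanh(as.numeric(p$W1 %*% h) + p$b1)
  delta <- matrix(o, p$L, p$nmodal, byrow = TRUE)
  list(h = h, o = o, delta = delta, phi = p$phi0 + delta)
}

#' MBF amplitude
#'
#' \eqn{\Psi(n) = \prod_i \phi_{i, n_i + 1}(n)} with the ONV-dependent
#' modal matrix of \code{\link{mbf_forward}}. Vectorized over columns of
#' a matrix argument.
#'
#' @param p an \code{mbf_params} object.
#' @param n occupation vector or \code{L x m} matrix.
#' @return numeric amplitudes.
#' @export
mbf_amplitude <- function(p, n) {
  as.numeric(cpp_amp_mbf(p$W0, p$b0, p$W1, p$b1, p$phi0,
                         as_onv_matrix(n, p$L)))
}

#' FNN baseline amplitude
#'
#' Scalar-head network: \eqn{\Psi(n) = \tanh(W_1 \tanh(W_0 n + b_0) +
#' b_1)}.
#'
#' @param p an \code{fnn_params} object.
#' @param n occupation vector or \code{L x m} matrix.
#' @return numeric amplitudes.
#' @export
fnn_amplitude <- function(p, n) {
  as.numeric(cpp_amp_fnn(p$W0, p$b0, p$W1, p$b1, as_onv_matrix(n, p$L)))
}

#' Amplitude closure for a parameter object
#'
#' @param p a parameter object (or already a function, returned as-is so
#'   table ansaetze plug in transparently).
#' @return \code{function(N)} mapping an \code{L x m} ONV matrix to
#'   amplitudes.
#' @export
amplitude_fn <- function(p) {
  if (is.function(p)) return(p)
  if (is(p, "mbf_params")) function(N) mbf_amplitude(p, N)
  else if (is(p, "fnn_params")) function(N) fnn_amplitude(p, N)
  else stop("no amplitude rule for class ", class(p)[1])
}

#' Logarithmic parameter derivatives
#'
#' \eqn{D_m(n) = \partial \log \Psi(n) / \partial \theta_m} for every
#' trainable parameter, via the chain rule through the modal product and
#' the two tanh layers. Rows belonging to configurations with amplitudes
#' at or below the caller's floor must be discarded by the caller.
#'
#' @param p a parameter object.
#' @param n occupation vector or \code{L x m} matrix.
#' @return \code{list(amp = <amplitudes>, D = <m x n_params(p) matrix>)}.
#' @export
log_derivatives <- function(p, n) {
  N <- as_onv_matrix(n, p$L)
  out <- if (is(p, "mbf_params")) {
    cpp_grad_mbf(p$W0, p$b0, p$W1, p$b1, p$phi0, N,
                 p$train_weights, p$train_phi0)
  } else if (is(p, "fnn_params")) {
    if (p$train_phi0) stop("the FNN head has no modal matrix to train")
    cpp_grad_fnn(p$W0, p$b0, p$W1, p$b1, N)
  } else {
    stop("no derivative rule for class ", class(p)[1])
  }
  out$amp <- as.numeric(out$amp)
  out
}

#' One-hot modal matrix for a reference configuration
#'
#' @param onv integer occupation vector.
#' @param nmodal number of basis states per mode.
#' @return \code{L x Nmodal} matrix with a single 1 per row at each
#'   mode's occupation.
#' @export
one_hot_modal <- function(onv, nmodal) {
  L <- length(onv)
  m <- matrix(0, L, nmodal)
  m[cbind(seq_len(L), onv + 1L)] <- 1
  m
}
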