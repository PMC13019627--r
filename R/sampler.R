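# Random anharmonic force fields emulating weak, moderate, and strong
# anharmonicity. Frequencies are uniform on [1500, 3000] cm^-1; raw cubic
# and quartic PES derivatives are drawn in Hartree atomic units with
# magnitudes N(lambda_nu, lambda_nu / 5), where
# lambda_nu = base(a.u.) * wbar^(nu/2) and wbar is the 2250 cm^-1
# midpoint frequency in a.u. Fully-, semi-, and off-diagonal tuples are
# damped by factors 1, 0.1, 0.01. Quartic constants are kept positive
# (a bound PES); cubic magnitudes receive an independent random sign per
# unique tuple. The stored force field holds the reduced constants in
# cm^-1.

.regime_bases <- c(weak = 50, moderate = 150, strong = 500)
.decay_factors <- c(full = 1, semi = 0.1, off = 0.01)

#' Anharmonicity regime scale constant
#'
#' @param regime \code{"weak"}, \code{"moderate"}, \code{"strong"}, or a
#'   positive numeric base in cm^-1.
#' @return base scale constant, cm^-1.
#' @export
regime_base <- function(regime) {
  if (is.numeric(regime)) {
    if (regime <= 0) stop("regime base must be positive")
    return(regime)
  }
  if (!regime %in% names(.regime_bases)) {
    stop("unknown anharmonicity regime '", regime,
         "' (use weak/moderate/strong or a numeric base)")
  }
  .regime_bases[[regime]]
}

# all sorted index tuples of length nu over 1..L, lexicographic order
sorted_tuples <- function(L, nu) {
  grid <- do.call(expand.grid, rep(list(seq_len(L)), nu))
  grid <- as.matrix(grid[, rev(seq_len(nu)), drop = FALSE])
  keep <- apply(grid, 1L, function(r) all(diff(r) >= 0))
  m <- grid[keep, , drop = FALSE]
  dimnames(m) <- NULL
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

#' Sample a random anharmonic force field
#'
#' @param L number of modes (>= 2 for the benchmark setting; 4 in the
#'   reference experiments).
#' @param regime3,regime4 anharmonicity regime of the cubic and quartic
#'   derivatives (see \code{\link{regime_base}}).
#' @param seed integer; the force field is a pure function of
#'   \code{(L, regime3, regime4, seed)}.
#' @param freq_range frequency sampling interval, cm^-1.
#' @param wbar_cm1 midpoint frequency entering the magnitude scale.
#' @return a \code{\link{force_field}} with reduced cubic and quartic
#'   constants in cm^-1 and no Coriolis data.
#' @examples
#' ff <- sample_force_field(4, "moderate", "moderate", seed = 1)
#' @export
sample_force_field <- function(L, regime3 = "moderate", regime4 = regime3,
                               seed, freq_range = c(1500, 3000),
                               wbar_cm1 = 2250) {
  if (L < 2L) stop("need at least two modes")
  base3 <- regime_base(regime3)
  base4 <- regime_base(regime4)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  w_cm <- runif(L, freq_range[1], freq_range[2])
  w_au <- w_cm * CM1_TO_HARTREE
  wbar_au <- wbar_cm1 * CM1_TO_HARTREE

  phi <- list()
  for (nu in c(3L, 4L)) {
    base_au <- (if (nu == 3L) base3 else base4) * CM1_TO_HARTREE
    lambda <- base_au * wbar_au^(nu / 2)
    idx <- sorted_tuples(L, nu)
    val_au <- numeric(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      mag <- max(0, rnorm(1L, lambda, lambda / 5))
      sgn <- if (nu == 3L) sample(c(-1, 1), 1L) else 1
      val_au[r] <- sgn * mag * .decay_factors[[tuple_class(idx[r, ])]]
    }
    phi[[as.character(nu)]] <- list(
      idx = idx,
      val = reduce_constants(idx, val_au, w_au) / CM1_TO_HARTREE
    )
  }
  force_field(w_cm, phi)
}

#' Anharmonic correction of the zero-point energy
#'
#' Difference between the exact ground-state energy of the full Watson
#' Hamiltonian and the harmonic zero-point energy \eqn{\sum_i w_i / 2},
#' computed by sparse exact diagonalization.
#'
#' @param ff a \code{\link{force_field}}.
#' @param nmax occupation cutoff used for the diagonalization.
#' @param ... passed to \code{\link{exact_spectrum}}.
#' @return anharmonic correction, cm^-1 (0 for a harmonic force field).
#' @export
anharmonic_correction <- function(ff, nmax, ...) {
  H <- watson_operator(ff, nmax, include_coriolis = FALSE)
  spec <- exact_spectrum(H, k = 1L, ...)
  spec$values[1] - sum(ff$w) / 2
}
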