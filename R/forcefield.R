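# Force fields: harmonic frequencies plus reduced anharmonic force
# constants of orders 3..6 and optional Coriolis coupling.

#' Construct a force field
#'
#' A force field bundles the per-mode harmonic frequencies \code{w}
#' (cm^-1), the reduced force-constant tensors \eqn{\Phi^{(\nu)}} for
#' orders \eqn{\nu \in \{3,\dots,6\}} (cm^-1, stored on unique sorted
#' index tuples; the tensors are totally symmetric), and optionally
#' Coriolis coupling data.
#'
#' @param w strictly positive harmonic frequencies, cm^-1.
#' @param phi named list of force-constant blocks keyed by order
#'   (\code{"3"} .. \code{"6"}). Each block is either a list
#'   \code{list(idx = <m x nu integer matrix>, val = <numeric m>)} or a
#'   plain matrix with \code{nu + 1} columns (indices then value). Index
#'   tuples are sorted on input; duplicate canonical tuples are an error.
#' @param coriolis \code{NULL}, or \code{list(B = <3 rotational constants,
#'   cm^-1>, xi = <list of three L x L antisymmetric matrices>)} for
#'   \eqn{\tau = x, y, z}.
#' @return object of class \code{vib_forcefield}.
#' @export
force_field <- function(w, phi = list(), coriolis = NULL) {
  w <- as.numeric(w)
  if (length(w) < 1L || any(!is.finite(w)) || any(w <= 0)) {
    stop("frequencies must be finite and strictly positive")
  }
  L <- length(w)
  blocks <- list()
  for (nm in names(phi)) {
    nu <- suppressWarnings(as.integer(nm))
    if (is.na(nu) || nu < 3L || nu > 6L) {
      stop("unsupported force-constant order '", nm, "' (allowed: 3..6)")
    }
    b <- phi[[nm]]
    if (is.matrix(b)) {
      b <- list(idx = b[, seq_len(nu), drop = FALSE], val = b[, nu + 1L])
    }
    idx <- matrix(as.integer(b$idx), ncol = nu)
    val <- as.numeric(b$val)
    if (nrow(idx) != length(val)) stop("index/value length mismatch for order ", nu)
    if (any(idx < 1L) || any(idx > L)) {
      stop("force-constant index out of range 1..", L, " for order ", nu)
    }
    idx <- t(apply(idx, 1L, sort))
    if (nu == 1L) idx <- t(idx)  # degenerate apply() shape, unreachable for nu>=3
    key <- apply(idx, 1L, paste, collapse = ",")
    if (anyDuplicated(key)) {
      stop("duplicate canonical index tuples for order ", nu,
           ": supply each sorted tuple once")
    }
    keep <- val != 0
    o <- order(key[keep])
    blocks[[as.character(nu)]] <- list(
      idx = idx[keep, , drop = FALSE][o, , drop = FALSE],
      val = val[keep][o]
    )
  }
  if (!is.null(coriolis)) {
    if (length(coriolis$B) != 3L) stop("coriolis$B must hold 3 rotational constants")
    if (length(coriolis$xi) != 3L) stop("coriolis$xi must hold 3 L x L matrices")
    for (t in 1:3) {
      xi <- as.matrix(coriolis$xi[[t]])
      if (!all(dim(xi) == c(L, L))) stop("xi matrices must be L x L")
      if (max(abs(xi + t(xi))) > 1e-10 * max(1, max(abs(xi)))) {
        stop("Coriolis xi matrix ", t, " is not antisymmetric")
      }
      coriolis$xi[[t]] <- xi
    }
    coriolis$B <- as.numeric(coriolis$B)
  }
  structure(list(L = L, w = w, phi = blocks, coriolis = coriolis),
            class = "vib_forcefield")
}

#' @export
print.vib_forcefield <- function(x, ...) {
  cat("<vib_forcefield> ", x$L, " modes, w in [",
      round(min(x$w), 1), ", ", round(max(x$w), 1), "] cm^-1\n", sep = "")
  for (nm in names(x$phi)) {
    cat("  order ", nm, ": ", nrow(x$phi[[nm]]$idx), " unique tuples, max |Phi| = ",
        signif(max(abs(x$phi[[nm]]$val)), 4), " cm^-1\n", sep = "")
  }
  if (!is.null(x$coriolis)) cat("  Coriolis coupling present\n")
  invisible(x)
}

#' Reduce (or un-reduce) raw potential derivatives by frequency factors
#'
#' The reduced force constant for an index tuple \eqn{(i_1,\dots,i_\nu)}
#' is \eqn{\Phi = \kappa / \sqrt{w_{i_1} \cdots w_{i_\nu}}}. Frequencies
#' and derivatives must be in consistent units (the sampler works in
#' Hartree atomic units and converts afterwards).
#'
#' @param idx \code{m x nu} integer matrix of index tuples.
#' @param val numeric vector of raw derivatives \eqn{\kappa} (or reduced
#'   constants when \code{inverse = TRUE}).
#' @param w harmonic frequencies.
#' @param inverse if \code{TRUE}, multiply instead of divide (recovers
#'   \eqn{\kappa} from \eqn{\Phi}).
#' @return numeric vector of the same length as \code{val}.
#' @export
reduce_constants <- function(idx, val, w, inverse = FALSE) {
  if (any(w <= 0)) stop("frequencies must be strictly positive")
  idx <- matrix(as.integer(idx), ncol = ncol(as.matrix(idx)))
  root <- sqrt(apply(idx, 1L, function(r) prod(w[r])))
  if (inverse) val * root else val / root
}

# multiplicity of a sorted index tuple under full permutation of indices
tuple_multiplicity <- function(tuple) {
  counts <- table(tuple)
  factorial(length(tuple)) / prod(factorial(counts))
}

# classification used by the sampler's off-diagonal decay factors
tuple_class <- function(tuple) {
  u <- length(unique(tuple))
  if (u == 1L) "full" else if (u == length(tuple)) "off" else "semi"
}
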