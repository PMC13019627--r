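# Second-quantized Watson Hamiltonian on a truncated Fock space.
#
# Every term of the Hamiltonian factorizes over modes, so the operator is
# stored as a flat term table: each term carries a scalar coefficient
# (cm^-1), the modes it acts on, and one small (Nmodal x Nmodal) matrix
# per involved mode. Position and momentum enter through the truncated
# ladder combinations X = b^dag + b and P = b^dag - b; products such as
# (b^dag + b)^k are taken as powers of the truncated X (sequential
# application of each ladder factor inside the truncated space). The
# assembled operator A is symmetrized, H = (A + t(A))/2: the untruncated
# operator is Hermitian, and symmetrization restores the property that
# sequential truncation of mixed X/P strings on the same mode can break
# at the occupation boundary.

#' Build the truncated second-quantized Watson operator
#'
#' Assembles the harmonic term \eqn{\sum_i w_i (b_i^\dagger b_i + 1/2)},
#' the potential terms
#' \eqn{\frac{1}{\nu!\,2^{\nu/2}} \sum \Phi^{(\nu)} \prod (b^\dagger + b)}
#' for each stored order \eqn{\nu \in \{3,\dots,6\}} (the order-3 and
#' order-4 prefactors are the familiar \eqn{1/(12\sqrt2)} and
#' \eqn{1/96}), and, when requested, the Coriolis term
#' \eqn{\frac14 B^\tau \xi^\tau_{ij} \xi^\tau_{kl}
#' \sqrt{w_j w_l / (w_i w_k)}
#' (b_i^\dagger{+}b_i)(b_j^\dagger{-}b_j)(b_k^\dagger{+}b_k)
#' (b_l^\dagger{-}b_l)}.
#'
#' @param ff a \code{\link{force_field}}.
#' @param nmax occupation cutoff per mode (\code{Nmodal = nmax + 1} basis
#'   states per mode).
#' @param include_coriolis include the Coriolis term when the force field
#'   carries one (default). Benchmark Hamiltonians typically switch it off.
#' @return object of class \code{watson_operator}.
#' @export
watson_operator <- function(ff, nmax, include_coriolis = TRUE) {
  stopifnot(is(ff, "vib_forcefield"))
  if (nmax < 1L) stop("nmax must be >= 1")
  L <- ff$L
  nmodal <- nmax + 1L
  occ <- 0:nmax

  X <- matrix(0, nmodal, nmodal)
  P <- matrix(0, nmodal, nmodal)
  for (k in 0:(nmax - 1L)) {
    X[k + 2L, k + 1L] <- sqrt(k + 1)   # b^dag
    X[k + 1L, k + 2L] <- sqrt(k + 1)   # b
    P[k + 2L, k + 1L] <- sqrt(k + 1)
    P[k + 1L, k + 2L] <- -sqrt(k + 1)
  }
  xpow <- vector("list", 7L)
  xpow[[1L]] <- diag(nmodal)
  for (k in 1:6) xpow[[k + 1L]] <- xpow[[k]] %*% X
  nop <- diag(occ)

  terms <- list()
  add_term <- function(coeff, modes, mats) {
    terms[[length(terms) + 1L]] <<- list(coeff = coeff, modes = modes, mats = mats)
  }

  # harmonic: per-mode number operator plus one global ZPE shift
  for (i in seq_len(L)) add_term(ff$w[i], i, list(nop))
  add_term(sum(ff$w) / 2, integer(0), list())

  # potential terms: multiplicity-weighted unique sorted tuples
  for (nm in names(ff$phi)) {
    nu <- as.integer(nm)
    pref <- 1 / (factorial(nu) * 2^(nu / 2))
    blk <- ff$phi[[nm]]
    for (r in seq_len(nrow(blk$idx))) {
      tuple <- blk$idx[r, ]
      counts <- table(tuple)
      modes <- as.integer(names(counts))
      mats <- lapply(as.integer(counts), function(c) xpow[[c + 1L]])
      add_term(pref * tuple_multiplicity(tuple) * blk$val[r], modes, mats)
    }
  }

  symmetric <- TRUE
  if (include_coriolis && !is.null(ff$coriolis)) {
    symmetric <- FALSE
    B <- ff$coriolis$B
    for (t in 1:3) {
      if (B[t] == 0) next
      xi <- ff$coriolis$xi[[t]]
      for (i in seq_len(L)) for (j in seq_len(L)) {
        if (xi[i, j] == 0) next
        for (k in seq_len(L)) for (l in seq_len(L)) {
          if (xi[k, l] == 0) next
          coeff <- 0.25 * B[t] * xi[i, j] * xi[k, l] *
            sqrt(ff$w[j] * ff$w[l] / (ff$w[i] * ff$w[k]))
          # written order (i, j, k, l); same-mode factors compose as a
          # left-to-right matrix product (rightmost factor acts first)
          seq_modes <- c(i, j, k, l)
          seq_mats <- list(X, P, X, P)
          modes <- unique(seq_modes)
          mats <- lapply(modes, function(m) {
            Reduce(`%*%`, seq_mats[seq_modes == m])
          })
          add_term(coeff, modes, mats)
        }
      }
    }
  }

  op <- list(ff = ff, nmax = nmax, nmodal = nmodal, L = L,
             terms = terms, xpow = xpow, pmat = P, symmetric = symmetric)
  if (!symmetric) {
    op$terms_t <- lapply(terms, function(tm) {
      tm$mats <- lapply(tm$mats, t)
      tm
    })
  }
  structure(op, class = "watson_operator")
}

#' @export
print.watson_operator <- function(x, ...) {
  cat("<watson_operator> L = ", x$L, ", Nmax = ", x$nmax,
      ", ", length(x$terms), " terms, dim = ",
      format(x$nmodal^x$L, big.mark = ","), "\n", sep = "")
  invisible(x)
}

# column of the (unsymmetrized) term-table assembly at configuration n:
# all n' with <n'|A|n> != 0 together with the elements, merged by code
assembly_column <- function(terms, n, nmodal) {
  base <- onv_encode(n, nmodal)
  all_codes <- numeric(0)
  all_vals <- numeric(0)
  for (tm in terms) {
    codes <- base
    vals <- tm$coeff
    ok <- TRUE
    for (j in seq_along(tm$modes)) {
      m <- tm$modes[j]
      col <- tm$mats[[j]][, n[m] + 1L]
      nz <- which(col != 0)
      if (length(nz) == 0L) { ok <- FALSE; break }
      shift <- (nz - 1 - n[m]) * nmodal^(m - 1)
      k <- length(codes)
      codes <- rep(codes, times = length(nz)) + rep(shift, each = k)
      vals <- rep(vals, times = length(nz)) * rep(col[nz], each = k)
    }
    if (!ok) next
    all_codes <- c(all_codes, codes)
    all_vals <- c(all_vals, vals)
  }
  agg <- rowsum(all_vals, group = all_codes)
  list(codes = as.numeric(rownames(agg)), vals = as.numeric(agg))
}

merge_columns <- function(a, b) {
  codes <- c(a$codes, b$codes)
  vals <- c(a$vals, b$vals) / 2
  agg <- rowsum(vals, group = codes)
  list(codes = as.numeric(rownames(agg)), vals = as.numeric(agg))
}

#' Enumerate the configurations connected to an ONV by the Hamiltonian
#'
#' Returns the complete, duplicate-merged set of configurations
#' \eqn{n'} with \eqn{\langle n'|H|n\rangle \neq 0} (the diagonal is
#' always included), using the symmetrized operator.
#'
#' @param H a \code{\link{watson_operator}}.
#' @param n integer occupation number vector inside the truncation.
#' @return \code{list(n = <L x m ONV matrix>, codes = <basis codes>,
#'   vals = <matrix elements, cm^-1>)}.
#' @export
connections <- function(H, n) {
  n <- as.integer(n)
  if (length(n) != H$L || any(n < 0L) || any(n > H$nmax)) {
    stop("configuration outside the truncated space")
  }
  col <- assembly_column(H$terms, n, H$nmodal)
  if (!H$symmetric) {
    col <- merge_columns(col, assembly_column(H$terms_t, n, H$nmodal))
  }
  self <- onv_encode(n, H$nmodal)
  keep <- col$vals != 0 | col$codes == self
  codes <- col$codes[keep]
  vals <- col$vals[keep]
  if (!any(codes == self)) {
    codes <- c(codes, self)
    vals <- c(vals, 0)
  }
  list(n = onv_decode(codes, H$L, H$nmodal), codes = codes, vals = vals)
}

#' Assemble the full sparse Hamiltonian matrix
#'
#' Enumerates the whole \eqn{(N_{modal})^L} basis (little-endian, mode 1
#' fastest) and builds the symmetric sparse matrix via Kronecker products
#' of the per-mode term factors. Intended for the exact-diagonalization
#' reference and for validation on small spaces.
#'
#' @param H a \code{\link{watson_operator}}.
#' @param guard refuse spaces larger than this many basis states.
#' @return symmetric \code{dgCMatrix}, cm^-1.
#' @export
to_matrix <- function(H, guard = 2e6) {
  dim <- H$nmodal^H$L
  if (dim > guard) {
    stop("basis of ", format(dim, big.mark = ","),
         " states exceeds the enumeration guard (", guard, ")")
  }
  dim <- as.integer(dim)
  eye <- Matrix::Diagonal(H$nmodal)
  A <- Matrix::Matrix(0, dim, dim, sparse = TRUE)
  for (tm in H$terms) {
    if (length(tm$modes) == 0L) {
      A <- A + Matrix::Diagonal(dim, tm$coeff)
      next
    }
    facs <- rep(list(eye), H$L)
    for (j in seq_along(tm$modes)) {
      facs[[tm$modes[j]]] <- methods::as(Matrix::Matrix(tm$mats[[j]], sparse = TRUE),
                                         "generalMatrix")
    }
    # mode 1 innermost in the Kronecker chain
    K <- Reduce(function(a, b) Matrix::kronecker(b, a), facs)
    A <- A + tm$coeff * K
  }
  A <- (A + Matrix::t(A)) / 2
  # general (dgC) storage: column slot access must see both triangles
  methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
}

#' Harmonic-oscillator energy of configurations
#'
#' \eqn{\sum_i w_i (n_i + 1/2)} for one ONV or a matrix of ONVs.
#'
#' @param ff a \code{\link{force_field}}.
#' @param n occupation vector or \code{L x m} matrix.
#' @return numeric energies, cm^-1.
#' @export
harmonic_energy <- function(ff, n) {
  if (is.matrix(n)) as.numeric(crossprod(n + 0.5, ff$w))
  else sum(ff$w * (n + 0.5))
}
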