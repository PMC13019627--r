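# Occupation number vectors (ONVs) and their integer encoding.
#
# The basis of the truncated L-mode Fock space is enumerated little-endian
# (mode 1 fastest): code(n) = sum_i n_i * Nmodal^(i-1), 0-based. Codes are
# stored as doubles so that spaces too large to enumerate (up to 2^53
# states) still hash and order exactly.

#' Encode occupation number vectors as basis indices
#'
#' @param n integer vector of length \code{L}, or an \code{L x m} matrix
#'   with one occupation number vector per column.
#' @param nmodal number of basis states per mode (\code{Nmax + 1}).
#' @return numeric vector of 0-based basis codes (mode 1 varies fastest).
#' @export
onv_encode <- function(n, nmodal) {
  if (is.matrix(n)) {
    as.numeric(crossprod(n, nmodal^(seq_len(nrow(n)) - 1)))
  } else {
    sum(n * nmodal^(seq_along(n) - 1))
  }
}

#' Decode basis indices back to occupation number vectors
#'
#' @param code numeric vector of 0-based basis codes.
#' @param L number of modes.
#' @param nmodal number of basis states per mode.
#' @return integer \code{L x length(code)} matrix, one ONV per column.
#' @export
onv_decode <- function(code, L, nmodal) {
  out <- matrix(0L, L, length(code))
  for (i in seq_len(L)) {
    out[i, ] <- as.integer(code %% nmodal)
    code <- code %/% nmodal
  }
  out
}

# big-endian key (mode 1 most significant): ties in amplitude-based
# selection are broken in true lexicographic ONV order
onv_lex_key <- function(N, nmodal) {
  L <- nrow(N)
  as.numeric(crossprod(N, nmodal^(L - seq_len(L))))
}

#' Apply a single ladder operator to an occupation number vector
#'
#' Bosonic creation/annihilation with the truncation convention that any
#' step leaving the \code{[0, Nmax]} window annihilates the state.
#'
#' @param n integer occupation number vector.
#' @param mode mode index (1-based).
#' @param kind \code{"create"} or \code{"annihilate"}.
#' @param nmax occupation cutoff per mode.
#' @return \code{list(n = <new ONV>, amp = <matrix element>)}, or
#'   \code{NULL} when the result leaves the truncated space (annihilating
#'   the vacuum, or creating on top of \code{Nmax}).
#' @examples
#' ladder_apply(c(2L, 0L), 1, "create", nmax = 4)   # amp sqrt(3)
#' ladder_apply(c(0L, 0L), 1, "annihilate", nmax = 4) # NULL
#' @export
ladder_apply <- function(n, mode, kind = c("create", "annihilate"), nmax) {
  kind <- match.arg(kind)
  if (mode < 1 || mode > length(n)) {
    stop("mode index ", mode, " out of range 1..", length(n))
  }
  k <- n[mode]
  if (kind == "create") {
    if (k >= nmax) return(NULL)
    n[mode] <- k + 1L
    list(n = n, amp = sqrt(k + 1))
  } else {
    if (k <= 0L) return(NULL)
    n[mode] <- k - 1L
    list(n = n, amp = sqrt(k))
  }
}
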