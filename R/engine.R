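# Selected-configuration evaluation of expectations, local energies, and
# parameter gradients.
#
# A "connector" abstracts column access to the symmetrized Hamiltonian:
# for enumerable spaces it is backed by the assembled sparse matrix
# (fast column slicing); otherwise columns are enumerated from the term
# table on demand and memoized, since they depend on H and the
# configuration only, never on the network parameters.

#' Create a connection provider for a Watson operator
#'
#' @param H a \code{\link{watson_operator}}.
#' @param backend \code{"auto"} (sparse matrix when the full space has at
#'   most \code{matrix_limit} states, term table otherwise),
#'   \code{"matrix"}, or \code{"termtable"}.
#' @param matrix_limit enumeration threshold for the auto choice.
#' @return function mapping a basis code to \code{list(codes, vals)}, the
#'   nonzero column of H (diagonal always present), with attributes
#'   \code{H} and \code{dim}.
#' @export
make_connector <- function(H, backend = c("auto", "matrix", "termtable"),
                           matrix_limit = 5e4) {
  backend <- match.arg(backend)
  dim <- H$nmodal^H$L
  if (backend == "auto") {
    backend <- if (dim <= matrix_limit) "matrix" else "termtable"
  }
  if (backend == "matrix") {
    M <- to_matrix(H)
    full_N <- onv_decode(seq_len(dim) - 1, H$L, H$nmodal)
    f <- function(code) {
      j <- as.integer(code) + 1L
      r <- M@p[j]:(M@p[j + 1L] - 1L) + 1L
      if (M@p[j] == M@p[j + 1L]) {
        list(codes = code, vals = 0)
      } else {
        codes <- as.numeric(M@i[r])
        vals <- M@x[r]
        if (!any(codes == code)) {
          codes <- c(codes, code)
          vals <- c(vals, 0)
        }
        list(codes = codes, vals = vals)
      }
    }
  } else {
    cache <- new.env(parent = emptyenv())
    f <- function(code) {
      key <- as.character(code)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      n <- as.integer(onv_decode(code, H$L, H$nmodal))
      con <- connections(H, n)
      val <- list(codes = con$codes, vals = con$vals)
      cache[[key]] <- val
      val
    }
  }
  attr(f, "H") <- H
  attr(f, "space_dim") <- dim
  if (backend == "matrix") {
    attr(f, "M") <- M
    attr(f, "full_N") <- full_N
  }
  f
}

as_connector <- function(H) {
  if (is.function(H)) H else make_connector(H)
}

#' Construct a selected configuration space
#'
#' @param n \code{L x m} matrix of member configurations (or a single
#'   vector).
#' @param nmodal basis states per mode.
#' @param Ns target size of the space.
#' @param K exploration factor: each update samples at most
#'   \code{K * Ns} connected candidates.
#' @return object of class \code{selected_space}.
#' @export
selected_space <- function(n, nmodal, Ns = 128L, K = 1L) {
  if (Ns < 1L || K < 1L) stop("Ns and K must be >= 1")
  N <- as_onv_matrix(n, if (is.matrix(n)) nrow(n) else length(n))
  codes <- onv_encode(N, nmodal)
  if (anyDuplicated(codes)) stop("selected space members must be unique")
  structure(list(N = N, codes = codes, nmodal = nmodal,
                 Ns = as.integer(Ns), K = as.integer(K)),
            class = "selected_space")
}

#' @export
print.selected_space <- function(x, ...) {
  cat("<selected_space> ", ncol(x$N), " configurations (Ns = ", x$Ns,
      ", K = ", x$K, ")\n", sep = "")
  invisible(x)
}

# flattened connection table for a set of codes:
#   group  - index of the source configuration
#   codes  - connected basis codes
#   vals   - matrix elements
flat_connections <- function(connector, codes) {
  cons <- lapply(codes, connector)
  len <- vapply(cons, function(c) length(c$codes), integer(1))
  list(group = rep(seq_along(codes), len),
       codes = unlist(lapply(cons, `[[`, "codes"), use.names = FALSE),
       vals = unlist(lapply(cons, `[[`, "vals"), use.names = FALSE),
       len = len)
}

#' Local energy of a configuration
#'
#' \eqn{E_{loc}(n) = \sum_{n'} \langle n|H|n'\rangle \Psi(n') / \Psi(n)}
#' with \eqn{n'} running over the complete connected set.
#'
#' @param H a \code{\link{watson_operator}} or a connector.
#' @param psi amplitude source: a parameter object or a function over
#'   ONV matrices.
#' @param n a single occupation number vector.
#' @return local energy, cm^-1.
#' @export
local_energy <- function(H, psi, n) {
  connector <- as_connector(H)
  Hop <- attr(connector, "H")
  psi <- amplitude_fn(psi)
  con <- connector(onv_encode(as.integer(n), Hop$nmodal))
  amps <- psi(onv_decode(con$codes, Hop$L, Hop$nmodal))
  a0 <- psi(as_onv_matrix(as.integer(n), Hop$L))
  if (a0 == 0) stop("local energy undefined: zero amplitude at n")
  sum(con$vals * amps) / a0
}

# shared evaluation core: local energies and probabilities over W
selected_eval <- function(connector, psi_fn, W, penalty = NULL,
                          floor_rel = 1e-12) {
  Hop <- attr(connector, "H")
  fc <- flat_connections(connector, W$codes)
  need <- unique(c(W$codes, fc$codes,
                   unlist(lapply(penalty$states, function(s) s$codes))))
  amps <- psi_fn(onv_decode(need, Hop$L, Hop$nmodal))
  look <- function(codes) amps[match(codes, need)]
  psiW <- look(W$codes)
  floor <- floor_rel * max(abs(psiW))
  live <- abs(psiW) > floor
  if (!any(live)) stop("all selected configurations fell below the amplitude floor")

  # rowsum orders rows by group value; groups are already 1..|W|
  eloc <- as.numeric(rowsum(fc$vals * look(fc$codes), group = fc$group)) / psiW
  if (!is.null(penalty)) {
    for (s in penalty$states) {
      ov <- sum(s$amp * look(s$codes))
      hit <- match(W$codes, s$codes)
      pen_amp <- ifelse(is.na(hit), 0, s$amp[hit])
      eloc <- eloc + penalty$z * pen_amp * ov / psiW
    }
    eloc <- eloc - penalty$zpe
  }
  p <- numeric(length(psiW))
  p[live] <- psiW[live]^2 / sum(psiW[live]^2)
  list(eloc = eloc, p = p, psiW = psiW, live = live,
       energy = sum(p[live] * eloc[live]))
}

#' Selected-space energy expectation
#'
#' The asymmetric estimator
#' \eqn{\langle H \rangle_W = \sum_{n \in W} P_{\Psi_W}(n) E_{loc}(n)}
#' with the probability normalized over the selected space only. With
#' \code{W} equal to the full space this is the exact Rayleigh quotient.
#'
#' @param H operator or connector.
#' @param psi amplitude source.
#' @param W a \code{\link{selected_space}}.
#' @param floor_rel relative amplitude floor: members with
#'   \code{|Psi| <= floor_rel * max|Psi over W|} are excluded.
#' @return energy, cm^-1.
#' @export
expectation_selected <- function(H, psi, W, floor_rel = 1e-12) {
  connector <- as_connector(H)
  selected_eval(connector, amplitude_fn(psi), W, floor_rel = floor_rel)$energy
}

#' Selected-space energy gradient
#'
#' \eqn{F_m = 2 \sum_{n \in W} P_{\Psi_W}(n) D_m(n) (E_{loc}(n) -
#' \langle H \rangle_W)} for real amplitudes, where \eqn{D_m} are the
#' logarithmic derivatives of \code{\link{log_derivatives}}.
#'
#' @param H operator or connector.
#' @param params a trainable parameter object.
#' @param W a \code{\link{selected_space}}.
#' @param floor_rel relative amplitude floor.
#' @return \code{list(F = <gradient>, energy = <expectation>)}.
#' @export
gradient_selected <- function(H, params, W, floor_rel = 1e-12) {
  selected_grad(as_connector(H), params, W, penalty = NULL,
                floor_rel = floor_rel)[c("F", "energy")]
}

# shared by gradient_selected and the optimization loops; penalty is
# list(z, zpe, states = list of state records) or NULL
selected_grad <- function(connector, params, W, penalty = NULL,
                          floor_rel = 1e-12) {
  ev <- selected_eval(connector, amplitude_fn(params), W, penalty = penalty,
                      floor_rel = floor_rel)
  gd <- log_derivatives(params, W$N)
  wgt <- ev$p * (ev$eloc - ev$energy)
  wgt[!ev$live] <- 0
  F <- 2 * as.numeric(crossprod(gd$D[ev$live, , drop = FALSE], wgt[ev$live]))
  list(F = F, energy = ev$energy, ev = ev)
}

#' Extend and reselect the configuration space
#'
#' Candidate pool: the current members plus at most \code{K * Ns}
#' configurations sampled uniformly without replacement from the
#' deduplicated union of all their Hamiltonian connections (minus the
#' members themselves). The \code{Ns} candidates of largest amplitude
#' magnitude survive; ties are broken in lexicographic ONV order.
#'
#' @param H operator or connector.
#' @param psi amplitude source.
#' @param W a \code{\link{selected_space}}.
#' @param Ns,K override the stored target size / exploration factor.
#' @param seed optional seed for the candidate draw (otherwise the
#'   current RNG stream is consumed).
#' @return a new \code{\link{selected_space}}.
#' @export
extend_and_select <- function(H, psi, W, Ns = W$Ns, K = W$K, seed = NULL) {
  connector <- as_connector(H)
  Hop <- attr(connector, "H")
  psi <- amplitude_fn(psi)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  pool <- select_pool(connector, W$codes, Ns, K)
  new_W_from_pool(Hop, psi, pool, Ns, K)
}

select_pool <- function(connector, codes, Ns, K, extra = NULL) {
  fc <- flat_connections(connector, codes)
  cand <- sort(setdiff(unique(fc$codes), codes))
  k <- min(length(cand), K * Ns)
  if (k > 0L && k < length(cand)) {
    cand <- cand[sample.int(length(cand), k)]
  }
  unique(c(codes, cand, extra))
}

new_W_from_pool <- function(Hop, psi_fn, pool, Ns, K = 1L) {
  N <- onv_decode(pool, Hop$L, Hop$nmodal)
  a <- psi_fn(N)
  o <- order(-abs(a), onv_lex_key(N, Hop$nmodal))
  keep <- o[seq_len(min(Ns, length(pool)))]
  selected_space(N[, keep, drop = FALSE], Hop$nmodal, Ns = Ns, K = K)
}
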