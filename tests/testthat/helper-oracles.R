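# Independent oracles used across the suite. The dense oracle expands
# every Hamiltonian term into explicit ladder-operator strings (2^nu per
# index sequence, summed over ALL index permutations of the symmetric
# tensors), applying each creation/annihilation factor sequentially in
# the truncated space via ladder_apply(). It shares no code with the
# term-table/Kronecker assembly it validates.

all_permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- list()
  for (i in seq_along(x)) {
    sub <- all_permutations(x[-i])
    out[[i]] <- cbind(x[i], sub)
  }
  m <- do.call(rbind, out)
  m[!duplicated(apply(m, 1L, paste, collapse = ",")), , drop = FALSE]
}

# apply a ladder string (factors right to left) to configuration n;
# kinds: +1 create, -1 annihilate; sgn_annih: per-factor sign picked up
# when the annihilator is chosen (X: +1, P: -1)
apply_string <- function(n, modes, kinds, nmax) {
  amp <- 1
  for (pos in rev(seq_along(modes))) {
    st <- ladder_apply(n, modes[pos],
                       if (kinds[pos] > 0) "create" else "annihilate", nmax)
    if (is.null(st)) return(NULL)
    n <- st$n
    amp <- amp * st$amp
  }
  list(n = n, amp = amp)
}

dense_oracle <- function(ff, nmax, include_coriolis = TRUE) {
  L <- ff$L
  nmodal <- nmax + 1L
  dim <- nmodal^L
  fullN <- onv_decode(0:(dim - 1), L, nmodal)
  A <- matrix(0, dim, dim)
  diag(A) <- harmonic_energy(ff, fullN)

  add_strings <- function(coeff, modes, annih_sign) {
    nu <- length(modes)
    for (string in 0:(2^nu - 1L)) {
      kinds <- ifelse(bitwAnd(string, bitwShiftL(1L, seq_len(nu) - 1L)) > 0,
                      1L, -1L)
      sgn <- prod(ifelse(kinds < 0, annih_sign, 1))
      for (col in seq_len(dim)) {
        st <- apply_string(fullN[, col], modes, kinds, nmax)
        if (!is.null(st)) {
          row <- onv_encode(st$n, nmodal) + 1L
          A[row, col] <<- A[row, col] + coeff * sgn * st$amp
        }
      }
    }
  }

  for (nm in names(ff$phi)) {
    nu <- as.integer(nm)
    pref <- 1 / (factorial(nu) * 2^(nu / 2))
    blk <- ff$phi[[nm]]
    for (r in seq_len(nrow(blk$idx))) {
      perms <- all_permutations(blk$idx[r, ])
      for (p in seq_len(nrow(perms))) {
        add_strings(pref * blk$val[r], perms[p, ], rep(1, nu))
      }
    }
  }
  if (include_coriolis && !is.null(ff$coriolis)) {
    for (t in 1:3) {
      B <- ff$coriolis$B[t]
      if (B == 0) next
      xi <- ff$coriolis$xi[[t]]
      for (i in 1:L) for (j in 1:L) for (k in 1:L) for (l in 1:L) {
        c0 <- xi[i, j] * xi[k, l]
        if (c0 == 0) next
        coeff <- 0.25 * B * c0 * sqrt(ff$w[j] * ff$w[l] / (ff$w[i] * ff$w[k]))
        # written order (X_i P_j X_k P_l); P picks up -1 on annihilation
        add_strings(coeff, c(i, j, k, l), c(1, -1, 1, -1))
      }
    }
  }
  (A + t(A)) / 2
}

rayleigh_quotient <- function(M, psi) {
  sum(psi * as.numeric(M %*% psi)) / sum(psi^2)
}

# small deterministic 2-mode anharmonic fixture
toy_ff_2mode <- function(seed = 21, regime = "moderate") {
  sample_force_field(2, regime, regime, seed = seed)
}

# tiny Coriolis-coupled fixture (antisymmetric xi, one rotational axis)
toy_ff_coriolis <- function() {
  xi <- matrix(c(0, 0.4, -0.4, 0), 2, 2, byrow = TRUE)
  zero <- matrix(0, 2, 2)
  force_field(c(1700, 2400),
              phi = list("3" = matrix(c(1, 1, 2, 25), 1),
                         "4" = matrix(c(1, 1, 2, 2, 18), 1)),
              coriolis = list(B = c(1.2, 0, 0), xi = list(xi, zero, zero)))
}
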