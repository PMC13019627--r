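# Watson operator construction, ladder algebra, connections, assembly.

test_that("ladder_apply implements truncated bosonic ladder algebra", {
  n <- c(2L, 0L, 5L)
  up <- ladder_apply(n, 1, "create", nmax = 5)
  expect_equal(up$amp, sqrt(3))
  expect_equal(up$n, c(3L, 0L, 5L))
  down <- ladder_apply(n, 1, "annihilate", nmax = 5)
  expect_equal(down$amp, sqrt(2))
  expect_equal(down$n, c(1L, 0L, 5L))
  # truncation convention: stepping out of [0, Nmax] annihilates
  expect_null(ladder_apply(n, 2, "annihilate", nmax = 5))
  expect_null(ladder_apply(n, 3, "create", nmax = 5))
  expect_error(ladder_apply(n, 4, "create", nmax = 5), "out of range")
})

test_that("harmonic-only operator is diagonal with sum w_i (n_i + 1/2)", {
  ff <- force_field(c(1500, 2100))
  H <- watson_operator(ff, 1)
  M <- as.matrix(to_matrix(H))
  expect_equal(M, diag(c(1800, 3300, 3900, 5400)), tolerance = 1e-12)
  for (n in list(c(0L, 0L), c(1L, 1L))) {
    con <- connections(H, n)
    expect_equal(length(con$vals), 1L)
    expect_equal(con$vals, harmonic_energy(ff, n))
  }
})

test_that("single-mode cubic and quartic matrix elements match closed forms", {
  phi3 <- 120
  ff3 <- force_field(2000, phi = list("3" = matrix(c(1, 1, 1, phi3), 1)))
  M3 <- as.matrix(to_matrix(watson_operator(ff3, 5)))
  # |0> -> |3> through the pure creation string: sqrt(1*2*3) / (12 sqrt 2)
  expect_equal(M3[4, 1], sqrt(6) / (12 * sqrt(2)) * phi3, tolerance = 1e-12)
  phi4 <- 77
  ff4 <- force_field(2000, phi = list("4" = matrix(c(1, 1, 1, 1, phi4), 1)))
  M4 <- as.matrix(to_matrix(watson_operator(ff4, 4)))
  # <0|(b^dag + b)^4|0> = 3; quartic prefactor 1/96
  expect_equal(M4[1, 1] - 1000, 3 / 96 * phi4, tolerance = 1e-12)
  # quartic parity: |0> connects to occupations {0, 2, 4}
  con <- connections(watson_operator(ff4, 4), 0L)
  expect_equal(sort(con$codes), c(0, 2, 4))
})

test_that("term-table assembly matches the brute-force ladder-string oracle", {
  cases <- list(
    force_field(1234, phi = list("3" = matrix(c(1, 1, 1, 60), 1),
                                 "4" = matrix(c(1, 1, 1, 1, 45), 1))),
    toy_ff_2mode(seed = 21),
    toy_ff_coriolis()
  )
  for (ff in cases) {
    for (nmax in c(3L, 5L)) {
      H <- watson_operator(ff, nmax)
      M <- as.matrix(to_matrix(H))
      O <- dense_oracle(ff, nmax)
      expect_lt(max(abs(M - O)), 1e-10)
    }
  }
})

test_that("higher-order potentials follow the 1/(nu! 2^(nu/2)) prefactor", {
  ff <- force_field(1800, phi = list("5" = matrix(c(rep(1, 5), 40), 1),
                                     "6" = matrix(c(rep(1, 6), 30), 1)))
  M <- as.matrix(to_matrix(watson_operator(ff, 6)))
  O <- dense_oracle(ff, 6)
  expect_lt(max(abs(M - O)), 1e-10)
  # <0|(b^dag+b)^6|0> = 15 (number of perfect matchings of 6 items)
  expect_equal(M[1, 1] - 900, 15 / (factorial(6) * 2^3) * 30, tolerance = 1e-10)
})

test_that("connections agree with assembled matrix columns and are symmetric", {
  ff <- toy_ff_coriolis()
  H <- watson_operator(ff, 4)
  M <- to_matrix(H)
  expect_equal(max(abs(M - Matrix::t(M))), 0)
  for (n in list(c(0L, 0L), c(2L, 1L), c(4L, 4L))) {
    con <- connections(H, n)
    col <- as.numeric(M[, onv_encode(n, H$nmodal) + 1L])
    expect_equal(con$vals, col[con$codes + 1L], tolerance = 1e-12)
    expect_equal(sum(col != 0), sum(con$vals != 0))
    # element symmetry n -> n' vs n' -> n
    for (j in seq_along(con$codes)) {
      back <- connections(H, con$n[, j])
      expect_equal(back$vals[back$codes == onv_encode(n, H$nmodal)],
                   con$vals[j], tolerance = 1e-12)
    }
  }
})

test_that("to_matrix guards oversized spaces and validates indices", {
  ff <- force_field(rep(2000, 10))
  H <- watson_operator(ff, 9)
  expect_error(to_matrix(H), "guard")
  expect_error(force_field(c(2000, 2100),
                           phi = list("3" = matrix(c(1, 2, 3, 5), 1))),
               "out of range")
  expect_error(force_field(c(2000, 2100),
                           phi = list("7" = matrix(c(rep(1, 7), 5), 1))),
               "unsupported")
})

test_that("reduce_constants divides by frequency roots and round-trips", {
  idx <- rbind(c(1, 1, 2), c(2, 3, 3))
  w <- c(0.01, 0.012, 0.009)
  val <- c(3e-7, -5e-7)
  red <- reduce_constants(idx, val, w)
  expect_equal(red[1], val[1] / sqrt(w[1] * w[1] * w[2]))
  expect_equal(reduce_constants(idx, red, w, inverse = TRUE), val,
               tolerance = 1e-15)
  expect_equal(reduce_constants(idx, c(0, 0), w), c(0, 0))
  # equal frequencies: scalar kappa * wbar^(-3/2)
  expect_equal(reduce_constants(matrix(c(1, 1, 1), 1), 2e-6, rep(0.01, 1)),
               2e-6 * 0.01^-1.5)
  expect_error(reduce_constants(idx, val, c(0.01, -1, 0.009)), "positive")
})

test_that("ground-state energy converges with the truncation on weak samples", {
  for (s in 1:2) {
    ff <- sample_force_field(2, "weak", "weak", seed = 70 + s)
    e <- vapply(c(4L, 6L, 8L, 10L), function(nm) {
      exact_spectrum(watson_operator(ff, nm), k = 1)$values[1]
    }, numeric(1))
    gaps <- abs(diff(e))
    expect_lt(gaps[3], gaps[1] + 1e-9)
    expect_lt(gaps[3], 1e-3)
  }
})
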