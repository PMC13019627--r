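# VSCF, ground-state optimization, shifts, excited-state ladder.

# independent mean-field oracle: alternating single-mode eigenproblems
# against the dense Hamiltonian
mp_oracle_energy <- function(M, L, nmodal, sweeps = 80, seed = 1) {
  set.seed(seed)
  dim <- nmodal^L
  fullN <- onv_decode(0:(dim - 1), L, nmodal)
  phis <- replicate(L, {
    v <- rnorm(nmodal)
    v / sqrt(sum(v^2))
  }, simplify = FALSE)
  for (sweep in seq_len(sweeps)) {
    for (i in seq_len(L)) {
      other <- rep(1, dim)
      for (j in setdiff(seq_len(L), i)) other <- other * phis[[j]][fullN[j, ] + 1]
      A <- matrix(0, nmodal, nmodal)
      for (a in seq_len(nmodal)) for (b in seq_len(nmodal)) {
        va <- numeric(dim)
        va[fullN[i, ] == a - 1] <- other[fullN[i, ] == a - 1]
        vb <- numeric(dim)
        vb[fullN[i, ] == b - 1] <- other[fullN[i, ] == b - 1]
        A[a, b] <- sum(va * as.numeric(M %*% vb))
      }
      ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
      phis[[i]] <- ev$vectors[, which.min(ev$values)]
    }
  }
  psi <- rep(1, dim)
  for (j in seq_len(L)) psi <- psi * phis[[j]][fullN[j, ] + 1]
  rayleigh_quotient(M, psi)
}

test_that("VSCF is exact for harmonic Hamiltonians", {
  ff <- force_field(c(1500, 2000, 2600))
  H <- watson_operator(ff, 4)
  cfg <- training_config(nmax = 4, ns_schedule = list(c(16L, 50L)), seed = 1,
                         vscf_steps = 150)
  v <- run_vscf(H, c(0L, 0L, 0L), cfg)
  expect_equal(v$energy, sum(ff$w) / 2, tolerance = 1e-6)
  # converged modal matrix is one-hot on the vacuum up to gauge
  expect_true(all(abs(abs(v$phi0[, 1]) - 1) < 1e-3))
})

test_that("VSCF energy sits between exact and bare-configuration bounds and
           matches the alternating mean-field oracle", {
  ff <- toy_ff_2mode(seed = 21)
  H <- watson_operator(ff, 5)
  conn <- make_connector(H)
  M <- attr(conn, "M")
  cfg <- training_config(nmax = 5, ns_schedule = list(c(36L, 20L)), seed = 4,
                         vscf_steps = 600)
  v <- run_vscf(conn, c(0L, 0L), cfg)
  e0 <- exact_spectrum(conn, k = 1)$values[1]
  expect_gte(v$energy, e0 - 1e-6)
  expect_lte(v$energy, M[1, 1] + 1e-6)
  e_mp <- mp_oracle_energy(M, 2, 6)
  expect_lt(abs(v$energy - e_mp), 0.1)
})

test_that("ground optimization solves harmonic Hamiltonians immediately", {
  ff <- force_field(c(1450, 1980, 2610))
  H <- watson_operator(ff, 4)
  cfg <- training_config(nmax = 4, ns_schedule = list(c(16L, 200L)), seed = 2,
                         vscf_steps = 100)
  run <- run_ground(H, cfg)
  expect_lt(abs(run$energy - sum(ff$w) / 2), 1e-6)
  expect_lte(nrow(run$log), 200L)
})

test_that("identical seeds give bit-identical iteration logs", {
  ff <- toy_ff_2mode(seed = 45)
  H <- watson_operator(ff, 4)
  cfg <- training_config(nmax = 4, ns_schedule = list(c(12L, 40L)), seed = 7,
                         vscf_steps = 30)
  r1 <- run_ground(H, cfg)
  r2 <- run_ground(H, cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$record$amp, r2$record$amp)
  cfg$seed <- 8L
  r3 <- run_ground(H, cfg)
  expect_false(identical(r1$log$energy, r3$log$energy))
})

test_that("staged Ns schedules grow the selected space and keep improving", {
  ff <- toy_ff_2mode(seed = 46)
  H <- watson_operator(ff, 5)
  conn <- make_connector(H)
  cfg <- training_config(nmax = 5, ns_schedule = list(c(8L, 150L), c(16L, 100L),
                                                      c(32L, 100L)),
                         seed = 3, vscf_steps = 100)
  run <- run_ground(conn, cfg)
  e0 <- exact_spectrum(conn, k = 1)$values[1]
  expect_equal(unique(run$log$n_selected[c(150, 250, 350)]), c(8, 16, 32))
  expect_lt(abs(run$energy - e0), 0.05)
  expect_error(training_config(nmax = 4, ns_schedule = list(c(32L, 10L),
                                                            c(16L, 10L))),
               "non-decreasing")
})

test_that("shift estimates reduce to plain VSCF and bound harmonic gaps", {
  ff <- force_field(c(1700, 2100, 2500))
  H <- watson_operator(ff, 4)
  conn <- make_connector(H)
  cfg <- training_config(nmax = 4, ns_schedule = list(c(16L, 20L)), seed = 5,
                         vscf_steps = 150)
  # zero priors: plain VSCF energy minus the supplied ZPE
  est0 <- estimate_shift(conn, list(), cfg, zpe = 100)
  expect_equal(est0$z, sum(ff$w) / 2 - 100, tolerance = 1e-6)
  # one prior (the exact vacuum): z_1 equals the smallest frequency
  sp <- exact_spectrum(conn, k = 2)
  est1 <- estimate_shift(conn, list(spectrum_state(sp, 1)), cfg,
                         zpe = sp$values[1])
  expect_equal(est1$z, min(ff$w), tolerance = 1e-5)
})

test_that("excited ladder reproduces harmonic transitions exactly", {
  ff <- force_field(c(1620, 1940, 2380))
  H <- watson_operator(ff, 4)
  cfg <- training_config(nmax = 4, ns_schedule = list(c(16L, 120L)), seed = 2,
                         vscf_steps = 120)
  st <- run_excited_ladder(H, 4, cfg)
  expect_equal(vapply(st, `[[`, numeric(1), "transition"),
               c(0, 1620, 1940, 2380), tolerance = 1e-6)
  expect_true(all(lengths(lapply(st, `[[`, "warnings")) == 0))
})

test_that("harmonic seed configurations follow the harmonic energy order", {
  ff <- force_field(c(1600, 1900, 2300))
  expect_equal(harmonic_seed_onv(ff, 4, 0), c(0L, 0L, 0L))
  expect_equal(harmonic_seed_onv(ff, 4, 1), c(1L, 0L, 0L))
  expect_equal(harmonic_seed_onv(ff, 4, 2), c(0L, 1L, 0L))
  expect_equal(harmonic_seed_onv(ff, 4, 3), c(0L, 0L, 1L))
  expect_equal(harmonic_seed_onv(ff, 4, 4), c(2L, 0L, 0L))
})

test_that("excited ladder matches exact spectra on an anharmonic toy", {
  ff <- toy_ff_2mode(seed = 47)
  H <- watson_operator(ff, 5)
  conn <- make_connector(H)
  sp <- exact_spectrum(conn, k = 3)
  cfg <- training_config(nmax = 5, ns_schedule = list(c(24L, 300L)), seed = 6,
                         vscf_steps = 200)
  st <- run_excited_ladder(conn, 3, cfg)
  for (i in 1:3) {
    expect_lt(abs(st[[i]]$energy - sp$values[i]), 0.5)
  }
  e <- vapply(st, `[[`, numeric(1), "energy")
  expect_true(all(diff(e) > 0))
  # pairwise overlaps on stored supports stay small
  for (i in 1:2) for (j in (i + 1):3) {
    hit <- match(st[[i]]$codes, st[[j]]$codes)
    ov <- sum(st[[i]]$amp * st[[j]]$amp[hit], na.rm = TRUE)
    expect_lt(abs(ov), 1e-2)
  }
})
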