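# Selected-configuration engine: local energies, expectations,
# gradients, extend-and-select.

test_that("exact eigenvectors give zero-variance local energies", {
  ff <- toy_ff_2mode(seed = 33)
  H <- watson_operator(ff, 4)
  sp <- exact_spectrum(H, k = 2)
  for (state in 1:2) {
    psi <- table_ansatz(sp, state)
    fullN <- onv_decode(0:(H$nmodal^2 - 1), 2, H$nmodal)
    amps <- psi(fullN)
    sup <- which(abs(amps) > 1e-6 * max(abs(amps)))
    eloc <- vapply(head(sup, 12), function(j) {
      local_energy(H, psi, fullN[, j])
    }, numeric(1))
    expect_equal(eloc, rep(sp$values[state], length(eloc)), tolerance = 1e-8)
  }
})

test_that("local energy of one-hot states on a harmonic Hamiltonian", {
  ff <- force_field(c(1600, 2200))
  H <- watson_operator(ff, 3)
  for (m in list(c(0L, 0L), c(2L, 1L))) {
    p <- init_params("mbf", one_hot_modal(m, 4), sigma = 0)
    expect_equal(local_energy(H, p, m), harmonic_energy(ff, m))
  }
})

test_that("local energy matches (H psi)/psi from the dense matrix", {
  ff <- toy_ff_2mode(seed = 34)
  H <- watson_operator(ff, 4)
  M <- as.matrix(to_matrix(H))
  set.seed(10)
  v <- abs(rnorm(nrow(M))) + 0.05
  sp_fake <- list(vectors = cbind(v / sqrt(sum(v^2))), values = 0,
                  L = 2, nmax = 4, nmodal = 5)
  psi <- table_ansatz(structure(sp_fake, class = "vib_spectrum"), 1)
  hv <- M %*% v / v
  fullN <- onv_decode(0:(nrow(M) - 1), 2, 5)
  for (j in c(1, 7, 19, 25)) {
    expect_equal(local_energy(H, psi, fullN[, j]), hv[j], tolerance = 1e-9)
  }
})

test_that("full-space expectation equals the dense Rayleigh quotient", {
  ff <- toy_ff_2mode(seed = 35)
  H <- watson_operator(ff, 4)
  M <- as.matrix(to_matrix(H))
  fullN <- onv_decode(0:(nrow(M) - 1), 2, 5)
  Wfull <- selected_space(fullN, 5, Ns = ncol(fullN))
  set.seed(11)
  p <- init_params("mbf", matrix(rnorm(10, 0.5, 0.3), 2), alpha = 2,
                   sigma = 0.3, seed = 12)
  e_engine <- expectation_selected(H, p, Wfull)
  psi <- mbf_amplitude(p, fullN)
  e_dense <- rayleigh_quotient(M, psi)
  expect_equal(e_engine, e_dense, tolerance = 1e-9)
  expect_gt(e_engine, exact_spectrum(H, k = 1)$values[1] - 1e-9)
  # exact eigenvector: expectation is the eigenvalue on any support
  sp <- exact_spectrum(H, k = 1)
  tab <- table_ansatz(sp, 1)
  Wsub <- selected_space(fullN[, order(-abs(sp$vectors[, 1]))[1:6]], 5, Ns = 6)
  expect_equal(expectation_selected(H, tab, Wsub), sp$values[1],
               tolerance = 1e-8)
})

test_that("truncated-space expectation matches a from-scratch evaluation", {
  ff <- toy_ff_2mode(seed = 36)
  H <- watson_operator(ff, 3)
  M <- as.matrix(to_matrix(H))
  fullN <- onv_decode(0:(nrow(M) - 1), 2, 4)
  set.seed(13)
  p <- init_params("mbf", matrix(rnorm(8, 0.6, 0.2), 2), alpha = 1,
                   sigma = 0.2, seed = 14)
  psi <- mbf_amplitude(p, fullN)
  keep <- order(-abs(psi))[1:8]
  W <- selected_space(fullN[, keep], 4, Ns = 8)
  # asymmetric estimator <Psi_W|H|Psi> / <Psi_W|Psi_W> by dense algebra
  psiW <- numeric(length(psi))
  psiW[keep] <- psi[keep]
  e_ref <- as.numeric(crossprod(psiW, M %*% psi)) / sum(psiW^2)
  expect_equal(expectation_selected(H, p, W), e_ref, tolerance = 1e-10)
})

test_that("gradient estimator matches finite differences on the full space", {
  ff <- toy_ff_2mode(seed = 37)
  H <- watson_operator(ff, 3)
  fullN <- onv_decode(0:(4^2 - 1), 2, 4)
  Wfull <- selected_space(fullN, 4, Ns = ncol(fullN))
  set.seed(15)
  p <- init_params("mbf", matrix(rnorm(8, 0.5, 0.3), 2), alpha = 2,
                   sigma = 0.3, seed = 16)
  F <- gradient_selected(H, p, Wfull)$F
  th <- params_vector(p)
  h <- 1e-5
  fd <- vapply(seq_along(th), function(m) {
    up <- th; up[m] <- up[m] + h
    dn <- th; dn[m] <- dn[m] - h
    (expectation_selected(H, set_params_vector(p, up), Wfull) -
     expectation_selected(H, set_params_vector(p, dn), Wfull)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(F - fd) / pmax(abs(fd), 1e-4)), 1e-4)
})

test_that("the negative gradient is a descent direction (20 trials)", {
  ff <- toy_ff_2mode(seed = 38)
  H <- watson_operator(ff, 3)
  fullN <- onv_decode(0:(4^2 - 1), 2, 4)
  Wfull <- selected_space(fullN, 4, Ns = ncol(fullN))
  for (trial in 1:20) {
    p <- init_params("mbf", matrix(rnorm(8, 0.5, 0.3), 2), alpha = 1,
                     sigma = 0.3, seed = 100 + trial)
    gr <- gradient_selected(H, p, Wfull)
    eta <- 1e-4 / (1 + sqrt(sum(gr$F^2)))
    p2 <- set_params_vector(p, params_vector(p) - eta * gr$F)
    expect_lt(expectation_selected(H, p2, Wfull), gr$energy)
  }
})

test_that("extend_and_select picks the exact top-Ns for exhaustive pools", {
  ff <- toy_ff_2mode(seed = 39)
  H <- watson_operator(ff, 3)
  set.seed(17)
  p <- init_params("mbf", matrix(rnorm(8, 0.5, 0.3), 2), alpha = 1,
                   sigma = 0.4, seed = 18)
  W0 <- selected_space(matrix(c(0L, 0L, 1L, 1L), 2), 4, Ns = 6, K = 50)
  Wn <- extend_and_select(H, p, W0, seed = 5)
  # brute force: union of members and all their connections, top Ns
  pool <- unique(c(W0$codes, unlist(lapply(seq_len(ncol(W0$N)), function(j) {
    connections(H, W0$N[, j])$codes
  }))))
  amps <- mbf_amplitude(p, onv_decode(pool, 2, 4))
  best <- pool[order(-abs(amps))][1:6]
  expect_setequal(Wn$codes, best)
  # Ns above the reachable space size: keeps everything, stable
  Wall <- extend_and_select(H, p, selected_space(c(0L, 0L), 4, Ns = 1000, K = 50),
                            seed = 6)
  Wall2 <- extend_and_select(H, p, Wall, seed = 7)
  expect_true(all(Wall$codes %in% Wall2$codes))
  # explicit amplitudes: the two largest survive
  sp3 <- list(vectors = cbind(c(0.9, 0.5, 0.1, rep(0, 13))), values = 0,
              L = 2, nmax = 3, nmodal = 4)
  tab <- table_ansatz(structure(sp3, class = "vib_spectrum"), 1)
  Wt <- selected_space(onv_decode(0:2, 2, 4), 4, Ns = 2, K = 50)
  Wt2 <- extend_and_select(H, tab, Wt, seed = 8)
  expect_setequal(Wt2$codes, c(0, 1))
})

test_that("selected weight coverage is non-decreasing in Ns", {
  ff <- toy_ff_2mode(seed = 40)
  H <- watson_operator(ff, 4)
  sp <- exact_spectrum(H, k = 1)
  psi <- sp$vectors[, 1]
  fullN <- onv_decode(0:(5^2 - 1), 2, 5)
  tab <- table_ansatz(sp, 1)
  cov <- vapply(c(2L, 5L, 10L, 20L), function(ns) {
    W <- extend_and_select(H, tab, selected_space(c(0L, 0L), 5, Ns = ns, K = 50),
                           seed = 9)
    W <- extend_and_select(H, tab, W, seed = 10)
    sum(psi[W$codes + 1]^2) / sum(psi^2)
  }, numeric(1))
  expect_true(all(diff(cov) >= -1e-12))
})
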