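# End-to-end procedures: VSCF pretraining, ground-state optimization,
# shift estimation, and the penalty-based excited-state ladder.

#' Training configuration
#'
#' @param nmax occupation cutoff per mode.
#' @param ns_schedule selected-space schedule: a two-column matrix (or a
#'   list of pairs) of \code{(Ns, steps)} stages; \code{Ns} must be
#'   non-decreasing across stages.
#' @param K exploration factor of the candidate sampling.
#' @param alpha hidden neuron density of the network.
#' @param eta0 base learning rate of the CoRe optimizer.
#' @param decay learning-rate decay factor \code{r} over the whole run.
#' @param seed integer controlling every random draw of the run
#'   (initialization noise and candidate sampling).
#' @param pretrain run a VSCF pretraining stage and use its modal matrix
#'   as the fixed part of the MBF ansatz.
#' @param sigma weight initialization scale of the MBF/FNN network.
#' @param floor_rel relative amplitude floor of the engine.
#' @param vscf_steps,vscf_noise iteration count of the VSCF stage and the
#'   exploration noise added to its one-hot initial modal matrix.
#' @param zprime initial penalty shift \eqn{z'} (cm^-1) used when
#'   estimating level-specific shifts.
#' @param shift_margin safety factor applied to the estimated shift.
#' @param overlap_tol excited states with residual overlap above this
#'   value against any previous state are flagged.
#' @return object of class \code{training_config}.
#' @export
training_config <- function(nmax, ns_schedule = list(c(128L, 1000L)),
                            K = 1L, alpha = 1, eta0 = 0.05, decay = 0.1,
                            seed = 1L, pretrain = TRUE, sigma = 0.01,
                            floor_rel = 1e-12, vscf_steps = 300L,
                            vscf_noise = 0.01, zprime = 1e4,
                            shift_margin = 1.1, overlap_tol = 1e-2) {
  if (is.list(ns_schedule)) ns_schedule <- do.call(rbind, ns_schedule)
  ns_schedule <- matrix(as.integer(ns_schedule), ncol = 2L,
                        dimnames = list(NULL, c("Ns", "steps")))
  if (nrow(ns_schedule) == 0L) stop("ns_schedule must not be empty")
  if (any(ns_schedule <= 0L)) stop("Ns and step counts must be positive")
  if (is.unsorted(ns_schedule[, "Ns"])) {
    stop("the Ns schedule must be non-decreasing")
  }
  structure(list(nmax = as.integer(nmax), ns_schedule = ns_schedule,
                 K = as.integer(K), alpha = alpha, eta0 = eta0,
                 decay = decay, seed = as.integer(seed),
                 pretrain = pretrain, sigma = sigma,
                 floor_rel = floor_rel, vscf_steps = as.integer(vscf_steps),
                 vscf_noise = vscf_noise, zprime = zprime,
                 shift_margin = shift_margin, overlap_tol = overlap_tol),
            class = "training_config")
}

new_state_record <- function(level, W, psiW, energy, zpe = NULL,
                             warnings = character(0)) {
  nrm <- sqrt(sum(psiW^2))
  structure(list(level = level, codes = W$codes, N = W$N,
                 amp = psiW / nrm, energy = energy,
                 transition = if (!is.null(zpe)) energy - zpe else NULL,
                 warnings = warnings),
            class = "vib_state")
}

#' @export
print.vib_state <- function(x, ...) {
  cat("<vib_state> level ", x$level, ": E = ", round(x$energy, 4),
      " cm^-1", sep = "")
  if (!is.null(x$transition)) {
    cat(", transition = ", round(x$transition, 4), " cm^-1", sep = "")
  }
  cat(", |support| = ", length(x$codes), "\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# overlap of amplitudes stored on (possibly different) supports
support_overlap <- function(a, b) {
  hit <- match(a$codes, b$codes)
  ok <- !is.na(hit)
  if (!any(ok)) return(0)
  sum(a$amp[ok] * b$amp[hit[ok]])
}

# the central selected-configuration optimization loop (steps 1-5):
# extend-and-select with the current state, evaluate the penalized
# gradient estimator, CoRe-update the trainable parameters.
sc_optimize <- function(connector, params, ns_schedule, K, eta0, decay,
                        seed_codes, penalty = NULL, floor_rel = 1e-12) {
  Hop <- attr(connector, "H")
  total <- sum(ns_schedule[, "steps"])
  st <- core_state(n_params(params), eta0 = eta0, decay = decay,
                   total_steps = total)
  theta <- params_vector(params)
  W <- selected_space(onv_decode(seed_codes, Hop$L, Hop$nmodal),
                      Hop$nmodal, Ns = ns_schedule[1L, "Ns"], K = K)
  pen_codes <- unlist(lapply(penalty$states, `[[`, "codes"))
  log <- matrix(NA_real_, total, 6L,
                dimnames = list(NULL, c("step", "energy", "n_selected",
                                        "pool_size", "grad_norm", "lr")))
  # fused fast path on enumerable spaces: one full-space amplitude batch
  # and one sparse matrix-vector product per iteration (same estimator)
  M <- attr(connector, "M")
  fast <- !is.null(M)
  if (fast) {
    fullN <- attr(connector, "full_N")
    lexkey <- onv_lex_key(fullN, Hop$nmodal)
    Mp <- M@p
    Mi <- M@i
    Widx <- as.integer(seed_codes) + 1L
    pen_idx <- as.integer(unique(pen_codes)) + 1L
    pstates <- lapply(penalty$states, function(s) {
      list(idx = as.integer(s$codes) + 1L, amp = s$amp)
    })
  }
  step <- 0L
  energy <- NA_real_
  for (stage in seq_len(nrow(ns_schedule))) {
    Ns <- ns_schedule[stage, "Ns"]
    for (it in seq_len(ns_schedule[stage, "steps"])) {
      step <- step + 1L
      if (fast) {
        amps <- amplitude_fn(params)(fullN)
        # extend-and-select on column indices of the assembled matrix
        nv <- Mp[Widx + 1L] - Mp[Widx]
        nbr <- unique(Mi[sequence(nv, from = Mp[Widx] + 1L)] + 1L)
        cand <- sort(setdiff(nbr, Widx))
        k <- min(length(cand), K * Ns)
        if (k > 0L && k < length(cand)) {
          cand <- cand[sample.int(length(cand), k)]
        }
        pool <- unique(c(Widx, cand, pen_idx))
        o <- order(-abs(amps[pool]), lexkey[pool])
        Widx <- pool[o[seq_len(min(Ns, length(pool)))]]
        # penalized local energies and gradient estimator
        psiW <- amps[Widx]
        floor <- floor_rel * max(abs(psiW))
        live <- abs(psiW) > floor
        if (!any(live)) stop("all selected configurations fell below the amplitude floor")
        eloc <- as.numeric(M %*% amps)[Widx] / psiW
        if (!is.null(penalty)) {
          for (s in pstates) {
            ov <- sum(s$amp * amps[s$idx])
            hit <- match(Widx, s$idx)
            pen_amp <- ifelse(is.na(hit), 0, s$amp[hit])
            eloc <- eloc + penalty$z * pen_amp * ov / psiW
          }
          eloc <- eloc - penalty$zpe
        }
        p <- numeric(length(psiW))
        p[live] <- psiW[live]^2 / sum(psiW[live]^2)
        energy <- sum(p[live] * eloc[live])
        gd <- log_derivatives(params, fullN[, Widx, drop = FALSE])
        wgt <- p * (eloc - energy)
        wgt[!live] <- 0
        F <- 2 * as.numeric(crossprod(gd$D[live, , drop = FALSE], wgt[live]))
        n_sel <- length(Widx)
        pool_size <- length(pool)
      } else {
        psi_fn <- amplitude_fn(params)
        pool <- select_pool(connector, W$codes, Ns, K, extra = pen_codes)
        W <- new_W_from_pool(Hop, psi_fn, pool, Ns, K)
        gr <- selected_grad(connector, params, W, penalty = penalty,
                            floor_rel = floor_rel)
        F <- gr$F
        energy <- gr$energy
        n_sel <- ncol(W$N)
        pool_size <- length(pool)
      }
      upd <- core_update(st, F)
      st <- upd$state
      theta <- theta + upd$increment
      params <- set_params_vector(params, theta)
      log[step, ] <- c(step, energy, n_sel, pool_size, sqrt(sum(F^2)),
                       learning_rate(step, total, decay, eta0))
    }
  }
  if (fast) {
    W <- selected_space(fullN[, Widx, drop = FALSE], Hop$nmodal,
                        Ns = ns_schedule[nrow(ns_schedule), "Ns"], K = K)
  }
  if (!is.finite(energy)) stop("optimization diverged (nonfinite energy)")
  list(params = params, W = W, energy = energy,
       log = as.data.frame(log))
}

#' VSCF: mean-field (modal product) solution by the same machinery
#'
#' Optimizes only the fixed modal matrix \code{phi0} with all network
#' weights frozen at zero, which makes the MBF ansatz an exact modal
#' product. \code{phi0} starts from the one-hot harmonic configuration
#' \code{seed_onv} plus a small exploration noise.
#'
#' @param H a \code{\link{watson_operator}} or connector.
#' @param seed_onv harmonic configuration seeding the mean field (the
#'   vacuum for the ground state).
#' @param cfg a \code{\link{training_config}}.
#' @param penalty optional internal penalty description (used for
#'   level-specific shift estimates).
#' @return \code{list(phi0, energy, W, log)}; \code{phi0} rows are
#'   normalized. The energy is the modal-product expectation on the final
#'   selected space (penalized when a penalty is given).
#' @export
run_vscf <- function(H, seed_onv, cfg, penalty = NULL) {
  connector <- as_connector(H)
  Hop <- attr(connector, "H")
  seed_onv <- as.integer(seed_onv)
  if (any(seed_onv < 0L) || any(seed_onv > Hop$nmax)) {
    stop("seed configuration outside the truncation")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  phi0 <- one_hot_modal(seed_onv, Hop$nmodal) +
    matrix(rnorm(Hop$L * Hop$nmodal, 0, cfg$vscf_noise), Hop$L)
  params <- init_params("mbf", phi0, alpha = 1 / Hop$L, sigma = 0)
  params$train_weights <- FALSE
  params$train_phi0 <- TRUE

  sched <- matrix(c(cfg$ns_schedule[1L, "Ns"], cfg$vscf_steps), 1L,
                  dimnames = list(NULL, c("Ns", "steps")))
  out <- sc_optimize(connector, params, sched, cfg$K, cfg$eta0, cfg$decay,
                     onv_encode(seed_onv, Hop$nmodal), penalty = penalty,
                     floor_rel = cfg$floor_rel)
  phi0 <- out$params$phi0
  phi0 <- sweep(phi0, 1L, sqrt(rowSums(phi0^2)), "/")
  list(phi0 = phi0, energy = out$energy, W = out$W, log = out$log)
}

# one full MBF (or FNN) optimization against an optionally penalized
# Hamiltonian; shared by run_ground and the excited-state ladder
run_level <- function(connector, cfg, level, seed_onv, penalty = NULL,
                      mode = "mbf", zpe = NULL) {
  Hop <- attr(connector, "H")
  vscf <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  if (cfg$pretrain && mode == "mbf") {
    vscf <- run_vscf(connector, seed_onv, cfg, penalty = penalty)
    phi0 <- vscf$phi0
    set.seed(cfg$seed + 1L)
  } else {
    # no pretraining: random initial guess (row-normalized modal matrix)
    set.seed(cfg$seed + 1L)
    phi0 <- matrix(rnorm(Hop$L * Hop$nmodal), Hop$L)
    phi0 <- sweep(phi0, 1L, sqrt(rowSums(phi0^2)), "/")
  }

  sigma <- if (mode == "fnn" && cfg$sigma == 0) 0.01 else cfg$sigma
  params <- init_params(mode, phi0, alpha = cfg$alpha, sigma = sigma)
  out <- sc_optimize(connector, params, cfg$ns_schedule, cfg$K, cfg$eta0,
                     cfg$decay, onv_encode(as.integer(seed_onv), Hop$nmodal),
                     penalty = penalty, floor_rel = cfg$floor_rel)
  # plain-H energy and amplitudes on the final support
  psiW <- amplitude_fn(out$params)(out$W$N)
  energy <- expectation_selected(connector, out$params, out$W,
                                 floor_rel = cfg$floor_rel)
  record <- new_state_record(level, out$W, psiW, energy, zpe = zpe)
  list(params = out$params, record = record, log = out$log, vscf = vscf,
       energy = energy)
}

#' Ground-state optimization
#'
#' Runs the optional VSCF pretraining followed by the selected-
#' configuration MBF (or FNN baseline) optimization over the configured
#' \code{Ns} schedule.
#'
#' @param H a \code{\link{watson_operator}} or connector.
#' @param cfg a \code{\link{training_config}}.
#' @param mode \code{"mbf"} or \code{"fnn"} (the baseline skips
#'   pretraining; its scalar head has no modal matrix).
#' @return \code{list(params, record, log, vscf, energy)} where
#'   \code{record} is the converged \code{vib_state} and \code{log} the
#'   per-iteration trace.
#' @export
run_ground <- function(H, cfg, mode = c("mbf", "fnn")) {
  mode <- match.arg(mode)
  connector <- as_connector(H)
  Hop <- attr(connector, "H")
  run_level(connector, cfg, level = 0L, seed_onv = rep(0L, Hop$L),
            mode = mode)
}

#' Level-specific penalty shift estimate
#'
#' Runs a VSCF calculation on the penalty-shifted Hamiltonian
#' \eqn{H + z' \sum_j |\Psi_j\rangle\langle\Psi_j| - ZPE} seeded at the
#' harmonic configuration of the target level; its variational energy is
#' an upper-bound estimate \eqn{z_n \ge E_n - ZPE} of the target
#' transition, used as the (tightened) shift of the production run.
#'
#' @param H operator or connector.
#' @param priors list of converged \code{vib_state} records below the
#'   target level (possibly empty).
#' @param cfg a \code{\link{training_config}}.
#' @param zpe zero-point energy to subtract; defaults to the energy of
#'   the first prior (the ground state) or 0.
#' @return \code{list(z = <estimate, cm^-1>, vscf = <the VSCF run>)}.
#' @export
estimate_shift <- function(H, priors, cfg,
                           zpe = if (length(priors)) priors[[1L]]$energy else 0) {
  connector <- as_connector(H)
  Hop <- attr(connector, "H")
  level <- length(priors)
  seed_onv <- harmonic_seed_onv(Hop$ff, Hop$nmax, level)
  penalty <- if (level > 0L) list(z = cfg$zprime, zpe = zpe, states = priors)
             else list(z = 0, zpe = zpe, states = list())
  vscf <- run_vscf(connector, seed_onv, cfg, penalty = penalty)
  list(z = vscf$energy, vscf = vscf)
}

#' Excited-state ladder via penalty-shifted Hamiltonians
#'
#' Solves the lowest \code{n_states} states in order. Each level \code{n}
#' first estimates its shift with \code{\link{estimate_shift}}, then
#' optimizes an MBF ansatz for the Hamiltonian penalized by projectors
#' onto all previously converged states with
#' \eqn{z = \mathrm{margin} \times z_n}; transitions are reported
#' relative to the converged level-0 energy.
#'
#' @param H a \code{\link{watson_operator}} or connector.
#' @param n_states number of states including the ground state.
#' @param cfg a \code{\link{training_config}}.
#' @return list of \code{vib_state} records (level 0 first). Records
#'   carry warning flags for residual overlaps above
#'   \code{cfg$overlap_tol} and for energies out of order.
#' @export
run_excited_ladder <- function(H, n_states, cfg) {
  if (n_states < 1L) stop("n_states must be >= 1")
  connector <- as_connector(H)
  Hop <- attr(connector, "H")
  ground <- run_ground(connector, cfg)
  zpe <- ground$energy
  ground$record$transition <- 0
  records <- list(ground$record)
  for (level in seq_len(n_states - 1L)) {
    est <- estimate_shift(connector, records, cfg, zpe = zpe)
    z <- cfg$shift_margin * est$z
    if (!is.finite(z) || z <= 0) {
      stop("nonpositive shift estimate at level ", level)
    }
    penalty <- list(z = z, zpe = zpe, states = records)
    seed_onv <- harmonic_seed_onv(Hop$ff, Hop$nmax, level)
    lev_cfg <- cfg
    lev_cfg$seed <- cfg$seed + 1000L * level
    run <- run_level(connector, lev_cfg, level, seed_onv,
                     penalty = penalty, zpe = zpe)
    rec <- run$record
    for (j in seq_along(records)) {
      ov <- abs(support_overlap(rec, records[[j]]))
      if (ov > cfg$overlap_tol) {
        rec$warnings <- c(rec$warnings,
                          sprintf("overlap %.3g with level %d", ov,
                                  records[[j]]$level))
      }
    }
    if (rec$energy < records[[length(records)]]$energy - 1e-6) {
      rec$warnings <- c(rec$warnings, "energy below previous level")
    }
    records[[level + 1L]] <- rec
  }
  records
}

# all ONVs with total quanta s and per-mode cap nmax (L x m matrix)
onvs_with_total <- function(L, s, nmax) {
  if (L == 1L) {
    if (s <= nmax) return(matrix(as.integer(s), 1L)) else
      return(matrix(integer(0), 1L))
  }
  cols <- list()
  for (k in 0:min(s, nmax)) {
    sub <- onvs_with_total(L - 1L, s - k, nmax)
    if (ncol(sub) > 0L) cols[[length(cols) + 1L]] <- rbind(k, sub)
  }
  if (!length(cols)) matrix(integer(0), L) else do.call(cbind, cols)
}

#' Harmonic seed configuration for a given level
#'
#' The configuration with the \code{level}-th lowest harmonic energy
#' (0 = vacuum); harmonic degeneracies are resolved in lexicographic ONV
#' order.
#'
#' @param ff a \code{\link{force_field}}.
#' @param nmax occupation cutoff.
#' @param level 0-based level index.
#' @return integer occupation number vector.
#' @export
harmonic_seed_onv <- function(ff, nmax, level) {
  # the level-th lowest harmonic configuration has at most `level` quanta
  cap <- min(level, ff$L * nmax)
  N <- do.call(cbind, lapply(0:cap, function(s) onvs_with_total(ff$L, s, nmax)))
  e <- harmonic_energy(ff, N)
  o <- order(e, onv_lex_key(N, nmax + 1L))
  if (level + 1L > ncol(N)) stop("level exceeds the truncated space")
  as.integer(N[, o[level + 1L]])
}
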