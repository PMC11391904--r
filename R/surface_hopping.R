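#' Surface-hopping configuration
#'
#' @param dt_fs nuclear time step (fs).
#' @param n_substeps electronic integration substeps per nuclear step.
#' @param t_max_fs total simulation time (fs).
#' @param decoherence "energy_based" (exponential damping of inactive
#'   amplitudes with the standard kinetic-energy-dependent time constant)
#'   or "none".
#' @param decoherence_c decoherence constant C (Hartree).
#' @param frustrated policy for energetically frustrated hops: "ignore"
#'   (velocities unchanged) or "reflect" (velocity component along the
#'   coupling vector reversed).
#' @param energy_drift_abort total-energy drift (Hartree) beyond which a
#'   trajectory is flagged invalid; default 0.2 eV.
#' @param seed RNG seed for the hop draws.
#' @return object of class `ndn_sh_config`.
#' @export
sh_config <- function(dt_fs = 0.5, n_substeps = 25L, t_max_fs = 100,
                      decoherence = c("energy_based", "none"),
                      decoherence_c = 0.1,
                      frustrated = c("ignore", "reflect"),
                      energy_drift_abort = ev_to_hartree(0.2), seed = 1L) {
  decoherence <- match.arg(decoherence)
  frustrated <- match.arg(frustrated)
  stopifnot(dt_fs > 0, n_substeps >= 1, t_max_fs > 0)
  structure(list(dt_fs = dt_fs, n_substeps = as.integer(n_substeps),
                 t_max_fs = t_max_fs, decoherence = decoherence,
                 decoherence_c = decoherence_c, frustrated = frustrated,
                 energy_drift_abort = energy_drift_abort,
                 seed = as.integer(seed)),
            class = "ndn_sh_config")
}

#' Surface-hopping trajectory state
#'
#' @param positions,velocities n x 3 matrices (Bohr, Bohr per a.u. time).
#' @param masses atomic masses (electron masses).
#' @param active active electronic state (0-based label).
#' @param coefficients complex electronic amplitudes (norm 1); defaults to
#'   the active-state basis vector.
#' @param n_states number of states S.
#' @param time time (a.u.).
#' @return object of class `ndn_sh_state`.
#' @export
sh_state <- function(positions, velocities, masses, active, n_states,
                     coefficients = NULL, time = 0) {
  if (is.null(coefficients)) {
    coefficients <- rep(0 + 0i, n_states)
    coefficients[active + 1L] <- 1 + 0i
  }
  nrm <- sqrt(sum(Mod(coefficients)^2))
  if (abs(nrm - 1) > 1e-6) stop("coefficient norm deviates from 1")
  if (active >= n_states) stop("active_state must be < n_states")
  structure(list(positions = as.matrix(positions),
                 velocities = as.matrix(velocities),
                 masses = as.numeric(masses), active = as.integer(active),
                 n_states = as.integer(n_states),
                 coefficients = coefficients, time = time),
            class = "ndn_sh_state")
}

kinetic_energy <- function(vel, masses) 0.5 * sum(masses * rowSums(vel^2))

#' One velocity-Verlet step
#'
#' Standard symplectic update of positions and velocities on the active
#' surface.
#'
#' @param state an [sh_state()].
#' @param forces_provider function(positions) returning a list with
#'   `energy` (scalar, active surface) and `forces` (n x 3).
#' @param dt time step (a.u.).
#' @return updated state with `time` advanced by `dt`.
#' @export
velocity_verlet_step <- function(state, forces_provider, dt) {
  f0 <- forces_provider(state$positions)
  if (!all(is.finite(f0$forces))) {
    stop("non-finite forces at t = ", state$time, " a.u.; positions:\n",
         paste(apply(state$positions, 1, paste, collapse = " "),
               collapse = "\n"))
  }
  vh <- state$velocities + 0.5 * dt * f0$forces / state$masses
  state$positions <- state$positions + dt * vh
  f1 <- forces_provider(state$positions)
  if (!all(is.finite(f1$forces))) {
    stop("non-finite forces after step at t = ", state$time + dt, " a.u.")
  }
  state$velocities <- vh + 0.5 * dt * f1$forces / state$masses
  state$time <- state$time + dt
  state
}

## v . C_jk coupling matrix (antisymmetric, S x S) from classical NACs
nac_dot_velocity <- function(nacs, velocities, n_states) {
  pairs <- state_pairs(n_states)
  w <- matrix(0, n_states, n_states)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "i"] + 1L; j <- pairs[k, "j"] + 1L
    w[i, j] <- sum(velocities * nacs[k, , ])
    w[j, i] <- -w[i, j]
  }
  w
}

#' Propagate electronic coefficients across one nuclear step
#'
#' Integrates i dc/dt = (E - i W) c in the adiabatic basis (W_jk = v.C_jk,
#' antisymmetric), with linear interpolation of E and W across the nuclear
#' step and a unitary matrix-exponential update per substep, so the norm
#' is preserved to machine precision.
#'
#' @param coefficients complex amplitudes at t.
#' @param energies_t,energies_tdt per-state energies at the endpoints.
#' @param w_t,w_tdt coupling matrices v.C at the endpoints.
#' @param dt nuclear step (a.u.).
#' @param n_substeps electronic substeps.
#' @return complex amplitudes at t + dt.
#' @export
propagate_coefficients <- function(coefficients, energies_t, energies_tdt,
                                   w_t, w_tdt, dt, n_substeps = 25L) {
  tau <- dt / n_substeps
  c0 <- coefficients
  two_level <- length(coefficients) == 2
  for (m in seq_len(n_substeps)) {
    frac <- (m - 0.5) / n_substeps
    e <- (1 - frac) * energies_t + frac * energies_tdt
    w <- (1 - frac) * w_t + frac * w_tdt
    if (two_level) {
      ## closed-form unitary for H = diag(e) - i W (Pauli decomposition)
      cmean <- (e[1] + e[2]) / 2
      v3 <- (e[1] - e[2]) / 2
      v2 <- w[1, 2]
      vn <- sqrt(v3^2 + v2^2)
      th <- vn * tau
      s <- if (vn > 0) sin(th) / vn else tau
      ph <- exp(-1i * cmean * tau)
      u11 <- ph * (cos(th) - 1i * s * v3)
      u12 <- ph * (-s * v2)
      u21 <- ph * (s * v2)
      u22 <- ph * (cos(th) + 1i * s * v3)
      c0 <- c(u11 * c0[1] + u12 * c0[2], u21 * c0[1] + u22 * c0[2])
    } else {
      h <- diag(e, nrow = length(e)) - 1i * w  # Hermitian, antisym. real W
      ee <- eigen(h, symmetric = TRUE)
      ph <- exp(-1i * ee$values * tau)
      c0 <- ee$vectors %*% (ph * (Conj(t(ee$vectors)) %*% c0))
    }
  }
  as.complex(c0)
}

#' Fewest-switches hop probabilities
#'
#' g_(a -> j) = max(0, 2 dt Re(c_a* c_j) W_aj / |c_a|^2): the fraction of
#' the active-state population flowing to j this step. Negative fluxes are
#' clamped to zero, the active state gets zero, and the vector is scaled
#' down if it exceeds unit total.
#'
#' @param coefficients complex amplitudes.
#' @param active active state (0-based).
#' @param w coupling matrix v.C.
#' @param dt nuclear step (a.u.).
#' @return per-state probability vector g (0-based order).
#' @export
hop_probabilities <- function(coefficients, active, w, dt) {
  a <- active + 1L
  pa <- Mod(coefficients[a])^2
  s <- length(coefficients)
  if (pa < 1e-12) {
    warning("active-state population below 1e-12; hop probabilities set to 0")
    return(rep(0, s))
  }
  g <- vapply(seq_len(s), function(j) {
    if (j == a) return(0)
    2 * dt * Re(Conj(coefficients[a]) * coefficients[j]) * w[a, j] / pa
  }, numeric(1))
  g <- pmax(g, 0)
  tot <- sum(g)
  if (tot > 1) g <- g / tot
  g
}

#' Attempt a stochastic hop with momentum rescaling
#'
#' Draws the target by inverse CDF against one uniform variate. On
#' acceptance the velocities are rescaled along the classical coupling
#' vector C_aj so total energy is conserved exactly; if the kinetic energy
#' along that direction cannot pay an uphill gap the hop is frustrated and
#' handled per policy.
#'
#' @param state an [sh_state()].
#' @param probabilities per-state hop probabilities.
#' @param energies per-state energies at the current geometry.
#' @param nacs classical NAC array (P x n x 3).
#' @param draw uniform random number in [0, 1).
#' @param frustrated "ignore" or "reflect".
#' @return list `state` (updated) and `record` (data.frame: time, from,
#'   to, probability, draw, outcome).
#' @export
attempt_hop <- function(state, probabilities, energies, nacs, draw,
                        frustrated = "ignore") {
  s <- state$n_states
  cum <- cumsum(probabilities)
  target <- which(draw < cum)[1]
  rec <- data.frame(time = state$time, from = state$active,
                    to = NA_integer_, probability = sum(probabilities),
                    draw = draw, outcome = "none",
                    stringsAsFactors = FALSE)
  if (is.na(target)) return(list(state = state, record = rec))
  a <- state$active + 1L
  dE <- energies[target] - energies[a]
  i <- min(a, target); j <- max(a, target)
  k <- pair_index(i - 1L, j - 1L, s)
  d <- matrix(nacs[k, , ], ncol = 3)
  dn <- sqrt(sum(d^2))
  if (dn < 1e-30) d[] <- 0 else d <- d / dn
  a2 <- 0.5 * sum(d^2 / state$masses)
  a1 <- sum(state$velocities * d)
  rec$to <- target - 1L
  rec$probability <- probabilities[target]
  disc <- a1^2 - 4 * a2 * dE
  if (a2 <= 0 || disc < 0) {
    rec$outcome <- "frustrated"
    if (frustrated == "reflect" && a2 > 0) {
      gam <- -a1 / a2
      state$velocities <- state$velocities + gam * d / state$masses
    }
    return(list(state = state, record = rec))
  }
  roots <- c((-a1 + sqrt(disc)) / (2 * a2), (-a1 - sqrt(disc)) / (2 * a2))
  gam <- roots[which.min(abs(roots))]
  state$velocities <- state$velocities + gam * d / state$masses
  state$active <- target - 1L
  rec$outcome <- "accepted"
  list(state = state, record = rec)
}

apply_decoherence <- function(coefficients, active, energies, ekin, dt,
                              c_const) {
  a <- active + 1L
  s <- length(coefficients)
  for (j in seq_len(s)) {
    if (j == a) next
    tau <- (1 + c_const / max(ekin, 1e-12)) / abs(energies[j] - energies[a])
    coefficients[j] <- coefficients[j] * exp(-dt / tau)
  }
  pa_other <- sum(Mod(coefficients[-a])^2)
  pa <- Mod(coefficients[a])^2
  if (pa > 0) {
    coefficients[a] <- coefficients[a] * sqrt(max(1 - pa_other, 0) / pa)
  }
  coefficients
}

#' Property provider backed by a diabatic model
#'
#' @param model a [diabatic_model()].
#' @return function(list of position matrices) -> list of property lists
#'   (`energies`, `forces`, `nacs`), the interface consumed by the
#'   surface-hopping engine.
#' @export
exact_provider <- function(model) {
  s <- model$n_states
  pairs <- state_pairs(s)
  p <- nrow(pairs)
  function(pos_list) {
    lapply(pos_list, function(pos) {
      q <- model_coords(model, pos)
      ee <- eigen(model$V(q), symmetric = TRUE)
      ord <- order(ee$values)
      lam <- ee$values[ord]
      u <- fix_eigenvector_signs(ee$vectors[, ord, drop = FALSE])
      jd <- mode_jacobian(model, pos)
      dv <- model$dV(q)
      elem <- lapply(dv, function(dm) crossprod(u, dm %*% u))
      na <- nrow(pos)
      forces <- array(0, c(s, na, 3))
      nacs <- array(0, c(p, na, 3))
      for (m in seq_len(model$n_modes)) {
        em <- elem[[m]]
        for (j in seq_len(s)) {
          forces[j, , ] <- forces[j, , ] - em[j, j] * jd$jac[[m]]
        }
        for (k in seq_len(p)) {
          i <- pairs[k, "i"] + 1L; j <- pairs[k, "j"] + 1L
          nacs[k, , ] <- nacs[k, , ] +
            (em[i, j] / (lam[j] - lam[i])) * jd$jac[[m]]
        }
      }
      list(energies = lam, forces = forces, nacs = nacs)
    })
  }
}

#' Property provider backed by a trained model
#'
#' Batches all requested geometries through one forward pass and converts
#' the predicted smoothed couplings to classical NACs.
#'
#' @param model a trained `ndn_model` with energy, force and NAC heads.
#' @param atomic_numbers element numbers of the propagated molecule.
#' @param gap_floor divisor floor for the un-smoothing.
#' @return provider function as in [exact_provider()].
#' @export
ml_provider <- function(model, atomic_numbers, gap_floor = 1e-8) {
  function(pos_list) {
    geoms <- lapply(pos_list, function(p) geometry(atomic_numbers, p))
    preds <- predict_all(model, geoms,
                         need = c("energies", "forces", "smooth_nacs"))
    if (inherits(preds, "ndn_prediction")) preds <- list(preds)
    lapply(preds, function(pr) {
      pr <- to_classical_nacs(pr, gap_floor)
      list(energies = pr$energies, forces = pr$forces, nacs = pr$nacs)
    })
  }
}

#' Run an ensemble of surface-hopping trajectories
#'
#' Propagates all trajectories in lockstep (the provider is called once
#' per step on the batch of live geometries): velocity Verlet on the
#' active surface, unitary electronic propagation with endpoint
#' interpolation, fewest-switches hops with momentum rescaling along the
#' coupling vector, optional energy-based decoherence, and per-step
#' monitoring of the total energy. A trajectory whose total-energy drift
#' exceeds the configured bound is flagged invalid from that time onward.
#' NAC signs are aligned between consecutive steps for continuity.
#' Reproducible from the config seed.
#'
#' @param provider property provider ([exact_provider()] / [ml_provider()]).
#' @param inits list of initial conditions
#'   ([sample_initial_conditions()]).
#' @param masses atomic masses (electron masses).
#' @param n_states number of electronic states.
#' @param config an [sh_config()].
#' @return object of class `ndn_trajectories`: `time_fs`, `active`
#'   (n_traj x n_time, 0-based states), `valid` (logical, same shape),
#'   `populations_coef` (n_traj x S x n_time), `etot` drift matrix, and
#'   `hops` (data.frame of hop records with trajectory ids).
#' @export
run_ensemble <- function(provider, inits, masses, n_states, config) {
  dt <- fs_to_aut(config$dt_fs)
  nstep <- round(config$t_max_fs / config$dt_fs)
  ntraj <- length(inits)
  s <- n_states
  p <- n_pairs(s)
  draws <- with_preserved_seed(config$seed,
                               matrix(stats::runif(nstep * ntraj),
                                      nstep, ntraj))
  st <- lapply(inits, function(ic) {
    sh_state(ic$positions, ic$velocities, masses, ic$state, s)
  })
  live <- rep(TRUE, ntraj)
  active <- matrix(NA_integer_, ntraj, nstep + 1)
  valid <- matrix(FALSE, ntraj, nstep + 1)
  popc <- array(NA_real_, c(ntraj, s, nstep + 1))
  etot <- matrix(NA_real_, ntraj, nstep + 1)
  hops <- list()

  props <- provider(lapply(st, `[[`, "positions"))
  e0 <- vapply(seq_len(ntraj), function(t) {
    props[[t]]$energies[st[[t]]$active + 1L] +
      kinetic_energy(st[[t]]$velocities, masses)
  }, numeric(1))
  for (t in seq_len(ntraj)) {
    active[t, 1] <- st[[t]]$active
    valid[t, 1] <- TRUE
    popc[t, , 1] <- Mod(st[[t]]$coefficients)^2
    etot[t, 1] <- e0[t]
  }

  for (step in seq_len(nstep)) {
    idx <- which(live)
    if (length(idx) == 0) break
    ## velocity-Verlet half-kick + drift
    vh <- pos1 <- vector("list", ntraj)
    for (t in idx) {
      f <- props[[t]]$forces[st[[t]]$active + 1L, , ]
      vh[[t]] <- st[[t]]$velocities + 0.5 * dt * f / masses
      pos1[[t]] <- st[[t]]$positions + dt * vh[[t]]
    }
    props1 <- provider(pos1[idx])
    names(props1) <- as.character(idx)
    for (t in idx) {
      pr1 <- props1[[as.character(t)]]
      pr0 <- props[[t]]
      ## NAC sign continuity between steps
      for (k in seq_len(p)) {
        if (sum(pr1$nacs[k, , ] * pr0$nacs[k, , ]) < 0) {
          pr1$nacs[k, , ] <- -pr1$nacs[k, , ]
        }
      }
      v0 <- st[[t]]$velocities
      st[[t]]$velocities <- vh[[t]] +
        0.5 * dt * pr1$forces[st[[t]]$active + 1L, , ] / masses
      st[[t]]$positions <- pos1[[t]]
      st[[t]]$time <- st[[t]]$time + dt
      w0 <- nac_dot_velocity(pr0$nacs, v0, s)
      w1 <- nac_dot_velocity(pr1$nacs, st[[t]]$velocities, s)
      st[[t]]$coefficients <- propagate_coefficients(
        st[[t]]$coefficients, pr0$energies, pr1$energies, w0, w1, dt,
        config$n_substeps)
      g <- hop_probabilities(st[[t]]$coefficients, st[[t]]$active, w1, dt)
      res <- attempt_hop(st[[t]], g, pr1$energies, pr1$nacs,
                         draws[step, t], config$frustrated)
      st[[t]] <- res$state
      if (res$record$outcome != "none") {
        hops[[length(hops) + 1]] <- cbind(traj = t, res$record)
      }
      if (config$decoherence == "energy_based") {
        st[[t]]$coefficients <- apply_decoherence(
          st[[t]]$coefficients, st[[t]]$active, pr1$energies,
          kinetic_energy(st[[t]]$velocities, masses), dt,
          config$decoherence_c)
      }
      props[[t]] <- pr1
      et <- pr1$energies[st[[t]]$active + 1L] +
        kinetic_energy(st[[t]]$velocities, masses)
      etot[t, step + 1] <- et
      if (abs(et - e0[t]) > config$energy_drift_abort) {
        live[t] <- FALSE
        next
      }
      active[t, step + 1] <- st[[t]]$active
      valid[t, step + 1] <- TRUE
      popc[t, , step + 1] <- Mod(st[[t]]$coefficients)^2
    }
  }
  structure(list(time_fs = (0:nstep) * config$dt_fs, active = active,
                 valid = valid, populations_coef = popc, etot = etot,
                 hops = if (length(hops)) do.call(rbind, hops) else
                   data.frame(),
                 n_states = s, config = config),
            class = "ndn_trajectories")
}

#' Run a single surface-hopping trajectory
#'
#' @inheritParams run_ensemble
#' @param init one initial condition (`positions`, `velocities`, `state`).
#' @return an `ndn_trajectories` object with one trajectory.
#' @export
run_trajectory <- function(provider, init, masses, n_states, config) {
  run_ensemble(provider, list(init), masses, n_states, config)
}

#' Ensemble state populations over time
#'
#' Fraction of (valid) trajectories in each active state at each time.
#' Trajectories flagged invalid are excluded from that time onward; times
#' with no valid trajectory are masked (NA).
#'
#' @param traj an `ndn_trajectories` object.
#' @return data.frame: time_fs, state (0-based), population, se (binomial
#'   standard error), n_valid.
#' @export
ensemble_populations <- function(traj) {
  s <- traj$n_states
  nt <- length(traj$time_fs)
  out <- do.call(rbind, lapply(seq_len(nt), function(it) {
    ok <- traj$valid[, it]
    n <- sum(ok)
    pop <- if (n == 0) rep(NA_real_, s) else {
      tabulate(traj$active[ok, it] + 1L, nbins = s) / n
    }
    data.frame(time_fs = traj$time_fs[it], state = 0:(s - 1),
               population = pop,
               se = if (n == 0) NA_real_ else sqrt(pop * (1 - pop) / n),
               n_valid = n)
  }))
  rownames(out) <- NULL
  out
}

## closed-form sequential-chain populations: state S_{m} decays to S_{m-1}
## with rate k_m; initial population on the top state
sequential_populations <- function(time, ks) {
  nst <- length(ks) + 1          # states S0..S_{nst-1}
  rates <- c(0, ks)              # rate of S_m is rates[m+1]
  ## analytic solution of the linear chain via matrix exponential on a
  ## small bidiagonal generator (handles equal rates robustly)
  a <- matrix(0, nst, nst)
  for (m in 2:nst) {
    a[m, m] <- -rates[m]
    a[m - 1, m] <- rates[m]
  }
  p0 <- c(rep(0, nst - 1), 1)
  t(vapply(time, function(tt) {
    as.numeric(Matrix_expm(a * tt) %*% p0)
  }, numeric(nst)))
}

## small dense matrix exponential (scaling and squaring with Pade-free
## Taylor; adequate for the tiny kinetics generators used here)
Matrix_expm <- function(a) {
  n <- nrow(a)
  nrm <- max(abs(a))
  j <- max(0, ceiling(log2(max(nrm, 1e-300))) + 1)
  a <- a / 2^j
  e <- diag(n) + a
  term <- a
  for (k in 2:12) {
    term <- term %*% a / k
    e <- e + term
  }
  for (i in seq_len(j)) e <- e %*% e
  e
}

#' Fit a sequential kinetics scheme to ensemble populations
#'
#' Least-squares fit of the closed-form populations of the first-order
#' chain S_(n-1) -> ... -> S_0 to the observed populations on a uniform
#' time grid; lifetimes are tau = 1/k.
#'
#' @param populations data.frame from [ensemble_populations()] or a
#'   matrix (n_time x n_states, columns S0 first).
#' @param time_fs time grid (fs; taken from the data.frame if omitted).
#' @param n_states number of states in the chain.
#' @return list: `k_per_fs`, `tau_fs` (Inf where the state does not
#'   decay), `residual` (RMS), `fitted` population matrix.
#' @export
fit_sequential_kinetics <- function(populations, time_fs = NULL,
                                    n_states = NULL) {
  if (is.data.frame(populations)) {
    if (is.null(n_states)) n_states <- max(populations$state) + 1L
    time_fs <- sort(unique(populations$time_fs))
    pop <- vapply(0:(n_states - 1), function(j) {
      populations$population[populations$state == j]
    }, numeric(length(time_fs)))
  } else {
    pop <- as.matrix(populations)
    if (is.null(n_states)) n_states <- ncol(pop)
  }
  keep <- stats::complete.cases(pop)
  pop <- pop[keep, , drop = FALSE]
  time_fs <- time_fs[keep]
  if (nrow(pop) < n_states + 1) {
    stop("too few time points to identify the sequential scheme")
  }
  top <- pop[, n_states]
  if (min(top) > 1 - 1e-6) {
    return(list(k_per_fs = rep(0, n_states - 1),
                tau_fs = rep(Inf, n_states - 1), residual = 0,
                fitted = pop, no_decay = TRUE))
  }
  if (max(top) - min(top) < 1e-4) {
    stop("populations are flat but not at unity; sequential rates are not ",
         "identifiable from this data")
  }
  ## crude initial guesses from 1/e crossing times
  guess <- vapply(seq_len(n_states - 1), function(m) {
    cross <- which(pop[, m + 1] < exp(-1) * max(pop[, m + 1]))[1]
    if (is.na(cross)) 1 / max(time_fs) else 1 / max(time_fs[cross], 1e-3)
  }, numeric(1))
  resid_fun <- function(logk) {
    ks <- exp(logk)
    as.numeric(sequential_populations(time_fs, ks) - pop)
  }
  fit <- minpack.lm::nls.lm(par = log(guess), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  ks <- exp(fit$par)
  fitted <- sequential_populations(time_fs, ks)
  list(k_per_fs = ks, tau_fs = 1 / ks,
       residual = sqrt(mean((fitted - pop)^2)), fitted = fitted,
       no_decay = FALSE)
}
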