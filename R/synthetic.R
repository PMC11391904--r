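#' Analytic diabatic model Hamiltonians
#'
#' A diabatic model defines a symmetric S x S potential matrix V(q) with
#' analytic gradients and a diabatic dipole model on a small set of
#' internal modes q. The modes are mapped onto bond-stretch coordinates of
#' a small pseudo-molecule (a diatomic for one mode, a bent triatomic for
#' two), so the exact adiabatic properties emerge as ordinary Cartesian
#' [multistate_sample()] objects and the entire pipeline - training,
#' dynamics, spectra - consumes them unchanged.
#'
#' @param n_states number of electronic states S.
#' @param V function(q) -> S x S symmetric matrix (Hartree).
#' @param dV function(q) -> list (one per mode) of S x S matrices dV/dq_m.
#' @param dcoef function(q) -> list (one per mode) of S x S diabatic
#'   dipole coefficient matrices; the Cartesian diabatic dipole is
#'   sum_m dcoef_m(q) * u_m with u_m the unit vector of bond m.
#' @param atomic_numbers,masses,ref_positions pseudo-molecule definition;
#'   masses in electron masses.
#' @param bonds m x 2 matrix of atom indices (a, b); mode q_m =
#'   |r_b - r_a| - r0_m. Bond b-atoms must be placeable sequentially.
#' @param r0 equilibrium bond lengths (Bohr).
#' @param seam declared exact-degeneracy point in mode coordinates, or NULL.
#' @param name model name.
#' @return object of class `ndn_diabatic`.
#' @export
diabatic_model <- function(n_states, V, dV, dcoef = NULL, atomic_numbers,
                           masses = atomic_mass(atomic_numbers),
                           ref_positions, bonds, r0, seam = NULL,
                           name = "diabatic") {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  ref_positions <- as.matrix(ref_positions)
  ref_dirs <- t(apply(bonds, 1, function(b) {
    d <- ref_positions[b[2], ] - ref_positions[b[1], ]
    d / sqrt(sum(d^2))
  }))
  if (nrow(bonds) == 1) ref_dirs <- matrix(ref_dirs, 1, 3)
  m <- structure(list(n_states = as.integer(n_states),
                      n_modes = nrow(bonds), V = V, dV = dV, dcoef = dcoef,
                      atomic_numbers = as.integer(atomic_numbers),
                      masses = as.numeric(masses),
                      ref_positions = ref_positions, bonds = bonds,
                      r0 = as.numeric(r0), ref_dirs = ref_dirs,
                      seam = seam, name = name),
                 class = "ndn_diabatic")
  gm <- mode_metric(m, model_positions(m, rep(0, m$n_modes)))
  m$mode_masses <- 1 / diag(gm)
  m
}

#' @export
print.ndn_diabatic <- function(x, ...) {
  cat("<diabatic model>", x$name, ":", x$n_states, "states,", x$n_modes,
      "modes,", length(x$atomic_numbers), "pseudo-atoms\n")
  invisible(x)
}

#' Cartesian positions realizing mode coordinates
#'
#' Builds the pseudo-molecule in its reference orientation with the bond
#' lengths set to r0 + q.
#'
#' @param model a [diabatic_model()].
#' @param q mode coordinate vector.
#' @return n x 3 position matrix (Bohr).
#' @export
model_positions <- function(model, q) {
  pos <- model$ref_positions
  pos[1, ] <- model$ref_positions[1, ]
  for (m in seq_len(model$n_modes)) {
    a <- model$bonds[m, 1]; b <- model$bonds[m, 2]
    pos[b, ] <- pos[a, ] + (model$r0[m] + q[m]) * model$ref_dirs[m, ]
  }
  pos
}

#' @rdname model_positions
#' @param positions n x 3 Cartesian positions.
#' @return mode coordinates recovered from bond lengths.
#' @export
model_coords <- function(model, positions) {
  vapply(seq_len(model$n_modes), function(m) {
    a <- model$bonds[m, 1]; b <- model$bonds[m, 2]
    sqrt(sum((positions[b, ] - positions[a, ])^2)) - model$r0[m]
  }, numeric(1))
}

model_geometry <- function(model, q) {
  geometry(model$atomic_numbers, model_positions(model, q))
}

## Jacobian dq_m/dR as list of n x 3 matrices, and bond unit vectors
mode_jacobian <- function(model, positions) {
  n <- nrow(positions)
  jac <- vector("list", model$n_modes)
  dirs <- matrix(0, model$n_modes, 3)
  for (m in seq_len(model$n_modes)) {
    a <- model$bonds[m, 1]; b <- model$bonds[m, 2]
    d <- positions[b, ] - positions[a, ]
    u <- d / sqrt(sum(d^2))
    dirs[m, ] <- u
    J <- matrix(0, n, 3)
    J[a, ] <- -u; J[b, ] <- u
    jac[[m]] <- J
  }
  list(jac = jac, dirs = dirs)
}

## G matrix G_kl = J_k' M^-1 J_l (Wilson metric of the bond coordinates)
mode_metric <- function(model, positions) {
  jd <- mode_jacobian(model, positions)
  nm <- model$n_modes
  g <- matrix(0, nm, nm)
  for (k in seq_len(nm)) {
    for (l in seq_len(nm)) {
      g[k, l] <- sum(jd$jac[[k]] * jd$jac[[l]] / model$masses)
    }
  }
  g
}

## deterministic eigenvector sign: largest-|component| entry positive,
## ties broken by lowest index (which.max picks the first maximum)
fix_eigenvector_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    k <- which.max(abs(u[, j]))
    if (u[k, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' Exact adiabatic properties of a diabatic model at a geometry
#'
#' Diagonalizes V(q), applies a deterministic eigenvector sign convention,
#' and returns a complete [multistate_sample()]: eigenvalue energies,
#' Hellmann-Feynman forces, derivative couplings (divergent at
#' degeneracies), their bounded smoothed counterparts, and
#' eigenvector-transformed dipoles.
#'
#' @param model a [diabatic_model()].
#' @param geom a [geometry()] of the model's pseudo-molecule (or a mode
#'   coordinate vector).
#' @param nac_singular_tol gap magnitude below which the raw NAC is flagged
#'   singular (error); the smoothed NACs remain well-defined.
#' @return an `ndn_sample` with all property blocks.
#' @export
adiabatize <- function(model, geom, nac_singular_tol = 1e-10) {
  if (!inherits(geom, "ndn_geometry")) {
    geom <- model_geometry(model, geom)
  }
  pos <- geom$positions
  q <- model_coords(model, pos)
  vm <- model$V(q)
  ee <- eigen(vm, symmetric = TRUE)
  ord <- order(ee$values)
  lam <- ee$values[ord]
  u <- fix_eigenvector_signs(ee$vectors[, ord, drop = FALSE])
  s <- model$n_states
  jd <- mode_jacobian(model, pos)
  dv <- model$dV(q)
  na <- nrow(pos)
  pairs <- state_pairs(s)
  p <- nrow(pairs)

  ## mode-space matrix elements u_i' dV_m u_j
  elem <- lapply(dv, function(dm) t(u) %*% dm %*% u)

  forces <- array(0, c(s, na, 3))
  for (j in seq_len(s)) {
    for (m in seq_len(model$n_modes)) {
      forces[j, , ] <- forces[j, , ] - elem[[m]][j, j] * jd$jac[[m]]
    }
  }
  smooth <- array(0, c(p, na, 3))
  nacs <- array(0, c(p, na, 3))
  for (k in seq_len(p)) {
    i <- pairs[k, "i"] + 1L; j <- pairs[k, "j"] + 1L
    gap <- lam[j] - lam[i]
    for (m in seq_len(model$n_modes)) {
      smooth[k, , ] <- smooth[k, , ] + elem[[m]][i, j] * jd$jac[[m]]
    }
    if (abs(gap) < nac_singular_tol) {
      stop("NAC singular: |E_", j - 1, " - E_", i - 1, "| = ",
           format(abs(gap)), " < ", nac_singular_tol,
           " at the requested geometry")
    }
    nacs[k, , ] <- smooth[k, , ] / gap
  }
  pd <- td <- NULL
  if (!is.null(model$dcoef)) {
    dc <- model$dcoef(q)
    dad <- array(0, c(s, s, 3))
    for (m in seq_len(model$n_modes)) {
      am <- t(u) %*% dc[[m]] %*% u
      for (a in 1:3) dad[, , a] <- dad[, , a] + am * jd$dirs[m, a]
    }
    pd <- t(vapply(seq_len(s), function(j) dad[j, j, ], numeric(3)))
    td <- if (p > 0) {
      t(vapply(seq_len(p), function(k) {
        dad[pairs[k, "i"] + 1L, pairs[k, "j"] + 1L, ]
      }, numeric(3)))
    } else matrix(0, 0, 3)
  }
  multistate_sample(geom, state_space(s), energies = lam, forces = forces,
                    nacs = nacs, smooth_nacs = smooth,
                    permanent_dipoles = pd, transition_dipoles = td)
}

#' Built-in analytic models
#'
#' `model_avoided_crossing_1d()`: two shifted harmonic diabats with a
#' constant coupling on one bond-stretch mode of a diatomic; reduces to
#' two crossing harmonic wells as the coupling goes to zero.
#'
#' `model_conical_2d()`: a two-state linear vibronic model on the two bond
#' stretches of a bent triatomic (tuning mode q1, coupling mode q2); the
#' adiabatic surfaces are exactly degenerate at the seam point
#' q = (delta / (kappa1 - kappa2), 0) where the raw couplings diverge as
#' 1/distance while the smoothed couplings stay bounded.
#'
#' `model_three_state_2d()`: three-state extension with a second accessible
#' seam.
#'
#' Default parameters are typical mid-infrared vibrational frequencies and
#' eV-scale vibronic couplings, scaled so that vertical excitation from
#' the Franck-Condon region reaches the intersection seam within a few
#' bond-stretch periods.
#'
#' @param k,q0,eps,coupling 1D model: force constant (Hartree/Bohr^2),
#'   horizontal and vertical offsets of the upper diabat, constant
#'   coupling (Hartree).
#' @param omega1,omega2 harmonic mode frequencies (Hartree).
#' @param kappa1,kappa2,kappa3 linear tuning-mode gradients (Hartree/Bohr).
#' @param delta,delta3 vertical diabatic energy offsets (Hartree).
#' @param lambda,lambda13,lambda23 linear coupling-mode constants
#'   (Hartree/Bohr).
#' @return a [diabatic_model()].
#' @export
model_avoided_crossing_1d <- function(k = 0.09, q0 = 0.5, eps = 0.01,
                                      coupling = 0.005) {
  V <- function(q) {
    x <- q[1]
    matrix(c(0.5 * k * x^2, coupling,
             coupling, 0.5 * k * (x - q0)^2 + eps), 2, 2)
  }
  dV <- function(q) {
    x <- q[1]
    list(matrix(c(k * x, 0, 0, k * (x - q0)), 2, 2))
  }
  dcoef <- function(q) {
    list(matrix(c(0.4, 0.6, 0.6, -0.2), 2, 2))
  }
  diabatic_model(2, V, dV, dcoef, atomic_numbers = c(1, 1),
                 ref_positions = rbind(c(0, 0, 0), c(1.4, 0, 0)),
                 bonds = rbind(c(1, 2)), r0 = 1.4,
                 name = "avoided_crossing_1d")
}

#' @rdname model_avoided_crossing_1d
#' @export
model_conical_2d <- function(omega1 = 0.007, omega2 = 0.014,
                             kappa1 = 0, kappa2 = -0.08, delta = 0.02,
                             lambda = 0.02) {
  stopifnot(omega1 > 0, omega2 > 0)
  z <- c(6L, 7L, 1L)
  masses <- atomic_mass(z)
  ref <- rbind(c(0, 0, 0), c(2.5, 0, 0),
               c(2.5 + 2.0 * cos(110 * pi / 180),
                 2.0 * sin(110 * pi / 180), 0))
  ## force constants from the bond-coordinate effective masses
  mu1 <- 1 / (1 / masses[1] + 1 / masses[2])
  mu2 <- 1 / (1 / masses[2] + 1 / masses[3])
  k1 <- mu1 * omega1^2
  k2 <- mu2 * omega2^2
  V <- function(q) {
    h <- 0.5 * k1 * q[1]^2 + 0.5 * k2 * q[2]^2
    matrix(c(h + kappa1 * q[1], lambda * q[2],
             lambda * q[2], h + kappa2 * q[1] + delta), 2, 2)
  }
  dV <- function(q) {
    list(matrix(c(k1 * q[1] + kappa1, 0, 0, k1 * q[1] + kappa2), 2, 2),
         matrix(c(k2 * q[2], lambda, lambda, k2 * q[2]), 2, 2))
  }
  dcoef <- function(q) {
    list(matrix(c(0.5, 0.3, 0.3, -0.3), 2, 2),
         matrix(c(0.2, 0.6, 0.6, 0.1), 2, 2))
  }
  seam <- c(delta / (kappa1 - kappa2), 0)
  m <- diabatic_model(2, V, dV, dcoef, atomic_numbers = z, masses = masses,
                      ref_positions = ref, bonds = rbind(c(1, 2), c(2, 3)),
                      r0 = c(2.5, 2.0), seam = seam, name = "conical_2d")
  m$mode_omegas <- c(omega1, omega2)
  m
}

#' @rdname model_avoided_crossing_1d
#' @export
model_three_state_2d <- function(omega1 = 0.007, omega2 = 0.014,
                                 kappa1 = 0, kappa2 = -0.08,
                                 kappa3 = -0.12, delta = 0.02,
                                 delta3 = 0.05, lambda = 0.02,
                                 lambda13 = 0.01, lambda23 = 0.02) {
  base <- model_conical_2d(omega1, omega2, kappa1, kappa2, delta, lambda)
  mu1 <- base$mode_masses[1]; mu2 <- base$mode_masses[2]
  k1 <- mu1 * omega1^2; k2 <- mu2 * omega2^2
  V <- function(q) {
    h <- 0.5 * k1 * q[1]^2 + 0.5 * k2 * q[2]^2
    matrix(c(h + kappa1 * q[1], lambda * q[2], lambda13 * q[2],
             lambda * q[2], h + kappa2 * q[1] + delta, lambda23 * q[2],
             lambda13 * q[2], lambda23 * q[2], h + kappa3 * q[1] + delta3),
           3, 3)
  }
  dV <- function(q) {
    list(matrix(c(k1 * q[1] + kappa1, 0, 0,
                  0, k1 * q[1] + kappa2, 0,
                  0, 0, k1 * q[1] + kappa3), 3, 3),
         matrix(c(k2 * q[2], lambda, lambda13,
                  lambda, k2 * q[2], lambda23,
                  lambda13, lambda23, k2 * q[2]), 3, 3))
  }
  dcoef <- function(q) {
    list(matrix(c(0.5, 0.3, 0.15, 0.3, -0.3, 0.25, 0.15, 0.25, 0.1), 3, 3),
         matrix(c(0.2, 0.6, 0.3, 0.6, 0.1, 0.4, 0.3, 0.4, -0.1), 3, 3))
  }
  m <- diabatic_model(3, V, dV, dcoef, atomic_numbers = base$atomic_numbers,
                      masses = base$masses,
                      ref_positions = base$ref_positions,
                      bonds = base$bonds, r0 = base$r0,
                      seam = base$seam, name = "three_state_2d")
  m$mode_omegas <- c(omega1, omega2)
  m
}

#' Sampling specification for synthetic datasets
#'
#' @param scheme "harmonic_wigner" (ground-state Wigner distribution of
#'   the declared well), "grid" (rectangular grid over `ranges`), or
#'   "uniform_box" (uniform over `ranges`).
#' @param n_samples number of samples (grid: per-axis counts via
#'   `grid_points`).
#' @param ranges n_modes x 2 matrix of mode-coordinate ranges.
#' @param grid_points integer vector of per-axis point counts (grid only).
#' @param seed RNG seed.
#' @param phase_corruption probability in [0, 1] that a sample's coupled
#'   properties (NACs, smoothed NACs and transition dipoles jointly) are
#'   flipped by a uniformly drawn random phase vector, emulating the
#'   arbitrary per-calculation wavefunction sign of quantum-chemistry
#'   output.
#' @return object of class `ndn_sampling_spec`.
#' @export
sampling_spec <- function(scheme = c("harmonic_wigner", "grid", "uniform_box"),
                          n_samples = 1000L, ranges = NULL,
                          grid_points = NULL, seed = 1L,
                          phase_corruption = 0) {
  scheme <- match.arg(scheme)
  stopifnot(phase_corruption >= 0, phase_corruption <= 1)
  structure(list(scheme = scheme, n_samples = as.integer(n_samples),
                 ranges = ranges, grid_points = grid_points,
                 seed = as.integer(seed),
                 phase_corruption = phase_corruption),
            class = "ndn_sampling_spec")
}

wigner_sigmas <- function(model) {
  if (is.null(model$mode_omegas)) {
    stop("model does not declare mode frequencies for Wigner sampling")
  }
  mu <- model$mode_masses; om <- model$mode_omegas
  list(q = sqrt(1 / (2 * mu * om)), p = sqrt(mu * om / 2))
}

#' Generate an exact synthetic dataset from a diabatic model
#'
#' Samples mode coordinates per the sampling spec, adiabatizes each
#' geometry and (optionally) corrupts the sign of coupled properties with
#' random phase vectors. Deterministic per seed.
#'
#' @param model a [diabatic_model()].
#' @param spec a [sampling_spec()].
#' @return a [dataset()] whose metadata records the model name and spec.
#' @export
generate_dataset <- function(model, spec) {
  qs <- with_preserved_seed(spec$seed, {
    switch(spec$scheme,
      harmonic_wigner = {
        sg <- wigner_sigmas(model)
        matrix(stats::rnorm(spec$n_samples * model$n_modes),
               spec$n_samples, model$n_modes) %*% diag(sg$q, model$n_modes)
      },
      uniform_box = {
        r <- spec$ranges
        sapply(seq_len(model$n_modes), function(m) {
          stats::runif(spec$n_samples, r[m, 1], r[m, 2])
        })
      },
      grid = {
        gp <- spec$grid_points
        axes <- lapply(seq_len(model$n_modes), function(m) {
          seq(spec$ranges[m, 1], spec$ranges[m, 2], length.out = gp[m])
        })
        as.matrix(expand.grid(axes))
      })
  })
  if (!is.matrix(qs)) qs <- matrix(qs, ncol = model$n_modes)
  n <- nrow(qs)
  flips <- with_preserved_seed(spec$seed + 1L, {
    pv <- phase_vectors(model$n_states)
    corrupt <- stats::runif(n) < spec$phase_corruption
    choice <- sample.int(nrow(pv), n, replace = TRUE)
    list(corrupt = corrupt, choice = choice, pv = pv)
  })
  pairs <- state_pairs(model$n_states)
  samples <- vector("list", n)
  for (t in seq_len(n)) {
    smp <- adiabatize(model, qs[t, ])
    if (flips$corrupt[t]) {
      sg <- pair_signs_from_vector(flips$pv[flips$choice[t], ], pairs)
      for (k in seq_len(nrow(pairs))) {
        smp$nacs[k, , ] <- sg[k] * smp$nacs[k, , ]
        smp$smooth_nacs[k, , ] <- sg[k] * smp$smooth_nacs[k, , ]
        if (!is.null(smp$transition_dipoles)) {
          smp$transition_dipoles[k, ] <- sg[k] * smp$transition_dipoles[k, ]
        }
      }
    }
    samples[[t]] <- smp
  }
  dataset(samples, list(provenance = paste0("synthetic:", model$name,
                                            " scheme=", spec$scheme,
                                            " seed=", spec$seed)))
}

#' Harmonic Wigner initial conditions
#'
#' Draws mode coordinates and momenta from the harmonic ground-state
#' Wigner distribution of the declared well (sigma_q^2 = 1/(2 m omega),
#' sigma_p^2 = m omega / 2, atomic units, per mode) and maps them to
#' Cartesian positions and velocities of the pseudo-molecule (velocities
#' solve the bond-rate equations through the Wilson metric, so the mode
#' momenta are exactly realized).
#'
#' @param model a [diabatic_model()] with declared mode frequencies.
#' @param state initial electronic state label (0-based; 1 = S1).
#' @param n number of initial conditions.
#' @param seed RNG seed.
#' @return list of initial conditions: each has `positions`, `velocities`,
#'   `state`, and the drawn mode coordinates/momenta `q`, `p`.
#' @export
sample_initial_conditions <- function(model, state, n, seed = 1L) {
  sg <- wigner_sigmas(model)
  nm <- model$n_modes
  draws <- with_preserved_seed(seed, {
    list(q = matrix(stats::rnorm(n * nm), n, nm) %*% diag(sg$q, nm),
         p = matrix(stats::rnorm(n * nm), n, nm) %*% diag(sg$p, nm))
  })
  lapply(seq_len(n), function(t) {
    q <- draws$q[t, ]; pm <- draws$p[t, ]
    pos <- model_positions(model, q)
    jd <- mode_jacobian(model, pos)
    v <- matrix(0, nrow(pos), 3)
    for (m in seq_len(nm)) v <- v + jd$jac[[m]] * pm[m] / model$masses
    list(positions = pos, velocities = v, state = as.integer(state),
         q = q, p = pm)
  })
}

#' Eigenvector sign change around a closed loop
#'
#' Tracks the lowest pair of adiabatic eigenvectors continuously around a
#' circle in mode space and reports the accumulated sign: -1 if the loop
#' encircles a conical intersection (geometric-phase signature), +1
#' otherwise.
#'
#' @param model a two-or-more-state [diabatic_model()] on >= 2 modes.
#' @param center,radius circle in the first two mode coordinates.
#' @param n_points discretization of the loop.
#' @return +1 or -1.
#' @export
eigenvector_loop_sign <- function(model, center, radius, n_points = 72) {
  ang <- seq(0, 2 * pi, length.out = n_points + 1)
  uprev <- NULL; u0 <- NULL
  for (a in ang) {
    q <- center
    q[1] <- center[1] + radius * cos(a)
    q[2] <- center[2] + radius * sin(a)
    ee <- eigen(model$V(q), symmetric = TRUE)
    u <- ee$vectors[, order(ee$values)[1]]
    if (is.null(uprev)) {
      u0 <- u
    } else if (sum(u * uprev) < 0) {
      u <- -u
    }
    uprev <- u
  }
  sign(sum(uprev * u0))
}
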