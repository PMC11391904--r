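## shared fixtures: built in code, no stored data

rand_rotation <- function() {
  q <- matrix(stats::rnorm(9), 3, 3)
  qq <- qr(q)
  r <- qr.Q(qq) %*% diag(sign(diag(qr.R(qq))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

## all 48 signed permutation matrices (full octahedral group)
octahedral_matrices <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  out <- list()
  for (p in perms) {
    for (r in seq_len(nrow(signs))) {
      m <- matrix(0, 3, 3)
      for (k in 1:3) m[k, p[k]] <- signs[r, k]
      out[[length(out) + 1]] <- m
    }
  }
  out
}

random_geom <- function(n = 4, z = NULL, spread = 1.5) {
  if (is.null(z)) z <- sample(c(1, 6, 7, 8), n, replace = TRUE)
  geometry(z, matrix(stats::rnorm(3 * n, sd = spread), n, 3))
}

tiny_nn <- function(kind = "equivariant", nac_mode = NULL, s = 2,
                    dipoles = TRUE, seed = 7, cutoff = 10) {
  if (is.null(nac_mode)) {
    nac_mode <- if (kind == "invariant") "virtual_derivative" else
      "equivariant_direct"
  }
  create_model(
    rep_config(kind, n_features = 8, n_interactions = 1, cutoff = cutoff,
               n_radial_basis = 6, seed = seed),
    head_config(TRUE, TRUE, TRUE, dipoles, nac_mode = nac_mode),
    state_space(s))
}

## two-state model with constant diagonal gap (never crosses), on a soft
## carbon-stretch mode that the 0.5 fs time step resolves well
gapped_model <- function(gap = 0.1, k = 0.09, coupling = 0) {
  V <- function(q) matrix(c(0.5 * k * q[1]^2, coupling,
                            coupling, 0.5 * k * q[1]^2 + gap), 2, 2)
  dV <- function(q) list(matrix(c(k * q[1], 0, 0, k * q[1]), 2, 2))
  m <- diabatic_model(2, V, dV, atomic_numbers = c(6, 6),
                      ref_positions = rbind(c(0, 0, 0), c(2.3, 0, 0)),
                      bonds = rbind(c(1, 2)), r0 = 2.3, name = "gapped")
  m$mode_omegas <- sqrt(k / m$mode_masses)
  m
}

## soft carbon-diatomic stretch: a slow mode that velocity Verlet at the
## production time step integrates with sub-1e-5 Ha energy error
single_state_model <- function(k = 0.09) {
  V <- function(q) matrix(0.5 * k * q[1]^2, 1, 1)
  dV <- function(q) list(matrix(k * q[1], 1, 1))
  m <- diabatic_model(1, V, dV, atomic_numbers = c(6, 6),
                      ref_positions = rbind(c(0, 0, 0), c(2.3, 0, 0)),
                      bonds = rbind(c(1, 2)), r0 = 2.3, name = "harmonic")
  m$mode_omegas <- sqrt(k / m$mode_masses)
  m
}

## ---- shared heavyweight fixtures for the acceptance suite ---------------
## trained once per session and reused across acceptance blocks

.acc_cache <- new.env(parent = emptyenv())

acc_dataset <- function() {
  if (is.null(.acc_cache$ds)) {
    .acc_cache$model <- model_conical_2d()
    .acc_cache$ds <- generate_dataset(
      .acc_cache$model,
      sampling_spec("harmonic_wigner", 2000, seed = 11,
                    phase_corruption = 1.0))
    .acc_cache$splits <- split_dataset(.acc_cache$ds, c(0.8, 0.1, 0.1),
                                       seed = 7)
  }
  list(model = .acc_cache$model, ds = .acc_cache$ds,
       splits = .acc_cache$splits)
}

## desk-scale training protocol used throughout the validation runs
acc_train_one <- function(kind, seed, splits) {
  rc <- rep_config(kind, n_features = 16, n_interactions = 1, cutoff = 10,
                   n_radial_basis = 8, seed = seed)
  hc <- head_config(TRUE, TRUE, TRUE, FALSE,
                    nac_mode = if (kind == "invariant") "virtual_derivative"
                    else "equivariant_direct")
  mdl <- create_model(rc, hc, state_space(2))
  tc <- train_config(epochs = 80, patience = 300, lr = 3e-3,
                     batch_size = 256, seed = seed,
                     phase_mode = "phase_vector")
  train_model(mdl, splits$train, splits$val, tc)
}

acc_trained <- function(kind, seed) {
  key <- paste0(kind, "_", seed)
  if (is.null(.acc_cache[[key]])) {
    d <- acc_dataset()
    .acc_cache[[key]] <- acc_train_one(kind, seed, d$splits)
  }
  .acc_cache[[key]]
}
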