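test_that("adiabatization reproduces the closed-form two-level solution", {
  c0 <- 0.01
  V <- function(q) matrix(c(q[1], c0, c0, -q[1]), 2, 2)
  dV <- function(q) list(matrix(c(1, 0, 0, -1), 2, 2))
  m <- diabatic_model(2, V, dV, atomic_numbers = c(1, 1),
                      ref_positions = rbind(c(0, 0, 0), c(1.4, 0, 0)),
                      bonds = rbind(c(1, 2)), r0 = 1.4)
  for (x in c(-0.4, 0.05, 0.3)) {
    smp <- adiabatize(m, x)
    expect_equal(smp$energies, c(-1, 1) * sqrt(x^2 + c0^2),
                 tolerance = 1e-12)
  }
  ## at x = 0 the gap is 2 c0
  s0 <- adiabatize(m, 0)
  expect_equal(diff(s0$energies), 2 * c0, tolerance = 1e-12)
})

test_that("a diagonal diabatic matrix gives zero couplings (commuting limit)", {
  V <- function(q) diag(c(0.5 * 0.09 * q[1]^2, 0.5 * 0.09 * q[1]^2 + 0.1))
  dV <- function(q) list(diag(c(0.09 * q[1], 0.09 * q[1])))
  m <- diabatic_model(2, V, dV, atomic_numbers = c(1, 1),
                      ref_positions = rbind(c(0, 0, 0), c(1.4, 0, 0)),
                      bonds = rbind(c(1, 2)), r0 = 1.4)
  smp <- adiabatize(m, 0.2)
  expect_equal(max(abs(smp$nacs)), 0)
  expect_equal(smp$energies, c(0.5 * 0.09 * 0.04, 0.5 * 0.09 * 0.04 + 0.1))
})

test_that("analytic couplings match finite-difference eigenvector overlaps", {
  m <- model_conical_2d()
  q <- c(0.08, 0.12)
  smp <- adiabatize(m, q)
  jd <- getFromNamespace("mode_jacobian", "namdnet")(m,
                                                     smp$geometry$positions)
  gram <- outer(1:2, 1:2, Vectorize(function(k, l) {
    sum(jd$jac[[k]] * jd$jac[[l]])
  }))
  proj <- vapply(1:2, function(k) sum(smp$nacs[1, , ] * jd$jac[[k]]),
                 numeric(1))
  c_modes <- solve(gram, proj)  # mode-space coupling components
  h <- 1e-6
  for (mode in 1:2) {
    qp <- q; qp[mode] <- qp[mode] + h
    qm <- q; qm[mode] <- qm[mode] - h
    up <- eigen(m$V(qp), symmetric = TRUE)
    um <- eigen(m$V(qm), symmetric = TRUE)
    vp <- up$vectors[, order(up$values)]
    vm <- um$vectors[, order(um$values)]
    for (j in 1:2) if (sum(vp[, j] * vm[, j]) < 0) vp[, j] <- -vp[, j]
    nac_fd <- sum(vm[, 1] * (vp[, 2] - vm[, 2])) / (2 * h)
    expect_lt(abs(abs(c_modes[mode]) - abs(nac_fd)),
              1e-5 * max(abs(nac_fd), 1e-8))
  }
})

test_that("analytic forces match finite differences of the eigenvalues", {
  m <- model_conical_2d()
  smp <- adiabatize(m, c(0.1, -0.15))
  pos <- smp$geometry$positions
  h <- 1e-5
  for (a in 1:3) {
    for (x in 1:3) {
      pp <- pos; pp[a, x] <- pp[a, x] + h
      pm <- pos; pm[a, x] <- pm[a, x] - h
      ep <- adiabatize(m, geometry(m$atomic_numbers, pp))$energies
      em <- adiabatize(m, geometry(m$atomic_numbers, pm))$energies
      fd <- -(ep - em) / (2 * h)
      for (j in 1:2) {
        expect_lt(abs(smp$forces[j, a, x] - fd[j]),
                  1e-6 * max(abs(fd[j]), 1e-4))
      }
    }
  }
})

test_that("the conical model has an exact seam with divergent raw couplings", {
  m <- model_conical_2d()
  gap <- diff(eigen(m$V(m$seam), symmetric = TRUE)$values)
  expect_lt(abs(gap), 1e-12)
  ## raw couplings blow up approaching the seam, smoothed ones stay bounded
  near <- m$seam + c(0, 1e-4)
  smp <- adiabatize(m, near)
  expect_gt(max(abs(smp$nacs)), 1e3)
  expect_lt(max(abs(smp$smooth_nacs)), 1)
  far <- adiabatize(m, m$seam + c(0, 0.3))
  expect_lt(max(abs(far$nacs)), max(abs(smp$nacs)) / 100)
  ## exactly at the seam the raw coupling is flagged singular
  expect_error(adiabatize(m, m$seam), "singular")
})

test_that("the avoided-crossing model reduces to two shifted wells without coupling", {
  m0 <- model_avoided_crossing_1d(coupling = 0)
  k <- 0.09; q0 <- 0.5; eps <- 0.01
  for (q in c(-0.2, 0.1, 0.8)) {
    smp <- adiabatize(m0, q)
    diab <- c(0.5 * k * q^2, 0.5 * k * (q - q0)^2 + eps)
    expect_equal(smp$energies, sort(diab), tolerance = 1e-12)
  }
})

test_that("eigenvector transport around the seam flips sign (geometric phase)", {
  m <- model_conical_2d()
  expect_equal(eigenvector_loop_sign(m, m$seam, 0.05), -1)
  expect_equal(eigenvector_loop_sign(m, m$seam + c(0.3, 0.3), 0.05), 1)
})

test_that("every generated sample is self-consistent", {
  m <- model_conical_2d()
  ds <- generate_dataset(m, sampling_spec("harmonic_wigner", 25, seed = 9,
                                          phase_corruption = 0.5))
  for (smp in ds$samples) {
    expect_equal(smp$smooth_nacs,
                 smooth_nacs_op(smp$nacs, smp$energies, smp$state_space),
                 tolerance = 1e-12)
    expect_true(all(diff(smp$energies) > 0))
  }
  ## determinism
  ds2 <- generate_dataset(m, sampling_spec("harmonic_wigner", 25, seed = 9,
                                           phase_corruption = 0.5))
  expect_identical(ds2$samples[[7]]$smooth_nacs, ds$samples[[7]]$smooth_nacs)
})

test_that("phase corruption flips signs but leaves physics invariant", {
  m <- model_conical_2d()
  clean <- generate_dataset(m, sampling_spec("harmonic_wigner", 200,
                                             seed = 12))
  dirty <- generate_dataset(m, sampling_spec("harmonic_wigner", 200,
                                             seed = 12,
                                             phase_corruption = 1))
  flips <- vapply(1:200, function(i) {
    s <- sign(sum(dirty$samples[[i]]$smooth_nacs *
                    clean$samples[[i]]$smooth_nacs))
    s < 0
  }, logical(1))
  ## S = 2: a uniform random phase vector flips the pair half the time
  expect_gt(mean(flips), 0.5 - 3 * sqrt(0.25 / 200))
  expect_lt(mean(flips), 0.5 + 3 * sqrt(0.25 / 200))
  for (i in c(1, 50, 200)) {
    expect_identical(dirty$samples[[i]]$energies, clean$samples[[i]]$energies)
    expect_equal(abs(dirty$samples[[i]]$nacs), abs(clean$samples[[i]]$nacs),
                 tolerance = 1e-15)
  }
})

test_that("Wigner initial conditions have the harmonic ground-state moments", {
  m <- model_conical_2d()
  n <- 10000
  ics <- sample_initial_conditions(m, 1, n, seed = 4)
  sg <- getFromNamespace("wigner_sigmas", "namdnet")(m)
  for (mode in 1:2) {
    qs <- vapply(ics, function(x) x$q[mode], numeric(1))
    ps <- vapply(ics, function(x) x$p[mode], numeric(1))
    se_var <- function(s2) s2 * sqrt(2 / (n - 1))
    expect_lt(abs(var(qs) - sg$q[mode]^2), 3 * se_var(sg$q[mode]^2))
    expect_lt(abs(var(ps) - sg$p[mode]^2), 3 * se_var(sg$p[mode]^2))
    expect_lt(abs(mean(qs)), 3 * sg$q[mode] / sqrt(n))
  }
  ## the Cartesian realization reproduces the drawn mode values exactly
  ic <- ics[[11]]
  expect_equal(model_coords(m, ic$positions), ic$q, tolerance = 1e-12)
  jd <- getFromNamespace("mode_jacobian", "namdnet")(m, ic$positions)
  qdot <- vapply(1:2, function(k) sum(jd$jac[[k]] * ic$velocities),
                 numeric(1))
  G <- getFromNamespace("mode_metric", "namdnet")(m, ic$positions)
  expect_equal(as.numeric(solve(G, qdot)), ic$p, tolerance = 1e-10)
})

test_that("grid and uniform sampling cover the requested ranges deterministically", {
  m <- model_conical_2d()
  sp <- sampling_spec("grid", ranges = rbind(c(-0.1, 0.1), c(-0.2, 0.2)),
                      grid_points = c(3, 5), seed = 1)
  ds <- generate_dataset(m, sp)
  expect_equal(length(ds$samples), 15)
  qs <- t(vapply(ds$samples, function(s) model_coords(m, s$geometry$positions),
                 numeric(2)))
  expect_equal(sort(unique(round(qs[, 1], 10))), c(-0.1, 0, 0.1))
  du <- generate_dataset(m, sampling_spec("uniform_box", 50,
                                          ranges = rbind(c(-0.1, 0.1),
                                                         c(-0.2, 0.2)),
                                          seed = 2))
  qu <- t(vapply(du$samples, function(s) model_coords(m, s$geometry$positions),
                 numeric(2)))
  expect_true(all(qu[, 1] >= -0.1 & qu[, 1] <= 0.1))
  expect_true(all(qu[, 2] >= -0.2 & qu[, 2] <= 0.2))
})
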