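test_that("velocity Verlet: free motion is exact, the oscillator conserves energy", {
  masses <- c(1837, 1837)
  st <- sh_state(rbind(c(0, 0, 0), c(1.4, 0, 0)),
                 rbind(c(0.001, 0, 0), c(0, 0.002, 0)), masses, 0, 1)
  free <- function(pos) list(energy = 0, forces = matrix(0, 2, 3))
  st1 <- velocity_verlet_step(st, free, 10)
  expect_equal(st1$positions, st$positions + 10 * st$velocities)
  expect_equal(st1$velocities, st$velocities)
  expect_equal(st1$time, 10)

  ## 1D harmonic oscillator, 1000 steps at dt = T/100
  k <- 0.09; mu <- 1837 / 2
  omega <- sqrt(k / mu)
  dt <- (2 * pi / omega) / 100
  spring <- function(pos) {
    q <- pos[2, 1] - pos[1, 1] - 1.4
    f <- matrix(0, 2, 3)
    f[2, 1] <- -k * q; f[1, 1] <- k * q
    list(energy = 0.5 * k * q^2, forces = f)
  }
  st <- sh_state(rbind(c(0, 0, 0), c(1.55, 0, 0)), matrix(0, 2, 3),
                 masses, 0, 1)
  etot <- function(s) {
    q <- s$positions[2, 1] - s$positions[1, 1] - 1.4
    0.5 * k * q^2 + kinetic_energy_of(s)
  }
  kinetic_energy_of <- function(s) 0.5 * sum(s$masses * rowSums(s$velocities^2))
  e0 <- etot(st)
  s2 <- st
  for (i in 1:1000) s2 <- velocity_verlet_step(s2, spring, dt)
  expect_lt(abs(etot(s2) - e0) / e0, 1e-5)

  ## time reversibility: reverse velocities and integrate back
  s3 <- s2
  s3$velocities <- -s3$velocities
  for (i in 1:1000) s3 <- velocity_verlet_step(s3, spring, dt)
  expect_equal(s3$positions, st$positions, tolerance = 1e-10)
  expect_error(velocity_verlet_step(st, function(p) {
    list(energy = 0, forces = matrix(NaN, 2, 3))
  }, dt), "non-finite")
})

test_that("electronic propagation: pure phases without coupling, unit norm always", {
  c0 <- c(1 / sqrt(2) + 0i, 1 / sqrt(2) + 0i)
  w0 <- matrix(0, 2, 2)
  c1 <- propagate_coefficients(c0, c(0, 0.1), c(0, 0.1), w0, w0, 1, 25)
  expect_equal(Mod(c1), Mod(c0), tolerance = 1e-12)
  expect_equal(Arg(c1[2]) - Arg(c0[2]), -0.1, tolerance = 1e-10)
  expect_equal(Arg(c1[1]), 0, tolerance = 1e-10)
  ## norm conservation over many random steps
  set.seed(33)
  cc <- c(1 + 0i, 0i, 0i)
  for (i in 1:2000) {
    w <- matrix(0, 3, 3)
    w[upper.tri(w)] <- rnorm(3, sd = 0.02)
    w <- w - t(w)
    e <- rnorm(3, sd = 0.1)
    cc <- propagate_coefficients(cc, e, e + rnorm(3, sd = 0.01), w, w,
                                 runif(1, 5, 30), 5)
    expect_lt(abs(sum(Mod(cc)^2) - 1), 1e-8)
  }
})

test_that("two-level dynamics reproduces the closed-form Rabi solution", {
  w12 <- 0.015
  w <- matrix(c(0, w12, -w12, 0), 2, 2)
  e <- c(0.05, 0.05)
  cc <- c(1 + 0i, 0i)
  tt <- 60
  out <- propagate_coefficients(cc, e, e, w, w, tt, 400)
  expect_equal(Mod(out[2])^2, sin(w12 * tt)^2, tolerance = 1e-6)
  expect_equal(Mod(out[1])^2, cos(w12 * tt)^2, tolerance = 1e-6)
  ## with a gap: compare against the matrix exponential of the generator
  e2 <- c(0, 0.2)
  h <- diag(e2) - 1i * w
  ee <- eigen(h)
  u <- ee$vectors %*% diag(exp(-1i * ee$values * tt)) %*% solve(ee$vectors)
  ref <- as.complex(u %*% cc)
  out2 <- propagate_coefficients(cc, e2, e2, w, w, tt, 400)
  expect_equal(Mod(out2), Mod(ref), tolerance = 1e-6)
})

test_that("hop probabilities clamp, normalize, and vanish without coupling", {
  cc <- c(sqrt(0.7) + 0i, sqrt(0.3) + 0i)
  expect_equal(hop_probabilities(cc, 0, matrix(0, 2, 2), 10), c(0, 0))
  w <- matrix(c(0, 0.02, -0.02, 0), 2, 2, byrow = TRUE)  # W_01 = +0.02
  g <- hop_probabilities(cc, 0, w, 10)
  expect_equal(g[1], 0)
  expect_gt(g[2], 0)
  ## reversed coupling sign: negative flux clamps to zero
  g2 <- hop_probabilities(cc, 0, -w, 10)
  expect_equal(g2[2], 0)
  ## huge dt cannot push the total above one
  g3 <- hop_probabilities(cc, 0, w, 1e5)
  expect_lte(sum(g3), 1)
  expect_warning(hop_probabilities(c(0i, 1 + 0i), 0, w, 10), "1e-12")
})

test_that("accepted hops rescale along the coupling vector and conserve energy", {
  masses <- c(1837, 1837)
  nacs <- array(0, c(1, 2, 3))
  nacs[1, , 1] <- c(1, -1)  # along x
  st <- sh_state(rbind(c(0, 0, 0), c(1.4, 0, 0)),
                 rbind(c(-5e-4, 0, 0), c(5e-4, 0, 0)), masses, 1, 2)
  en <- c(0, 0.01)  # hop down by 0.01 Ha
  ke0 <- 0.5 * sum(masses * rowSums(st$velocities^2))
  res <- attempt_hop(st, c(1, 0), en, nacs, draw = 0.5)
  expect_equal(res$record$outcome, "accepted")
  expect_equal(res$state$active, 0L)
  ke1 <- 0.5 * sum(masses * rowSums(res$state$velocities^2))
  expect_equal(ke1 - ke0, 0.01, tolerance = 1e-9)
  ## only the x components changed
  expect_equal(res$state$velocities[, 2:3], st$velocities[, 2:3])

  ## uphill hop beyond the available projected kinetic energy is frustrated
  st2 <- sh_state(rbind(c(0, 0, 0), c(1.4, 0, 0)),
                  rbind(c(-1e-5, 0, 0), c(1e-5, 0, 0)), masses, 0, 2)
  en2 <- c(0, 0.05)
  res2 <- attempt_hop(st2, c(0, 1), en2, nacs, draw = 0.1)
  expect_equal(res2$record$outcome, "frustrated")
  expect_equal(res2$state$active, 0L)
  expect_equal(res2$state$velocities, st2$velocities)
  ## reflect policy reverses the projected component, conserving energy
  res3 <- attempt_hop(st2, c(0, 1), en2, nacs, draw = 0.1,
                      frustrated = "reflect")
  ke_r <- 0.5 * sum(masses * rowSums(res3$state$velocities^2))
  ke_0 <- 0.5 * sum(masses * rowSums(st2$velocities^2))
  expect_equal(ke_r, ke_0, tolerance = 1e-12)
  expect_equal(res3$state$velocities[, 1], -st2$velocities[, 1],
               tolerance = 1e-12)
  ## zero probabilities: no hop attempted
  res4 <- attempt_hop(st2, c(0, 0), en2, nacs, draw = 0.99)
  expect_equal(res4$record$outcome, "none")
})

test_that("hop statistics agree with the coherent population transfer", {
  ## slow two-state crossing emulated by a smooth coupling pulse; the
  ## integrated fewest-switches hop fraction must match the population
  ## moved by the coefficient propagation
  set.seed(34)
  n <- 2000
  dt <- 0.25; nstep <- 400
  cc <- c(1 + 0i, 0i)
  draws <- matrix(runif(nstep * n), nstep, n)
  alive <- rep(TRUE, n)
  hopped <- 0
  for (s in 1:nstep) {
    t <- (s - 0.5) * dt
    wt <- 0.025 * exp(-((t - 50) / 12)^2)
    w <- matrix(c(0, wt, -wt, 0), 2, 2)
    cc <- propagate_coefficients(cc, c(0, 0.001), c(0, 0.001), w, w, dt, 5)
    g <- hop_probabilities(cc, 0, w, dt)
    newly <- alive & (draws[s, ] < g[2])
    hopped <- hopped + sum(newly)
    alive <- alive & !newly
  }
  transfer <- Mod(cc[2])^2
  expect_gt(transfer, 0.1)
  expect_lt(abs(hopped / n - transfer), 0.02)
})

test_that("trajectories on a single surface hop never and conserve energy", {
  m1 <- single_state_model()
  ics <- sample_initial_conditions(m1, 0, 3, seed = 5)
  conf <- sh_config(t_max_fs = 100, dt_fs = 0.5, seed = 1)
  traj <- run_ensemble(exact_provider(m1), ics, m1$masses, 1, conf)
  expect_equal(nrow(traj$hops), 0)
  drift <- max(abs(traj$etot - traj$etot[, 1]), na.rm = TRUE)
  expect_lt(drift, 1e-5)
  expect_true(all(traj$valid))
})

test_that("zero coupling keeps the initial state populated", {
  m <- gapped_model(coupling = 0)
  ics <- sample_initial_conditions(m, 1, 4, seed = 6)
  conf <- sh_config(t_max_fs = 50, seed = 2)
  traj <- run_ensemble(exact_provider(m), ics, m$masses, 2, conf)
  expect_true(all(traj$active == 1L))
  pops <- ensemble_populations(traj)
  expect_true(all(pops$population[pops$state == 1] == 1))
})

test_that("ensembles are reproducible from the seed and count populations correctly", {
  m <- model_conical_2d()
  ics <- sample_initial_conditions(m, 1, 6, seed = 7)
  conf <- sh_config(t_max_fs = 30, seed = 11)
  t1 <- run_ensemble(exact_provider(m), ics, m$masses, 2, conf)
  t2 <- run_ensemble(exact_provider(m), ics, m$masses, 2, conf)
  expect_identical(t1$hops, t2$hops)
  expect_identical(t1$active, t2$active)
  pops <- ensemble_populations(t1)
  it <- length(t1$time_fs)
  expect_equal(pops$population[pops$time_fs == t1$time_fs[it] &
                                 pops$state == 1],
               mean(t1$active[, it] == 1))
  ## rows sum to one over contributing trajectories
  sums <- tapply(pops$population, pops$time_fs, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("sequential kinetics fitting recovers synthetic lifetimes within 1%", {
  tgrid <- seq(0, 150, by = 0.5)
  ns <- asNamespace("namdnet")
  pop <- ns$sequential_populations(tgrid, c(1 / 50, 1 / 20))
  fit <- fit_sequential_kinetics(pop, tgrid, 3)
  expect_lt(abs(fit$tau_fs[1] - 50) / 50, 0.01)
  expect_lt(abs(fit$tau_fs[2] - 20) / 20, 0.01)
  ## with sampling noise the recovery degrades gracefully
  set.seed(35)
  noisy <- pmin(pmax(pop + matrix(rnorm(length(pop), sd = 0.01),
                                  nrow(pop)), 0), 1)
  fit2 <- fit_sequential_kinetics(noisy, tgrid, 3)
  expect_lt(abs(fit2$tau_fs[2] - 20) / 20, 0.1)
  ## zero rates: constant populations yield an infinite-lifetime flag
  flat <- matrix(c(rep(0, length(tgrid)), rep(0, length(tgrid)),
                   rep(1, length(tgrid))), ncol = 3)
  fit3 <- fit_sequential_kinetics(flat, tgrid, 3)
  expect_true(fit3$no_decay)
  expect_true(all(is.infinite(fit3$tau_fs)))
  ## flat but not at unity: not identifiable
  bad <- matrix(0.5, length(tgrid), 2)
  expect_error(fit_sequential_kinetics(bad, tgrid, 2), "identifiable")
  ## uniform time rescaling rescales the lifetimes consistently
  fit4 <- fit_sequential_kinetics(pop, tgrid * 2, 3)
  expect_equal(fit4$tau_fs, fit$tau_fs * 2, tolerance = 1e-6)
})
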