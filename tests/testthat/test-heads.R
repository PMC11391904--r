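test_that("predicted energies are invariant, forces and couplings covariant", {
  set.seed(11)
  for (kind in c("invariant", "equivariant")) {
    mdl <- tiny_nn(kind)
    g <- random_geom(4)
    pr <- predict_all(mdl, g)
    R <- rand_rotation(); tr <- rnorm(3)
    g2 <- geometry(g$atomic_numbers, g$positions %*% t(R) +
                     rep(tr, each = 4))
    pr2 <- predict_all(mdl, g2)
    expect_equal(pr2$energies, pr$energies, tolerance = 1e-6)
    for (j in 1:2) {
      expect_equal(pr2$forces[j, , ], pr$forces[j, , ] %*% t(R),
                   tolerance = 1e-5)
    }
    expect_equal(pr2$smooth_nacs[1, , ], pr$smooth_nacs[1, , ] %*% t(R),
                 tolerance = 1e-5)
    expect_equal(pr2$permanent_dipoles, pr$permanent_dipoles %*% t(R),
                 tolerance = 1e-5)
    expect_equal(pr2$transition_dipoles, pr$transition_dipoles %*% t(R),
                 tolerance = 1e-5)
  }
})

test_that("all vector outputs are exactly covariant under the octahedral group", {
  set.seed(12)
  mdl <- tiny_nn("equivariant")
  g <- random_geom(3)
  pr <- predict_all(mdl, g)
  for (Q in octahedral_matrices()) {
    g2 <- geometry(g$atomic_numbers, g$positions %*% t(Q))
    pr2 <- predict_all(mdl, g2)
    expect_equal(pr2$forces[1, , ], pr$forces[1, , ] %*% t(Q),
                 tolerance = 1e-8)
    expect_equal(pr2$smooth_nacs[1, , ], pr$smooth_nacs[1, , ] %*% t(Q),
                 tolerance = 1e-8)
    expect_equal(pr2$transition_dipoles, pr$transition_dipoles %*% t(Q),
                 tolerance = 1e-8)
  }
})

test_that("forces are exact derivatives: finite differences and zero net force", {
  set.seed(13)
  for (kind in c("invariant", "equivariant")) {
    mdl <- tiny_nn(kind, dipoles = FALSE)
    g <- random_geom(3)
    pr <- predict_all(mdl, g, need = c("energies", "forces"))
    h <- 1e-4
    for (a in 1:3) {
      for (x in 1:3) {
        pp <- g$positions; pp[a, x] <- pp[a, x] + h
        pm <- g$positions; pm[a, x] <- pm[a, x] - h
        ep <- predict_energies(mdl, geometry(g$atomic_numbers, pp))
        em <- predict_energies(mdl, geometry(g$atomic_numbers, pm))
        fd <- -(ep - em) / (2 * h)
        for (j in 1:2) {
          expect_lt(abs(pr$forces[j, a, x] - fd[j]),
                    1e-4 * max(abs(fd[j]), 1e-6))
        }
      }
    }
    expect_lt(max(abs(colSums(pr$forces[1, , ]))), 1e-8)
    expect_lt(max(abs(colSums(pr$forces[2, , ]))), 1e-8)
  }
})

test_that("virtual-derivative couplings are the exact gradient of the virtual scalar", {
  set.seed(14)
  mdl <- tiny_nn("invariant", nac_mode = "virtual_derivative",
                 dipoles = FALSE)
  g <- random_geom(3)
  pr <- predict_all(mdl, g, need = "smooth_nacs")
  virt_scalar <- function(pos) {
    b <- getFromNamespace("make_batch", "namdnet")(
      list(geometry(g$atomic_numbers, pos)), mdl$rep$cutoff)
    fw <- getFromNamespace("model_forward", "namdnet")(
      mdl, b, need = "smooth_nacs")
    fw$virtual$value[1, 1]
  }
  h <- 1e-4
  for (a in 1:3) {
    for (x in 1:3) {
      pp <- g$positions; pp[a, x] <- pp[a, x] + h
      pm <- g$positions; pm[a, x] <- pm[a, x] - h
      fd <- (virt_scalar(pp) - virt_scalar(pm)) / (2 * h)
      expect_lt(abs(pr$smooth_nacs[1, a, x] - fd),
                1e-4 * max(abs(fd), 1e-6))
    }
  }
})

test_that("energies are size-consistent for well-separated fragments", {
  set.seed(15)
  mdl <- tiny_nn("equivariant", dipoles = FALSE, cutoff = 4)
  f1 <- matrix(rnorm(6, sd = 0.8), 2, 3)
  f2 <- matrix(rnorm(6, sd = 0.8), 2, 3) + 50
  z1 <- c(6, 1); z2 <- c(8, 1)
  e1 <- predict_energies(mdl, geometry(z1, f1))
  e2 <- predict_energies(mdl, geometry(z2, f2))
  ec <- predict_energies(mdl, geometry(c(z1, z2), rbind(f1, f2)))
  expect_equal(ec, e1 + e2 - mdl$offsets, tolerance = 1e-8)
})

test_that("dipoles obey the charge-model sum rules and translation invariance", {
  set.seed(16)
  mdl <- tiny_nn("equivariant")
  g <- random_geom(4)
  g <- geometry(g$atomic_numbers, g$positions, total_charge = 1L)
  pr <- predict_dipoles(mdl, g)
  s <- 2; p <- 1
  ## batch charges: first s columns permanent (sum to total charge after
  ## recentering), next p transition (sum to zero)
  b <- getFromNamespace("make_batch", "namdnet")(list(g), mdl$rep$cutoff)
  fw <- getFromNamespace("model_forward", "namdnet")(mdl, b, need = "dipoles")
  for (j in 1:s) {
    qsum_raw <- sum(fw$charges$value[, j])
    mu_manual <- colSums((fw$charges$value[, j] +
                            (1 - qsum_raw) / 4) *
                           sweep(g$positions, 2, colMeans(g$positions)))
    expect_equal(pr$permanent_dipoles[j, ], mu_manual, tolerance = 1e-10)
  }
  gt <- geometry(g$atomic_numbers, g$positions + 5, total_charge = 1L)
  prt <- predict_dipoles(mdl, gt)
  expect_equal(prt$transition_dipoles, pr$transition_dipoles,
               tolerance = 1e-10)
})

test_that("classical NACs delegate to the un-smoothing rule; errors are explicit", {
  set.seed(17)
  mdl <- tiny_nn("equivariant", dipoles = FALSE)
  g <- random_geom(3)
  pr <- predict_all(mdl, g)
  out <- to_classical_nacs(pr, gap_floor = 1e-8)
  expect_equal(out$nacs,
               unsmooth_nacs_op(pr$smooth_nacs, pr$energies, 2, 1e-8),
               tolerance = 1e-15)
  pr$smooth_nacs <- NULL
  expect_error(to_classical_nacs(pr), "lacks")
  mdl_e <- create_model(rep_config("equivariant", n_features = 8,
                                   n_interactions = 1, n_radial_basis = 6),
                        head_config(TRUE, FALSE, FALSE, FALSE),
                        state_space(2))
  expect_error(predict_all(mdl_e, g, need = "smooth_nacs"), "no NAC head")
  expect_error(create_model(rep_config("invariant"),
                            head_config(TRUE, TRUE, TRUE, FALSE,
                                        nac_mode = "equivariant_direct"),
                            state_space(2)),
               "equivariant")
})

test_that("a batch of predictions equals the same geometries predicted singly", {
  set.seed(18)
  mdl <- tiny_nn("equivariant")
  geoms <- lapply(1:4, function(i) random_geom(3, z = c(6, 1, 1)))
  batched <- predict_all(mdl, geoms)
  for (i in 1:4) {
    single <- predict_all(mdl, geoms[[i]])
    expect_equal(batched[[i]]$energies, single$energies, tolerance = 1e-10)
    expect_equal(batched[[i]]$forces, single$forces, tolerance = 1e-10)
    expect_equal(batched[[i]]$smooth_nacs, single$smooth_nacs,
                 tolerance = 1e-10)
    expect_equal(batched[[i]]$transition_dipoles, single$transition_dipoles,
                 tolerance = 1e-10)
  }
})
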