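const_target_ds <- function(n = 40) {
  ss <- state_space(2)
  smps <- lapply(seq_len(n), function(i) {
    g <- geometry(c(6, 1), rbind(c(0, 0, 0),
                                 c(1.6 + 0.4 * sin(i), 0.1 * cos(i), 0)))
    multistate_sample(g, ss, energies = c(-0.5, 0.25))
  })
  dataset(smps)
}

energy_only_nn <- function(seed = 2) {
  create_model(rep_config("invariant", n_features = 8, n_interactions = 1,
                          n_radial_basis = 6, seed = seed),
               head_config(TRUE, FALSE, FALSE, FALSE), state_space(2))
}

test_that("a constant-target dataset is learned to below 1e-6 within 200 epochs", {
  ds <- const_target_ds()
  sp <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = 1)
  tc <- train_config(epochs = 200, patience = 300, lr = 3e-3,
                     batch_size = 16, seed = 1)
  mdl <- train_model(energy_only_nn(), sp$train, sp$val, tc)
  hist <- attr(mdl, "history")
  expect_lt(min(hist$val_loss), 1e-6)
})

test_that("patience stops a frozen model after exactly that many flat epochs", {
  ds <- const_target_ds(20)
  sp <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 1)
  tc <- train_config(epochs = 100, patience = 4, lr = 0, batch_size = 16,
                     seed = 1)
  mdl <- train_model(energy_only_nn(), sp$train, sp$val, tc)
  expect_equal(nrow(attr(mdl, "history")), 1 + 4)
  expect_equal(attr(mdl, "best_epoch"), 1)
})

test_that("training is reproducible from the seed", {
  ds <- const_target_ds(24)
  sp <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 2)
  tc <- train_config(epochs = 10, patience = 300, lr = 2e-3,
                     batch_size = 8, seed = 42)
  m1 <- train_model(energy_only_nn(), sp$train, sp$val, tc)
  m2 <- train_model(energy_only_nn(), sp$train, sp$val, tc)
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  expect_identical(m1$params, m2$params)
})

test_that("the returned checkpoint is the best-validation one", {
  ds <- const_target_ds(30)
  sp <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 3)
  tc <- train_config(epochs = 30, patience = 300, lr = 5e-3,
                     batch_size = 8, seed = 9)
  mdl <- train_model(energy_only_nn(), sp$train, sp$val, tc)
  hist <- attr(mdl, "history")
  best <- attr(mdl, "best_epoch")
  expect_equal(hist$val_loss[best], min(hist$val_loss))
  ## re-evaluating the returned parameters reproduces the best loss
  ev <- evaluate_model(mdl, sp$val)
  mse <- ev$rmse[ev$property == "energies"]^2
  expect_equal(mse, min(hist$val_loss), tolerance = 1e-10)
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- const_target_ds(20)
  sp <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 1)
  tc <- train_config(epochs = 50, patience = 300, lr = 1e200,
                     batch_size = 16, seed = 1, grad_clip = Inf)
  expect_error(train_model(energy_only_nn(), sp$train, sp$val, tc),
               "diverged")
})

test_that("parameter gradients of the combined loss match finite differences", {
  set.seed(30)
  cm <- model_conical_2d()
  ds <- generate_dataset(cm, sampling_spec("harmonic_wigner", 6, seed = 5))
  mdl <- tiny_nn("equivariant", dipoles = FALSE)
  ns <- asNamespace("namdnet")
  b <- ns$make_batch(lapply(ds$samples, `[[`, "geometry"), mdl$rep$cutoff)
  tg <- ns$batch_targets(ds$samples, b, mdl$states)
  tc <- train_config(phase_mode = "none")
  loss_of <- function(m) {
    fw <- ns$model_forward(m, b, need = c("energies", "forces",
                                          "smooth_nacs"))
    ns$batch_loss_node(m, fw, b, tg, tc)$value[1]
  }
  fw <- ns$model_forward(mdl, b, need = c("energies", "forces",
                                          "smooth_nacs"),
                         track_params = TRUE)
  loss <- ns$batch_loss_node(mdl, fw, b, tg, tc)
  grads <- ns$ag_grad(loss, fw$params)
  h <- 1e-5
  for (nm in c("emb", "b1_Wf", "b1_U", "We2", "bg2")) {
    k <- match(nm, names(mdl$params))
    gmat <- grads[[k]]$value
    idx <- which(abs(gmat) == max(abs(gmat)), arr.ind = TRUE)[1, ]
    mp <- mdl; mp$params[[nm]][idx[1], idx[2]] <-
      mp$params[[nm]][idx[1], idx[2]] + h
    mm <- mdl; mm$params[[nm]][idx[1], idx[2]] <-
      mm$params[[nm]][idx[1], idx[2]] - h
    fd <- (loss_of(mp) - loss_of(mm)) / (2 * h)
    expect_equal(gmat[idx[1], idx[2]], fd,
                 tolerance = 1e-4 * max(abs(fd), 1e-8))
  }
})

test_that("evaluation scores match an independent recomputation", {
  set.seed(31)
  cm <- model_conical_2d()
  ds <- generate_dataset(cm, sampling_spec("harmonic_wigner", 20, seed = 6))
  mdl <- tiny_nn("equivariant")
  ev <- evaluate_model(mdl, ds)
  expect_true(all(ev$rmse >= ev$mae - 1e-12))
  ## brute force, per sample, phase-optimal scoring
  abs_e <- c(); abs_n <- c()
  for (smp in ds$samples) {
    pr <- predict_all(mdl, smp$geometry)
    abs_e <- c(abs_e, abs(pr$energies - smp$energies))
    d_plus <- sum(abs(pr$smooth_nacs[1, , ] - smp$smooth_nacs[1, , ])^2) +
      sum(abs(pr$transition_dipoles[1, ] - smp$transition_dipoles[1, ])^2)
    d_minus <- sum(abs(pr$smooth_nacs[1, , ] + smp$smooth_nacs[1, , ])^2) +
      sum(abs(pr$transition_dipoles[1, ] + smp$transition_dipoles[1, ])^2)
    sg <- if (d_plus <= d_minus) 1 else -1
    abs_n <- c(abs_n, abs(pr$smooth_nacs[1, , ] - sg * smp$smooth_nacs[1, , ]))
  }
  expect_equal(ev$mae[ev$property == "energies"], mean(abs_e),
               tolerance = 1e-12)
  expect_equal(ev$mae[ev$property == "smooth_nacs"], mean(abs_n),
               tolerance = 1e-12)
  ## constant offset on energies gives MAE = RMSE = offset
  perfect <- ds
  ds0 <- dataset(lapply(ds$samples, function(s) {
    pr <- predict_all(mdl, s$geometry)
    multistate_sample(s$geometry, s$state_space,
                      energies = pr$energies + 0.3)
  }))
  ev0 <- evaluate_model(mdl, ds0)
  expect_equal(ev0$mae[ev0$property == "energies"], 0.3, tolerance = 1e-9)
  expect_equal(ev0$rmse[ev0$property == "energies"], 0.3, tolerance = 1e-9)
})
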