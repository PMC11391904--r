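#' Training configuration
#'
#' @param epochs maximum number of epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (samples).
#' @param seed RNG seed; training is fully reproducible from (seed, config,
#'   split).
#' @param phase_mode phase handling for coupled properties: "none",
#'   "pairwise" or "phase_vector".
#' @param weights named loss weights `c(E=, F=, C=, mu=)`.
#' @param atomistic if `TRUE`, per-atom normalization of the coupled-state
#'   losses before reduction.
#' @param grad_clip global gradient-norm clip (`Inf` to disable).
#' @return object of class `ndn_train_config`.
#' @export
train_config <- function(epochs = 500L, patience = 300L, lr = 1e-3,
                         batch_size = 128L, seed = 1L,
                         phase_mode = c("phase_vector", "pairwise", "none"),
                         weights = c(E = 1, F = 1, C = 1, mu = 1),
                         atomistic = FALSE, grad_clip = 10) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(patience >= 1, epochs >= 1, lr >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), patience = as.integer(patience),
                 lr = lr, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), phase_mode = phase_mode,
                 weights = weights, atomistic = atomistic,
                 grad_clip = grad_clip),
            class = "ndn_train_config")
}

## stack reference arrays of a set of samples to batch layout
batch_targets <- function(samples, batch, states) {
  s <- states$n_states; p <- n_pairs(states)
  nm <- batch$n_mol; natm <- batch$n_atoms
  tg <- list()
  if (!is.null(samples[[1]]$energies)) {
    tg$energies <- t(vapply(samples, `[[`, numeric(s), "energies"))
    if (nm == 1) tg$energies <- matrix(tg$energies, 1, s)
  }
  if (!is.null(samples[[1]]$forces)) {
    tg$forces <- lapply(seq_len(s), function(j) {
      do.call(rbind, lapply(samples, function(x) x$forces[j, , , drop = TRUE]))
    })
  }
  if (!is.null(samples[[1]]$smooth_nacs)) {
    tg$smooth_nacs <- lapply(seq_len(p), function(k) {
      do.call(rbind, lapply(samples, function(x) {
        matrix(x$smooth_nacs[k, , ], ncol = 3)
      }))
    })
  }
  if (!is.null(samples[[1]]$permanent_dipoles)) {
    tg$permanent_dipoles <- lapply(seq_len(s), function(j) {
      t(vapply(samples, function(x) x$permanent_dipoles[j, ], numeric(3)))
    })
    tg$transition_dipoles <- lapply(seq_len(p), function(k) {
      t(vapply(samples, function(x) x$transition_dipoles[k, ], numeric(3)))
    })
  }
  tg
}

## build the scalar loss node for one batch; signs for coupled properties
## are chosen from current values (constant during differentiation)
batch_loss_node <- function(model, fw, batch, tg, cfg) {
  s <- model$states$n_states
  p <- n_pairs(model$states)
  w <- cfg$weights
  terms <- list()
  mse_node <- function(prednode, refmat, rowweight = NULL) {
    d <- ag_sub(prednode, ag_const(refmat))
    sq <- ag_square(d)
    if (!is.null(rowweight)) sq <- ag_mul(sq, ag_const(rowweight))
    ag_div(ag_sum_all(sq), ag_const(matrix(length(refmat), 1, 1)))
  }
  if (!is.null(tg$energies)) {
    terms$E <- ag_mul(ag_const(matrix(w[["E"]], 1, 1)),
                      mse_node(fw$energies, tg$energies))
  }
  if (!is.null(tg$forces) && !is.null(fw$forces)) {
    fsum <- NULL
    for (j in seq_len(s)) {
      t <- ag_sum_all(ag_square(ag_sub(fw$forces[[j]],
                                       ag_const(tg$forces[[j]]))))
      fsum <- if (is.null(fsum)) t else ag_add(fsum, t)
    }
    ntot <- s * batch$n_atoms * 3
    terms$F <- ag_mul(ag_const(matrix(w[["F"]] / ntot, 1, 1)), fsum)
  }
  ## coupled: joint sign per (sample, pair) over NACs + transition dipoles
  has_nac <- !is.null(tg$smooth_nacs) && !is.null(fw$smooth_nacs)
  has_tdm <- !is.null(tg$transition_dipoles) && !is.null(fw$transition_dipoles)
  if (has_nac || has_tdm) {
    nmol <- batch$n_mol
    aw <- if (cfg$atomistic) {
      mean(batch$nat_per_mol) / batch$nat_per_mol
    } else rep(1, nmol)
    cross <- matrix(0, nmol, max(p, 1))
    if (has_nac && p > 0) {
      nC <- p * batch$n_atoms * 3
      for (k in seq_len(p)) {
        cr <- rowSums(fw$smooth_nacs[[k]]$value * tg$smooth_nacs[[k]])
        cross[, k] <- cross[, k] +
          (w[["C"]] / nC) * as.numeric(rowsum(cr, batch$mol))
      }
    }
    if (has_tdm && p > 0) {
      nT <- p * nmol * 3
      for (k in seq_len(p)) {
        cross[, k] <- cross[, k] + (w[["mu"]] / nT) *
          rowSums(fw$transition_dipoles[[k]]$value * tg$transition_dipoles[[k]])
      }
    }
    signs <- matrix(1, nmol, max(p, 1))
    if (cfg$phase_mode == "pairwise") {
      signs <- sign(cross); signs[signs == 0] <- 1
    } else if (cfg$phase_mode == "phase_vector") {
      for (m in seq_len(nmol)) {
        signs[m, ] <- best_phase_signs(cross[m, ], s, "phase_vector")
      }
    }
    if (has_nac && p > 0) {
      nC <- p * batch$n_atoms * 3
      csum <- NULL
      for (k in seq_len(p)) {
        sgn_rows <- (signs[, k] * aw)[batch$mol]  # per atom row
        ref <- tg$smooth_nacs[[k]] * signs[batch$mol, k]
        sq <- ag_square(ag_sub(fw$smooth_nacs[[k]], ag_const(ref)))
        if (cfg$atomistic) sq <- ag_mul(sq, ag_const(matrix(aw[batch$mol],
                                                            ncol = 1)))
        t <- ag_sum_all(sq)
        csum <- if (is.null(csum)) t else ag_add(csum, t)
      }
      terms$C <- ag_mul(ag_const(matrix(w[["C"]] / nC, 1, 1)), csum)
    }
    if (has_tdm && p > 0) {
      nT <- p * nmol * 3
      tsum <- NULL
      for (k in seq_len(p)) {
        ref <- tg$transition_dipoles[[k]] * signs[, k]
        t <- ag_sum_all(ag_square(ag_sub(fw$transition_dipoles[[k]],
                                         ag_const(ref))))
        tsum <- if (is.null(tsum)) t else ag_add(tsum, t)
      }
      terms$mu_t <- ag_mul(ag_const(matrix(w[["mu"]] / nT, 1, 1)), tsum)
    }
  }
  if (!is.null(tg$permanent_dipoles) && !is.null(fw$permanent_dipoles)) {
    dsum <- NULL
    for (j in seq_len(s)) {
      t <- ag_sum_all(ag_square(ag_sub(fw$permanent_dipoles[[j]],
                                       ag_const(tg$permanent_dipoles[[j]]))))
      dsum <- if (is.null(dsum)) t else ag_add(dsum, t)
    }
    terms$mu_p <- ag_mul(ag_const(matrix(w[["mu"]] / (s * batch$n_mol * 3),
                                         1, 1)), dsum)
  }
  Reduce(ag_add, terms)
}

needed_blocks <- function(heads) {
  c(if (heads$energies) "energies", if (heads$forces) "forces",
    if (heads$nacs) "smooth_nacs", if (heads$dipoles) "dipoles")
}

#' Train a model
#'
#' Minibatch Adam on the combined loss, with early stopping on the
#' validation loss and return of the best-validation parameters. The
#' energy reference offsets are fitted on the training split before
#' optimization. Coupled-state properties are scored through the
#' configured phase-free loss; the minimizing sign assignment is treated
#' as constant during differentiation.
#'
#' @param model a [create_model()] object.
#' @param train,val training and validation [dataset()]s.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress every `verbose` epochs (0 = silent).
#' @return the trained model (class `ndn_model`), with a `history`
#'   data.frame attribute (epoch, train_loss, val_loss, lr) and
#'   `best_epoch`.
#' @export
train_model <- function(model, train, val, config = train_config(),
                        verbose = 0) {
  stopifnot(length(train$samples) > 0, length(val$samples) > 0)
  model$offsets <- fit_energy_reference(train)
  need <- needed_blocks(model$heads)
  cutoff <- model$rep$cutoff
  ntr <- length(train$samples)
  tr_geoms <- lapply(train$samples, `[[`, "geometry")
  tr_pairs <- lapply(tr_geoms, function(g) neighbor_pairs(g$positions, cutoff))

  ## pre-assemble validation batch(es)
  val_chunks <- chunk_indices(length(val$samples), 512L)
  val_pack <- lapply(val_chunks, function(ix) {
    b <- make_batch(lapply(val$samples[ix], `[[`, "geometry"), cutoff)
    list(batch = b, tg = batch_targets(val$samples[ix], b, model$states))
  })
  eval_loss <- function() {
    tot <- 0; n <- 0
    for (vp in val_pack) {
      fw <- model_forward(model, vp$batch, need = need, track_params = FALSE)
      l <- batch_loss_node(model, fw, vp$batch, vp$tg, config)$value[1]
      tot <- tot + l * vp$batch$n_mol
      n <- n + vp$batch$n_mol
    }
    tot / n
  }

  adam_m <- lapply(model$params, function(x) array(0, dim(x)))
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(loss = Inf, params = model$params, offsets = model$offsets,
               epoch = 0L)
  stall <- 0L

  with_preserved_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(ntr)
      ep_loss <- 0
      for (ix in chunk_indices(ntr, config$batch_size, perm)) {
        b <- make_batch(tr_geoms[ix], cutoff, tr_pairs[ix])
        tg <- batch_targets(train$samples[ix], b, model$states)
        fw <- model_forward(model, b, need = need, track_params = TRUE)
        loss <- batch_loss_node(model, fw, b, tg, config)
        lv <- loss$value[1]
        if (!is.finite(lv)) {
          stop("training diverged: non-finite loss at epoch ", ep,
               ", batch samples [", paste(utils::head(ix, 5), collapse = ","),
               "...]")
        }
        ep_loss <- ep_loss + lv * length(ix)
        grads <- ag_grad(loss, fw$params)
        gn2 <- sum(vapply(grads, function(g) sum(g$value^2), numeric(1)))
        scale <- if (is.finite(config$grad_clip) &&
                     sqrt(gn2) > config$grad_clip) {
          config$grad_clip / sqrt(gn2)
        } else 1
        step <- step + 1
        for (nm in names(model$params)) {
          g <- grads[[match(nm, names(model$params))]]$value * scale
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            config$lr * mhat / (sqrt(vhat) + eps)
        }
      }
      vl <- eval_loss()
      if (!is.finite(vl)) {
        stop("training diverged: non-finite validation loss at epoch ", ep)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ntr,
                                     val_loss = vl))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = model$params,
                     offsets = model$offsets, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (verbose > 0 && ep %% verbose == 0) {
        message(sprintf("epoch %d  train %.3e  val %.3e", ep,
                        ep_loss / ntr, vl))
      }
      if (stall >= config$patience) break
    }
  })
  model$params <- best$params
  model$offsets <- best$offsets
  attr(model, "history") <- hist
  attr(model, "best_epoch") <- best$epoch
  model
}

chunk_indices <- function(n, size, perm = seq_len(n)) {
  split(perm, ceiling(seq_along(perm) / size))
}

#' Per-property MAE and RMSE of a model on a dataset
#'
#' Coupled-state properties (smoothed NACs, transition dipoles) are scored
#' modulo the best phase vector per sample (joint over both properties),
#' since their absolute sign is not an observable.
#'
#' @param model a trained model.
#' @param ds a [dataset()] carrying reference blocks.
#' @param chunk samples per prediction batch.
#' @return data.frame with columns property, mae, rmse, n_components.
#' @export
evaluate_model <- function(model, ds, chunk = 400L) {
  s <- model$states$n_states
  p <- n_pairs(model$states)
  acc <- new.env()
  add <- function(nm, err) {
    prev <- acc[[nm]]
    if (is.null(prev)) prev <- c(sa = 0, sq = 0, n = 0)
    acc[[nm]] <- prev + c(sum(abs(err)), sum(err^2), length(err))
  }
  for (ix in chunk_indices(length(ds$samples), chunk)) {
    preds <- predict_all(model, lapply(ds$samples[ix], `[[`, "geometry"))
    for (q in seq_along(ix)) {
      smp <- ds$samples[[ix[q]]]; pr <- preds[[q]]
      if (!is.null(smp$energies) && !is.null(pr$energies)) {
        add("energies", pr$energies - smp$energies)
      }
      if (!is.null(smp$forces) && !is.null(pr$forces)) {
        add("forces", pr$forces - smp$forces)
      }
      cross <- rep(0, max(p, 1))
      has_nac <- !is.null(smp$smooth_nacs) && !is.null(pr$smooth_nacs)
      has_tdm <- !is.null(smp$transition_dipoles) &&
        !is.null(pr$transition_dipoles)
      if (has_nac) {
        for (k in seq_len(p)) {
          cross[k] <- cross[k] + sum(pr$smooth_nacs[k, , ] *
                                       smp$smooth_nacs[k, , ])
        }
      }
      if (has_tdm) {
        for (k in seq_len(p)) {
          cross[k] <- cross[k] + sum(pr$transition_dipoles[k, ] *
                                       smp$transition_dipoles[k, ])
        }
      }
      if ((has_nac || has_tdm) && p > 0) {
        sg <- best_phase_signs(cross, s, "phase_vector")
        if (has_nac) {
          for (k in seq_len(p)) {
            add("smooth_nacs", pr$smooth_nacs[k, , ] -
                  sg[k] * smp$smooth_nacs[k, , ])
          }
        }
        if (has_tdm) {
          for (k in seq_len(p)) {
            add("transition_dipoles", pr$transition_dipoles[k, ] -
                  sg[k] * smp$transition_dipoles[k, ])
          }
        }
      }
      if (!is.null(smp$permanent_dipoles) && !is.null(pr$permanent_dipoles)) {
        add("permanent_dipoles", pr$permanent_dipoles - smp$permanent_dipoles)
      }
    }
  }
  nms <- ls(acc)
  out <- data.frame(
    property = nms,
    mae = vapply(nms, function(n) acc[[n]]["sa"] / acc[[n]]["n"], numeric(1)),
    rmse = vapply(nms, function(n) sqrt(acc[[n]]["sq"] / acc[[n]]["n"]),
                  numeric(1)),
    n_components = vapply(nms, function(n) acc[[n]]["n"], numeric(1)),
    row.names = NULL)
  out
}
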