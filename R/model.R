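#' Property head configuration
#'
#' Selects which multi-state observables the model predicts and how the
#' smoothed coupling vectors are produced: `equivariant_direct` gates the
#' per-atom vector features (equivariant representation only), while
#' `virtual_derivative` differentiates a per-pair invariant scalar with
#' respect to the nuclear coordinates (works for both kinds and is the
#' only option for the invariant one).
#'
#' @param energies,forces,nacs,dipoles logical switches.
#' @param nac_mode "equivariant_direct" or "virtual_derivative".
#' @return object of class `ndn_head_config`.
#' @export
head_config <- function(energies = TRUE, forces = TRUE, nacs = FALSE,
                        dipoles = FALSE,
                        nac_mode = c("equivariant_direct",
                                     "virtual_derivative")) {
  nac_mode <- match.arg(nac_mode)
  if (forces && !energies) stop("forces require the energy head")
  structure(list(energies = energies, forces = forces, nacs = nacs,
                 dipoles = dipoles, nac_mode = nac_mode),
            class = "ndn_head_config")
}

init_head_params <- function(cfg, heads, s, p) {
  f <- cfg$n_features
  out <- list()
  if (heads$energies) {
    out$We1 <- dense_init(f, f); out$be1 <- matrix(0, 1, f)
    out$We2 <- dense_init(f, s, rng_sd = 0.1 / sqrt(f)); out$be2 <- matrix(0, 1, s)
  }
  if (heads$nacs) {
    if (heads$nac_mode == "virtual_derivative") {
      out$Wv1 <- dense_init(f, f); out$bv1 <- matrix(0, 1, f)
      out$Wv2 <- dense_init(f, p, rng_sd = 0.1 / sqrt(f)); out$bv2 <- matrix(0, 1, p)
    } else {
      out$Wg1 <- dense_init(f, f); out$bg1 <- matrix(0, 1, f)
      out$Wg2 <- dense_init(f, p * f, rng_sd = 0.1 / sqrt(f))
      out$bg2 <- matrix(0, 1, p * f)
    }
  }
  if (heads$dipoles) {
    out$Wq1 <- dense_init(f, f); out$bq1 <- matrix(0, 1, f)
    out$Wq2 <- dense_init(f, s + p, rng_sd = 0.1 / sqrt(f))
    out$bq2 <- matrix(0, 1, s + p)
  }
  out
}

#' Create a multi-state neural network potential
#'
#' @param rep a [rep_config()].
#' @param heads a [head_config()].
#' @param states a [state_space()].
#' @return object of class `ndn_model` with freshly initialized parameters
#'   (deterministic in `rep$seed`) and zero energy offsets.
#' @export
create_model <- function(rep, heads, states) {
  stopifnot(inherits(rep, "ndn_rep_config"), inherits(heads, "ndn_head_config"),
            inherits(states, "ndn_state_space"))
  if (heads$nacs && heads$nac_mode == "equivariant_direct" &&
      rep$kind == "invariant") {
    stop("equivariant_direct NAC head requires the equivariant representation; ",
         "use nac_mode = 'virtual_derivative'")
  }
  s <- states$n_states
  p <- n_pairs(states)
  params <- with_preserved_seed(rep$seed, {
    c(init_representation_params(rep), init_head_params(rep, heads, s, p))
  })
  structure(list(rep = rep, heads = heads, states = states, params = params,
                 offsets = rep(0, s)),
            class = "ndn_model")
}

#' @export
print.ndn_model <- function(x, ...) {
  cat("<ndn_model>", x$rep$kind, "representation, F =", x$rep$n_features,
      ",", x$rep$n_interactions, "blocks,", x$states$n_states, "states\n")
  cat("  heads:", paste(names(Filter(isTRUE, x$heads[1:4])), collapse = ", "),
      if (x$heads$nacs) paste0("(nac_mode=", x$heads$nac_mode, ")") else "", "\n")
  invisible(x)
}

## Full forward pass over a batch. `need` selects outputs; `track_params`
## makes parameter leaves differentiable (training). Returns graph nodes.
model_forward <- function(model, batch, need = c("energies"),
                          track_params = FALSE) {
  cfg <- model$rep
  heads <- model$heads
  s <- model$states$n_states
  p <- n_pairs(model$states)
  need_posgrad <- any(c("forces", "smooth_nacs") %in% need) &&
    (("forces" %in% need) ||
       ("smooth_nacs" %in% need && heads$nac_mode == "virtual_derivative"))
  pn <- ag_leaf(batch$pos, track = need_posgrad || "dipoles" %in% need)
  P <- if (track_params) lapply(model$params, function(m) ag_leaf(m, TRUE))
       else lapply(model$params, ag_const)
  repr <- rep_forward(cfg, P, batch, pn)
  sfeat <- repr$s
  out <- list(pos = pn, params = P, batch = batch)

  if ("energies" %in% need || "forces" %in% need) {
    if (!heads$energies) stop("model has no energy head; trained heads: ",
                              paste(names(Filter(isTRUE, heads[1:4])), collapse = ", "))
    eps <- dense(ag_ssp(dense(sfeat, P$We1, P$be1)), P$We2, P$be2)
    emol <- ag_rowscatter(eps, batch$mol, batch$n_mol)
    emol <- ag_add(emol, ag_const(matrix(model$offsets, 1, s)))
    out$energies <- emol
  }
  if ("forces" %in% need) {
    out$forces <- lapply(seq_len(s), function(j) {
      seed <- matrix(0, batch$n_mol, s); seed[, j] <- 1
      ag_neg(ag_grad(out$energies, pn, seed)[[1]])
    })
  }
  if ("smooth_nacs" %in% need) {
    if (!heads$nacs) stop("model has no NAC head; trained heads: ",
                          paste(names(Filter(isTRUE, heads[1:4])), collapse = ", "))
    if (heads$nac_mode == "virtual_derivative") {
      virt <- dense(ag_ssp(dense(sfeat, P$Wv1, P$bv1)), P$Wv2, P$bv2)
      vmol <- ag_rowscatter(virt, batch$mol, batch$n_mol)
      out$virtual <- vmol
      out$smooth_nacs <- lapply(seq_len(p), function(k) {
        seed <- matrix(0, batch$n_mol, p); seed[, k] <- 1
        ag_grad(vmol, pn, seed)[[1]]
      })
    } else {
      f <- cfg$n_features
      gates <- dense(ag_ssp(dense(sfeat, P$Wg1, P$bg1)), P$Wg2, P$bg2)
      out$smooth_nacs <- lapply(seq_len(p), function(k) {
        gk <- ag_colgather(gates, (k - 1) * f + seq_len(f))
        ag_cbind(lapply(1:3, function(a) ag_sumcols(ag_mul(gk, repr$v[[a]]))))
      })
    }
  }
  if ("dipoles" %in% need) {
    if (!heads$dipoles) stop("model has no dipole head; trained heads: ",
                             paste(names(Filter(isTRUE, heads[1:4])), collapse = ", "))
    q <- dense(ag_ssp(dense(sfeat, P$Wq1, P$bq1)), P$Wq2, P$bq2)
    natm <- ag_const(matrix(batch$nat_per_mol, batch$n_mol, 1))
    relpos <- lapply(1:3, function(a) {
      pa <- ag_colgather(pn, a)
      cent <- ag_div(ag_rowscatter(pa, batch$mol, batch$n_mol), natm)
      ag_sub(pa, ag_rowgather(cent, batch$mol))
    })
    recenter <- function(qcol, qtot) {
      qsum <- ag_rowscatter(qcol, batch$mol, batch$n_mol)
      corr <- ag_div(ag_sub(ag_const(matrix(qtot, batch$n_mol, 1)), qsum), natm)
      ag_add(qcol, ag_rowgather(corr, batch$mol))
    }
    dip <- function(qcol) {
      ag_cbind(lapply(1:3, function(a) {
        ag_rowscatter(ag_mul(qcol, relpos[[a]]), batch$mol, batch$n_mol)
      }))
    }
    out$charges <- q
    out$permanent_dipoles <- lapply(seq_len(s), function(j) {
      dip(recenter(ag_colgather(q, j), batch$charge))
    })
    out$transition_dipoles <- lapply(seq_len(p), function(k) {
      dip(recenter(ag_colgather(q, s + k), 0))
    })
  }
  out
}

#' Predict all configured properties for one or more geometries
#'
#' One forward pass serves all heads. Forces are the exact negative
#' gradients of the predicted state energies; smoothed couplings come from
#' the configured NAC head; dipoles from the atomic charge model.
#'
#' @param model a trained [create_model()] object.
#' @param geoms a [geometry()] or list of geometries.
#' @param need character vector of property blocks, default all configured.
#' @return an `ndn_prediction` (single geometry) or list thereof: fields
#'   `energies` (S), `forces` (S x n x 3), `smooth_nacs` (P x n x 3),
#'   `permanent_dipoles` (S x 3), `transition_dipoles` (P x 3), `charges`.
#' @export
predict_all <- function(model, geoms, need = NULL) {
  single <- inherits(geoms, "ndn_geometry")
  if (single) geoms <- list(geoms)
  if (is.null(need)) {
    need <- c(if (model$heads$energies) "energies",
              if (model$heads$forces) "forces",
              if (model$heads$nacs) "smooth_nacs",
              if (model$heads$dipoles) "dipoles")
  }
  batch <- make_batch(geoms, model$rep$cutoff)
  fw <- model_forward(model, batch, need = need)
  s <- model$states$n_states
  p <- n_pairs(model$states)
  res <- lapply(seq_along(geoms), function(m) {
    na <- batch$nat_per_mol[m]
    rows <- batch$atom_offset[m] + seq_len(na)
    pr <- list(state_space = model$states, geometry = geoms[[m]])
    if (!is.null(fw$energies)) pr$energies <- as.numeric(fw$energies$value[m, ])
    if (!is.null(fw$forces)) {
      arr <- array(0, c(s, na, 3))
      for (j in seq_len(s)) arr[j, , ] <- fw$forces[[j]]$value[rows, ]
      pr$forces <- arr
    }
    if (!is.null(fw$smooth_nacs)) {
      arr <- array(0, c(p, na, 3))
      for (k in seq_len(p)) arr[k, , ] <- fw$smooth_nacs[[k]]$value[rows, ]
      pr$smooth_nacs <- arr
    }
    if (!is.null(fw$permanent_dipoles)) {
      pr$permanent_dipoles <- do.call(rbind, lapply(fw$permanent_dipoles,
                                                    function(x) x$value[m, ]))
      pr$transition_dipoles <- if (p > 0) {
        do.call(rbind, lapply(fw$transition_dipoles, function(x) x$value[m, ]))
      } else matrix(0, 0, 3)
      pr$charges <- fw$charges$value[rows, , drop = FALSE]
    }
    structure(pr, class = "ndn_prediction")
  })
  if (single) res[[1]] else res
}

#' Convert predicted smoothed couplings to classical NAC vectors
#'
#' Divides each smoothed coupling by the predicted energy gap (with a
#' floored magnitude), the prediction-time inverse of the smoothing used
#' in training.
#'
#' @param prediction an `ndn_prediction` with energies and smooth_nacs.
#' @param gap_floor positive floor on |E_j - E_i| (Hartree).
#' @return the prediction with a `nacs` field added.
#' @export
to_classical_nacs <- function(prediction, gap_floor = 1e-8) {
  if (is.null(prediction$smooth_nacs) || is.null(prediction$energies)) {
    stop("prediction lacks energies and/or smooth_nacs; available: ",
         paste(intersect(names(prediction),
                         c("energies", "forces", "smooth_nacs", "permanent_dipoles")),
               collapse = ", "))
  }
  prediction$nacs <- unsmooth_nacs_op(prediction$smooth_nacs,
                                      prediction$energies,
                                      prediction$state_space, gap_floor)
  prediction
}

#' Predict per-state energies only
#' @inheritParams predict_all
#' @return numeric vector (single geometry) or matrix n_geom x S.
#' @export
predict_energies <- function(model, geoms) {
  single <- inherits(geoms, "ndn_geometry")
  pr <- predict_all(model, geoms, need = "energies")
  if (single) pr$energies else t(vapply(pr, `[[`, numeric(model$states$n_states),
                                        "energies"))
}

#' Predict per-state forces
#' @inheritParams predict_all
#' @return S x n x 3 array (single geometry) or list of such arrays.
#' @export
predict_forces <- function(model, geoms) {
  single <- inherits(geoms, "ndn_geometry")
  pr <- predict_all(model, geoms, need = c("energies", "forces"))
  if (single) pr$forces else lapply(pr, `[[`, "forces")
}

#' Predict smoothed NAC vectors
#' @inheritParams predict_all
#' @return P x n x 3 array (single geometry) or list of such arrays.
#' @export
predict_smooth_nacs <- function(model, geoms) {
  single <- inherits(geoms, "ndn_geometry")
  pr <- predict_all(model, geoms, need = "smooth_nacs")
  if (single) pr$smooth_nacs else lapply(pr, `[[`, "smooth_nacs")
}

#' Predict dipole moments and atomic charges
#' @inheritParams predict_all
#' @return prediction object(s) with dipole fields.
#' @export
predict_dipoles <- function(model, geoms) {
  predict_all(model, geoms, need = "dipoles")
}

#' Save / load a model checkpoint
#'
#' Plain-text JSON checkpoint holding configuration, parameters, energy
#' offsets and the unit convention.
#'
#' @param model a `ndn_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    schema = 1L, units = "atomic",
    rep = unclass(model$rep), heads = unclass(model$heads),
    n_states = model$states$n_states,
    offsets = model$offsets,
    ## parameters serialized as %.17g strings: exact double round trip
    params = lapply(model$params, function(m) list(dim = dim(m),
                                                   data = sprintf("%.17g", m)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- do.call(rep_config, obj$rep[c("kind", "n_features", "n_interactions",
                                       "cutoff", "n_radial_basis", "seed")])
  heads <- do.call(head_config, obj$heads)
  m <- create_model(rep, heads, state_space(obj$n_states))
  m$params <- lapply(obj$params, function(p) {
    matrix(as.numeric(p$data), p$dim[1], p$dim[2])
  })
  m$offsets <- as.numeric(obj$offsets)
  m
}
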