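#' Rectangular scan grid over two model coordinates
#'
#' Builds geometries and exact reference samples of a diabatic model on a
#' complete rectangular grid of its first two mode coordinates.
#'
#' @param model a [diabatic_model()] with >= 2 modes.
#' @param axis1,axis2 numeric vectors of mode-coordinate values.
#' @return object of class `ndn_grid`: axes, `geometries` (row-major,
#'   axis2 fastest), `references` (exact samples; NULL where the raw NAC
#'   is singular).
#' @export
model_grid_scan <- function(model, axis1, axis2) {
  nodes <- expand.grid(a2 = axis2, a1 = axis1)[, c("a1", "a2")]
  geoms <- vector("list", nrow(nodes))
  refs <- vector("list", nrow(nodes))
  for (r in seq_len(nrow(nodes))) {
    q <- c(nodes$a1[r], nodes$a2[r])
    geoms[[r]] <- model_geometry(model, q)
    refs[[r]] <- tryCatch(adiabatize(model, q), error = function(e) NULL)
  }
  structure(list(axis1 = axis1, axis2 = axis2, nodes = nodes,
                 geometries = geoms, references = refs),
            class = "ndn_grid")
}

#' Per-node prediction error map on a grid scan
#'
#' log10 of the mean absolute component error of a model prediction
#' against the grid references, with coupled properties scored modulo the
#' best phase vector per node. Errors are floored at 1e-12 before the
#' logarithm so perfect nodes stay finite.
#'
#' @param model trained model.
#' @param grid an [model_grid_scan()] object.
#' @param property one of "energies", "forces", "smooth_nacs",
#'   "transition_dipoles", "permanent_dipoles".
#' @param pair optional 1-based flat pair (or state) index restricting the
#'   error to one pair/state.
#' @return data.frame: axis1, axis2, log10_error.
#' @export
prediction_error_map <- function(model, grid, property = "smooth_nacs",
                                 pair = NULL) {
  need <- switch(property,
                 energies = "energies",
                 forces = c("energies", "forces"),
                 smooth_nacs = "smooth_nacs",
                 transition_dipoles = "dipoles",
                 permanent_dipoles = "dipoles",
                 stop("unknown property: ", property))
  preds <- predict_all(model, grid$geometries, need = need)
  s <- model$states$n_states
  p <- n_pairs(model$states)
  err <- vapply(seq_along(preds), function(r) {
    ref <- grid$references[[r]]
    if (is.null(ref)) return(NA_real_)
    pr <- preds[[r]]
    if (property %in% c("smooth_nacs", "transition_dipoles")) {
      cross <- rep(0, p)
      for (k in seq_len(p)) {
        if (!is.null(pr$smooth_nacs)) {
          cross[k] <- cross[k] + sum(pr$smooth_nacs[k, , ] *
                                       ref$smooth_nacs[k, , ])
        }
        if (!is.null(pr$transition_dipoles)) {
          cross[k] <- cross[k] + sum(pr$transition_dipoles[k, ] *
                                       ref$transition_dipoles[k, ])
        }
      }
      sg <- best_phase_signs(cross, s, "phase_vector")
      if (property == "smooth_nacs") {
        ks <- if (is.null(pair)) seq_len(p) else pair
        mean(vapply(ks, function(k) {
          mean(abs(pr$smooth_nacs[k, , ] - sg[k] * ref$smooth_nacs[k, , ]))
        }, numeric(1)))
      } else {
        ks <- if (is.null(pair)) seq_len(p) else pair
        mean(vapply(ks, function(k) {
          mean(abs(pr$transition_dipoles[k, ] -
                     sg[k] * ref$transition_dipoles[k, ]))
        }, numeric(1)))
      }
    } else if (property == "energies") {
      js <- if (is.null(pair)) seq_len(s) else pair
      mean(abs(pr$energies[js] - ref$energies[js]))
    } else if (property == "forces") {
      js <- if (is.null(pair)) seq_len(s) else pair
      mean(abs(pr$forces[js, , ] - ref$forces[js, , ]))
    } else {
      js <- if (is.null(pair)) seq_len(s) else pair
      mean(abs(pr$permanent_dipoles[js, ] - ref$permanent_dipoles[js, ]))
    }
  }, numeric(1))
  data.frame(axis1 = grid$nodes$a1, axis2 = grid$nodes$a2,
             log10_error = log10(pmax(err, 1e-12)))
}

#' Difference of two error maps
#'
#' Elementwise map_a - map_b on identical grids; negative values mean
#' model a is more accurate at that node. Antisymmetric under swapping the
#' arguments.
#'
#' @param map_a,map_b data.frames from [prediction_error_map()].
#' @return data.frame: axis1, axis2, delta.
#' @export
error_difference_map <- function(map_a, map_b) {
  if (!identical(map_a$axis1, map_b$axis1) ||
      !identical(map_a$axis2, map_b$axis2)) {
    stop("error maps are on different grids")
  }
  data.frame(axis1 = map_a$axis1, axis2 = map_a$axis2,
             delta = map_a$log10_error - map_b$log10_error)
}

## ---- internal-coordinate editing for scan construction -------------------

#' Edit internal coordinates by rigid-fragment moves
#'
#' `set_bond_length()` translates the fragment on the j-side of bond i-j
#' along the bond axis; `set_dihedral()` rotates it rigidly about the j-k
#' axis so the dihedral i-j-k-l takes the requested value. Fragments are
#' identified by connectivity if not given. Other coordinates are frozen.
#'
#' @param geom a [geometry()].
#' @param i,j,k,l 1-based atom indices.
#' @param value target bond length (Bohr) / dihedral angle (degrees).
#' @param moving_atoms indices of the atoms to move (default: atom j / l
#'   side).
#' @return modified geometry.
#' @export
set_bond_length <- function(geom, i, j, value, moving_atoms = j) {
  pos <- geom$positions
  d <- pos[j, ] - pos[i, ]
  u <- d / sqrt(sum(d^2))
  shift <- (value - sqrt(sum(d^2))) * u
  pos[moving_atoms, ] <- sweep(pos[moving_atoms, , drop = FALSE], 2, -shift)
  geometry(geom$atomic_numbers, pos, geom$total_charge)
}

#' @rdname set_bond_length
#' @export
set_dihedral <- function(geom, i, j, k, l, value, moving_atoms = l) {
  pos <- geom$positions
  cur <- dihedral_angle(pos, i, j, k, l)
  ang <- -(value - cur) * pi / 180
  axis <- pos[k, ] - pos[j, ]
  axis <- axis / sqrt(sum(axis^2))
  rot <- rotation_about_axis(axis, ang)
  orig <- pos[k, ]
  for (a in moving_atoms) {
    pos[a, ] <- as.numeric(rot %*% (pos[a, ] - orig)) + orig
  }
  geometry(geom$atomic_numbers, pos, geom$total_charge)
}

#' Dihedral angle i-j-k-l in degrees
#' @param pos n x 3 position matrix.
#' @param i,j,k,l atom indices.
#' @return signed dihedral in (-180, 180].
#' @export
dihedral_angle <- function(pos, i, j, k, l) {
  b1 <- pos[j, ] - pos[i, ]
  b2 <- pos[k, ] - pos[j, ]
  b3 <- pos[l, ] - pos[k, ]
  n1 <- crossprod3(b1, b2)
  n2 <- crossprod3(b2, b3)
  m1 <- crossprod3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_about_axis <- function(u, theta) {
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}
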