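#' Representation configuration
#'
#' Settings of the atomistic feature builder: an invariant continuous-filter
#' message-passing network (scalar features only) or an equivariant variant
#' that additionally carries per-atom vector features and can output
#' vectorial properties directly.
#'
#' @param kind "invariant" or "equivariant".
#' @param n_features feature width F per atom.
#' @param n_interactions number of message-passing blocks.
#' @param cutoff neighbor cutoff radius (Bohr).
#' @param n_radial_basis number of Gaussian radial basis functions.
#' @param seed integer seed for parameter initialization.
#' @return object of class `ndn_rep_config`.
#' @export
rep_config <- function(kind = c("equivariant", "invariant"), n_features = 32L,
                       n_interactions = 2L, cutoff = 10, n_radial_basis = 16L,
                       seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_features > 0, n_interactions >= 1, cutoff > 0,
            n_radial_basis > 0)
  structure(list(kind = kind, n_features = as.integer(n_features),
                 n_interactions = as.integer(n_interactions),
                 cutoff = as.numeric(cutoff),
                 n_radial_basis = as.integer(n_radial_basis),
                 seed = as.integer(seed)),
            class = "ndn_rep_config")
}

#' Neighbor list within a cutoff
#'
#' All ordered pairs (a, b), a != b, with |r_b - r_a| <= cutoff, with the
#' displacement vectors r_b - r_a and distances.
#'
#' @param geom a [geometry()].
#' @param cutoff radius in Bohr.
#' @return data.frame with columns i, j (1-based atom indices), dx, dy, dz,
#'   d.
#' @export
build_neighborhood <- function(geom, cutoff) {
  stopifnot(cutoff > 0)
  pos <- geom$positions
  np <- neighbor_pairs(pos, cutoff)
  if (length(np$i) == 0) {
    return(data.frame(i = integer(0), j = integer(0), dx = numeric(0),
                      dy = numeric(0), dz = numeric(0), d = numeric(0)))
  }
  dvec <- pos[np$j, , drop = FALSE] - pos[np$i, , drop = FALSE]
  data.frame(i = np$i, j = np$j, dx = dvec[, 1], dy = dvec[, 2],
             dz = dvec[, 3], d = sqrt(rowSums(dvec^2)))
}

## fast pair enumeration (i-major order), no data.frame allocation
neighbor_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2) return(list(i = integer(0), j = integer(0)))
  ii <- rep(seq_len(n), each = n)
  jj <- rep.int(seq_len(n), n)
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  d2 <- .rowSums((pos[jj, ] - pos[ii, ])^2, length(ii), 3L)
  keep <- d2 <= cutoff^2
  list(i = ii[keep], j = jj[keep])
}

#' Radial basis expansion with a smooth cutoff envelope
#'
#' Gaussian basis functions with centers evenly spaced on (0, cutoff],
#' multiplied by the cosine envelope 0.5 (cos(pi r / r_c) + 1), which is
#' smooth and identically zero at and beyond the cutoff.
#'
#' @param distance numeric vector of distances (Bohr), > 0.
#' @param config a [rep_config()].
#' @return matrix length(distance) x n_radial_basis.
#' @export
radial_basis <- function(distance, config) {
  rc <- config$cutoff
  k <- config$n_radial_basis
  mu <- seq(0, rc, length.out = k)
  delta <- mu[2] - mu[1]
  gam <- 1 / (2 * delta^2)
  f <- exp(-gam * outer(distance, mu, `-`)^2)
  env <- ifelse(distance < rc, 0.5 * (cos(pi * distance / rc) + 1), 0)
  f * env
}

## ---- parameter initialization -------------------------------------------

.MAX_Z <- 20L

dense_init <- function(nin, nout, rng_sd = NULL) {
  sd <- if (is.null(rng_sd)) 1 / sqrt(nin) else rng_sd
  matrix(stats::rnorm(nin * nout, sd = sd), nin, nout)
}

init_representation_params <- function(cfg) {
  f <- cfg$n_features; k <- cfg$n_radial_basis
  p <- list(emb = matrix(stats::rnorm(.MAX_Z * f, sd = 1), .MAX_Z, f))
  for (t in seq_len(cfg$n_interactions)) {
    tag <- paste0("b", t, "_")
    if (cfg$kind == "invariant") {
      p[[paste0(tag, "Win")]] <- dense_init(f, f)
      p[[paste0(tag, "bin")]] <- matrix(0, 1, f)
      p[[paste0(tag, "Wf1")]] <- dense_init(k, f)
      p[[paste0(tag, "bf1")]] <- matrix(0, 1, f)
      p[[paste0(tag, "Wf2")]] <- dense_init(f, f)
      p[[paste0(tag, "bf2")]] <- matrix(0, 1, f)
      p[[paste0(tag, "W2")]] <- dense_init(f, f)
      p[[paste0(tag, "b2")]] <- matrix(0, 1, f)
      p[[paste0(tag, "W3")]] <- dense_init(f, f)
      p[[paste0(tag, "b3")]] <- matrix(0, 1, f)
    } else {
      p[[paste0(tag, "Wp1")]] <- dense_init(f, f)
      p[[paste0(tag, "bp1")]] <- matrix(0, 1, f)
      p[[paste0(tag, "Wp2")]] <- dense_init(f, 3 * f)
      p[[paste0(tag, "bp2")]] <- matrix(0, 1, 3 * f)
      p[[paste0(tag, "Wf")]] <- dense_init(k, 3 * f)
      p[[paste0(tag, "bf")]] <- matrix(0, 1, 3 * f)
      p[[paste0(tag, "U")]] <- dense_init(f, f)
      p[[paste0(tag, "V")]] <- dense_init(f, f)
      p[[paste0(tag, "Wa1s")]] <- dense_init(f, f)
      p[[paste0(tag, "Wa1n")]] <- dense_init(f, f)
      p[[paste0(tag, "ba1")]] <- matrix(0, 1, f)
      p[[paste0(tag, "Wa2")]] <- dense_init(f, 3 * f)
      p[[paste0(tag, "ba2")]] <- matrix(0, 1, 3 * f)
    }
  }
  p
}

## ---- batched forward pass ------------------------------------------------

## A batch stacks the atoms of several molecules: Z, pos (N x 3), mol
## (atom -> molecule), pair lists with global atom indices.
make_batch <- function(geoms, cutoff, pair_cache = NULL) {
  nmol <- length(geoms)
  zs <- lapply(geoms, `[[`, "atomic_numbers")
  nat <- vapply(zs, length, integer(1))
  off <- cumsum(c(0L, nat))
  pos <- do.call(rbind, lapply(geoms, `[[`, "positions"))
  if (is.null(pair_cache)) {
    pair_cache <- lapply(geoms, function(g) {
      neighbor_pairs(g$positions, cutoff)
    })
  }
  pairs_i <- unlist(lapply(seq_len(nmol),
                           function(m) pair_cache[[m]]$i + off[m]))
  pairs_j <- unlist(lapply(seq_len(nmol),
                           function(m) pair_cache[[m]]$j + off[m]))
  list(Z = unlist(zs), pos = pos, mol = rep(seq_len(nmol), nat),
       n_mol = nmol, n_atoms = sum(nat), nat_per_mol = nat,
       atom_offset = off, ii = as.integer(pairs_i),
       jj = as.integer(pairs_j),
       charge = vapply(geoms, `[[`, integer(1), "total_charge"))
}

dense <- function(x, W, b) ag_add(ag_matmul(x, W), b)

## forward through the representation; returns scalar features node `s`
## (N x F) and for the equivariant kind vector features `v` (list of three
## N x F nodes, one per Cartesian component)
rep_forward <- function(cfg, P, batch, pn) {
  f <- cfg$n_features
  n <- batch$n_atoms
  ii <- batch$ii; jj <- batch$jj
  has_pairs <- length(ii) > 0

  s <- ag_rowgather(P$emb, batch$Z)
  v <- NULL
  if (cfg$kind == "equivariant") {
    zero <- ag_const(matrix(0, n, f))
    v <- list(zero, zero, zero)
  }
  if (!has_pairs) return(list(s = s, v = v))

  disp <- ag_sub(ag_rowgather(pn, jj), ag_rowgather(pn, ii))
  d2 <- ag_sumcols(ag_square(disp))
  d <- ag_sqrt(d2)
  rc <- cfg$cutoff; k <- cfg$n_radial_basis
  mu <- ag_const(matrix(seq(0, rc, length.out = k), 1, k))
  delta <- rc / (k - 1)
  gam <- ag_const(matrix(1 / (2 * delta^2), 1, 1))
  rbf <- ag_exp(ag_neg(ag_mul(gam, ag_square(ag_sub(d, mu)))))
  env <- ag_mul(ag_const(matrix(0.5, 1, 1)),
                ag_add(ag_cos(ag_mul(d, ag_const(matrix(pi / rc, 1, 1)))),
                       ag_const(matrix(1, 1, 1))))
  rbf <- ag_mul(rbf, env)

  if (cfg$kind == "invariant") {
    for (t in seq_len(cfg$n_interactions)) {
      g <- function(nm) P[[paste0("b", t, "_", nm)]]
      xin <- dense(s, g("Win"), g("bin"))
      filt <- dense(ag_ssp(dense(rbf, g("Wf1"), g("bf1"))), g("Wf2"), g("bf2"))
      filt <- ag_mul(filt, env)
      msg <- ag_mul(ag_rowgather(xin, jj), filt)
      agg <- ag_rowscatter(msg, ii, n)
      y <- dense(ag_ssp(dense(agg, g("W2"), g("b2"))), g("W3"), g("b3"))
      s <- ag_add(s, y)
    }
  } else {
    dirn <- lapply(1:3, function(a) ag_div(ag_colgather(disp, a), d))
    for (t in seq_len(cfg$n_interactions)) {
      g <- function(nm) P[[paste0("b", t, "_", nm)]]
      phi <- dense(ag_ssp(dense(s, g("Wp1"), g("bp1"))), g("Wp2"), g("bp2"))
      filt <- ag_mul(dense(rbf, g("Wf"), g("bf")), env)
      phj <- ag_rowgather(phi, jj)
      w <- ag_mul(phj, filt)  # n_pairs x 3F
      ws <- ag_colgather(w, seq_len(f))
      wvv <- ag_colgather(w, f + seq_len(f))
      wvs <- ag_colgather(w, 2 * f + seq_len(f))
      s <- ag_add(s, ag_rowscatter(ws, ii, n))
      for (a in 1:3) {
        dv <- ag_add(ag_mul(wvv, ag_rowgather(v[[a]], jj)),
                     ag_mul(wvs, dirn[[a]]))
        v[[a]] <- ag_add(v[[a]], ag_rowscatter(dv, ii, n))
      }
      ## update block: channel mixing + gated residuals
      u <- lapply(v, function(va) ag_matmul(va, g("U")))
      wv <- lapply(v, function(va) ag_matmul(va, g("V")))
      wn2 <- ag_add(ag_add(ag_square(wv[[1]]), ag_square(wv[[2]])),
                    ag_square(wv[[3]]))
      wnorm <- ag_sqrt(ag_add(wn2, ag_const(matrix(1e-10, 1, 1))))
      a1 <- ag_ssp(ag_add(ag_add(ag_matmul(s, g("Wa1s")),
                                 ag_matmul(wnorm, g("Wa1n"))), g("ba1")))
      a2 <- dense(a1, g("Wa2"), g("ba2"))
      ass <- ag_colgather(a2, seq_len(f))
      asv <- ag_colgather(a2, f + seq_len(f))
      avv <- ag_colgather(a2, 2 * f + seq_len(f))
      uv <- ag_add(ag_add(ag_mul(u[[1]], wv[[1]]), ag_mul(u[[2]], wv[[2]])),
                   ag_mul(u[[3]], wv[[3]]))
      s <- ag_add(s, ag_add(ass, ag_mul(asv, uv)))
      for (a in 1:3) v[[a]] <- ag_add(v[[a]], ag_mul(avv, u[[a]]))
    }
  }
  list(s = s, v = v)
}

#' Encode a geometry into atomic features
#'
#' Runs the configured message-passing representation and returns the
#' per-atom features: rotation/translation-invariant scalars, and for the
#' equivariant kind also per-atom vector features that rotate with the
#' molecule.
#'
#' @param geom a [geometry()].
#' @param config a [rep_config()].
#' @param params parameter list from the model (or `NULL` to initialize
#'   fresh parameters from `config$seed`).
#' @return list with `scalars` (n x F matrix) and `vectors` (n x F x 3
#'   array, or `NULL` for the invariant kind).
#' @export
encode <- function(geom, config, params = NULL) {
  if (is.null(params)) {
    params <- with_preserved_seed(config$seed,
                                  init_representation_params(config))
  }
  batch <- make_batch(list(geom), config$cutoff)
  pn <- ag_const(batch$pos)
  P <- lapply(params, ag_const)
  out <- rep_forward(config, P, batch, pn)
  vec <- NULL
  if (!is.null(out$v)) {
    f <- config$n_features
    vec <- array(0, c(batch$n_atoms, f, 3))
    for (a in 1:3) vec[, , a] <- out$v[[a]]$value
  }
  list(scalars = out$s$value, vectors = vec)
}
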