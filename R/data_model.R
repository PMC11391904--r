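#' Molecular geometry
#'
#' A geometry holds element identities, Cartesian positions (Bohr) and the
#' total molecular charge. Positions are an n x 3 matrix.
#'
#' @param atomic_numbers integer vector of element numbers (>= 1).
#' @param positions n x 3 numeric matrix of Cartesian coordinates in Bohr.
#' @param total_charge integer total charge in elementary charges.
#' @return an object of class `ndn_geometry`.
#' @export
geometry <- function(atomic_numbers, positions, total_charge = 0L) {
  atomic_numbers <- as.integer(atomic_numbers)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (nrow(positions) != length(atomic_numbers)) {
    stop("number of positions (", nrow(positions),
         ") does not match number of atomic numbers (",
         length(atomic_numbers), ")")
  }
  if (any(atomic_numbers < 1L)) stop("atomic numbers must be >= 1")
  if (!all(is.finite(positions))) stop("positions must be finite")
  structure(list(atomic_numbers = atomic_numbers,
                 positions = unname(positions),
                 total_charge = as.integer(total_charge)),
            class = "ndn_geometry")
}

#' @export
print.ndn_geometry <- function(x, ...) {
  cat("<geometry>", length(x$atomic_numbers), "atoms, charge",
      x$total_charge, "\n")
  invisible(x)
}

n_atoms <- function(g) length(g$atomic_numbers)

#' Electronic state space
#'
#' Describes S singlet states and the lexicographic ordering of state pairs
#' (i, j), i < j (0-based labels S0, S1, ...). Pair k of `state_pairs()` is
#' the pair with flat index k.
#'
#' @param n_states integer number of states S >= 1.
#' @return an object of class `ndn_state_space`.
#' @export
state_space <- function(n_states) {
  n_states <- as.integer(n_states)
  if (n_states < 1L) stop("n_states must be >= 1")
  structure(list(n_states = n_states), class = "ndn_state_space")
}

#' Enumerate ordered state pairs
#'
#' @param ss a `ndn_state_space` or integer S.
#' @return matrix with columns `i`, `j` (0-based state labels, i < j) in
#'   lexicographic order; row k is flat pair index k.
#' @export
state_pairs <- function(ss) {
  s <- if (inherits(ss, "ndn_state_space")) ss$n_states else as.integer(ss)
  if (s < 2L) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  idx <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m <- cbind(i = idx[, "row"] - 1L, j = idx[, "col"] - 1L)
  m[order(m[, "i"], m[, "j"]), , drop = FALSE]
}

#' Flat index of a state pair
#'
#' @param i,j 0-based state labels with i < j.
#' @param ss state space (or integer S).
#' @return 1-based flat index into the lexicographic pair list.
#' @export
pair_index <- function(i, j, ss) {
  p <- state_pairs(ss)
  k <- which(p[, "i"] == i & p[, "j"] == j)
  if (length(k) != 1) stop("no such pair (", i, ",", j, ")")
  k
}

n_pairs <- function(ss) {
  s <- if (inherits(ss, "ndn_state_space")) ss$n_states else as.integer(ss)
  s * (s - 1L) / 2L
}

#' One geometry with its electronic-state properties
#'
#' Bundles a geometry with per-state energies (Hartree), forces
#' (Hartree/Bohr, array S x n x 3), per-pair NAC vectors (1/Bohr, array
#' P x n x 3), smoothed NACs (Hartree/Bohr), and permanent/transition
#' dipoles (a.u.; S x 3 and P x 3). Any property block may be absent
#' (`NULL`). Pair ordering follows [state_pairs()]; only the i < j member
#' of each pair is stored (C_ji = -C_ij is derived, never stored).
#'
#' @param geometry a [geometry()].
#' @param state_space a [state_space()].
#' @param energies,forces,nacs,smooth_nacs,permanent_dipoles,transition_dipoles
#'   property arrays or `NULL`.
#' @param check_smooth if `TRUE` and both NAC blocks plus energies are
#'   present, verify the smoothing identity C~_ij = C_ij (E_j - E_i) to
#'   1e-12 relative.
#' @return object of class `ndn_sample`.
#' @export
multistate_sample <- function(geometry, state_space, energies = NULL,
                              forces = NULL, nacs = NULL, smooth_nacs = NULL,
                              permanent_dipoles = NULL,
                              transition_dipoles = NULL,
                              check_smooth = TRUE) {
  stopifnot(inherits(geometry, "ndn_geometry"),
            inherits(state_space, "ndn_state_space"))
  s <- state_space$n_states
  p <- n_pairs(state_space)
  na <- n_atoms(geometry)
  chk_state_arr <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as_prop_array(x, s, na)
    x
  }
  chk_pair_arr <- function(x, nm) {
    if (is.null(x)) return(NULL)
    as_prop_array(x, p, na)
  }
  if (!is.null(energies)) {
    energies <- as.numeric(energies)
    if (length(energies) != s) stop("energies must have length ", s)
  }
  forces <- chk_state_arr(forces)
  nacs <- chk_pair_arr(nacs)
  smooth_nacs <- chk_pair_arr(smooth_nacs)
  if (!is.null(permanent_dipoles)) {
    permanent_dipoles <- matrix(as.numeric(permanent_dipoles), s, 3)
  }
  if (!is.null(transition_dipoles)) {
    transition_dipoles <- matrix(as.numeric(transition_dipoles), p, 3)
  }
  out <- structure(list(geometry = geometry, state_space = state_space,
                        energies = energies, forces = forces, nacs = nacs,
                        smooth_nacs = smooth_nacs,
                        permanent_dipoles = permanent_dipoles,
                        transition_dipoles = transition_dipoles),
                   class = "ndn_sample")
  if (check_smooth && !is.null(nacs) && !is.null(smooth_nacs) &&
      !is.null(energies)) {
    expect <- smooth_nacs_op(nacs, energies, state_space)
    scale <- max(abs(expect), abs(smooth_nacs), 1e-300)
    if (max(abs(expect - smooth_nacs)) > 1e-12 * scale) {
      stop("smooth_nacs inconsistent with nacs * (E_j - E_i) beyond 1e-12 relative")
    }
  }
  out
}

as_prop_array <- function(x, d1, na) {
  x <- array(as.numeric(x), dim = c(d1, na, 3))
  x
}

#' Smooth NAC vectors by the energy gap
#'
#' Scales each raw coupling vector C_ij by the adiabatic gap (E_j - E_i),
#' j > i, giving the smoothed couplings C~_ij that stay finite at
#' conical intersections and are the quantity the networks are trained on.
#'
#' @param nacs per-pair per-atom couplings, array P x n x 3 (1/Bohr).
#' @param energies per-state energies (Hartree), length S.
#' @param state_space a [state_space()] (or integer S).
#' @return array P x n x 3 of smoothed couplings (Hartree/Bohr).
#' @export
smooth_nacs_op <- function(nacs, energies, state_space) {
  s <- if (inherits(state_space, "ndn_state_space")) state_space$n_states else state_space
  pr <- state_pairs(s)
  if (length(energies) != s) stop("energies length does not match state space")
  nacs <- array(nacs, dim = dim_or3(nacs, nrow(pr)))
  if (dim(nacs)[1] != nrow(pr)) stop("pair count mismatch: got ", dim(nacs)[1],
                                     ", expected ", nrow(pr))
  gaps <- energies[pr[, "j"] + 1L] - energies[pr[, "i"] + 1L]
  out <- nacs
  for (k in seq_len(nrow(pr))) out[k, , ] <- nacs[k, , ] * gaps[k]
  out
}

#' Recover raw NAC vectors from smoothed couplings
#'
#' Inverse of [smooth_nacs_op()]: divides by the gap, with a floor on its
#' magnitude so the operation is total near degeneracies (the raw coupling
#' diverges there; the floored divisor keeps it finite). The sign of the
#' gap is preserved.
#'
#' @param smooth_nacs array P x n x 3 (Hartree/Bohr).
#' @param energies per-state energies (Hartree).
#' @param state_space a [state_space()] (or integer S).
#' @param gap_floor positive lower bound on |E_j - E_i| (Hartree).
#' @return array P x n x 3 of classical couplings (1/Bohr).
#' @export
unsmooth_nacs_op <- function(smooth_nacs, energies, state_space,
                             gap_floor = 1e-8) {
  if (gap_floor <= 0) stop("gap_floor must be > 0")
  s <- if (inherits(state_space, "ndn_state_space")) state_space$n_states else state_space
  pr <- state_pairs(s)
  if (length(energies) != s) stop("energies length does not match state space")
  smooth_nacs <- array(smooth_nacs, dim = dim_or3(smooth_nacs, nrow(pr)))
  if (dim(smooth_nacs)[1] != nrow(pr)) stop("pair count mismatch")
  gaps <- energies[pr[, "j"] + 1L] - energies[pr[, "i"] + 1L]
  div <- sign(gaps)
  div[div == 0] <- 1
  div <- div * pmax(abs(gaps), gap_floor)
  out <- smooth_nacs
  for (k in seq_len(nrow(pr))) out[k, , ] <- smooth_nacs[k, , ] / div[k]
  out
}

dim_or3 <- function(x, d1) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3) {
    n <- length(x) / (3 * d1)
    if (n != round(n)) stop("property array has wrong length")
    c(d1, n, 3)
  } else d
}

#' Ordered collection of multi-state samples
#'
#' @param samples list of [multistate_sample()] objects sharing one state
#'   space.
#' @param metadata named list; `provenance` free text. Units are internal
#'   atomic units once a dataset object exists.
#' @return object of class `ndn_dataset`.
#' @export
dataset <- function(samples, metadata = list()) {
  if (length(samples) > 0) {
    s0 <- samples[[1]]$state_space$n_states
    ok <- vapply(samples, function(x) x$state_space$n_states == s0, logical(1))
    if (!all(ok)) stop("all samples must share one state space")
  }
  structure(list(samples = samples, metadata = metadata),
            class = "ndn_dataset")
}

#' @export
print.ndn_dataset <- function(x, ...) {
  s <- if (length(x$samples)) x$samples[[1]]$state_space$n_states else NA
  cat("<dataset>", length(x$samples), "samples,", s, "states\n")
  invisible(x)
}

#' @export
length.ndn_dataset <- function(x) length(x$samples)

#' Split a dataset into train/validation/test parts
#'
#' Draws a uniform random permutation of the samples from the given seed
#' and partitions it. Counts are floors of fraction * n with the remainder
#' assigned by largest fractional part, so the partition is disjoint and
#' exhaustive.
#'
#' @param ds a [dataset()].
#' @param fractions numeric length 3 (train, val, test), positive, summing
#'   to 1 within 1e-9.
#' @param seed integer RNG seed.
#' @return named list of three datasets `train`, `val`, `test`, each with
#'   an `indices` attribute giving the source positions.
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(ds, "ndn_dataset"), length(fractions) == 3)
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(ds$samples)
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    fr <- fractions * n - counts
    counts[order(fr, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(fr, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  if (any(counts == 0)) {
    stop("split produces an empty part (counts ",
         paste(counts, collapse = "/"), "); adjust fractions")
  }
  perm <- with_preserved_seed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(counts[1])],
              val = perm[counts[1] + seq_len(counts[2])],
              test = perm[counts[1] + counts[2] + seq_len(counts[3])])
  out <- lapply(idx, function(i) {
    d <- dataset(ds$samples[i], ds$metadata)
    attr(d, "indices") <- i
    d
  })
  out
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-state energy reference offsets
#'
#' Computes the per-state mean energy of a training split; subtracting it
#' centers the regression targets. `apply_energy_reference()` with
#' `invert = TRUE` restores the original scale exactly.
#'
#' @param ds training dataset with energies present.
#' @return numeric vector of per-state offsets (Hartree).
#' @export
fit_energy_reference <- function(ds) {
  stopifnot(inherits(ds, "ndn_dataset"), length(ds$samples) > 0)
  e <- t(vapply(ds$samples, function(x) x$energies,
                numeric(ds$samples[[1]]$state_space$n_states)))
  if (length(ds$samples) == 1) e <- matrix(e, nrow = 1)
  colMeans(e)
}

#' @rdname fit_energy_reference
#' @param offsets per-state offsets from [fit_energy_reference()].
#' @param invert if `TRUE`, add the offsets back instead of subtracting.
#' @export
apply_energy_reference <- function(ds, offsets, invert = FALSE) {
  sgn <- if (invert) 1 else -1
  ds$samples <- lapply(ds$samples, function(x) {
    if (!is.null(x$energies)) x$energies <- x$energies + sgn * offsets
    x
  })
  ds
}
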