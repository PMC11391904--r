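#' Oscillator strength of a vertical transition
#'
#' f = (2/3) dE |mu|^2 in atomic units, from the excitation energy and the
#' 2-norm of the transition dipole vector; invariant under rotation of mu.
#'
#' @param delta_e excitation energy E_j - E_i (Hartree), > 0.
#' @param transition_dipole length-3 vector (a.u.).
#' @return dimensionless oscillator strength.
#' @export
oscillator_strength <- function(delta_e, transition_dipole) {
  if (any(delta_e <= 0)) {
    stop("oscillator strength requires an upward transition (delta_e > 0)")
  }
  (2 / 3) * delta_e * sum(transition_dipole^2)
}

#' Gaussian broadening of a stick spectrum
#'
#' I(E) = sum_sticks f G(E; E_abs, sigma) with sigma = fwhm / (2 sqrt(2 ln 2))
#' and unit-area Gaussians, so the integrated intensity equals the summed
#' oscillator strength.
#'
#' @param sticks data.frame with columns `energy_ev` and `f`.
#' @param fwhm_ev full width at half maximum (eV).
#' @param grid_ev energy axis (eV); should span the sticks +- 5 sigma.
#' @return data.frame `energy_ev`, `intensity` (per eV).
#' @export
broaden <- function(sticks, fwhm_ev = 0.1, grid_ev) {
  stopifnot(fwhm_ev > 0)
  sigma <- fwhm_ev / (2 * sqrt(2 * log(2)))
  lo <- min(sticks$energy_ev) - 5 * sigma
  hi <- max(sticks$energy_ev) + 5 * sigma
  if (nrow(sticks) > 0 && (min(grid_ev) > lo || max(grid_ev) < hi)) {
    inside <- sticks$energy_ev >= min(grid_ev) - 5 * sigma &
      sticks$energy_ev <= max(grid_ev) + 5 * sigma
    lost <- 1 - sum(sticks$f[inside]) / max(sum(sticks$f), 1e-300)
    warning(sprintf(
      "grid does not span all sticks +-5 sigma; ~%.2f%% of intensity truncated",
      100 * lost))
  }
  intensity <- rep(0, length(grid_ev))
  for (r in seq_len(nrow(sticks))) {
    intensity <- intensity + sticks$f[r] *
      stats::dnorm(grid_ev, sticks$energy_ev[r], sigma)
  }
  data.frame(energy_ev = grid_ev, intensity = intensity)
}

#' Ensemble absorption spectrum from model predictions
#'
#' Predicts per-state energies and transition dipoles for each geometry,
#' forms sticks (E_abs = E_j - E_i, f from [oscillator_strength()]) for
#' the requested pairs, broadens them and averages over the geometries
#' with equal weights.
#'
#' @param model trained model with energy and dipole heads.
#' @param geoms list of [geometry()] objects (e.g. a Wigner ensemble).
#' @param pairs matrix of 0-based (i, j) rows, or NULL for all pairs from
#'   the lowest state.
#' @param fwhm_ev Gaussian FWHM (eV).
#' @param grid_ev energy axis (eV); autogenerated from the sticks if NULL.
#' @return list: `spectrum` (data.frame energy_ev, intensity), `sticks`
#'   (data.frame geometry, i, j, energy_ev, f).
#' @export
ensemble_spectrum <- function(model, geoms, pairs = NULL, fwhm_ev = 0.1,
                              grid_ev = NULL) {
  if (!model$heads$dipoles || !model$heads$energies) {
    stop("ensemble spectrum requires energy and dipole heads; trained heads: ",
         paste(names(Filter(isTRUE, model$heads[1:4])), collapse = ", "))
  }
  if (inherits(geoms, "ndn_geometry")) geoms <- list(geoms)
  preds <- predict_all(model, geoms, need = c("energies", "dipoles"))
  allp <- state_pairs(model$states)
  if (is.null(pairs)) pairs <- allp[allp[, "i"] == 0, , drop = FALSE]
  sticks <- do.call(rbind, lapply(seq_along(preds), function(g) {
    pr <- preds[[g]]
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      k <- pair_index(i, j, model$states)
      de <- pr$energies[j + 1] - pr$energies[i + 1]
      if (de <= 0) return(NULL)
      data.frame(geometry = g, i = i, j = j,
                 energy_ev = hartree_to_ev(de),
                 f = oscillator_strength(de, pr$transition_dipoles[k, ]))
    }))
  }))
  if (is.null(grid_ev)) {
    sigma <- fwhm_ev / (2 * sqrt(2 * log(2)))
    grid_ev <- seq(min(sticks$energy_ev) - 6 * sigma,
                   max(sticks$energy_ev) + 6 * sigma, by = sigma / 8)
  }
  spec <- broaden(sticks, fwhm_ev, grid_ev)
  spec$intensity <- spec$intensity / length(geoms)
  list(spectrum = spec, sticks = sticks)
}
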