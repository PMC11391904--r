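#' Mean squared error over all components
#'
#' @param pred,ref numeric arrays of identical shape.
#' @return scalar MSE; zero iff the arrays are equal.
#' @export
property_loss <- function(pred, ref) {
  if (!identical(length(pred), length(ref))) {
    stop("shape mismatch: ", length(pred), " vs ", length(ref), " components")
  }
  mean((as.numeric(pred) - as.numeric(ref))^2)
}

#' Enumerate per-state phase vectors
#'
#' All sign assignments p in \{-1, +1\}^S with p_1 = +1 (the global sign is
#' unobservable, so 2^(S-1) distinct vectors remain). The sign carried by
#' pair (i, j) is p_i * p_j.
#'
#' @param n_states S.
#' @return matrix 2^(S-1) x S of signs.
#' @export
phase_vectors <- function(n_states) {
  if (n_states == 1) return(matrix(1, 1, 1))
  rest <- as.matrix(expand.grid(rep(list(c(1, -1)), n_states - 1)))
  unname(cbind(1, rest))
}

## per-pair signs implied by a phase vector
pair_signs_from_vector <- function(pvec, pairs) {
  pvec[pairs[, "i"] + 1L] * pvec[pairs[, "j"] + 1L]
}

## Normalize input: a list of per-pair property arrays. Accepts a single
## array whose first dimension is the pair index, or a list of such arrays
## (properties sharing one sign per pair, e.g. NAC + transition dipole).
as_pair_list <- function(x) {
  if (is.list(x) && !is.null(dim(x[[1]]))) return(x)
  if (is.list(x)) return(x)
  list(x)
}

pair_slab <- function(arr, k) {
  d <- dim(arr)
  if (is.null(d)) return(arr[k])
  if (length(d) == 2) return(arr[k, ])
  arr[k, , ]
}

## sum of squared error and cross terms per pair, over all listed properties
pair_sq_terms <- function(pred, ref) {
  pred <- as_pair_list(pred); ref <- as_pair_list(ref)
  np <- if (!is.null(dim(pred[[1]]))) dim(pred[[1]])[1] else length(pred[[1]])
  sq <- cross <- numeric(np)
  ntot <- 0
  for (q in seq_along(pred)) {
    dp <- dim(pred[[q]])
    if (!identical(dim(pred[[q]]), dim(ref[[q]])) ||
        !identical(length(pred[[q]]), length(ref[[q]]))) {
      stop("shape mismatch between predicted and reference pair properties")
    }
    for (k in seq_len(np)) {
      p <- as.numeric(pair_slab(pred[[q]], k))
      r <- as.numeric(pair_slab(ref[[q]], k))
      sq[k] <- sq[k] + sum(p^2) + sum(r^2)
      cross[k] <- cross[k] + sum(p * r)
      if (k == 1) ntot <- ntot + length(p) * np
    }
  }
  list(sq = sq, cross = cross, n = ntot)
}

#' Phase-free loss with independent per-pair signs
#'
#' For each state pair the squared error is minimized over the sign of the
#' predicted pair property (NAC and transition dipole of the same pair
#' share one sign), then averaged over all components. This relaxes the
#' per-state phase consistency and is therefore a lower bound on
#' [phase_vector_loss()].
#'
#' @param pred,ref per-pair property arrays (first dimension = pair index)
#'   or lists of such arrays sharing signs.
#' @return scalar loss; invariant to flipping any reference pair's sign.
#' @export
pairwise_phase_loss <- function(pred, ref) {
  t <- pair_sq_terms(pred, ref)
  sum(t$sq - 2 * abs(t$cross)) / t$n
}

#' Phase-free loss minimized over consistent phase vectors
#'
#' Minimizes the total squared error over all 2^(S-1) per-state phase
#' vectors, where pair (i, j) carries sign p_i * p_j. Exactly invariant to
#' applying any phase vector to the references; always >= the pairwise
#' loss and <= the plain MSE.
#'
#' @inheritParams pairwise_phase_loss
#' @param state_space a [state_space()] (or integer S <= 12).
#' @return scalar loss.
#' @export
phase_vector_loss <- function(pred, ref, state_space) {
  s <- if (inherits(state_space, "ndn_state_space")) state_space$n_states else state_space
  if (s > 12) stop("phase-vector enumeration infeasible for S = ", s,
                   " (2^(S-1) vectors); use the pairwise phase loss")
  pairs <- state_pairs(s)
  t <- pair_sq_terms(pred, ref)
  if (length(t$sq) != nrow(pairs)) stop("pair count does not match state space")
  pv <- phase_vectors(s)
  best <- Inf
  for (r in seq_len(nrow(pv))) {
    sg <- pair_signs_from_vector(pv[r, ], pairs)
    tot <- sum(t$sq - 2 * sg * t$cross)
    if (tot < best) best <- tot
  }
  best / t$n
}

## best phase vector (index + per-pair signs) for one sample, by values
best_phase_signs <- function(cross_by_pair, s, mode) {
  pairs <- state_pairs(s)
  if (mode == "pairwise") {
    sg <- sign(cross_by_pair); sg[sg == 0] <- 1
    return(sg)
  }
  pv <- phase_vectors(s)
  tots <- apply(pv, 1, function(v) sum(pair_signs_from_vector(v, pairs) *
                                         cross_by_pair))
  pair_signs_from_vector(pv[which.max(tots), ], pairs)
}

#' Combined multi-property training loss
#'
#' Weighted sum over the active properties P of t_P * L_P, with the
#' coupled-state properties (smoothed NACs and transition dipoles) routed
#' through the selected phase-free loss. Linear in each weight.
#'
#' @param prediction an `ndn_prediction` (see [predict_all()]).
#' @param sample an `ndn_sample` with the reference blocks.
#' @param weights named numeric weights, e.g. `c(E = 1, F = 1, C = 1, mu = 1)`;
#'   every property present in both prediction and sample must have one.
#' @param phase_mode "none", "pairwise" or "phase_vector".
#' @return scalar loss.
#' @export
combined_loss <- function(prediction, sample,
                          weights = c(E = 1, F = 1, C = 1, mu = 1),
                          phase_mode = c("phase_vector", "pairwise", "none")) {
  phase_mode <- match.arg(phase_mode)
  s <- sample$state_space$n_states
  total <- 0
  w <- function(nm) {
    if (is.na(weights[nm]) || is.null(weights[nm])) {
      stop("no loss weight defined for active property ", nm)
    }
    unname(weights[nm])
  }
  if (!is.null(prediction$energies) && !is.null(sample$energies)) {
    total <- total + w("E") * property_loss(prediction$energies, sample$energies)
  }
  if (!is.null(prediction$forces) && !is.null(sample$forces)) {
    total <- total + w("F") * property_loss(prediction$forces, sample$forces)
  }
  coupled_pred <- list(); coupled_ref <- list()
  if (!is.null(prediction$smooth_nacs) && !is.null(sample$smooth_nacs)) {
    coupled_pred$nac <- prediction$smooth_nacs
    coupled_ref$nac <- sample$smooth_nacs
  }
  if (!is.null(prediction$transition_dipoles) &&
      !is.null(sample$transition_dipoles)) {
    coupled_pred$tdm <- prediction$transition_dipoles
    coupled_ref$tdm <- sample$transition_dipoles
  }
  if (length(coupled_pred)) {
    ## NAC and transition dipole of a pair share one sign: minimize the
    ## weighted total over the common sign assignment
    wts <- c(nac = unname(if (!is.null(coupled_pred$nac)) w("C") else 0),
             tdm = unname(if (!is.null(coupled_pred$tdm)) w("mu") else 0))
    terms <- lapply(names(coupled_pred), function(nm) {
      t <- pair_sq_terms(coupled_pred[[nm]], coupled_ref[[nm]])
      list(a = wts[[nm]] / t$n, sq = t$sq, cross = t$cross)
    })
    A_sq <- Reduce(`+`, lapply(terms, function(t) t$a * t$sq))
    A_cross <- Reduce(`+`, lapply(terms, function(t) t$a * t$cross))
    sg <- switch(phase_mode,
                 none = rep(1, length(A_cross)),
                 pairwise = { x <- sign(A_cross); x[x == 0] <- 1; x },
                 phase_vector = best_phase_signs(A_cross, s, "phase_vector"))
    total <- total + sum(A_sq - 2 * sg * A_cross)
  }
  if (!is.null(prediction$permanent_dipoles) &&
      !is.null(sample$permanent_dipoles)) {
    total <- total + w("mu") * property_loss(prediction$permanent_dipoles,
                                             sample$permanent_dipoles)
  }
  total
}
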