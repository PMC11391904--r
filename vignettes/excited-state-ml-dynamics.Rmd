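---
title: "Learned excited-state surfaces and surface-hopping dynamics: models, losses, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned excited-state surfaces and surface-hopping dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
regression targets and why they are shaped the way they are, the phase-free
losses, the surface-hopping scheme, the analytic reference models, and the
numerical decisions a user may want to audit or change.

## The regression problem

A nonadiabatic molecular dynamics simulation needs, at every visited
geometry $R$, the adiabatic state energies $E_j(R)$, the nuclear forces
$F_j = -\partial E_j/\partial R$, and the nonadiabatic coupling vectors
$C_{ij} = \langle \Psi_i | \partial \Psi_j / \partial R \rangle$ between
state pairs; absorption spectra additionally need transition dipoles
$\mu_{ij}$ and permanent dipoles $\mu_j$. `namdnet` fits all of these with
atomistic message-passing networks so that a single forward pass serves
every head (`predict_all()`).

Two properties of the targets dictate the design:

1. **Couplings diverge at conical intersections**, $C_{ij} \propto
   1/(E_j - E_i)$. Fitting a quantity with poles is hopeless, so the
   trained target is the smoothed coupling
   $\tilde C_{ij} = C_{ij}\,(E_j - E_i)$, which is bounded through the
   seam (for the analytic models below it equals the eigenvector-projected
   gradient of the diabatic potential matrix and is manifestly smooth away
   from the seam). `smooth_nacs_op()` / `unsmooth_nacs_op()` implement the
   two directions; at prediction time the classical coupling is recovered
   by dividing by the *predicted* gap with a floored magnitude
   (`gap_floor`, default $10^{-8}$ Ha) so the operation is total. The
   identity $\tilde C = C\,(E_j - E_i)$ is verified to $10^{-12}$ relative
   on every loaded sample that carries both blocks.

2. **Signs of pair properties are not observables.** Each electronic
   wavefunction carries an arbitrary global sign $p_j = \pm 1$, so every
   quantity attached to a state pair ($\tilde C_{ij}$, $\mu_{ij}$)
   changes sign under $p_i p_j$ from one quantum-chemistry calculation to
   the next. The package treats the sign structure as part of the loss,
   not of the data (below).

## Representations and heads

Two feature builders are provided behind one configuration surface
(`rep_config()`):

* `invariant`: per-element embeddings refined by continuous-filter
  convolutions over interatomic distances (Gaussian radial basis with a
  cosine cutoff envelope that vanishes smoothly at the cutoff radius).
  Scalar features only; all outputs built from them are rotation
  invariant. Vectorial targets are obtained as analytic gradients of
  auxiliary *virtual* invariant scalars (one per state pair), which makes
  them exactly covariant by construction.
* `equivariant`: additionally carries per-atom vector features updated
  from neighbor directions and gated channel mixings, so vectorial
  targets can be read out directly as gated combinations of the vector
  channels.

Heads (`head_config()`): per-state energies as sums of atomwise
contributions plus per-state reference offsets (fitted as training-set
means); forces as exact negative gradients of the energy head — never a
separate head, so energy/force consistency is structural; smoothed
couplings either `equivariant_direct` or `virtual_derivative` (the only
option for the invariant branch, and selectable for the equivariant one so
the two routes can be compared within one model family); dipoles through
an atomic partial-charge model $\mu = \sum_a q_a (R_a - \bar R)$ with
charges re-centered per molecule — to the total molecular charge for
permanent dipoles, to zero for transition dipoles, which makes the latter
rigorously translation invariant. The geometric centroid is used as the
origin so permanent dipoles of ions are well defined.

Everything is differentiated with a small reverse-mode tape
(`R/autograd.R`) whose backward passes build graph nodes, so the
force and virtual-derivative outputs (themselves gradients) can be
differentiated again with respect to the parameters during training.
Gradient correctness is pinned by finite-difference tests at relative
tolerance $10^{-4}$ (step $10^{-4}$ Bohr) and symmetry tests under 50
random rigid motions plus the 48 signed permutation matrices.

Defaults: 32 features, 2 interaction blocks, cutoff 10 Bohr, 16 radial
basis functions, shifted-softplus nonlinearities, seeded N(0, 1/fan-in)
initialization. All sizes are configurable; the validation protocol below
deliberately uses a smaller network.

## Phase-free training

For coupled-state properties grouped per pair (the NAC and transition
dipole of a pair share one sign), two losses are implemented:

* `pairwise_phase_loss()`: $\sum_{ij} \min_{s=\pm1} L(s\,\hat y_{ij},
  y_{ij})$ — each pair picks its own sign. Cheap and fully sign-blind,
  but it can silently accept sign patterns no wavefunction phases could
  produce.
* `phase_vector_loss()`: $\min_{p \in \{\pm1\}^S, p_1 = +1} \sum_{ij}
  L(p_i p_j\,\hat y_{ij}, y_{ij})$ — one consistent per-state sign
  vector, enumerated exhaustively ($2^{S-1}$ vectors; refused for
  $S > 12$ with a pointer to the pairwise loss).

Exact properties (tested): the phase-vector loss is invariant under any
phase vector applied to the references; `pairwise ≤ phase_vector ≤ MSE`
always; for $S = 2$ the two coincide; for $S = 3$ a single flipped pair
separates them. During optimization the minimizing sign assignment is
treated as a constant of the differentiation (the min is piecewise smooth;
this is the standard subgradient choice). The combined loss is
$\sum_P t_P L_P$ with per-property weights (default 1, matching a
balanced-weight training convention) and an optional per-atom
normalization variant of the coupled-property terms (`atomistic`).

Training uses minibatch Adam (default learning rate $10^{-3}$, the
validation protocol passes $3\times10^{-3}$), global gradient-norm
clipping at 10, early stopping on the validation loss with patience 300
epochs, and returns the best-validation parameters. Runs are reproducible
from `(seed, config, split)`.

## Analytic diabatic models as ground truth

`diabatic_model()` wraps a symmetric potential matrix $V(q)$ with analytic
gradients on a few internal modes. Adiabatic reference data come from
exact linear algebra: energies are eigenvalues, forces Hellmann–Feynman
expectations $-u_j^\top \nabla V u_j$, couplings
$u_i^\top \nabla V u_j/(E_j - E_i)$, dipoles eigenvector-transformed
diabatic dipole matrices. Eigenvector signs follow a fixed convention
(largest-magnitude component positive, ties to the lowest index);
`phase_corruption` then applies a uniformly drawn phase vector per sample
to emulate raw quantum-chemistry output. Note that with $S = 2$ half of
the drawn vectors are the identity, so "corruption probability 1" flips
roughly half the samples.

The modes are mapped onto **bond stretches of a small pseudo-molecule** —
a diatomic for one mode, a bent C–N–H-like triatomic for two — rather
than onto free planar coordinates of a single atom: a lone atom has no
neighbors, so a distance-based message-passing model would be constant in
its coordinates, and absolute planar coordinates would break the rotation
invariance the whole pipeline assumes. With the bond mapping the
downstream modules consume perfectly ordinary geometries and Cartesian
property arrays, so the tests exercise the real code path.

Built-ins: a 1D avoided crossing (two shifted harmonic wells, constant
coupling), a 2D two-state linear vibronic model with tuning mode $q_1$ and
coupling mode $q_2$, and a 3-state extension. The 2D model's parameters
(frequencies 0.007 and 0.014 Ha — mid-infrared stretches for the chosen
masses; tuning gradient −0.08 Ha/Bohr, coupling 0.02 Ha/Bohr, vertical
offset 0.02 Ha) are typical vibronic magnitudes chosen once so that a
vertical excitation from the Franck–Condon region reaches the seam within
a few stretch periods — the model is deliberately seam-proximal so that
100 fs of dynamics shows ultrafast internal conversion. The degeneracy at
$q = (\delta/(\kappa_1-\kappa_2), 0)$ is exact by construction; the raw
coupling diverges on approach while the smoothed one stays bounded, and an
eigenvector transported around the seam acquires the geometric-phase sign
flip (both tested).

Wigner initial conditions draw mode coordinates and momenta from the
harmonic ground-state distribution, $\sigma_q^2 = 1/(2 m \omega)$,
$\sigma_p^2 = m\omega/2$, with the effective mode masses taken from the
diagonal of the inverse Wilson metric $G = J M^{-1} J^\top$ of the bond
coordinates (kinetic coupling between the two bonds through the shared
atom is neglected *for the sampling widths only*; the Cartesian velocities
are constructed through $G^{-1}$ so the drawn mode momenta are realized
exactly). Sampled marginals are verified against these variances at
$n = 10^4$ within 3 standard errors.

## Surface hopping

The engine (`run_ensemble()` / `run_trajectory()`) implements Tully-style
fewest switches:

* Nuclei: velocity Verlet on the active surface, default $\Delta t =
  0.5$ fs.
* Electrons: $i\dot c_j = E_j c_j - i \sum_k (v \cdot C_{jk}) c_k$ in the
  adiabatic basis, integrated with 25 unitary substeps per nuclear step,
  linearly interpolating $E$ and $v\cdot C$ between the step endpoints.
  For two states the substep exponential is evaluated in closed form
  (Pauli decomposition); the general path diagonalizes the Hermitian
  generator. Norm conservation is machine-exact per substep.
* Hops: $g_{a\to j} = \max(0,\, 2\Delta t\,\mathrm{Re}(c_a^* c_j)\,
  (v\cdot C_{aj})/|c_a|^2)$, target drawn by inverse CDF against one
  uniform variate (pre-drawn per step and trajectory so ensembles are
  reproducible regardless of aborted trajectories). Accepted hops rescale
  velocities along $C_{aj}$ to conserve total energy exactly (quadratic
  solve; the smaller-magnitude root); energetically frustrated hops leave
  velocities unchanged by default or reflect the projected component
  (`frustrated = "reflect"`), which conserves energy exactly.
* Decoherence: the standard energy-based damping of inactive amplitudes
  with constant $C = 0.1$ Ha, on by default, switchable off.
* Sign continuity: predicted coupling vectors are aligned with the
  previous step's by sign (their global sign is arbitrary frame to
  frame).
* Validity: the total energy is monitored every step; a trajectory whose
  drift exceeds 0.2 eV (configurable) is flagged invalid from that time
  onward and excluded from later population averages — times with no
  valid trajectory are masked.

Populations are fractions of active states among valid trajectories with
binomial standard errors. `fit_sequential_kinetics()` fits the closed-form
populations of the first-order chain $S_{n-1} \to \dots \to S_0$ (via a
small matrix exponential, so equal rates need no special casing) by
Levenberg–Marquardt on log-rates; flat-at-unity populations return an
infinite-lifetime flag, flat-below-unity populations are rejected as
non-identifiable.

Two numerical facts worth knowing. First, velocity Verlet's energy error
scales as $(\omega\Delta t)^2$: at 0.5 fs a hydrogen-stretch mode shows
bounded oscillations of a few $10^{-5}$ Ha, a soft carbon-stretch mode a
few $10^{-7}$ Ha; the $10^{-4}$ Ha conservation checks therefore run on
smooth (uncoupled or single-state) surfaces. Second, the *lower adiabatic
surface of a conical model has a derivative discontinuity at the seam*;
any fixed-step integrator that crosses it picks up an error unrelated to
the hop algebra (hops themselves conserve energy to $10^{-9}$ Ha, tested
separately), which is exactly what the drift monitor is for.

## Spectra

Oscillator strengths use the standard atomic-units form
$f = \tfrac{2}{3}\,\Delta E\,\lVert\mu_{ij}\rVert^2$; downward transitions
are an error, zero dipoles give zero. Broadening sums unit-area Gaussians
($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, default FWHM 0.1 eV), so the
integrated intensity equals the summed oscillator strength (checked to
$10^{-6}$ relative) and a single broadened stick has the configured FWHM
within the grid resolution. Ensemble spectra weight all supplied
geometries equally (configurable only by the user's choice of geometry
list).

## Validation protocol and problem sizes

The package validates itself at desk scale, chosen once: 2000 Wigner
samples of the 2D conical model with full phase corruption, an 80/10/10
split, networks with 16 features, 1 interaction block and 8 radial basis
functions, batch 256, learning rate $3\times10^{-3}$, 80 epochs, three
seeds per representation kind; 200-trajectory ensembles for the
ML-vs-exact dynamics comparison at 0.5 fs over 100 fs. At these sizes the
held-out errors sit an order of magnitude or more below the acceptance
thresholds (energies $5\times10^{-3}$ Ha, forces $10^{-2}$ Ha/Bohr,
smoothed couplings $5\times10^{-2}$ a.u.) and the full validation run
completes in roughly a quarter hour on one CPU.

One statistical choice deserves a note: ML-driven and exact-surface
populations are compared at six well-separated times (every 20 fs), each
required to agree within $3\sigma$ of the combined binomial error. A
maximum-z test over a dense time grid is *not* used: calibration with two
exact-surface ensembles under independent seeds shows such a max over ~20
correlated points exceeds $3\sigma$ in roughly a third of null runs, so it
would reject perfectly matching dynamics.

## What the synthetic benchmark does and does not show

The analytic models reproduce the statistical structure that makes
excited-state learning hard — several coupled states, a true conical
intersection with divergent raw couplings, random per-sample phase flips —
on low-dimensional, noise-free surfaces with small pseudo-molecules.
Passing tests therefore demonstrate the correctness of the machinery
(symmetries, derivatives, losses, hopping algebra, reproducibility) and
the *relative* behavior of the two representations, not chemical accuracy
on real molecules: real datasets bring high-dimensional conformational
spaces, electronic-structure noise, state-ordering ambiguities, and
training-set coverage problems (trajectories leaving the sampled region —
visible as total-energy drift — are flagged, not fixed). Known
limitations: singlet states only; no spin–orbit coupling; exhaustive
phase-vector enumeration is exponential in the state count; the built-in
kinetics model assumes an irreversible sequential chain and is not
meaningful for strongly recrossing systems.
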