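# namdnet

Machine-learned potentials and surface-hopping dynamics for electronically
excited molecules, in R.

Photochemistry — cis/trans isomerization, internal conversion after light
absorption, radiationless decay through conical intersections — is governed
by several coupled potential energy surfaces and by the nonadiabatic
coupling (NAC) vectors that connect them. Quantum-chemistry calculations of
these quantities are far too expensive to drive the thousands of
trajectories a surface-hopping simulation needs, so `namdnet` learns them:
message-passing neural network potentials predict, for every geometry, the
energies `E_j` and forces `F_j = -dE_j/dR` of each singlet state, the
coupling vectors between state pairs, and permanent/transition dipole
moments. A built-in fewest-switches surface-hopping (FSSH) engine and a
Franck–Condon spectrum module consume the trained models, and analytic
diabatic Hamiltonians (avoided crossings, a conical-intersection model)
supply exact reference data so the whole pipeline can be validated
end-to-end without any external electronic-structure code.

Two learning problems make excited states harder than ground states, and
both are addressed explicitly:

* **Coupling singularities.** The NAC diverges as states become degenerate,
  `C_ij ∝ 1/(E_j − E_i)`. Models are therefore trained on the *smoothed*
  couplings `C̃_ij = C_ij (E_j − E_i)`, which stay bounded at conical
  intersections; predictions are converted back with a floored divisor at
  inference time (`to_classical_nacs()`).
* **The wavefunction phase problem.** Each electronic state carries an
  arbitrary sign, so pair properties (NACs, transition dipoles) have an
  arbitrary sign per data point. Two phase-free losses are provided: a
  per-pair sign minimization, and a stricter minimization over all
  2^(S−1) consistent per-state phase vectors, `min_p Σ_ij L(p_i p_j ·
  pred_ij, ref_ij)`.

Both a rotationally invariant representation (scalar features, continuous-
filter convolutions; vectorial outputs via derivatives of virtual scalars)
and an equivariant one (additional per-atom vector features; direct
vectorial prediction) are implemented, so their accuracy on vectorial
excited-state properties can be compared within one code base. Forces are
always exact analytic derivatives of the predicted energies — the package
ships its own reverse-mode autodiff tape with support for the second-order
derivatives that force/NAC training requires.

The FSSH engine propagates nuclei with velocity Verlet on the active
surface, integrates the electronic amplitudes with a unitary
matrix-exponential substep scheme, hops stochastically with probability
`g_{a→j} = max(0, 2Δt Re(c_a* c_j)(v·C_aj)/|c_a|²)`, rescales velocities
along the coupling vector to conserve total energy, applies an optional
energy-based decoherence correction, and monitors total-energy drift to
flag unreliable trajectories. Ensemble populations, binomial errors, and
sequential-kinetics lifetimes (`τ = 1/k`) are computed from the trajectory
logs. Absorption spectra use `f = (2/3) ΔE |μ_ij|²` (atomic units) with
Gaussian broadening (default FWHM 0.1 eV).

## Worked example

Train an equivariant model on phase-corrupted samples of the built-in
two-state conical-intersection model, then run ML-driven surface hopping:

```r
library(namdnet)

model <- model_conical_2d()                 # analytic diabatic reference
ds <- generate_dataset(model, sampling_spec("harmonic_wigner", 400, seed = 1,
                                            phase_corruption = 1.0))
splits <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 1)

nn <- create_model(
  rep_config("equivariant", n_features = 16, n_interactions = 1,
             n_radial_basis = 8, seed = 1),
  head_config(energies = TRUE, forces = TRUE, nacs = TRUE, dipoles = FALSE),
  state_space(2))
nn <- train_model(nn, splits$train, splits$val,
                  train_config(epochs = 40, lr = 3e-3, batch_size = 128,
                               seed = 1, phase_mode = "phase_vector"))
evaluate_model(nn, splits$test)
#>      property     mae    rmse n_components
#> 1    energies 0.00105 0.00143           80
#> 2      forces 0.00603 0.01050          720
#> 3 smooth_nacs 0.00326 0.00642          360
```

Held-out mean absolute errors are ~1 mHa for state energies, ~6 mHa/Bohr
for forces and ~3×10⁻³ a.u. for the smoothed couplings — small fractions
of the surface variation — even though every training sample had its
coupled-property signs randomized (the phase-vector loss recovers them).

```r
ics <- sample_initial_conditions(model, state = 1, n = 50, seed = 2)
traj <- run_ensemble(ml_provider(nn, model$atomic_numbers), ics,
                     model$masses, n_states = 2,
                     sh_config(t_max_fs = 60, seed = 3))
subset(ensemble_populations(traj), time_fs %in% c(0, 20, 40, 60) & state == 1)
#>  time_fs state population     se n_valid
#>        0     1       1.00 0.0000      50
#>       20     1       0.52 0.0707      50
#>       40     1       0.40 0.0693      50
#>       60     1       0.42 0.0698      50
```

Starting on S1, half the ensemble has decayed through the intersection
seam within ~20 fs; the plateau with recrossings afterwards is the
expected behavior of this strongly coupled small-gap model.

A command-line workflow (`make-synthetic`, `train`, `dynamics`, `spectra`,
`error-map`, ...) is available through `ndn_main()` or the
`inst/cli/namdnet` launcher; every run writes a `manifest.json` with the
configuration hash and seed.

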