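# nsemd

Neutron spin echo (NSE) observables and internal-mode analysis from
molecular trajectories, in R.

## The problem

NSE spectroscopy on protein solutions measures the normalized coherent
intermediate scattering function I(Q,t)/I(Q,0) at nanometer length scales
and nanosecond times — exactly where the rigid-body tumbling of a protein
multimer overlaps with its large-scale internal modes. Deciding how much
of the measured Q-dependent diffusivity comes from internal motion (and
*which* motions carry it) requires a computational chain: simulate or load
trajectories, compute the coherent ISF, extract effective diffusion
coefficients by cumulant analysis, build a rigid-body hydrodynamic
reference, strip roto-translation to isolate internal modes, localize them
(PCA, conformational networks, collective variables), and correct measured
spectra for finite-concentration effects. `nsemd` packages that chain for
structural-biophysics users working on multimeric enzymes (the synthetic
study system is an LDH-like homotetramer with tagged catalytic loops).

## The core quantities

* Cumulant analysis of the ISF: ln I(Q,t)/I(Q,0) = −Γt + (K₂/2)t², with
  D_eff(Q) = Γ/Q² (Å²/ns).
* First-cumulant rigid-body spectrum for diffusion tensors D^T, D^R
  (bead-model Rotne–Prager–Yamakawa hydrodynamics, evaluated at the center
  of diffusion):

      D(Q) = [ Σ_jk b_j b_k ⟨ e^{iQ·(r_j−r_k)} (Q·D^T·Q + L_j·D^R·L_k) ⟩ ]
             / [ Q² Σ_jk b_j b_k ⟨ e^{iQ·(r_j−r_k)} ⟩ ],   L_k = r_k × Q

* Additive decomposition D_tot(Q) = D_rigid(Q) + D_int(Q), with D_int from
  roto-translation-removed trajectories.
* Solution correction D₀(Q) = D_eff(Q)·S(Q)/H(Q): S(Q) from a SAXS
  concentration series extrapolated to C = 0, H anchored to a DLS
  translational diffusion constant.
* Harmonic-approximation collective-variable diffusivity D = ⟨δd²⟩/τ for
  inter-loop distances; leader-algorithm + Markov clustering for the
  conformational-substate network.

Every stage is testable without external data through seeded generators:
rigid-body Brownian dynamics with anisotropic tensors, exact
Ornstein–Uhlenbeck internal modes, toy tetramers with exact loop
geometry, and synthetic SAXS series with imposed S(Q).

## Worked example

```r
library(nsemd)
tt <- toy_tetramer(25, loop_spec = list(n_loop = 5,
                                        distances = c(45, 60, 75)), seed = 1)
beads <- build_bead_model(tt$system, "one_bead_per_residue")
tens <- diffusion_tensor(beads, temperature = 298,
                         viscosity = d2o_viscosity(298))
print(tens)
#> Rigid-body tensors (100 beads, T = 298 K, eta = 1.099 cP, rescale = 1)
#>   tr(D_T)/3 = 7.636 A^2/ns, tr(D_R)/3 = 0.006085 rad^2/ns
#>   coupling magnitude |D_C| = 0.00329

tr <- simulate_rigid_bd(tt$system, tens, 5e4, 0.05, seed = 42)
Q <- seq(0.05, 0.25, length.out = 6)
eff <- spectrum_with_error(tr, tt$system, Q, fit_window = "auto",
                           n_orientations = 24, max_lag = 1.5)
rigid <- rigid_body_spectrum(tt$system, tens, Q)
round(cbind(Q = Q, simulated = eff$D, formula = rigid$D), 3)
#>         Q simulated formula
#> [1,] 0.05     8.138   8.158
#> [2,] 0.09    10.810  10.879
#> [3,] 0.13    10.868  10.992
#> [4,] 0.17    11.006  11.040
#> [5,] 0.21    11.118  11.159
#> [6,] 0.25    11.044  11.069
```

The simulated cumulant spectrum tracks the closed-form rigid-body curve:
flat near the translational value tr(D_T)/3 ≈ 7.6 Å²/ns at low Q, rising
where rotation contributes, with a first maximum where the inter-subunit
correlations peak. Adding Ornstein–Uhlenbeck loop modes
(`add_internal_ou()`) and removing roto-translation
(`remove_rototranslation()` → `internal_spectrum()`) yields the internal
contribution that `compose_total()` adds back onto the rigid curve.

A complete configured run (spectra, fluctuation profiles, networks, CV
traces, manifest):

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "nsemd"))
```

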