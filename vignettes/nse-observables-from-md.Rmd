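---
title: "Computing neutron spin echo observables and internal-mode diffusivities from molecular trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing neutron spin echo observables and internal-mode diffusivities from molecular trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsemd)
```

## The observable and the model

Neutron spin echo (NSE) spectroscopy measures the normalized coherent
intermediate scattering function $I(Q,t)/I(Q,0)$ of a protein solution
directly in the time domain, out to tens of nanoseconds. At the probed
wavevectors ($Q \sim 0.03$–$0.25\,\mathrm{\AA}^{-1}$) the signal is
dominated by cross-correlations of separated scattering centers, so it
reports the relative motion of protein domains — rigid-body translation
and rotation of the whole multimer, plus whatever large-scale internal
modes are thermally active.

`nsemd` implements the computational chain that connects a molecular
trajectory (or a rigid structure) to this observable and decomposes it:

1. **Coherent ISF** (`coherent_isf()`): for scattering lengths $b_k$ and
   positions $r_k(t)$,
   $$I(Q,t) = \Big\langle \sum_{j,k} b_j b_k\,
   e^{i\mathbf{Q}\cdot[\mathbf{r}_j(t_0+t)-\mathbf{r}_k(t_0)]}
   \Big\rangle_{t_0,\hat{Q}},$$
   averaged over time origins and over a deterministic spherical Fibonacci
   set of $\hat Q$ directions (solution isotropy). A low-discrepancy set
   beats random directions at equal cost and needs no seed.
2. **Cumulant analysis** (`cumulant_fit()`): least squares of
   $\ln I(Q,t)/I(Q,0) = -\Gamma t + \tfrac{K_2}{2}t^2$ over the initial
   decay; the effective diffusion coefficient is
   $D_{\mathrm{eff}}(Q)=\Gamma/Q^2$. Only the first two cumulants are
   fitted; $K_3$ is deliberately excluded (the third-order term is not
   identifiable on noisy short-window data and the first two terms
   describe the decays well).
3. **Rigid-body reference** (`diffusion_tensor()`,
   `rigid_body_spectrum()`): a bead model of the structure yields the
   translational and rotational diffusion tensors $D^T\!, D^R$ via the
   Rotne–Prager–Yamakawa pair mobility, supermatrix inversion, and
   contraction to a $6\times6$ rigid-body friction matrix at the center of
   diffusion. The first-cumulant rigid-body spectrum is
   $$D(Q) = \frac{\sum_{j,k} b_j b_k \big\langle e^{i\mathbf{Q}\cdot
   (\mathbf{r}_j-\mathbf{r}_k)}\,(\mathbf{Q}\!\cdot\! D^T\!\cdot\!\mathbf{Q}
   + \mathbf{L}_j\!\cdot\! D^R\!\cdot\!\mathbf{L}_k)\big\rangle_{\hat Q}}
   {Q^2 \sum_{j,k} b_j b_k \big\langle e^{i\mathbf{Q}\cdot(\mathbf{r}_j-
   \mathbf{r}_k)}\big\rangle_{\hat Q}},
   \qquad \mathbf{L}_k = \mathbf{r}_k \times \mathbf{Q}.$$
4. **Decomposition** (`remove_translation()`, `remove_rototranslation()`,
   `internal_spectrum()`, `compose_total()`): frame-wise superposition
   onto a reference isolates internal motion; the total spectrum is
   modeled as $D_{\mathrm{tot}}(Q) = D^{\mathrm{rigid}}(Q) +
   D^{\mathrm{Int}}(Q)$, an additivity assumption the test suite makes
   falsifiable (see below).
5. **Localization** (`pca_modes()`, `mode_contribution()`,
   `msf_profile()`, `leader_cluster()`, `markov_cluster()`, `loop_cv()`,
   `harmonic_diffusivity()`, `classify_active_site()`): principal
   component analysis and mode-projected virtual trajectories quantify how
   much of $D^{\mathrm{Int}}$ the leading modes carry; leader-algorithm
   clustering plus Markov clustering turn the trajectory into a network of
   conformational substates and kinetic basins; collective loop-distance
   variables get a harmonic-approximation diffusivity
   $D = \langle\delta d^2\rangle/\tau$.
6. **Solution corrections** (`structure_factor_from_series()`,
   `apply_solution_correction()`): measured spectra at finite
   concentration are corrected to infinite dilution via
   $D_0(Q) = D_{\mathrm{eff}}(Q)\,S(Q)/H(Q)$, with $S(Q)$ from a SAXS
   concentration series and $H(Q)$ anchored to a DLS translational
   diffusion constant.

Units throughout: $Q$ in $\mathrm{\AA}^{-1}$, $t$ in ns, $D$ in
$\mathrm{\AA}^2/\mathrm{ns}$, temperatures in K, viscosities in cP.

## Parameters that matter, and their defaults

* **Orientational average.** `coherent_isf()` defaults to 64 Fibonacci
  directions; the trajectory route converges quickly in direction count
  because the time/origin average already mixes orientations. The
  closed-form `rigid_body_spectrum()` defaults to 512 directions: its
  rotational cross term $\mathbf{L}_j \cdot D^R \cdot \mathbf{L}_k$
  converges noticeably more slowly in the angular average, and the
  evaluation is cheap for a single structure. Both routes share the same
  direction construction.
* **Cumulant fit window.** The default window is 0–50 ns, the window
  appropriate for NSE-scale data. For strongly decaying synthetic curves
  the package also provides `fit_window = "auto"`, which ends the window
  where $\ln I$ has dropped by 0.3 (at least 5 lag points). The first
  cumulant is a $t\to0$ property: restricting the fit to the initial decay
  keeps the two-term truncation bias below sampling noise at high $Q$,
  which a fixed long window does not.
* **Bead model.** One bead per residue with an effective 2.9 Å radius, the
  standard style for protein hydrodynamics at residue resolution; per-atom
  and user-supplied modes exist. The per-bead spin friction
  $8\pi\eta a^3$ is included so a single bead reproduces the
  Stokes–Einstein–Debye law exactly and sparse models stay well posed.
* **Superposition.** Uniform weights over the selection; the default
  reference is the trajectory mean after one pre-alignment pass (one
  iteration), which minimizes leakage of rigid motion into apparent
  internal motion. A crystal-structure reference can be supplied.
  Whether to superpose on C$\alpha$ or all atoms is left to the caller's
  selection; the toy systems here are single-bead residues.
* **Clustering.** RMSD leader algorithm at a 1.5 Å cutoff, first-created
  leader wins (deterministic); RMSD is computed after optimal
  superposition onto the candidate leader — on roto-translation-removed
  trajectories this is nearly moot, but it makes the routine safe on raw
  input. Markov clustering defaults: expansion 2, inflation 1.8, prune
  $10^{-6}$ — common MCL practice.
* **Solution correction.** $S(Q)$ by linear-in-$C$ extrapolation of
  $I(Q,C)/C$ (the dilute-regime virial behaviour; higher orders are a
  parameter), renormalized so the top decile of $Q$ averages to 1.
  $H(Q)$ is treated as a $Q$-independent scalar over the anchor window
  $Q > 0.06\,\mathrm{\AA}^{-1}$, where model calculations show no
  oscillatory structure in the hydrodynamic function; no microscopic
  $H(Q)$ is implemented.
* **Collective variable.** The loop–loop distance is the **mean** over
  matched C$\alpha$ pairs (not the raw sum), so it carries Å units of a
  physical distance; the `reduce = "sum"` convention is exposed for
  comparison. The ACF is fitted down to $1/e$ by default and the
  estimator refuses traces shorter than five decorrelation times.
* **D$_2$O viscosity** (`d2o_viscosity()`): a Vogel fit for light water
  scaled by the heavy-water ratio 1.23; adequate over 280–340 K and
  overridable everywhere a viscosity enters.

## What the synthetic generators emulate

Real input data for this analysis — microsecond all-atom MD of a solvated
tetramer and beamline scattering curves — cannot ship with a package, so
every stage is validated against seeded generators with known ground
truth:

* `simulate_rigid_bd()` propagates a rigid body by Euler–Maruyama steps
  with anisotropic body-frame tensors (translation covariance $2D^Tdt$
  rotated to the lab frame; rotational kicks with covariance $2D^Rdt$
  composed onto the orientation and re-orthonormalized).
* `add_internal_ou()` superimposes Ornstein–Uhlenbeck processes of
  prescribed variance $\sigma_i^2$ and relaxation $\tau_i$ along
  orthonormal body-frame mode directions, using the exact OU update.
  `orthogonalize_modes()` projects mode directions onto the internal
  subspace so they carry no net roto-translation.
* `toy_tetramer()` builds a four-subunit D2-symmetric bead structure whose
  tagged "catalytic loop" centroids sit at exact pairwise distances
  (default 45/60/75 Å, the Pythagorean rectangle spanning the 36–75 Å
  range of loop separations in an LDH-sized tetramer).
* `synthetic_saxs_series()` and `ideal_nse_curves()` generate scattering
  fixtures with imposed $S(Q)$ and imposed cumulants.

Noise streams are separated per component (translation, rotation, each OU
mode) through seeds derived from the user seed, so adding a mode never
perturbs the rigid-body realization — ablations stay comparable.

What these generators deliberately do **not** emulate: force-field
physics, solvent-mediated friction on internal modes, anharmonic
conformational jumps, and temperature dependence beyond user-specified
parameter ladders. Passing tests therefore certify the *estimators and
transformations*, not any claim about real proteins; applied to real
trajectories the same estimators inherit the force field's biases, which
is why rigid-body motion is taken from bead-model hydrodynamics (anchored
to DLS via `rescale_tensors()`) and only the internal part from the
trajectory.

## Numerical choices

* The ISF kernel reduces the double atom sum to
  $A(\mathbf{q},t)\,\overline{A(\mathbf{q},t_0)}$ with
  $A=\sum_k b_k e^{i\mathbf{q}\cdot r_k}$, evaluated in compiled code with
  a complex recurrence over arithmetic $Q$ grids; time origins can be
  strided (overlapping origins are kept by default — slightly correlated
  but lower-variance).
* Trajectory-derived spectra get standard errors by block averaging
  (`spectrum_with_error()`, default 8 contiguous blocks): each block is
  analyzed independently and the across-block spread propagated. All
  oracle-equivalence tests compare in units of these errors.
* Per-$Q$ cumulant-fit failures become flagged `NA` gaps with a warning,
  never silent drops; $F(Q)$ below a numerical floor in the rigid formula
  is flagged the same way.
* The center of diffusion is found by solving the $3\times3$ linear system
  that makes the translation–rotation coupling block symmetric, then the
  $6\times6$ friction matrix is rebuilt about that origin; the coupling is
  excluded from the spectrum formula (as in the displayed first-cumulant
  expression) but reported as a diagnostic.
* Degenerate inputs error early and by name: coincident beads, collinear
  superposition selections, constant CV traces, all-zero scattering
  lengths, anchor windows without support, non-overlapping SAXS grids.
* MCL works on the column-stochastic transpose (the classical convention),
  extracts attractors from the limit diagonal, and merges overlapping
  attractor sets through connected components; reducible chains return
  their communicating classes exactly.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` choose sizes that make the
statistical checks sharp on a single CPU: a 100-bead toy tetramer with
$2\times10^5$ Brownian-dynamics frames for the central
simulation-vs-formula equivalence (8 $Q$ points, agreement within 3
combined block standard errors); 20 independent seeds of
$3\times10^4$-frame BD+OU trajectories for the mode-recovery statistics
(trace length 750 $\tau$, where the $O(\tau/T)$ estimator biases are far
below the seed-to-seed spread); a 320-bead LDH-scale synthetic tetramer
for the structure-derived observables. The demo pipeline config trims the
same workflow to a few thousand frames per temperature.

## Known limitations

* $H(Q)$ is a scalar anchor, not a microscopic hydrodynamic function; the
  corrected spectrum's *shape* below the anchor window inherits $S(Q)$
  errors directly.
* The harmonic-approximation diffusivity assumes a single dominant
  relaxation; multi-exponential ACFs are fitted on their initial decay
  only and the variance/timescale attribution blurs when timescales mix.
* Finite-trace estimates of OU variance and $\tau$ each carry a
  $\sim 2\tau/T$ downward bias (their ratio cancels in $D$); traces
  shorter than $5\tau$ are refused rather than estimated.
* The leader algorithm is order-dependent by construction (first leader
  wins); this is deterministic and documented, but cluster counts are
  comparable only across runs with the same frame order and stride.
* XTC trajectories are not read; DCD (and in-memory arrays) are the
  supported trajectory inputs, PDB the structure input.

## A worked example

```{r example, eval = FALSE}
library(nsemd)

## synthetic study system: LDH-like toy tetramer, loops 45/60/75 A apart
tt <- toy_tetramer(25, loop_spec = list(n_loop = 5,
                                        distances = c(45, 60, 75)), seed = 1)
beads <- build_bead_model(tt$system, "one_bead_per_residue")
tens <- diffusion_tensor(beads, temperature = 298,
                         viscosity = d2o_viscosity(298))

## ground-truth dynamics: rigid-body BD + one loop mode (sigma^2 = 4 A^2,
## tau = 2 ns)
loopA <- select_atoms(tt$system, chains = "A", resno_range = tt$loop_range)
U <- orthogonalize_modes(localized_modes(tt$system$natoms, list(loopA),
                                         matrix(c(1, 0, 0), 1)),
                         tt$reference)
tr <- simulate_rigid_bd(tt$system, tens, 5e4, 0.05, seed = 42) |>
  add_internal_ou(U, variances = 4, taus = 2, seed = 43)

## effective spectrum vs rigid-body reference + internal part
Q <- seq(0.05, 0.25, length.out = 6)
eff <- spectrum_with_error(tr, tt$system, Q, fit_window = "auto",
                           n_orientations = 24, max_lag = 1.5)
fitted <- remove_rototranslation(tr)
int <- internal_spectrum(fitted, tt$system, Q, fit_window = "auto",
                         n_orientations = 24, max_lag = 1.5)
comp <- compose_total(rigid_body_spectrum(tt$system, tens, Q), int)

## localization: PCA, fluctuation profile, kinetic network, loop CV
ms <- pca_modes(fitted)
msf <- msf_profile(fitted, tt$system)
net <- kinetic_network(leader_cluster(fitted, cutoff = 1.5))
hd <- harmonic_diffusivity(loop_cv(tr, tt$system, tt$loop_range, "A", "B"))
```

The same workflow, end to end with outputs on disk, is one call:

```{r pipeline, eval = FALSE}
run_pipeline(system.file("extdata", "demo_config.yaml", package = "nsemd"))
```
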