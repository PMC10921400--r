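---
title: "A pairwise-additive hydrogen peroxide model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pairwise-additive hydrogen peroxide model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxff)
```

This vignette documents the model implemented by `peroxff`, the assumptions
behind each property estimator, the synthetic generators used for
verification, and the numerical design decisions. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
compute.

## The model

Hydrogen peroxide is represented by four sites in an H1–O1–O2–H2 chain.
Bonds and angles are harmonic; hydrogens carry charge `+q_H` and each oxygen
`-q_H` (the molecule is neutral by construction); Lennard-Jones interactions
act between oxygen sites only. Seven physical parameters define the model
(`model_parameters()` holds the optimized set):

```{r}
model_parameters()
```

### Torsional potential

The O–O torsion uses a Ryckaert–Bellemans expansion
$V(\psi) = \sum_{n=0}^{5} c_n \cos^n\psi$ with $\psi = a_d - 180^\circ$, so
that the IUPAC cis conformation ($a_d = 0$) falls on the large barrier and
trans ($a_d = \pm 180^\circ$) on the small one. The expansion is constrained
to a single free scale: $c_0 = 0.312\,c_2$, $c_1 = -c_2$,
$c_3 = 0.300\,c_2$, $c_4 = c_5 = 0$. In the variable $x = \cos\psi$ the
potential is the cubic $c_2(0.312 - x + x^2 + 0.3 x^3)$, whose interior
stationary point solves $-1 + 2x + 0.9x^2 = 0$, i.e.
$x = (-2 + \sqrt{7.6})/1.8$, placing the skew minimum at
$a_d = \pm 114.86^\circ$ with depth $0.090626\,c_2$ independent of the other
parameters. The test suite verifies this closed form against an exhaustive
$0.01^\circ$ grid.

```{r}
prof <- dihedral_profile(model_parameters())
c(a_d_min = prof$a_d_min, v_min = prof$v_min,
  cis = prof$cis_barrier, trans = prof$trans_barrier)
```

Two caveats worth recording:

- The constrained expansion necessarily puts the minimum at
  $\pm 114.86^\circ$. Reference descriptions of the condensed-phase
  conformer sometimes quote a wider equilibrium dihedral (near
  $\pm 130^\circ$ in some experimental determinations of the free molecule).
  The package follows the printed coefficient constraints; the minimum
  location is a *consequence*, not an input.
- The published gas-phase reference energy ($U_g^{\min} = -1.53$ kJ/mol)
  includes topology-level terms beyond the bare RB expansion, so it is not
  derivable from the seven parameters alone. `gas_reference()` therefore
  accepts the value as configuration; `gas_minimum()` computes the RB-only
  minimum when that is what is wanted.

### Exclusion policy

Intramolecular Lennard-Jones is always excluded. Two charge policies are
supported: `exclude_all_intra` (no intramolecular Coulomb; the default) and
`opls_14_half` (the 1-4 H–H pair survives, scaled by `fudge_qq`, following
OPLS conventions). The choice is encoded in the topology file via the
presence of a `[ pairs ]` section, and `read_topology()` infers it back.

## Property estimators and their assumptions

All estimators consume plain time series or tables, so they can be driven
by real trajectory post-processing output or by the synthetic generators.

- **NPT fluctuations** (`npt_fluctuations`): $\kappa_T = \langle\delta
  V^2\rangle / (\langle V\rangle RT)$, $\alpha_P = \langle\delta V \delta
  H\rangle / (\langle V\rangle R T^2)$, $C_P = \langle\delta H^2\rangle /
  (R T^2)$ per mole of molecules, with whole-box energies in kJ/mol.
  Estimates are block averages over 10 contiguous blocks; blocks more than
  three standard deviations from the block mean are discarded (a simple
  robustness guard against rare events in a block). Assumes a converged,
  stationary NPT ensemble.
- **Derived caloric quantities** (`derived_caloric`):
  $C_V = C_P - T V \alpha_P^2 / \kappa_T$ and $\kappa_S = \kappa_T C_V /
  C_P$. These imply the stability inequalities $C_V \le C_P$ and
  $\kappa_S \le \kappa_T$, which the tests assert over random feasible
  inputs; infeasible combinations (non-positive $C_V$) are rejected with an
  error rather than silently returned.
- **Dielectric constant** (`dielectric_constant`): box-dipole fluctuation
  formula $\varepsilon = 1 + 4\pi k_e (\langle M^2\rangle - \langle
  M\rangle^2) / (3\langle V\rangle RT)$ with per-component mean subtraction,
  valid under conducting (tin-foil) boundary conditions.
- **Diffusion** (`diffusion_einstein`): Einstein relation, least squares on
  the 10–50 % window of the multi-origin MSD. Origins are strided at
  1/100th of the trajectory length; denser origin averaging measurably
  reduces the estimator variance and is standard practice. A negative
  fitted slope is clamped to zero and flagged.
- **Viscosity** (`viscosity_cosine_flow`): stationary response to a cosine
  acceleration profile, $\eta = A\rho / (v_{\max} k^2)$, $k = 2\pi/L_z$.
  Assumes the transient has been discarded.
- **Hydrogen bonds** (`hydrogen_bonds`): geometric criterion, donor–acceptor
  O···O distance $\le$ 0.35 nm and hydrogen–donor–acceptor angle (vertex at
  the donor oxygen) $\le 30^\circ$, minimum image in an orthorhombic box.
  `angle_vertex = "hydrogen"` switches to the donor–H–acceptor angle
  (deviation from linearity), the other common convention.
- **Vaporization** (`enthalpy_of_vaporization`): $\Delta H_{vap} = U_g(T) -
  U_l + RT$ with $U_g(T) = U_g^{\min} + 3RT$ for the flexible 4-site
  molecule (3N−6 internal modes, no constraints); `rigid = TRUE` drops the
  thermal term for rigid reference models. The self-polarization correction
  $E_{pol} = k_e(\Delta\mu)^2 / (2\alpha')$ uses a polarizability volume 30
  % above the SPC/E water value.
- **Coexistence** (`partition_phases`, `critical_point`,
  `boiling_temperature`, `vapor_pressure`, `surface_tension`): slab
  profiles are fit with the standard two-interface tanh form
  (Levenberg–Marquardt via `minpack.lm`); coexisting densities are fit
  simultaneously to the law of rectilinear diameters and the scaling law
  with the critical exponent fixed at $\beta = 0.32$. $T_c$ is profiled:
  for each trial $T_c$ the remaining parameters are linear least squares,
  and a one-dimensional optimizer minimizes over $T_c$. Vapor pressure
  switches from the virial route ($\langle P_{zz}\rangle$) to the ideal-gas
  route below 2 bar, where the virial estimate becomes noise-dominated.

## The target function and surrogate optimizer

The parametrization minimizes
$F = \sum_i w_{c,i}\, w_{p,i} \left((x_i - x_{e,i})/x_{e,i}\right)^2$
over 22 property/condition pairs (pure liquid and a 70 wt% aqueous
mixture), with composition weight 0.25 for mixture entries and property
weight 0.5 for viscosity. Squared relative deviations make $F$ smooth,
scale-free and zero exactly at a perfect match; the form is encapsulated in
`target_function()` so an alternative penalty could be swapped in one
place.

The surrogate is a small fully connected regressor from the normalized
parameter cube to the 22 normalized properties, trained full-batch with
adaptive-moment updates and MSE loss; the architecture grid is
ReLu/Sigm × 1–3 layers × 2/4/8/16 units (`"ReLu/1/8"` notation). Three
implementation details matter:

- Hidden ReLU biases are initialized at 1.5 so every unit is active over
  the whole input cube at the start; with inputs confined to $[0,1]^7$,
  zero-bias initialization routinely strands units in dead basins and stalls
  training at a poor plateau. Units may still deactivate later if the fit
  wants it.
- Output normalization is bound to the training-table column extrema, so a
  trained model carries its own denormalization.
- Training is deterministic given the seed (weight initialization is the
  only randomness), which the tests rely on.

Global search draws uniform samples in the unit cube (row-major, so a
fixed seed yields nested sample sets as `n` grows), and local refinement is
greedy random descent with out-of-range proposals rejected, never clamped —
clamping would bias the search onto the box faces. Refinement evaluates the
true objective (in production, a short simulation; here, the synthetic
oracle), mirroring the two-stage surrogate-then-direct strategy.

## Synthetic generators: what they emulate and what they do not

The generators invert each estimator's defining formula so that ground
truth is known exactly:

- `gen_fluctuation_series` draws an uncorrelated bivariate Gaussian
  $(V, H)$ series with moments chosen to reproduce requested $\kappa_T$,
  $\alpha_P$, $C_P$ (rejecting jointly infeasible triples), isotropic
  Gaussian box dipoles for $\varepsilon$, Gaussian random walks for $D$,
  and a noisy stationary profile amplitude for $\eta$. Frame-to-frame
  correlation is deliberately absent: the fluctuation estimators depend on
  sample moments only, so white-noise series test exactly the estimator
  algebra. What this does *not* emulate is autocorrelation-driven error
  underestimation in real trajectories — block errors on real data mean
  something only with blocks longer than the correlation time.
- `gen_coexistence_fixtures` builds coexisting densities exactly on the
  rectilinear/scaling forms, vapor pressures exactly Clausius–Clapeyron,
  and tanh slab profiles consistent with each row, with optional relative
  Gaussian noise. The verification grid extends to $0.97\,T_c$: the scaling
  form pins $T_c$ only when the width of the coexistence curve is sampled
  near its closure, which is also how simulation studies choose their
  temperature ladders. Fitting only far-subcritical data leaves $T_c$
  weakly identified — that is a property of the physics, not the fitter.
- `oracle_spec`/`oracle_properties` define a smooth quadratic
  parameter-to-property map $y_j = x_{e,j}(1 + d^\top A_j d)$ with seeded
  positive-semidefinite $A_j$ and offset $d$ from a constructed optimum, so
  the default target function is globally minimized (F = 0) exactly at the
  constructed parameter vector, with optional 2 % relative noise (5 % for
  viscosity, the noisiest observable). Real parameter-to-property maps are
  not exactly quadratic; the oracle tests the pipeline's plumbing and
  convergence, not simulation fidelity.

## Numerical choices

- Physical constants are centralized in `phys_constants()`
  ($R = 8.31446\times10^{-3}$ kJ/mol/K, $k_e = 138.935458$ kJ mol⁻¹ nm e⁻²,
  1 D = 0.0208194 e·nm, pressure conversion 16.6054 bar per kJ mol⁻¹ nm⁻³).
- Profile refinement (`dihedral_profile`) follows a coarse grid with
  golden-section refinement; grids and tolerances are stated in the
  function signatures.
- The tanh interface fit starts from the half-maximum crossing points and
  bounds all parameters to physical ranges; a profile without at least 5 %
  density contrast is rejected as single-phase rather than fit.
- The boiling-point fit uses a centered quadratic on the lowest-pressure
  points bracketing the target pressure, growing the selection until it
  brackets; extrapolated roots outside the fitted range are rejected.
- Problem sizes in the tests (2×10⁵ thermo frames, 10⁵ dipole frames,
  512 walkers × 10⁴ steps, 1000/300 training/validation tables, 10⁵ search
  samples) are the package's own choices of realistic production scales,
  fixed before the acceptance tolerances were evaluated.

## Limitations

- The package post-processes and emulates; it does not integrate equations
  of motion. Claims about the real substance require real trajectories.
- Estimator error bars assume weakly correlated blocks; no automatic
  correlation-time analysis is performed.
- The critical exponent is fixed at the Ising-like value 0.32; fitting it
  would require data far closer to criticality than slab simulations give.
- The surrogate grid is intentionally small (24 architectures, full-batch
  training); it is a parametrization tool, not a general regression
  library.
- The mixture half of the property layout uses nominal reference anchors;
  replacing them with a curated experimental set is a configuration task,
  not a code change.
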