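---
title: "Adaptive flat-histogram free energies from reaction-coordinate graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive flat-histogram free energies from reaction-coordinate graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearcf)
```

## The method

The package estimates free-energy surfaces $W(\xi)$ over one or more
reaction coordinates (RCs) $\xi = (\xi_1, \dots, \xi_d)$ by adaptive
flat-histogram biasing. Sampling is equalized over RC space when the system
potential and the biasing potential cancel,

$$W(\xi) + U(\xi) = 0,$$

so the ideal bias is $U(\xi) = -W(\xi)$, which is unknown at the outset.
The iteration starts from $U_1 = 0$: an unbiased simulation yields a
probability density $P_1(\xi)$, Boltzmann inversion gives the first
estimate $W_1(\xi) = -k_B T \ln P_1(\xi)$, and the next bias is
$U_2 = -W_1$. Later iterations sample a *biased* density $P_n'$, from which
the unbiased density is recovered as
$P_n(\xi) = C\, P_n'(\xi)\, e^{U_n(\xi)/k_B T}$ before the next inversion
and update. At convergence the histogram of visits is flat — quantified
here by the ratio of the highest to the lowest visited-bin count — and the
final $W$ is the negative of the converged bias, min-shifted to zero.

Replicas within an iteration run independently under the same bias
("embarrassingly parallel") and their histograms are combined by the
weighted histogram analysis method (WHAM). By default the package carries
WHAM **across** iterations as well: every past iteration's pooled
histogram enters the estimate together with the bias that generated it.
This is a pure estimator choice — both scopes estimate the same $W$ — but
the cross-iteration form uses every sample collected; on the shipped 1D
water-dimer campaign it reduces the run-to-run spread of the well depth
from about ±0.13 to ±0.04 kcal/mol. `wham_history = FALSE` restores the
within-iteration-only scheme.

## Reaction coordinates as graphs

RCs are declared as directed acyclic graphs whose leaves are atoms and
whose internal nodes are centers of mass, difference vectors,
cross-product plane normals, and finally scalar distances, angles and
dihedrals. The forward pass evaluates node values bottom-up from the
atomic coordinates; the biasing force is carried back down by the chain
rule,

$$\vec F_a = -\sum_i \frac{\partial U}{\partial \xi_i}
             \frac{\partial \xi_i}{\partial \vec x_a},$$

where $\partial \xi_i / \partial \vec x_a$ is the sum over graph paths of
products of per-edge partial derivatives (the entries of the derivative
matrix, whose sparsity pattern is the graph adjacency matrix). Two
implementations coexist and are tested against each other and against
central finite differences: a compiled reverse-mode sweep used inside the
MD loop, and a plain-R path-product evaluation (`backend = "paths"`)
that multiplies the derivative-matrix blocks explicitly. Forces arriving
at a center-of-mass node are redistributed over its atoms by mass
fraction, so internal-coordinate biasing forces conserve both momentum
and angular momentum.

The angle gradient is the exact derivative of
$\theta = \arccos(\hat u \cdot \hat v)$,
$\partial\theta/\partial u = -(\hat v - \cos\theta\,\hat u)/(|u|\sin\theta)$
— the normalized double-cross-product form; finite-difference agreement to
$10^{-6}$ relative is part of the acceptance suite.

### Dihedral conventions

For a dihedral between plane normals $\vec m = \vec b_1 \times \vec r$ and
$\vec n = \vec b_2 \times \vec r$ two conventions are provided:

* `arccos`: $\varphi = \arccos(\hat m \cdot \hat n) \in [0°, 180°]$ — the
  textbook unsigned form. Its gradient is singular exactly at 0° and 180°,
  and it cannot distinguish $\pm\varphi$.
* `signed360` (and `signed180`): the atan2 form using the shared axis,
  $\varphi = \mathrm{atan2}((\vec m \times \vec n)\cdot\hat r,\;
  \vec m \cdot \vec n)$, mapped to $[0°, 360°)$. Because $\vec m$ and
  $\vec n$ are both exactly perpendicular to $\vec r$, the explicit axis
  partial vanishes and the gradient is regular wherever $\vec m, \vec n$
  are nonzero.

A bare dihedral node defaults to `arccos`. The shipped 4D water-dimer
graph uses `signed360`: it pairs with a periodic $[0°, 360°)$ grid (the
unsigned form would leave half of such a grid unvisitable) and it is
non-singular at the planar arrangement $\varphi = 180°$ where the
surface's minimum sits.

Geometries in which an angle or dihedral vector collapses below
$10^{-8}$ Å make that RC undefined for the step: its value is `NA`, its
biasing-force contribution is zero, and a warning (or a per-replica
counter) is raised — a transient degenerate geometry must not kill a
replica mid-campaign.

## The grid, unbinned excursions and spline gradients

The bias lives on a regular grid over RC space (defaults: 1D
$r \in [2.2, 6.0]$ Å × 64 bins; 2D $r \times \varphi$ 64 × 36; 4D
$(r, \theta_1, \theta_2, \varphi)$ 32 × 18 × 18 × 18 with periodic
$\varphi$), spanning the axis ranges of the systems they describe. Samples
leaving a non-periodic dimension are not binned; instead a harmonic wall
($k_\mathrm{wall} = 10$ kcal/mol per RC-unit², configurable) pushes the
coordinate back onto the grid. Never-visited bins take
$W = \max(W_\mathrm{visited}) + k_B T$: the Boltzmann inversion of zero
counts is undefined, and one thermal unit above the observed ceiling makes
the next bias mildly attractive there without overdriving the system.
Flatness ratios are computed over visited bins only.

Between bin centers the bias and its gradient
$\partial U/\partial \xi$ come from a tensor-product interpolating cubic
spline (C2), solved per dimension in the B-spline basis — natural closure
on bounded dimensions, periodic closure on periodic ones — and evaluated
in compiled code. Both `mode = "cubic"` and `mode = "b_spline"` yield this
same interpolant; the mode is kept for interface symmetry. Spline node
values are reproduced to $10^{-10}$, a linear field returns its exact
slope, and the gradient of $\sin\xi$ on 64 bins tracks $\cos\xi$ to
$10^{-3}$.

## The toy MD engine

The engine exists so the biasing machinery can be exercised end-to-end
without external software. Units are AKMA-style (Å, amu, kcal/mol; the
internal time unit is ≈48.888 fs, all interfaces use fs).

* **Water dimer** — flexible TIP3P-style: harmonic bonds
  ($k_b = 450$ kcal/mol/Å², $r_0 = 0.9572$ Å) and angle
  ($k_\theta = 55$ kcal/mol/rad², $\theta_0 = 104.52°$), TIP3P charges
  (−0.834/+0.417 e) and Lennard-Jones terms with CHARMM-style
  combination. Flexible bonds avoid constraint solvers at the cost of a
  stiff O–H stretch (period ≈10 fs): at the 1 fs campaign timestep the
  NVE energy oscillates by a few percent, and strict conservation
  (relative drift < $10^{-3}$ per 100 ps, verified by the suite) requires
  0.5 fs. Thermostatted campaign runs use 1 fs.
* **Boundary** — campaign presets use a 12 Å periodic cube with minimum
  image and a 14 Å cutoff (inactive under minimum image, where no pair
  distance exceeds ≈10.4 Å). This was chosen over a spherical restraint
  after comparing the two: in the periodic cell the dissociated dimer
  still interacts with periodic images, which raises the large-$r$
  plateau; the box is part of the conditions under which the shipped
  observables (well position and depth) are defined. A soft harmonic
  cavity about the origin (radius 6 Å) remains the standalone
  `water_force_field()` default for free-standing toy runs.
* **Analytic particles** — a particle whose coordinates *are* the RCs,
  with closed-form potentials: the 1D double well
  $W(x) = a(x^2-1)^2$ ($a = 2$ kcal/mol) and a harmonic well. These are
  the convergence fixtures: the campaign must recover the known $W$
  (RMSD < 0.3 kcal/mol over bins with $W < 5$ kcal/mol at the shipped
  budget), and imposing $U = -W$ exactly must flatten sampling (verified
  by a chi-squared uniformity test on decorrelated subsamples). Custom R
  potentials integrate through `velocity_verlet_step()`'s force-provider
  interface; the compiled fast path covers the named potentials.
* **Integration and thermostats** — velocity Verlet; the biasing force is
  added to the engine force at every force evaluation, i.e. before each
  position update. Thermostats: Langevin (exact Ornstein-Uhlenbeck
  velocity step; friction in fs⁻¹, default 0.001), deterministic velocity
  scaling, and a single-chain Nose-Hoover ($\tau = 0.1$ ps, 10 substeps —
  the dimer campaign default, at 300 K). Kinetic temperature holds within
  3% on the shipped systems. Note the single-chain Nose-Hoover thermostat
  is not ergodic on a lone harmonic mode; the suite tests it on the
  dimer.
* **Determinism** — every stochastic term in a replica derives from one
  integer seed; campaign replicas get counter-derived seeds from the
  master seed, so a campaign is a pure function of its configuration.
  Checkpoints store states and biases at 17 significant digits because a
  12-digit round-trip visibly diverges a chaotic trajectory within a few
  picoseconds; with full precision a resumed campaign reproduces the
  uninterrupted bias sequence exactly (tested).

## Campaign driver

`run_campaign()` loops: build the spline of the current bias → run K
replicas (default 16 × 20 ps for 1D, continuing each replica from its
previous endpoint) → WHAM → inversion → $U \leftarrow -W$ → flatness
check. It stops at the flatness threshold (1D default 2.5:1, matching the
ratio at which the shipped 1D campaign levels off; generic default 3:1) or the
iteration cap (1D default 15), and aborts with a diagnostic if flatness
worsens more than twofold on three consecutive iterations. Replicas that
error are excluded from WHAM with a warning; a campaign fails only when
all replicas fail.

## Analyses

* `find_minima()` — local minima over the full Moore neighborhood
  ($3^d - 1$ neighbors, periodic wrap), visited bins only, a bin counting
  as a minimum when no visited neighbor lies below it; sorted by $W$ with
  lexicographic tie-breaking.
* `boltzmann_project()` — reduced surfaces
  $W_{proj} = -k_B T \ln \sum e^{-W/k_B T}$ over the dropped dimensions,
  min-shifted; staged projection equals direct projection.
* `dipole_autocorrelation()` — $Q(t) = \langle D(0)\cdot D(t)\rangle$
  with $D$ the total dipole from the point charges; raw dot product by
  default (a normalized variant is an option, since either convention is
  seen in practice).
* `fit_exponential()` — single $e^{-(t+x)/\tau}$ and double
  $e^{-(t+x_1)/\tau_1} + e^{-(t+x_2)/\tau_2}$ models, exactly in this
  offset-in-the-exponent form (the offsets act as amplitude parameters
  $e^{-x/\tau}$). Levenberg-Marquardt with log-linear starting values;
  the fit window runs from lag 0 to the first lag below 5% of $Q(0)$
  (unweighted; the model has no noise floor term, so including the long
  flat tail would bias $\tau_2$). $\tau_1 < \tau_2$ is enforced by
  relabeling. Recovery of generating parameters within three standard
  errors on 1%-noise synthetic decays is part of the acceptance suite.
* `classify_configuration()` — nearest-template assignment of
  $(\theta_1, \theta_2)$ to the Chain, Cyclic and Bifurcated hydrogen-bond
  geometries (each with its molecule-exchange swap), a ±20° acceptance
  window per angle, and a 5 Å dissociation cutoff on $r$; bound frames
  outside every window keep the nearest label but are flagged, so each
  frame always carries exactly one label.
* `project_trajectory()` — per-frame bin assignment and $W$ lookup with
  out-of-grid flagging.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run reduced-scale campaigns
chosen to converge reproducibly on one core: 1D water dimer 16 replicas ×
20 ps × ≤15 iterations; double well 16 × 100 ps × ≤10 iterations; 4D water
dimer 32 replicas × 50 ps × 12 iterations on the 32 × 18 × 18 × 18 grid.
A production-scale campaign (say 128 replicas × 50 ps per iteration)
would sharpen the 4D volume further; at the shipped budget it is still
visibly noisy at its sparsely-visited edges, which is why the 4D checks are phrased on
Boltzmann-projected low-dimensional surfaces, where every bin aggregates
many 4D cells.

## What the toy systems do and do not show

Passing the shipped checks demonstrates that the bias construction,
chain-rule force propagation, WHAM combination and inversion are correct
(analytic-potential recovery is exact to sampling error), and that the
full loop reproduces the classical water-dimer observables at their
stated tolerances. It does not validate a production force field (the
flexible TIP3P variant overbinds slightly relative to rigid TIP3P — the
1D well converges near −1.95 kcal/mol here), says nothing about
electronic-structure effects (no quantum treatment is included), and the
two-molecule system cannot exhibit condensed-phase physics. The
dipole-relaxation fitting machinery is validated on synthetic decays
generated at literature-scale parameters, not on ab initio trajectories.

## Known limitations

* Rigid-water constraint algorithms are deliberately absent; the 1 fs
  NVE drift of the flexible model is the documented consequence.
* The arccos dihedral's gradient singularity at 0°/180° means biased
  sampling across planar geometries should use the signed convention.
* Error bars on $W$ (e.g. by bootstrap over replicas) are not provided.
* No Ewald summation: periodic electrostatics are minimum-image
  truncated, adequate for a two-molecule cell only.
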