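# fearcf — adaptive flat-histogram free energies from reaction-coordinate graphs

`fearcf` computes multidimensional free-energy surfaces W(ξ) by adaptive
flat-histogram biasing along reaction coordinates (RCs) that are declared
as graphs over atomic coordinates. It is aimed at molecular-simulation
method developers and students who want a self-contained, fully
inspectable implementation of the whole loop: RC definition → chain-rule
biasing forces → biased dynamics → WHAM → bias update → convergence.

## The method

Sampling over a set of RCs ξ = (ξ₁…ξ_d) is flat when the system potential
and the bias cancel,

    W(ξ) + U(ξ) = 0,

so the ideal bias is U = −W. Starting from U₁ = 0, each iteration n runs K
independent replicas under the current bias, combines their histograms by
the weighted histogram analysis method (WHAM) into an unbiased density

    P_n(ξ) = C P′_n(ξ) exp(U_n(ξ)/k_B T),

inverts it, W_n = −k_B T ln P_n, and updates U_{n+1} = −W_n, until the
ratio of the most- to least-visited bin falls below a threshold. RCs are
directed acyclic graphs whose leaves are atoms and whose internal nodes
are centers of mass, difference vectors, cross-product normals, and scalar
distances/angles/dihedrals; the biasing force on atom a is

    F_a = − Σ_i (∂U/∂ξ_i) (∂ξ_i/∂x_a),

with each Jacobian accumulated as products of per-edge partial derivatives
along the graph paths from RC node to atom. Bias gradients between grid
bins come from tensor-product interpolating cubic splines.

The package ships a toy MD engine (flexible TIP3P-style water dimer in a
12 Å periodic cell, plus analytic test particles with closed-form
potentials), velocity-Verlet integration with Langevin, velocity-scaling
and Nose-Hoover thermostats, a campaign driver with checkpoint/resume,
and post-processing: free-energy minima, Boltzmann-averaged projections,
dipole–dipole autocorrelation with single/double exponential relaxation
fits, trajectory projection onto the free-energy volume, and geometric
classification of water-dimer hydrogen-bond configurations
(Chain/Cyclic/Bifurcated).

## Worked example

A reduced 1D campaign on the water dimer — the O–O distance RC on
r ∈ [2.2, 6.0] Å, 64 bins, 16 replicas × 20 ps per iteration at 300 K:

```r
library(fearcf)
cfg  <- water_dimer_1d_config(master_seed = 3)
camp <- run_campaign(cfg)
camp
#> Flat-histogram campaign: 11 iteration(s), converged
#>   final flatness 2.29:1; W range [0.000, 27.839] kcal/mol

r <- bin_centers(cfg$grid, 1)
W <- as.numeric(camp$grid$W)
r[which.min(W)]                       # position of the free-energy minimum
#> [1] 2.823438
min(W) - mean(W[r > 5])               # well depth vs the dissociated plateau
#> [1] -1.903822
```

The minimum near r ≈ 2.8–2.9 Å is the hydrogen-bonded dimer (O–O distance
minus the 0.9572 Å O–H bond gives the H-bond length ≈ 1.9 Å); the well
depth of roughly −1.9 kcal/mol sits between van-der-Waals and covalent
bond strengths, as expected for a classical water–water hydrogen bond.
The large W values near r = 2.2 Å are the steep repulsive wall.

The analytic double-well fixture shows the recovery property directly:

```r
cfg  <- double_well_config(master_seed = 1)
camp <- run_campaign(cfg)
x <- bin_centers(cfg$grid, 1)
Wt <- 2 * (x^2 - 1)^2; Wt <- Wt - min(Wt)
W  <- as.numeric(camp$grid$W)
sqrt(mean((W[Wt < 5] - min(W[Wt < 5]) - Wt[Wt < 5])^2))  # RMSD, kcal/mol
#> [1] 0.02592202
```

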