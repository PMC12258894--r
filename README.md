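# voltgate

Analysis toolkit for voltage activation of ion channels from atomistic
simulation output, built around the machinery needed to study
voltage-sensor domains (VSDs) of non-canonical channels such as BK: small
helix movements, sub-unit gating charges, and allosteric sensor–pore
coupling through residue networks.

## What it computes

**Gating-charge bookkeeping.** The total gating charge per voltage sensor
is accumulated over charged residues as

    ΔQ = Σ_i q_i [ f_c(i) − f_o(i) ],

where `q_i` is the residue charge and the coupling fraction `f_s(i)` —
the fraction of the transmembrane potential the charge experiences in
state `s` — is the difference quotient of charging free energies at two
voltages,

    f_s(i) = [ΔG_s(V2, q_i) − ΔG_s(V1, q_i)] / [q_i (V2 − V1)].

Each `ΔG` comes from thermodynamic integration of the mean force
⟨δH/δλ⟩ over a λ-grid (trapezoid on the standard 0, 0.1, …, 1.0 grid),
with per-window block-averaged errors propagated through the quadrature
weights.

**Electrostatic potential maps.** Atomic charges are smeared into
spherical Gaussians, ρ_i(r) = q_i (β/√π)³ exp(−β²|r−r_i|²) with
β = 0.25 Å⁻¹ on a 1 Å periodic grid, and the Poisson equation
∇²φ = −4πρ is solved spectrally; a linear external ramp imposes the
membrane voltage (E = V/L_z). Maps export as OpenDX in millivolts and
can be sliced on a plane through anchor atoms.

**Structural descriptors.** Charged-group z-displacements (Arg CZ,
Asp/Glu carboxyl carbon proxies), helix tilt from the principal axis of
Cα coordinates, center-of-mass displacements with Boltzmann-inverted
lateral free-energy surfaces, superposed RMSD, pore water counts and a
simplified axial pore-radius profile, ion permeation counting by a
two-boundary state machine, and single-channel conductance
g = Ne/(VT).

**Residue networks.** Contact edges (min heavy-atom distance ≤ 5 Å in
≥ 75 % of frames) weighted by w_ij = −ln|C_ij| from the 3-D displacement
correlation; Floyd–Warshall optimal paths, exhaustive suboptimal paths
within a 50 % length tolerance, and Girvan–Newman dynamic communities
scored by modularity.

**Information flow.** Mutual information M_ij = H_i + H_j − H_ij between
per-residue fluctuation magnitudes, with densities estimated by Gaussian
mixture models (BIC-selected); the MI-weighted contact network's
Laplacian L = D − A is solved for potentials P with one unit of current
injected at a source residue and extracted at sinks, and per-node flow
f_i = ½ Σ_j |P_i − P_j| A_ij ranks every residue's contribution to
sensor–pore coupling.

Every stage has a synthetic-data generator with planted ground truth
(harmonic ensembles with planted covariance, closed-form TI profiles,
linear-slab coupling systems, ideal helix bundles, ion tracks with known
crossing counts), so the whole pipeline is testable without trajectories.

## Worked example

Literature-reported per-residue contributions for the BK Core-MT VSD,
accumulated through the gating-charge decomposition:

```r
library(voltgate)
lit <- bk_gating_contributions()
tab <- gating_charge(lit$residue_id, lit$q,
                     f_closed = lit$dq / lit$q,
                     f_open   = rep(0, nrow(lit)),
                     labels   = lit$label)
tab
#> Gating-charge decomposition (e):
#>  residue_id label  q f_closed f_open     dq error
#>         153  D153 -1   -0.080      0  0.080    NA
#>         167  R167  1    0.002      0  0.002    NA
#>         186  D186 -1    0.010      0 -0.010    NA
#>         207  R207  1    0.040      0  0.040    NA
#>         210  R210  1    0.250      0  0.250    NA
#>         213  R213  1    0.190      0  0.190    NA
#>         219  E219 -1    0.090      0 -0.090    NA
#> total dQ = 0.4620 e
```

The full-precision sum is 0.462 e (reported rounded as ~0.45 e per VSD),
with R210 + R213 contributing 0.44 e — about 95 % of the raw sum. A
synthetic linear-slab system checks the full TI → coupling-fraction →
ΔQ pipeline end to end:

```r
sys <- make_slab_coupling_system(depths_closed = 0.60,
                                 depths_open   = 0.35, charges = 1)
slab_recovery_check(sys)$table$dq
#> [1] 0.25
```

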