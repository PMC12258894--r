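---
title: "Voltage-gating analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-gating analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltgate)
```

voltgate packages the analysis machinery for studying how an ion
channel's voltage-sensor domain (VSD) responds to membrane potential:
how much gating charge individual residues carry, how the protein
reshapes the local electric field, which structural descriptors track
activation, and which residues mediate the allosteric coupling between
the sensor and the pore. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic
generators emulate, and the numerical decisions that were genuinely
open.

## Gating charges from charging free energies

The total gating charge per sensor is a sum over charged residues,

$$\Delta Q = \sum_i q_i\,[f_c(i) - f_o(i)],$$

where $f_s(i)$ is the *coupling fraction*: the fraction of the applied
transmembrane potential that residue $i$'s charge effectively
experiences in conformational state $s$ (closed $c$ or open $o$). It is
measured as a difference quotient of charging free energies at two
voltages,

$$f_s(i) = \frac{\Delta G_s(V_2, q_i) - \Delta G_s(V_1, q_i)}
               {q_i\,(V_2 - V_1)},$$

which makes it invariant under any shift of the free-energy zero and
under exchanging $V_1$ and $V_2$. The default voltage pair is $V_1 = 0$
and $V_2 = +0.75$ V, the potential at which activation transitions are
simulated; both are configurable. Free energies are converted to
electron-volts internally (1 kcal/mol = 0.0433641 eV) so that $q V$ is
in e·V and $f$ is dimensionless.

$\Delta G_s(V, q_i)$ — the cost of growing the residue's charge from 0
to $q_i$ — is integrated from thermodynamic-integration mean forces
$\langle \delta H / \delta\lambda\rangle_\lambda$ on a $\lambda$ grid.
The grid is taken from the data, never assumed; the canonical design is
$\lambda = 0, 0.1, \dots, 1.0$. Quadrature is the trapezoid rule and
nothing fancier: with eleven noisy windows no higher-order rule is
justified, and the trapezoid's bias is transparent — it is exact for
mean-force profiles up to linear in $\lambda$, and a pure quadratic
with unit integral evaluates to 1.005 on the 11-point grid, a
documented 0.5 % bias rather than a hidden one. Per-window block
series, when present, yield window standard errors that propagate
through the trapezoid weights in quadrature.

The default residue set for BK-type sensors is D153, R167, D186, R207,
R210, R213 and E219; any set is accepted. The shipped literature table
of per-residue contributions sums to 0.462 e at full precision; the
source reports this rounded as ~0.45 e (and 0.44 e elsewhere). The
package always reports full-precision sums — `attr(tab, "dQ")` is the
exact sum of the `dq` column — and leaves rounding to the reader, since
no single rounding reproduces every printed variant. Against the raw
sum, R210 + R213 carry 0.44/0.462 = 95 % of the total (97 % against the
rounded 0.45).

### The linear-slab validation system

`make_slab_coupling_system()` realizes the idealized geometry in which
the coupling fraction has a closed form: a charge at fractional
membrane depth $d$ inside a perfectly linear field has
$\Delta G_s(V, q) = q V d$ exactly, so the recovered fraction must
equal the planted depth. The generator emits genuine TI datasets
(constant mean-force profiles, optionally noisy with per-window
blocks), so validation exercises the same integration and bookkeeping
code paths as real data, not a shortcut. Noise-free recovery is exact
to machine precision; with window noise of 0.1 kcal/mol the recovered
total is unbiased within the propagated standard error. Note the state
order: $\Delta q_i = q_i (f_c - f_o)$, so a +1 e charge whose depth
goes from 0.60 (closed) to 0.35 (open) contributes +0.25 e.

## Smeared-charge Poisson maps

Electrostatic potential maps use the smoothed-charge representation:
each atomic charge becomes a spherical Gaussian
$\rho_i(r) = q_i (\beta/\sqrt{\pi})^3 e^{-\beta^2 |r - r_i|^2}$ with
inverse width $\beta = 0.25$ Å⁻¹ on a periodic grid of 1 Å spacing
(both configurable). Deposition exploits that the Gaussian — and its
periodic image sum — factorizes into per-axis profiles, truncated where
the density drops below $10^{-10}$ of the peak (a bit-reproducible cost
bound); small boxes are handled by explicit per-axis image shells
rather than refused.

The Poisson equation $\nabla^2 \phi = -4\pi\rho$ (Gaussian units,
potential in e/Å, × 14.39964 for volts) is solved spectrally with
continuous-$k$ eigenvalues, which is spectrally accurate for the smooth
Gaussian density. The $k = 0$ mode is set to zero: this fixes the
mean-zero gauge and, for net-charged systems, is exactly the uniform
neutralizing background — flagged in the output metadata rather than
silent. The solver is linear and translation-equivariant to $10^{-10}$,
and agrees with a real-space erf image-sum oracle
($\phi = \sum q\,\mathrm{erf}(\beta r)/r$ over lattice images) to well
under 2 % at probes ≥ 2 Å from charge centers.

The membrane voltage is a linear ramp with total drop $V$ across the
box along $z$ ($|E| = V/L_z$; 750 mV over 110 Å gives 6.82 mV/Å). The
source material does not state which $z$ direction is intracellular,
so the sign convention is a parameter: by default positive
(depolarizing) voltage puts the higher potential on the low-$z$
(intracellular) side. The ramp is stored separately from the protein
field and folded in at query/export time, keeping the pure protein
contribution inspectable. Exported OpenDX grids carry millivolts,
z-fastest value ordering — the convention of the grid files common
visualization tools emit — which a fixture with asymmetric values pins
down in the tests.

## Structural descriptors

Charged-group positions are proxied by the guanidinium CZ for Arg and
the sidechain carboxyl carbon for Asp/Glu; z-displacements are measured
from a reference frame with no whole-protein drift correction (the
selectivity filter is restrained in the source simulations, anchoring
the frame), optionally averaged per subunit (chain) and smoothed with a
centered running window (default 100 frames, shrunk at the edges).

Helix tilt is the angle between the dominant singular vector of the
centered axis-atom (Cα) coordinates and $+z$. The axis sign is fixed by
the N→C direction and the angle folded into [0°, 90°], removing the
sign ambiguity inherent to principal axes. RMSD superposes each frame
by least squares on a fit selection (by design the restrained filter
region when analyzing pores) before measuring over the report
selection.

The pore is an axial slab with a radial cutoff: bounds are fixed $z$
values or per-frame centroids of anchor selections (e.g. "the plane of
the P320 centers of mass"); the radial cutoff defaults to 8 Å —
the source describes the region only "roughly", so the value is
configurable and the default was chosen once as a typical inner-cavity
radius. The pore axis is the per-frame (x, y) centroid of the filter
selection, a stable anchor since that region is restrained. The radius
profile is a simplified axial profiler (minimum over nearby atoms of
axis distance minus vdW radius, clamped at zero; empty slices report a
flagged maximum probe radius) — deliberately not a Monte-Carlo
sphere-squeezing reimplementation.

Permeation counting is a two-boundary state machine: an event requires
full traversal — entry through one slab boundary and exit through the
other without first retreating through the entry side — so partial
crossings and boundary wiggles never count, and time reversal exactly
swaps up/down counts. Conductance is the arithmetic
$g = N_{\mathrm{net}}\,e/(VT)$: 7 upward events over 2 μs at 750 mV
give 0.748 pS.

## Residue networks and coupling paths

Nodes are residues at their Cα positions. Contacts require the minimum
heavy-atom distance within 5 Å in at least 75 % of frames. Sequence
neighbors up to offset 1 are excluded by default to avoid trivial
backbone paths (set `neighbor_exclusion = 0` for the literal
definition, which leaves them in). The correlation $C_{ij}$ uses full
3-D displacement dot products — the convention of the established
dynamic-network tooling — not per-component averages.

Edge weights are $w_{ij} = -\ln|C_{ij}|$. The magnitude is deliberate:
a bare $-\log C$ is undefined for anti-correlated pairs, and the
established convention treats strong anti-correlation as strong
coupling. Natural log only rescales path lengths and never changes
their ranking. $C_{ij} = 0$ edges are dropped with a warning (infinite
weight). Note the deliberate type separation: the correlation matrix
weighting this network and the boolean contact map masking the
information-flow network are different objects that share a symbol in
parts of the literature; the package never coerces one into the other.

Optimal paths come from Floyd–Warshall all-pairs distances with greedy
reconstruction that always picks the smallest eligible next node, making
the result the lexicographically smallest shortest path — a
deterministic tie-break. Suboptimal paths are all simple paths with
length strictly below $(1 + \mathrm{tol})\times$ the optimal (default
tolerance 0.5), enumerated by depth-first search pruned against the
Floyd–Warshall distance-to-sink bound, capped at 1000 with a truncation
flag. "Deviate by less than 50 %" is read as a strict inequality, and
the boundary case (a direct edge at exactly 1.5 × the optimal length)
is excluded and tested explicitly. Floating-point boundary comparisons
use a relative epsilon of $10^{-9}$.

Communities follow the divisive Girvan–Newman procedure: repeatedly
remove the highest-betweenness edge (betweenness computed with the
$-\ln|C|$ weights as distances; ties broken by smallest edge index) and
keep the partition of maximum modularity, with modularity computed on
$|C|$ edge strengths. Distances and strengths are distinct roles of the
same edge data, and conflating them (as off-the-shelf weighted
edge-betweenness clustering does) inverts the meaning of one or the
other; the explicit loop keeps both correct and deterministic. A
connected graph scores modularity 0 as a single community, so a uniform
clique is never split.

## Information flow

Each node's fluctuation magnitude $x_t = |r_t - \langle r \rangle|$
feeds a Gaussian-mixture density estimate; entropies are the plug-in
$H = -\tfrac{1}{N}\sum_n \ln \hat\rho(x_n)$ in nats (the unit is a
choice, labeled throughout). The mixture size is selected by BIC over
1–5 components via model-based hierarchical initialization (subsampled
for large $n$), which is deterministic under a fixed seed; random
multi-restart EM would add variance without accuracy here, since the
targeted densities are smooth and low-dimensional. Joint entropies use
a 2-D mixture on paired samples, and
$M_{ij} = H_i + H_j - H_{ij}$. Small negative MI estimates — a
finite-sample artifact — are clamped to zero and counted in
diagnostics; deterministically related pairs, whose continuous MI
diverges, return a configured saturation value with a degeneracy flag.
Because closed-form oracles exist for signed Gaussian samples but not
for distance magnitudes, the estimator accepts either: tests feed
signed samples where exact entropies are known (e.g.
$\tfrac12\ln 2\pi e$ for a standard normal, $M = -\tfrac12\ln(1-\rho^2)$
for bivariate normals), production analyses use distances.

The flow network masks MI by the boolean contact map,
$A_{ij} = C_{ij} M_{ij}$ (occupancy fractions are *not* used as
weights — the mask is the contact map, as stated). With Laplacian
$L = D - A$, sink rows and columns are removed, the reduced system
$\tilde L P = b$ is solved with one unit of supply at the source, sinks
held at potential zero (all of them, for multiple sinks), and
$f_i = \tfrac12 \sum_j |P_i - P_j| A_{ij}$. Conservation makes
$f = 0.5$ exact at a sole source or sink, and the net current out of
the source is checked to $10^{-10}$ on every solve. The flow is
invariant under uniform scaling of $A$; potentials scale inversely.

## Synthetic data: what it emulates and what it does not

Every generator plants its ground truth and is seed-deterministic:

- `sample_harmonic_ensemble()` draws i.i.d. frames from a multivariate
  normal with planted node covariance (the same matrix per Cartesian
  axis unless per-axis matrices are given, so planted entries equal the
  3-D displacement correlations downstream code measures). Frames are
  i.i.d. *by design*: every in-scope network statistic is a function of
  the stationary distribution only, so kinetics would add cost without
  adding test power.
- `make_ti_dataset()` evaluates constant/linear/quadratic/tabulated
  mean-force profiles with closed-form integrals attached; noise
  defaults to zero so integrals are exact in tests, with a noisy mode
  (and per-window blocks) for error-bar tests.
- `make_helix_bundle()` builds ideal α-helices (1.5 Å rise, 100°
  twist per residue) at prescribed tilts, with CZ/CG/CD proxy atoms on
  charged residues.
- `make_ion_tracks()` plants exact full-crossing counts with wide
  margins and 3σ-truncated jitter, plus decoy tracks that enter the
  slab and retreat.

What passing these tests shows: the estimators, quadratures, solvers
and graph algorithms are correct on data whose statistical structure
matches their assumptions. What it does not show: robustness to
features of real trajectories that the generators deliberately omit —
kinetic correlation between frames (which inflates effective errors
beyond the i.i.d. block estimate), anharmonic and multimodal
fluctuations, force-field physics, lipids and explicit water structure.
Conclusions about a real channel still require real trajectories.

## Problem sizes, formats and limitations

The shipped tests and the acceptance script run at deliberately modest
sizes chosen to exercise every code path with tight oracles: a 100 Å
box at 1 Å spacing for the Poisson oracle, $10^4$–$10^5$ frames for
statistical estimators, 200 random graphs of up to 12 nodes against
exhaustive path enumeration, 10–20 seeds for planted-recovery and bias
checks. Structures are read from PDB, trajectories from CHARMM-format
DCD (the package includes a minimal DCD writer so fixtures round-trip
through the real reader; XTC is not supported), grids from/to OpenDX,
and tabular inputs (TI mean forces, charge/radius sidecars, matrices)
from CSV. Charges and radii are never inferred from a force field: they
come from a sidecar table, with a deliberately simple formal-charge
default for standard amino acids. Terminal cap atoms are excluded from
descriptor selections by default. The Poisson stage has no mobile-ion
screening or dielectric heterogeneity (it is not Poisson–Boltzmann),
and the pore profiler is axial-only by design.
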