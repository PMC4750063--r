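---
title: "Model and methods: membrane tubulation by curved protein rods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: membrane tubulation by curved protein rods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(bartube)
```

## The physical problem

BAR-superfamily proteins are banana-shaped rods that adsorb onto
biomembranes and bend them along the rod axis. At high surface density they
drive the protrusion of membrane tubules. Beyond the well-studied curvature
along the rod (`C_rod`), a rod also carries an effective *side* curvature
`C_side` perpendicular to its axis, generated by protein–protein and
membrane–protein contacts. This package simulates how that side curvature
reorganises the *pathway* of tubulation: negative `C_side` stabilises
branched, percolated rod networks that cover the membrane and delay tubule
protrusion, while positive `C_side` destabilises branches so that many
tubules protrude quickly from independent linear assemblies.

## The particle model

The membrane is a solvent-free, meshless one-layer sheet: each particle has
a position and a unit orientation vector `u` (its local normal) and the
sheet self-assembles through the potential
\[
U = U_{\mathrm{rep}} + U_{\mathrm{att}} + U_{\mathrm{tilt}} +
U_{\mathrm{bend}} + U_{\mathrm{bond}} + U_{\mathrm{angle}} .
\]

* **Repulsion** — truncated, shifted exponential,
  $\varepsilon_{\mathrm{rep}} e^{-20 (r/\sigma - 1)}$, giving an excluded
  volume of diameter $\sigma$ (the length unit).
* **Multibody attraction** — each particle accumulates a local density
  $\rho_i = \sum_j w(r_{ij})$ with a compact $C^1$ weight ($w = 1$ for
  $r \le r_{\mathrm{att}}$, cosine ramp to 0 at $r_{\mathrm{cut}}$) and
  gains energy $\varepsilon_{\mathrm{att}}\, u_{\mathrm{att}}(\rho_i)$ where
  $u_{\mathrm{att}}$ decreases linearly and saturates above $\rho^*$. The
  saturation makes the sheet fluid: particles gain nothing by packing beyond
  the target coordination, so there is no crystallisation pressure, while
  the linear branch holds the sheet together against thermal fluctuations.
* **Tilt** — $\tfrac{k_{\mathrm{tilt}}}{2}[(\mathbf u_i\cdot\hat{\mathbf
  r}_{ij})^2 + (\mathbf u_j\cdot\hat{\mathbf r}_{ij})^2]\, w(r_{ij})$
  penalises orientations tipping into the pair axis.
* **Bending** — $\tfrac{k_{\mathrm{bend}}}{2}\,|\mathbf u_i - \mathbf u_j +
  C_{\mathrm{bd}}\, \mathbf r_{ij}|^2\, w(r_{ij})$. The offset
  $C_{\mathrm{bd}}$ is the *pair spontaneous curvature*: scaling it with the
  pair separation makes the minimum an arc of curvature exactly
  $C_{\mathrm{bd}}$, with positive values bowing the sheet towards the
  orientation side.

A protein rod is a chain of `N_sg = 10` membrane particles with contour
length `r_rod = 10` sigma, held by stiff harmonic bonds
($k_{\mathrm{bond}} = 100$) and by a chain turning term
$\tfrac{k_{\mathrm{angle}}}{2}\,|\hat{\mathbf t}_{k+1} - \hat{\mathbf t}_k +
C_{\mathrm{rod}}\,\ell\, \mathbf u|^2$ whose minimum is a circular arc of
curvature `C_rod` bending along the particle normal — rods are semi-flexible
rather than rigid so one integrator serves all particles. Using the plain
turning angle alone would leave the bending direction free (a rod could curl
in-plane); coupling the turn to the orientation vector supplies the
anisotropy at no extra cost.

The side curvature enters through the bending pair offset:

| pair | offset |
|------|--------|
| two particles of *different* rods | `C_side` |
| rod particle – membrane particle | `C_side / 2` |
| two membrane particles | `C_0` (default 0) |
| same rod | excluded (chain terms handle it) |

"Contact" between rods is simply the support of the pair potential (any
distinct-rod pair within `r_cut`); no separate contact radius is introduced.
Non-bonded same-rod pairs are also excluded from the attraction so a rod
cannot collapse onto itself. There is no direct rod–rod attraction:
assembly is membrane-mediated.

## Dynamics and ensemble

Positions follow underdamped Langevin dynamics (BAOAB splitting,
$\zeta = 1$, $m = 1$, $dt = 0.002$); orientations carry an angular velocity
in the tangent plane, torques are $-\mathbf u \times \partial U/\partial
\mathbf u$, and the orientation is rotated exactly about the angular
velocity axis and renormalised. With friction and noise off the scheme is
conservative (energy drift below $10^{-4}$ relative per 1000 steps), which
the tests use as an integrator check. Hydrodynamic interactions are
deliberately absent: only static network stability matters for the pathway
competition studied here, though absolute rates carry a dynamical prefactor.

The projected area is controlled by Metropolis box moves every 20 steps
(amplitude 0.5% of the area): an affine rescale of x,y accepted with
probability $\min\{1, e^{-(\Delta U - \gamma \Delta A)/k_BT}\}$. At
$\gamma = 0$ this realises the tensionless membrane; positive $\gamma$
expands the frame and suppresses protrusion.

The tubulation protocol equilibrates rods with `C_rod = C_side = 0`,
switches the curvatures on at $t = 0$, and records frames and observables.
Durations are quoted in the diffusive time unit $\tau = r_\mathrm{rod}^2/D$.

## Calibration

The cited family of meshless models fixes emergent rather than microscopic
constants, so the package calibrates its free stiffnesses against the
emergent bending rigidity: `calibrate_bending()` adjusts `k_bend` by secant
iteration until the tensionless, rod-free sheet measures
$\kappa = 15\,k_BT$. With the shipped defaults
($\varepsilon_{\mathrm{rep}} = \varepsilon_{\mathrm{att}} = 4$,
$\rho^* = 6$, $k_{\mathrm{tilt}} = 10$, $k_{\mathrm{bend}} = 16.5$) the
calibration runs used here (N = 1024 patches, 40&#8239;000 equilibration steps
under tension moves, 250 frames of 200 steps at fixed area) measured
$\kappa/k_BT = 15.1$ and $14.8$ on two independent replicates, a tensionless
area per particle $a_0 \approx 1.75\,\sigma^2$, and an in-plane diffusion
coefficient $D \approx 0.057\,\sigma^2$ per time unit, i.e.
$\tau = r_\mathrm{rod}^2/D \approx 1.8\times 10^3$ time units. The area
compression modulus from the area fluctuations at $\gamma = 0$ is
$K_A \approx 15\,k_BT/\sigma^2$; the edge line tension is not calibrated.

$\kappa$ is estimated from the height-fluctuation spectrum: the height field
is binned on a 2-sigma grid, frames with empty cells (tears, overhangs) are
rejected, and per-mode rigidities $\kappa_q = k_BT A /(q^4 \langle |\hat
h_q|^2\rangle)$ are averaged over the window $q < 2\pi/(5\sigma)$ with a
bootstrap over frames for the error bar. On synthetic Gaussian fields of
known rigidity the estimator recovers $\kappa \in \{10, 15, 30, 60\}$ to
well within 5% (see the test suite). $D$ comes from the linear regime of
the in-plane mean-square displacement, $\langle \Delta r_{xy}^2\rangle =
4Dt$, with an explicit check that the log-log slope is 1.

## Observables

* **Clusters** — single linkage on rod centre-of-mass distances with
  threshold `r_rod/2` (minimum image; rod chains unwrapped across the
  boundaries). The mean cluster size is weight-averaged by default
  ($\sum N_i^2 / \sum N_i$) because a single percolated cluster should
  dominate the signal; the number average is available.
* **Cluster height** — per cluster, the variance of segment heights about
  the cluster's centre of mass; `z_cl` is the root of the plain average of
  per-cluster variances. It separates flat networks (small `z_cl`) from
  protruding tubules (large `z_cl`).
* **Percolation** — a cluster percolates in x (or y) when a rod connects to
  its own periodic image with nonzero winding number, detected by tracking
  minimum-image displacements along linkage edges.
* **Pathway** — `net` when a both-direction percolating cluster holding at
  least half of all rods persists for 20 tau before the first protrusion;
  `part` when percolation occurs but fails the coverage or persistence
  test; `iso` when no percolation precedes the protrusion. The coverage
  fraction (0.5) is a package choice exposed as a parameter, as the source
  analysis does not pin it numerically.
* **Tubules** — particles higher than `h_min = 1.5 r_rod` over the median
  plane (or over the fitted sphere, for vesicles, signed for
  inward/outward) mark protrusions; the component is grown down to
  `0.5 r_rod` to orient its principal axis, the radius is the mean
  cylindrical radius of the distal part, and a protrusion must persist for
  5 consecutive frames to set the first-protrusion time. All thresholds are
  arguments, validated against constructed cylinder fixtures.

## The geometric array model

The analytic companion model compares a striped (unbranched) and a
hexagonal (branched network) arrangement of rod assemblies, rectangles of
width `r_rod` with rigidities $\kappa_{r1} = 40\,k_BT$ along and
$\kappa_{r2} = \kappa = 15\,k_BT$ perpendicular to the rods.

In the striped array, strips curved up with $C_1$ along the rod axis
alternate with bare strips curved back with $-C_2$; continuity of the
membrane normal across the pattern forces
$C_2 = \phi_{\mathrm{rod}} C_1/(1 - \phi_{\mathrm{rod}})$.

The hexagonal array is a honeycomb with side $L_h$: rod rectangles of
length $L_h - r_\mathrm{rod}/\sqrt3$ on the edges (region I), equilateral
vertex triangles of side $r_\mathrm{rod}$ (region II), and interior
hexagons of side $L_h - r_\mathrm{rod}/\sqrt3$ (region III). The flat areas
close exactly, and fixing region I's area fraction to $\phi_{\mathrm{rod}}$
gives
\[
L_h = r_\mathrm{rod}\,\frac{1 + \sqrt{1 - 2\phi_{\mathrm{rod}}}}
{\sqrt3\,\phi_{\mathrm{rod}}},
\]
so the hexagonal construction exists only for $\phi_{\mathrm{rod}} \le 1/2$
— which is why `critical_network_density()` flags onset extents below
$L_h(1/2)$ as unbounded rather than chasing densities towards 1. Region I
is a saddle ($C_1$ along the rods, $-C_3$ across), regions II and III are
spherical caps of curvature $C_1$ (forced by continuity with the strip
ends) and $-C_4$. Normal continuity along the two independent lattice
directions gives $C_3 = C_4 = C_1 r_\mathrm{rod}/(\sqrt3 L_1)$ with
$L_1 = L_h - r_\mathrm{rod}/\sqrt3$, and the three-fold contact of strip
ends at a vertex closes the cap angle as $\theta_2 = \pi/3 -
C_1 r_\mathrm{rod}/2$: at $\theta_2 = 0$ the three strip-end arcs wrap the
whole vertex and $C_1$ reaches its maximum $2\pi/(3 r_\mathrm{rod})$.
Spherical caps carry the standard Helfrich energy density
$\tfrac{\kappa}{2}(2C)^2$; each region's area is taken at its flat value
(small-slope treatment). Energies are reported per unit projected area,
non-dimensionalised by $r_\mathrm{rod}^2$ — ratios, signs and minimiser
locations do not depend on this normalisation.

Both arrays share the curvature $C_1$ along the rods, so
$\Delta F = F_{\mathrm{hex}} - F_{\mathrm{st}}$ is evaluated in its
algebraically cancelled form and is exactly independent of
$C_{\mathrm{rod}}$ and $\kappa_{r1}$. The minimum of $\Delta F$ is negative
only for $C_{\mathrm{side}} < 0$ — the energetic reason the branched
network is a (meta)stable intermediate — and, in this construction, the
minimum at $\phi_{\mathrm{rod}} = 0.5$ is 2.16 times that at 0.4
(about twice as deep, the hexagonal geometry at one-half density being the
degenerate close-packed case):

```{r geometry-example}
library(bartube)
p4 <- array_params(phi_rod = 0.4, kappa = 15, kappa_r2 = 15, C_side = -1)
glance(delta_F(p4))
p5 <- array_params(phi_rod = 0.5, kappa = 15, kappa_r2 = 15, C_side = -1)
attr(delta_F(p5), "min_dF") / attr(delta_F(p4), "min_dF")
```

```{r geometry-plot, fig.height = 3.5}
autoplot(delta_F(p4))
```

## What the synthetic generators emulate

Test fixtures are built in code: cylinder-on-patch configurations with
known tubule count and radius, rod lattices with known cluster partitions
and winding (percolation) structure, Gaussian height fields of known
rigidity, and Brownian walkers of known diffusivity. They validate the
*measurement* machinery exactly, but they do not probe force-field realism:
passing them shows the observables are read correctly, not that the model
reproduces any particular lipid or protein. The simulation tests below are
the physical checks.

## Problem sizes used by the shipped tests

The full study conditions (flat patches of N = 25 600 with 1024 rods,
vesicles of N = 9 600, runs of hundreds of tau, eight seeds per point) are
cluster-scale; the package supports them, and its test suite exercises the
identical code paths at reduced scale chosen as the smallest systems whose
physics is still unambiguous:

* kappa check: N = 1024 patch, 40k + 50k steps (the calibration protocol).
* Tubulation: N = 900 patches (phi_rod = 0.4, 36 rods, `C_rod r_rod = 4`),
  a fraction of a tau of production — long enough for rods to assemble and
  the first tubules to protrude for `C_side r_rod = -1` and `+1` alike, and
  for the low-density (phi_rod = 0.1) twin runs to show that no percolated
  network forms there for either sign.
* Tension suppression: the same system under a strong imposed tension
  (200 kT/r_rod^2), checked against the tensionless twin: protrusion growth
  is suppressed.

One deliberately *untested* claim: which side-curvature sign forms the
longer-lived percolated network, and the resulting ordering of protrusion
times, requires a box holding several hexagonal network cells. The network
mesh size at phi_rod = 0.4 is L_h ≈ 2.1 r_rod = 21 sigma, so a patch below
roughly N = 4000 contains only about two cells and the net/part/iso
distinction cannot express itself; matched small-box runs confirm that the
single-seed protrusion-time ordering is not reproducible at N = 900. The
package runs the discriminating experiment at full scale
(`run_protocol()` + `classify_pathway()` at N = 25 600, several seeds, tens
of tau), and the classification rules themselves are tested exactly on
synthetic observable series. Absolute protrusion times in physical tau
additionally depend on the thermostat friction (a dynamical prefactor the
model does not calibrate), so comparisons should always be between matched
runs.

## Numerical choices and degenerate inputs

* Single cutoff `r_cut = 2.1 sigma` with the ramp from `r_att = 1.9 sigma`
  for both the attraction and the curvature weights; smooth and compact is
  all that matters.
* Cell-list neighbour search falls back to an exact O(N^2) scan for small
  or thin boxes where a 3x3x3 cell stencil would be ambiguous.
* The flat-patch box height (60 sigma) keeps tubules of a few tens of sigma
  from meeting their periodic image; vesicles get a 15-sigma clearance.
* A NaN in the forces aborts the run and dumps a diagnostic frame.
* `hex_constraints()` rejects `C_1` outside `[0, 2 pi/(3 r_rod))`;
  `delta_F()` handles the domain edge by one-sided search.
* Golden-section refinement of the `delta_F` minimiser uses a 1e-10
  bracket tolerance seeded by a 512-point grid.
* Seeds: every stochastic routine takes an explicit seed; identical seeds
  give bit-identical trajectories on one platform.

## Known limitations

* One-layer sheet: no bilayer leaflets, no electrostatics, no explicit
  solvent, no hydrodynamics; vesicle volume is unconstrained.
* The rod is semi-flexible with finite `k_bond`, `k_angle` = 100; extreme
  parameter choices (e.g. `C_rod r_rod` >> 4) may need a smaller timestep.
* Tubule radii are read from the distal part of a protrusion; strongly
  branched tubules report a single effective radius per connected
  component.
* The geometric model is a small-slope, constant-curvature idealisation;
  its quantitative minima inherit that approximation (and the printed
  factor between the network minima at densities 0.5 and 0.4 is 2.16, i.e.
  "about twice").
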