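---
title: "Simulating flat clathrin lattice dynamics with fclsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating flat clathrin lattice dynamics with fclsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fclsim)
```

## The model

fclsim simulates the self-assembly of clathrin triskelia into flat lattices
on a membrane patch. The domain is a cube of edge $L$ (default
$1\,\mu\mathrm{m}$); its bottom face is the plasma membrane, the volume
above it the adjacent cytosol. Two species are represented:

* **Clathrin** — a rigid planar pinwheel with three leg binding sites at
  120° spacing (radius 12.5 nm from the center, in the body plane) and one
  AP-2 binding site 2 nm below the center. Clathrin diffuses in the cytosol
  and binds other clathrins head-to-head: a formed bond holds the two leg
  sites exactly 5 nm apart with both bodies, and all six leg sites, in one
  plane. The planar 120° geometry closes into hexagonal rings, which is what
  makes the assembled lattices flat and gives the ~30 nm center-to-center
  lattice spacing.
* **AP-2** — a zero-volume adaptor confined to the membrane. Clathrin-bound
  AP-2 is represented explicitly as a rigid appendage directly beneath the
  host's AP-2 site; *unbound* AP-2 is an implicit well-mixed membrane pool
  tracked only by number. Binding to AP-2 orients the clathrin's AP-2-site
  axis perpendicular to the membrane, so membrane-bound assemblies lie flat
  at a fixed height.

Binding is cooperative through a gate: the clathrin–clathrin association
rate is zero unless at least one of the two partners belongs to an
AP-2-containing cluster. Assembly therefore nucleates at the membrane —
an AP-2-bound clathrin recruits cytosolic clathrin — and every
membrane-bound cluster contains at least one AP-2. "Bound to AP-2" is
evaluated at cluster level because nucleation proceeds from AP-2-anchored
clusters and the anchored cluster as a whole is the recruiting unit.

### Diffusion

Translational and rotational diffusion coefficients come from the
Stokes–Einstein relations $D = k_BT/(6\pi\eta r)$ and
$D_R = k_BT/(8\pi\eta r^3)$ at $T = 298.15$ K in water
($\eta = 8.9\times10^{-4}$ Pa·s). The clathrin default is
$D_\mathrm{Clat} = 13\,\mu\mathrm{m^2/s}$, isotropic, with the rotational
coefficient derived from the radius this implies (so the pair is
hydrodynamically consistent). AP-2 has $D_z = 0$ and
$D_{R,x} = D_{R,y} = 0$ (membrane confinement); its in-plane coefficients
use a 10 nm hydrodynamic radius. A bound cluster diffuses as one unit with
per-axis coefficients

$$D_\mathrm{cluster} = \Big[\sum_i D_i^{-1}\Big]^{-1}, \qquad
  D_{R,\mathrm{cluster}} = \Big[\sum_i D_{R,i}^{-1/3}\Big]^{-3},$$

which follow from adding member hydrodynamic radii. Any zero member
component forces the cluster component to zero, so an AP-2-containing
cluster cannot leave the membrane or tilt out of its plane.

### Reactions

Per step of $\Delta t = 3\,\mu s$, dissociation of each bond fires with the
Poisson probability $1-\exp(-k_\mathrm{off}\Delta t)$. Associations use a
volume-reaction (Doi-style) acceptance: two free sites closer than the
reaction radius $\sigma$ react with probability $1-\exp(-\lambda\Delta t)$,
$\lambda = k_\mathrm{micro}/V_\sigma$ with $V_\sigma = \tfrac43\pi\sigma^3$
in 3D and $\pi\sigma^2$ when both partners are membrane-bound (2D). The 3D
rate converts to 2D as $k_\mathrm{2D} = k_\mathrm{3D}/h$ with
$h = 10$ nm, the height of the membrane reaction layer. This acceptance is
simpler than propagator-reweighting schemes; what downstream statistics
depend on is the macroscopic rate, and a well-mixed calibration test in the
suite verifies that dilute A+B kinetics reproduce an ODE solution of
$d[AB]/dt = k[A][B]$ within 25 %. The scheme saturates when
$\lambda\Delta t \gtrsim 1$ (association then becomes encounter-limited,
as for any fixed-step particle scheme); the calibration is run in the
dilute, reaction-limited regime where the mapping is quantitative.

Unbound AP-2 is captured from the implicit pool: a clathrin whose AP-2
site is within $h$ of the membrane binds with probability
$1-\exp(-k_\mathrm{2D}\,\rho_\mathrm{free}\,\Delta t)$, where
$\rho_\mathrm{free}$ is the free-pool surface density. On acceptance an
explicit AP-2 appears beneath the site and the pool decrements; on
unbinding it returns. Pool totals are conserved exactly.

### The step

Each step executes, in order: (1) dissociation tests over all bonds;
(2) association tests — AP-2 layer first, then clathrin–clathrin candidate
site pairs in RNG-shuffled order; (3) Brownian moves of every cluster with
no frozen member (per-axis Gaussian displacements with variance
$2D_p\Delta t$, rotations by per-axis Gaussian angles applied about the
x-, y-, z-axes through the cluster centroid, in that order); (4) per-axis
mirror reflection at the walls ($p \to -p$ at 0, $p \to 2L-p$ at $L$; for a
cluster the whole body is translated by the mirror displacement of its
offending extreme member, which reduces to the plain mirror for a single
molecule); (5) excluded-volume resolution — any proposed configuration
with two clathrin centers closer than 10 nm has the conflicting clusters
redrawn, up to 100 times, after which the still-conflicting clusters keep
their pre-move pose. Molecules that reacted in a step are frozen and do not
diffuse in that step. Associations whose snapped-in bound pose would place
any center or site outside the closed box, or violate excluded volume, are
rejected.

## Numerical choices

* Orientations are unit quaternions, renormalized after every rotation.
  Coplanarity of bound pairs is constructed analytically (the partner pose
  is closed-form, never solved iteratively); tolerances are
  $10^{-6}$ nm for coplanarity and $10^{-9}$ for perpendicularity checks.
* The domain is closed: coordinates exactly on a face are inside;
  association rejection uses a strict outside test with a $10^{-9}$ nm
  guard against round-off.
* Ring-closure bonds (between two sites of the *same* cluster) are not
  formed: the head-to-head snap fixes the bound pose exactly, which a
  rigid ring generally cannot satisfy. Clusters are therefore trees in the
  bond graph; since all statistics derive from connected components, the
  analysis is unaffected, but lattice interiors are bonded more sparsely
  than a fully cross-linked lattice would be, which makes the shipped
  dissociation rates effective per-contact rates rather than microscopic
  ones.
* Candidate pairs are enumerated by a two-level scan (molecule centers
  within $2r_\mathrm{leg}+\sigma$, then the 3×3 site pairs) and visited in
  RNG-shuffled order; multiple candidates for one site are resolved by
  that order. When both sides of an accepted bond are mobile, the smaller
  cluster moves to the snapped pose; a free partner always moves to meet a
  membrane-bound one.
* One counter-based RNG (xoshiro256++, Marsaglia-polar normals) drives
  each run; the seed fixes the initial condition and every draw, so runs
  are bit-reproducible. Draws are consumed in the documented step order,
  and axes with zero diffusion coefficient consume no draws.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `box_edge` | 1000 | nm | membrane patch / domain edge |
| `dt` | 3 | µs | time step |
| `n_clathrin` | 300 | – | clathrin count (conserved) |
| `n_ap2` | 150 | – | AP-2 total (explicit + implicit pool) |
| `k_cc_gated` | 45.65 | µM⁻¹s⁻¹ | clathrin–clathrin rate when AP-2-gated (50 × 0.913) |
| `k_cc_free` | 0 | µM⁻¹s⁻¹ | ungated clathrin–clathrin rate |
| `k_ap2_clat` | 0.0012 | µM⁻¹s⁻¹ | clathrin–AP-2 association rate |
| `koff_cc` | 1 | s⁻¹ | clathrin–clathrin dissociation (placeholder) |
| `koff_ap2_clat` | 0.1 | s⁻¹ | clathrin–AP-2 dissociation (placeholder) |
| `reaction_radius` | 1 | nm | Doi capture radius σ |
| `capture_height` | 10 | nm | membrane reaction layer h (one excluded diameter) |
| `d_clat` | 13 | µm²/s | clathrin translational coefficient |

The two dissociation defaults are placeholders: the source kinetic set
this model family uses ships them in supplementary material we do not
restate, so `parse_config()` warns whenever a configuration leaves them
implicit. Results that depend on them are always reported against the
configured values.

## Stimulus schedules

A `parameter_schedule` holds breakpoints of piecewise-constant overrides:
absolute AP-2 numbers and multipliers (relative to baseline, never
compounded) for the rates and the clathrin diffusion coefficient. The
shipped `egf_protocol4.yaml` emulates a growth-factor stimulus: at time 0
the AP-2 number rises 100 → 200, the gated clathrin–clathrin rate
increases 50-fold and $D_\mathrm{Clat}$ drops to 1/50; at 30 simulated
minutes all three revert. When a breakpoint lowers the AP-2 number, free
pool molecules are removed first; if those do not suffice, the excess is
flagged and removed as bound AP-2 happens to unbind — a bound adaptor is
never forcibly ripped out of a lattice.

## Scale of the shipped study conditions

A full-scale reference run (300 clathrins, 30 simulated minutes,
$6\times10^8$ steps) is cluster-computing scale. The package therefore
ships desk-scale study conditions (`desk_small.yaml`): a quarter of the
membrane area (500 nm box), 60 clathrins, and 3 simulated seconds. Time
compression cannot be achieved by scaling rate constants alone, because
clathrin–clathrin capture is encounter-limited; the desk conditions
instead enlarge the reaction radius to 2.5 nm, scale the AP-2 capture
rate 2000-fold, and raise the dissociation rates to 10 s⁻¹
(clathrin–clathrin) and 20 s⁻¹ (AP-2), so that nucleation, growth, anchor
turnover and cluster-number transitions all occur within the run. AP-2
sweep values are scaled by membrane area (`desk_condition()` maps a
full-scale AP-2 number to its quarter-area analog). Under these conditions
the qualitative phase behavior of the full model is reproduced: a scarce
AP-2 analog yields no counted cluster, an abundant analog a single giant
cluster, and the cluster-number/size/dwell trends with the
clathrin–clathrin rate and the diffusion coefficient keep their full-scale
directions. The test suite runs these conditions with a handful of seeds;
problem sizes in the suite (10³–10⁶ steps, 1–60 molecules) were chosen so
each check exercises the property it names with useful statistical power.

## Analysis definitions

* **Clusters** are connected components of the clathrin–clathrin bond
  graph; an AP-2-bound monomer is a membrane cluster of one. A cluster is
  *membrane-bound* if it contains an AP-2 and *counted* if it holds more
  than 10 clathrins (the size class used for cluster-number statistics;
  configurable and reported in all outputs).
* **Cluster area** is the convex hull of the member x–y projections
  dilated by the 12.5 nm footprint disc (Minkowski sum,
  $A + Pr + \pi r^2$). The hull-plus-dilation contour is deterministic and
  has a closed form, unlike an alpha-shape, and visually matches the
  enclosing outlines drawn around lattice images.
* **$t_c$** is the first time the membrane-bound clathrin count strictly
  exceeds 90 % of its value in the final frame; statistics are restricted
  to frames after $t_c$. If the final count is zero, $t_c$ is undefined
  and the run simply has no membrane population (zero counted clusters).
* **Patterns**: frames sharing one counted-cluster number form a pattern;
  the most possible pattern is the modal one (ties resolved toward the
  smaller number). The mean cluster size of a pattern is the unweighted
  mean over that pattern's frames.
* **Dwelling times** are maximal constant runs of the counted-cluster
  series; runs truncated by the window boundary are flagged censored and
  excluded from mean dwells. Dwell resolution equals the frame interval
  (0.1 s at analysis-grade settings) and is reported with the results.

## Synthetic data

Two generators make every stage testable without external data. Initial
conditions place clathrin centers uniformly in the box at pairwise
distance ≥ 10 nm with uniform random orientations and a fully free AP-2
pool. Label masks for the image-metrics module are generated as
non-overlapping ellipses with log-normal areas (defaults give a mean of
0.05 µm²), uniform centers and orientations, returning exact ground truth.
These emulate the *geometry* of electron-microscopy-derived lattice masks —
region sizes, density, centroid spacing — but not imaging artifacts,
segmentation errors, or correlated shapes, so passing mask tests
demonstrates correctness of the metrics, not robustness to real imaging
noise. Likewise, the simulator's tests demonstrate the model's stated
behavior on synthetic conditions; they do not validate the biological
parameter values themselves.

## Known limitations

* Clathrin legs are rigid; leg flexibility, light chains, and membrane
  curvature coupling (dome/pit transitions) are out of scope — every
  assembly is planar by construction.
* The association acceptance is calibrated, not propagator-exact; at high
  microscopic rates it is encounter-limited, and the effect of the
  diffusion coefficient on cluster merging partly reflects this scheme
  (as it does for related acceptance criteria in the literature).
* Unbound AP-2 is a well-mixed pool: spatial AP-2 gradients on the
  membrane are not represented.
* The signaling network upstream of a stimulus is not modeled; schedules
  impose its presumed kinetic consequences directly.
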