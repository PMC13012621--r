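# fclsim

Particle-based simulation of flat clathrin lattice (FCL) assembly on a
membrane patch, with the cluster-dynamics statistics used to characterize
it and metrics for experimentally derived lattice label masks.

## The problem

Clathrin triskelia form two kinds of assemblies on the plasma membrane:
short-lived Ω-shaped endocytic pits and long-lived *flat* lattices that act
as signaling platforms. Several flat lattices typically coexist within a
square micron of membrane, their number and size fluctuate without any
stimulus, and growth-factor stimulation transiently increases both before
they relax to baseline. `fclsim` is for researchers who want to explore the
kinetic mechanisms behind these behaviors: it simulates clathrin and its
membrane adaptor AP-2 as rigid bodies undergoing Brownian motion and
stochastic binding/unbinding in a reflecting 1 µm box whose floor is the
membrane, and summarizes the resulting trajectories into the statistics the
imaging literature reports.

## The model in brief

* Clathrin: rigid planar pinwheel; three leg sites at 120° (12.5 nm
  radius), one AP-2 site 2 nm below center. Head-to-head leg binding with a
  5 nm bond gap and enforced coplanarity produces flat hexagonal lattices
  (~30 nm spacing). Excluded volume 10 nm between centers.
* AP-2: zero-volume membrane-confined dot; explicit when clathrin-bound,
  otherwise an implicit well-mixed pool. Clathrin–clathrin binding is
  *gated*: the rate is zero unless at least one partner's cluster contains
  an AP-2, so lattices nucleate at the membrane.
* Diffusion: Stokes–Einstein translational/rotational coefficients
  (clathrin default 13 µm²/s); a bound cluster moves as one unit with
  per-axis composed coefficients `D = (Σ 1/D_i)^-1` and
  `D_R = (Σ D_R,i^(-1/3))^-3`, so membrane-bound clusters stay in plane.
* Kinetics: per 3 µs step, dissociation with probability `1-exp(-k Δt)`;
  association by a calibrated Doi-style acceptance within a reaction
  radius, verified against an ODE oracle in the test suite.
* Schedules: piecewise-constant parameter overrides emulate stimuli (e.g.
  the shipped protocol doubling AP-2, raising the clathrin–clathrin rate
  50× and slowing clathrin diffusion 50×, reverting after 30 min).

Statistics: membrane recruitment time `t_c` (90 % of the final
membrane-bound count), counted-cluster number (clusters with >10
clathrins), its modal value after `t_c` ("most possible pattern"),
per-pattern mean cluster area (convex hull ⊕ 12.5 nm footprint disc), and
dwelling times of the cluster-number series. The mask module computes the
same per-lattice areas and 1 µm × 1 µm neighbor counts from integer label
masks (CSV or TIFF), with a synthetic elliptical-mask generator for
testing.

## Worked example

A desk-scale run (500 nm box, 60 clathrins, seconds of simulated time —
see the methods vignette for how these conditions relate to the full-scale
system):

```r
library(fclsim)

cfg <- parse_config(reference_config("desk_small"))
cfg$n_ap2 <- 100L          # abundant-adaptor condition
traj <- run_simulation(cfg)
print(traj)
#> fclsim trajectory: 60 frames, 60 clathrins, L = 500 nm
#>   simulated time: 3 s; seed: 1
#>   events: bind_cc 1624, unbind_cc 1566, bind_ap2 2732, unbind_ap2 2687

summary <- analyze_trajectory(traj)
print(summary)
#> fclsim cluster-dynamics summary
#>   frames: 60  (interval 0.000833 min)
#>   t_c: 0.0075 min
#>   most possible pattern: 1 counted cluster(s)
#>   mean cluster size (pattern): 0.09535 um^2
#>   mean dwelling time (pattern): 0.003095 min
```

Reading: membrane recruitment plateaus within half a simulated second
(`t_c` ≈ 0.0075 min); afterwards the system most often shows a single
counted cluster (>10 clathrins) — the "one giant cluster" regime of
abundant AP-2 — with a mean projected area of ~0.095 µm², and the cluster
number holds between transitions for ~0.19 s at this desk scale (dwell
resolution is the 0.05 s frame interval). With the scarce-adaptor analog
(`cfg$n_ap2 <- 2L`) the same pipeline reports a modal counted-cluster
number of 0: adaptors are too few to nucleate and anchor a lattice.

Mask metrics on a synthetic lattice mask:

```r
sm  <- synthetic_mask(20, field_size = 5, pixel_size = 0.02, seed = 14)
rec <- fcl_records(sm$mask)
rec$neighbors <- neighbor_counts(rec, window = 1)
head(rec, 3)
#>   label    x    y   area neighbors
#> 1     1 4.78 2.56 0.0324         0
#> 2     2 4.29 0.96 0.0936         1
#> 3     3 1.81 3.31 0.0436         1
```

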