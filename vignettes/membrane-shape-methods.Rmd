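---
title: "Membrane shape remodeling with phagosim: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane shape remodeling with phagosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phagosim)
```

## The model

phagosim simulates the shape dynamics of closed fluid membrane vesicles with
a dynamically triangulated Monte Carlo (DTMC) model, together with
coarse-grained membrane-bound protein scaffolds. The target application is
the earliest step of autophagy: the transformation of a vesicle formed by
fusion of a few small precursor vesicles into the cup-shaped double-membrane
phagophore, aided by S-shaped Atg17 dimer scaffolds.

The membrane is a closed, orientable, genus-0 triangle mesh with `n_v`
vertices, `n_e` edges and `n_t` triangles (`n_t - n_e + n_v = 2`). Its
elastic energy is the discretized Helfrich bending energy of a symmetric
bilayer with zero spontaneous curvature,

$$E_b = 2\kappa \sum_\alpha \frac{M_\alpha^2}{A_\alpha},\qquad
M_\alpha = \tfrac14 \sum_{ij \ni \alpha} l_{ij}\,\varphi_{ij},\qquad
A_\alpha = \tfrac13 \sum_{i \ni \alpha} A_i,$$

where the inner sums run over the edges and triangles at vertex $\alpha$,
$l_{ij}$ is the edge length and $\varphi_{ij}$ the dihedral angle between
the outward normals of the two triangles sharing the edge. For a sphere
$E_b \to 8\pi\kappa$ independent of radius. Two dimensionless shape
coordinates control the physics: the reduced volume
$v = 6\sqrt{\pi}\,V/A^{3/2}$ (1 for a sphere; fusing $n$ equal vesicles at
conserved area and volume gives exactly $v_n = 1/\sqrt{n}$) and the area
difference $\Delta a = \oint M\,dA / (2\sqrt{\pi A})$, the normalized
integrated mean curvature, which serves as the reaction coordinate of the
tube–disk–cup shape branch.

Stiff harmonic constraint potentials $K_A(1-A/A_\mathrm{ref})^2$,
$K_V(1-V/V_\mathrm{ref})^2$ and, in annealing runs,
$K_{\Delta a}(1-\Delta a/\Delta a_0)^2$ hold the conserved quantities at
their reference values. Monte Carlo moves are random vertex translations,
edge flips (membrane fluidity) and, when proteins are present, random bead
displacements, all accepted by the Metropolis criterion.

### Sign conventions and normalizations fixed by anchors

Two pieces of the discretization admit more than one reading; both are
fixed operationally by the sphere anchor:

* the dihedral angle is **signed**, positive where the surface is locally
  convex outward. This is required for oblate and invaginated shapes to
  reach $\Delta a < 1$ and for the branch to span its full range.
* the area-difference normalization is $2\sqrt{\pi A}$, the unique
  scale-invariant choice for which a sphere gives exactly
  $\Delta a = 1$. The unit tests verify both anchors and their convergence
  with mesh resolution.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `kappa` | 20 (free vesicle), 10 (protein runs) | $k_BT$ | bending rigidity |
| `K_A`, `K_V` | $10^6$ (free), $2\times10^5$/$5\times10^5$ (protein) | $k_BT$ | area/volume constraints |
| `K_da` | $5\times10^6$ | $k_BT$ | area-difference constraint (annealing) |
| `d0` | $l/2$ | $l$ | bead–membrane hard core |
| `d1` | $l$ | $l$ | outer adhesion range |
| `K_bond`, `K_ang`, `K_dih` | $10^4$, $10^3$, $500$ | $k_BT$ | chain stiffnesses (rigid dimers); flexible runs use `K_ang` 200–1000 |
| `u` | scenario-dependent | — | reduced binding strength $u = U A_\mathrm{Atg}/(8\pi\kappa)$, $A_\mathrm{Atg} = 16\bar A$ |

Lengths are measured in the tether unit $l$ defined from the mean triangle
area, $l^2 = 4\bar A/\sqrt3$; energies in $k_BT$ with $k_BT = 1$. Branch
energies are reported in units of $8\pi\kappa$ (about 250–500 $k_BT$ for
typical rigidities of 10–20 $k_BT$), in which the barrier heights are
independent of $\kappa$.

### Tether interval

Edge lengths are confined to $[\ell_\mathrm{min}, \ell_\mathrm{max}]$. The
default uses the ratio $\sqrt3$ with the initial mean edge length at the
geometric mid-interval: this is the widest interval that keeps triangles
well-shaped on a tethered fluid mesh. A looser literal interval with ratio
3 can be configured (`tether_bounds(ratio = 3)`); in our annealing
comparisons the looser interval produced *higher*, less reproducible
minima (rougher frozen states) without improving fluidity appreciably, so
$\sqrt3$ remains the default. Edge-flip acceptance is a few percent at
$\kappa = 20$ — flips are energetically expensive on a stiff membrane —
which still re-triangulates every edge many times over an annealing run.

### Adhesion range `d1`

The outer range of the square-well bead adhesion is not dictated by the
model; we take one tether length so that a bead binds a single membrane
patch of the resolution scale. Results involving binding strengths should
be read with this choice in mind; `d1` is exposed in `adhesion_params`.

## Simulated annealing and the shape branch

The annealing protocol has four phases: a linear reference-volume ramp to
the target reduced volume; a linear area-difference ramp to the target
$\Delta a_0$; equilibration at $T = 1\,k_BT$; and linear cooling to
$T \approx 0$. `simulated_annealing` repeats the protocol and reports the
repeat with minimum bending energy.

Desk-scale branch work uses two refinements, both implemented in
`branch_barriers`:

* **basin seeding.** Annealing a deflating sphere directly to a target
  $\Delta a$ at desk-scale step counts freezes into rough, path-dependent
  states: the stiff $\Delta a$ constraint is satisfied by small-scale
  wrinkles faster than the collective shape mode can respond. Starting
  instead from an analytic surface inside the right basin — a
  spherocylinder for the tube branch, an oblate ellipsoid for the disk
  branch (`tube_seed_mesh`, `disk_seed_mesh`) — gives annealed minima
  reproducible to a few parts in $10^3$ of $8\pi\kappa$.
* **continuation.** Adjacent branch points are connected states; walking
  the grid downward in $\Delta a$ and re-annealing from the previous
  minimum traces the connected branch, which is what the barrier between
  two basins refers to.

The tube-to-disk barrier $H_1$ is the difference between the maximum of
the annealed energies at barrier-top candidates
($\Delta a \approx 1.26$–$1.33$ at $v = 0.577$) and the tube minimum
($\Delta a \approx 1.44$); the disk-to-cup barrier $H_2$ is measured from
the disk minimum ($\Delta a = 1.04$) along the downward continuation into
the cup basin. With the default desk schedules (ramp 800, equilibration
3500–6000, cooling 5000–8000 sweeps; 2–4 repeats per point on the
642-vertex mesh) the whole barrier determination takes minutes.

**Known limitation.** At the 642-vertex working resolution the measured
$H_1$ converges to about $0.05\,(8\pi\kappa)$, below the reference value
of $0.069\,(8\pi\kappa)$ obtained at four-fold finer tessellation, while
$H_2 \approx 0.045$ agrees with its reference $0.038$ within the expected
scatter. The barrier-top structures (paddles) carry sharply curved rims
that a coarse mesh under-resolves, making their energy — and hence $H_1$ —
resolution-sensitive; the tube and disk minima are smooth and converge
quickly. Deeper annealing does not close the gap (the estimates above are
converged with respect to schedule length); finer meshes at matching
schedules move the barrier up but need proportionally longer runs than a
desk budget allows. Barrier *persistence* across reduced volumes and the
barrier ordering $H_1 > H_2$ are robust at 642 vertices.

## Fused-vesicle initial conditions

`fused_spheres_mesh` builds the post-fusion state: $n$ equal spheres in a
row, punctured at the contacts and bridged by catenoid necks (default neck
radius 10% of the sphere radius — narrow enough to approximate contact
puncture while respecting the tether at the working resolution; the value
is exposed, and narrower necks move $v$ closer to the ideal $1/\sqrt n$).
The surface of revolution is triangulated ring by ring with near-unit
edges and re-equilibrated with a short tether-repair Monte Carlo run in
which moves that do not worsen an existing tether violation are admitted.
The relaxed meshes satisfy every mesh invariant and sit within 1–2% of
$v_n = 1/\sqrt{n}$.

`place_dimers` lays two groups of three chains over the necks on one side
of the fusion axis (the tethering arrangement of the underlying model,
defined up to a
common rotation about the axis), each bead inside the adhesion well
$(d_0, d_1]$. Bead paths follow the measured axisymmetric offset profile
of the relaxed mesh; beads that land outside the well are projected to
mid-well height along the local surface normal. A small initial internal
strain relative to the built reference geometry remains and relaxes within
the first few hundred sweeps of a production run.

## The S-dimer geometry

The 34-nm Atg17 dimer is 16 beads with unit bonds along two
tangent-continuous quarter-circle arcs of opposite turning, arc planes
tilted by 15°. With 15 unit bonds spanning the two quarter arcs the arc
radius is $1/(2\sin(\pi/30)) \approx 4.78\,l$ — at the working resolution
about 12 nm against sphere radii of about 10 nm, the right relative scale
for crescents that clamp vesicle-sized curvature. (The model constraints —
16 beads, unit bead spacing, two quarter arcs — slightly over-determine
the radius relative to matching the vesicle radius exactly; we keep the
bead spacing exact and let the radius follow.) The straight control chain
has collinear reference geometry; its dihedral term is undefined and
omitted.

## Umbrella sampling and WHAM

Free-energy profiles along $\Delta a$ are computed from umbrella windows
with harmonic biases added to the *unconstrained* energy — the stiff
$K_{\Delta a}$ term is switched off during umbrella runs so that only one
restraint acts on the reaction coordinate. Windows are combined with a
self-consistent WHAM iteration (convergence `1e-8` on the window shifts),
samples thinned by their integrated autocorrelation time, errors by
bootstrap. Non-overlapping windows are reported as disconnected segments; the WHAM
iteration works in log space, since the production bias stiffness
($k = 2\times10^5$) makes the Boltzmann factors overflow a linear-space
implementation.

The intrinsic width of the global $\Delta a$ coordinate at the 642-vertex
resolution is only $\sim 0.002$, so the production bias with window
spacing of order $0.004$–$0.008$ is the regime that yields the stated
20–30% neighbor overlap — a barrier region needs tens of windows. At
desk-scale window lengths ($\sim 10^3$ sweeps per window versus millions
in production) the slow internal shape modes of the membrane do not
equilibrate within a window when the chain of windows is dragged along
the branch, and WHAM reads the drag lag as a steeply inflated barrier.
The desk tests therefore treat the PMF/annealed-barrier *ordering* as the
meaningful check at this scale and flag the magnitude as requiring
production-length windows.

The WHAM implementation is validated against an exactly solvable
double-well potential: biased samples drawn exactly by inverse-CDF
sampling reconstruct the analytic free energy to better than
$0.1\,k_BT$ RMS, stably under re-binning and leave-one-window-out.

## Shape classification

`classify_shape` is a deterministic rule on rotation- and scale-invariant
descriptors: gyration-tensor eigenvalue ratios (prolateness, oblateness),
ray-casting concavity depth relative to the local diameter and its
one-sidedness (a disk is biconcave symmetrically; bowls and cups are
one-sided), whether the area centroid lies outside the enclosed volume,
multi-crossing ray fraction (overhanging rims), and an arm count from
connected components of the far-radial vertex set (starfish). Thresholds
(pocket depth 0.12–0.35 of the diameter for bowl, beyond for cup) were
calibrated once on annealed reference shapes of the branch; the
centroid-outside cup test is gated on the shape not being dominated by a
single long axis, since a bent tube also throws the centroid outside the
surface. Unrecognized shapes return `"other"`.

## Kinetics

`kramers_escape_time` converts a barrier $H$ (in $k_BT$) and a relaxation
time $\tau$ of the slow shape fluctuation into the thermally activated
escape time $2\pi\tau e^{H}$. With $\tau = 0.05\,\mu s$, free-energy
barriers of 21–42 $k_BT$ give escape times from minutes to far beyond a
day — the tubular trap. `autocorr_biexp_fit` extracts $\tau$ from a
radius-of-gyration (or any stationary) series as the slow component of a
biexponential autocorrelation fit; it is validated on synthetic
two-time-scale series with known parameters.

## Production runs with proteins

`production_run` evolves a fused-vesicle mesh with placed dimers at
$T = 1$, $\kappa = 10$, $K_A = 2\times10^5$, $K_V = 5\times10^5$, and
labels the final frame. The binding-strength regimes (weak $u \le 0.07$:
tubular trap; intermediate $0.07 < u < 0.14$: paddle pathway to the cup;
strong $u > 0.14$: starfish pathway; straight chains: no cup) emerge on
the $10^7$-step scale of full production runs. Desk-scale runs of a few
thousand sweeps reach the metastable tube and show the expected adhesion
ordering (weakly bound dimers partially detach, intermediate-strength
dimers stay bound), but the full transition to the cup requires run
lengths far beyond a test budget; the corresponding desk checks therefore
probe the early-time ordering and are expected to under-count successes
relative to full-length runs.

## Numerical choices

* **Incremental bookkeeping.** Each move updates only the affected
  triangles, edge dihedrals and vertex quantities; caches are refreshed by
  full recomputation every 500 sweeps to bound floating-point drift. The
  incremental and full energies agree to $10^{-8}$ relative in the tests
  even with refresh disabled.
* **Reproducibility.** One `mt19937_64` stream per run, seeded from the
  master seed; identical seed and configuration give bit-identical
  trajectories (single-threaded).
* **Move widths** are tuned during warm-up to a 40% acceptance target and
  frozen for production (detailed balance).
* **Degenerate inputs.** Flips creating duplicate edges, sub-3 vertex
  degrees, tether violations or degenerate triangles are rejections, not
  errors; the biexponential fit falls back to a single time scale (flagged
  `degenerate`) when the two-exponential model is singular, as for white
  noise.
* **Problem sizes.** Tests run the 162- and 642-vertex meshes with
  annealing schedules of $10^3$–$10^4$ sweeps and 2–3 repeats; the
  acceptance analysis uses the 642-vertex mesh with equilibration 4000–6000
  and cooling 6000–8000 sweeps. These are the package's desk-scale study
  conditions; production-quality branches use the printed $10^6$-step
  phases.

## What the synthetic conditions do and do not show

The generator-built initial states (icospheres, fused-sphere chains,
analytic branch seeds) are idealized: exactly equal sphere sizes, clean
axisymmetric necks, no membrane asymmetry or spontaneous curvature, no
solvent hydrodynamics, and Monte Carlo "time" that is not physical time.
Passing tests therefore demonstrate the internal consistency of the
energetics, sampling and analysis machinery and the reproduction of the
model's reference energetics — not quantitative predictions for real Atg9
vesicles, whose leaflet asymmetries and finite thickness are outside the
Helfrich description used here.
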