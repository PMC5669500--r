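# phagosim

Dynamically triangulated membrane Monte Carlo for phagophore formation.

## The problem

The phagophore — the cup-shaped double-membrane precursor of the
autophagosome — is thought to arise in yeast from the fusion of about three
small Atg9 vesicles. Membrane elasticity makes this far from automatic:
fusing `n` equal vesicles at conserved area and volume lowers the reduced
volume to `v_n = 1/sqrt(n)` (0.577 for n = 3), which makes the cup the
globally preferred shape, but the post-fusion vesicle is kinetically
trapped in an elongated tube behind a substantial bending-energy barrier.
S-shaped Atg17 dimer scaffolds bound to the membrane can carry it over.

`phagosim` is an R package (with a compiled Monte Carlo core) for
quantifying this energetics:

* a **dynamically triangulated Monte Carlo** (DTMC) membrane: closed
  genus-0 triangle mesh, vertex moves plus edge flips under a tether
  constraint, discretized Helfrich bending energy
  `E_b = 2*kappa * sum_a M_a^2 / A_a` with harmonic constraints on area
  `A`, volume `V` and the area difference
  `da = (integral of M dA) / (2*sqrt(pi*A))` (the shape-branch reaction
  coordinate; `da = 1` for a sphere, `v = 6*sqrt(pi)*V/A^(3/2)`);
* **simulated annealing** shape-branch scans and barrier extraction
  (tube -> disk barrier `H1`, disk -> cup barrier `H2`, in `8*pi*kappa`
  units);
* a **coarse-grained Atg17 dimer**: 16 beads on two tilted quarter-circle
  arcs (or a straight control chain), harmonic bond/angle/dihedral shape
  restraints, square-well membrane adhesion with reduced binding strength
  `u = U*A_Atg/(8*pi*kappa)`;
* **umbrella sampling + WHAM** free-energy profiles along `da`,
  biexponential autocorrelation fits, and **Kramers escape times**
  `2*pi*tau*exp(H)`;
* fused-multi-sphere initial conditions with catenoid necks, dimer
  placement, a descriptor-based shape classifier
  (sphere/tube/disk/paddle/bowl/cup/starfish), and PLY/OFF/VTK mesh I/O.

## Worked example

```r
library(phagosim)

m <- build_icosphere(3)        # the 642-vertex working mesh
mesh_counts(m)
#> n_v  n_e  n_t
#> 642 1920 1280
shape_state(m)
#>          A        V      v     da      E_b E_b_8pk
#> 1 554.2563 1225.173 0.9985 1.0008 503.6083  1.0019
```

The sphere anchors of the discretization: bending energy `8*pi*kappa`
(here `kappa = 20`, so 502.7), area difference 1 and reduced volume 1, all
to a fraction of a percent at this resolution.

```r
f3 <- fused_spheres_mesh(3, subdivision = 3, seed = 1)
shape_state(f3)
#>          A        V     v     da      E_b E_b_8pk
#> 1 622.0464 847.5649 0.581 1.5008 1501.372  2.9869
classify_shape(f3)$label
#> [1] "tube"
```

Three fused spheres: reduced volume within 1% of `1/sqrt(3) = 0.5774`,
bending energy close to three sphere energies (`3 * 8*pi*kappa`), and an
elongated (pearled-tube) shape with `da ~ 1.5`.

```r
bb <- branch_barriers(v_target = 1/sqrt(3), seed = 1)   # minutes on 1 CPU
bb$H1; bb$H2      # tube->disk and disk->cup barriers, in 8*pi*kappa units
kramers_escape_time(0.05e-6, 21) / 60
#> [1] 6.905303    # minutes: a 21 k_B T barrier is a real kinetic trap
```

`branch_barriers` anneals the 642-vertex membrane at the stationary points
of the shape branch (tube minimum at `da ~ 1.44`, barrier-top candidates
near 1.3, disk minimum at 1.04 with downward continuation into the cup)
and reports the barrier heights; the escape-time line converts a
free-energy barrier into the waiting time that makes Atg17 assistance
necessary.

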