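---
title: "tetrasim: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetrasim: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the stochastic reaction-diffusion model and its assumptions, the geometry
machinery around it, the parameters that matter and why their defaults
are what they are, and the places where the design was genuinely open and
a choice had to be made.

## The model

`tetrasim` simulates reaction-diffusion systems with the spatial
Gillespie approach: the geometry is a tetrahedral mesh whose elements are
treated as well-mixed subvolumes, chemical kinetics inside each
tetrahedron follow stochastic mass action, and diffusion is the hop of a
single molecule across a shared face. The simulator samples the exact
trajectory distribution of this reaction-diffusion master equation with
Gillespie's direct method: waiting times are exponential in the total
propensity `a0`, and the firing channel is chosen with probability
proportional to its propensity.

The assumptions inherited from this framework:

* each tetrahedron is well mixed on the timescale of its fastest event —
  mesh resolution must be finer than reaction-diffusion length scales of
  interest;
* molecules are point-like and do not interact except through declared
  reactions (no crowding, no volume exclusion);
* rate constants are position-independent within a compartment.

### Units

All geometry is SI (metres, m², m³). Rate constants use the molar
convention: `M·s⁻¹` for order 0, `s⁻¹` for order 1, `M⁻¹s⁻¹` for order 2;
conversion to per-element stochastic rates multiplies/divides by
`N_A · V` with `V` in litres. Concentrations reported by `sim_conc()` are
molar. Mixing metres for geometry with litres in kinetics is deliberate:
it matches how rate constants are tabulated in the biochemistry
literature.

### The diffusion rate

For a molecule in tetrahedron `i` with face-neighbor `j`, the hop
propensity per molecule is

    d_ij = D · A_ij / (V_i · h_ij)

with `A_ij` the shared-face area and `h_ij` a distance between the two
barycenters — the two-point flux approximation of Fick's law. The flux
through a face is driven by the concentration gradient along the face
*normal*, so by default `h_ij` is the barycenter distance projected onto
the face normal. On meshes whose barycenter connections are orthogonal
to the faces the two choices coincide; on Kuhn-subdivided voxel meshes
they do not, and the plain Euclidean distance systematically
under-transports — measured effective diffusivity ≈ 0.90·D on a thin
bar, versus ≈ 1.02·D with the projected distance. `build_solver()`
exposes the choice (`diffusion_h = "projected"`/`"euclidean"`), and the
formula lives in one place for substitution. Either form satisfies the
detailed-balance symmetry `d_ij · V_i = d_ji · V_j`, making the uniform
distribution stationary — the thin-bar test verifies the resulting
Gaussian statistics against `N(x₀, 2Dt)` by Kolmogorov–Smirnov.

### Surface reactions and channels

Patches (triangle sets between one or two compartments) host surface
species. A surface reaction may involve participants `on` the membrane,
in the `inner` volume, or in the `outer` volume; the volumetric
participants are taken from the tetrahedron directly behind each triangle
on the corresponding side, which keeps the SSA coupling local. For the
unit conversion of order-2 surface reactions the volume of the first
volumetric participant's tetrahedron is used (the inner one if both
participants are membrane-bound). Multi-state channels are simply groups
of surface species declared as a `channel_state_set`; transitions are
ordinary surface reactions, so channel-count conservation is structural
rather than enforced.

The IP3 receptor demonstration (`ip3r_demo_model()`) encodes the
seven-state topology — native, IP3-bound, open, and four sequentially
Ca-bound inactivated states — with Ca released from the ER through open
receptors. Two modelling choices were open and are fixed as follows:
inactivated states do not bind IP3, and the open-channel Ca flux is a
mass-action surface reaction (`R_open + Ca_ER → R_open + Ca_cyt`) whose
constant the user must supply; no kinetic constants are bundled because
the package takes none as authoritative.

## The solver implementation

Every event channel — volume reaction, diffusion hop, surface reaction,
surface-diffusion hop — is compiled to one normal form: a rate prefactor
times falling factorials of reactant counts, plus a list of count deltas.
The C++ core keeps the propensity of each channel, groups channels by
their host element, and organizes group sums in a 4-ary sum-tree:
selecting an event costs one log-depth descent plus a scan of a handful
of in-group channels, and an event updates only the channels that depend
on the changed counts (a dependency graph built at solver construction).
This is still the exact direct method — the data structure only changes
the cost of finding the chosen channel, not its distribution.

Checkpoint semantics: `run_until(state, t)` executes events while the
next event time is ≤ `t` and then sets the clock to exactly `t`; the
exponential clock is memoryless, so discarding the partial waiting time
is distribution-preserving. Callbacks in `run_with_checkpoints()` and
`sync_run()` therefore observe the state strictly before the first event
past each checkpoint, and multiple simulations recorded through
`sync_run()` share bit-identical checkpoint timestamps.

Determinism: each `sim_state` owns one seeded 64-bit Mersenne Twister
stream used for event sampling and multinomial injections; identical
seeds give identical trajectories. Render-point sampling deliberately
uses R's session RNG instead, so drawing pictures of a state never
perturbs the simulation stream.

Numerical guards: degenerate tetrahedra are rejected at mesh build
(volume below `1e-18 ×` the bounding-box diagonal cubed — scale-free);
propensities are floored at zero; the incremental propensity table is
testable against a full rebuild (`propensities(state, rebuild = TRUE)`)
and agrees to 1e-9 relative in the suite; a negative count after an event
is a hard internal error, never silently clamped.

## Geometry machinery

**Indexing.** Internal element ids are 1-based and contiguous (the R
convention); ids from source mesh files are reachable only through the
per-class `index_map`, a bijection tested on random permutations.

**Selection.** The bounding-object method takes a convex primitive
(axis-aligned box, sphere, or cylinder) and selects elements by testing
representative points. Which test points an element must place inside
the primitive is ambiguous for elements straddling the boundary, so the
mode is explicit: `barycenter` (default — matches voxel-assignment
intuition),
`all_vertices` (fully inside) and `any_vertex` (touching). Containment is
inclusive with tolerance `1e-12 ×` the primitive scale so points exactly
on analytic surfaces select deterministically. Only convex primitives are
supported; composite regions are set operations on the returned id
lists. Screen-space (interactive) range selection is a GUI gesture and
out of scope; its effect is reproduced by primitive selection plus skin
filtering (`skin_triangles()`, `inner_tets()`).

**Compartments, patches, ROIs.** Compartments are disjoint tet sets;
patches are triangle sets whose members must separate the inner
compartment from the outer one — a triangle with both incident tets in
one compartment is rejected, since such a membrane would be interior to a
well-mixed region. ROIs are named, ordered element-id lists stored on the
mesh and reused for injection, recording and display filtering. The XML
archive persists all of this with full-precision (`%.17g`) coordinates;
round trips are value-exact and a second save is byte-identical, which
the suite checks.

## The synthetic geometry generator

The generator replaces an external interactive mesher: implicit solids
are voxelized on a regular grid (inside test at the voxel center) and
each inside voxel is split into the six Kuhn tetrahedra, giving a
conforming mesh by construction. What this emulates well: connectivity,
volumes, compartment topology of simple and moderately complex shapes.
What it does not emulate: surface-adaptive element sizing and smooth
curved boundaries — surfaces are staircases at the voxel scale, and the
enclosed volume carries an `O(h)` error that oscillates in sign with grid
parity (the suite therefore checks volume convergence across an 8×
refinement, not adjacent halvings). Conclusions that depend on smooth
boundary geometry should not lean on these meshes; diffusion and trapping
behaviour, which depend on volumes and connectivity, are robust.

The spiny dendrite is a shaft cylinder (defaults: length 20 µm, diameter
0.7 µm) with `round(density × length)` spines, each a spherical head on a
cylindrical neck attached radially. Placement draws axial position and
azimuth uniformly from a seeded stream and rejects a candidate whose head
center is within one head diameter of an accepted spine — the 3D
non-overlap condition (an axial-only exclusion would make densities
beyond ~1.7 spines/µm unsatisfiable). Spine dimensions default to head
radius 0.3 µm, neck radius 0.1 µm, neck length 0.5 µm — package choices
in the range electron microscopy reports for hippocampal spines. The
default voxel size `d/8` resolves the neck with ≥ 2 voxels across. The
`"shaft"` ROI (tets whose barycenter lies in the analytic shaft cylinder)
is registered automatically; `injection_zone_roi()` adds the central
cylindrical zone by bounding-object selection.

Spine count is exact rather than Poisson-sampled so that the density
claim is directly testable; a Poisson alternative would only add
replicate-level variance.

## Study conditions and problem sizes

The dendrite example fixes geometry (20 µm × 0.7 µm shaft; densities
0, 2, 4, 8 spines/µm; 2000 molecules into a central 0.7 µm × 0.7 µm
zone) but not the diffusion coefficient or observation time. The package
fixes them once:

* `D = 1e-12 m²/s` (1 µm²/s) — typical of a small cytosolic protein or a
  dextran-conjugated dye;
* comparison time `t = 6 s` for the density ordering. The escape time of
  a spine head through its neck is roughly
  `V_head·L_neck/(D·A_neck) ≈ 1.8 s` at these dimensions, and the
  shaft-restricted spread only orders cleanly once trap exchange has
  equilibrated over a few escape times. At much shorter times two effects
  compete: trapping both slows transport (narrowing) and preferentially
  removes lagging molecules from the shaft population (apparent
  widening), and the net separation between neighbouring densities is
  within sampling noise of 2000 molecules.
* the ordering runs voxelize at `d/6` instead of the `d/8` default; at
  ~10⁵ tets per mesh and ~10⁷ events per replicate this keeps the
  40-replicate experiment near ten minutes of CPU while still resolving
  the neck with ~1.7 voxels.

The thin-bar diffusion calibration uses an 8 µm bar with 10⁴ molecules
to t = 0.2 s (σ ≈ 0.63 µm, far from the ends); positions are jittered
uniformly within their element before the Kolmogorov–Smirnov comparison,
since binning at voxel centers would otherwise discretize the empirical
CDF at the test's sensitivity.

## Render-point generation

Counts-to-points conversion draws exactly one uniform position per
molecule inside its element: sorted uniforms in tetrahedra (barycentric
weights `(s₁, s₂−s₁, s₃−s₂, 1−s₃)`), the square-root construction in
triangles. Both are exact and constant-cost; the suite verifies the
Beta(1,3)/Beta(1,2) barycentric marginals and equal occupancy of the
eight equal-volume midpoint sub-tets.

Two caps regulate output size: `max_points` per visual component and
`max_density` (points per m³ or m²); once the totals exceed
`max_points`, each element emits `min(count, floor(density × measure))`
points. Auto-adjust rescales the density once per update by
`max_points / actual_total` — a single pass, not a fixed-point loop, so
relative densities across elements are preserved only approximately
(documented reading of a ratio-based adjustment). Per-element reduction
keeps `min(count, cap)` rather than proportional thinning, implementing
the cap literally as a ceiling.

Channel components on membranes keep persistent positions: a copy gets a
uniform position in its triangle at initialization, state transitions
relabel it in place, and a position is redrawn only when a copy moves to
another triangle. Without an event log, the tracker reconciles stored
points against per-triangle totals, moving the minimal number of copies —
exactly one position changes for an isolated surface-diffusion hop.

Displays hold references to shared components ("many-to-many"
association): a snapshot generates each referenced component's cloud once
and every display that contains it references that single instance.

## Quantitative outputs

Histograms along an axis (`axial_distribution()`) and the spread summary
(`axial_spread()`) bin molecules by their element's barycenter, not by
sampled render positions — deterministic and independent of the render
RNG, at the cost of sub-element spatial resolution (irrelevant at the
bin widths of interest). Bins are half-open with the last bin closed;
mass conservation and bin-merging consistency are tested. Time series
align across simulations through shared checkpoints (`sync_run()`).

## Known limitations

* No next-subvolume or tau-leaping acceleration; desk-scale meshes
  (≲ 3×10⁵ tets) and ≲ 10⁸ events per run are the intended envelope.
* Voxelized boundaries: no surface-adaptive meshing; curved membranes
  are staircases at the voxel scale.
* Surface diffusion uses the same two-point flux form as volume
  diffusion on the triangle edge graph; patches with highly irregular
  triangulations will see first-order accuracy only.
* Membrane potential (electro-diffusion, voltage-gated rates) is out of
  scope.
* Mesh import covers Abaqus `*NODE`/`*ELEMENT` (C3D4, S3) without
  part/instance assemblies or continuation lines, TetGen `.node/.ele`,
  and Gmsh MSH 2.2 ASCII only.
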