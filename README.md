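# tetrasim

Spatial stochastic reaction-diffusion simulation on tetrahedral meshes,
with the geometry-preparation and visualization-side computations that
such simulations need: mesh import and archiving, bounding-object element
selection, compartments/patches/ROI datasets, a synthetic geometry
generator (boxes, smooth and spiny dendrites, nested two-compartment
solids), render-point generation with density capping, and quantitative
spatial/temporal outputs.

## Who this is for

Computational neuroscientists and systems biologists who model
reaction-diffusion systems where stochasticity and spatial structure
matter — calcium signalling in dendritic spines, membrane channel
kinetics, molecule trapping in complex morphologies — and who want a
self-contained R toolchain from mesh to figures.

## The method

The solver is a spatial extension of Gillespie's Stochastic Simulation
Algorithm. The tetrahedral mesh partitions the geometry into well-mixed
subvolumes; chemical kinetics inside a tetrahedron of volume `V` follow
mass action with molar rate constants mapped to stochastic propensities

    a = k·N_A·V_L          (order 0, k in M·s⁻¹, V_L in litres)
    a = k·n                (order 1, k in s⁻¹)
    a = k/(N_A·V_L)·n_A·n_B  (order 2, k in M⁻¹s⁻¹; n(n−1) for identical
                              reactants)

and diffusion is the transport of single molecules between face-adjacent
tetrahedra with per-molecule hop rate

    d_ij = D·A_ij / (V_i·h_ij)

(`A_ij` shared-face area, `h_ij` the barycenter distance projected onto
the face normal) — the finite-volume discretization of Fick's law. Surface reactions live on patch triangles
and may consume/produce molecules in the volumes on either side, which is
how multi-state membrane channels (e.g. the IP3 receptor) are expressed.
Event times and identities are sampled exactly with the direct method.

Because an SSA state stores counts per subvolume, not positions,
visualization requires generated positions: for each update the package
draws, per element, exactly as many uniform random points as there are
molecules (sorted-uniforms barycentric sampling in tetrahedra,
square-root construction in triangles), with configurable maximum-points
and maximum-density caps.

## Worked example: diffusion along a spiny dendrite

Molecules transiently trapped in dendritic spines slow diffusion along
the dendrite. Generate a 20 µm × 0.7 µm dendritic shaft, inject 2000
molecules of a diffusible species (D = 1 µm²/s) into a central
0.7 µm × 0.7 µm cylindrical zone selected with a bounding cylinder, and
compare the axial spread in the shaft with and without spines:

```r
library(tetrasim)

run <- smooth_dendrite_injection_run(n_molecules = 2000,
                                     t_end = 0.01, dt_update = 1e-3,
                                     seed = 1)
run$totals
#>  [1] 2000 2000 2000 2000 2000 2000 2000 2000 2000 2000 2000
```

Diffusion only moves molecules, so the total is 2000 at every checkpoint.
The density comparison (this is the long computation — about 13 minutes
for 10 replicates × 4 densities):

```r
out <- spine_density_experiment(densities = c(0, 2e6, 4e6, 8e6),
                                replicates = 10, seed = 1)
round(colMeans(out$spreads) * 1e6, 2)
#> [1] 3.45 3.17 2.92 2.54
```

The four numbers are the mean axial standard deviations (µm) of the
molecules inside the shaft ROI at t = 6 s for 0, 2, 4 and 8 spines/µm:
spread falls monotonically as spine density rises — the anomalous
diffusion signature. `axial_distribution()` produces the corresponding
spatial histograms and `plot_outputs()` renders them.

Mesh I/O, element selection, and model association compose into a
prepared, archivable geometry:

```r
raw  <- read_abaqus(system.file("extdata", "twotet.inp", package = "tetrasim"))
mesh <- tetmesh_from_raw(raw)
mesh <- make_compartment(mesh, "cyt", seq_len(nrow(mesh$tets)), "cyt_vsys")
save_archive(mesh, "prepared.xml")   # XML archive; load_archive() restores it
```

A thin command-line wrapper over these functions is installed at
`inst/cli/tetrasim.R` (subcommands `import`, `genmesh`, `select`, `run`).

## Vignette

`vignettes/tetrasim-methods.Rmd` documents the model and its assumptions,
the discretization and unit conventions, the synthetic-geometry
generator, the chosen study conditions, numerical tolerances, and known
limitations.
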