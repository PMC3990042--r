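# ---------------------------------------------------------------------------
# Canned study protocols built from the package's parts, so that tests,
# scripts and users run the identical procedure.
# ---------------------------------------------------------------------------

#' Diffusion on a smooth dendrite with central injection
#'
#' Generates the smooth dendritic shaft (default 20 um x 0.7 um), selects
#' the central cylindrical injection zone (0.7 um x 0.7 um) with the
#' indirect bounding-object method, injects `n_molecules` of one diffusible
#' species, and runs diffusion-only SSA to `t_end` with checkpoints every
#' `dt_update`, recording the total count at every checkpoint.
#'
#' @param n_molecules Molecules injected (default 2000).
#' @param D Diffusion coefficient (m^2/s).
#' @param t_end End time (s).
#' @param dt_update Checkpoint interval (s).
#' @param seed RNG seed.
#' @param spec Dendrite spec; default the 20 um x 0.7 um smooth shaft.
#' @return List with `times`, `totals` (count per checkpoint), and the
#'   final `state`.
#' @export
smooth_dendrite_injection_run <- function(n_molecules = 2000, D = 1e-12,
                                          t_end = 0.01, dt_update = 1e-3,
                                          seed = 1L,
                                          spec = spiny_dendrite_spec()) {
  gen <- spiny_dendrite_mesh(spec)
  gen$mesh <- make_compartment(gen$mesh, "cyt",
                               seq_len(nrow(gen$mesh$tets)), "vsys")
  gen <- injection_zone_roi(gen)
  model <- build_model("X", volume_systems = list(volume_system(
    "vsys", diffusion = list(diffusion_rule("dX", "X", D)))))
  st <- build_solver(model, gen$mesh, seed = seed)
  inject_into_roi(st, "injection_zone", "X", n_molecules)
  rec <- run_with_checkpoints(st, t_end, dt_update, function(s, t)
    unname(sim_count(s, "cyt", "X")))
  list(times = rec$times, totals = unlist(rec$values), state = st,
       generated = gen)
}

#' Anomalous diffusion across spine densities
#'
#' The spiny-dendrite comparison: one mesh per density (20 um x 0.7 um
#' shaft, spines at `densities` per metre), `n_molecules` of a single
#' diffusible species injected into the central 0.7 um x 0.7 um zone, run
#' to `t_end`, and the axial spread (standard deviation of molecule
#' positions along the shaft axis) measured within the `"shaft"` ROI so
#' that molecules trapped in spines are filtered out. Replicates rerun the
#' SSA with fresh seeds on the same geometries.
#'
#' Spine trapping slows axial transport, so the spread at fixed time
#' decreases with spine density once the trap exchange has equilibrated
#' (several times the neck escape time); `t_end` defaults to 6 s at
#' D = 1e-12 m^2/s for that reason. The runs use a voxel size of
#' `shaft_diameter / 6`.
#'
#' @param densities Spine densities in spines/m.
#' @param n_molecules Injected molecules per run.
#' @param D Diffusion coefficient (m^2/s).
#' @param t_end Comparison time (s).
#' @param replicates Number of SSA replicates per density.
#' @param voxel_size Voxelization resolution for these runs.
#' @param seed Base seed (geometry uses `seed + density index`; SSA
#'   replicates use derived seeds).
#' @param progress Print one line per run.
#' @return List with `spreads` (replicates x densities matrix, metres),
#'   `shaft_counts` (same shape), and `densities`.
#' @export
spine_density_experiment <- function(densities = c(0, 2e6, 4e6, 8e6),
                                     n_molecules = 2000, D = 1e-12,
                                     t_end = 6, replicates = 10,
                                     voxel_size = 0.7e-6 / 6,
                                     seed = 1L, progress = FALSE) {
  model <- build_model("X", volume_systems = list(volume_system(
    "vsys", diffusion = list(diffusion_rule("dX", "X", D)))))
  spreads <- matrix(NA_real_, nrow = replicates, ncol = length(densities))
  shaft_counts <- matrix(NA_real_, nrow = replicates,
                         ncol = length(densities))
  for (j in seq_along(densities)) {
    gen <- spiny_dendrite_mesh(spiny_dendrite_spec(
      spine_density = densities[j], voxel_size = voxel_size,
      seed = seed + j))
    gen$mesh <- make_compartment(gen$mesh, "cyt",
                                 seq_len(nrow(gen$mesh$tets)), "vsys")
    gen <- injection_zone_roi(gen)
    st <- build_solver(model, gen$mesh, seed = seed)
    for (r in seq_len(replicates)) {
      reset_state(st, seed = seed + 1000L * j + r)
      inject_into_roi(st, "injection_zone", "X", n_molecules)
      run_until(st, t_end)
      spreads[r, j] <- axial_spread(st, "X", restriction = "shaft")
      shaft_counts[r, j] <- sim_count(st, "shaft", "X")
      if (progress)
        message(sprintf("density %g /um, replicate %d: spread %.3g um",
                        densities[j] / 1e6, r, spreads[r, j] * 1e6))
    }
  }
  list(spreads = spreads, shaft_counts = shaft_counts,
       densities = densities)
}
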