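# ---------------------------------------------------------------------------
# Programmatic mesh generation: implicit solids are voxelized on a regular
# grid (inside test at the voxel center) and each inside voxel is split into
# the 6 Kuhn tetrahedra, which yields a conforming tetrahedral mesh by
# construction. Used for test fixtures (boxes), the smooth/spiny dendrite
# geometries, and the nested two-compartment toy.
# ---------------------------------------------------------------------------

# Run code with a private RNG stream; the session RNG state is untouched.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 6 Kuhn tetrahedra of the unit cube: vertex-offset triples per tet, built
# from the 6 axis permutations of the path (0,0,0) -> (1,1,1). Sharing the
# main diagonal in every cell makes the subdivision conforming across cells.
.KUHN_PERMS <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
.kuhn_offsets <- local({
  out <- vector("list", 6L)
  for (p in 1:6) {
    perm <- .KUHN_PERMS[p, ]
    o <- matrix(0L, 4L, 3L)
    o[2, perm[1]] <- 1L
    o[3, ] <- o[2, ]; o[3, perm[2]] <- 1L
    o[4, ] <- 1L
    out[[p]] <- o
  }
  out
})

# cells: m x 3 integer matrix of 0-based grid coordinates of inside voxels;
# h: length-3 voxel edge lengths; origin: coords of grid corner (0,0,0).
.tetmesh_from_cells <- function(cells, h, origin = c(0, 0, 0)) {
  if (!nrow(cells)) stop("voxelization produced no inside cells")
  m <- nrow(cells)
  kx <- max(cells[, 1]) + 2L
  ky <- max(cells[, 2]) + 2L
  # grid-corner linear key (doubles: exact far beyond any grid used here)
  keys <- matrix(0, nrow = m, ncol = 24L)
  col <- 0L
  for (p in 1:6) {
    off <- .kuhn_offsets[[p]]
    for (v in 1:4) {
      col <- col + 1L
      keys[, col] <- (cells[, 1] + off[v, 1]) +
        kx * ((cells[, 2] + off[v, 2]) + ky * (cells[, 3] + off[v, 3]))
    }
  }
  kv <- as.vector(keys)
  uk <- sort(unique(kv))
  idx <- matrix(match(kv, uk), nrow = m, ncol = 24L)
  # columns of `keys` are (p1v1 p1v2 p1v3 p1v4 p2v1 ...); one tet per
  # (cell, permutation)
  tets <- do.call(rbind, lapply(1:6, function(p)
    idx[, (p - 1L) * 4L + (1:4), drop = FALSE]))
  ii <- uk %% kx
  rest <- (uk - ii) / kx
  jj <- rest %% ky
  kk2 <- (rest - jj) / ky
  verts <- cbind(origin[1] + ii * h[1],
                 origin[2] + jj * h[2],
                 origin[3] + kk2 * h[3])
  build_tetmesh(verts, tets)
}

#' Box mesh by Kuhn subdivision
#'
#' A rectangular box split into `divisions` cells per axis, each cell split
#' into 6 Kuhn tetrahedra; the mesh is conforming and its tet volumes sum to
#' the box volume exactly (up to roundoff).
#'
#' @param dims Length-3 box edge lengths (metres).
#' @param divisions Length-3 (or scalar) number of cells per axis.
#' @param origin Coordinates of the box corner (default the origin).
#' @return A `tetmesh` with `6 * prod(divisions)` tets.
#' @export
box_mesh <- function(dims, divisions = c(1L, 1L, 1L), origin = c(0, 0, 0)) {
  dims <- as.numeric(dims)
  divisions <- as.integer(rep(divisions, length.out = 3L))
  if (any(dims <= 0) || any(divisions < 1L))
    stop("box_mesh needs positive dims and divisions >= 1")
  cells <- as.matrix(expand.grid(ix = 0:(divisions[1] - 1L),
                                 iy = 0:(divisions[2] - 1L),
                                 iz = 0:(divisions[3] - 1L)))
  storage.mode(cells) <- "integer"
  .tetmesh_from_cells(cells, dims / divisions, origin)
}

#' Specification of a simplified spiny dendrite
#'
#' A dendritic shaft cylinder with simplified spines (spherical head on a
#' cylindrical neck) attached at random axial positions and azimuths. The
#' number of spines is exactly `round(spine_density * shaft_length)`.
#' Default spine dimensions (head radius 0.3 um, neck radius 0.1 um, neck
#' length 0.5 um) are package choices in the range reported by EM studies of
#' hippocampal spines; the default voxel size `shaft_diameter / 8` resolves
#' the neck with at least two voxels across.
#'
#' @param shaft_length Shaft length in metres (default 20 um).
#' @param shaft_diameter Shaft diameter in metres (default 0.7 um).
#' @param spine_density Spines per metre of shaft (e.g. `8e6` = 8/um).
#' @param head_radius,neck_radius,neck_length Spine dimensions (metres).
#' @param voxel_size Voxelization edge length (metres).
#' @param seed Integer seed for spine placement.
#' @return A `spiny_dendrite_spec`.
#' @export
spiny_dendrite_spec <- function(shaft_length = 20e-6,
                                shaft_diameter = 0.7e-6,
                                spine_density = 0,
                                head_radius = 0.3e-6,
                                neck_radius = 0.1e-6,
                                neck_length = 0.5e-6,
                                voxel_size = shaft_diameter / 8,
                                seed = 1L) {
  if (shaft_length <= 0 || shaft_diameter <= 0 || voxel_size <= 0)
    stop("shaft_length, shaft_diameter and voxel_size must be positive")
  if (spine_density < 0) stop("spine_density must be >= 0")
  if (!(neck_radius < head_radius && head_radius < shaft_diameter))
    stop("need neck_radius < head_radius < shaft_diameter")
  structure(list(shaft_length = shaft_length, shaft_diameter = shaft_diameter,
                 spine_density = spine_density, head_radius = head_radius,
                 neck_radius = neck_radius, neck_length = neck_length,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "spiny_dendrite_spec")
}

# draw non-overlapping spine anchors; returns data.frame(x, theta)
.place_spines <- function(spec, n_spines, max_attempts = 10000L) {
  L <- spec$shaft_length
  clearance <- spec$head_radius
  rc <- spec$shaft_diameter / 2 + spec$neck_length + spec$head_radius
  xs <- numeric(0); th <- numeric(0)
  hx <- numeric(0); hy <- numeric(0); hz <- numeric(0)
  for (s in seq_len(n_spines)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- runif(1, clearance, L - clearance)
      t <- runif(1, 0, 2 * pi)
      cy <- rc * cos(t); cz <- rc * sin(t)
      if (length(hx)) {
        d2 <- (hx - x)^2 + (hy - cy)^2 + (hz - cz)^2
        if (min(d2) < (2 * spec$head_radius)^2) next
      }
      xs <- c(xs, x); th <- c(th, t)
      hx <- c(hx, x); hy <- c(hy, cy); hz <- c(hz, cz)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("spine placement failed after ", max_attempts,
           " attempts: density too high for non-overlapping heads")
  }
  data.frame(x = xs, theta = th)
}

#' Generate a smooth or spiny dendrite mesh
#'
#' Voxelizes the implicit solid (shaft cylinder union spine necks and heads)
#' at `spec$voxel_size` and tetrahedralizes the inside voxels. Spine count
#' is exactly `round(spine_density * shaft_length)`; placement draws axial
#' position and azimuth from a seeded stream, rejecting overlapping heads
#' (3D head-center distance below one head diameter). The ROI `"shaft"`
#' (tets whose barycenter lies inside the analytic shaft cylinder) is
#' registered automatically. Deterministic for a fixed spec and seed.
#'
#' @param spec A `spiny_dendrite_spec`.
#' @return A `generated_mesh`: list with `mesh`, `spine_count`,
#'   `spine_anchors` (axial position, azimuth, head center), `axis_origin`,
#'   `axis_dir`, and the `spec`.
#' @export
spiny_dendrite_mesh <- function(spec) {
  stopifnot(inherits(spec, "spiny_dendrite_spec"))
  L <- spec$shaft_length; R <- spec$shaft_diameter / 2; h <- spec$voxel_size
  n_spines <- round(spec$spine_density * L)
  anchors <- if (n_spines > 0)
    .with_seed(spec$seed, .place_spines(spec, n_spines))
  else data.frame(x = numeric(0), theta = numeric(0))

  rmax <- if (n_spines > 0)
    R + spec$neck_length + 2 * spec$head_radius else R
  nx <- ceiling(L / h)
  nyz <- 2L * ceiling(rmax / h)
  oy <- -nyz * h / 2
  cx <- (seq_len(nx) - 0.5) * h
  cyz <- oy + (seq_len(nyz) - 0.5) * h
  keep_x <- cx <= L                      # centers inside [0, L]
  cx <- cx[keep_x]
  grid <- expand.grid(ix = seq_along(cx), iy = seq_len(nyz),
                      iz = seq_len(nyz))
  px <- cx[grid$ix]; py <- cyz[grid$iy]; pz <- cyz[grid$iz]
  inside <- (py^2 + pz^2) <= R^2         # shaft (px always in [0, L])

  if (n_spines > 0) {
    rc_head <- R + spec$neck_length + spec$head_radius
    r_in <- max(R - h, 0)                # neck starts just inside the shaft
    r_out <- R + spec$neck_length
    for (s in seq_len(n_spines)) {
      x0 <- anchors$x[s]; t0 <- anchors$theta[s]
      u <- c(cos(t0), sin(t0))           # radial direction in (y, z)
      hc <- c(x0, rc_head * u)
      reach <- rc_head + spec$head_radius
      cand <- which(!inside &
                    abs(px - x0) <= reach &
                    abs(py - hc[2]) <= reach &
                    abs(pz - hc[3]) <= reach)
      if (!length(cand)) next
      qx <- px[cand]; qy <- py[cand]; qz <- pz[cand]
      # head sphere
      hit <- (qx - hc[1])^2 + (qy - hc[2])^2 + (qz - hc[3])^2 <=
        spec$head_radius^2
      # neck: radial cylinder of radius neck_radius from r_in to r_out
      rad <- qy * u[1] + qz * u[2]       # signed radial coordinate
      perp2 <- (qx - x0)^2 + (qy - rad * u[1])^2 + (qz - rad * u[2])^2
      hit <- hit | (rad >= r_in & rad <= r_out & perp2 <= spec$neck_radius^2)
      inside[cand[hit]] <- TRUE
    }
  }

  cells <- cbind(grid$ix[inside] - 1L, grid$iy[inside] - 1L,
                 grid$iz[inside] - 1L)
  storage.mode(cells) <- "integer"
  mesh <- .tetmesh_from_cells(cells, c(h, h, h), c(0, oy, oy))

  bc <- mesh$tet_barycenters
  shaft <- which(bc[, 1] >= 0 & bc[, 1] <= L &
                 (bc[, 2]^2 + bc[, 3]^2) <= R^2)
  mesh <- add_roi(mesh, "shaft", "tetrahedron", shaft)

  structure(list(mesh = mesh, spec = spec, spine_count = n_spines,
                 spine_anchors = anchors,
                 axis_origin = c(0, 0, 0), axis_dir = c(1, 0, 0)),
            class = "generated_mesh")
}

#' @export
print.generated_mesh <- function(x, ...) {
  cat(sprintf("<generated_mesh> %d spines, shaft %.3g m x %.3g m\n",
              x$spine_count, x$spec$shaft_length, x$spec$shaft_diameter))
  print(x$mesh)
  invisible(x)
}

#' Register the central injection-zone ROI on a dendrite mesh
#'
#' Selects tets (barycenter mode) inside a cylindrical zone centered at the
#' shaft midpoint and stores them as ROI `"injection_zone"`.
#'
#' @param gen A `generated_mesh` from [spiny_dendrite_mesh()].
#' @param zone_length Zone length along the shaft axis (default 0.7 um).
#' @param zone_diameter Zone diameter (default 0.7 um).
#' @return The modified `generated_mesh`.
#' @export
injection_zone_roi <- function(gen, zone_length = 0.7e-6,
                               zone_diameter = 0.7e-6) {
  stopifnot(inherits(gen, "generated_mesh"))
  L <- gen$spec$shaft_length
  mid <- gen$axis_origin + gen$axis_dir * L / 2
  p0 <- mid - gen$axis_dir * zone_length / 2
  p1 <- mid + gen$axis_dir * zone_length / 2
  sel <- select_tets(gen$mesh, cylinder_bound(p0, p1, zone_diameter / 2),
                     mode = "barycenter")
  if (!length(sel))
    stop("injection zone selected no tets (zone below mesh resolution)")
  gen$mesh <- add_roi(gen$mesh, "injection_zone", "tetrahedron", sel)
  gen
}

#' Nested two-compartment ball mesh with an interface patch
#'
#' Voxelizes a ball of `outer_radius`, classifies tets by barycenter radius
#' into compartments `"inner"` and `"outer"`, and labels the faces between
#' the two classes as the patch `"interface"` (inner compartment `"inner"`,
#' outer compartment `"outer"`). The geometry mirrors an organelle (for
#' example the ER) nested inside the cytosol of a spine.
#'
#' @param outer_radius,inner_radius Ball radii (metres), `inner < outer`.
#' @param voxel_size Voxel edge length; must be at most `inner_radius / 2`.
#' @param volume_system_ids Named list with optional elements `inner` and
#'   `outer`: volume-system ids to attach to the compartments.
#' @param surface_system_ids Surface-system ids for the interface patch.
#' @return A `tetmesh` with two compartments and one patch.
#' @export
nested_sphere_mesh <- function(outer_radius, inner_radius, voxel_size,
                               volume_system_ids = list(),
                               surface_system_ids = character()) {
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop("need 0 < inner_radius < outer_radius")
  if (inner_radius < 2 * voxel_size)
    stop("inner_radius below mesh resolution (need >= 2 voxel_size)")
  h <- voxel_size
  n <- 2L * ceiling(outer_radius / h)
  o <- -n * h / 2
  ctr <- o + (seq_len(n) - 0.5) * h
  grid <- expand.grid(ix = seq_len(n), iy = seq_len(n), iz = seq_len(n))
  inside <- ctr[grid$ix]^2 + ctr[grid$iy]^2 + ctr[grid$iz]^2 <=
    outer_radius^2
  cells <- cbind(grid$ix[inside] - 1L, grid$iy[inside] - 1L,
                 grid$iz[inside] - 1L)
  storage.mode(cells) <- "integer"
  mesh <- .tetmesh_from_cells(cells, c(h, h, h), c(o, o, o))

  bc <- mesh$tet_barycenters
  r2 <- bc[, 1]^2 + bc[, 2]^2 + bc[, 3]^2
  inner_ids <- which(r2 < inner_radius^2)
  outer_ids <- which(r2 >= inner_radius^2)
  mesh <- make_compartment(mesh, "inner", inner_ids,
                           volume_system_ids$inner %||% character())
  mesh <- make_compartment(mesh, "outer", outer_ids,
                           volume_system_ids$outer %||% character())
  is_inner <- logical(nrow(mesh$tets))
  is_inner[inner_ids] <- TRUE
  f <- mesh$faces[!is.na(mesh$faces$tet2), ]
  ifc <- f[xor(is_inner[f$tet1], is_inner[f$tet2]), ]
  lab <- label_tri_faces(mesh, cbind(ifc$v1, ifc$v2, ifc$v3))
  make_patch(lab$mesh, "interface", lab$tri_ids, inner = "inner",
             outer = "outer", surface_system_ids = surface_system_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
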