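# ---------------------------------------------------------------------------
# Render-point generation: the visualization-side computation. At each
# update, every dynamic visual component asks its elements for their
# molecule counts and generates exactly that many uniformly distributed
# random positions inside them (sorted-uniforms barycentric sampling; exact
# and constant-cost), unless the max-points / max-density policy caps the
# total. Rendering itself is out of scope: point clouds are plain tables,
# exportable to CSV/PLY for any viewer.
# ---------------------------------------------------------------------------

#' Uniform random points inside a tetrahedron
#'
#' Exact uniform sampling by sorted uniforms: draw `u1,u2,u3 ~ U(0,1)`,
#' sort to `s1<=s2<=s3`, and use barycentric weights
#' `(s1, s2-s1, s3-s2, 1-s3)`.
#'
#' @param tet_coords 4 x 3 matrix of vertex coordinates.
#' @param n Number of points.
#' @return An `n` x 3 matrix of positions (uses the session RNG).
#' @export
sample_in_tet <- function(tet_coords, n = 1L) {
  tet_coords <- matrix(as.numeric(tet_coords), ncol = 3L)
  if (tet_volume(tet_coords[1, ], tet_coords[2, ], tet_coords[3, ],
                 tet_coords[4, ]) <= 0)
    stop("degenerate tetrahedron in sample_in_tet")
  w <- .tet_bary_weights(n)
  w %*% tet_coords
}

# n x 4 barycentric weights, uniform over the simplex
.tet_bary_weights <- function(n) {
  u <- matrix(stats::runif(3L * n), ncol = 3L)
  s1 <- pmin(u[, 1], u[, 2], u[, 3])
  s3 <- pmax(u[, 1], u[, 2], u[, 3])
  s2 <- u[, 1] + u[, 2] + u[, 3] - s1 - s3
  cbind(s1, s2 - s1, s3 - s2, 1 - s3)
}

#' Uniform random points inside a triangle
#'
#' Barycentric construction `v1 = 1 - sqrt(u1)`, `v2 = u2 * sqrt(u1)`:
#' exact uniform sampling in the triangle plane.
#'
#' @param tri_coords 3 x 3 matrix of vertex coordinates.
#' @param n Number of points.
#' @return An `n` x 3 matrix of positions.
#' @export
sample_in_tri <- function(tri_coords, n = 1L) {
  tri_coords <- matrix(as.numeric(tri_coords), ncol = 3L)
  if (.tri_areas(tri_coords, matrix(1:3, 1)) <= 0)
    stop("degenerate triangle in sample_in_tri")
  w <- .tri_bary_weights(n)
  w %*% tri_coords
}

.tri_bary_weights <- function(n) {
  r1 <- sqrt(stats::runif(n))
  u2 <- stats::runif(n)
  v1 <- 1 - r1
  v2 <- u2 * r1
  cbind(v1, v2, 1 - v1 - v2)
}

# sample counts[k] points in element k (tets or tris); returns positions +
# element ids
.sample_elements <- function(mesh, elems, counts, kind) {
  total <- sum(counts)
  if (total == 0)
    return(list(pos = matrix(numeric(0), ncol = 3L), elem = integer(0)))
  idx <- rep(seq_along(elems), counts)
  if (kind == "tet") {
    w <- .tet_bary_weights(total)
    conn <- mesh$tets[elems[idx], , drop = FALSE]
    pos <- w[, 1] * mesh$vertices[conn[, 1], , drop = FALSE] +
           w[, 2] * mesh$vertices[conn[, 2], , drop = FALSE] +
           w[, 3] * mesh$vertices[conn[, 3], , drop = FALSE] +
           w[, 4] * mesh$vertices[conn[, 4], , drop = FALSE]
  } else {
    w <- .tri_bary_weights(total)
    conn <- mesh$tris[elems[idx], , drop = FALSE]
    pos <- w[, 1] * mesh$vertices[conn[, 1], , drop = FALSE] +
           w[, 2] * mesh$vertices[conn[, 2], , drop = FALSE] +
           w[, 3] * mesh$vertices[conn[, 3], , drop = FALSE]
  }
  list(pos = pos, elem = elems[idx])
}

#' Render policy: point-count and point-density caps
#'
#' `max_points` bounds the number of points a component may generate per
#' update; `max_density` bounds points per m^3 (tets) or m^2 (tris) in each
#' element, the per-element cap being `floor(max_density * measure)`. With
#' `auto_adjust`, the density is rescaled once per update by the ratio of
#' `max_points` to the uncapped total before the per-element caps apply.
#'
#' @param max_points Maximum points per component (>= 1).
#' @param max_density Maximum point density (points/m^3 or points/m^2), or
#'   `NULL`.
#' @param auto_adjust Rescale the density automatically when the total
#'   exceeds `max_points`.
#' @return A `render_policy`.
#' @export
render_policy <- function(max_points = Inf, max_density = NULL,
                          auto_adjust = FALSE) {
  if (max_points < 1) stop("max_points must be >= 1")
  if (!is.null(max_density) && max_density <= 0)
    stop("max_density must be positive")
  structure(list(max_points = max_points, max_density = max_density,
                 auto_adjust = auto_adjust), class = "render_policy")
}

#' Dynamic visual component
#'
#' Binds a species (or channel-state set) to a set of mesh elements — a
#' compartment, patch, ROI or explicit element list — with a render policy
#' and opaque appearance metadata. Static kinds (`compartment_mesh`,
#' `patch_mesh`) carry only geometry.
#'
#' @param id Component id.
#' @param kind One of `compartment_mesh`, `patch_mesh`,
#'   `compartment_species`, `patch_species`, `tet_species`, `tri_species`,
#'   `patch_channel`, `tri_channel`.
#' @param target Compartment/patch/ROI name, or integer element ids.
#' @param species Species id (dynamic kinds) or character vector of channel
#'   state ids (channel kinds).
#' @param policy A [render_policy()].
#' @param appearance Opaque list (color, size, ...) carried through.
#' @return A `visual_component`.
#' @export
visual_component <- function(id, kind, target, species = NULL,
                             policy = render_policy(),
                             appearance = list()) {
  kind <- match.arg(kind, c("compartment_mesh", "patch_mesh",
                            "compartment_species", "patch_species",
                            "tet_species", "tri_species",
                            "patch_channel", "tri_channel"))
  dynamic <- !kind %in% c("compartment_mesh", "patch_mesh")
  if (dynamic && is.null(species))
    stop("dynamic component '", id, "' needs a species or state set")
  structure(list(id = id, kind = kind, target = target, species = species,
                 policy = policy, appearance = appearance,
                 dynamic = dynamic),
            class = "visual_component")
}

# resolve a component's elements on a state: list(kind, elems)
.component_elements <- function(component, state) {
  mesh <- state$mesh
  tgt <- component$target
  switch(component$kind,
    compartment_mesh = ,
    compartment_species = list(
      kind = "tet", elems = mesh$compartments[[tgt]]$tet_indices),
    patch_mesh = ,
    patch_channel = ,
    patch_species = list(kind = "tri",
                         elems = mesh$patches[[tgt]]$tri_indices),
    tet_species = if (is.character(tgt))
      list(kind = "tet", elems = get_roi(mesh, tgt)$indices)
      else list(kind = "tet", elems = as.integer(tgt)),
    tri_species = ,
    tri_channel = if (is.character(tgt))
      list(kind = "tri", elems = get_roi(mesh, tgt)$indices)
      else list(kind = "tri", elems = as.integer(tgt)))
}

#' Generate the render-point cloud of a dynamic component
#'
#' Reads the component's per-element molecule counts from the simulation
#' state and generates the exact number of uniform random positions, unless
#' the render policy caps them: per-element points are
#' `min(count, floor(density * measure))` once a cap binds.
#'
#' @param component A dynamic [visual_component()].
#' @param state A `sim_state`.
#' @return A `point_cloud`: data.frame with `x,y,z`, `element`, `species`,
#'   `t`.
#' @export
generate_points <- function(component, state) {
  if (!component$dynamic) stop("component '", component$id, "' is static")
  el <- .component_elements(component, state)
  sp <- component$species[1]
  counts <- element_counts(state,
                           list(kind = el$kind, elems = el$elems), sp)
  measure <- if (el$kind == "tet") state$mesh$tet_volumes[el$elems]
             else state$mesh$tri_areas[el$elems]
  npts <- .capped_counts(counts, measure, component$policy)
  smp <- .sample_elements(state$mesh, el$elems, npts, el$kind)
  n <- length(smp$elem)
  structure(data.frame(x = smp$pos[, 1], y = smp$pos[, 2], z = smp$pos[, 3],
                       element = smp$elem,
                       species = rep(sp, n),
                       t = rep(sim_time(state), n)),
            class = c("point_cloud", "data.frame"))
}

.capped_counts <- function(counts, measure, policy) {
  total <- sum(counts)
  if (total == 0) return(integer(length(counts)))
  dens <- policy$max_density
  over <- total > policy$max_points
  if (over && is.null(dens) && !policy$auto_adjust)
    stop("point total ", total, " exceeds max_points with no density cap ",
         "and auto_adjust disabled")
  if (policy$auto_adjust && over) {
    base <- if (is.null(dens)) total / sum(measure) else dens
    dens <- base * policy$max_points / total
  }
  if (is.null(dens)) return(as.integer(counts))
  pmin(as.integer(counts), as.integer(floor(dens * measure)))
}

# ---- persistent channel positions -----------------------------------------

#' Persistent positions for multi-state channel components
#'
#' Channel copies on a patch get a fixed uniform position in their triangle
#' at initialization; subsequent state transitions change only the state
#' label, and a position is re-drawn only when a copy moves to another
#' triangle (surface diffusion). `channel_tracker()` initializes from the
#' current state; `update_channel_positions()` reconciles the stored
#' positions with a later state.
#'
#' @param component A `patch_channel`/`tri_channel` [visual_component()]
#'   whose `species` is the vector of state ids.
#' @param state A `sim_state`.
#' @return A `channel_tracker` environment with element `points`
#'   (data.frame `x,y,z,element,state`).
#' @export
channel_tracker <- function(component, state) {
  if (!component$kind %in% c("patch_channel", "tri_channel"))
    stop("channel tracker needs a patch_channel/tri_channel component")
  el <- .component_elements(component, state)
  pts <- .channel_points_for(state, el$elems, component$species)
  tr <- new.env(parent = emptyenv())
  tr$component <- component
  tr$points <- pts
  class(tr) <- "channel_tracker"
  tr
}

.channel_points_for <- function(state, tris, states) {
  out <- list()
  for (st in states) {
    counts <- element_counts(state, list(kind = "tri", elems = tris), st)
    smp <- .sample_elements(state$mesh, tris, counts, "tri")
    if (length(smp$elem))
      out[[st]] <- data.frame(x = smp$pos[, 1], y = smp$pos[, 2],
                              z = smp$pos[, 3], element = smp$elem,
                              state = st)
  }
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      element = integer(0), state = character(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @rdname channel_tracker
#' @param tracker A `channel_tracker`.
#' @return The tracker, invisibly (its `points` reconciled with `state`).
#' @export
update_channel_positions <- function(tracker, state) {
  comp <- tracker$component
  el <- .component_elements(comp, state)
  tris <- el$elems
  states <- comp$species
  # current per-(tri,state) counts and stored points
  want_tot <- rowSums(matrix(vapply(states, function(st)
    element_counts(state, list(kind = "tri", elems = tris), st),
    numeric(length(tris))), nrow = length(tris)))
  pts <- tracker$points
  have_tot <- tabulate(match(pts$element, tris), nbins = length(tris))
  if (sum(want_tot) != nrow(pts))
    stop("channel copy number changed outside state transitions")
  # move surplus copies to deficit triangles (surface-diffusion hops):
  # each moved copy is re-sampled uniformly in its destination triangle
  deficit <- want_tot - have_tot
  if (any(deficit != 0)) {
    drop_rows <- integer(0)
    for (k in which(deficit < 0)) {
      rows <- which(pts$element == tris[k])
      drop_rows <- c(drop_rows, utils::tail(rows, -deficit[k]))
    }
    pts <- pts[setdiff(seq_len(nrow(pts)), drop_rows), , drop = FALSE]
    add_counts <- pmax(deficit, 0)
    smp <- .sample_elements(state$mesh, tris, add_counts, "tri")
    if (length(smp$elem))
      pts <- rbind(pts, data.frame(x = smp$pos[, 1], y = smp$pos[, 2],
                                   z = smp$pos[, 3], element = smp$elem,
                                   state = NA_character_))
  }
  # reassign state labels per triangle to match the simulation counts;
  # positions are untouched
  for (k in seq_along(tris)) {
    rows <- which(pts$element == tris[k])
    if (!length(rows)) next
    labs <- unlist(lapply(states, function(st) {
      n <- element_counts(state, list(kind = "tri", elems = tris[k]), st)
      rep(st, n)
    }))
    pts$state[rows] <- labs
  }
  rownames(pts) <- NULL
  tracker$points <- pts
  invisible(tracker)
}

# ---- displays -------------------------------------------------------------

#' Visual scene: components shared across displays
#'
#' A scene holds visual components once and lets any number of displays
#' reference them (many-to-many association). A snapshot generates each
#' referenced dynamic component's point cloud exactly once and every
#' display that contains the component references that single instance.
#'
#' @return A `visual_scene` environment.
#' @export
visual_scene <- function() {
  sc <- new.env(parent = emptyenv())
  sc$components <- list()
  sc$displays <- list()
  class(sc) <- "visual_scene"
  sc
}

#' @rdname visual_scene
#' @param scene A `visual_scene`.
#' @param component A [visual_component()].
#' @export
add_component <- function(scene, component) {
  scene$components[[component$id]] <- component
  invisible(scene)
}

#' Assemble components into a display
#' @param scene A `visual_scene`.
#' @param display_id Display id.
#' @param component_ids Ids of components to show (must be registered).
#' @return The scene, invisibly.
#' @export
assemble_display <- function(scene, display_id, component_ids) {
  unknown <- setdiff(component_ids, names(scene$components))
  if (length(unknown))
    stop("unknown component id(s): ", paste(unknown, collapse = ", "))
  scene$displays[[display_id]] <- component_ids
  invisible(scene)
}

#' Snapshot all displays of a scene
#'
#' Generates point clouds for every dynamic component referenced by at
#' least one display (once per component) and returns, per display, the
#' list of clouds plus the static components' geometry references.
#'
#' @param scene A `visual_scene`.
#' @param state A `sim_state`.
#' @return List with `clouds` (per component id) and `displays` (per
#'   display id: list of component ids with their shared cloud).
#' @export
snapshot <- function(scene, state) {
  used <- unique(unlist(scene$displays))
  clouds <- list()
  for (cid in used) {
    comp <- scene$components[[cid]]
    if (comp$dynamic) clouds[[cid]] <- generate_points(comp, state)
  }
  displays <- lapply(scene$displays, function(cids) {
    lapply(stats::setNames(cids, cids), function(cid) {
      comp <- scene$components[[cid]]
      if (comp$dynamic) clouds[[cid]] else comp
    })
  })
  list(clouds = clouds, displays = displays)
}

# ---- export ---------------------------------------------------------------

#' Export a point cloud
#'
#' CSV (`x,y,z,element,species,t`) or ASCII PLY for external viewers.
#'
#' @param cloud A `point_cloud`.
#' @param path Output path.
#' @param format `"csv"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
export_point_cloud <- function(cloud, path, format = c("csv", "ply")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(cloud, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(cloud)),
                 "property float x", "property float y", "property float z",
                 "end_header"), con)
    writeLines(sprintf("%g %g %g", cloud$x, cloud$y, cloud$z), con)
  }
  invisible(path)
}
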