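# ---------------------------------------------------------------------------
# Bounding-object element selection.
#
# Elements are picked by testing representative points (barycenter, all
# vertices, or any vertex) against a convex bounding primitive with an
# inclusive containment predicate. Composite regions are built from the
# returned id lists with ordinary set operations.
# ---------------------------------------------------------------------------

#' Axis-aligned box bounding primitive
#' @param min_corner,max_corner Numeric length-3 corners (metres),
#'   `min_corner < max_corner` componentwise.
#' @return A `bounding_primitive`.
#' @export
axis_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner); max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L ||
      !all(min_corner < max_corner))
    stop("axis_box needs min_corner < max_corner componentwise")
  structure(list(kind = "axis_box", min = min_corner, max = max_corner),
            class = "bounding_primitive")
}

#' Spherical bounding primitive
#' @param center Numeric length-3 center (metres).
#' @param radius Positive radius (metres).
#' @return A `bounding_primitive`.
#' @export
sphere_bound <- function(center, radius) {
  if (length(center) != 3L || !is.finite(radius) || radius <= 0)
    stop("sphere needs a 3D center and radius > 0")
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "bounding_primitive")
}

#' Finite cylinder bounding primitive
#' @param p0,p1 Numeric length-3 axis endpoints (distinct, metres).
#' @param radius Positive radius (metres).
#' @return A `bounding_primitive`.
#' @export
cylinder_bound <- function(p0, p1, radius) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L || all(p0 == p1) ||
      !is.finite(radius) || radius <= 0)
    stop("cylinder needs two distinct endpoints and radius > 0")
  structure(list(kind = "cylinder", p0 = p0, p1 = p1,
                 radius = as.numeric(radius)),
            class = "bounding_primitive")
}

# characteristic length used to scale the inclusive-containment tolerance
.primitive_scale <- function(bound) {
  switch(bound$kind,
         axis_box = max(bound$max - bound$min),
         sphere = bound$radius,
         cylinder = max(sqrt(sum((bound$p1 - bound$p0)^2)), bound$radius))
}

#' Test points against a bounding primitive
#'
#' Inclusive containment with tolerance `1e-12` times the primitive's
#' characteristic length, so points exactly on analytic surfaces select
#' deterministically.
#'
#' @param bound A `bounding_primitive`.
#' @param points Numeric matrix, one point per row (3 columns).
#' @return Logical vector, one entry per point.
#' @export
contains_points <- function(bound, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  tol <- 1e-12 * .primitive_scale(bound)
  switch(bound$kind,
    axis_box = {
      points[, 1] >= bound$min[1] - tol & points[, 1] <= bound$max[1] + tol &
      points[, 2] >= bound$min[2] - tol & points[, 2] <= bound$max[2] + tol &
      points[, 3] >= bound$min[3] - tol & points[, 3] <= bound$max[3] + tol
    },
    sphere = {
      dx <- points[, 1] - bound$center[1]
      dy <- points[, 2] - bound$center[2]
      dz <- points[, 3] - bound$center[3]
      sqrt(dx^2 + dy^2 + dz^2) <= bound$radius + tol
    },
    cylinder = {
      ax <- bound$p1 - bound$p0
      len2 <- sum(ax^2)
      dx <- points[, 1] - bound$p0[1]
      dy <- points[, 2] - bound$p0[2]
      dz <- points[, 3] - bound$p0[3]
      s <- (dx * ax[1] + dy * ax[2] + dz * ax[3]) / len2   # axial fraction
      rx <- dx - s * ax[1]; ry <- dy - s * ax[2]; rz <- dz - s * ax[3]
      len <- sqrt(len2)
      s * len >= -tol & s * len <= len + tol &
        sqrt(rx^2 + ry^2 + rz^2) <= bound$radius + tol
    })
}

.select_elements <- function(mesh, bound, mode, conn, barycenters) {
  mode <- match.arg(mode, c("barycenter", "all_vertices", "any_vertex"))
  if (!nrow(conn)) return(integer(0))
  if (mode == "barycenter") {
    hit <- contains_points(bound, barycenters)
  } else {
    nvert <- ncol(conn)
    inside <- matrix(FALSE, nrow = nrow(conn), ncol = nvert)
    for (k in seq_len(nvert))
      inside[, k] <- contains_points(bound,
                                     mesh$vertices[conn[, k], , drop = FALSE])
    hit <- if (mode == "all_vertices") rowSums(inside) == nvert
           else rowSums(inside) > 0L
  }
  sort(which(hit))
}

#' Select tetrahedra overlapping a bounding object
#'
#' Indirect bounding-object selection: a convex primitive is placed over the
#' mesh and every tetrahedron whose test points (per `mode`) fall inside it
#' is returned. `"barycenter"` (default) tests the element barycenter,
#' `"all_vertices"` requires every vertex inside, `"any_vertex"` accepts any
#' vertex inside.
#'
#' @param mesh A `tetmesh`.
#' @param bound A `bounding_primitive`.
#' @param mode Selection mode.
#' @return Sorted internal tet ids.
#' @export
select_tets <- function(mesh, bound, mode = "barycenter") {
  .select_elements(mesh, bound, mode, mesh$tets, mesh$tet_barycenters)
}

#' Select labeled triangles overlapping a bounding object
#' @inheritParams select_tets
#' @return Sorted internal triangle ids.
#' @export
select_tris <- function(mesh, bound, mode = "barycenter") {
  .select_elements(mesh, bound, mode, mesh$tris, mesh$tri_barycenters)
}

# vertex triples (rows) of all faces incident to exactly one tet
.skin_face_matrix <- function(mesh) {
  f <- mesh$faces[is.na(mesh$faces$tet2), ]
  cbind(f$v1, f$v2, f$v3)
}

#' Skin triangles of a mesh
#'
#' Skin elements are the faces directly visible from the outside, i.e. faces
#' incident to exactly one tetrahedron. Faces not yet present in the labeled
#' triangle set are labeled on demand.
#'
#' @param mesh A `tetmesh`.
#' @return List with `mesh` (skin faces labeled) and `tri_ids` (internal ids
#'   of the skin triangles).
#' @export
skin_triangles <- function(mesh) {
  lab <- label_tri_faces(mesh, .skin_face_matrix(mesh))
  list(mesh = lab$mesh, tri_ids = sort(lab$tri_ids))
}

# internal tet ids owning at least one skin face
.skin_tets <- function(mesh) {
  unique(mesh$faces$tet1[is.na(mesh$faces$tet2)])
}

#' Inner tetrahedra inside a bounding object
#'
#' Tets fully inside the bound (`all_vertices` mode) that do not own any
#' skin face, i.e. the selection excludes everything visible from outside.
#'
#' @param mesh A `tetmesh`.
#' @param bound A `bounding_primitive`.
#' @return Sorted internal tet ids.
#' @export
inner_tets <- function(mesh, bound) {
  sel <- select_tets(mesh, bound, mode = "all_vertices")
  sort(setdiff(sel, .skin_tets(mesh)))
}

#' Point-in-tetrahedron test
#'
#' True iff every barycentric coordinate of `p` with respect to the tet is
#' `>= -tol` (inclusive boundary).
#'
#' @param p Numeric length-3 point.
#' @param tet_coords 4 x 3 matrix of tet vertex coordinates.
#' @param tol Barycentric tolerance (default `1e-12`).
#' @return Logical scalar.
#' @export
point_in_tet <- function(p, tet_coords, tol = 1e-12) {
  tet_coords <- matrix(as.numeric(tet_coords), ncol = 3L)
  m <- t(tet_coords[2:4, ] - matrix(tet_coords[1, ], 3, 3, byrow = TRUE))
  if (abs(det(m)) < .Machine$double.xmin)
    stop("degenerate tetrahedron in point_in_tet")
  b <- solve(m, as.numeric(p) - tet_coords[1, ])
  all(c(1 - sum(b), b) >= -tol)
}
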