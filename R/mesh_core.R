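#' @useDynLib tetrasim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

# data.table non-standard evaluation symbols
utils::globalVariables(c("gid", "tet", "lface", "v1", "v2", "v3", "ord",
                         "tri", ".N", ".GRP"))

# ---------------------------------------------------------------------------
# Tetrahedral mesh core: construction, derived geometry, dual indexing,
# compartments / patches / ROI datasets.
# All coordinates are metres; volumes m^3; areas m^2.
# Internal element indices are 1-based and contiguous; indices from source
# mesh files are reachable only through the per-class IndexMap.
# ---------------------------------------------------------------------------

#' Volume of a tetrahedron
#'
#' Unsigned volume `|det(c1-c0, c2-c0, c3-c0)| / 6`. Returns 0 for coplanar
#' input; callers decide whether that is an error.
#'
#' @param c0,c1,c2,c3 Numeric length-3 vertex coordinates (metres).
#' @return Volume in m^3.
#' @export
tet_volume <- function(c0, c1, c2, c3) {
  m <- cbind(c1 - c0, c2 - c0, c3 - c0)
  abs(det(m)) / 6
}

# Signed volumes for all tets at once; verts n x 3, tets T x 4.
.signed_volumes <- function(verts, tets) {
  a <- verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 2], , drop = FALSE] - a
  c <- verts[tets[, 3], , drop = FALSE] - a
  d <- verts[tets[, 4], , drop = FALSE] - a
  # det of rows (b, c, d) via triple product b . (c x d)
  cx <- c[, 2] * d[, 3] - c[, 3] * d[, 2]
  cy <- c[, 3] * d[, 1] - c[, 1] * d[, 3]
  cz <- c[, 1] * d[, 2] - c[, 2] * d[, 1]
  (b[, 1] * cx + b[, 2] * cy + b[, 3] * cz) / 6
}

.tri_areas <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 2], , drop = FALSE] - a
  c <- verts[tris[, 3], , drop = FALSE] - a
  nx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  ny <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  nz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

.barycenters <- function(verts, conn) {
  n <- ncol(conn)
  out <- verts[conn[, 1], , drop = FALSE]
  for (k in 2:n) out <- out + verts[conn[, k], , drop = FALSE]
  out / n
}

# Vectorized ascending sort of each row of a 4-column integer matrix.
.rowsort4 <- function(m) {
  a <- m[, 1]; b <- m[, 2]; c3 <- m[, 3]; d <- m[, 4]
  lo <- pmin(a, b); hi <- pmax(a, b); a <- lo; b <- hi
  lo <- pmin(c3, d); hi <- pmax(c3, d); c3 <- lo; d <- hi
  lo <- pmin(a, c3); hi <- pmax(a, c3); a <- lo; c3 <- hi
  lo <- pmin(b, d); hi <- pmax(b, d); b <- lo; d <- hi
  lo <- pmin(b, c3); hi <- pmax(b, c3); b <- lo; c3 <- hi
  cbind(a, b, c3, d, deparse.level = 0)
}

# Local face k of a tet is the face opposite vertex k.
.LOCAL_FACES <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))

# All 4T faces as a data.table with sorted vertex triples, tet id, local face.
.face_table <- function(tets) {
  nt <- nrow(tets)
  f <- matrix(0L, nrow = 4L * nt, ncol = 3L)
  for (k in 1:4) {
    idx <- seq_len(nt) + (k - 1L) * nt
    f[idx, ] <- tets[, .LOCAL_FACES[k, ], drop = FALSE]
  }
  # sort each row (3 columns: sorting network)
  a <- pmin(f[, 1], f[, 2]); b <- pmax(f[, 1], f[, 2])
  c3 <- f[, 3]
  v1 <- pmin(a, c3); c3 <- pmax(a, c3)
  v2 <- pmin(b, c3); v3 <- pmax(b, c3)
  data.table(
    v1 = v1, v2 = v2, v3 = v3,
    tet = rep(seq_len(nt), times = 4L),
    lface = rep(1:4, each = nt)
  )
}

#' Build a tetrahedral mesh with derived geometry
#'
#' Constructs a `tetmesh` object from raw vertex coordinates and tetrahedron
#' connectivity. Tetrahedra are re-oriented to positive signed volume,
#' per-element volumes/areas/barycenters are computed, and the face-adjacency
#' map is built from shared faces. Degenerate tetrahedra (volume below
#' `1e-18` times the cube of the bounding-box diagonal) are rejected.
#'
#' @param vertices Numeric matrix, one row per vertex, 3 columns (metres).
#' @param tets Integer matrix, one row per tetrahedron, 4 vertex indices.
#' @param tris Optional integer matrix of labeled triangles (3 columns).
#' @param source_ids Optional list with elements `vertex`, `tetrahedron`,
#'   `triangle` giving source-file ids in internal order; defaults to
#'   1..n for each class.
#' @return A `tetmesh` object.
#' @export
build_tetmesh <- function(vertices, tets, tris = NULL, source_ids = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (nrow(vertices) < 4L || ncol(vertices) != 3L)
    stop("need at least 4 vertices with 3 coordinates each")
  if (ncol(tets) != 4L || nrow(tets) < 1L)
    stop("tets must be a matrix with 4 vertex indices per row")
  nv <- nrow(vertices)
  if (any(tets < 1L) || any(tets > nv))
    stop("tet connectivity references out-of-range vertex id")
  srt <- .rowsort4(tets)
  if (any(srt[, 1] == srt[, 2] | srt[, 2] == srt[, 3] | srt[, 3] == srt[, 4]))
    stop("tet with repeated vertex id")
  if (anyDuplicated(as.data.frame(srt)) > 0L)
    stop("duplicated tetrahedron (same vertex set appears twice)")

  sv <- .signed_volumes(vertices, tets)
  flip <- which(sv < 0)
  if (length(flip)) {  # swap vertices 3,4 to make volume positive
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    sv[flip] <- -sv[flip]
  }
  bbox <- apply(vertices, 2L, range)
  diag3 <- sqrt(sum((bbox[2L, ] - bbox[1L, ])^2))^3
  if (any(sv <= 1e-18 * diag3))
    stop("degenerate tetrahedron (volume below tolerance): index ",
         which(sv <= 1e-18 * diag3)[1L])

  ft <- .face_table(tets)
  data.table::setkeyv(ft, c("v1", "v2", "v3"))
  grp <- ft[, .N, by = c("v1", "v2", "v3")]
  if (any(grp$N > 2L))
    stop("non-manifold mesh: a face is shared by more than 2 tets")
  # neighbor assignment: within each 2-face group, pair the rows
  ft[, gid := .GRP, by = c("v1", "v2", "v3")]
  data.table::setorder(ft, gid)
  nfg <- ft[, .N, by = gid]$N
  two <- which(rep(nfg, nfg) == 2L)
  nt <- nrow(tets)
  neigh <- matrix(NA_integer_, nrow = nt, ncol = 4L)
  nface <- matrix(NA_integer_, nrow = nt, ncol = 4L)
  if (length(two)) {
    first <- two[seq(1L, length(two), by = 2L)]
    second <- two[seq(2L, length(two), by = 2L)]
    t1 <- ft$tet[first]; f1 <- ft$lface[first]
    t2 <- ft$tet[second]; f2 <- ft$lface[second]
    neigh[cbind(t1, f1)] <- t2
    nface[cbind(t1, f1)] <- f2
    neigh[cbind(t2, f2)] <- t1
    nface[cbind(t2, f2)] <- f1
  }
  faces <- ft[, list(tet1 = tet[1L], lface1 = lface[1L],
                     tet2 = if (.N == 2L) tet[2L] else NA_integer_,
                     lface2 = if (.N == 2L) lface[2L] else NA_integer_),
              by = c("v1", "v2", "v3")]

  if (!is.null(tris)) {
    tris <- as.matrix(tris)
    storage.mode(tris) <- "integer"
    if (nrow(tris) && (any(tris < 1L) || any(tris > nv)))
      stop("tri connectivity references out-of-range vertex id")
  } else {
    tris <- matrix(integer(0), ncol = 3L)
  }

  mk_map <- function(cls, n, src) {
    if (is.null(src)) src <- seq_len(n)
    if (length(src) != n) stop("source id vector length mismatch for ", cls)
    index_map(cls, src)
  }
  maps <- list(
    vertex = mk_map("vertex", nv, source_ids$vertex),
    tetrahedron = mk_map("tetrahedron", nt, source_ids$tetrahedron),
    triangle = mk_map("triangle", nrow(tris), source_ids$triangle)
  )

  mesh <- structure(list(
    vertices = vertices,
    tets = tets,
    tris = tris,
    tet_volumes = sv,
    tri_areas = if (nrow(tris)) .tri_areas(vertices, tris) else numeric(0),
    tet_barycenters = .barycenters(vertices, tets),
    tri_barycenters = if (nrow(tris)) .barycenters(vertices, tris)
                      else matrix(numeric(0), ncol = 3L),
    tet_neighbors = neigh,
    face_of_neighbor = nface,
    faces = faces,
    compartments = list(),
    patches = list(),
    rois = list(),
    index_maps = maps
  ), class = "tetmesh")
  mesh
}

#' @export
print.tetmesh <- function(x, ...) {
  cat(sprintf(
    "<tetmesh> %d vertices, %d tets, %d labeled tris\n  total volume %.6g m^3\n",
    nrow(x$vertices), nrow(x$tets), nrow(x$tris), sum(x$tet_volumes)))
  if (length(x$compartments))
    cat("  compartments:", paste(names(x$compartments), collapse = ", "), "\n")
  if (length(x$patches))
    cat("  patches:", paste(names(x$patches), collapse = ", "), "\n")
  if (length(x$rois))
    cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# IndexMap: bijection between source-file element ids and internal ids
# ---------------------------------------------------------------------------

#' Create an index map between source and internal element ids
#'
#' Internal ids are contiguous `1..n` in insertion order; `source` gives the
#' matching source-file id for each internal id.
#'
#' @param element_class One of `"vertex"`, `"triangle"`, `"tetrahedron"`.
#' @param source Integer vector of source ids, one per internal element.
#' @return An `index_map` object.
#' @export
index_map <- function(element_class, source) {
  element_class <- match.arg(element_class,
                             c("vertex", "triangle", "tetrahedron"))
  source <- as.integer(source)
  if (anyDuplicated(source)) stop("duplicate source ids in index map")
  structure(list(element_class = element_class, source = source),
            class = "index_map")
}

#' Translate source ids to internal ids
#' @param map An `index_map`.
#' @param source_id Integer vector of source-file ids.
#' @return Internal ids (1-based).
#' @export
to_internal <- function(map, source_id) {
  i <- match(as.integer(source_id), map$source)
  if (anyNA(i))
    stop("unknown source ", map$element_class, " id: ",
         paste(source_id[is.na(i)], collapse = ", "))
  i
}

#' Translate internal ids back to source ids
#' @param map An `index_map`.
#' @param internal_id Internal ids (1-based).
#' @return Source-file ids.
#' @export
to_source <- function(map, internal_id) {
  internal_id <- as.integer(internal_id)
  if (any(internal_id < 1L) || any(internal_id > length(map$source)))
    stop("unknown internal ", map$element_class, " id: ",
         paste(internal_id[internal_id < 1L | internal_id > length(map$source)],
               collapse = ", "))
  map$source[internal_id]
}

# ---------------------------------------------------------------------------
# ROI datasets
# ---------------------------------------------------------------------------

.n_elements <- function(mesh, element_class) {
  switch(element_class,
         vertex = nrow(mesh$vertices),
         triangle = nrow(mesh$tris),
         tetrahedron = nrow(mesh$tets),
         stop("unknown element class: ", element_class))
}

#' Store a named Region of Interest on a mesh
#'
#' ROIs are named, ordered lists of internal element ids reused for
#' injection, recording, or display filtering.
#'
#' @param mesh A `tetmesh`.
#' @param name Unique ROI name.
#' @param element_class `"vertex"`, `"triangle"`, or `"tetrahedron"`.
#' @param indices Internal element ids (order preserved).
#' @return The modified mesh (assign it back).
#' @export
add_roi <- function(mesh, name, element_class, indices) {
  element_class <- match.arg(element_class,
                             c("vertex", "triangle", "tetrahedron"))
  if (name %in% names(mesh$rois)) stop("ROI name already used: ", name)
  indices <- as.integer(indices)
  n <- .n_elements(mesh, element_class)
  if (length(indices) && (any(indices < 1L) || any(indices > n)))
    stop("ROI '", name, "' has out-of-range ", element_class, " index")
  mesh$rois[[name]] <- list(name = name, element_class = element_class,
                            indices = indices)
  mesh
}

#' Retrieve a stored ROI by name
#' @param mesh A `tetmesh`.
#' @param name ROI name.
#' @return The ROI record (`name`, `element_class`, `indices`).
#' @export
get_roi <- function(mesh, name) {
  if (!name %in% names(mesh$rois)) stop("no ROI named '", name, "'")
  mesh$rois[[name]]
}

# ---------------------------------------------------------------------------
# Compartments and patches
# ---------------------------------------------------------------------------

#' Create a compartment (3D region) on a mesh
#'
#' A compartment is a named set of tetrahedra inside which volume reactions
#' and diffusion apply. Volume-system ids from the biochemical model are
#' attached here and resolved when the solver is built. Tet sets of distinct
#' compartments must be disjoint.
#'
#' @param mesh A `tetmesh`.
#' @param name Compartment name.
#' @param tet_indices Internal tet ids.
#' @param volume_system_ids Character vector of volume-system ids.
#' @return The modified mesh.
#' @export
make_compartment <- function(mesh, name, tet_indices,
                             volume_system_ids = character()) {
  if (name %in% names(mesh$compartments))
    stop("compartment name already used: ", name)
  tet_indices <- sort(unique(as.integer(tet_indices)))
  nt <- nrow(mesh$tets)
  if (!length(tet_indices)) stop("compartment must contain at least one tet")
  if (any(tet_indices < 1L) || any(tet_indices > nt))
    stop("compartment '", name, "' has out-of-range tet index")
  owned <- unlist(lapply(mesh$compartments, `[[`, "tet_indices"))
  if (any(tet_indices %in% owned))
    stop("tet already owned by another compartment")
  mesh$compartments[[name]] <- list(
    name = name, tet_indices = tet_indices,
    volume = sum(mesh$tet_volumes[tet_indices]),
    volume_system_ids = as.character(volume_system_ids))
  mesh
}

# Incident tets of labeled triangles: rows = tris, cols tet1/tet2 (NA if skin)
.tri_incident_tets <- function(mesh, tri_indices) {
  tv <- mesh$tris[tri_indices, , drop = FALSE]
  a <- pmin(tv[, 1], tv[, 2]); b <- pmax(tv[, 1], tv[, 2])
  c3 <- tv[, 3]
  hi <- pmax(a, c3)
  dt <- data.table(v1 = pmin(a, c3), v2 = pmin(b, hi), v3 = pmax(b, hi),
                   ord = seq_len(nrow(tv)))
  res <- mesh$faces[dt, on = c("v1", "v2", "v3")]
  data.table::setorder(res, ord)
  if (anyNA(res$tet1))
    stop("labeled triangle is not a face of any tetrahedron")
  cbind(res$tet1, res$tet2)
}

#' Create a patch (2D membrane) on a mesh
#'
#' A patch is a named set of labeled triangles forming a surface attached to
#' one (inner) or two (inner + outer) compartments; surface-system ids are
#' attached for later solver construction. Every member triangle must be a
#' face of a tet of the inner compartment, and (when an outer compartment is
#' given) its second incident tet must belong to the outer compartment.
#' Triangles whose two incident tets lie in the same compartment are
#' rejected.
#'
#' @param mesh A `tetmesh`.
#' @param name Patch name.
#' @param tri_indices Internal ids of labeled triangles.
#' @param inner Name of the inner compartment.
#' @param outer Name of the outer compartment, or `NULL` for a boundary patch.
#' @param surface_system_ids Character vector of surface-system ids.
#' @return The modified mesh.
#' @export
make_patch <- function(mesh, name, tri_indices, inner, outer = NULL,
                       surface_system_ids = character()) {
  if (name %in% names(mesh$patches)) stop("patch name already used: ", name)
  if (!inner %in% names(mesh$compartments))
    stop("unknown inner compartment: ", inner)
  if (!is.null(outer) && !outer %in% names(mesh$compartments))
    stop("unknown outer compartment: ", outer)
  tri_indices <- as.integer(tri_indices)
  if (!length(tri_indices)) stop("patch must contain at least one triangle")
  if (any(tri_indices < 1L) || any(tri_indices > nrow(mesh$tris)))
    stop("patch '", name, "' has out-of-range triangle index")
  inc <- .tri_incident_tets(mesh, tri_indices)
  in_tets <- mesh$compartments[[inner]]$tet_indices
  t1_in <- inc[, 1] %in% in_tets
  t2_in <- !is.na(inc[, 2]) & inc[, 2] %in% in_tets
  if (any(t1_in & t2_in))
    stop("patch triangle has both incident tets in the inner compartment")
  if (any(!t1_in & !t2_in))
    stop("patch triangle not adjacent to inner compartment '", inner, "'")
  inner_tet <- ifelse(t1_in, inc[, 1], inc[, 2])
  other_tet <- ifelse(t1_in, inc[, 2], inc[, 1])
  if (!is.null(outer)) {
    out_tets <- mesh$compartments[[outer]]$tet_indices
    if (any(is.na(other_tet)) || !all(other_tet %in% out_tets))
      stop("patch triangle not adjacent to outer compartment '", outer, "'")
  }
  mesh$patches[[name]] <- list(
    name = name, tri_indices = tri_indices,
    inner_compartment = inner, outer_compartment = outer,
    inner_tet = as.integer(inner_tet),
    outer_tet = as.integer(other_tet),
    area = sum(mesh$tri_areas[tri_indices]),
    surface_system_ids = as.character(surface_system_ids))
  mesh
}

#' Label tetrahedron faces as triangles
#'
#' Appends the given faces (vertex triples) to the mesh's labeled-triangle
#' set, skipping faces already labeled, and extends the triangle index map.
#' Used to create patch triangles on demand when the source file carried no
#' surface elements.
#'
#' @param mesh A `tetmesh`.
#' @param face_matrix Integer matrix of vertex triples (one face per row).
#' @return List with `mesh` (updated) and `tri_ids` (internal ids of all
#'   requested faces, existing or newly created).
#' @export
label_tri_faces <- function(mesh, face_matrix) {
  face_matrix <- matrix(as.integer(face_matrix), ncol = 3L)
  skey <- function(m) {
    a <- pmin(m[, 1], m[, 2]); b <- pmax(m[, 1], m[, 2]); c3 <- m[, 3]
    paste(pmin(a, c3), pmin(b, pmax(a, c3)), pmax(b, pmax(a, c3)))
  }
  want <- skey(face_matrix)
  have <- if (nrow(mesh$tris)) skey(mesh$tris) else character(0)
  pos <- match(want, have)
  new <- which(is.na(pos))
  new <- new[!duplicated(want[new])]
  if (length(new)) {
    add <- face_matrix[new, , drop = FALSE]
    old_n <- nrow(mesh$tris)
    mesh$tris <- rbind(mesh$tris, add)
    mesh$tri_areas <- c(mesh$tri_areas, .tri_areas(mesh$vertices, add))
    mesh$tri_barycenters <- rbind(mesh$tri_barycenters,
                                  .barycenters(mesh$vertices, add))
    old_src <- mesh$index_maps$triangle$source
    nxt <- if (length(old_src)) max(old_src) else 0L
    mesh$index_maps$triangle <- index_map(
      "triangle", c(old_src, nxt + seq_len(nrow(add))))
    have <- c(have, skey(add))
    pos <- match(want, have)
  }
  list(mesh = mesh, tri_ids = pos)
}
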