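# ---------------------------------------------------------------------------
# Mesh format readers (Abaqus .inp, TetGen .node/.ele, Gmsh .msh v2.2
# ASCII) and the XML archive that persists a prepared mesh together with
# its compartments, patches, biochemical-system associations, ROI datasets
# and index maps.
# ---------------------------------------------------------------------------

.raw_mesh <- function(format, vertex_ids, vertex_coords,
                      tet_ids, tet_conn, tri_ids = integer(0),
                      tri_conn = matrix(integer(0), ncol = 3L),
                      tri_labels = integer(0)) {
  bad <- setdiff(unique(c(tet_conn, tri_conn)), vertex_ids)
  if (length(bad))
    stop("element connectivity references undeclared vertex id(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  structure(list(format = format,
                 vertex_ids = as.integer(vertex_ids),
                 vertex_coords = vertex_coords,
                 tet_ids = as.integer(tet_ids), tet_conn = tet_conn,
                 tri_ids = as.integer(tri_ids), tri_conn = tri_conn,
                 tri_labels = tri_labels),
            class = "raw_mesh")
}

#' Build a `tetmesh` from an imported raw mesh
#'
#' Maps source vertex ids to contiguous internal ids and constructs the
#' mesh; the source/internal mappings for vertices, tets and triangles are
#' stored in the mesh's index maps.
#'
#' @param raw A `raw_mesh` from one of the readers.
#' @return A `tetmesh`.
#' @export
tetmesh_from_raw <- function(raw) {
  stopifnot(inherits(raw, "raw_mesh"))
  conn <- matrix(match(raw$tet_conn, raw$vertex_ids),
                 ncol = 4L)
  tris <- if (nrow(raw$tri_conn))
    matrix(match(raw$tri_conn, raw$vertex_ids), ncol = 3L) else NULL
  build_tetmesh(raw$vertex_coords, conn, tris,
                source_ids = list(vertex = raw$vertex_ids,
                                  tetrahedron = raw$tet_ids,
                                  triangle = raw$tri_ids))
}

# ---- Abaqus ---------------------------------------------------------------

#' Read an Abaqus .inp mesh (ASCII subset)
#'
#' Line-oriented parser for `*NODE` and `*ELEMENT` keyword blocks with
#' case-insensitive keywords and comma-separated records. 4-node solid
#' elements (`TYPE=C3D4`) become tetrahedra and 3-node surface elements
#' (`TYPE=S3`/`STRI3`) become labeled triangles; any other element type is
#' an error (with its line number). Continuation lines are not supported.
#'
#' @param path Path to the .inp file.
#' @return A `raw_mesh`.
#' @export
read_abaqus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vid <- integer(0); vco <- list()
  tid <- integer(0); tconn <- list()
  sid <- integer(0); sconn <- list()
  section <- "none"
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "**")) next
    if (startsWith(raw, "*")) {
      kw <- toupper(sub("[ ,].*$", "", raw))
      if (kw == "*NODE") {
        section <- "node"
      } else if (kw == "*ELEMENT") {
        type <- toupper(sub(".*TYPE *= *([A-Za-z0-9]+).*", "\\1", raw,
                            ignore.case = TRUE))
        if (type %in% c("C3D4")) section <- "tet"
        else if (type %in% c("S3", "STRI3")) section <- "tri"
        else stop("unsupported Abaqus element type '", type,
                  "' at line ", ln)
      } else {
        section <- "none"   # other keyword blocks are skipped
      }
      next
    }
    if (section == "none") next
    if (endsWith(raw, ","))
      stop("continuation lines are not supported (line ", ln, ")")
    parts <- as.numeric(strsplit(raw, ",")[[1]])
    if (section == "node") {
      if (length(parts) < 4L) stop("malformed node record at line ", ln)
      vid <- c(vid, as.integer(parts[1]))
      vco[[length(vco) + 1L]] <- parts[2:4]
    } else if (section == "tet") {
      if (length(parts) != 5L)
        stop("C3D4 element needs 4 nodes (line ", ln, ")")
      tid <- c(tid, as.integer(parts[1]))
      tconn[[length(tconn) + 1L]] <- as.integer(parts[2:5])
    } else {
      if (length(parts) != 4L)
        stop("S3 element needs 3 nodes (line ", ln, ")")
      sid <- c(sid, as.integer(parts[1]))
      sconn[[length(sconn) + 1L]] <- as.integer(parts[2:4])
    }
  }
  if (!length(vid)) stop("no *NODE section found in ", path)
  if (!length(tid)) stop("no C3D4 elements found in ", path)
  .raw_mesh("abaqus", vid, do.call(rbind, vco), tid,
            do.call(rbind, tconn), sid,
            if (length(sconn)) do.call(rbind, sconn)
            else matrix(integer(0), ncol = 3L),
            rep(NA_integer_, length(sid)))
}

#' Write a raw mesh as an Abaqus .inp file
#' @param raw A `raw_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abaqus <- function(raw, path) {
  stopifnot(inherits(raw, "raw_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.17g, %.17g, %.17g", raw$vertex_ids,
                     raw$vertex_coords[, 1], raw$vertex_coords[, 2],
                     raw$vertex_coords[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", raw$tet_ids,
                     raw$tet_conn[, 1], raw$tet_conn[, 2],
                     raw$tet_conn[, 3], raw$tet_conn[, 4]), con)
  if (length(raw$tri_ids)) {
    writeLines("*ELEMENT, TYPE=S3", con)
    writeLines(sprintf("%d, %d, %d, %d", raw$tri_ids,
                       raw$tri_conn[, 1], raw$tri_conn[, 2],
                       raw$tri_conn[, 3]), con)
  }
  invisible(path)
}

# ---- TetGen ---------------------------------------------------------------

.tetgen_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines[nzchar(trimws(lines))]
}

.split_nums <- function(line) as.numeric(strsplit(trimws(line), "[ \t]+")[[1]])

#' Read a TetGen .node/.ele mesh pair
#'
#' Honours the first-line headers (`<#points> <dim> <#attrs> <#markers>`
#' and `<#tets> <#nodes/tet> <#attrs>`); 0- or 1-based numbering is
#' detected from the first node id. Comment (`#`) text is ignored.
#'
#' @param node_path Path to the .node file.
#' @param ele_path Path to the matching .ele file.
#' @return A `raw_mesh`.
#' @export
read_tetgen <- function(node_path, ele_path) {
  nl <- .tetgen_lines(node_path)
  hd <- .split_nums(nl[1])
  npts <- as.integer(hd[1]); dim <- as.integer(hd[2])
  if (dim != 3L) stop("TetGen .node dimension must be 3, got ", dim)
  if (length(nl) - 1L != npts)
    stop("TetGen .node header declares ", npts, " points but file has ",
         length(nl) - 1L, " records")
  rec <- t(vapply(nl[-1], .split_nums, numeric(4 + hd[3] + hd[4]),
                  USE.NAMES = FALSE))
  vid <- as.integer(rec[, 1])
  vco <- rec[, 2:4, drop = FALSE]

  el <- .tetgen_lines(ele_path)
  eh <- .split_nums(el[1])
  ntets <- as.integer(eh[1]); npt <- as.integer(eh[2])
  if (npt != 4L) stop("only 4-node tetrahedra supported in .ele, got ", npt)
  if (length(el) - 1L != ntets)
    stop("TetGen .ele header declares ", ntets, " tets but file has ",
         length(el) - 1L, " records")
  erec <- t(vapply(el[-1], .split_nums, numeric(5 + eh[3]),
                   USE.NAMES = FALSE))
  tid <- as.integer(erec[, 1])
  tconn <- matrix(as.integer(erec[, 2:5]), ncol = 4L)
  .raw_mesh("tetgen", vid, vco, tid, tconn)
}

# ---- Gmsh -----------------------------------------------------------------

#' Read a Gmsh .msh file (MSH 2.2 ASCII)
#'
#' Element type 4 (4-node tetrahedron) becomes a tet, type 2 (3-node
#' triangle) a labeled triangle whose first tag (physical group) is kept as
#' its label; points and lines are ignored. Binary files and other MSH
#' versions raise an explicit error.
#'
#' @param path Path to the .msh file.
#' @return A `raw_mesh`.
#' @export
read_gmsh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fmt <- which(trimws(lines) == "$MeshFormat")
  if (!length(fmt)) stop("not a Gmsh MSH file (no $MeshFormat): ", path)
  hd <- .split_nums(lines[fmt[1] + 1L])
  if (abs(hd[1] - 2.2) > 1e-9)
    stop("unsupported MSH version ", hd[1], " (only 2.2 ASCII)")
  if (hd[2] != 0) stop("binary MSH files are not supported")

  nsec <- which(trimws(lines) == "$Nodes")
  if (!length(nsec)) stop("missing $Nodes section")
  nn <- as.integer(lines[nsec[1] + 1L])
  nrec <- t(vapply(lines[nsec[1] + 1L + seq_len(nn)], .split_nums,
                   numeric(4), USE.NAMES = FALSE))
  vid <- as.integer(nrec[, 1]); vco <- nrec[, 2:4, drop = FALSE]

  esec <- which(trimws(lines) == "$Elements")
  if (!length(esec)) stop("missing $Elements section")
  ne <- as.integer(lines[esec[1] + 1L])
  tid <- integer(0); tconn <- list()
  sid <- integer(0); sconn <- list(); slab <- integer(0)
  for (q in seq_len(ne)) {
    parts <- .split_nums(lines[esec[1] + 1L + q])
    id <- as.integer(parts[1]); type <- as.integer(parts[2])
    ntags <- as.integer(parts[3])
    nodes <- as.integer(parts[-(1:(3 + ntags))])
    if (type == 4L) {
      tid <- c(tid, id); tconn[[length(tconn) + 1L]] <- nodes
    } else if (type == 2L) {
      sid <- c(sid, id); sconn[[length(sconn) + 1L]] <- nodes
      slab <- c(slab, if (ntags >= 1L) as.integer(parts[4]) else NA_integer_)
    } else if (!type %in% c(1L, 15L)) {
      stop("unsupported Gmsh element type ", type)
    }
  }
  if (!length(tid)) stop("no tetrahedra (type 4) in ", path)
  .raw_mesh("gmsh", vid, vco, tid, do.call(rbind, tconn), sid,
            if (length(sconn)) do.call(rbind, sconn)
            else matrix(integer(0), ncol = 3L), slab)
}

# ---- XML archive ----------------------------------------------------------

.fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = " ")
.fmt_ints <- function(x) paste(as.integer(x), collapse = " ")
.parse_nums <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
  as.numeric(strsplit(trimws(s), "[ \n\t]+")[[1]])
}
.parse_ints <- function(s) as.integer(.parse_nums(s))

#' Save a prepared mesh to an XML archive
#'
#' Persists vertices, connectivity, labeled triangles, compartments with
#' their volume-system ids, patches with surface-system ids, ROI datasets
#' and the source/internal index maps. Coordinates are serialized with full
#' double precision so that save/load round trips are value-exact and a
#' second save is byte-identical.
#'
#' @param mesh A `tetmesh`.
#' @param path Output path (.xml).
#' @return `path`, invisibly.
#' @export
save_archive <- function(mesh, path) {
  stopifnot(inherits(mesh, "tetmesh"))
  doc <- xml2::xml_new_root("tetmesh", version = "1")
  xml2::xml_add_child(doc, "vertices",
                      .fmt_nums(t(mesh$vertices)),
                      n = as.character(nrow(mesh$vertices)),
                      source = .fmt_ints(mesh$index_maps$vertex$source))
  xml2::xml_add_child(doc, "tets", .fmt_ints(t(mesh$tets)),
                      n = as.character(nrow(mesh$tets)),
                      source = .fmt_ints(mesh$index_maps$tetrahedron$source))
  xml2::xml_add_child(doc, "tris", .fmt_ints(t(mesh$tris)),
                      n = as.character(nrow(mesh$tris)),
                      source = .fmt_ints(mesh$index_maps$triangle$source))
  comps <- xml2::xml_add_child(doc, "compartments")
  for (cp in mesh$compartments)
    xml2::xml_add_child(comps, "compartment", .fmt_ints(cp$tet_indices),
                        name = cp$name,
                        vsys = paste(cp$volume_system_ids, collapse = " "))
  pats <- xml2::xml_add_child(doc, "patches")
  for (p in mesh$patches)
    xml2::xml_add_child(pats, "patch", .fmt_ints(p$tri_indices),
                        name = p$name, inner = p$inner_compartment,
                        outer = if (is.null(p$outer_compartment)) ""
                                else p$outer_compartment,
                        ssys = paste(p$surface_system_ids, collapse = " "))
  rois <- xml2::xml_add_child(doc, "rois")
  for (r in mesh$rois)
    xml2::xml_add_child(rois, "roi", .fmt_ints(r$indices),
                        name = r$name, class = r$element_class)
  xml2::write_xml(doc, path)
  invisible(path)
}

.xml_attr1 <- function(node, name) xml2::xml_attr(node, name)

#' Load a mesh archive
#'
#' Rebuilds the mesh (re-deriving volumes, areas, barycenters and
#' adjacency) and re-registers compartments, patches and ROIs with full
#' validation; a dangling element reference is an error naming the
#' offending block.
#'
#' @param path Archive path written by [save_archive()].
#' @return A `tetmesh`.
#' @export
load_archive <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "tetmesh")
    stop("not a tetmesh archive: root element is <",
         xml2::xml_name(doc), ">")
  get1 <- function(nm) {
    node <- xml2::xml_find_first(doc, nm)
    if (inherits(node, "xml_missing")) stop("archive missing <", nm, "> block")
    node
  }
  vn <- get1("vertices")
  verts <- matrix(.parse_nums(xml2::xml_text(vn)), ncol = 3L, byrow = TRUE)
  if (nrow(verts) != as.integer(.xml_attr1(vn, "n")))
    stop("vertex count mismatch in <vertices>")
  tn <- get1("tets")
  tets <- matrix(.parse_ints(xml2::xml_text(tn)), ncol = 4L, byrow = TRUE)
  if (nrow(tets) != as.integer(.xml_attr1(tn, "n")))
    stop("tet count mismatch in <tets>")
  rn <- get1("tris")
  tri_txt <- .parse_ints(xml2::xml_text(rn))
  tris <- if (length(tri_txt)) matrix(tri_txt, ncol = 3L, byrow = TRUE)
          else NULL
  mesh <- build_tetmesh(
    verts, tets, tris,
    source_ids = list(
      vertex = .parse_ints(.xml_attr1(vn, "source")),
      tetrahedron = .parse_ints(.xml_attr1(tn, "source")),
      triangle = .parse_ints(.xml_attr1(rn, "source"))))
  for (cp in xml2::xml_find_all(doc, "compartments/compartment")) {
    vsys <- strsplit(trimws(.xml_attr1(cp, "vsys")), " +")[[1]]
    mesh <- make_compartment(mesh, .xml_attr1(cp, "name"),
                             .parse_ints(xml2::xml_text(cp)),
                             vsys[nzchar(vsys)])
  }
  for (p in xml2::xml_find_all(doc, "patches/patch")) {
    ssys <- strsplit(trimws(.xml_attr1(p, "ssys")), " +")[[1]]
    outer <- .xml_attr1(p, "outer")
    mesh <- make_patch(mesh, .xml_attr1(p, "name"),
                       .parse_ints(xml2::xml_text(p)),
                       inner = .xml_attr1(p, "inner"),
                       outer = if (nzchar(outer)) outer else NULL,
                       surface_system_ids = ssys[nzchar(ssys)])
  }
  for (r in xml2::xml_find_all(doc, "rois/roi")) {
    mesh <- add_roi(mesh, .xml_attr1(r, "name"), .xml_attr1(r, "class"),
                    .parse_ints(xml2::xml_text(r)))
  }
  mesh
}
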