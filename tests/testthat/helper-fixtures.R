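# Shared fixture builders. Everything is generated in code; no binary data.

unit_tet_verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

unit_tet_mesh <- function() build_tetmesh(unit_tet_verts, rbind(1:4))

two_tet_mesh <- function() {
  verts <- rbind(unit_tet_verts, c(1, 1, 1))
  build_tetmesh(verts, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
}

# one diffusible species in a volume system
diffusion_model <- function(D = 1e-12, species = "X", vsys = "vsys") {
  build_model(species, volume_systems = list(
    volume_system(vsys, diffusion = list(
      diffusion_rule(paste0("d", species), species, D)))))
}

# mesh with a single whole-mesh compartment attached to `vsys`
with_compartment <- function(mesh, vsys = "vsys", name = "comp") {
  make_compartment(mesh, name, seq_len(nrow(mesh$tets)), vsys)
}

# brute-force selection oracle: loop every element, test points per mode
oracle_select <- function(mesh, bound, mode, what = "tet") {
  conn <- if (what == "tet") mesh$tets else mesh$tris
  bary <- if (what == "tet") mesh$tet_barycenters else mesh$tri_barycenters
  hits <- integer(0)
  for (i in seq_len(nrow(conn))) {
    if (mode == "barycenter") {
      ok <- contains_points(bound, rbind(bary[i, ]))
    } else {
      ins <- vapply(seq_len(ncol(conn)), function(k)
        contains_points(bound, rbind(mesh$vertices[conn[i, k], ])),
        logical(1))
      ok <- if (mode == "all_vertices") all(ins) else any(ins)
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# enumerate faces incident to exactly one tet by hashing sorted triples
oracle_skin_count <- function(mesh) {
  keys <- character(0)
  combs <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (i in seq_len(nrow(mesh$tets)))
    for (cc in combs)
      keys <- c(keys, paste(sort(mesh$tets[i, cc]), collapse = "-"))
  sum(table(keys) == 1L)
}

extdata <- function(name) system.file("extdata", name, package = "tetrasim")
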