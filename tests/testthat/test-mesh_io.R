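test_that("the packaged Abaqus fixture parses and keeps source ids", {
  raw <- read_abaqus(extdata("onetet.inp"))
  expect_equal(length(raw$vertex_ids), 4L)
  expect_equal(nrow(raw$tet_conn), 1L)
  m <- tetmesh_from_raw(raw)
  expect_equal(to_source(m$index_maps$tetrahedron, 1L), 1L)
  expect_equal(sum(m$tet_volumes), 1 / 6)
})

test_that("Abaqus write/read round trip reproduces the raw mesh", {
  raw <- read_abaqus(extdata("twotet.inp"))
  tmp <- tempfile(fileext = ".inp")
  write_abaqus(raw, tmp)
  again <- read_abaqus(tmp)
  expect_equal(again$vertex_ids, raw$vertex_ids)
  expect_equal(again$vertex_coords, raw$vertex_coords)
  expect_equal(again$tet_conn, raw$tet_conn)
})

test_that("unsupported Abaqus element types raise with a line number", {
  tmp <- tempfile(fileext = ".inp")
  writeLines(c("*NODE", "1, 0, 0, 0", "2, 1, 0, 0", "3, 0, 1, 0",
               "4, 0, 0, 1", "*ELEMENT, TYPE=C3D8",
               "1, 1, 2, 3, 4, 1, 2, 3, 4"), tmp)
  expect_error(read_abaqus(tmp), "C3D8.*line 6")
})

test_that("TetGen reader honours headers and detects 0-based numbering", {
  raw <- read_tetgen(extdata("twotet.node"), extdata("twotet.ele"))
  expect_equal(nrow(raw$tet_conn), 2L)
  m1 <- tetmesh_from_raw(raw)
  # same fixture rewritten 0-based must give the identical internal mesh
  nd <- tempfile(fileext = ".node"); el <- tempfile(fileext = ".ele")
  writeLines(c("5 3 0 0",
               paste(0:4, c(0, 1, 0, 0, 1), c(0, 0, 1, 0, 1),
                     c(0, 0, 0, 1, 1))), nd)
  writeLines(c("2 4 0", "0 0 1 2 3", "1 1 2 3 4"), el)
  m2 <- tetmesh_from_raw(read_tetgen(nd, el))
  expect_equal(m2$vertices, m1$vertices)
  expect_equal(m2$tets, m1$tets)
})

test_that("TetGen reader validates counts, dimension, and node references", {
  nd <- tempfile(fileext = ".node"); el <- tempfile(fileext = ".ele")
  writeLines(c("2 3 0 0", "1 0 0 0", "2 1 0 0", "3 0 1 0"), nd)
  expect_error(read_tetgen(nd, el), "declares 2 points")
  writeLines(c("4 2 0 0", "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1"), nd)
  expect_error(read_tetgen(nd, el), "dimension")
  writeLines(c("4 3 0 0", "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1"), nd)
  writeLines(c("1 4 0", "1 1 2 3 99"), el)
  expect_error(read_tetgen(nd, el), "undeclared vertex")
})

test_that("Gmsh v2.2 reader parses tets and labeled triangles", {
  raw <- read_gmsh(extdata("twotet.msh"))
  expect_equal(nrow(raw$tet_conn), 2L)
  # a file with one tet and four labeled triangles
  tmp <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "4", "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
               "$EndNodes", "$Elements", "5",
               "1 4 2 0 1 1 2 3 4",
               "2 2 2 7 1 1 2 3", "3 2 2 7 1 1 2 4",
               "4 2 2 7 1 1 3 4", "5 2 2 7 1 2 3 4",
               "$EndElements"), tmp)
  raw2 <- read_gmsh(tmp)
  expect_equal(nrow(raw2$tet_conn), 1L)
  expect_equal(nrow(raw2$tri_conn), 4L)
  expect_equal(raw2$tri_labels, rep(7L, 4L))
})

test_that("non-2.2 and binary MSH files are rejected", {
  tmp <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat"), tmp)
  expect_error(read_gmsh(tmp), "version")
  writeLines(c("$MeshFormat", "2.2 1 8", "$EndMeshFormat"), tmp)
  expect_error(read_gmsh(tmp), "binary")
})

test_that("the three readers agree on the two-tet fixture", {
  ma <- tetmesh_from_raw(read_abaqus(extdata("twotet.inp")))
  mt <- tetmesh_from_raw(read_tetgen(extdata("twotet.node"),
                                     extdata("twotet.ele")))
  mg <- tetmesh_from_raw(read_gmsh(extdata("twotet.msh")))
  expect_equal(mt$vertices, ma$vertices)
  expect_equal(mg$vertices, ma$vertices)
  expect_equal(mt$tets, ma$tets)
  expect_equal(mg$tets, ma$tets)
  expect_equal(mt$tet_volumes, ma$tet_volumes)
  expect_equal(mg$tet_volumes, ma$tet_volumes)
})

test_that("XML archive round trip preserves the prepared mesh exactly", {
  m <- nested_sphere_mesh(0.6e-6, 0.3e-6, 0.1e-6,
                          volume_system_ids = list(inner = "er_vsys",
                                                   outer = "cyt_vsys"),
                          surface_system_ids = "memb_ssys")
  m <- add_roi(m, "core", "tetrahedron",
               m$compartments$inner$tet_indices[1:5])
  tmp <- tempfile(fileext = ".xml")
  save_archive(m, tmp)
  m2 <- load_archive(tmp)
  expect_identical(m2$vertices, m$vertices)
  expect_identical(m2$tets, m$tets)
  expect_identical(m2$tris, m$tris)
  expect_equal(m2$compartments, m$compartments)
  expect_equal(m2$patches, m$patches)
  expect_equal(m2$rois, m$rois)
  expect_identical(sum(m2$tet_volumes), sum(m$tet_volumes))
})

test_that("second-pass archive serialization is byte-stable", {
  gen <- spiny_dendrite_mesh(spiny_dendrite_spec(
    shaft_length = 4e-6, spine_density = 0))
  t1 <- tempfile(fileext = ".xml"); t2 <- tempfile(fileext = ".xml")
  save_archive(gen$mesh, t1)
  save_archive(load_archive(t1), t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  expect_identical(sum(load_archive(t2)$tet_volumes),
                   sum(gen$mesh$tet_volumes))
})

test_that("archives with dangling ROI references fail to load", {
  m <- two_tet_mesh()
  m <- add_roi(m, "z", "tetrahedron", 1L)
  tmp <- tempfile(fileext = ".xml")
  save_archive(m, tmp)
  txt <- readLines(tmp)
  txt <- sub("<roi name=\"z\" class=\"tetrahedron\">1</roi>",
             "<roi name=\"z\" class=\"tetrahedron\">99</roi>", txt)
  writeLines(txt, tmp)
  expect_error(load_archive(tmp), "out-of-range")
})
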