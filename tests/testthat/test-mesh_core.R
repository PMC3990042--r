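test_that("tet_volume matches the analytic determinant formula", {
  expect_equal(tet_volume(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               1 / 6)
  expect_equal(tet_volume(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)),
               8 / 6)
  expect_equal(tet_volume(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               0)
})

test_that("unit tetrahedron mesh has volume 1/6 and 4 skin faces", {
  m <- unit_tet_mesh()
  expect_equal(sum(m$tet_volumes), 1 / 6)
  expect_true(all(is.na(m$tet_neighbors)))
  expect_equal(nrow(m$faces), 4L)
  expect_true(all(is.na(m$faces$tet2)))
})

test_that("two glued tets list each other as neighbors and leave 6 skin faces", {
  m <- two_tet_mesh()
  expect_equal(sort(stats::na.omit(as.vector(m$tet_neighbors[1, ]))), 2L)
  expect_equal(sort(stats::na.omit(as.vector(m$tet_neighbors[2, ]))), 1L)
  expect_equal(sum(is.na(m$faces$tet2)), 6L)
  expect_equal(nrow(m$faces), 7L)
})

test_that("degenerate and malformed tets are rejected", {
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(build_tetmesh(flat, rbind(1:4)), "degenerate")
  expect_error(build_tetmesh(unit_tet_verts, rbind(c(1, 2, 3, 9))),
               "out-of-range")
  expect_error(build_tetmesh(unit_tet_verts, rbind(c(1, 2, 3, 3))),
               "repeated")
  expect_error(
    build_tetmesh(rbind(unit_tet_verts, c(1, 1, 1)),
                  rbind(c(1, 2, 3, 4), c(1, 2, 4, 3))),
    "duplicated")
})

test_that("box mesh volumes sum to the analytic box volume", {
  b <- box_mesh(c(1, 1, 1), c(2, 2, 2))
  expect_equal(nrow(b$tets), 48L)
  expect_equal(sum(b$tet_volumes), 1, tolerance = 1e-12)
  b2 <- box_mesh(c(2, 1, 1), c(3, 2, 2))
  expect_equal(sum(b2$tet_volumes), 2, tolerance = 1e-12)
})

test_that("face incidence is 1 or 2 and the neighbor relation is symmetric", {
  b <- box_mesh(c(1, 2, 0.5), c(3, 2, 2))
  inc <- 2L - is.na(b$faces$tet2)
  expect_true(all(inc %in% c(1L, 2L)))
  for (i in seq_len(nrow(b$tets))) {
    for (j in stats::na.omit(b$tet_neighbors[i, ])) {
      expect_true(i %in% b$tet_neighbors[j, ])
    }
  }
})

test_that("index maps round-trip under randomized source permutations", {
  set.seed(11)
  for (rep in 1:5) {
    src <- sample(1000L, 30L)
    im <- index_map("tetrahedron", src)
    expect_equal(to_source(im, to_internal(im, src)), src)
    expect_equal(to_internal(im, to_source(im, seq_len(30L))), seq_len(30L))
  }
  im <- index_map("tetrahedron", c(101L, 205L, 33L))
  expect_equal(to_internal(im, 205L), 2L)
  expect_equal(to_source(im, 1L), 101L)
  expect_error(to_internal(im, 999L), "tetrahedron")
  expect_error(to_source(im, 7L), "tetrahedron")
})

test_that("ROIs store ordered element lists retrievable by name", {
  m <- two_tet_mesh()
  m <- add_roi(m, "injection", "tetrahedron", c(2L, 1L))
  expect_equal(get_roi(m, "injection")$indices, c(2L, 1L))
  expect_error(add_roi(m, "injection", "tetrahedron", 1L), "already used")
  expect_error(add_roi(m, "bad", "tetrahedron", 99L), "out-of-range")
  expect_error(get_roi(m, "missing"), "no ROI")
})

test_that("compartments are disjoint and their volumes sum member tet volumes", {
  b <- box_mesh(c(1, 1, 1), c(2, 2, 2))
  left <- which(b$tet_barycenters[, 1] < 0.5)
  right <- setdiff(seq_len(nrow(b$tets)), left)
  b <- make_compartment(b, "L", left, "vs1")
  b <- make_compartment(b, "R", right, "vs2")
  expect_error(make_compartment(b, "L2", left[1]), "owned")
  # brute-force volume cross-check
  vol_oracle <- 0
  for (i in left) vol_oracle <- vol_oracle +
      tet_volume(b$vertices[b$tets[i, 1], ], b$vertices[b$tets[i, 2], ],
                 b$vertices[b$tets[i, 3], ], b$vertices[b$tets[i, 4], ])
  expect_equal(b$compartments$L$volume, vol_oracle)
  # joint cover implies volumes partition the total
  expect_equal(b$compartments$L$volume + b$compartments$R$volume,
               sum(b$tet_volumes))
})

test_that("nested-sphere components partition the mesh with a valid patch", {
  m <- nested_sphere_mesh(0.6e-6, 0.3e-6, 0.1e-6)
  all_tets <- sort(c(m$compartments$inner$tet_indices,
                     m$compartments$outer$tet_indices))
  expect_equal(all_tets, seq_len(nrow(m$tets)))
  p <- m$patches$interface
  expect_gt(length(p$tri_indices), 0L)
  # each interface triangle has exactly one incident tet per compartment
  expect_true(all(p$inner_tet %in% m$compartments$inner$tet_indices))
  expect_true(all(p$outer_tet %in% m$compartments$outer$tet_indices))
  expect_equal(p$area, sum(m$tri_areas[p$tri_indices]))
})

test_that("patches reject triangles not separating the two compartments", {
  b <- box_mesh(c(1, 1, 1), c(2, 2, 2))
  left <- which(b$tet_barycenters[, 1] < 0.5)
  b <- make_compartment(b, "L", left)
  # a skin face of an L tet has no second compartment: outer patch must fail
  sk <- skin_triangles(b)
  b2 <- sk$mesh
  lt <- which(sk$tri_ids > 0)
  expect_error(make_patch(b2, "p", sk$tri_ids[1], inner = "missing"),
               "unknown inner")
  expect_error(make_patch(b2, "p", sk$tri_ids, inner = "L", outer = "L"),
               "unknown outer|not adjacent|both incident")
})
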