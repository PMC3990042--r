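test_that("tetrahedron samples are contained and centered on the barycenter", {
  set.seed(101)
  tc <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0.5, 0.5, 1.5))
  pts <- sample_in_tet(tc, 1e5)
  ok <- vapply(sample(1e5, 500), function(i)
    point_in_tet(pts[i, ], tc, tol = 1e-12), logical(1))
  expect_true(all(ok))
  ctr <- colMeans(tc)
  # CLT bound: per-coordinate sd of a uniform point in a simplex is
  # bounded by the coordinate range; 4 sigma of the mean estimator
  sds <- apply(pts, 2, sd)
  expect_true(all(abs(colMeans(pts) - ctr) < 4 * sds / sqrt(1e5)))
  expect_error(sample_in_tet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(1, 1, 0))), "degenerate")
})

test_that("tetrahedron sampling is uniform across the 8 midpoint sub-tets", {
  # the midpoint subdivision of a tet yields 8 equal-volume pieces; a
  # uniform sampler must populate them equally (chi-square, alpha = 0.001)
  set.seed(202)
  n <- 1e5
  u <- matrix(runif(3 * n), ncol = 3)
  s1 <- pmin(u[, 1], u[, 2], u[, 3])
  s3 <- pmax(u[, 1], u[, 2], u[, 3])
  s2 <- u[, 1] + u[, 2] + u[, 3] - s1 - s3
  w <- cbind(s1, s2 - s1, s3 - s2, 1 - s3)
  # classify by which barycentric coordinate (if any) exceeds 1/2
  big <- w > 0.5
  grp <- ifelse(rowSums(big) == 1L, apply(big, 1, which.max), 0L)
  # pieces: 4 corner cells (one per vertex) each 1/8, remainder 1/2
  cnt <- c(sum(grp == 0), tabulate(grp[grp > 0], 4))
  expected <- n * c(1 / 2, rep(1 / 8, 4))
  chi2 <- sum((cnt - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 4))
})

test_that("barycentric marginals match their Beta laws (KS, alpha = 0.001)", {
  set.seed(303)
  n <- 1e5
  w4 <- tetrasim:::.tet_bary_weights(n)
  # each barycentric coordinate of a uniform point in a 3-simplex is
  # Beta(1, 3); in a triangle, Beta(1, 2)
  for (k in 1:4) {
    # suppressed warning: sporadic ties from the 32-bit uniform grid
    ks <- suppressWarnings(stats::ks.test(w4[, k], stats::pbeta, 1, 3))
    expect_gt(ks$p.value, 0.001)
  }
  w3 <- tetrasim:::.tri_bary_weights(n)
  for (k in 1:3) {
    ks <- suppressWarnings(stats::ks.test(w3[, k], stats::pbeta, 1, 2))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("triangle samples lie in the plane, inside, centered on the centroid", {
  set.seed(404)
  tc <- rbind(c(0, 0, 1), c(2, 0, 1), c(0, 3, 1))
  pts <- sample_in_tri(tc, 1e5)
  expect_true(all(abs(pts[, 3] - 1) < 1e-12))
  expect_true(all(pts[, 1] >= -1e-12 & pts[, 2] >= -1e-12 &
                  pts[, 1] / 2 + pts[, 2] / 3 <= 1 + 1e-12))
  ctr <- colMeans(tc)
  sds <- apply(pts, 2, sd)
  expect_true(all(abs(colMeans(pts)[1:2] - ctr[1:2]) <
                  4 * sds[1:2] / sqrt(1e5)))
  expect_error(sample_in_tri(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "degenerate")
})

test_that("generate_points emits exactly one point per molecule below caps", {
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(1, 1, 1)))
  st <- build_solver(diffusion_model(D = 0), b, seed = 1)
  set_count(st, 1L, "X", 3); set_count(st, 2L, "X", 5)
  comp <- visual_component("c", "compartment_species", "comp",
                           species = "X")
  set.seed(7)
  cloud <- generate_points(comp, st)
  expect_equal(nrow(cloud), 8L)
  expect_equal(sort(unique(cloud$element)), c(1L, 2L))
  expect_equal(as.vector(table(factor(cloud$element, levels = 1:6))),
               c(3L, 5L, 0L, 0L, 0L, 0L))
  # every point inside its element
  for (i in seq_len(nrow(cloud))) {
    tet <- b$tets[cloud$element[i], ]
    expect_true(point_in_tet(c(cloud$x[i], cloud$y[i], cloud$z[i]),
                             b$vertices[tet, ], tol = 1e-9))
  }
  # zero molecules -> empty cloud
  reset_state(st, 1)
  expect_equal(nrow(generate_points(comp, st)), 0L)
})

test_that("density caps and auto-adjust bound the emitted points", {
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(1, 1, 1)))
  st <- build_solver(diffusion_model(D = 0), b, seed = 1)
  set_count(st, 1L, "X", 1e6)
  vol <- b$tet_volumes[1]
  # explicit density cap
  pol <- render_policy(max_points = 1e4, max_density = 1e3 / vol)
  comp <- visual_component("c", "tet_species", 1:6, species = "X",
                           policy = pol)
  set.seed(8)
  cloud <- generate_points(comp, st)
  expect_equal(nrow(cloud), floor(1e3))
  # auto-adjust: density rescaled by max/actual before the per-element cap
  pol2 <- render_policy(max_points = 1e4, auto_adjust = TRUE)
  comp2 <- visual_component("c2", "tet_species", 1:6, species = "X",
                            policy = pol2)
  cloud2 <- generate_points(comp2, st)
  dens_adj <- (1e6 / sum(b$tet_volumes)) * (1e4 / 1e6)
  expect_lte(nrow(cloud2), 1e4)
  expect_lte(nrow(cloud2), floor(dens_adj * vol))
  # overflow with no cap and no auto-adjust is an error
  comp3 <- visual_component("c3", "tet_species", 1:6, species = "X",
                            policy = render_policy(max_points = 10))
  expect_error(generate_points(comp3, st), "exceeds max_points")
})

test_that("channel positions persist across updates and move only on hops", {
  ns <- nested_sphere_mesh(0.6e-6, 0.3e-6, 0.1e-6,
                           surface_system_ids = "ss")
  smod <- build_model(c("S", "P"), surface_systems = list(
    surface_system("ss", reactions = list(
      surface_reaction("flip", reactants = list(surface = c(S = 1)),
                       products = list(surface = c(P = 1)), kcst = 50)))))
  st <- build_solver(smod, ns, seed = 3)
  inject_onto_patch(st, "interface", "S", 30)
  comp <- visual_component("ch", "patch_channel", "interface",
                           species = c("S", "P"))
  set.seed(11)
  tr <- channel_tracker(comp, st)
  expect_equal(nrow(tr$points), 30L)
  pos0 <- tr$points[order(tr$points$element), c("x", "y", "z")]
  # flips happen but no surface diffusion: positions identical
  run_until(st, 0.05)
  update_channel_positions(tr, st)
  pos1 <- tr$points[order(tr$points$element), c("x", "y", "z")]
  expect_equal(unname(as.matrix(pos1)), unname(as.matrix(pos0)))
  expect_gt(sum(tr$points$state == "P"), 0)
  # simulate one hop by hand: move one copy to a neighbouring triangle
  tris <- ns$patches$interface$tri_indices
  from <- tr$points$element[1]
  to <- setdiff(tris, from)[1]
  n_from <- sum(tr$points$element == from)
  sp <- tr$points$state[tr$points$element == from][1]
  cnt_to <- element_counts(st, list(kind = "tri", elems = to), sp)
  set_count(st, from, sp, sum(tr$points$element == from &
                                tr$points$state == sp) - 1L, kind = "tri")
  set_count(st, to, sp, cnt_to + 1L, kind = "tri")
  update_channel_positions(tr, st)
  expect_equal(sum(tr$points$element == from), n_from - 1L)
  expect_equal(nrow(tr$points), 30L)
  # the moved copy lies inside the destination triangle's plane bbox
  moved <- tr$points[tr$points$element == to, ]
  expect_gt(nrow(moved), 0)
})

test_that("components shared between displays are generated once", {
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(2, 2, 2)))
  mod <- build_model(c("A", "B"), volume_systems = list(volume_system(
    "vsys", diffusion = list(diffusion_rule("dA", "A", 0),
                             diffusion_rule("dB", "B", 0)))))
  st <- build_solver(mod, b, seed = 2)
  set_count(st, 1L, "A", 40); set_count(st, 5L, "B", 25)
  sc <- visual_scene()
  add_component(sc, visual_component("geom", "compartment_mesh", "comp"))
  add_component(sc, visual_component("A", "compartment_species", "comp",
                                     species = "A"))
  add_component(sc, visual_component("B", "compartment_species", "comp",
                                     species = "B"))
  assemble_display(sc, "all", c("geom", "A", "B"))
  assemble_display(sc, "onlyA", c("geom", "A"))
  expect_error(assemble_display(sc, "bad", "nope"), "unknown component")
  set.seed(3)
  snap <- snapshot(sc, st)
  expect_identical(snap$displays$all$A, snap$clouds$A)
  expect_identical(snap$displays$onlyA$A, snap$clouds$A)
  # display with only static components has no point clouds
  sc2 <- visual_scene()
  add_component(sc2, visual_component("geom", "compartment_mesh", "comp"))
  assemble_display(sc2, "static", "geom")
  expect_length(snapshot(sc2, st)$clouds, 0L)
  # split view vs all-in-one bookkeeping: per-species counts agree
  nA <- nrow(snap$clouds$A); nB <- nrow(snap$clouds$B)
  expect_equal(nA, 40L)
  expect_equal(nB, 25L)
})

test_that("point clouds export to CSV and PLY", {
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(1, 1, 1)))
  st <- build_solver(diffusion_model(D = 0), b, seed = 1)
  set_count(st, 1L, "X", 5)
  comp <- visual_component("c", "compartment_species", "comp",
                           species = "X")
  set.seed(2)
  cloud <- generate_points(comp, st)
  csv <- tempfile(fileext = ".csv"); ply <- tempfile(fileext = ".ply")
  export_point_cloud(cloud, csv, "csv")
  expect_equal(nrow(utils::read.csv(csv)), 5L)
  export_point_cloud(cloud, ply, "ply")
  expect_equal(readLines(ply)[3], "element vertex 5")
})
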