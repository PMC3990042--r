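test_that("channel instantiation counts follow the model-geometry association", {
  # 1-species diffusion on two glued tets in one compartment: 2 channels
  m <- with_compartment(two_tet_mesh())
  st <- build_solver(diffusion_model(), m, seed = 1)
  expect_equal(sum(st$channel_kind == "diffusion"), 2L)
  # reaction-only model on an N-tet compartment: N channels
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(2, 2, 2)))
  mod <- build_model(c("A", "B"), volume_systems = list(
    volume_system("vsys", reactions = list(
      reaction("r", c(A = 1), c(B = 1), kcst = 1)))))
  st2 <- build_solver(mod, b, seed = 1)
  expect_equal(length(st2$channel_kind), nrow(b$tets))
  expect_true(all(st2$channel_kind == "reaction"))
  # surface reaction on a patch of M tris: M channels
  ns <- nested_sphere_mesh(0.6e-6, 0.3e-6, 0.1e-6,
                           surface_system_ids = "ss")
  smod <- build_model(c("S", "P"), surface_systems = list(
    surface_system("ss", reactions = list(
      surface_reaction("flip", reactants = list(surface = c(S = 1)),
                       products = list(surface = c(P = 1)), kcst = 1)))))
  st3 <- build_solver(smod, ns, seed = 1)
  expect_equal(length(st3$channel_kind),
               length(ns$patches$interface$tri_indices))
  # dangling system id
  bad <- make_compartment(two_tet_mesh(), "c", 1:2, "nope")
  expect_error(build_solver(diffusion_model(), bad, seed = 1),
               "unknown volume system")
})

test_that("reaction propensities follow mass action with molar unit mapping", {
  r1 <- reaction("decay", c(A = 1), c(), kcst = 2)
  expect_equal(reaction_propensity(r1, c(A = 5), 1e-18), 10)
  expect_equal(reaction_propensity(r1, c(A = 0), 1e-18), 0)
  # order-2 unit oracle: k = 1e6 M^-1 s^-1 in V = 1 fL with 100 of each.
  # Independent dimensional analysis: per-pair rate = k / (N_A * V[L]),
  # V = 1e-18 m^3 = 1e-15 L  =>  a = 1e6/(6.02214076e23*1e-15)*100*100
  r2 <- reaction("bind", c(A = 1, B = 1), c(), kcst = 1e6)
  oracle <- 1e6 / (6.02214076e23 * 1e-15) * 100 * 100
  expect_equal(reaction_propensity(r2, c(A = 100, B = 100), 1e-18), oracle,
               tolerance = 1e-12)
  # homodimerization: n(n-1) pairs
  r3 <- reaction("dimer", c(A = 2), c(), kcst = 1e6)
  expect_equal(reaction_propensity(r3, c(A = 10), 1e-18),
               1e6 / (6.02214076e23 * 1e-15) * 10 * 9)
})

test_that("diffusion propensities use the finite-volume hop rate", {
  m <- two_tet_mesh()
  expect_equal(diffusion_propensity(m, 1e-12, 1L, 2L, 0), 0)
  expect_error(diffusion_propensity(m, 1e-12, 1L, 1L, 5), "not.*adjacent")
  # detailed-balance factor symmetry: d_ij * V_i == d_ji * V_j
  dij <- diffusion_propensity(m, 1e-12, 1L, 2L, 1)
  dji <- diffusion_propensity(m, 1e-12, 2L, 1L, 1)
  expect_equal(dij * m$tet_volumes[1], dji * m$tet_volumes[2],
               tolerance = 1e-12)
})

test_that("diffusion on a thin bar reproduces 1D Gaussian statistics", {
  # 10^4 molecules released in the central slab of a bar; after t the axial
  # variance must match 2Dt and the empirical distribution (jittered
  # uniformly within elements) must pass a KS test against N(x0, 2Dt)
  D <- 1e-12
  bar <- box_mesh(c(8e-6, 0.4e-6, 0.4e-6), c(80, 4, 4))
  bar <- with_compartment(bar)
  ctr <- which(abs(bar$tet_barycenters[, 1] - 4e-6) < 0.05e-6)
  bar <- add_roi(bar, "mid", "tetrahedron", ctr)
  st <- build_solver(diffusion_model(D = D), bar, seed = 77)
  inject_into_roi(st, "mid", "X", 10000)
  t_end <- 0.2   # sigma = 0.63 um << bar half-length
  run_until(st, t_end)
  comp <- visual_component("pts", "compartment_species", "comp",
                           species = "X")
  set.seed(1234)
  cloud <- generate_points(comp, st)
  x <- cloud$x
  expect_equal(length(x), 10000L)
  sigma2 <- 2 * D * t_end + (0.1e-6)^2 / 12   # + initial slab width
  expect_lt(abs(var(x) - sigma2) / sigma2, 0.10)
  ks <- stats::ks.test(x, "pnorm", mean = 4e-6, sd = sqrt(sigma2))
  expect_gt(ks$p.value, 0.001)
})

test_that("single-voxel decay matches the analytic linear death process", {
  m <- with_compartment(unit_tet_mesh())
  mod <- build_model(c("A", "B"), volume_systems = list(
    volume_system("vsys", reactions = list(
      reaction("r", c(A = 1), c(B = 1), kcst = 1)))))
  st <- build_solver(mod, m, seed = 500)
  n0 <- 1000; t_end <- 0.5; reps <- 200
  finals <- numeric(reps)
  for (k in seq_len(reps)) {
    reset_state(st, seed = 1000 + k)
    set_count(st, 1L, "A", n0)
    run_until(st, t_end)
    finals[k] <- sim_count(st, scope_tet(1L), "A")
  }
  expected <- n0 * exp(-t_end)
  se <- sqrt(n0 * exp(-t_end) * (1 - exp(-t_end))) / sqrt(reps)
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("A<->B equilibrium on one tet satisfies detailed balance", {
  m <- with_compartment(unit_tet_mesh())
  mod <- build_model(c("A", "B"), volume_systems = list(
    volume_system("vsys", reactions = list(
      reaction("f", c(A = 1), c(B = 1), kcst = 2),
      reaction("b", c(B = 1), c(A = 1), kcst = 1)))))
  st <- build_solver(mod, m, seed = 21)
  set_count(st, 1L, "A", 900)
  # sample the stationary mean of A over checkpoints after burn-in
  run_until(st, 5)
  rec <- run_with_checkpoints(st, 25, 0.1, function(s, t)
    sim_count(s, scope_tet(1L), "A"))
  mA <- mean(unlist(rec$values))
  expect_lt(abs(mA - 300) / 300, 0.05)    # k_b/(k_f+k_b) * 900
})

test_that("injection is multinomial in tet volumes and conserves totals", {
  m <- with_compartment(two_tet_mesh())
  m <- add_roi(m, "both", "tetrahedron", 1:2)
  st <- build_solver(diffusion_model(D = 0), m, seed = 5)
  inject_into_roi(st, "both", "X", 2000)
  expect_equal(unname(sim_count(st, "comp", "X")), 2000)
  # single-tet ROI: everything lands there
  m1 <- add_roi(m, "one", "tetrahedron", 2L)
  st1 <- build_solver(diffusion_model(D = 0), m1, seed = 5)
  inject_into_roi(st1, "one", "X", 77)
  expect_equal(unname(sim_count(st1, scope_tet(2L), "X")), 77)
  expect_equal(unname(sim_count(st1, scope_tet(1L), "X")), 0)
  expect_error(inject_into_roi(st1, list(name = "e",
    element_class = "tetrahedron", indices = integer(0)), "X", 5), "empty")
  # over repeated injections the per-tet mean is proportional to volume
  reps <- 500; n <- 100
  tot <- c(0, 0)
  for (k in seq_len(reps)) {
    reset_state(st, seed = 7000 + k)
    inject_into_roi(st, "both", "X", n)
    tot <- tot + element_counts(st, "both", "X")
  }
  p1 <- m$tet_volumes[1] / sum(m$tet_volumes)
  se <- sqrt(reps * n * p1 * (1 - p1))
  expect_lt(abs(tot[1] - reps * n * p1), 3 * se)
})

test_that("counts and concentrations convert through Avogadro's number", {
  m <- with_compartment(unit_tet_mesh())
  st <- build_solver(diffusion_model(D = 0), m, seed = 1)
  expect_equal(unname(sim_count(st, "comp", "X")), 0)
  set_count(st, 1L, "X", 1)
  v_l <- m$tet_volumes[1] * 1e3
  expect_equal(unname(sim_conc(st, "comp", "X")),
               1 / (6.02214076e23 * v_l))
  # 1 molecule in 1.660539e-21 m^3 is 1 uM
  vv <- 1.660539e-21
  sc <- vv^(1 / 3)
  mm <- with_compartment(build_tetmesh(unit_tet_verts * sc * 6^(1 / 3),
                                       rbind(1:4)))
  st2 <- build_solver(diffusion_model(D = 0), mm, seed = 1)
  set_count(st2, 1L, "X", 1)
  expect_equal(unname(sim_conc(st2, "comp", "X")), 1e-6, tolerance = 1e-4)
})

test_that("diffusion conserves the total count at every checkpoint", {
  b <- with_compartment(box_mesh(c(2e-6, 1e-6, 1e-6), c(8, 4, 4)))
  b <- add_roi(b, "seed", "tetrahedron", 1:10)
  st <- build_solver(diffusion_model(D = 1e-12), b, seed = 9)
  inject_into_roi(st, "seed", "X", 1500)
  rec <- run_with_checkpoints(st, 0.05, 0.005, function(s, t)
    unname(sim_count(s, "comp", "X")))
  expect_true(all(unlist(rec$values) == 1500))
  expect_equal(rec$times, seq(0, 0.05, by = 0.005))
})

test_that("zero total propensity returns immediately at t_end", {
  m <- with_compartment(unit_tet_mesh())
  st <- build_solver(diffusion_model(D = 1e-12), m, seed = 1)
  run_until(st, 3.5)       # no molecules anywhere
  expect_equal(sim_time(st), 3.5)
  expect_equal(total_propensity(st), 0)
})

test_that("incremental propensity table matches a full rebuild during a run", {
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(4, 4, 4)))
  b <- add_roi(b, "seed", "tetrahedron", 1:5)
  mod <- build_model(c("X", "Y"), volume_systems = list(volume_system(
    "vsys",
    reactions = list(reaction("conv", c(X = 1), c(Y = 1), kcst = 5)),
    diffusion = list(diffusion_rule("dX", "X", 1e-12),
                     diffusion_rule("dY", "Y", 2e-12)))))
  st <- build_solver(mod, b, seed = 13)
  inject_into_roi(st, "seed", "X", 400)
  for (k in 1:20) {
    run_until(st, sim_time(st) + 2e-4)
    inc <- propensities(st)
    full <- propensities(st, rebuild = TRUE)
    expect_lt(max(abs(inc - full)) / max(full), 1e-9)
    expect_equal(total_propensity(st), sum(full),
                 tolerance = 1e-9)
  }
})

test_that("identical seeds give identical trajectories", {
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(3, 3, 3)))
  b <- add_roi(b, "seed", "tetrahedron", 1:4)
  mk <- function() {
    st <- build_solver(diffusion_model(D = 1e-12), b, seed = 42)
    inject_into_roi(st, "seed", "X", 300)
    run_until(st, 0.01)
    element_counts(st, "comp", "X")
  }
  expect_identical(mk(), mk())
})

test_that("sync_run aligns records across simulations bit-exactly", {
  b <- with_compartment(box_mesh(c(1e-6, 1e-6, 1e-6), c(3, 3, 3)))
  b <- add_roi(b, "seed", "tetrahedron", 1:4)
  mod <- diffusion_model(D = 1e-12)
  sims <- lapply(1:3, function(k) {
    st <- build_solver(mod, b, seed = k)
    inject_into_roi(st, "seed", "X", 100)
    st
  })
  out <- sync_run(sims, 0.02, 0.002, function(s, t)
    c(n = unname(sim_count(s, "comp", "X")), t = t))
  expect_length(out$records, 3L)
  lens <- vapply(out$records, nrow, 0L)
  expect_true(all(lens == length(out$times)))
  for (r in out$records) expect_identical(unname(r[, "t"]), out$times)
  # degenerate case: one sim equals run_with_checkpoints
  st <- build_solver(mod, b, seed = 9)
  inject_into_roi(st, "seed", "X", 100)
  one <- sync_run(list(st), 0.02, 0.002, function(s, t)
    unname(sim_count(s, "comp", "X")))
  st2 <- build_solver(mod, b, seed = 9)
  inject_into_roi(st2, "seed", "X", 100)
  two <- run_with_checkpoints(st2, 0.02, 0.002, function(s, t)
    unname(sim_count(s, "comp", "X")))
  expect_equal(as.vector(one$records[[1]]), unlist(two$values))
})

test_that("channel-state transitions conserve total channel copies", {
  rates <- c(kf_R_IP3 = 1e9, kb_R_IP3 = 20, kf_RIP3_Ca = 5e8,
             kb_RIP3_Ca = 10, kf_Ca1 = 2e8, kf_Ca2 = 2e8, kf_Ca3 = 2e8,
             kf_Ca4 = 2e8, kb_Ca1 = 5, kb_Ca2 = 5, kb_Ca3 = 5, kb_Ca4 = 5,
             k_flux = 1e9, D_Ca = 2e-10, D_IP3 = 2e-10)
  model <- ip3r_demo_model(rates)
  mesh <- nested_sphere_mesh(0.6e-6, 0.3e-6, 0.1e-6,
                             volume_system_ids = list(inner = "er_vsys",
                                                      outer = "cyt_vsys"),
                             surface_system_ids = "memb_ssys")
  st <- build_solver(model, mesh, seed = 11)
  inject_onto_patch(st, "interface", "R", 40)
  inject_into_roi(st, list(name = "c", element_class = "tetrahedron",
                           indices = mesh$compartments$outer$tet_indices),
                  "IP3", 300)
  inject_into_roi(st, list(name = "e", element_class = "tetrahedron",
                           indices = mesh$compartments$inner$tet_indices),
                  "Ca", 500)
  states <- c("R", "R_IP3", "R_open", paste0("R_Ca", 1:4))
  rec <- run_with_checkpoints(st, 0.02, 0.002, function(s, t) {
    cts <- sim_count(s, "interface")
    c(channels = sum(cts[states]), ca_total = unname(
      sim_count(s, "inner", "Ca") + sim_count(s, "outer", "Ca")))
  })
  vals <- do.call(rbind, rec$values)
  expect_true(all(vals[, "channels"] == 40))
  expect_true(all(vals[, "ca_total"] == 500))
})
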