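test_that("assembled stiffness is symmetric with rigid modes in the null space", {
  m <- triangulate_polygon(rect_polygon(4, 2), 0.5)
  sys <- fe_assemble(m, default_materials(), 1)
  K <- sys$K
  kmax <- max(abs(K))
  expect_lt(max(abs(K - Matrix::t(K))) / kmax, 1e-12)
  tx <- rep(c(1, 0), nrow(m$nodes))
  ty <- rep(c(0, 1), nrow(m$nodes))
  expect_lt(max(abs(K %*% tx)) / kmax, 1e-9)
  expect_lt(max(abs(K %*% ty)) / kmax, 1e-9)
  ## thickness scales every entry linearly
  sys2 <- fe_assemble(m, default_materials(), 2)
  expect_lt(max(abs(sys2$K - 2 * K)) / kmax, 1e-12)
})

test_that("zero loads give zero displacement and zero SED", {
  m <- triangulate_polygon(rect_polygon(4, 2), 0.5)
  sys <- fe_assemble(m, default_materials(), 1)
  lc <- bench_load_case(c(4, 1), c(0, 0),
                        function(nodes) which(nodes[, 2] < 1e-9))
  lc$loads <- list()   # no loads at all
  lc$fixed_boundary <- function(nodes) which(nodes[, 2] < 1e-9)
  d <- fe_solve(sys, lc)
  expect_equal(max(abs(d$u)), 0)
  sed <- strain_energy_density(sys, d)
  expect_equal(max(sed$sed), 0)
})

test_that("the uniaxial patch test reproduces the closed form", {
  pp <- patch_problem()
  U_exp <- pp$sigma0^2 / (2 * pp$E)
  expect_rel_equal(pp$sed$sed, U_exp, 1e-8)
  ## work-energy identity
  expect_rel_equal(attr(pp$sed, "total_energy"), pp$disp$external_work, 1e-8)
  ## displacement linear in position: u_x = sigma0 x / E
  ux_exp <- pp$sigma0 * pp$mesh$nodes[, 1] / pp$E
  expect_lt(max(abs(pp$disp$u[, 1] - ux_exp)), 1e-8 * max(abs(ux_exp)))
})

test_that("patch-test error does not grow under refinement", {
  err <- vapply(c(1, 0.25), function(a) {
    pp <- patch_problem(max_area = a)
    max(abs(pp$sed$sed - pp$sigma0^2 / (2 * pp$E))) / (pp$sigma0^2 / (2 * pp$E))
  }, 0)
  expect_lt(err[2], max(err[1], 1e-10) * 1.5)
})

test_that("cantilever tip deflection matches Timoshenko beam theory within 2%", {
  L <- 100; hgt <- 10; P <- 100; E <- 17000; nu <- 0.3; th <- 1
  m <- triangulate_polygon(rect_polygon(L, hgt), 0.5)
  sys <- fe_assemble(m, default_materials(list(CORTICAL = list(youngs_modulus = E))), th)
  lc <- bench_load_case(c(L, hgt / 2), c(0, -P),
                        function(nodes) which(nodes[, 1] < 1e-9))
  d <- fe_solve(sys, lc)
  expect_lt(d$residual, 1e-9)
  I <- th * hgt^3 / 12
  G <- E / (2 * (1 + nu))
  delta <- P * L^3 / (3 * E * I) + P * L / (5 / 6 * G * th * hgt)
  tip <- which.min((m$nodes[, 1] - L)^2 + (m$nodes[, 2] - hgt / 2)^2)
  expect_lt(abs(abs(d$u[tip, 2]) - delta) / delta, 0.02)
})

test_that("SED scales quadratically with the load", {
  m <- triangulate_polygon(rect_polygon(10, 4), 1)
  sys <- fe_assemble(m, default_materials(), 2)
  fixed <- function(nodes) which(nodes[, 1] < 1e-9)
  d1 <- fe_solve(sys, bench_load_case(c(10, 2), c(30, -80), fixed))
  d3 <- fe_solve(sys, bench_load_case(c(10, 2), 3 * c(30, -80), fixed))
  s1 <- strain_energy_density(sys, d1)
  s3 <- strain_energy_density(sys, d3)
  expect_rel_equal(s3$sed, 9 * s1$sed, 1e-8)
})

test_that("mirrored mesh and loads give the mirrored solution", {
  m <- triangulate_polygon(rect_polygon(6, 3), 0.5)
  mm <- m
  mm$nodes[, 1] <- -mm$nodes[, 1]
  mm$triangles <- mm$triangles[, c(1, 3, 2)]   # restore CCW
  mm$centroid[, 1] <- -mm$centroid[, 1]
  sys <- fe_assemble(m, default_materials(), 1)
  sysm <- fe_assemble(mm, default_materials(), 1)
  fixed <- function(nodes) which(nodes[, 2] < 1e-9)
  d <- fe_solve(sys, bench_load_case(c(5, 3), c(20, -50), fixed))
  dm <- fe_solve(sysm, bench_load_case(c(-5, 3), c(-20, -50), fixed))
  expect_lt(max(abs(dm$u[, 1] + d$u[, 1])), 1e-8 * max(abs(d$u)))
  expect_lt(max(abs(dm$u[, 2] - d$u[, 2])), 1e-8 * max(abs(d$u)))
})

test_that("the work-energy identity holds on the full femur solve", {
  sol <- default_solution()
  expect_lt(sol$disp$residual, 1e-9)
  expect_rel_equal(attr(sol$sed, "total_energy"), sol$disp$external_work, 1e-8)
  expect_true(all(sol$sed$sed >= 0))
})

test_that("the rigid neck transfer conserves force and moment", {
  sol <- default_solution()
  mesh <- sol$mesh
  jl <- sol$load_case$loads$joint
  di <- stemshield:::distribute_load_rigid(mesh, jl,
                                           stemshield:::implant_top_nodes(mesh))
  expect_equal(c(sum(di$fx), sum(di$fy)), jl$force, tolerance = 1e-9)
  r <- mesh$nodes[di$nodes, , drop = FALSE]
  mom <- sum(r[, 1] * di$fy - r[, 2] * di$fx)
  mom_exp <- jl$location[1] * jl$force[2] - jl$location[2] * jl$force[1]
  expect_equal(mom, mom_exp, tolerance = 1e-6 * abs(mom_exp))
})

test_that("interface band nests with band width and excludes the implant", {
  mesh <- default_mesh()
  placed <- default_placed()
  b1 <- interface_band(mesh, placed, 1)
  b3 <- interface_band(mesh, placed, 3)
  b6 <- interface_band(mesh, placed, 6)
  expect_true(all(b1 %in% b3))
  expect_true(all(b3 %in% b6))
  expect_gt(length(b6), length(b3))
  expect_false(any(mesh$region_tag[b6] == "IMPLANT"))
  ball <- interface_band(mesh, placed, 1e9)
  expect_setequal(ball, which(mesh$region_tag != "IMPLANT"))
  expect_error(interface_band(mesh, placed, 0), class = "invalid_parameter")
})

test_that("under-constrained systems are rejected", {
  m <- triangulate_polygon(rect_polygon(4, 2), 1)
  sys <- fe_assemble(m, default_materials(), 1)
  lc <- bench_load_case(c(4, 1), c(1, 1), function(nodes) integer(0))
  expect_error(fe_solve(sys, lc), class = "solver_failure")
})
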