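# Shared fixtures, memoized so the expensive femur solve runs once per
# test session. All fixtures are built in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

default_femur <- function() fixture("femur", build_femur_contour)

default_placed <- function(stem_type = "MINIMA", angle = 0) {
  key <- paste0("placed_", stem_type, "_", angle)
  fixture(key, function()
    place_stem(default_femur(), build_stem_contour(stem_type), angle))
}

default_mesh <- function(max_area = 1.0) {
  key <- paste0("mesh_", max_area)
  fixture(key, function()
    triangulate(default_femur(), default_placed(), max_area))
}

## full default-patient solve at production mesh density
default_solution <- function() {
  fixture("solution", function() {
    femur <- default_femur()
    mesh <- default_mesh()
    mat <- default_materials()
    lc <- build_load_case(list(body_weight = 70, pauwels_angle = 16), femur)
    sys <- fe_assemble(mesh, mat, lc$thickness)
    disp <- fe_solve(sys, lc)
    sed <- strain_energy_density(sys, disp)
    list(femur = femur, mesh = mesh, materials = mat, load_case = lc,
         system = sys, disp = disp, sed = sed)
  })
}

rect_polygon <- function(w, h) {
  matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE)
}

## uniaxial-traction patch problem on a w x h rectangle; returns the solved
## pieces so several tests can assert against the closed form
patch_problem <- function(w = 10, h = 4, sigma0 = 5, max_area = 0.5,
                          E = 17000, thickness = 2) {
  mesh <- triangulate_polygon(rect_polygon(w, h), max_area)
  mat <- default_materials(list(CORTICAL = list(youngs_modulus = E)))
  sys <- fe_assemble(mesh, mat, thickness)
  right <- which(abs(mesh$nodes[, 1] - w) < 1e-9)
  o <- order(mesh$nodes[right, 2])
  rn <- right[o]
  seg <- diff(mesh$nodes[rn, 2])
  trib <- c(seg / 2, 0) + c(0, seg / 2)      # consistent traction lumping
  f <- numeric(sys$ndof)
  f[2 * rn - 1] <- sigma0 * thickness * trib
  left <- which(abs(mesh$nodes[, 1]) < 1e-9)
  fixed_dof <- c(2 * left - 1, 2 * left[which.min(abs(mesh$nodes[left, 2] - h / 2))])
  free <- setdiff(seq_len(sys$ndof), fixed_dof)
  u <- numeric(sys$ndof)
  u[free] <- as.numeric(Matrix::solve(sys$K[free, free], f[free]))
  disp <- structure(list(u = matrix(u, ncol = 2, byrow = TRUE), f = f,
                         fixed_nodes = left, residual = 0,
                         external_work = 0.5 * sum(f * u)),
                    class = "displacement_field")
  list(mesh = mesh, sys = sys, disp = disp, f = f, sigma0 = sigma0, E = E,
       sed = strain_energy_density(sys, disp))
}

## simple point-load load case for benchmark meshes
bench_load_case <- function(loc, force, fixed_sel) {
  list(loads = list(structure(list(location = loc, force = force),
                              class = "point_load")),
       fixed_boundary = fixed_sel)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), .Machine$double.eps), tol)
}
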