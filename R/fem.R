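## Plane-stress linear elasticity on the tagged triangle mesh with 3-node
## constant-strain triangles (CST). Sparse symmetric assembly, direct
## factorization (deterministic), per-element strain energy density.
## Units: mm, N, MPa; energies in N*mm (mJ); SED in MPa = 10^6 J/m^3.

element_geometry <- function(mesh) {
  tri <- mesh$triangles; nd <- mesh$nodes
  x1 <- nd[tri[, 1], 1]; y1 <- nd[tri[, 1], 2]
  x2 <- nd[tri[, 2], 1]; y2 <- nd[tri[, 2], 2]
  x3 <- nd[tri[, 3], 1]; y3 <- nd[tri[, 3], 2]
  list(b1 = y2 - y3, b2 = y3 - y1, b3 = y1 - y2,
       c1 = x3 - x2, c2 = x1 - x3, c3 = x2 - x1,
       area = 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)))
}

element_materials <- function(mesh, materials) {
  E <- vapply(materials, `[[`, 0, "youngs_modulus")[mesh$region_tag]
  nu <- vapply(materials, `[[`, 0, "poisson_ratio")[mesh$region_tag]
  rho <- vapply(materials, `[[`, 0, "density")[mesh$region_tag]
  if (any(E <= 0)) stemshield_stop("non-positive Young's modulus",
                                   "singular_material")
  list(E = E, nu = nu, rho = rho,
       d11 = E / (1 - nu^2), d12 = nu * E / (1 - nu^2), d33 = E / (2 * (1 + nu)))
}

#' Assemble the plane-stress stiffness system
#'
#' Vectorized CST assembly into a sparse symmetric matrix of dimension
#' `2 * n_nodes`.
#'
#' @param mesh `fe_mesh`.
#' @param materials material table from [default_materials()].
#' @param thickness plane-stress slab thickness, mm.
#' @return `fe_system`: `K` (dgCMatrix), `mesh`, `materials`, `thickness`,
#'   `ndof`.
#' @export
fe_assemble <- function(mesh, materials = default_materials(), thickness = 10) {
  g <- element_geometry(mesh)
  mt <- element_materials(mesh, materials)
  tri <- mesh$triangles
  m <- nrow(tri)
  b <- cbind(g$b1, g$b2, g$b3)
  cc <- cbind(g$c1, g$c2, g$c3)
  scale <- thickness / (4 * g$area)
  dofx <- 2L * tri - 1L   # m x 3
  dofy <- 2L * tri
  ii <- jj <- integer(36L * m); xx <- numeric(36L * m)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    bi <- b[, i]; bj <- b[, j]; ci <- cc[, i]; cj <- cc[, j]
    vals <- list(
      list(dofx[, i], dofx[, j], mt$d11 * bi * bj + mt$d33 * ci * cj),
      list(dofx[, i], dofy[, j], mt$d12 * bi * cj + mt$d33 * ci * bj),
      list(dofy[, i], dofx[, j], mt$d12 * ci * bj + mt$d33 * bi * cj),
      list(dofy[, i], dofy[, j], mt$d11 * ci * cj + mt$d33 * bi * bj))
    for (v in vals) {
      idx <- k + seq_len(m)
      ii[idx] <- v[[1]]; jj[idx] <- v[[2]]; xx[idx] <- scale * v[[3]]
      k <- k + m
    }
  }
  ndof <- 2L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  structure(list(K = K, mesh = mesh, materials = materials,
                 thickness = thickness, ndof = ndof,
                 elem_geom = g, elem_mat = mt),
            class = "fe_system")
}

## Distribute a point load onto the three nodes of the nearest triangle with
## barycentric (affine) weights. Weights sum to 1 and are linear in the
## location, so total force and moment are conserved even slightly outside
## the mesh (extrapolated weights). Returns per-node force contributions.
distribute_point_load <- function(mesh, load) {
  p <- load$location
  d2 <- (mesh$centroid[, 1] - p[1])^2 + (mesh$centroid[, 2] - p[2])^2
  tri <- mesh$triangles[which.min(d2), ]
  v <- mesh$nodes[tri, , drop = FALSE]
  A <- rbind(t(v), c(1, 1, 1))
  w <- solve(A, c(p, 1))
  list(nodes = tri, fx = w * load$force[1], fy = w * load$force[2])
}

## Transfer a remote point load onto a node set as if connected rigidly
## (e.g. the implant neck carrying the joint force to the stem shoulder):
## minimal-norm nodal forces that reproduce the total force and the moment
## of the load about the node-set centroid.
distribute_load_rigid <- function(mesh, load, nodes) {
  r <- mesh$nodes[nodes, , drop = FALSE]
  rbar <- colMeans(r)
  d <- sweep(r, 2, rbar)
  n <- length(nodes)
  F <- load$force
  arm <- load$location - rbar
  m <- arm[1] * F[2] - arm[2] * F[1]       # z-moment about the set centroid
  denom <- sum(d^2)
  alpha <- if (denom > 0) m / denom else 0
  list(nodes = nodes,
       fx = F[1] / n - alpha * d[, 2],
       fy = F[2] / n + alpha * d[, 1])
}

## Nodes of the implant shoulder: implant-element nodes within `depth` of
## the most proximal implant node, measured along +y.
implant_top_nodes <- function(mesh, depth = 8) {
  imp <- unique(as.vector(mesh$triangles[mesh$region_tag == "IMPLANT", ]))
  if (!length(imp))
    stemshield_stop("no implant elements for load attachment", "solver_failure")
  ytop <- max(mesh$nodes[imp, 2])
  imp[mesh$nodes[imp, 2] >= ytop - depth]
}

#' Solve the constrained plane-stress system
#'
#' Fixed nodes (both displacement components) are eliminated; the reduced
#' SPD system is solved by sparse Cholesky factorization.
#'
#' @param system `fe_system` from [fe_assemble()].
#' @param load_case `load_case` from [build_load_case()], or a list with
#'   `loads` (list of `point_load`) and `fixed_boundary` (function of the
#'   node matrix returning fixed node indices).
#' @return `displacement_field`: `u` (n x 2, mm; zero at fixed nodes),
#'   `f` (global load vector, N), `fixed_nodes`, `residual` (relative),
#'   `external_work` (0.5 f.u, N*mm).
#' @export
fe_solve <- function(system, load_case) {
  mesh <- system$mesh
  fixed <- load_case$fixed_boundary(mesh$nodes)
  if (length(fixed) < 2)
    stemshield_stop("need >= 2 fixed nodes to remove rigid modes",
                    "solver_failure")
  ndof <- system$ndof
  f <- numeric(ndof)
  for (ld in load_case$loads) {
    di <- if (identical(ld$attach, "implant_top"))
      distribute_load_rigid(mesh, ld, implant_top_nodes(mesh))
    else distribute_point_load(mesh, ld)
    ix <- 2L * di$nodes - 1L
    f[ix] <- f[ix] + di$fx
    f[ix + 1L] <- f[ix + 1L] + di$fy
  }
  fixed_dof <- c(2L * fixed - 1L, 2L * fixed)
  free <- setdiff(seq_len(ndof), fixed_dof)
  Kff <- system$K[free, free]
  uf <- tryCatch(as.numeric(Matrix::solve(Kff, f[free])),
                 error = function(e)
                   stemshield_stop(paste("singular constrained system:",
                                         conditionMessage(e)),
                                   "solver_failure"))
  ## one step of iterative refinement keeps the relative residual near
  ## machine precision on ill-scaled multi-material systems
  r <- f[free] - as.numeric(Kff %*% uf)
  uf <- uf + as.numeric(Matrix::solve(Kff, r))
  u <- numeric(ndof)
  u[free] <- uf
  rnorm_f <- sqrt(sum(f^2))
  residual <- if (rnorm_f > 0)
    sqrt(sum((as.numeric(Kff %*% uf) - f[free])^2)) / rnorm_f else 0
  structure(list(u = matrix(u, ncol = 2, byrow = TRUE), f = f,
                 fixed_nodes = fixed, residual = residual,
                 external_work = 0.5 * sum(f * u)),
            class = "displacement_field")
}

element_strain_stress <- function(system, disp) {
  g <- system$elem_geom; mt <- system$elem_mat
  tri <- system$mesh$triangles
  ux <- disp$u[, 1]; uy <- disp$u[, 2]
  inv2A <- 1 / (2 * g$area)
  ex <- (g$b1 * ux[tri[, 1]] + g$b2 * ux[tri[, 2]] + g$b3 * ux[tri[, 3]]) * inv2A
  ey <- (g$c1 * uy[tri[, 1]] + g$c2 * uy[tri[, 2]] + g$c3 * uy[tri[, 3]]) * inv2A
  gxy <- (g$c1 * ux[tri[, 1]] + g$c2 * ux[tri[, 2]] + g$c3 * ux[tri[, 3]] +
          g$b1 * uy[tri[, 1]] + g$b2 * uy[tri[, 2]] + g$b3 * uy[tri[, 3]]) * inv2A
  sx <- mt$d11 * ex + mt$d12 * ey
  sy <- mt$d12 * ex + mt$d11 * ey
  txy <- mt$d33 * gxy
  list(ex = ex, ey = ey, gxy = gxy, sx = sx, sy = sy, txy = txy)
}

#' Per-element strain energy density
#'
#' `U = 0.5 * sigma : epsilon` under the plane-stress constitutive law,
#' reported in MPa (1 MPa = 10^6 J/m^3). Carries element centroid, area and
#' region tag for downstream aggregation.
#'
#' @param system `fe_system`.
#' @param disp `displacement_field` from [fe_solve()].
#' @return `sed_field`: data frame with `sed` (MPa), `von_mises` (MPa),
#'   `area` (mm^2), `cx`, `cy`, `region_tag`; attribute `total_energy`
#'   (N*mm) and `thickness`.
#' @export
strain_energy_density <- function(system, disp) {
  ss <- element_strain_stress(system, disp)
  U <- 0.5 * (ss$sx * ss$ex + ss$sy * ss$ey + ss$txy * ss$gxy)
  U[U < 0 & U > -1e-18] <- 0   # clip tiny negative round-off
  vm <- sqrt(ss$sx^2 + ss$sy^2 - ss$sx * ss$sy + 3 * ss$txy^2)
  mesh <- system$mesh
  out <- data.frame(sed = U, von_mises = vm, area = mesh$area,
                    cx = mesh$centroid[, 1], cy = mesh$centroid[, 2],
                    region_tag = mesh$region_tag,
                    stringsAsFactors = FALSE)
  attr(out, "total_energy") <- sum(U * mesh$area) * system$thickness
  attr(out, "thickness") <- system$thickness
  class(out) <- c("sed_field", "data.frame")
  out
}

#' Bone elements in the bone-implant interface band
#'
#' @param mesh `fe_mesh`.
#' @param placed `placed_stem`.
#' @param band_width band width in mm (default 3): bone elements whose
#'   centroid lies within this distance of the stem contour.
#' @return integer vector of element indices.
#' @export
interface_band <- function(mesh, placed, band_width = 3) {
  if (band_width <= 0)
    stemshield_stop("band width must be positive", "invalid_parameter")
  segs <- polygon_segments(placed$stem$contour)
  d <- .cpp_min_dist_to_segments(mesh$centroid, segs)
  which(mesh$region_tag != "IMPLANT" & d <= band_width)
}
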