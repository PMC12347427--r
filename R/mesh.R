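## Conforming constrained triangulation of the multi-material domain and the
## material table. The Delaunay kernel lives in src/delaunay.cpp; this file
## adds boundary densification, mutual splitting of crossing constraint
## contours, interior point seeding, constraint-edge recovery by midpoint
## insertion, region tagging by centroid, and maximum-area refinement.

REGION_TAGS <- c("CORTICAL", "CANCELLOUS", "IMPLANT")

pt_key <- function(pts) sprintf("%.6f|%.6f", pts[, 1], pts[, 2])

## Split every segment of A at its proper intersections with segments of B.
## Segments are n x 4 matrices (x1 y1 x2 y2).
split_segments_at <- function(A, B, eps = 1e-9) {
  out <- vector("list", nrow(A))
  qx <- B[, 1]; qy <- B[, 2]; sx <- B[, 3] - B[, 1]; sy <- B[, 4] - B[, 2]
  for (i in seq_len(nrow(A))) {
    px <- A[i, 1]; py <- A[i, 2]
    rx <- A[i, 3] - px; ry <- A[i, 4] - py
    denom <- rx * sy - ry * sx
    ok <- abs(denom) > 1e-12
    t <- u <- rep(NA_real_, nrow(B))
    t[ok] <- ((qx - px) * sy - (qy - py) * sx)[ok] / denom[ok]
    u[ok] <- ((qx - px) * ry - (qy - py) * rx)[ok] / denom[ok]
    hit <- ok & t > eps & t < 1 - eps & u > -eps & u < 1 + eps
    ts <- sort(unique(round(t[hit], 9)))
    if (!length(ts)) { out[[i]] <- A[i, , drop = FALSE]; next }
    brk <- c(0, ts, 1)
    segs <- matrix(NA_real_, length(brk) - 1L, 4L)
    for (k in seq_len(length(brk) - 1L)) {
      segs[k, ] <- c(px + brk[k] * rx, py + brk[k] * ry,
                     px + brk[k + 1] * rx, py + brk[k + 1] * ry)
    }
    out[[i]] <- segs
  }
  do.call(rbind, out)
}

seg_midpoints <- function(segs)
  cbind((segs[, 1] + segs[, 3]) / 2, (segs[, 2] + segs[, 4]) / 2)

## Delaunay with a deterministic symbolic-style perturbation: exactly
## collinear / cocircular inputs (equally spaced boundary points) make the
## incremental incircle test degenerate, so the triangulation runs on
## hash-jittered copies (~5e-8 h, far below any feature size) while all
## geometry downstream keeps the exact coordinates.
delaunay_perturbed <- function(pts, h) {
  amp <- 5e-8 * h
  jx <- amp * sin(pts[, 1] * 12345.678 + pts[, 2] * 987.654 + 0.123)
  jy <- amp * sin(pts[, 1] * 543.21 + pts[, 2] * 6789.123 + 0.456)
  .cpp_delaunay(cbind(pts[, 1] + jx, pts[, 2] + jy))
}

## Core mesher. `outer` bounds the domain; `regions` is an ordered list
## (highest priority first) of list(tag=, poly=); points outside every
## region get `base_tag`.
cdt_mesh <- function(outer, regions = list(), base_tag = "CORTICAL",
                     max_element_area = 1.0, jitter_seed = 42L) {
  if (max_element_area <= 0)
    stemshield_stop("max_element_area must be positive", "invalid_parameter")
  h <- sqrt(2 * max_element_area)
  hb <- 0.75 * h

  contours <- c(list(outer), lapply(regions, `[[`, "poly"))
  seglist <- lapply(contours, function(p) polygon_segments(densify_polygon(p, hb)))

  ## mutual splitting so no two constraint segments properly cross
  nset <- length(seglist)
  if (nset > 1) {
    for (i in seq_len(nset)) for (j in seq_len(nset)) if (i != j)
      seglist[[i]] <- split_segments_at(seglist[[i]], seglist[[j]])
    ## drop segments of lower-priority region boundaries buried inside a
    ## higher-priority region (e.g. endosteal boundary inside the implant)
    if (length(regions) > 1) {
      for (ri in 2:length(regions)) {
        idx <- ri + 1L
        keep <- rep(TRUE, nrow(seglist[[idx]]))
        for (rj in 1:(ri - 1L)) {
          keep <- keep & !points_in_polygon(seg_midpoints(seglist[[idx]]),
                                            regions[[rj]]$poly)
        }
        seglist[[idx]] <- seglist[[idx]][keep, , drop = FALSE]
      }
    }
  }
  segs <- do.call(rbind, seglist)

  ## constraint points
  cpts <- rbind(segs[, 1:2], segs[, 3:4])
  cpts <- cpts[!duplicated(pt_key(cpts)), , drop = FALSE]

  ## interior seeding: jittered hexagonal lattice, clear of constraints
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(jitter_seed)
  bb <- apply(outer, 2, range)
  xs <- seq(bb[1, 1] + h / 2, bb[2, 1], by = h)
  ys <- seq(bb[1, 2] + h / 2, bb[2, 2], by = 0.866 * h)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  odd <- (round((grid[, 2] - ys[1]) / (0.866 * h)) %% 2) == 1
  grid[odd, 1] <- grid[odd, 1] + h / 2
  grid <- grid + matrix(stats::runif(2 * nrow(grid), -0.05 * h, 0.05 * h),
                        ncol = 2)
  keep <- points_in_polygon(grid, outer)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid)) {
    d <- .cpp_min_dist_to_segments(grid, segs)
    grid <- grid[d > 0.55 * h, , drop = FALSE]
  }

  pts <- rbind(cpts, grid)
  pts <- pts[!duplicated(pt_key(pts)), , drop = FALSE]

  ## constraint segments as coordinate pairs -> recovered by midpoint
  ## insertion until each is an edge of the Delaunay triangulation
  for (iter in 1:12) {
    tri <- delaunay_perturbed(pts, h)
    key <- pt_key(pts)
    idx <- function(m) match(pt_key(m), key)
    e1 <- idx(segs[, 1:2]); e2 <- idx(segs[, 3:4])
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    tedges <- c(ekey(tri[, 1], tri[, 2]), ekey(tri[, 2], tri[, 3]),
                ekey(tri[, 3], tri[, 1]))
    missing <- which(is.na(e1) | is.na(e2) | !(ekey(e1, e2) %in% tedges))
    if (!length(missing)) break
    mids <- seg_midpoints(segs[missing, , drop = FALSE])
    newsegs <- rbind(cbind(segs[missing, 1:2, drop = FALSE], mids),
                     cbind(mids, segs[missing, 3:4, drop = FALSE]))
    segs <- rbind(segs[-missing, , drop = FALSE], newsegs)
    pts <- rbind(pts, mids)
    pts <- pts[!duplicated(pt_key(pts)), , drop = FALSE]
  }

  build <- function(pts, tri) {
    x1 <- pts[tri[, 1], 1]; y1 <- pts[tri[, 1], 2]
    x2 <- pts[tri[, 2], 1]; y2 <- pts[tri[, 2], 2]
    x3 <- pts[tri[, 3], 1]; y3 <- pts[tri[, 3], 2]
    area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
    cen <- cbind((x1 + x2 + x3) / 3, (y1 + y2 + y3) / 3)
    list(area = area, cen = cen)
  }

  ## area refinement: insert centroids of oversized interior triangles
  for (ref in 1:6) {
    g <- build(pts, tri)
    inside <- points_in_polygon(g$cen, outer)
    big <- which(inside & g$area > max_element_area & g$area > 1e-9)
    if (!length(big)) break
    pts <- rbind(pts, g$cen[big, , drop = FALSE])
    pts <- pts[!duplicated(pt_key(pts)), , drop = FALSE]
    tri <- delaunay_perturbed(pts, h)
  }

  g <- build(pts, tri)
  keep <- g$area > 1e-9 & points_in_polygon(g$cen, outer)
  tri <- tri[keep, , drop = FALSE]
  area <- g$area[keep]; cen <- g$cen[keep, , drop = FALSE]

  ## region tagging by centroid, highest priority region first; centroids
  ## within 1e-9 of a region boundary are nudged towards the incenter
  tag <- rep(base_tag, nrow(tri))
  if (length(regions)) {
    test_pt <- cen
    allsegs <- segs
    d <- .cpp_min_dist_to_segments(cen, allsegs)
    close <- which(d < 1e-9)
    if (length(close)) {
      for (ci in close) {
        v <- pts[tri[ci, ], , drop = FALSE]
        el <- sqrt(rowSums((v[c(2, 3, 1), ] - v)^2)) # |ab|,|bc|,|ca|
        wgt <- c(el[2], el[3], el[1]); wgt <- wgt / sum(wgt)
        inc <- colSums(v * wgt)
        test_pt[ci, ] <- 0.999 * cen[ci, ] + 0.001 * inc
      }
    }
    assigned <- rep(FALSE, nrow(tri))
    for (rg in regions) {
      hit <- !assigned & points_in_polygon(test_pt, rg$poly)
      tag[hit] <- rg$tag
      assigned <- assigned | hit
    }
  }

  structure(list(nodes = pts, triangles = tri, region_tag = tag,
                 area = area, centroid = cen,
                 max_element_area = max_element_area, h = h),
            class = "fe_mesh")
}

#' Triangulate a single polygonal region
#'
#' Convenience mesher for benchmark domains (patch test, cantilever).
#'
#' @param poly CCW polygon matrix.
#' @param max_element_area maximum triangle area, mm^2.
#' @param tag region tag for every element.
#' @return `fe_mesh` object.
#' @export
triangulate_polygon <- function(poly, max_element_area = 1.0,
                                tag = "CORTICAL") {
  validate_contour(poly)
  cdt_mesh(orient_ccw(poly), regions = list(), base_tag = tag,
           max_element_area = max_element_area)
}

#' Triangulate a femur with a placed stem
#'
#' Multi-material conforming mesh: cortical shell, cancellous interior,
#' implant. Region boundaries (periosteal, endosteal, stem contours) are
#' preserved as mesh edges; element tags are assigned by centroid with the
#' implant taking priority over the cancellous region where the stem
#' penetrates the endosteal boundary.
#'
#' @param femur `femur_geometry`.
#' @param placed `placed_stem`, or `NULL` for an intact (implant-free) bone.
#' @param max_element_area maximum triangle area, mm^2 (default 1.0:
#'   roughly 10^4 elements, desk-scale solve).
#' @return `fe_mesh` object.
#' @export
triangulate <- function(femur, placed = NULL, max_element_area = 1.0) {
  regions <- list()
  if (!is.null(placed))
    regions <- c(regions, list(list(tag = "IMPLANT", poly = placed$stem$contour)))
  regions <- c(regions, list(list(tag = "CANCELLOUS", poly = femur$endosteal)))
  mesh <- tryCatch(
    cdt_mesh(femur$periosteal, regions = regions, base_tag = "CORTICAL",
             max_element_area = max_element_area),
    error = function(e) {
      if (inherits(e, "stemshield_error")) stop(e)
      stemshield_stop(paste("meshing failure:", conditionMessage(e)),
                      "meshing_failure")
    })
  mesh
}

#' Default material table
#'
#' Homogeneous linear-elastic material classes. The source study cites an
#' external material reference without printing values; these defaults are
#' standard literature values and are fully overridable.
#'
#' @param overrides nested list, e.g.
#'   `list(CANCELLOUS = list(youngs_modulus = 800))`.
#' @return named list per region with `youngs_modulus` (MPa),
#'   `poisson_ratio`, `density` (kg/m^3).
#' @export
default_materials <- function(overrides = list()) {
  mat <- list(
    CORTICAL   = list(youngs_modulus = 17000, poisson_ratio = 0.3, density = 1800),
    CANCELLOUS = list(youngs_modulus = 1000,  poisson_ratio = 0.3, density = 600),
    IMPLANT    = list(youngs_modulus = 110000, poisson_ratio = 0.3, density = 4500))
  for (k in names(overrides))
    mat[[k]] <- utils::modifyList(mat[[k]], overrides[[k]])
  for (k in names(mat)) {
    m <- mat[[k]]
    if (m$youngs_modulus <= 0)
      stemshield_stop("Young's modulus must be positive", "invalid_parameter")
    if (m$poisson_ratio <= 0 || m$poisson_ratio >= 0.5)
      stemshield_stop("Poisson ratio must be in (0, 0.5)", "invalid_parameter")
    if (m$density <= 0)
      stemshield_stop("density must be positive", "invalid_parameter")
  }
  mat
}

## Edge/triangle incidence: every edge must belong to at most 2 triangles.
mesh_edge_incidence <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Write a mesh and cell fields to a legacy ASCII VTK file
#'
#' @param mesh `fe_mesh`.
#' @param path output file path (`.vtk`).
#' @param cell_data named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               "stemshield mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  fields <- c(list(region = as.numeric(factor(mesh$region_tag,
                                              levels = REGION_TAGS))),
              cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.9g", fields[[nm]]), con)
  }
  invisible(path)
}
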