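#' @useDynLib atriumkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Assemble per-view fragments into one oriented point cloud
#'
#' Concatenates the fragments and verifies that the pooled points are not all
#' coplanar (a single imaging plane cannot constrain a 3D surface). Rank is
#' assessed from the singular values of the centred point matrix.
#'
#' @param fragments List of [oriented_points()] fragments (empty ones ignored).
#' @param frame Optional frame index used in error messages.
#' @return An [oriented_points()] cloud with N >= 4 non-coplanar points.
#' @export
assemble_cloud <- function(fragments, frame = NULL) {
  fragments <- Filter(function(f) nrow(f$points_mm) > 0, fragments)
  if (length(fragments) == 0) stop("no points: all fragments are empty")
  pts <- do.call(rbind, lapply(fragments, `[[`, "points_mm"))
  nrm <- do.call(rbind, lapply(fragments, `[[`, "normals"))
  if (nrow(pts) < 4) stop("need at least 4 points for reconstruction")
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] <= 1e-7 * sv[1])
    stop("reconstruction impossible",
         if (!is.null(frame)) paste0(" at frame ", frame),
         ": all points are coplanar")
  oriented_points(pts, nrm)
}

# ---- separable tensor operations on a cubic grid ---------------------------

# multiply matrix M (n x n) along the given axis of a 3D array
tensor_mult <- function(A, M, axis) {
  d <- dim(A)
  perm <- c(axis, setdiff(1:3, axis))
  Ap <- aperm(A, perm)
  B <- M %*% matrix(Ap, nrow = d[axis])
  dim(B) <- d[perm]
  aperm(B, order(perm))
}

# type-I discrete sine transform matrix (its own inverse up to 2/(n+1))
dst_matrix <- function(n) {
  k <- seq_len(n)
  sin(pi * outer(k, k) / (n + 1))
}

# solve the 7-point discrete Poisson equation lap(u) = f with zero Dirichlet
# values just outside the grid, by sine-transform diagonalisation
poisson_solve_dirichlet <- function(f, h) {
  n <- dim(f)[1]
  S <- dst_matrix(n)
  lam <- 2 * cos(pi * seq_len(n) / (n + 1)) - 2
  fh <- tensor_mult(tensor_mult(tensor_mult(f, S, 1), S, 2), S, 3)
  den <- (outer(outer(lam, lam, "+"), lam, "+")) / h^2
  uh <- fh / den
  u <- tensor_mult(tensor_mult(tensor_mult(uh, S, 1), S, 2), S, 3)
  u * (2 / (n + 1))^3
}

# banded Gaussian convolution matrix with zero extension beyond the grid
gaussian_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  m <- ceiling(4 * sigma)
  k <- stats::dnorm(-m:m, sd = sigma)
  k <- k / sum(k)
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  G <- matrix(0, n, n)
  G[idx <= m] <- k[idx[idx <= m] + m + 1]
  G
}

smooth_gaussian3 <- function(A, sigma) {
  if (sigma <= 0) return(A)
  G <- gaussian_conv_matrix(dim(A)[1], sigma)
  tensor_mult(tensor_mult(tensor_mult(A, G, 1), G, 2), G, 3)
}

# scatter values into a cubic grid with trilinear weights; g is N x 3 of
# 0-based fractional grid coordinates, vals an N-vector
splat_trilinear <- function(n, g, vals) {
  i0 <- pmin(pmax(floor(g), 0), n - 2)
  fr <- g - i0
  acc <- numeric(n^3)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- 1 + (i0[, 1] + dx) + n * (i0[, 2] + dy) + n^2 * (i0[, 3] + dz)
    s <- rowsum(w * vals, idx)
    ii <- as.integer(rownames(s))
    acc[ii] <- acc[ii] + s[, 1]
  }
  array(acc, dim = c(n, n, n))
}

# gather: trilinear interpolation of a cubic grid at 0-based coordinates
sample_trilinear <- function(A, g) {
  n <- dim(A)[1]
  i0 <- pmin(pmax(floor(g), 0), n - 2)
  fr <- g - i0
  out <- numeric(nrow(g))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- 1 + (i0[, 1] + dx) + n * (i0[, 2] + dy) + n^2 * (i0[, 3] + dz)
    out <- out + w * A[idx]
  }
  out
}

# central-difference divergence with zero extension, spacing h
divergence3 <- function(Vx, Vy, Vz, h) {
  n <- dim(Vx)[1]
  d <- function(A, axis) {
    Ap <- array(0, dim(A)); Am <- array(0, dim(A))
    idx <- seq_len(n)
    if (axis == 1) { Ap[idx[-n], , ] <- A[idx[-1], , ]; Am[idx[-1], , ] <- A[idx[-n], , ] }
    if (axis == 2) { Ap[, idx[-n], ] <- A[, idx[-1], ]; Am[, idx[-1], ] <- A[, idx[-n], ] }
    if (axis == 3) { Ap[, , idx[-n]] <- A[, , idx[-1]]; Am[, , idx[-1]] <- A[, , idx[-n]] }
    (Ap - Am) / (2 * h)
  }
  d(Vx, 1) + d(Vy, 2) + d(Vz, 3)
}

#' Poisson indicator-function solve on a regular grid
#'
#' Reconstructs the chamber indicator function chi from an oriented point
#' cloud: the (inward-pointing) normal field is splatted trilinearly onto a
#' cubic grid, smoothed with a Gaussian, and chi is obtained by solving the
#' Poisson equation `lap(chi) = div(V)` with zero-Dirichlet boundary using an
#' exact sine-transform solver. The iso-value is the mean of chi sampled at
#' the input points, mirroring the standard convention.
#'
#' Because the points sample the surface only along the plane-intersection
#' curves, each point's contribution is weighted by the inverse of the local
#' point density (estimated on the same grid), so densely sampled curves do
#' not dominate the field.
#'
#' @param cloud An [oriented_points()] cloud (non-coplanar, N >= 4).
#' @param grid_res Grid resolution per axis (>= 16); default 96.
#' @param smoothing_sigma_vox Gaussian width in voxels; default 1.5.
#' @param padding_frac Bounding-box padding fraction per side; default 0.25.
#' @param density_normalize Weight points by inverse local density (default).
#' @return An object of class `indicator_grid` with fields `chi` (R x R x R),
#'   `grid_origin_mm`, `voxel_mm` and `iso_value`.
#' @export
poisson_indicator <- function(cloud, grid_res = 96, smoothing_sigma_vox = 1.5,
                              padding_frac = 0.25, density_normalize = TRUE) {
  stopifnot(inherits(cloud, "oriented_points"))
  if (grid_res < 16) stop("grid_res must be >= 16")
  pts <- cloud$points_mm
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  ext <- hi - lo
  side <- max(ext * (1 + 2 * padding_frac))
  if (side <= 0) stop("degenerate point cloud: zero extent")
  ctr <- (lo + hi) / 2
  origin <- ctr - side / 2
  h <- side / (grid_res - 1)
  g <- sweep(pts, 2, origin) / h
  if (any(g < 0.999) || any(g > grid_res - 1.999))
    warning("grid too small to separate the surface from the boundary")

  wts <- rep(1, nrow(pts))
  if (density_normalize) {
    D <- splat_trilinear(grid_res, g, wts)
    D <- smooth_gaussian3(D, smoothing_sigma_vox)
    rho <- sample_trilinear(D, g)
    wts <- 1 / pmax(rho, 1e-12)
  }
  # indicator gradient points inward: splat minus the outward normals
  Vx <- smooth_gaussian3(splat_trilinear(grid_res, g, -cloud$normals[, 1] * wts),
                         smoothing_sigma_vox)
  Vy <- smooth_gaussian3(splat_trilinear(grid_res, g, -cloud$normals[, 2] * wts),
                         smoothing_sigma_vox)
  Vz <- smooth_gaussian3(splat_trilinear(grid_res, g, -cloud$normals[, 3] * wts),
                         smoothing_sigma_vox)
  f <- divergence3(Vx, Vy, Vz, h)
  chi <- poisson_solve_dirichlet(f, h)
  if (any(!is.finite(chi)))
    stop("Poisson solve failed: non-finite values in the indicator field ",
         "(grid_res = ", grid_res, ", n_points = ", nrow(pts), ")")
  iso <- mean(sample_trilinear(chi, g))
  structure(list(chi = chi, grid_origin_mm = origin, voxel_mm = h,
                 iso_value = iso),
            class = "indicator_grid")
}

#' Triangle mesh
#'
#' @param vertices_mm V x 3 matrix of vertex coordinates (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices_mm, faces) {
  vertices_mm <- as.matrix(vertices_mm)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices_mm) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices_mm)))
    stop("face indices out of range")
  structure(list(vertices_mm = vertices_mm, faces = faces),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh>", nrow(x$vertices_mm), "vertices,",
      nrow(x$faces), "faces\n")
  invisible(x)
}

# open (count != 2) undirected edges of a mesh; empty matrix when watertight
open_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab != 2]
  if (length(bad) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(strsplit(bad, " "), as.integer))
}

#' Extract the iso-surface of an indicator grid as a triangle mesh
#'
#' The iso-surface at `iso_value` is extracted by marching tetrahedra (each
#' grid cube split into six tetrahedra, which yields a watertight,
#' consistently oriented mesh with no ambiguous cases); vertices are mapped to
#' mm coordinates, orientation is fixed so the signed volume is positive, and
#' only the largest connected component is retained (with a warning when
#' additional components were present).
#'
#' @param grid An `indicator_grid` from [poisson_indicator()].
#' @param iso Iso-value; defaults to the grid's `iso_value`.
#' @param keep_largest Retain only the largest connected component (default).
#' @return A [tri_mesh()].
#' @export
extract_mesh <- function(grid, iso = grid$iso_value, keep_largest = TRUE) {
  stopifnot(inherits(grid, "indicator_grid"))
  rng <- range(grid$chi)
  if (!(iso > rng[1] && iso < rng[2]))
    stop("iso value ", format(iso), " is not strictly inside the field range [",
         format(rng[1]), ", ", format(rng[2]), "]")
  mt <- marching_tets(grid$chi, iso)
  if (nrow(mt$faces) == 0) stop("reconstruction failed: empty iso-surface")
  verts <- sweep(mt$vertices * grid$voxel_mm, 2, grid$grid_origin_mm, "+")
  faces <- mt$faces
  if (keep_largest) {
    gr <- igraph::graph_from_edgelist(
      rbind(faces[, c(1, 2)], faces[, c(2, 3)]), directed = FALSE)
    comp <- igraph::components(gr)$membership
    fcomp <- comp[faces[, 1]]
    keep_id <- as.integer(names(which.max(table(fcomp))))
    if (length(unique(fcomp)) > 1)
      warning("iso-surface has ", length(unique(fcomp)),
              " components; only the largest is retained")
    faces <- faces[fcomp == keep_id, , drop = FALSE]
    used <- sort(unique(as.vector(faces)))
    remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
    verts <- verts[used, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3)
  }
  m <- tri_mesh(verts, faces)
  if (signed_volume_mm3(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# divergence-theorem signed volume in mm^3 (positive for outward orientation)
signed_volume_mm3 <- function(mesh) {
  v <- mesh$vertices_mm; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Volume enclosed by a watertight triangle mesh, in mL
#'
#' @param mesh A watertight, consistently oriented [tri_mesh()] in mm units.
#' @return Enclosed volume in mL (1 mL = 1000 mm^3).
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  oe <- open_edges(mesh)
  if (nrow(oe) > 0)
    stop("mesh is not watertight; ", nrow(oe), " open edge(s), e.g. ",
         paste(utils::head(apply(oe, 1, paste, collapse = "-"), 5),
               collapse = ", "))
  signed_volume_mm3(mesh) / 1000
}

#' Volume trace over the cardiac cycle
#'
#' @param volumes_ml Numeric vector of per-frame volumes (mL); NA marks a
#'   frame whose reconstruction failed.
#' @param status Optional character vector of per-frame status messages.
#' @return An object of class `volume_trace`.
#' @export
volume_trace <- function(volumes_ml, status = NULL) {
  volumes_ml <- as.numeric(volumes_ml)
  if (is.null(status)) status <- ifelse(is.na(volumes_ml), "failed", "ok")
  stopifnot(length(status) == length(volumes_ml))
  structure(list(volumes_ml = volumes_ml, status = status,
                 n_frames = length(volumes_ml)),
            class = "volume_trace")
}

#' @export
print.volume_trace <- function(x, ...) {
  ok <- !is.na(x$volumes_ml)
  cat("<volume_trace>", x$n_frames, "frames,", sum(!ok), "failed\n")
  if (any(ok))
    cat(sprintf("  volume range %.1f - %.1f mL\n",
                min(x$volumes_ml[ok]), max(x$volumes_ml[ok])))
  invisible(x)
}

#' Reconstruct a volume trace from multi-view cine segmentations
#'
#' Runs the per-frame pipeline (fragments -> cloud -> indicator -> mesh ->
#' volume) across all frames. A frame whose reconstruction fails carries an
#' NA volume and its error message in the status field; if no frame offers at
#' least two distinct plane orientations the whole study fails.
#'
#' @param views List of [cine_segmentation()] objects sharing a frame count.
#' @param grid_res,smoothing_sigma,padding Reconstruction parameters passed to
#'   [poisson_indicator()].
#' @return A [volume_trace()].
#' @export
reconstruct_trace <- function(views, grid_res = 96, smoothing_sigma = 1.5,
                              padding = 0.25) {
  stopifnot(length(views) >= 1,
            all(vapply(views, inherits, TRUE, "cine_segmentation")))
  nf <- unique(vapply(views, `[[`, 1L, "n_frames"))
  if (length(nf) != 1) stop("views disagree on frame count")
  normals <- lapply(views, function(v) round(plane_normal(v$geometry), 6))
  n_orient <- length(unique(lapply(normals, function(n) {
    if (sum(n * c(1, 1, 1)) < 0) n <- -n  # identify antiparallel planes
    paste(n, collapse = ",")
  })))
  if (n_orient < 2)
    stop("fewer than 2 distinct plane orientations: reconstruction impossible")

  vols <- rep(NA_real_, nf)
  status <- rep("ok", nf)
  for (t in seq_len(nf)) {
    res <- tryCatch({
      frags <- list()
      for (v in views) {
        if (sum(v$masks[, , t]) > 0)
          frags[[length(frags) + 1]] <- fragment_from_mask(frame_mask(v, t))
      }
      cloud <- assemble_cloud(frags, frame = t)
      grid <- poisson_indicator(cloud, grid_res = grid_res,
                                smoothing_sigma_vox = smoothing_sigma,
                                padding_frac = padding)
      mesh <- suppressWarnings(extract_mesh(grid))
      mesh_volume(mesh)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[t] <- paste("failed:", conditionMessage(res))
    } else {
      vols[t] <- res
    }
  }
  volume_trace(vols, status)
}
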