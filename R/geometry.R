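#' Plane geometry in the patient coordinate system
#'
#' Describes how a 2D image grid is embedded in 3D patient coordinates, using
#' the DICOM convention: `row_cosine` is the unit direction of increasing
#' column index (the first Image Orientation (Patient) triplet), `col_cosine`
#' the unit direction of increasing row index (the second triplet), and
#' `origin_mm` the position of the centre of pixel (0, 0) (the Image Position
#' (Patient) tag).
#'
#' @param origin_mm Numeric 3-vector, position of pixel (0,0) centre in mm.
#' @param row_cosine Unit 3-vector, direction of increasing column index.
#' @param col_cosine Unit 3-vector, direction of increasing row index.
#' @param spacing_mm Numeric pair: (between-rows, between-columns) spacing, mm.
#' @param thickness_mm Slice thickness in mm (>= 0).
#' @param view Optional view label, e.g. `"lax_2ch"`, `"sax_3"`.
#' @return An object of class `plane_geometry`.
#' @export
plane_geometry <- function(origin_mm, row_cosine, col_cosine,
                           spacing_mm, thickness_mm = 0, view = NULL) {
  origin_mm <- as.numeric(origin_mm)
  row_cosine <- as.numeric(row_cosine)
  col_cosine <- as.numeric(col_cosine)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(origin_mm) == 3, length(row_cosine) == 3,
            length(col_cosine) == 3, length(spacing_mm) == 2)
  if (abs(sqrt(sum(row_cosine^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(col_cosine^2)) - 1) > 1e-9)
    stop("direction cosines must have unit length (tolerance 1e-9)")
  if (abs(sum(row_cosine * col_cosine)) > 1e-6)
    stop("row_cosine and col_cosine must be orthogonal (tolerance 1e-6)")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (thickness_mm < 0) stop("thickness_mm must be >= 0")
  structure(list(origin_mm = origin_mm, row_cosine = row_cosine,
                 col_cosine = col_cosine, spacing_mm = spacing_mm,
                 thickness_mm = thickness_mm, view = view),
            class = "plane_geometry")
}

#' @export
print.plane_geometry <- function(x, ...) {
  cat("<plane_geometry>", if (!is.null(x$view)) paste0("view=", x$view), "\n")
  cat("  origin (mm):", format(x$origin_mm, digits = 6), "\n")
  cat("  spacing (mm):", format(x$spacing_mm, digits = 4),
      " thickness (mm):", format(x$thickness_mm, digits = 4), "\n")
  invisible(x)
}

#' Unit normal of an imaging plane
#'
#' @param geom A [plane_geometry()].
#' @return Unit 3-vector orthogonal to the view plane.
#' @export
plane_normal <- function(geom) {
  n <- c(geom$row_cosine[2] * geom$col_cosine[3] - geom$row_cosine[3] * geom$col_cosine[2],
         geom$row_cosine[3] * geom$col_cosine[1] - geom$row_cosine[1] * geom$col_cosine[3],
         geom$row_cosine[1] * geom$col_cosine[2] - geom$row_cosine[2] * geom$col_cosine[1])
  n / sqrt(sum(n^2))
}

#' Binary segmentation mask on an imaging plane
#'
#' @param pixels Integer/logical H x W matrix with values in \{0, 1\}.
#' @param geometry A [plane_geometry()] locating the grid in patient space.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(pixels, geometry) {
  if (is.logical(pixels)) pixels <- pixels + 0L
  pixels <- as.matrix(pixels)
  if (!all(pixels %in% c(0, 1))) stop("mask pixels must be binary (0/1)")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("mask must be at least 1x1")
  stopifnot(inherits(geometry, "plane_geometry"))
  structure(list(pixels = pixels, geometry = geometry),
            class = "segmentation_mask")
}

#' Map pixel indices to patient coordinates
#'
#' Applies the DICOM pixel-to-patient mapping
#' `P = origin + col * spacing[2] * row_cosine + row * spacing[1] * col_cosine`
#' with 0-based indices and the pixel-centre convention.
#'
#' @param row,col 0-based pixel indices (vectors of equal length).
#' @param geom A [plane_geometry()].
#' @param H,W Optional grid dimensions for range checking.
#' @return N x 3 matrix of patient coordinates in mm.
#' @export
pixel_to_patient <- function(row, col, geom, H = NULL, W = NULL) {
  if (length(row) != length(col)) stop("row and col must have equal length")
  if (any(row < 0) || any(col < 0)) stop("pixel index out of range")
  if (!is.null(H) && any(row >= H)) stop("pixel row index out of range")
  if (!is.null(W) && any(col >= W)) stop("pixel col index out of range")
  outer(rep(1, length(row)), geom$origin_mm) +
    outer(col * geom$spacing_mm[2], geom$row_cosine) +
    outer(row * geom$spacing_mm[1], geom$col_cosine)
}

# binary erosion by shifting; pixels outside the grid count as background
erode_binary <- function(px, structuring = c("cross", "square")) {
  structuring <- match.arg(structuring)
  H <- nrow(px); W <- ncol(px)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, H, W)
    rs <- seq_len(H); cs <- seq_len(W)
    rsrc <- rs - dr; csrc <- cs - dc
    ok_r <- rsrc >= 1 & rsrc <= H; ok_c <- csrc >= 1 & csrc <= W
    out[rs[ok_r], cs[ok_c]] <- m[rsrc[ok_r], csrc[ok_c]]
    out
  }
  offs <- if (structuring == "cross") {
    list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    expand_offs <- expand.grid(dr = -1:1, dc = -1:1)
    lapply(seq_len(nrow(expand_offs)),
           function(i) c(expand_offs$dr[i], expand_offs$dc[i]))
  }
  out <- matrix(1L, H, W)
  for (o in offs) out <- out * shift(px, o[1], o[2])
  out
}

#' Extract the perimeter of a binary mask
#'
#' The perimeter is the mask minus its binary erosion; by default the erosion
#' uses the 3x3 cross (4-connectivity) structuring element.
#'
#' @param mask A [segmentation_mask()].
#' @param structuring `"cross"` (default) or `"square"` structuring element.
#' @return A [segmentation_mask()] containing only the perimeter pixels.
#' @export
extract_perimeter <- function(mask, structuring = c("cross", "square")) {
  stopifnot(inherits(mask, "segmentation_mask"))
  er <- erode_binary(mask$pixels, match.arg(structuring))
  segmentation_mask(mask$pixels * (1L - er), mask$geometry)
}

#' Oriented boundary points from one view's mask
#'
#' Perimeter pixels are mapped into patient coordinates; each point's normal
#' is the unit vector from the 3D centroid of all segmented pixels of the mask
#' to the point, projected onto the view plane and renormalised, so that
#' normals point radially outwards and lie in the imaging plane. A perimeter
#' point coincident with the centroid has no defined direction and is dropped
#' with a warning.
#'
#' @param mask A non-empty [segmentation_mask()].
#' @param structuring Structuring element for the perimeter extraction.
#' @return An object of class `oriented_points` with fields `points_mm`
#'   (N x 3), `normals` (N x 3, unit, in-plane) and `source_view`.
#' @export
fragment_from_mask <- function(mask, structuring = c("cross", "square")) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (sum(mask$pixels) == 0) stop("empty mask: no segmented pixels")
  geom <- mask$geometry
  all_idx <- which(mask$pixels == 1, arr.ind = TRUE)
  all_pts <- pixel_to_patient(all_idx[, 1] - 1, all_idx[, 2] - 1, geom)
  centroid <- colMeans(all_pts)

  per <- extract_perimeter(mask, structuring)
  per_idx <- which(per$pixels == 1, arr.ind = TRUE)
  pts <- pixel_to_patient(per_idx[, 1] - 1, per_idx[, 2] - 1, geom)

  pn <- plane_normal(geom)
  d <- pts - outer(rep(1, nrow(pts)), centroid)
  # project onto the view plane (numerically a no-op when points are in-plane)
  d <- d - outer(drop(d %*% pn), pn)
  len <- sqrt(rowSums(d^2))
  keep <- len > 1e-9
  if (any(!keep))
    warning(sum(!keep), " perimeter point(s) coincident with the centroid dropped")
  pts <- pts[keep, , drop = FALSE]
  normals <- d[keep, , drop = FALSE] / len[keep]
  oriented_points(pts, normals, source_view = geom$view)
}

#' Oriented point set
#'
#' @param points_mm N x 3 matrix of positions in mm.
#' @param normals N x 3 matrix of unit normals.
#' @param source_view Optional view label.
#' @return An object of class `oriented_points`.
#' @export
oriented_points <- function(points_mm, normals, source_view = NULL) {
  points_mm <- as.matrix(points_mm); normals <- as.matrix(normals)
  if (nrow(points_mm) > 0) {
    stopifnot(ncol(points_mm) == 3, ncol(normals) == 3,
              nrow(points_mm) == nrow(normals))
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-9)) stop("normals must have unit length")
  }
  structure(list(points_mm = points_mm, normals = normals,
                 source_view = source_view),
            class = "oriented_points")
}

#' @export
print.oriented_points <- function(x, ...) {
  cat("<oriented_points> n =", nrow(x$points_mm),
      if (!is.null(x$source_view)) paste0("view=", x$source_view), "\n")
  invisible(x)
}

#' Cine segmentation: one view's mask stack over the cardiac cycle
#'
#' @param masks H x W x T array of binary masks (one slice per frame).
#' @param geometry A [plane_geometry()] shared by all frames.
#' @param view Optional view label (defaults to the geometry's).
#' @return An object of class `cine_segmentation`.
#' @export
cine_segmentation <- function(masks, geometry, view = NULL) {
  masks <- as.array(masks)
  if (length(dim(masks)) == 2) dim(masks) <- c(dim(masks), 1)
  stopifnot(length(dim(masks)) == 3, inherits(geometry, "plane_geometry"))
  if (!all(masks %in% c(0, 1))) stop("masks must be binary (0/1)")
  if (is.null(view)) view <- geometry$view
  structure(list(masks = masks, geometry = geometry, view = view,
                 n_frames = dim(masks)[3]),
            class = "cine_segmentation")
}

#' @export
print.cine_segmentation <- function(x, ...) {
  d <- dim(x$masks)
  cat("<cine_segmentation>", if (!is.null(x$view)) paste0("view=", x$view),
      sprintf("%dx%d pixels, %d frames\n", d[1], d[2], d[3]))
  invisible(x)
}

# single-frame mask of a cine as a segmentation_mask
frame_mask <- function(cine, t) {
  segmentation_mask(cine$masks[, , t], cine$geometry)
}
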