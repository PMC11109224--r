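#' Number of connected foreground components of a mask
#'
#' @param mask A [segmentation_mask()] or a binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer component count (0 for an empty mask).
#' @export
count_components <- function(mask, connectivity = 8) {
  px <- if (inherits(mask, "segmentation_mask")) mask$pixels else as.matrix(mask)
  stopifnot(connectivity %in% c(4, 8))
  fg <- which(px == 1)
  if (length(fg) == 0) return(0L)
  H <- nrow(px); W <- ncol(px)
  id <- matrix(NA_integer_, H, W)
  id[fg] <- seq_along(fg)
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  edges <- NULL
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- seq_len(H - abs(dr)); c1 <- if (dc >= 0) seq_len(W - dc) else seq(1 - dc, W)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) edges <- rbind(edges, cbind(a[ok], b[ok]))
  }
  if (is.null(edges))
    return(length(fg))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  as.integer(igraph::components(g)$no)
}

#' Population statistics of maximum frame-to-frame pixel deltas
#'
#' Summarises, over a cohort of studies, the maximum absolute frame-to-frame
#' change in segmented pixel count; the frame-jump QC flag compares each
#' study's maximum delta against `mean + 5 * sd` of these.
#'
#' @param max_deltas Numeric vector: one maximum delta per study (n >= 2).
#' @return An object of class `population_delta_stats`.
#' @export
population_delta_stats <- function(max_deltas) {
  max_deltas <- as.numeric(max_deltas)
  if (length(max_deltas) < 2) stop("need at least 2 studies for population stats")
  structure(list(mean_of_max_delta = mean(max_deltas),
                 sd_of_max_delta = stats::sd(max_deltas),
                 n_studies = length(max_deltas)),
            class = "population_delta_stats")
}

# per-frame pixel counts of a cine view
frame_pixel_counts <- function(cine) {
  apply(cine$masks, 3, sum)
}

#' Quality-control flags for one cine segmentation
#'
#' Implements four heuristics: (a) more than one connected component in any
#' frame; (b) the maximum frame-to-frame change in segmented pixel count
#' exceeds five population standard deviations beyond the population mean;
#' (c) any frame with zero segmented pixels; (d) frame count differs from the
#' expected number (50).
#'
#' @param cine A [cine_segmentation()].
#' @param pop A [population_delta_stats()] object, or NULL (frame-jump flag is
#'   then NA).
#' @param expected_frames Expected frame count, default 50.
#' @param connectivity Connectivity used for component counting (default 8).
#' @return An object of class `qc_report` with the four flags, the maximum
#'   frame delta and per-frame component counts.
#' @export
qc_flags <- function(cine, pop = NULL, expected_frames = 50, connectivity = 8) {
  stopifnot(inherits(cine, "cine_segmentation"))
  if (!is.null(pop)) stopifnot(inherits(pop, "population_delta_stats"))
  counts <- frame_pixel_counts(cine)
  comp <- vapply(seq_len(cine$n_frames), function(t)
    count_components(cine$masks[, , t], connectivity), integer(1))
  max_delta <- if (length(counts) > 1) max(abs(diff(counts))) else 0
  flag_jump <- if (is.null(pop)) NA else
    max_delta > pop$mean_of_max_delta + 5 * pop$sd_of_max_delta
  structure(list(
    flag_multi_component = any(comp > 1),
    flag_frame_jump = flag_jump,
    flag_empty_frame = any(counts == 0),
    flag_bad_frame_count = cine$n_frames != expected_frames,
    max_frame_delta_px = as.integer(max_delta),
    component_counts = comp),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  flags <- c(multi_component = x$flag_multi_component,
             frame_jump = x$flag_frame_jump,
             empty_frame = x$flag_empty_frame,
             bad_frame_count = x$flag_bad_frame_count)
  cat("<qc_report> flags:",
      if (any(flags, na.rm = TRUE)) paste(names(flags)[which(flags)], collapse = ", ")
      else "none", "\n")
  cat("  max frame-to-frame delta:", x$max_frame_delta_px, "px\n")
  invisible(x)
}

#' Cohort-mode quality control
#'
#' Computes the population delta statistics from all studies in one batch and
#' returns per-study flags plus the statistics used.
#'
#' @param cines List of [cine_segmentation()] objects (one view per study).
#' @param expected_frames,connectivity As in [qc_flags()].
#' @return List with `reports` (per-study [qc_flags()] output) and `pop`.
#' @export
qc_cohort <- function(cines, expected_frames = 50, connectivity = 8) {
  stopifnot(length(cines) >= 2)
  deltas <- vapply(cines, function(cn) {
    counts <- frame_pixel_counts(cn)
    if (length(counts) > 1) max(abs(diff(counts))) else 0
  }, numeric(1))
  pop <- population_delta_stats(deltas)
  reports <- lapply(cines, qc_flags, pop = pop,
                    expected_frames = expected_frames,
                    connectivity = connectivity)
  list(reports = reports, pop = pop)
}

# perimeter pixel coordinates in mm (pixel centres, in-plane 2D)
perimeter_mm <- function(mask, structuring = "cross") {
  per <- extract_perimeter(mask, structuring)
  idx <- which(per$pixels == 1, arr.ind = TRUE)
  sp <- mask$geometry$spacing_mm
  cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2])
}

check_same_shape <- function(a, b) {
  stopifnot(inherits(a, "segmentation_mask"), inherits(b, "segmentation_mask"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("masks have different shapes: ",
         paste(dim(a$pixels), collapse = "x"), " vs ",
         paste(dim(b$pixels), collapse = "x"))
}

#' Sorensen-Dice coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [segmentation_mask()]s of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_shape(a, b)
  na <- sum(a$pixels); nb <- sum(b$pixels)
  if (na + nb == 0) return(1)
  2 * sum(a$pixels * b$pixels) / (na + nb)
}

# minimum distances (mm) from each perimeter point of a to perimeter of b
perimeter_min_dists <- function(a, b, structuring = "cross") {
  check_same_shape(a, b)
  pa <- perimeter_mm(a, structuring)
  pb <- perimeter_mm(b, structuring)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("empty perimeter: both masks must be non-empty")
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Directed Hausdorff distance between mask perimeters, in mm
#'
#' The maximum over perimeter points of `a` of the distance to the nearest
#' perimeter point of `b` (directed a -> b; generally asymmetric). Distances
#' are between pixel centres using the masks' pixel spacing.
#'
#' @param a,b Non-empty [segmentation_mask()]s of the same shape.
#' @param symmetric If TRUE, return `max(h(a,b), h(b,a))`.
#' @return Distance in mm.
#' @export
directed_hausdorff_mm <- function(a, b, symmetric = FALSE) {
  h_ab <- max(perimeter_min_dists(a, b))
  if (!symmetric) return(h_ab)
  max(h_ab, max(perimeter_min_dists(b, a)))
}

#' Mean contour distance between mask perimeters, in mm
#'
#' The average over perimeter points of `a` of the distance to the nearest
#' perimeter point of `b` (directed a -> b).
#'
#' @inheritParams directed_hausdorff_mm
#' @return Distance in mm.
#' @export
mean_contour_distance_mm <- function(a, b) {
  mean(perimeter_min_dists(a, b))
}
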