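#' Read a plane-geometry sidecar JSON
#'
#' Expected keys: `image_position_patient` (3), `image_orientation_patient`
#' (6: row direction then column direction), `pixel_spacing` (2),
#' `slice_thickness`, `view`.
#'
#' @param path Path to the JSON sidecar.
#' @return A [plane_geometry()].
#' @export
read_geometry_sidecar <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("image_position_patient", "image_orientation_patient",
            "pixel_spacing")
  miss <- setdiff(need, names(j))
  if (length(miss) > 0)
    stop("sidecar ", path, " missing key(s): ", paste(miss, collapse = ", "))
  plane_geometry(origin_mm = j$image_position_patient,
                 row_cosine = j$image_orientation_patient[1:3],
                 col_cosine = j$image_orientation_patient[4:6],
                 spacing_mm = j$pixel_spacing,
                 thickness_mm = if (is.null(j$slice_thickness)) 0
                                else j$slice_thickness,
                 view = j$view)
}

#' Write a plane-geometry sidecar JSON
#'
#' @param geom A [plane_geometry()].
#' @param path Output path.
#' @export
write_geometry_sidecar <- function(geom, path) {
  jsonlite::write_json(list(
    image_position_patient = geom$origin_mm,
    image_orientation_patient = c(geom$row_cosine, geom$col_cosine),
    pixel_spacing = geom$spacing_mm,
    slice_thickness = geom$thickness_mm,
    view = geom$view), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

normalize_binary <- function(a) {
  u <- sort(unique(as.vector(a)))
  if (all(u %in% c(0, 1))) return(a)
  if (all(u %in% c(0, 255))) return(a / 255)
  if (all(a >= 0 & a <= 1)) return(round(a))  # PNG scales to [0,1]
  stop("mask values must be {0,1} or {0,255}; got range ",
       paste(range(a), collapse = ".."))
}

#' Write a cine segmentation as NIfTI plus sidecar
#'
#' @param cine A [cine_segmentation()].
#' @param stem Output path stem; writes `<stem>.nii.gz` and `<stem>.json`.
#' @export
write_cine_nifti <- function(cine, stem) {
  RNifti::writeNifti(cine$masks, paste0(stem, ".nii.gz"))
  write_geometry_sidecar(cine$geometry, paste0(stem, ".json"))
  invisible(stem)
}

#' Read a cine segmentation from NIfTI plus sidecar
#'
#' @param stem Path stem as used by [write_cine_nifti()].
#' @return A [cine_segmentation()].
#' @export
read_cine_nifti <- function(stem) {
  masks <- as.array(RNifti::readNifti(paste0(stem, ".nii.gz")))
  geom <- read_geometry_sidecar(paste0(stem, ".json"))
  cine_segmentation(normalize_binary(masks), geom)
}

#' Write a cine segmentation as a numbered PNG stack plus sidecar
#'
#' @param cine A [cine_segmentation()].
#' @param dir Output directory (one `frame_###.png` per frame + `geometry.json`).
#' @export
write_cine_png <- function(cine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(cine$n_frames))
    png::writePNG(cine$masks[, , t] + 0,
                  file.path(dir, sprintf("frame_%03d.png", t)))
  write_geometry_sidecar(cine$geometry, file.path(dir, "geometry.json"))
  invisible(dir)
}

#' Read a cine segmentation from a numbered PNG stack plus sidecar
#'
#' @param dir Directory written by [write_cine_png()].
#' @return A [cine_segmentation()].
#' @export
read_cine_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    normalize_binary(img)
  })
  masks <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  geom <- read_geometry_sidecar(file.path(dir, "geometry.json"))
  cine_segmentation(masks, geom)
}

#' Write a mesh as binary little-endian PLY
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "ply\nformat binary_little_endian 1.0\n",
    "element vertex ", nrow(mesh$vertices_mm), "\n",
    "property float x\nproperty float y\nproperty float z\n",
    "element face ", nrow(mesh$faces), "\n",
    "property list uchar int vertex_indices\nend_header\n")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(t(mesh$vertices_mm)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

#' Write a mesh as binary STL
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices_mm; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    len <- sqrt(sum(n^2))
    if (len > 0) n <- n / len
    writeBin(as.numeric(c(n, a, b, cc)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

#' Write a volume trace as CSV
#'
#' Columns: `frame` (0-based), `volume_ml`, `status`.
#'
#' @param trace A [volume_trace()].
#' @param path Output path.
#' @export
write_volume_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "volume_trace"))
  utils::write.csv(data.frame(frame = seq_along(trace$volumes_ml) - 1,
                              volume_ml = sprintf("%.6f", trace$volumes_ml),
                              status = trace$status),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
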