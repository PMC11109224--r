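#' Left atrial phenotypes from a volume trace
#'
#' Computes the maximum LA volume (LAmax), minimum LA volume (LAmin), stroke
#' volume (LASV = LAmax - LAmin) and emptying fraction (LAEF = LASV / LAmax)
#' from a complete per-frame volume trace, optionally adding body-surface-area
#' indexed volumes (mL/m^2).
#'
#' @param trace A [volume_trace()] with no missing frames.
#' @param bsa_m2 Optional body surface area in m^2 for indexed volumes.
#' @return An object of class `la_phenotypes` with fields `la_max_ml`,
#'   `la_min_ml`, `la_sv_ml`, `la_ef_frac`, and (when `bsa_m2` is supplied)
#'   `la_max_i`, `la_min_i`, `la_sv_i` and `bsa_m2`.
#' @export
la_phenotypes <- function(trace, bsa_m2 = NULL) {
  stopifnot(inherits(trace, "volume_trace"))
  if (anyNA(trace$volumes_ml))
    stop("incomplete trace: ", sum(is.na(trace$volumes_ml)),
         " frame(s) missing; phenotypes require a complete trace")
  v <- trace$volumes_ml
  if (any(v < 0)) stop("negative volumes in trace")
  la_max <- max(v); la_min <- min(v)
  la_sv <- la_max - la_min
  if (la_max == 0) stop("LAmax is zero: emptying fraction undefined")
  out <- list(la_max_ml = la_max, la_min_ml = la_min, la_sv_ml = la_sv,
              la_ef_frac = la_sv / la_max)
  if (!is.null(bsa_m2)) {
    if (bsa_m2 <= 0) stop("bsa_m2 must be positive")
    out$bsa_m2 <- bsa_m2
    out$la_max_i <- la_max / bsa_m2
    out$la_min_i <- la_min / bsa_m2
    out$la_sv_i <- la_sv / bsa_m2
  }
  structure(out, class = "la_phenotypes")
}

#' @export
print.la_phenotypes <- function(x, ...) {
  cat(sprintf("LA phenotypes: LAmax %.1f mL, LAmin %.1f mL, LASV %.1f mL, LAEF %.1f%%\n",
              x$la_max_ml, x$la_min_ml, x$la_sv_ml, 100 * x$la_ef_frac))
  if (!is.null(x$bsa_m2))
    cat(sprintf("  BSA-indexed (BSA %.2f m2): LAmax %.1f, LAmin %.1f, LASV %.1f mL/m2\n",
                x$bsa_m2, x$la_max_i, x$la_min_i, x$la_sv_i))
  invisible(x)
}

#' Body surface area
#'
#' Du Bois (default): `0.007184 * weight^0.425 * height^0.725`;
#' Mosteller: `sqrt(height * weight / 3600)`.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @param method `"dubois"` (default) or `"mosteller"`.
#' @return Body surface area in m^2.
#' @export
body_surface_area <- function(height_cm, weight_kg,
                              method = c("dubois", "mosteller")) {
  method <- match.arg(method)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  switch(method,
         dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
         mosteller = sqrt(height_cm * weight_kg / 3600))
}

# fixed channel order of the filling-curve tensor
FILLING_CHANNELS <- c("lax4ch_la", "lax4ch_ra", "lax4ch_lv", "lax4ch_rv",
                      "lax3ch_la", "lax3ch_lv", "lax2ch_la", "lax2ch_lv")

#' Build the 8-channel filling-curve tensor
#'
#' Each channel is a per-frame chamber pixel count from one long-axis view
#' (4ch: LA, RA, LV, RV; 3ch: LA, LV; 2ch: LA, LV). Channels are normalised by
#' their own maximum over the cycle, so the tensor carries only relative size
#' changes; a case missing any channel (or with a zero-maximum channel) is
#' excluded with an error.
#'
#' @param area_curves T x 8 numeric matrix of pixel counts (columns in the
#'   fixed channel order), or a named list of 8 per-channel vectors.
#' @return A T x 8 matrix in \[0, 1\] with a per-channel maximum of exactly 1,
#'   of class `filling_tensor`.
#' @export
filling_tensor <- function(area_curves) {
  if (is.list(area_curves) && !is.data.frame(area_curves)) {
    missing_ch <- setdiff(FILLING_CHANNELS, names(area_curves))
    if (length(missing_ch) > 0)
      stop("case excluded: channel(s) missing: ",
           paste(missing_ch, collapse = ", "))
    area_curves <- do.call(cbind, area_curves[FILLING_CHANNELS])
  }
  area_curves <- as.matrix(area_curves)
  if (ncol(area_curves) != 8)
    stop("case excluded: all 8 channels are required (got ",
         ncol(area_curves), ")")
  if (anyNA(area_curves))
    stop("case excluded: missing values in channels")
  mx <- apply(area_curves, 2, max)
  if (any(mx <= 0))
    stop("case excluded: zero-maximum channel(s): ",
         paste(which(mx <= 0), collapse = ", "))
  out <- sweep(area_curves, 2, mx, "/")
  colnames(out) <- FILLING_CHANNELS
  structure(out, class = c("filling_tensor", "matrix", "array"))
}

#' Heuristic filling-pattern classifier
#'
#' A simple reference rule standing behind the pluggable classifier interface
#' (tensor in, label out): the mean of the LA channels is examined over the
#' final quarter of the cycle, and the pattern is called `"normal"` when a
#' late-cycle dip (the atrial contraction) deeper than `dip_frac` of the
#' normalised range is present, `"abnormal"` otherwise. This rule is package
#' plumbing for testing the interface, not a trained model.
#'
#' @param tensor A [filling_tensor()].
#' @param dip_frac Minimum dip depth (fraction of the normalised scale).
#' @return `"normal"` or `"abnormal"`.
#' @export
classify_filling <- function(tensor, dip_frac = 0.05) {
  stopifnot(inherits(tensor, "filling_tensor"))
  la <- rowMeans(tensor[, c("lax4ch_la", "lax3ch_la", "lax2ch_la")])
  tt <- length(la)
  w <- seq(ceiling(0.75 * tt), tt)
  seg <- la[w]
  dip <- max(cummax(seg) - seg)
  if (dip >= dip_frac) "normal" else "abnormal"
}
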