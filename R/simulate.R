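#' Specification of a sliced geometric phantom
#'
#' Defines a time-varying convex chamber (sphere, ellipsoid, or two disjoint
#' lobes) together with a view plan that mirrors the cardiac MRI acquisition:
#' three long-axis planes rotated about the long axis through the chamber
#' centre, plus a short-axis stack perpendicular to the long axis (8-mm
#' planes with 2-mm gaps by default). Semi-axes may be constant or functions
#' of the frame index, and the analytic volume is available in closed form
#' for every frame.
#'
#' @param shape `"sphere"`, `"ellipsoid"` or `"two_lobe"`.
#' @param semi_axes_mm Numeric 3-vector, or a function of frame index
#'   (1-based) returning one; for a sphere a single radius is accepted.
#' @param center_mm Chamber centre in patient coordinates (mm).
#' @param long_axis Unit direction of the long axis.
#' @param n_frames Frames per cine; default 50.
#' @param lax_angles_deg Rotations of the long-axis planes about the long
#'   axis; default `c(0, 60, 120)`.
#' @param sax_slices Number of short-axis slices; default 6.
#' @param sax_thickness_mm,sax_gap_mm Short-axis plane thickness and gap.
#' @param lax_spacing_mm,sax_spacing_mm In-plane pixel spacing.
#' @param jitter_sd_px Boundary jitter (pixels) applied to mask edges.
#' @param lobe_offset_mm For `"two_lobe"`: centre offset of the second lobe.
#' @param lobe_scale For `"two_lobe"`: semi-axis scale of the second lobe.
#' @param seed Seed for the jitter.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid", "two_lobe"),
                         semi_axes_mm = 30, center_mm = c(0, 0, 0),
                         long_axis = c(0, 0, 1), n_frames = 50,
                         lax_angles_deg = c(0, 60, 120), sax_slices = 6,
                         sax_thickness_mm = 8, sax_gap_mm = 2,
                         lax_spacing_mm = 1.83, sax_spacing_mm = 1.86,
                         jitter_sd_px = 0, lobe_offset_mm = c(0, 0, 90),
                         lobe_scale = 0.5, seed = 1) {
  shape <- match.arg(shape)
  axes_fun <- if (is.function(semi_axes_mm)) {
    semi_axes_mm
  } else {
    ax <- as.numeric(semi_axes_mm)
    if (length(ax) == 1) ax <- rep(ax, 3)
    stopifnot(length(ax) == 3)
    function(t) ax
  }
  for (t in c(1, n_frames))
    if (any(axes_fun(t) <= 0)) stop("semi-axes must be positive at all frames")
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  structure(list(shape = shape, axes_fun = axes_fun,
                 center_mm = as.numeric(center_mm), long_axis = long_axis,
                 n_frames = n_frames, lax_angles_deg = lax_angles_deg,
                 sax_slices = sax_slices, sax_thickness_mm = sax_thickness_mm,
                 sax_gap_mm = sax_gap_mm, lax_spacing_mm = lax_spacing_mm,
                 sax_spacing_mm = sax_spacing_mm, jitter_sd_px = jitter_sd_px,
                 lobe_offset_mm = as.numeric(lobe_offset_mm),
                 lobe_scale = lobe_scale, seed = seed),
            class = "phantom_spec")
}

# orthonormal basis completing a unit vector u
complete_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(v, w)
}

# signed radial distance (mm) from each point to the phantom surface,
# negative inside; axes aligned with (long, v, w) at the centre
phantom_sdist <- function(spec, pts, t) {
  ax <- spec$axes_fun(t)
  B <- complete_basis(spec$long_axis)
  d_one <- function(ctr, ax) {
    d <- sweep(pts, 2, ctr)
    u1 <- d %*% spec$long_axis
    u2 <- d %*% B[, 1]
    u3 <- d %*% B[, 2]
    rq <- sqrt((u1 / ax[1])^2 + (u2 / ax[2])^2 + (u3 / ax[3])^2)
    nd <- sqrt(u1^2 + u2^2 + u3^2)
    # distance along the ray from the centre to the surface crossing
    ifelse(rq > 0, nd * (1 - 1 / rq), -min(ax))
  }
  dist <- d_one(spec$center_mm, ax)
  if (spec$shape == "two_lobe")
    dist <- pmin(dist, d_one(spec$center_mm + spec$lobe_offset_mm,
                             ax * spec$lobe_scale))
  dist
}

phantom_volume_ml <- function(spec, t) {
  ax <- spec$axes_fun(t)
  v <- 4 / 3 * pi * prod(ax)
  if (spec$shape == "two_lobe")
    v <- v + 4 / 3 * pi * prod(ax * spec$lobe_scale)
  v / 1000
}

# geometry for one phantom plane: in-plane directions e_col (row_cosine) and
# e_row (col_cosine), centred on `center`, covering fov_mm
phantom_plane <- function(center, e_col, e_row, spacing, fov_mm,
                          thickness, view) {
  n <- ceiling(fov_mm / spacing)
  origin <- center - (n - 1) / 2 * spacing * e_row - (n - 1) / 2 * spacing * e_col
  list(geom = plane_geometry(origin, e_col, e_row, c(spacing, spacing),
                             thickness, view),
       H = n, W = n)
}

#' Generate a sliced phantom with known analytic volume
#'
#' Rasterises the plane/shape cross-sections of the phantom into binary cine
#' masks with full plane-geometry sidecars, one [cine_segmentation()] per
#' imaging plane, and returns the analytic per-frame volume as ground truth.
#' Boundary jitter (if requested) perturbs the rasterisation boundary by a
#' seeded Gaussian offset of about `jitter_sd_px` pixels.
#'
#' @param spec A [phantom_spec()].
#' @return List with `views` (list of [cine_segmentation()]), `truth`
#'   (a [volume_trace()] of analytic volumes in mL) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  max_ax <- max(vapply(seq_len(spec$n_frames),
                       function(t) max(spec$axes_fun(t)), numeric(1)))
  fov <- 2 * max_ax * 1.5
  B <- complete_basis(spec$long_axis)

  planes <- list()
  for (a in spec$lax_angles_deg) {
    phi <- a * pi / 180
    e2 <- cos(phi) * B[, 1] + sin(phi) * B[, 2]
    planes[[length(planes) + 1]] <-
      c(phantom_plane(spec$center_mm, spec$long_axis, e2,
                      spec$lax_spacing_mm, fov, 6,
                      paste0("lax_", a)), list(spacing_view = "lax"))
  }
  if (spec$sax_slices > 0) {
    step <- spec$sax_thickness_mm + spec$sax_gap_mm
    offs <- (seq_len(spec$sax_slices) - (spec$sax_slices + 1) / 2) * step
    for (s in seq_len(spec$sax_slices)) {
      ctr <- spec$center_mm + offs[s] * spec$long_axis
      planes[[length(planes) + 1]] <-
        c(phantom_plane(ctr, B[, 1], B[, 2], spec$sax_spacing_mm, fov,
                        spec$sax_thickness_mm, paste0("sax_", s)),
          list(spacing_view = "sax"))
    }
  }

  views <- withr::with_seed(as.integer(spec$seed), {
    lapply(planes, function(pl) {
      H <- pl$H; W <- pl$W
      idx <- expand.grid(row = seq_len(H) - 1, col = seq_len(W) - 1)
      pts <- pixel_to_patient(idx$row, idx$col, pl$geom)
      masks <- array(0L, dim = c(H, W, spec$n_frames))
      px <- pl$geom$spacing_mm[1]
      for (t in seq_len(spec$n_frames)) {
        dist <- phantom_sdist(spec, pts, t)
        # coverage convention: a pixel is foreground when it covers the
        # boundary, i.e. its centre is within half a pixel of the surface,
        # so perimeter pixel centres straddle the analytic contour
        thr <- 0.5 * px
        if (spec$jitter_sd_px > 0)
          thr <- thr + stats::rnorm(length(dist), 0, spec$jitter_sd_px) * px
        masks[, , t] <- matrix(as.integer(dist <= thr), H, W)
      }
      if (all(masks == 0))
        warning("plane ", pl$geom$view, " misses the phantom in every frame")
      cine_segmentation(masks, pl$geom)
    })
  })
  truth <- volume_trace(vapply(seq_len(spec$n_frames),
                               function(t) phantom_volume_ml(spec, t),
                               numeric(1)))
  list(views = views, truth = truth, spec = spec)
}

#' Generate 8-channel chamber filling curves
#'
#' Emits smooth per-chamber area curves over one cardiac cycle, in pixel
#' counts: atrial channels fill during ventricular systole, empty passively
#' in early diastole, and (with `kick = TRUE`) show the late-cycle atrial
#' contraction dip; ventricular channels run in anti-phase. The returned
#' label is the ground truth for classifier-interface tests.
#'
#' @param kick Include the atrial contraction dip (TRUE = normal pattern).
#' @param noise_sd Relative Gaussian noise on the counts.
#' @param seed Seed for the noise.
#' @param n_frames Frames per cycle; default 50.
#' @return List with `curves` (n_frames x 8 matrix of pixel counts, columns
#'   in the fixed channel order) and `label` (`"normal"` / `"abnormal"`).
#' @export
make_filling_curves <- function(kick = TRUE, noise_sd = 0, seed = 1,
                                n_frames = 50) {
  stopifnot(noise_sd >= 0)
  t <- (seq_len(n_frames) - 1) / n_frames
  ramp <- function(t, t0, t1) pmin(1, pmax(0, (t - t0) / (t1 - t0)))
  smoothstep <- function(x) x * x * (3 - 2 * x)
  # atrial volume: fill to max at t=0.40, passive emptying to t=0.70
  la <- 0.45 + 0.55 * smoothstep(ramp(t, 0.02, 0.40)) -
    0.45 * smoothstep(ramp(t, 0.42, 0.70))
  if (kick) {
    # atrial contraction: dip centred around t=0.88, partial refill at cycle end
    la <- la - 0.22 * exp(-((t - 0.88) / 0.06)^2)
  } else {
    # AF-like: no organised contraction; slight monotone drift to cycle end
    la <- la - 0.03 * smoothstep(ramp(t, 0.75, 1.0))
  }
  # ventricles in anti-phase: empty during systole, refill in diastole
  lv <- 1 - 0.6 * smoothstep(ramp(t, 0.02, 0.35)) +
    0.45 * smoothstep(ramp(t, 0.45, 0.80)) +
    (if (kick) 0.15 else 0.05) * smoothstep(ramp(t, 0.82, 0.98))
  base <- c(lax4ch_la = 620, lax4ch_ra = 540, lax4ch_lv = 980,
            lax4ch_rv = 900, lax3ch_la = 480, lax3ch_lv = 860,
            lax2ch_la = 560, lax2ch_lv = 910)
  shapes <- cbind(la, la, lv, lv, la, lv, la, lv)
  curves <- sweep(shapes, 2, base, "*")
  if (noise_sd > 0)
    curves <- withr::with_seed(as.integer(seed), {
      pmax(curves * (1 + matrix(stats::rnorm(length(curves), 0, noise_sd),
                                nrow(curves))), 1)
    })
  colnames(curves) <- FILLING_CHANNELS
  list(curves = curves, label = if (kick) "normal" else "abnormal")
}

#' Generate a lead-SNP table with a known number of clusters
#'
#' Plants `n_clusters` clusters of SNPs on the autosomes such that SNPs
#' within a cluster span at most `intra_span_kb` while neighbouring clusters
#' are separated by more than `inter_gap_kb`, so the greedy merge with a
#' window between those two spans recovers exactly `n_clusters` loci.
#'
#' @param n_clusters Number of clusters to plant.
#' @param snps_per_cluster SNPs per cluster; default 2.
#' @param intra_span_kb Maximum within-cluster span (kb); default 100.
#' @param inter_gap_kb Minimum between-cluster gap (kb); default 2000.
#' @param seed Seed for positions and p-values.
#' @return A lead-SNP `data.frame` with a `cluster` column as ground truth.
#' @export
make_leadsnp_table <- function(n_clusters, snps_per_cluster = 2,
                               intra_span_kb = 100, inter_gap_kb = 2000,
                               seed = 1) {
  stopifnot(n_clusters >= 1, snps_per_cluster >= 1)
  if (intra_span_kb >= inter_gap_kb)
    stop("intra_span_kb must be smaller than inter_gap_kb")
  chrom_len_kb <- 240000
  per_chrom <- ceiling(n_clusters / 22)
  if (per_chrom * (inter_gap_kb + intra_span_kb) > chrom_len_kb - 2000)
    stop("infeasible spacing: ", n_clusters, " clusters with ",
         inter_gap_kb, " kb gaps do not fit on 22 chromosomes")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    alleles <- c("A", "C", "G", "T")
    for (cl in seq_len(n_clusters)) {
      chr <- as.character(((cl - 1) %% 22) + 1)
      slot <- (cl - 1) %/% 22
      start_kb <- 1000 + slot * (inter_gap_kb + intra_span_kb)
      pos <- sort(start_kb * 1000 +
                    sample.int(intra_span_kb * 1000, snps_per_cluster))
      ea <- sample(alleles, snps_per_cluster, replace = TRUE)
      oa <- vapply(ea, function(a) {
        sample(setdiff(alleles, c(a, c(A = "T", T = "A", C = "G", G = "C")[a])), 1)
      }, character(1))
      rows[[cl]] <- data.frame(
        trait = "SIM", chr = chr, bp = pos,
        rsid = sprintf("rs%d", 10^6 + (cl - 1) * snps_per_cluster +
                         seq_len(snps_per_cluster)),
        ea = ea, oa = oa,
        eaf = round(stats::runif(snps_per_cluster, 0.05, 0.95), 3),
        beta = round(stats::rnorm(snps_per_cluster, 0, 0.05), 4),
        se = 0.007,
        p = 10^-stats::runif(snps_per_cluster, 8.1, 20),
        cluster = cl, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a two-sample MR dataset with known causal effect
#'
#' Draws exposure effects from the effect distribution, forms outcome effects
#' as `theta * beta_exposure + pleiotropy + noise`, and assigns standard
#' errors from the two sample sizes. A configurable fraction of variants is
#' palindromic and a fraction has swapped allele labels in the outcome table,
#' to exercise harmonization. Variants are placed far apart so instrument
#' selection keeps them all.
#'
#' @param k Number of instruments (>= 3).
#' @param theta True causal effect.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero direct effects) or
#'   `"directional"` (mean `pleio_c`).
#' @param pleio_c Pleiotropy scale: SD under `"balanced"`, mean under
#'   `"directional"` (SD `pleio_c / 2`).
#' @param inside_violation Correlate the direct effects with instrument
#'   strength (violates the InSIDE assumption).
#' @param n_exposure,n_outcome Sample sizes governing the SEs.
#' @param beta_sd SD of the true exposure effect distribution.
#' @param frac_palindromic Fraction of A/T-or-C/G variants.
#' @param frac_swapped Fraction of outcome rows with swapped allele labels.
#' @param seed Seed.
#' @return List with `exposure` and `outcome` tables plus `truth` (theta and
#'   per-variant direct effects).
#' @export
make_mr_dataset <- function(k = 50, theta = 0.5,
                            pleiotropy = c("none", "balanced", "directional"),
                            pleio_c = 0.05, inside_violation = FALSE,
                            n_exposure = 35000, n_outcome = 60000,
                            beta_sd = 0.06, frac_palindromic = 0,
                            frac_swapped = 0.25, seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(k >= 3)
  withr::with_seed(as.integer(seed), {
    maf <- stats::runif(k, 0.1, 0.5)
    se_x <- 1 / sqrt(2 * n_exposure * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * n_outcome * maf * (1 - maf))
    bx <- stats::rnorm(k, 0, beta_sd)
    # keep instruments strong enough to be selected at p < 1e-6
    weak <- abs(bx) < 6 * se_x
    bx[weak] <- sign(bx[weak] + (bx[weak] == 0)) * 6 * se_x[weak]
    alpha <- switch(pleiotropy,
                    none = rep(0, k),
                    balanced = stats::rnorm(k, 0, pleio_c),
                    directional = stats::rnorm(k, pleio_c, pleio_c / 2))
    if (inside_violation) alpha <- alpha + 0.5 * abs(bx)
    # direct effects act relative to the exposure-increasing allele, so
    # directional pleiotropy survives re-orientation of arbitrary effect
    # alleles (balanced pleiotropy is symmetric and unaffected)
    by <- theta * bx + sign(bx) * alpha + stats::rnorm(k, 0, se_y)

    n_pal <- round(frac_palindromic * k)
    pal <- seq_len(k) <= n_pal
    ea <- oa <- character(k)
    pal_pairs <- list(c("A", "T"), c("C", "G"))
    npal_pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
    for (i in seq_len(k)) {
      pr <- if (pal[i]) pal_pairs[[sample.int(2, 1)]]
            else npal_pairs[[sample.int(4, 1)]]
      if (stats::runif(1) < 0.5) pr <- rev(pr)
      ea[i] <- pr[1]; oa[i] <- pr[2]
    }
    chr <- as.character(((seq_len(k) - 1) %% 22) + 1)
    bp <- 1e6 + ((seq_len(k) - 1) %/% 22) * 2e7
    rsid <- sprintf("rs%d", 5e6 + seq_len(k))

    exposure <- data.frame(
      trait = "exposure", chr = chr, bp = bp, rsid = rsid, ea = ea, oa = oa,
      eaf = maf, beta = bx, se = se_x,
      p = 2 * stats::pnorm(-abs(bx / se_x)), stringsAsFactors = FALSE)
    swapped <- stats::runif(k) < frac_swapped
    outcome <- data.frame(
      trait = "outcome", chr = chr, bp = bp, rsid = rsid,
      ea = ifelse(swapped, oa, ea), oa = ifelse(swapped, ea, oa),
      eaf = ifelse(swapped, 1 - maf, maf),
      beta = ifelse(swapped, -by, by), se = se_y,
      p = 2 * stats::pnorm(-abs(by / se_y)), stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = theta, alpha = alpha, palindromic = pal,
                      swapped = swapped))
  })
}
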