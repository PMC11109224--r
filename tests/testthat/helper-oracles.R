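# Independent brute-force oracles used across the test files. These are
# deliberately naive re-derivations (double loops, full enumeration) so they
# share no code path with the implementations they check.

# axis-aligned unit-spacing geometry for quick mask construction
flat_geom <- function(spacing = c(1, 1), view = NULL) {
  plane_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), spacing, 0, view)
}

mask_of <- function(px, spacing = c(1, 1)) {
  segmentation_mask(px, flat_geom(spacing))
}

# oracle perimeter: pixel is on the perimeter if set and any 4-neighbour
# (or out-of-grid) is background
oracle_perimeter <- function(px) {
  H <- nrow(px); W <- ncol(px)
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (px[r, c] != 1) next
    nb <- c(
      if (r > 1) px[r - 1, c] else 0, if (r < H) px[r + 1, c] else 0,
      if (c > 1) px[r, c - 1] else 0, if (c < W) px[r, c + 1] else 0)
    if (any(nb == 0)) out[r, c] <- 1L
  }
  out
}

# oracle directed distances: all pairwise distances between perimeter pixel
# centres (mm), min per source point
oracle_min_dists <- function(a_px, b_px, spacing = c(1, 1)) {
  pa <- which(oracle_perimeter(a_px) == 1, arr.ind = TRUE)
  pb <- which(oracle_perimeter(b_px) == 1, arr.ind = TRUE)
  stopifnot(nrow(pa) > 0, nrow(pb) > 0)
  vapply(seq_len(nrow(pa)), function(i) {
    dmin <- Inf
    for (j in seq_len(nrow(pb))) {
      d <- sqrt(((pa[i, 1] - pb[j, 1]) * spacing[1])^2 +
                ((pa[i, 2] - pb[j, 2]) * spacing[2])^2)
      if (d < dmin) dmin <- d
    }
    dmin
  }, numeric(1))
}

# oracle component count by explicit flood fill
oracle_components <- function(px, connectivity = 8) {
  H <- nrow(px); W <- ncol(px)
  seen <- matrix(FALSE, H, W)
  offs <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  n <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (px[r0, c0] != 1 || seen[r0, c0]) next
    n <- n + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- cur[1] + offs$dr[k]; c <- cur[2] + offs$dc[k]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            px[r, c] == 1 && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  n
}

# oracle HWE exact p by direct enumeration with log-factorials
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het
  n_b <- 2 * n_hom_alt + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lfactorial(n) - lfactorial(homr) - lfactorial(h) - lfactorial(homc) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[hets == n_het]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# assemble one frame of a phantom into a cloud (skipping empty planes)
phantom_cloud <- function(views, t = 1) {
  frags <- list()
  for (v in views) {
    if (sum(v$masks[, , t]) > 0)
      frags[[length(frags) + 1]] <-
        fragment_from_mask(segmentation_mask(v$masks[, , t], v$geometry))
  }
  assemble_cloud(frags)
}

phantom_volume <- function(views, t = 1, grid_res = 96, ...) {
  grid <- poisson_indicator(phantom_cloud(views, t), grid_res = grid_res, ...)
  mesh_volume(suppressWarnings(extract_mesh(grid)))
}
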