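test_that("assemble_cloud concatenates fragments and rejects coplanar input", {
  sq <- matrix(0L, 9, 9); sq[3:7, 3:7] <- 1L
  gx <- plane_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1))
  gz <- plane_geometry(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 1))
  fx <- fragment_from_mask(segmentation_mask(sq, gx))
  fz <- fragment_from_mask(segmentation_mask(sq, gz))
  cloud <- assemble_cloud(list(fx, fz))
  expect_equal(nrow(cloud$points_mm), 32)  # two 5x5 block perimeters
  sv <- svd(scale(cloud$points_mm, scale = FALSE))$d
  expect_gt(sv[3], 1e-6 * sv[1])

  expect_error(assemble_cloud(list(fx)), "coplanar")
  expect_error(assemble_cloud(list()), "no points")

  ph <- suppressWarnings(make_phantom(
    phantom_spec("sphere", 30, n_frames = 1, sax_slices = 0)))
  cl <- phantom_cloud(ph$views)
  sv <- svd(scale(cl$points_mm, scale = FALSE))$d
  expect_gt(sv[3], 1e-6 * sv[1])
})

test_that("indicator field separates interior from exterior", {
  ph <- suppressWarnings(make_phantom(phantom_spec("sphere", 30, n_frames = 1)))
  cloud <- phantom_cloud(ph$views)
  grid <- poisson_indicator(cloud, grid_res = 64)
  n <- dim(grid$chi)[1]
  centre <- grid$chi[n / 2, n / 2, n / 2]
  corner <- grid$chi[1, 1, 1]
  expect_gt(centre, grid$iso_value)
  expect_gt(grid$iso_value, corner)

  # flipping all normals yields the complementary field
  flipped <- oriented_points(cloud$points_mm, -cloud$normals)
  gflip <- poisson_indicator(flipped, grid_res = 64)
  expect_lt(gflip$chi[n / 2, n / 2, n / 2], gflip$iso_value)
})

test_that("extract_mesh recovers an analytic sphere within 2%", {
  # closed-form field chi = r0 - |x - c| sampled on a 96-grid, iso 0
  n <- 96; r0 <- 30
  h <- 80 / (n - 1)
  ax <- (seq_len(n) - (n + 1) / 2) * h
  chi <- array(0, c(n, n, n))
  for (k in seq_len(n))
    chi[, , k] <- r0 - sqrt(outer(ax^2, ax^2, "+") + ax[k]^2)
  grid <- structure(list(chi = chi, grid_origin_mm = c(0, 0, 0),
                         voxel_mm = h, iso_value = 0),
                    class = "indicator_grid")
  mesh <- extract_mesh(grid)
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * r0^3 / 1000, tolerance = 0.02)

  # constant field: iso not bracketed
  gconst <- structure(list(chi = array(1, c(16, 16, 16)),
                           grid_origin_mm = c(0, 0, 0), voxel_mm = 1,
                           iso_value = 1), class = "indicator_grid")
  expect_error(extract_mesh(gconst), "not strictly inside")

  # two-lobe field: only the larger lobe is retained, with a warning
  chi2 <- array(0, c(48, 48, 48))
  axs <- seq_len(48) - 0.5
  for (k in 1:48)
    chi2[, , k] <- pmax(
      10 - sqrt(outer((axs - 14)^2, (axs - 24)^2, "+") + (axs[k] - 24)^2),
      5 - sqrt(outer((axs - 36)^2, (axs - 24)^2, "+") + (axs[k] - 24)^2))
  g2 <- structure(list(chi = chi2, grid_origin_mm = c(0, 0, 0),
                       voxel_mm = 1, iso_value = 0),
                  class = "indicator_grid")
  expect_warning(m2 <- extract_mesh(g2), "components")
  expect_equal(mesh_volume(m2), 4 / 3 * pi * 10^3 / 1000, tolerance = 0.05)
})

test_that("mesh_volume applies the divergence theorem and demands watertightness", {
  # unit cube, 12 triangles, consistently outward
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = 1
  cube <- tri_mesh(v, f)
  expect_equal(mesh_volume(cube), 0.001)

  holed <- tri_mesh(v, f[-1, ])
  expect_error(mesh_volume(holed), "not watertight")

  # icosphere-like check via marching tetrahedra on a fine analytic field
  n <- 128; r0 <- 30; h <- 70 / (n - 1)
  ax <- (seq_len(n) - (n + 1) / 2) * h
  chi <- array(0, c(n, n, n))
  for (k in seq_len(n))
    chi[, , k] <- r0 - sqrt(outer(ax^2, ax^2, "+") + ax[k]^2)
  g <- structure(list(chi = chi, grid_origin_mm = c(0, 0, 0), voxel_mm = h,
                      iso_value = 0), class = "indicator_grid")
  expect_equal(mesh_volume(extract_mesh(g)), 113.097, tolerance = 0.005)
})

test_that("phantom volume recovery is accurate, monotone in resolution, and rigid-invariant", {
  radii <- c(20, 30, 40, 50, 60)
  err32 <- err96 <- numeric(length(radii))
  for (i in seq_along(radii)) {
    ph <- suppressWarnings(make_phantom(
      phantom_spec("sphere", radii[i], n_frames = 1)))
    truth <- ph$truth$volumes_ml[1]
    err32[i] <- abs(phantom_volume(ph$views, grid_res = 32) - truth)
    err96[i] <- abs(phantom_volume(ph$views, grid_res = 96) - truth)
    expect_lt(err96[i] / truth, 0.05)
  }
  expect_lt(mean(err96), mean(err32))

  # rigid transform of all plane geometries changes the volume by < 1%
  ph <- suppressWarnings(make_phantom(phantom_spec("sphere", 30, n_frames = 1)))
  v0 <- phantom_volume(ph$views, grid_res = 64)
  th <- pi / 5
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  shift <- c(15, -8, 22)
  views2 <- lapply(ph$views, function(vw) {
    g <- vw$geometry
    cine_segmentation(vw$masks, plane_geometry(
      drop(Rm %*% g$origin_mm) + shift, drop(Rm %*% g$row_cosine),
      drop(Rm %*% g$col_cosine), g$spacing_mm, g$thickness_mm, g$view))
  })
  v1 <- phantom_volume(views2, grid_res = 64)
  expect_lt(abs(v1 - v0) / v0, 0.01)
})

test_that("reconstruct_trace tracks a pulsating sphere and tolerates failures", {
  nf <- 25
  spec <- phantom_spec("sphere",
                       semi_axes_mm = function(t) rep(25 + 5 * sin(2 * pi * (t - 1) / nf), 3),
                       n_frames = nf)
  ph <- suppressWarnings(make_phantom(spec))
  tr <- reconstruct_trace(ph$views, grid_res = 48)
  expect_false(anyNA(tr$volumes_ml))
  expect_lte(abs(which.max(tr$volumes_ml) - which.max(ph$truth$volumes_ml)), 1)
  expect_lte(abs(which.min(tr$volumes_ml) - which.min(ph$truth$volumes_ml)), 1)

  # constant phantom: trace constant within reconstruction noise
  phc <- suppressWarnings(make_phantom(phantom_spec("sphere", 28, n_frames = 4)))
  trc <- reconstruct_trace(phc$views, grid_res = 48)
  expect_lt(sd(trc$volumes_ml) / mean(trc$volumes_ml), 0.02)

  # short-axis stack omitted: still reconstructed, volume within 8%
  ph3 <- suppressWarnings(make_phantom(
    phantom_spec("sphere", 30, n_frames = 1, sax_slices = 0)))
  tr3 <- reconstruct_trace(ph3$views, grid_res = 96)
  expect_lt(abs(tr3$volumes_ml[1] - ph3$truth$volumes_ml[1]) /
              ph3$truth$volumes_ml[1], 0.08)

  # a frame left with a single plane fails with a marker, others succeed
  ph2 <- suppressWarnings(make_phantom(phantom_spec("sphere", 25, n_frames = 3)))
  views <- ph2$views
  for (i in seq_along(views)[-1]) views[[i]]$masks[, , 2] <- 0L
  tr2 <- reconstruct_trace(views, grid_res = 32)
  expect_true(is.na(tr2$volumes_ml[2]))
  expect_match(tr2$status[2], "failed")
  expect_false(anyNA(tr2$volumes_ml[-2]))

  # all views share one orientation: global failure
  same <- list(ph2$views[[4]], ph2$views[[5]])  # two parallel SAX planes
  expect_error(reconstruct_trace(same, grid_res = 32), "orientation")
})
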