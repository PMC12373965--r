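# Unit-level solver physics on small grids; the full imaging properties of
# the 4F system are exercised in the acceptance suite.

test_that("grid construction enforces stability and boundary thickness", {
  expect_error(wave_grid(20, 20, courant = 0.9), "unstable")
  expect_error(wave_grid(20, 20, spatial_step = 1 / 2, sponge_lambda = 3),
               "10 cells")
  g <- wave_grid(20, 20, spatial_step = 1 / 10)
  expect_equal(g$nz, 200)
})

test_that("map builders respect n >= 1 and are deterministic per seed", {
  g <- wave_grid(20, 20, spatial_step = 1 / 10)
  m <- refractive_map(g)
  m <- add_lens(m, g, 10, 8, 6)
  m <- add_scatterer(m, g, 5, 0)
  d1 <- add_diffuser(refractive_map(g), g, 8, width_lambda = 10, seed = 7)
  d2 <- add_diffuser(refractive_map(g), g, 8, width_lambda = 10, seed = 7)
  d3 <- add_diffuser(refractive_map(g), g, 8, width_lambda = 10, seed = 8)
  expect_true(all(m >= 1))
  expect_equal(max(m), 2.5)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  bad <- m; bad[5, 5] <- 0.5
  expect_error(propagate(bad, g, 15, rep(1, g$nx), duration = 2), "n >= 1")
})

test_that("a plane wave propagates undistorted through free space", {
  g <- wave_grid(30, 60, spatial_step = 1 / 10)
  m <- refractive_map(g)
  res <- propagate(m, g, src_row = g$sponge_cells + 10, rep(1, g$nx),
                   duration = 20, avg_periods = 3)
  x <- (seq_len(g$nx) - (g$nx + 1) / 2) * g$dx
  probe <- res$intensity[g$sponge_cells + 50, abs(x) <= 5]
  amp <- sqrt(2 * probe)
  expect_lt((max(amp) - min(amp)) / mean(amp), 0.01)
})

test_that("the solver is linear in the source", {
  g <- wave_grid(30, 30, spatial_step = 1 / 10)
  m <- refractive_map(g)
  x <- (seq_len(g$nx) - (g$nx + 1) / 2) * g$dx
  a1 <- exp(-(x - 4)^2); a2 <- exp(-(x + 4)^2)
  r1 <- propagate(m, g, 40, a1, duration = 20)
  r2 <- propagate(m, g, 40, a2, duration = 20)
  r12 <- propagate(m, g, 40, a1 + a2, duration = 20)
  expect_lt(max(abs(r12$field - (r1$field + r2$field))) /
              max(abs(r12$field)), 1e-10)
})

test_that("a point source radiates a circular wave at phase speed c/n", {
  g <- wave_grid(40, 40, spatial_step = 1 / 15)
  m <- refractive_map(g)
  amp <- numeric(g$nx); amp[round(g$nx / 2)] <- 1
  res <- propagate(m, g, round(g$nz / 2), amp, duration = 30)
  src_row <- round(g$nz / 2); src_col <- round(g$nx / 2)
  # steady-state wavelength from zero-crossing spacing; phase speed =
  # wavelength x frequency with frequency 1
  wavelength_along <- function(v) {
    zc <- which(v[-1] * v[-length(v)] < 0)
    zc <- zc + v[zc] / (v[zc] - v[zc + 1])
    2 * mean(diff(zc)) * g$dx
  }
  band <- src_col + round(4 / g$dx):round(12 / g$dx)
  lam_row <- wavelength_along(res$field[src_row, band])
  lam_col <- wavelength_along(res$field[band, src_col])
  expect_equal(lam_row, 1, tolerance = 0.01)
  # circular front: same wavelength in every direction; the diagonal samples
  # are spaced 1/15 wavelength along the diagonal arc by construction
  s <- seq(3, 8.5, by = 1 / 15)
  diag_idx <- cbind(src_row + round(s * 0.7071 / g$dx),
                    src_col + round(s * 0.7071 / g$dx))
  lam_diag <- wavelength_along(res$field[diag_idx])
  expect_equal(lam_col, lam_row, tolerance = 0.005)
  expect_equal(lam_diag, 1, tolerance = 0.01)
})

test_that("field energy decays after the source is switched off", {
  g <- wave_grid(30, 30, spatial_step = 1 / 10)
  m <- refractive_map(g)
  res <- propagate(m, g, round(g$nz / 2), rep(1, g$nx), duration = 50,
                   source_off_period = 10, energy_trace = TRUE)
  per <- ceiling(1 / g$dt)
  nper <- floor(length(res$trace) / per)
  E <- vapply(seq_len(nper), function(k) {
    mean(res$trace[((k - 1) * per + 1):(k * per)])
  }, numeric(1))
  # after the off-ramp completes (period 11) the boundary layers drain the
  # energy monotonically and almost completely
  late <- E[13:nper]
  expect_true(all(diff(late) <= 1e-9 * max(E)))
  expect_lt(E[nper], 1e-3 * max(E))
})

test_that("simulated camera images are deterministic given the seed", {
  sys <- four_f_system(focal_lambda = 9, half_aperture_lambda = 7,
                       spatial_step = 1 / 10, sample_offset_lambda = 6)
  s1 <- simulate_camera_image(sys, 2, seed = 5)
  s2 <- simulate_camera_image(sys, 2, seed = 5)
  s3 <- simulate_camera_image(sys, 2, seed = 6)
  expect_identical(s1$camera, s2$camera)
  expect_false(identical(s1$camera, s3$camera))
  expect_true(all(s1$camera >= 0))
  expect_error(simulate_camera_image(sys, 0), ">= 1")
})

test_that("axial profile values are pointwise properties of the system", {
  sys <- four_f_system(focal_lambda = 9, half_aperture_lambda = 7,
                       spatial_step = 1 / 10, sample_offset_lambda = 6)
  a <- axial_contrast_scan(sys, seq(-4, 4, by = 2), n_realizations = 3,
                           seed = 2)
  b <- axial_contrast_scan(sys, seq(-4, 4, by = 4), n_realizations = 3,
                           seed = 2)
  shared <- intersect(a$z, b$z)
  expect_equal(a$value[match(shared, a$z)], b$value[match(shared, b$z)])
})

test_that("the scatterer separates from the transmitted wave in the BFP", {
  sys <- four_f_system(spatial_step = 1 / 10, scatterer_n = 2.5)
  b0 <- back_focal_plane_analysis(sys, scatterer = FALSE)
  b1 <- back_focal_plane_analysis(sys, scatterer = TRUE)
  expect_lt(b0$outside_fraction, 0.02)
  expect_gt(b1$outside_fraction, 5 * b0$outside_fraction)
  # a larger scatterer has a narrower forward-scattering lobe
  sys3 <- four_f_system(spatial_step = 1 / 10, scatterer_n = 2.5,
                        scatterer_diameter_lambda = 3)
  b3 <- back_focal_plane_analysis(sys3, scatterer = TRUE)
  spread <- function(b, ref) {
    d <- pmax(b$bfp - ref$bfp, 0)
    sqrt(sum(d * b$x^2) / sum(d))
  }
  expect_lt(spread(b3, b0), spread(b1, b0))
})
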