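test_that("cell detection counts disjoint blobs and respects symmetry", {
  # ~100 disjoint bright blobs
  spec <- phantom_spec(fov_mm = sqrt(100 / 1600), density = 1600,
                       modulation = 20, seed = 12)
  ph <- gen_endothelial_mosaic(spec)
  img <- highpass(ph$image, 121)
  n_true <- nrow(ph$truth$centers)
  det_b <- detect_cells(img, 1, "bright", scale_um = ph$truth$cell_spacing_um,
                        mask = ph$truth$mask_bright)
  n_bright_true <- sum(ph$truth$bright)
  expect_lt(abs(nrow(det_b) - n_bright_true), 0.05 * n_true + 1)
  # inverted image with flipped sign gives identical detections
  det_d <- detect_cells(-img, 1, "dark", scale_um = ph$truth$cell_spacing_um,
                        mask = ph$truth$mask_bright)
  expect_identical(det_b$row, det_d$row)
  expect_identical(det_b$col, det_d$col)
  # blank image: nothing to detect
  blank <- detect_cells(matrix(1, 100, 100), 1, "bright", scale_um = 20)
  expect_equal(nrow(blank), 0)
  # global affine intensity change leaves detections untouched
  det_s <- detect_cells(2.5 * img + 40, 1, "bright",
                        scale_um = ph$truth$cell_spacing_um,
                        mask = ph$truth$mask_bright)
  expect_identical(det_b$row, det_s$row)
})

test_that("cell density is count over area", {
  expect_equal(cell_density(288, area_mm2 = 0.09), 3200)
  expect_equal(cell_density(0, area_mm2 = 0.5), 0)
  expect_error(cell_density(10, area_mm2 = 0), "positive")
})

test_that("lens-epithelium-scale density (5000/mm^2) is recovered", {
  spec <- phantom_spec(fov_mm = 0.4, density = 5000, modulation = 20,
                       noise_sd = 2, seed = 4)
  ph <- gen_endothelial_mosaic(spec)
  det <- detect_cells(highpass(ph$image, 121), 1, "bright",
                      scale_um = ph$truth$cell_spacing_um,
                      mask = ph$truth$mask_bright)
  expect_equal(cell_density(det), 5000, tolerance = 0.1)
})

test_that("nerve length density handles polylines and skeletons", {
  seg <- cbind(seq(1, 1001, length.out = 500), rep(5, 500))  # 1 mm at 1 um/px
  tr <- nerve_trace(polylines = list(seg), pixel_pitch_um = 1, area_mm2 = 1)
  expect_equal(nerve_length_density(tr), 1, tolerance = 1e-6)
  empty <- nerve_trace(pixel_pitch_um = 1, area_mm2 = 1)
  expect_equal(nerve_length_density(empty), 0)
  # straight skeleton row of known length
  sk <- matrix(FALSE, 50, 1001); sk[25, 1:1000] <- TRUE
  tr2 <- nerve_trace(skeleton = sk, pixel_pitch_um = 1, area_mm2 = 1)
  expect_equal(nerve_length_density(tr2), 0.948, tolerance = 0.01)
})

test_that("nerve phantom density is recovered from the traced skeleton", {
  spec <- phantom_spec(fov_mm = 1, density = 22, modulation = 20, seed = 6)
  ph <- gen_nerve_layer(spec)
  tr <- trace_nerves(highpass(ph$image, 121), 1)
  expect_equal(nerve_length_density(tr), 22, tolerance = 0.1)
})

test_that("skeletonization thins strokes to unit width", {
  m <- matrix(FALSE, 30, 30)
  m[10:13, 5:25] <- TRUE   # 4-px-thick horizontal bar
  sk <- skeletonize(m)
  expect_true(all(colSums(sk[, 7:23]) == 1))
  expect_lt(sum(sk), sum(m) / 3)
})

test_that("mean cell diameter is the arithmetic mean", {
  expect_equal(mean_cell_diameter(c(38, 40, 42)), 40)
  expect_equal(mean_cell_diameter(17.5), 17.5)
  expect_error(mean_cell_diameter(numeric(0)), "no diameters")
})

test_that("rendered cell diameters are recovered within 15%", {
  for (cfg in list(c(40, 500), c(20, 1200), c(10, 3000))) {
    spec <- phantom_spec(fov_mm = 0.5, density = cfg[2], modulation = 20,
                         seed = 7)
    ph <- gen_endothelial_mosaic(spec, cell_diameter_um = cfg[1])
    img <- highpass(ph$image, 121)
    det <- detect_cells(img, 1, "bright",
                        scale_um = ph$truth$cell_spacing_um,
                        mask = ph$truth$mask_bright)
    d <- measure_cell_diameters(img, det)
    expect_equal(mean_cell_diameter(d[is.finite(d)]), cfg[1],
                 tolerance = 0.15)
  }
})

test_that("snr follows the amplitude-dB convention and is scale invariant", {
  set.seed(8)
  img <- matrix(100, 60, 60)
  img[1:15, 1:15] <- rnorm(225, 0, 1.779)
  noise <- matrix(FALSE, 60, 60); noise[1:15, 1:15] <- TRUE
  expect_equal(snr_db(img, !noise, noise), 35, tolerance = 0.02)
  expect_equal(snr_db(3 * img, !noise, noise), snr_db(img, !noise, noise))
  expect_equal(snr_db(img, !noise, noise, convention = "power"),
               snr_db(img, !noise, noise) / 2)
  # mean 100 against noise of sd ~100 gives ~0 dB
  img0 <- matrix(100, 10, 10)
  img0[, 1:5] <- c(-100, 100)
  noise0 <- matrix(FALSE, 10, 10); noise0[, 1:5] <- TRUE
  expect_equal(snr_db(img0, !noise0, noise0), 0, tolerance = 0.1)
  expect_error(snr_db(img0, matrix(TRUE, 10, 10), matrix(TRUE, 10, 10)),
               "disjoint")
})
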