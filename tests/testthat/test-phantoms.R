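test_that("mosaic generator hits the target count and is deterministic", {
  spec <- phantom_spec(fov_mm = c(1, 0.5), density = 3200, seed = 5)
  ph <- gen_endothelial_mosaic(spec)
  expect_equal(nrow(ph$truth$centers), round(3200 * 0.5))
  ph2 <- gen_endothelial_mosaic(spec)
  expect_identical(ph$image, ph2$image)
  # both contrast signs coexist
  expect_gt(sum(ph$truth$bright), 50)
  expect_gt(sum(ph$truth$dark), 50)
  # flat background at zero density
  flat <- gen_endothelial_mosaic(phantom_spec(fov_mm = 0.2, density = 0))
  expect_equal(max(flat$image) - min(flat$image), 0)
  expect_error(gen_endothelial_mosaic(phantom_spec(density = 100)),
               "within")
  expect_error(gen_endothelial_mosaic(phantom_spec(density = 9000)),
               "within")
})

test_that("nerve generator lands on the target length and is deterministic", {
  spec <- phantom_spec(fov_mm = 1, density = 22, seed = 2)
  ph <- gen_nerve_layer(spec)
  expect_equal(ph$truth$total_length_mm, 22, tolerance = 0.02)
  expect_identical(gen_nerve_layer(spec)$image, ph$image)
  none <- gen_nerve_layer(phantom_spec(fov_mm = 0.3, density = 0))
  expect_equal(length(none$truth$polylines), 0)
  expect_equal(max(none$image) - min(none$image), 0)
})

test_that("scatterer stacks cross the bright/invisible/dark transition", {
  spec <- phantom_spec(fov_mm = 0.2, modulation = 10, seed = 3)
  zr <- spec$params$z_rayleigh_um
  zo <- c(-zr, 0, zr)
  st <- gen_scatterer_stack(spec, zo, n_scatterers = 10)
  ctr <- round(st$truth$centers)
  dev <- vapply(1:3, function(k) max(abs(st$stack$frames[[k]][ctr] - 100)),
                numeric(1))
  expect_lt(dev[2], 1e-9)            # invisible in focus
  expect_gt(dev[1], 1)               # visible off focus
  expect_equal(st$truth$rel_modulation[1], -st$truth$rel_modulation[3])
  # smaller source: scatterer visible over more slices
  zwide <- seq(-4 * zr, 4 * zr, length.out = 9)
  small <- gen_scatterer_stack(phantom_spec(fov_mm = 0.2, modulation = 10,
                                            source_diameter_mm = 0.3,
                                            seed = 3), zwide)
  big <- gen_scatterer_stack(phantom_spec(fov_mm = 0.2, modulation = 10,
                                          source_diameter_mm = 15,
                                          seed = 3), zwide)
  visible <- function(st) sum(abs(st$truth$rel_modulation) > 0.2)
  expect_gt(visible(small), visible(big))
  # deterministic per seed
  st2 <- gen_scatterer_stack(spec, zo, n_scatterers = 10)
  expect_identical(st$stack$frames, st2$stack$frames)
})

test_that("camera artifacts are seeded, shared across frames, removable", {
  spec0 <- phantom_spec(fov_mm = 0.2, density = 0)
  img <- matrix(100, 200, 200)
  # all artifact parameters zero: identity
  ident <- add_camera_artifacts(img, spec0)
  expect_identical(ident$image, img)
  spec <- phantom_spec(fov_mm = 0.2, density = 0, fixed_pattern_rms = 4,
                       bayer_amplitude = 3, noise_sd = 1, seed = 9)
  a1 <- add_camera_artifacts(img, spec)
  a2 <- add_camera_artifacts(img, spec)
  expect_identical(a1$image, a2$image)
  expect_equal(sqrt(mean(a1$artifacts$fixed_pattern^2)), 4, tolerance = 1e-9)
  # the fixed pattern is shared across a stack
  st <- image_stack(list(img, img))
  as <- add_camera_artifacts(st, spec)
  expect_identical(as$artifacts$fixed_pattern,
                   add_camera_artifacts(img, spec)$artifacts$fixed_pattern)
  # closed loop with the pipeline: bayer_smooth halves the injected peak
  checker <- outer(1:200, 1:200, function(r, c) (-1)^(r + c))
  peak <- function(m) abs(mean(m * checker))
  sm <- bayer_smooth(a1$image)
  expect_lt(peak(sm), 0.5 * peak(a1$image))
})

test_that("injected fixed pattern is attenuated by the pipeline closed loop", {
  spec <- phantom_spec(fov_mm = 0.6, density = 22, modulation = 20,
                       fixed_pattern_rms = 5, seed = 13)
  ph <- gen_nerve_layer(spec)
  st <- shifted_stack(ph$image, 50, 77)
  art <- add_camera_artifacts(st, spec)
  cleaned <- remove_fixed_pattern(art$stack)
  # correlation of the cleaned frames with the injected pattern
  fp <- art$artifacts$fixed_pattern
  leak <- vapply(cleaned$frames, function(f) {
    sum(f * fp) / sum(fp^2)
  }, numeric(1))
  expect_lt(max(abs(leak)) * sqrt(mean(fp^2)), 0.15 * sqrt(mean(fp^2)))
})
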