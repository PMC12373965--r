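test_that("bayer smoothing suppresses the period-2 mosaic modulation", {
  const <- matrix(7, 40, 40)
  expect_equal(bayer_smooth(const), const)
  # synthetic Bayer checkerboard: measure the Nyquist spectral component
  checker <- outer(1:64, 1:64, function(r, c) (-1)^(r + c))
  img <- 100 + 5 * checker
  peak <- function(m) abs(mean(m * checker))
  sm <- bayer_smooth(img)
  expect_lt(peak(sm), 0.5 * peak(img))
  expect_equal(mean(sm), mean(img), tolerance = 1e-6)
  # impulse response recovers the 3x3 kernel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  k <- bayer_smooth(imp)[10:12, 10:12]
  g <- exp(-(-1:1)^2 / (2 * 0.8^2)); g <- g / sum(g)
  expect_equal(k, outer(g, g), tolerance = 1e-10)
  expect_warning(bayer_smooth(const, camera = "mono_global"), "no-op")
})

test_that("fixed-pattern removal subtracts the temporal mean", {
  f <- matrix(rnorm(400), 20, 20)
  st <- image_stack(replicate(12, f, simplify = FALSE))
  out <- remove_fixed_pattern(st)
  expect_true(all(vapply(out$frames, function(x) max(abs(x)), numeric(1)) <
                    1e-12))
  # pattern-free moving stack: output differs from input by the per-pixel mean
  frames <- replicate(10, matrix(rnorm(400), 20, 20), simplify = FALSE)
  st2 <- image_stack(frames)
  avg <- Reduce(`+`, frames) / 10
  out2 <- remove_fixed_pattern(st2)
  expect_equal(out2$frames[[3]], frames[[3]] - avg)
  expect_error(remove_fixed_pattern(image_stack(frames[1])), "stack")
})

test_that("fixed pattern is strongly attenuated on a translating stack", {
  set.seed(11)
  # smooth translating texture plus a static pattern of known RMS
  big <- gaussian_smooth(matrix(rnorm(600 * 600), 600, 600), 4) * 30
  fp <- matrix(rnorm(160000), 400, 400)
  fp <- 5 * fp / sqrt(mean(fp^2))
  offs <- cbind(sample(1:200, 50), sample(1:200, 50))
  frames <- lapply(1:50, function(k) {
    big[offs[k, 1] + 1:400, offs[k, 2] + 1:400] + fp
  })
  out <- remove_fixed_pattern(image_stack(frames))
  # static component of the cleaned stack, via the temporal median oracle
  static <- apply(simplify2array(out$frames), c(1, 2), median)
  expect_lt(sqrt(mean(static^2)), 0.15 * sqrt(mean(fp^2)))
})

test_that("large-kernel high-pass removes backgrounds, keeps small features", {
  expect_lt(max(abs(highpass(matrix(3.7, 150, 150)))), 1e-9)
  # small bright disc on a constant background
  img <- matrix(50, 200, 200)
  xy <- as.matrix(expand.grid(1:200, 1:200))
  disc <- matrix((xy[, 1] - 100)^2 + (xy[, 2] - 100)^2 <= 10^2, 200, 200)
  img[disc] <- 70
  hp <- highpass(img, 121)
  expect_equal(max(hp), 20, tolerance = 0.1)
  expect_lt(abs(median(hp[!disc])), 1)
  # slow ramp mostly removed in the interior
  ramp <- outer(seq(0, 50, length.out = 300), rep(1, 300))
  hpr <- highpass(ramp, 121)
  expect_lt(max(abs(hpr[100:200, 100:200])), 0.05 * 50)
  expect_error(highpass(img, 120), "odd")
  # gaussian variant also zeroes a constant
  expect_lt(max(abs(highpass(matrix(2, 80, 80), 31, method = "gaussian"))),
            1e-9)
})

test_that("frame averaging reduces white noise by sqrt(n)", {
  set.seed(21)
  frames <- replicate(40, matrix(5 + rnorm(128 * 128), 128, 128),
                      simplify = FALSE)
  st <- image_stack(frames)
  expect_identical(average_frames(st, 1), frames[[1]])
  avg <- average_frames(st, 40)
  expect_equal(sd(avg), 1 / sqrt(40), tolerance = 0.1)
  same <- image_stack(replicate(5, frames[[1]], simplify = FALSE))
  expect_equal(average_frames(same), frames[[1]])
  expect_error(average_frames(st, 41), "between")
})

test_that("pulse-frame selection picks the brightest frame, earliest on ties", {
  mk <- function(v) lapply(v, function(m) matrix(m, 4, 4))
  buf <- image_stack(mk(c(3, 9, 5)))
  expect_equal(attr(select_pulse_frame(buf), "index"), 2)
  ties <- image_stack(mk(c(2, 2, 2)))
  expect_equal(attr(select_pulse_frame(ties), "index"), 1)
  # simulated duty-cycle buffer: the single lit frame always wins
  set.seed(3)
  for (i in 1:10) {
    bright <- sample(1:10, 1)
    v <- rep(1, 10); v[bright] <- 8
    frames <- lapply(v, function(m) matrix(m + rnorm(16, 0, 0.1), 4, 4))
    expect_equal(attr(select_pulse_frame(image_stack(frames)), "index"),
                 bright)
  }
})

test_that("two-phase subtraction doubles the flipping structure", {
  a <- matrix(rnorm(100), 10, 10)
  expect_equal(two_phase_subtract(a, a), matrix(0, 10, 10))
  b <- matrix(rnorm(100) + 5, 10, 10)
  expect_equal(two_phase_subtract(a, b, gain_match = FALSE),
               -two_phase_subtract(b, a, gain_match = FALSE))
  expect_error(two_phase_subtract(a, matrix(0, 5, 5)), "shape")
  # scatterers rendered at opposite defocus phases through the contrast model
  spec <- phantom_spec(fov_mm = 0.2, modulation = 10, seed = 4)
  zr <- spec$params$z_rayleigh_um
  st <- gen_scatterer_stack(spec, z_offsets_um = c(-zr, zr), n_scatterers = 8)
  fa <- st$stack$frames[[1]]; fb <- st$stack$frames[[2]]
  d <- two_phase_subtract(fa, fb)
  single_mod <- max(abs(fa - 100))
  ctr <- round(st$truth$centers)
  at_scatterers <- abs(d[ctr])
  expect_equal(max(at_scatterers), 2 * single_mod, tolerance = 0.05)
  # defocus-symmetric background: pixels far from every scatterer
  xy <- as.matrix(expand.grid(seq_len(nrow(d)), seq_len(ncol(d))))
  dist2 <- Reduce(pmin, lapply(seq_len(nrow(ctr)), function(i) {
    (xy[, 1] - ctr[i, 1])^2 + (xy[, 2] - ctr[i, 2])^2
  }))
  far <- abs(d)[matrix(dist2 > 20^2, nrow(d))]
  expect_lt(max(far), 0.1 * max(at_scatterers))
})

test_that("the per-camera chain applies the published stage order", {
  set.seed(9)
  frames <- replicate(12, matrix(100 + rnorm(10000), 100, 100),
                      simplify = FALSE)
  mono <- image_stack(frames, camera = "mono_global")
  out <- process_stack(mono, highpass_kernel = 31, average = 5)
  expect_true(is.matrix(out))
  expect_lt(abs(mean(out)), 0.5)
  color <- image_stack(frames[1], camera = "color_rolling")
  out2 <- process_stack(color, highpass_kernel = 31)
  expect_s3_class(out2, "image_stack")
})
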