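test_that("source projection reproduces the prototype spot sizes", {
  adult <- eye_geometry()
  model <- eye_preset("artificial_model")
  expect_equal(project_source_to_sclera(illumination_train(1.8, 40, 40, 18),
                                        adult), 1.7)
  expect_equal(project_source_to_sclera(illumination_train(1.8, 40, 40, 10),
                                        adult), 3.06, tolerance = 1e-12)
  expect_equal(project_source_to_sclera(
    illumination_train(1.8, 50, 50, 18, aperture_diameter = 0.2), model),
    0.3, tolerance = 0.1)
  expect_equal(project_source_to_sclera(illumination_train(1.8, 8, 50, 18),
                                        model), 15, tolerance = 0.05)
  expect_error(illumination_train(1.8, -40, 40, 18), "positive")
})

test_that("scleral diffusion broadens the spot as 2*sqrt(s0^2 + 2 z l*)", {
  eye <- eye_geometry()
  expect_equal(scleral_broadening(1.7, eye), 2.4, tolerance = 0.02)
  expect_equal(scleral_broadening(3, eye), 3.4, tolerance = 0.01)
  # no sclera, no diffusion
  dry <- eye_geometry(sclera_thickness = 1e-12)
  for (d in c(0.1, 1, 4)) {
    expect_equal(scleral_broadening(d, dry), d, tolerance = 1e-4)
  }
  # monotone in both arguments
  d <- seq(0, 5, by = 0.5)
  b <- vapply(d, scleral_broadening, numeric(1), eye = eye)
  expect_true(all(diff(b) > 0))
  expect_true(all(b >= d))
  thick <- eye_geometry(sclera_thickness = 2)
  expect_gt(scleral_broadening(2, thick), scleral_broadening(2, eye))
  expect_error(scleral_broadening(-1, eye), "non-negative")
})

test_that("illumination NA follows n*sin(arctan(r/L)) and is bounded", {
  eye <- eye_geometry()
  expect_equal(illumination_na(0.3, eye), 0.01, tolerance = 0.1)
  expect_equal(illumination_na(15, eye), 0.43, tolerance = 0.02)
  expect_identical(illumination_na(0, eye), 0)
  d <- seq(0, 200, length.out = 50)
  nas <- vapply(d, illumination_na, numeric(1), eye = eye)
  expect_true(all(diff(nas) > 0))
  expect_true(all(nas < eye$n_cornea_lens))
})

test_that("effective NA averages and clamps at the detection aperture", {
  det <- detection_config(0.3)
  expect_equal(effective_na(0.3, det), 0.3)
  expect_equal(effective_na(0.0730, det), 0.1865)
  expect_equal(effective_na(0.43, det), 0.3)
})

test_that("resolution and DOF keep exact unit consistency", {
  eye <- eye_geometry()
  det <- detection_config(0.3)
  rep1 <- resolution_dof(0.3, det, eye)
  expect_equal(rep1$lateral_resolution_um, 0.61 * 0.85 / 0.3)
  # halving / quartering scalings
  rep2 <- resolution_dof(0.6, det, eye)
  expect_equal(rep2$lateral_resolution_um, rep1$lateral_resolution_um / 2)
  expect_equal(rep2$depth_of_field_um, rep1$depth_of_field_um / 4)
  # identities hold for arbitrary reports
  for (na in c(0.05, 0.19, 0.44)) {
    r <- resolution_dof(na, det, eye)
    expect_equal(r$lateral_resolution_um * r$na_effective, 0.61 * det$wavelength)
    expect_equal(r$depth_of_field_um * r$na_effective^2,
                 eye$n_cornea_lens * det$wavelength)
  }
  expect_error(resolution_dof(0, det, eye), "positive")
})

test_that("full chain matches an independent straight-line recomputation", {
  set.seed(42)
  for (i in 1:100) {
    L <- runif(1, 18, 28); fe <- runif(1, 14, 26); n <- runif(1, 1.3, 1.5)
    z <- runif(1, 0.5, 1.5); mus <- runif(1, 20, 40)
    na_d <- runif(1, 0.1, 0.6); lam <- runif(1, 0.4, 1.1)
    spot <- runif(1, 0.2, 16)
    eye <- eye_geometry(L, fe, n, z, mus)
    det <- detection_config(na_d, lam, eye)
    got <- optics_chain(spot, det, eye)
    # straight-line oracle, printed formulas only
    l_star <- 10 / mus
    d_diff <- 2 * sqrt((spot / 2)^2 + 2 * z * l_star)
    na_i <- n * sin(atan(d_diff / 2 / L))
    na_eff <- (min(na_i, na_d) + na_d) / 2
    expect_equal(got$diffused_spot_mm, d_diff, tolerance = 1e-12)
    expect_equal(got$na_illumination, na_i, tolerance = 1e-12)
    expect_equal(got$na_effective, na_eff, tolerance = 1e-12)
    expect_equal(got$lateral_resolution_um, 0.61 * lam / na_eff,
                 tolerance = 1e-12)
    expect_equal(got$depth_of_field_um, n * lam / na_eff^2,
                 tolerance = 1e-12)
  }
})

test_that("presets and the etendue diagnostic are wired up", {
  expect_equal(eye_preset("child")$eye_focal_length, 15)
  expect_equal(eye_preset("artificial_model")$eye_focal_length, 25)
  e <- illumination_etendue(1.8, 0.3)
  expect_true(attr(e, "informative_only"))
  expect_gt(e, 0)
})
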