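test_that("lift-off on a step curve returns the step area", {
  a <- seq(70, 30, by = -0.5)
  p <- ifelse(a >= 50, 0, 5)
  crv <- isotherm_curve(a, p, "compression")
  expect_equal(detect_lift_off(crv, threshold = 0.5), 50,
               tolerance = 0.06 / 50)  # within the 0.5 grid, scaled
})

test_that("lift-off errors when pressure never exceeds the threshold", {
  crv <- isotherm_curve(seq(70, 30, by = -1), rep(0, 41), "compression")
  expect_error(detect_lift_off(crv), "no lift-off")
})

test_that("lift-off ignores extra below-threshold samples at larger areas", {
  params <- synthetic_params(noise_sd = 0, seed = 2)
  crv <- generate_isotherm(params)
  base <- detect_lift_off(crv)
  extra_a <- seq(90, 76, by = -1)
  crv2 <- isotherm_curve(c(extra_a, crv$area),
                         c(rep(0.05, length(extra_a)), crv$pressure),
                         "compression")
  expect_equal(detect_lift_off(crv2), base)
})

test_that("lift-off recovers the generator truth within one grid step", {
  params <- synthetic_params(noise_sd = 0, seed = 2)
  crv <- generate_isotherm(params)
  grid <- abs(mean(diff(crv$area)))
  expect_equal(detect_lift_off(crv), synthetic_truth(params)$A_lift_off,
               tolerance = grid / synthetic_truth(params)$A_lift_off)
})

test_that("collapse pressure-max recovers the generator plateau pressure", {
  params <- synthetic_params(noise_sd = 0, seed = 2)
  crv <- generate_isotherm(params)
  cp <- detect_collapse(crv, mode = "pressure_max")
  expect_equal(cp$pressure, 45.0, tolerance = 1e-3)
  expect_false(cp$plateau_absent)
})

test_that("kink mode falls back on a strictly linear rising branch", {
  crv <- linear_branch(m = 1.5, b = 100, a_from = 60, a_to = 35, clip = FALSE)
  cp <- detect_collapse(crv, mode = "kink")
  expect_true(cp$plateau_absent)
  # fallback endpoint: the pressure maximum of the branch (smallest area)
  expect_equal(cp$area, min(crv$area), tolerance = 0.01)
})

test_that("pressure-max and kink agree on a branch with a plateau", {
  a <- seq(60, 20, by = -0.1)
  # rise to a 36 mN/m peak at a = 30, then a plateau just below the peak
  p <- ifelse(a >= 30, pmax(36 - 1.8 * (a - 30), 0), 35.5)
  crv <- isotherm_curve(a, p, "compression")
  pm <- detect_collapse(crv, mode = "pressure_max", window = 7)
  kk <- detect_collapse(crv, mode = "kink", window = 7)
  expect_false(kk$plateau_absent)
  da <- abs(mean(diff(a)))
  expect_lt(abs(pm$area - kk$area), 2 * da + 1e-9)
})

test_that("monotone non-increasing pressure has no collapse", {
  a <- seq(60, 30, length.out = 50)
  crv <- isotherm_curve(a, 5 + 0.5 * a, "compression")  # pi falls as A falls
  expect_error(detect_collapse(crv), "no collapse")
})

test_that("chi is the collapse/lift-off ratio with half-up reporting", {
  ref <- reference_descriptors()
  chi <- compute_chi(ref$A_collapse, ref$A_lift_off)
  expect_equal(round_half_up(chi, 3), ref$chi)
  expect_error(compute_chi(5, 5), "smaller")
  expect_error(compute_chi(-1, 5), "positive")
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(0.0725, 3), 0.073)
  expect_equal(round_half_up(0.0625, 3), 0.063)  # round() would give 0.062
  expect_equal(round_half_up(-0.0725, 3), -0.073)
})

test_that("dynamic-rise slope is exact on a noiseless line", {
  crv <- linear_branch(m = 1.79, b = 120, a_from = 64, a_to = 22, n = 300)
  s1 <- fit_slope_le_lc(crv, pi_collapse = max(crv$pressure),
                        a_collapse = min(crv$area))
  expect_equal(as.numeric(s1), -1.79, tolerance = 1e-10)
  # independent of the region bounds on a pure line
  s2 <- fit_slope_le_lc(crv, lower = 0.4, upper = 0.6,
                        pi_collapse = max(crv$pressure),
                        a_collapse = min(crv$area))
  expect_equal(as.numeric(s2), -1.79, tolerance = 1e-10)
  expect_gt(attr(s1, "r.squared"), 0.999999)
})

test_that("dynamic-rise slope tolerates pressure noise", {
  set.seed(7)
  a <- seq(64, 22, length.out = 200)
  p <- 120 - 1.79 * a + stats::rnorm(200, sd = 0.1)
  crv <- isotherm_curve(a, p, "compression")
  s <- fit_slope_le_lc(crv, pi_collapse = 120 - 1.79 * 22, a_collapse = 22)
  expect_equal(as.numeric(s), -1.79, tolerance = 0.05 / 1.79)
})

test_that("slope fit demands enough samples in the region", {
  crv <- linear_branch(n = 200)
  expect_error(fit_slope_le_lc(crv, lower = 0.499, upper = 0.501,
                               pi_collapse = max(crv$pressure),
                               a_collapse = min(crv$area)),
               "insufficient data")
})

test_that("area shift at a reference pressure behaves affinely", {
  params <- synthetic_params(noise_sd = 0, seed = 4)
  crv <- generate_isotherm(params)
  expect_equal(area_shift_at_pressure(crv, crv, 30), 0)
  shifted <- isotherm_curve(crv$area * 1.10, crv$pressure, "compression")
  expect_equal(area_shift_at_pressure(crv, shifted, 30), 10,
               tolerance = 1e-9)
  shifted2 <- isotherm_curve(crv$area * 1.073, crv$pressure, "compression")
  expect_equal(area_shift_at_pressure(crv, shifted2, 30), 7.3,
               tolerance = 0.1 / 7.3)
})

test_that("area shift is antisymmetric up to the ratio transform", {
  params <- synthetic_params(noise_sd = 0, seed = 4)
  a <- generate_isotherm(params)
  b <- isotherm_curve(a$area * 1.15, a$pressure, "compression")
  s_ab <- area_shift_at_pressure(a, b, 30)
  s_ba <- area_shift_at_pressure(b, a, 30)
  expect_equal(s_ab, -s_ba / (1 + s_ba / 100), tolerance = 1e-8)
})

test_that("area shift errors when the pressure is not attained", {
  crv <- linear_branch(m = 0.2, b = 20, a_from = 60, a_to = 30)  # max pi 14
  params <- synthetic_params(noise_sd = 0, seed = 4)
  expect_error(area_shift_at_pressure(generate_isotherm(params), crv, 30),
               "outside")
})

test_that("extract_features returns the full descriptor row", {
  params <- synthetic_params(noise_sd = 0.05, seed = 9)
  feats <- extract_features(generate_isotherm(params))
  expect_named(feats, c("A_lift_off", "A_collapse", "pi_collapse", "A_max",
                        "pi_max", "Cs1_max", "chi", "a_LE_LC", "phase"))
  tr <- synthetic_truth(params)
  expect_equal(feats$pi_collapse, tr$pi_collapse, tolerance = 0.01)
  expect_equal(feats$a_LE_LC, tr$a_LE_LC, tolerance = 0.02)
  expect_equal(feats$phase, "liquid_condensed")
})
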