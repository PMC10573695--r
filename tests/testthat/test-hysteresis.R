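test_that("a fully retraced loop has Rv = 100", {
  cy <- damped_cycle(f = 1.0)
  res <- reversibility_factor(cy)
  expect_equal(res$Rv, 100, tolerance = 1e-9)
  expect_false(res$flagged)
})

test_that("pointwise damping of the expansion scales Rv linearly", {
  for (f in c(0.5, 0.671)) {
    res <- reversibility_factor(damped_cycle(f = f))
    expect_equal(res$Rv, 100 * f, tolerance = 1e-9)
  }
})

test_that("Rv above 100 is allowed but flagged", {
  params <- synthetic_params(noise_sd = 0, seed = 1, loop_damping = 1,
                             n_samples = 300L)
  cy <- generate_hysteresis(params)[[1L]]
  boosted <- isotherm_curve(cy$expansion$area, 1.2 * cy$expansion$pressure,
                            "expansion")
  res <- reversibility_factor(hysteresis_cycle(cy$compression, boosted))
  expect_equal(res$Rv, 120, tolerance = 1e-6)
  expect_true(res$flagged)
})

test_that("Rv is invariant under uniform rescaling of pi and of A", {
  cy <- damped_cycle(f = 0.7)
  base <- reversibility_factor(cy)$Rv
  k <- 2.5
  cy_p <- hysteresis_cycle(
    isotherm_curve(cy$compression$area, k * cy$compression$pressure,
                   "compression"),
    isotherm_curve(cy$expansion$area, k * cy$expansion$pressure,
                   "expansion"))
  expect_equal(reversibility_factor(cy_p)$Rv, base, tolerance = 1e-6)
  cy_a <- hysteresis_cycle(
    isotherm_curve(k * cy$compression$area, cy$compression$pressure,
                   "compression"),
    isotherm_curve(k * cy$expansion$area, cy$expansion$pressure,
                   "expansion"))
  expect_equal(reversibility_factor(cy_a)$Rv, base, tolerance = 1e-6)
})

test_that("trapezoid integration matches adaptive quadrature on the model", {
  params <- synthetic_params(noise_sd = 0, seed = 1, n_samples = 500L)
  crv <- generate_isotherm(params)
  a_low <- 30
  a_high <- 55
  fine <- stats::integrate(function(a) synthetic_pressure(a, params),
                           a_low, a_high, subdivisions = 2000L,
                           rel.tol = 1e-10)$value
  cy <- hysteresis_cycle(crv,
                         isotherm_curve(rev(crv$area), rev(crv$pressure),
                                        "expansion"))
  res <- reversibility_factor(cy, bounds = "fixed",
                              fixed_bounds = c(a_low, a_high))
  expect_equal(res$compression_integral, fine, tolerance = 1e-3)
})

test_that("negative pressures are clamped for integration only", {
  a <- seq(60, 20, by = -0.5)  # grid contains the kink at a = 30
  p <- 30 - a  # negative for a > 30
  comp <- isotherm_curve(a, p, "compression")
  expn <- isotherm_curve(rev(a), rev(0.5 * p), "expansion")
  res <- reversibility_factor(hysteresis_cycle(comp, expn),
                              bounds = "fixed", fixed_bounds = c(20, 60))
  # clamped integrals: int max(30 - a, 0) da from 20 to 30 = 50
  expect_equal(res$compression_integral, 50, tolerance = 1e-9)
  expect_equal(res$Rv, 50, tolerance = 1e-9)
})

test_that("incomplete cycles and zero compression work are rejected", {
  comp <- linear_branch(n = 50)
  expect_error(reversibility_factor(hysteresis_cycle(comp, NULL)),
               "incomplete")
  flat_c <- isotherm_curve(seq(60, 20, length.out = 50), rep(0, 50),
                           "compression")
  flat_e <- isotherm_curve(seq(20, 60, length.out = 50), rep(0, 50),
                           "expansion")
  expect_error(reversibility_factor(hysteresis_cycle(flat_c, flat_e),
                                    bounds = "fixed",
                                    fixed_bounds = c(25, 55)),
               "compression integral")
})

test_that("loop_trend reports strict monotone increase and lift-off shifts", {
  mk <- function(rv, i, ahigh = 61.6) {
    data.frame(loop_index = i, Rv = rv, A_low = 19, A_high = ahigh,
               compression_integral = 1, expansion_integral = rv / 100,
               clipped = FALSE, flagged = FALSE)
  }
  up <- rbind(mk(67.10, 1), mk(79.44, 2, 60.1), mk(82.39, 3, 58.6))
  tr <- loop_trend(up)
  expect_true(tr$monotone_increase)
  expect_equal(tr$per_loop$liftoff_shift, c(0, -1.5, -3.0))
  down <- rbind(mk(52.42, 1), mk(75.62, 2), mk(44.45, 3))
  expect_false(loop_trend(down)$monotone_increase)
  tie <- rbind(mk(50, 1), mk(50, 2))
  expect_false(loop_trend(tie)$monotone_increase)
  single <- loop_trend(mk(80, 1))
  expect_true(is.na(single$monotone_increase))
  expect_equal(nrow(single$per_loop), 1L)
})
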