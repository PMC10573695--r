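# Shared fixture builders. All synthetic inputs are generated in code.

# A noiseless linear compression branch pi = b - m * A, clipped at zero.
linear_branch <- function(m = 1.2, b = 80, a_from = 60, a_to = 20,
                          n = 200, clip = TRUE) {
  a <- seq(a_from, a_to, length.out = n)
  p <- b - m * a
  if (clip) p <- pmax(p, 0)
  isotherm_curve(a, p, direction = "compression")
}

# A triangular (compression + expansion) area sweep trace with n_loops
# loops; pressure follows a simple linear law of area.
triangle_trace <- function(n_loops = 3, n_half = 60, a_hi = 70, a_lo = 20,
                           area_noise_sd = 0, seed = 42) {
  set.seed(seed)
  a <- numeric(0)
  for (i in seq_len(n_loops)) {
    down <- seq(a_hi, a_lo, length.out = n_half)
    # drop both endpoints so the apex/trough samples are never duplicated
    up <- seq(a_lo, a_hi, length.out = n_half)[-c(1L, n_half)]
    a <- c(a, down, up)
  }
  a <- c(a, a_hi)  # close the final sweep
  if (area_noise_sd > 0) a <- a + stats::rnorm(length(a), sd = area_noise_sd)
  p <- pmax(0, 45 - 0.9 * a)
  df <- data.frame(time = seq_along(a), area_per_molecule = a,
                   surface_pressure = p)
  class(df) <- c("trough_trace", "data.frame")
  df
}

# A hysteresis cycle whose expansion pressures are `f` times the
# compression pressures on the same area grid.
damped_cycle <- function(f = 0.5, index = 1L, n = 400) {
  params <- synthetic_params(noise_sd = 0, seed = 1, loop_damping = f,
                             n_samples = n)
  generate_hysteresis(params)[[1L]]
}
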