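#' Parameters of the synthetic isotherm model
#'
#' A piecewise equation-of-state model generating realistic compression
#' isotherms with closed-form ground truth, used to validate every
#' analysis stage:
#'
#' * a zero-pressure gas region for `A >= A_liftoff`;
#' * a Volmer-type liquid-expanded rise
#'   `pi = kT_eff / (A - A0) - pi_offset` between the LE/LC transition
#'   point `(A_t, pi_t)` and lift-off, with `pi_offset` fixed by
#'   `pi(A_liftoff) = 0` and `kT_eff` by continuity at the transition;
#' * a linear liquid-condensed branch of slope `-m_LC` down to the
#'   collapse pressure `pi_c`;
#' * a flat collapse plateau of length `plateau_len`.
#'
#' Gaussian noise of standard deviation `noise_sd` is added to the
#' pressure only; the area grid is exact (pressure sensing dominates the
#' noise of Wilhelmy systems). Generation is always seeded.
#'
#' The closed-form truths (see [synthetic_truth()]): lift-off area
#' `A_liftoff`; collapse at `A_collapse = A_t - (pi_c - pi_t)/m_LC` with
#' pressure `pi_c`; dynamic-rise slope `-m_LC`; modulus maximum
#' `Cs1_max = m_LC * A_t` attained at `(A_t, pi_t)`; and per-loop
#' reversibility `Rv_i = 100 * f_i` for damping factors `f_i`.
#'
#' The defaults emulate a soy-phospholipid monolayer: lift-off near
#' 62 A^2/molecule, collapse at 45 mN/m, maximum compression modulus near
#' 68 mN/m, and three loops whose reversibility echoes typical
#' lipid-film hysteresis.
#'
#' @param A_liftoff True lift-off area, A^2/molecule.
#' @param A0 Volmer co-area (excluded area), A^2/molecule; `A0 < A_t`.
#' @param A_t,pi_t LE/LC transition point (A^2/molecule, mN/m);
#'   `A0 < A_t < A_liftoff`, `pi_t < pi_c`.
#' @param m_LC Magnitude of the liquid-condensed slope, mN/m per
#'   A^2/molecule (> 0). Must exceed the Volmer slope at the transition
#'   so the isotherm steepens through it.
#' @param pi_c Collapse pressure, mN/m.
#' @param plateau_len Length of the collapse plateau, A^2/molecule.
#' @param A_start Largest sampled area, A^2/molecule (> `A_liftoff`).
#' @param n_samples Number of samples per branch.
#' @param noise_sd Gaussian pressure noise, mN/m.
#' @param seed RNG seed (required; no unseeded path).
#' @param loop_damping Vector of damping factors `f_i` in (0, 1], one per
#'   hysteresis loop; loop i's expansion pressures are `f_i` times its
#'   compression pressures.
#' @param loop_area_shift Leftward area shift of successive loops,
#'   A^2/molecule per loop.
#' @param kT_eff Optional explicit LE-branch scale (mN/m * A^2); if
#'   given it must agree with the value implied by continuity at
#'   `(A_t, pi_t)`, otherwise a parameter error is raised.
#' @return A list of class `synthetic_params` (with derived `kT_eff`,
#'   `pi_offset`, `A_collapse`, `A_end`).
#' @export
synthetic_params <- function(A_liftoff = 61.6, A0 = 5, A_t = 38.2,
                             pi_t = 10.5, m_LC = 1.79, pi_c = 45,
                             plateau_len = 5, A_start = 75,
                             n_samples = 1000L, noise_sd = 0.1,
                             seed = 1L,
                             loop_damping = c(0.671, 0.794, 0.824),
                             loop_area_shift = 1.5,
                             kT_eff = NULL) {
  if (!(A0 < A_t && A_t < A_liftoff)) {
    stop("need A0 < A_t < A_liftoff", call. = FALSE)
  }
  if (!(pi_t > 0 && pi_t < pi_c)) stop("need 0 < pi_t < pi_c", call. = FALSE)
  if (m_LC <= 0) stop("`m_LC` must be positive", call. = FALSE)
  if (A_start <= A_liftoff) stop("`A_start` must exceed `A_liftoff`",
                                 call. = FALSE)
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  if (any(loop_damping <= 0 | loop_damping > 1)) {
    stop("damping factors must lie in (0, 1]", call. = FALSE)
  }
  kT_implied <- pi_t / (1 / (A_t - A0) - 1 / (A_liftoff - A0))
  if (!is.null(kT_eff)) {
    if (abs(kT_eff - kT_implied) > 1e-6 * kT_implied) {
      stop(sprintf(paste0("inconsistent parameters: kT_eff = %.6g does not ",
                          "join the branches continuously (implied %.6g)"),
                   kT_eff, kT_implied), call. = FALSE)
    }
  }
  kT_eff <- kT_implied
  volmer_slope_t <- kT_eff / (A_t - A0)^2
  if (m_LC <= volmer_slope_t) {
    stop(sprintf(paste0("inconsistent parameters: LC slope m_LC = %.3g must ",
                        "exceed the Volmer slope %.3g at the transition"),
                 m_LC, volmer_slope_t), call. = FALSE)
  }
  A_collapse <- A_t - (pi_c - pi_t) / m_LC
  A_end <- A_collapse - plateau_len
  if (A_end <= 0) stop("plateau extends below zero area", call. = FALSE)
  structure(list(A_liftoff = A_liftoff, A0 = A0, A_t = A_t, pi_t = pi_t,
                 m_LC = m_LC, pi_c = pi_c, plateau_len = plateau_len,
                 A_start = A_start, n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 loop_damping = loop_damping,
                 loop_area_shift = loop_area_shift,
                 kT_eff = kT_eff,
                 pi_offset = kT_eff / (A_liftoff - A0),
                 A_collapse = A_collapse, A_end = A_end),
            class = "synthetic_params")
}

#' Closed-form ground truth of a synthetic parameter set
#'
#' @param params A [synthetic_params()] object.
#' @return A list: `A_lift_off`, `A_collapse`, `pi_collapse`, `A_max`,
#'   `pi_max`, `Cs1_max`, `a_LE_LC`, `Rv` (vector, percent).
#' @export
synthetic_truth <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  list(A_lift_off = params$A_liftoff,
       A_collapse = params$A_collapse,
       pi_collapse = params$pi_c,
       A_max = params$A_t,
       pi_max = params$pi_t,
       Cs1_max = params$m_LC * params$A_t,
       a_LE_LC = -params$m_LC,
       Rv = 100 * params$loop_damping)
}

#' Noiseless model pressure at given areas
#'
#' Evaluates the piecewise equation of state of [synthetic_params()].
#'
#' @param A Areas in A^2/molecule (vectorised).
#' @param params A [synthetic_params()] object.
#' @return Surface pressure in mN/m.
#' @export
synthetic_pressure <- function(A, params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- numeric(length(A))
  gas <- A >= params$A_liftoff
  le <- A < params$A_liftoff & A >= params$A_t
  lc <- A < params$A_t & A >= params$A_collapse
  plateau <- A < params$A_collapse
  p[gas] <- 0
  p[le] <- params$kT_eff / (A[le] - params$A0) - params$pi_offset
  p[lc] <- params$pi_t + params$m_LC * (params$A_t - A[lc])
  p[plateau] <- params$pi_c
  p
}

#' Generate one synthetic compression branch
#'
#' Samples the model uniformly in area from `A_start` down to the end of
#' the collapse plateau and adds seeded Gaussian pressure noise.
#' Two calls with the same parameters (hence the same seed) are
#' identical.
#'
#' @param params A [synthetic_params()] object.
#' @return An `isotherm_curve` (direction `"compression"`) whose metadata
#'   records the generating parameters.
#' @examples
#' p <- synthetic_params(noise_sd = 0, seed = 7)
#' crv <- generate_isotherm(p)
#' max(crv$pressure)  # collapse pressure, 45 by construction
#' @export
generate_isotherm <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  a <- seq(params$A_start, params$A_end, length.out = params$n_samples)
  p <- synthetic_pressure(a, params)
  set.seed(params$seed)
  if (params$noise_sd > 0) {
    p <- p + stats::rnorm(length(p), sd = params$noise_sd)
  }
  isotherm_curve(a, p, direction = "compression",
                 metadata = list(params = params))
}

#' Generate synthetic hysteresis loops
#'
#' Loop i's compression branch is the base isotherm shifted towards
#' smaller areas by `(i - 1) * loop_area_shift`; its expansion branch
#' retraces the same areas with pressures damped by the factor `f_i`
#' (`loop_damping[i]`), so the true reversibility of loop i is exactly
#' `100 * f_i` percent under per-loop bounds. Noise is drawn once, in
#' sequence, from the seeded generator.
#'
#' @param params A [synthetic_params()] object.
#' @return A list of [hysteresis_cycle()] objects, one per damping
#'   factor.
#' @export
generate_hysteresis <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  base_a <- seq(params$A_start, params$A_end, length.out = params$n_samples)
  base_p <- synthetic_pressure(base_a, params)
  set.seed(params$seed)
  cycles <- vector("list", length(params$loop_damping))
  for (i in seq_along(params$loop_damping)) {
    f <- params$loop_damping[i]
    a_i <- base_a - (i - 1) * params$loop_area_shift
    if (any(a_i <= 0)) stop("loop area shift drives areas below zero",
                            call. = FALSE)
    p_comp <- base_p
    p_exp <- f * base_p
    if (params$noise_sd > 0) {
      p_comp <- p_comp + stats::rnorm(length(a_i), sd = params$noise_sd)
      p_exp <- p_exp + stats::rnorm(length(a_i), sd = params$noise_sd)
    }
    comp <- isotherm_curve(a_i, p_comp, "compression",
                           metadata = list(loop = i))
    expn <- isotherm_curve(rev(a_i), rev(p_exp), "expansion",
                           metadata = list(loop = i))
    cycles[[i]] <- hysteresis_cycle(comp, expn, index = i)
  }
  cycles
}

#' Serialise synthetic cycles as a canonical trace plus truth sidecar
#'
#' Concatenates the loops into one time-ordered trace (constant sampling
#' interval `dt`), writes it in the canonical delimited format readable
#' by [read_trace()], and writes the closed-form ground truth next to it
#' as JSON (`<path>.truth.json`) for test harnesses.
#'
#' @param params A [synthetic_params()] object.
#' @param path Output trace path.
#' @param dt Sampling interval in seconds (default 1).
#' @param sidecar Write the truth sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_synthetic_trace <- function(params, path, dt = 1, sidecar = TRUE) {
  cycles <- generate_hysteresis(params)
  a <- numeric(0)
  p <- numeric(0)
  for (cy in cycles) {
    a <- c(a, cy$compression$area, cy$expansion$area)
    p <- c(p, cy$compression$pressure, cy$expansion$pressure)
  }
  df <- data.frame(time = dt * (seq_along(a) - 1), area_per_molecule = a,
                   surface_pressure = p)
  attr(df, "metadata") <- list(generator = "langmuir::write_synthetic_trace",
                               seed = params$seed,
                               n_loops = length(params$loop_damping))
  write_trace(df, path)
  if (sidecar) {
    jsonlite::write_json(synthetic_truth(params),
                         paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
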