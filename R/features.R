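#' Lift-off area of a compression branch
#'
#' The lift-off area is the largest area per molecule at which the surface
#' pressure departs from the zero baseline. Scanning from large to small
#' areas, the detector finds the first point where the pressure exceeds
#' `threshold` and stays above it for `run_length` consecutive samples,
#' interpolates the threshold crossing linearly between the bracketing
#' samples, and then (default) removes the threshold-induced bias by
#' fitting a straight line to the initial rise (pressures between the
#' threshold and `band_upper`) and extrapolating it back to the baseline.
#' With `refine = "crossing"` the interpolated threshold crossing itself is
#' returned.
#'
#' @param curve An `isotherm_curve`, direction `"compression"`.
#' @param threshold Detection threshold in mN/m (default 0.5, chosen above
#'   typical baseline drift).
#' @param run_length Number of consecutive samples the pressure must stay
#'   above threshold (default 5); suppresses noise spikes.
#' @param refine `"extrapolate"` (default) or `"crossing"`, see Details.
#' @param band_upper Upper pressure bound of the initial-rise fit band in
#'   mN/m; default `max(6 * threshold, 3)`.
#' @param baseline Baseline pressure extrapolated to (default 0 mN/m).
#' @return Lift-off area in A^2/molecule.
#' @export
detect_lift_off <- function(curve, threshold = 0.5, run_length = 5L,
                            refine = c("extrapolate", "crossing"),
                            band_upper = max(6 * threshold, 3),
                            baseline = 0) {
  stopifnot(inherits(curve, "isotherm_curve"))
  refine <- match.arg(refine)
  if (curve$direction != "compression") {
    stop("lift-off is defined on a compression branch", call. = FALSE)
  }
  o <- order(curve$area, decreasing = TRUE)
  a <- curve$area[o]
  p <- curve$pressure[o]
  n <- length(a)
  above <- p > threshold
  run_length <- max(1L, as.integer(run_length))
  start <- NA_integer_
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= run_length) {
      start <- starts[k]
      break
    }
  }
  if (is.na(start)) {
    stop("no lift-off: pressure never exceeds the threshold for ",
         run_length, " consecutive samples", call. = FALSE)
  }
  if (start == 1L) {
    # branch begins above threshold; no bracketing sample at larger area
    a_cross <- a[1L]
  } else {
    i0 <- start - 1L
    a_cross <- a[i0] + (a[start] - a[i0]) *
      (threshold - p[i0]) / (p[start] - p[i0])
  }
  if (refine == "crossing") return(a_cross)

  # bias correction: extrapolate the initial rise back to the baseline.
  # A quadratic captures the curvature of the foot of the isotherm; the
  # smaller root above the crossing is the baseline intercept. Falls back
  # to a straight line, then to the raw crossing, on degenerate fits.
  band <- which(a <= a_cross & p <= band_upper & p > baseline)
  if (length(band) >= 10L) {
    ac <- mean(a[band])
    fit <- stats::lm.fit(cbind(1, a[band] - ac, (a[band] - ac)^2), p[band])
    cf <- fit$coefficients
    if (all(is.finite(cf))) {
      disc <- cf[2L]^2 - 4 * cf[3L] * (cf[1L] - baseline)
      if (abs(cf[3L]) > 1e-12 && disc >= 0) {
        roots <- ac + (-cf[2L] + c(-1, 1) * sqrt(disc)) / (2 * cf[3L])
        roots <- roots[roots >= a_cross & roots <= max(a)]
        if (length(roots)) return(unname(min(roots)))
      }
    }
  }
  if (length(band) >= 5L) {
    fit <- stats::lm.fit(cbind(1, a[band]), p[band])
    slope <- fit$coefficients[2L]
    if (is.finite(slope) && slope < -1e-10) {
      a_zero <- (baseline - fit$coefficients[1L]) / slope
      if (is.finite(a_zero) && a_zero >= a_cross && a_zero <= max(a)) {
        return(unname(a_zero))
      }
    }
  }
  a_cross
}

#' Collapse point of a compression branch
#'
#' Locates the monolayer collapse, the point at which the film fails under
#' compression. `mode = "pressure_max"` takes the global maximum of the
#' (smoothed) pressure; `mode = "kink"` takes the onset of the collapse
#' plateau, i.e. the point of most negative second derivative of the
#' smoothed pi(A) curve, and falls back to the pressure maximum (with a
#' `plateau_absent` flag) when no kink exceeds the curvature threshold.
#'
#' @param curve An `isotherm_curve`, direction `"compression"`.
#' @param mode `"pressure_max"` (default) or `"kink"`.
#' @param window,order Smoothing window/order for the local-polynomial fit
#'   (default window `NULL`: odd, about n/32 samples, clamped to
#'   \[11, 51\]; default order 2).
#' @param curvature_threshold Minimum |d2 pi / dA2| (mN/m per
#'   (A^2/molecule)^2) for a kink to count (default 0.05).
#' @return A list with `area` (A^2/molecule), `pressure` (mN/m), `mode`
#'   used and `plateau_absent` flag.
#' @export
detect_collapse <- function(curve, mode = c("pressure_max", "kink"),
                            window = NULL, order = 2L,
                            curvature_threshold = 0.05) {
  stopifnot(inherits(curve, "isotherm_curve"))
  mode <- match.arg(mode)
  if (curve$direction != "compression") {
    stop("collapse is defined on a compression branch", call. = FALSE)
  }
  o <- order(curve$area)
  a <- curve$area[o]
  p <- curve$pressure[o]
  n <- length(a)
  win <- resolve_window(window, n)
  p_s <- local_poly(a, p, window = win, order = order, deriv = 0L)
  i_max <- which.max(p_s)
  # a collapse requires the pressure to have risen: reject branches whose
  # maximum sits at the large-area end (monotone non-increasing pi)
  if (i_max == n || p_s[i_max] <= p_s[n] + 1e-12) {
    stop("no collapse: pressure does not rise along the branch",
         call. = FALSE)
  }
  if (mode == "pressure_max") {
    return(list(area = a[i_max], pressure = p_s[i_max],
                mode = mode, plateau_absent = FALSE))
  }
  d2 <- local_poly(a, p, window = win, order = max(order, 2L), deriv = 2L)
  # plateau onset: most negative curvature at or above the pressure-max area
  cand <- which(a >= a[i_max])
  j <- cand[which.min(d2[cand])]
  if (is.finite(d2[j]) && d2[j] <= -abs(curvature_threshold)) {
    list(area = a[j], pressure = p_s[j], mode = mode, plateau_absent = FALSE)
  } else {
    list(area = a[i_max], pressure = p_s[i_max], mode = mode,
         plateau_absent = TRUE)
  }
}

#' Packing compression ratio chi
#'
#' `chi = A_collapse / A_lift_off`, a dimensionless measure of how far the
#' molecular packing compresses between film onset and failure. Reported
#' values are conventionally rounded half-up to 3 decimals; see
#' [round_half_up()].
#'
#' @param a_collapse Collapse area in A^2/molecule (vectorised).
#' @param a_lift_off Lift-off area in A^2/molecule (vectorised).
#' @return The ratio, unrounded.
#' @examples
#' compute_chi(4.2, 61.6)                  # 0.0681...
#' round_half_up(compute_chi(4.2, 61.6), 3)  # 0.068
#' @export
compute_chi <- function(a_collapse, a_lift_off) {
  if (any(a_collapse <= 0) || any(a_lift_off <= 0)) {
    stop("areas must be positive", call. = FALSE)
  }
  if (any(a_collapse >= a_lift_off)) {
    stop("`a_collapse` must be smaller than `a_lift_off`", call. = FALSE)
  }
  a_collapse / a_lift_off
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (0.0725 -> 0.073),
#' matching how isotherm descriptor tables are conventionally printed,
#' unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 3L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Slope of the dynamic-rise (LE/LC) region
#'
#' Ordinary least-squares slope of pi against A over the region where the
#' pressure lies between `lower` and `upper` fractions of the collapse
#' pressure (defaults 0.25 and 0.75), restricted to areas above the
#' collapse area. The region bounds exclude both the curved lift-off foot
#' and the collapse plateau. On a compression branch the slope is
#' negative; smaller magnitude indicates easier molecular rearrangement.
#'
#' @param curve An `isotherm_curve`, direction `"compression"`.
#' @param lower,upper Fractions of the collapse pressure bounding the fit
#'   region (0 < lower < upper < 1).
#' @param pi_collapse Collapse pressure in mN/m; detected with
#'   [detect_collapse()] when `NULL`.
#' @param a_collapse Collapse area; detected when `NULL`.
#' @param min_samples Minimum samples required in the region (default 5).
#' @return The slope in mN/m per A^2/molecule, with attributes
#'   `r.squared` and `n`.
#' @export
fit_slope_le_lc <- function(curve, lower = 0.25, upper = 0.75,
                            pi_collapse = NULL, a_collapse = NULL,
                            min_samples = 5L) {
  stopifnot(inherits(curve, "isotherm_curve"))
  if (!(lower > 0 && lower < upper && upper < 1)) {
    stop("need 0 < lower < upper < 1", call. = FALSE)
  }
  if (is.null(pi_collapse) || is.null(a_collapse)) {
    cp <- detect_collapse(curve)
    if (is.null(pi_collapse)) pi_collapse <- cp$pressure
    if (is.null(a_collapse)) a_collapse <- cp$area
  }
  a <- curve$area
  p <- curve$pressure
  sel <- p >= lower * pi_collapse & p <= upper * pi_collapse &
    a >= a_collapse
  if (sum(sel) < min_samples) {
    stop(sprintf("insufficient data: %d samples in the fit region (need %d)",
                 sum(sel), min_samples), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, a[sel]), p[sel])
  slope <- unname(fit$coefficients[2L])
  ss_tot <- sum((p[sel] - mean(p[sel]))^2)
  attr(slope, "r.squared") <- if (ss_tot > 0)
    1 - sum(fit$residuals^2) / ss_tot else NA_real_
  attr(slope, "n") <- sum(sel)
  slope
}

#' Relative area shift between two isotherms at a reference pressure
#'
#' Interpolates the area at which each compression branch attains the
#' reference pressure (on its monotone rising segment) and returns the
#' percentage change of the test curve relative to the reference:
#' `100 * (A_test - A_ref) / A_ref`. Positive values mean the test
#' isotherm is expanded (shifted towards larger areas), as when subphase
#' molecules insert into the film.
#'
#' @param reference,test Compression `isotherm_curve`s.
#' @param pi_ref Reference surface pressure in mN/m (default 30, within
#'   the biologically relevant packing range).
#' @return Percent area change (a single number).
#' @export
area_shift_at_pressure <- function(reference, test, pi_ref = 30) {
  a_ref <- area_at_pressure(reference, pi_ref)
  a_test <- area_at_pressure(test, pi_ref)
  100 * (a_test - a_ref) / a_ref
}

#' Interpolate the area at a target pressure on the rising segment
#'
#' @param curve A compression `isotherm_curve`.
#' @param pi_ref Target surface pressure in mN/m.
#' @return Area in A^2/molecule.
#' @export
area_at_pressure <- function(curve, pi_ref) {
  seg <- rising_segment(curve)
  if (pi_ref < min(seg$pressure) || pi_ref > max(seg$pressure)) {
    stop(sprintf("pressure %.3g mN/m outside the rising range [%.3g, %.3g]",
                 pi_ref, min(seg$pressure), max(seg$pressure)),
         call. = FALSE)
  }
  stats::approx(seg$pressure, seg$area, xout = pi_ref, ties = "ordered")$y
}

#' Extract the standard descriptor set from a compression branch
#'
#' Convenience wrapper returning the eight scalar descriptors of one
#' compression branch: lift-off area, collapse area and pressure, the
#' area/pressure/value of the compressibility-modulus maximum, the packing
#' ratio chi, and the dynamic-rise slope, plus the phase label derived
#' from Cs^-1_max.
#'
#' @param curve An `isotherm_curve`, direction `"compression"`.
#' @param config An [analysis_config()] list of thresholds.
#' @return A one-row data.frame with columns `A_lift_off`, `A_collapse`,
#'   `pi_collapse`, `A_max`, `pi_max`, `Cs1_max`, `chi`, `a_LE_LC`,
#'   `phase`.
#' @export
extract_features <- function(curve, config = analysis_config()) {
  a_lift <- detect_lift_off(curve, threshold = config$liftoff_threshold,
                            run_length = config$liftoff_run_length)
  cp <- detect_collapse(curve, mode = config$collapse_mode,
                        window = config$smoothing_window,
                        order = config$smoothing_order)
  cc <- compressibility_modulus(curve, window = config$smoothing_window,
                                order = config$smoothing_order,
                                liftoff_threshold = config$liftoff_threshold,
                                liftoff_run = config$liftoff_run_length)
  slope <- fit_slope_le_lc(curve, lower = config$slope_lower,
                           upper = config$slope_upper,
                           pi_collapse = cp$pressure, a_collapse = cp$area)
  phase <- classify_phase(attr(cc, "Cs1_max"),
                          thresholds = config$phase_thresholds,
                          boundary_delta = config$boundary_delta)
  data.frame(
    A_lift_off = a_lift,
    A_collapse = cp$area,
    pi_collapse = cp$pressure,
    A_max = attr(cc, "A_max"),
    pi_max = attr(cc, "pi_max"),
    Cs1_max = attr(cc, "Cs1_max"),
    chi = round_half_up(compute_chi(cp$area, a_lift), 3L),
    a_LE_LC = as.numeric(slope),
    phase = phase$label,
    stringsAsFactors = FALSE)
}
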