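#' Compression reversibility factor of one hysteresis loop
#'
#' The reversibility factor is the ratio of the work recovered on
#' expansion to the work spent on compression, expressed as a percentage:
#'
#'   Rv = 100 * (integral of pi dA, expansion) /
#'              (integral of pi dA, compression)
#'
#' with both integrals taken between the lift-off and collapse areas.
#' By default (`bounds = "per_loop"`) the bounds are this loop's own
#' lift-off and collapse areas detected on its compression branch;
#' `bounds = "fixed"` uses caller-supplied bounds instead. Bounds are
#' clipped to the area range both branches actually cover (a `clipped`
#' flag records when this happens), pressures are clamped at zero for the
#' integration only, and each branch is integrated by the trapezoid rule
#' after sorting by increasing area, with linearly interpolated endpoint
#' values. 100 percent means a fully reversible loop; values above 100
#' are allowed but flagged.
#'
#' @param cycle A [hysteresis_cycle()] with both branches present.
#' @param bounds `"per_loop"` (default) or `"fixed"`.
#' @param fixed_bounds Numeric `c(A_low, A_high)` when `bounds = "fixed"`.
#' @param liftoff_threshold,liftoff_run,collapse_mode,window,order
#'   Detection settings forwarded to [detect_lift_off()] and
#'   [detect_collapse()] for per-loop bounds.
#' @return A one-row data.frame: `loop_index`, `Rv` (percent), `A_low`,
#'   `A_high`, `compression_integral`, `expansion_integral`
#'   (mN/m * A^2/molecule), `clipped`, `flagged` (Rv > 100).
#' @export
reversibility_factor <- function(cycle, bounds = c("per_loop", "fixed"),
                                 fixed_bounds = NULL,
                                 liftoff_threshold = 0.5, liftoff_run = 5L,
                                 collapse_mode = "pressure_max",
                                 window = NULL, order = 2L) {
  stopifnot(inherits(cycle, "hysteresis_cycle"))
  bounds <- match.arg(bounds)
  comp <- cycle$compression
  expn <- cycle$expansion
  if (is.null(comp) || is.null(expn)) {
    stop("cycle is incomplete: both branches are required", call. = FALSE)
  }
  if (bounds == "per_loop") {
    a_high <- detect_lift_off(comp, threshold = liftoff_threshold,
                              run_length = liftoff_run)
    a_low <- detect_collapse(comp, mode = collapse_mode,
                             window = window, order = order)$area
  } else {
    if (is.null(fixed_bounds) || length(fixed_bounds) != 2L) {
      stop("`fixed_bounds` must be c(A_low, A_high)", call. = FALSE)
    }
    a_low <- min(fixed_bounds)
    a_high <- max(fixed_bounds)
  }
  shared_lo <- max(min(comp$area), min(expn$area))
  shared_hi <- min(max(comp$area), max(expn$area))
  clipped <- a_low < shared_lo || a_high > shared_hi
  a_low <- max(a_low, shared_lo)
  a_high <- min(a_high, shared_hi)
  if (a_low >= a_high) {
    stop("integration bounds collapse to an empty interval", call. = FALSE)
  }
  ci <- branch_integral(comp, a_low, a_high)
  ei <- branch_integral(expn, a_low, a_high)
  if (ci <= 0) {
    stop("undefined ratio: compression integral is zero", call. = FALSE)
  }
  rv <- 100 * ei / ci
  data.frame(loop_index = cycle$index, Rv = rv,
             A_low = a_low, A_high = a_high,
             compression_integral = ci, expansion_integral = ei,
             clipped = clipped, flagged = rv > 100)
}

# Trapezoid integral of max(pi, 0) dA over [a_low, a_high] on one branch,
# with interpolated endpoint values. Assumes a_low/a_high inside the
# branch's area range.
branch_integral <- function(curve, a_low, a_high) {
  o <- order(curve$area)
  a <- curve$area[o]
  p <- pmax(curve$pressure[o], 0)
  inside <- a > a_low & a < a_high
  p_lo <- stats::approx(a, p, xout = a_low, ties = "ordered")$y
  p_hi <- stats::approx(a, p, xout = a_high, ties = "ordered")$y
  aa <- c(a_low, a[inside], a_high)
  pp <- c(p_lo, p[inside], p_hi)
  pracma::trapz(aa, pp)
}

#' Trend summary over successive hysteresis loops
#'
#' Collates per-loop reversibility results: successive Rv differences, a
#' strict monotone-increase flag, and the shift of each loop's lift-off
#' area relative to loop 1 (negative shifts mean the loop moved towards
#' smaller areas, as when film material is lost to the subphase).
#'
#' @param results A data.frame of rows from [reversibility_factor()]
#'   (ordered by loop), or a list of such rows.
#' @return A list with `per_loop` (data.frame incl. `dRv` and
#'   `liftoff_shift`), `monotone_increase` (logical; `NA` for a single
#'   loop).
#' @export
loop_trend <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  results <- results[order(results$loop_index), , drop = FALSE]
  n <- nrow(results)
  d_rv <- c(NA_real_, diff(results$Rv))
  shift <- results$A_high - results$A_high[1L]
  per_loop <- data.frame(results,
                         dRv = d_rv, liftoff_shift = shift)
  monotone <- if (n >= 2L) all(diff(results$Rv) > 0) else NA
  list(per_loop = per_loop, monotone_increase = monotone)
}
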