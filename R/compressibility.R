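#' Compressibility modulus curve of a compression branch
#'
#' The in-plane compressibility modulus (compression modulus) of a
#' monolayer is
#'
#'   Cs^-1(A) = -A * dpi/dA   (mN/m)
#'
#' Because the derivative amplifies sensor noise, dpi/dA is estimated by
#' local-polynomial (Savitzky-Golay) differentiation with a configurable
#' window and order; endpoints use one-sided fits. The curve maximum is
#' searched between the lift-off and collapse areas so that post-collapse
#' plateau artifacts cannot produce spurious spikes; if either landmark
#' cannot be detected the full sampled range is used.
#'
#' @param curve An `isotherm_curve`, direction `"compression"`, with at
#'   least 7 samples.
#' @param window Smoothing window in samples (odd). Default `NULL` picks
#'   an odd window of about n/32 samples, clamped to \[11, 51\], scaling
#'   the noise averaging with the sampling density. Shrunk with a warning
#'   when the branch is shorter than the window.
#' @param order Polynomial order of the local fit (default 2).
#' @param restrict If `TRUE` (default), restrict the maximum search to the
#'   detected lift-off/collapse area range.
#' @param liftoff_threshold,liftoff_run Passed to [detect_lift_off()] for
#'   the restriction.
#'
#' @return An object of class `compressibility_curve`: a data.frame with
#'   columns `area`, `pressure` (smoothed) and `modulus`, plus attributes
#'   `Cs1_max`, `A_max`, `pi_max` and `smoothing` (window/order used).
#' @examples
#' a <- seq(60, 20, length.out = 500)
#' crv <- isotherm_curve(a, 500 / a, "compression")  # ideal 2D gas
#' cc <- compressibility_modulus(crv, restrict = FALSE)
#' max(abs(cc$modulus - cc$pressure) / cc$pressure)  # analytic identity
#' @export
compressibility_modulus <- function(curve, window = NULL, order = 2L,
                                    restrict = TRUE,
                                    liftoff_threshold = 0.5,
                                    liftoff_run = 5L) {
  stopifnot(inherits(curve, "isotherm_curve"))
  if (curve$direction != "compression") {
    stop("compressibility modulus is computed on a compression branch",
         call. = FALSE)
  }
  n <- length(curve$area)
  if (n < 7L) stop("need at least 7 samples", call. = FALSE)
  o <- order(curve$area)   # ascending area; result is orientation-free
  a <- curve$area[o]
  p <- curve$pressure[o]
  win <- resolve_window(window, n)
  p_smooth <- local_poly(a, p, window = win, order = order, deriv = 0L)
  dp <- local_poly(a, p, window = win, order = order, deriv = 1L)
  modulus <- -a * dp

  lo <- min(a)
  hi <- max(a)
  if (restrict) {
    al <- tryCatch(
      detect_lift_off(curve, threshold = liftoff_threshold,
                      run_length = liftoff_run),
      error = function(e) NA_real_)
    ac <- tryCatch(
      detect_collapse(curve, mode = "pressure_max",
                      window = win, order = order)$area,
      error = function(e) NA_real_)
    if (!is.na(al)) hi <- min(hi, al)
    if (!is.na(ac)) lo <- max(lo, ac)
    if (lo >= hi) {
      lo <- min(a)
      hi <- max(a)
    }
  }
  in_range <- a >= lo & a <= hi
  if (!any(in_range)) in_range <- rep(TRUE, length(a))
  i_max <- which(in_range)[which.max(modulus[in_range])]

  out <- data.frame(area = a, pressure = p_smooth, modulus = modulus)
  attr(out, "Cs1_max") <- modulus[i_max]
  attr(out, "A_max") <- a[i_max]
  attr(out, "pi_max") <- p_smooth[i_max]
  attr(out, "search_range") <- c(lo, hi)
  attr(out, "smoothing") <- list(window = win, order = order)
  class(out) <- c("compressibility_curve", "data.frame")
  out
}

#' @export
print.compressibility_curve <- function(x, ...) {
  cat(sprintf("<compressibility_curve: %d samples>\n", nrow(x)))
  cat(sprintf("  Cs1_max = %.2f mN/m at A = %.2f A^2/molecule (pi = %.2f mN/m)\n",
              attr(x, "Cs1_max"), attr(x, "A_max"), attr(x, "pi_max")))
  invisible(x)
}

#' Phase-state threshold table
#'
#' Bands of the maximum compressibility modulus used to label the phase
#' state of a monolayer. The `"default"` preset places the liquid-expanded
#' / liquid-condensed boundary at 50 mN/m:
#' gaseous below 12.5; liquid_expanded in \[12.5, 50); liquid_condensed in
#' \[50, 100); condensed in \[100, 250); solid at 250 and above. The
#' `"davies_rideal"` preset is the classical alternative with the
#' liquid-condensed band starting at 100 mN/m and an intermediate band in
#' between.
#'
#' @param preset `"default"` or `"davies_rideal"`.
#' @return A data.frame with columns `lower` (inclusive) and `label`.
#' @export
phase_thresholds <- function(preset = c("default", "davies_rideal")) {
  preset <- match.arg(preset)
  switch(preset,
    default = data.frame(
      lower = c(0, 12.5, 50, 100, 250),
      label = c("gaseous", "liquid_expanded", "liquid_condensed",
                "condensed", "solid"),
      stringsAsFactors = FALSE),
    davies_rideal = data.frame(
      lower = c(0, 12.5, 100, 250),
      label = c("gaseous", "liquid_expanded", "liquid_condensed", "solid"),
      stringsAsFactors = FALSE))
}

#' Classify the monolayer phase state from Cs^-1_max
#'
#' The label is a step function of the maximum compressibility modulus
#' over the configured threshold table. Values within `boundary_delta` of
#' the liquid-expanded/liquid-condensed boundary (50 mN/m in the default
#' table) are additionally flagged as lying at the LE/LC boundary; their
#' `label` becomes `"boundary_LE_LC"` while `band` keeps the step-function
#' assignment. Set `boundary_delta = 0` to disable the flag.
#'
#' @param cs1_max Maximum compressibility modulus in mN/m (vectorised,
#'   must be >= 0).
#' @param thresholds Threshold table from [phase_thresholds()].
#' @param boundary_delta Half-width delta of the boundary band in mN/m
#'   (default 2).
#' @param boundary_at Centre of the boundary band (default 50 mN/m).
#' @return A data.frame with columns `cs1_max`, `band`, `boundary`,
#'   `label`.
#' @examples
#' classify_phase(c(37.7, 50.2, 68.4))
#' @export
classify_phase <- function(cs1_max, thresholds = phase_thresholds(),
                           boundary_delta = 2, boundary_at = 50) {
  if (any(!is.finite(cs1_max)) || any(cs1_max < 0)) {
    stop("`cs1_max` must be finite and >= 0", call. = FALSE)
  }
  idx <- findInterval(cs1_max, thresholds$lower)
  idx[idx < 1L] <- 1L
  band <- thresholds$label[idx]
  boundary <- abs(cs1_max - boundary_at) <= boundary_delta & boundary_delta > 0
  label <- ifelse(boundary, "boundary_LE_LC", band)
  data.frame(cs1_max = cs1_max, band = band, boundary = boundary,
             label = label, stringsAsFactors = FALSE)
}
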