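#' Construct an isotherm curve
#'
#' An `isotherm_curve` holds one branch of a surface pressure--area (pi--A)
#' experiment: paired samples of area per molecule and surface pressure,
#' ordered in acquisition (time) order. A compression branch has strictly
#' decreasing area, an expansion branch strictly increasing area.
#'
#' @param area Numeric vector of areas per molecule (A^2/molecule), all
#'   positive, strictly monotone in the direction given by `direction`.
#' @param pressure Numeric vector of surface pressures (mN/m), same length
#'   as `area`, all finite. Small negative values (noisy baselines) are
#'   permitted.
#' @param direction Either `"compression"` or `"expansion"`.
#' @param metadata Optional named list carried along (lipid name, subphase,
#'   temperature, barrier speed, flags set by the pipeline, ...).
#'
#' @return An object of class `isotherm_curve`: a list with elements
#'   `area`, `pressure`, `direction`, `metadata`.
#' @examples
#' crv <- isotherm_curve(area = seq(60, 20, by = -0.5),
#'                       pressure = pmax(0, 30 - 0.75 * seq(60, 20, by = -0.5)),
#'                       direction = "compression")
#' crv
#' @export
isotherm_curve <- function(area, pressure,
                           direction = c("compression", "expansion"),
                           metadata = list()) {
  direction <- match.arg(direction)
  area <- as.numeric(area)
  pressure <- as.numeric(pressure)
  if (length(area) != length(pressure)) {
    stop("`area` and `pressure` must have the same length", call. = FALSE)
  }
  if (length(area) < 3L) {
    stop("an isotherm curve needs at least 3 samples", call. = FALSE)
  }
  if (!all(is.finite(area)) || !all(is.finite(pressure))) {
    stop("`area` and `pressure` must be finite", call. = FALSE)
  }
  if (any(area <= 0)) {
    stop("all `area` values must be positive", call. = FALSE)
  }
  d <- diff(area)
  if (direction == "compression" && any(d >= 0)) {
    stop("compression branch must have strictly decreasing area", call. = FALSE)
  }
  if (direction == "expansion" && any(d <= 0)) {
    stop("expansion branch must have strictly increasing area", call. = FALSE)
  }
  structure(list(area = area, pressure = pressure,
                 direction = direction, metadata = metadata),
            class = "isotherm_curve")
}

#' @export
print.isotherm_curve <- function(x, ...) {
  cat(sprintf("<isotherm_curve: %s, %d samples>\n", x$direction,
              length(x$area)))
  cat(sprintf("  area     %.2f .. %.2f A^2/molecule\n",
              min(x$area), max(x$area)))
  cat(sprintf("  pressure %.2f .. %.2f mN/m\n",
              min(x$pressure), max(x$pressure)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.isotherm_curve <- function(x, ...) {
  data.frame(area = x$area, pressure = x$pressure,
             direction = x$direction, stringsAsFactors = FALSE)
}

#' @export
length.isotherm_curve <- function(x) length(x$area)

#' Construct a hysteresis cycle
#'
#' One compression--decompression loop: a compression branch paired with the
#' expansion branch that follows it. Incomplete cycles (one branch missing,
#' e.g. a trailing compression at the end of a trace) are allowed when the
#' missing branch is `NULL`; they carry an `incomplete` flag in `metadata`.
#'
#' @param compression An `isotherm_curve` with direction `"compression"`,
#'   or `NULL`.
#' @param expansion An `isotherm_curve` with direction `"expansion"`,
#'   or `NULL`.
#' @param index 1-based loop number within the parent trace.
#' @param metadata Named list of flags (e.g. `incomplete = TRUE`).
#'
#' @return An object of class `hysteresis_cycle`.
#' @export
hysteresis_cycle <- function(compression, expansion = NULL, index = 1L,
                             metadata = list()) {
  if (is.null(compression) && is.null(expansion)) {
    stop("a cycle needs at least one branch", call. = FALSE)
  }
  if (!is.null(compression)) {
    stopifnot(inherits(compression, "isotherm_curve"))
    if (compression$direction != "compression") {
      stop("`compression` must be a compression branch", call. = FALSE)
    }
  }
  if (!is.null(expansion)) {
    stopifnot(inherits(expansion, "isotherm_curve"))
    if (expansion$direction != "expansion") {
      stop("`expansion` must be an expansion branch", call. = FALSE)
    }
  }
  if (!is.null(compression) && !is.null(expansion)) {
    lo <- max(min(compression$area), min(expansion$area))
    hi <- min(max(compression$area), max(expansion$area))
    if (lo >= hi) {
      stop("compression and expansion branches share no area range",
           call. = FALSE)
    }
  } else {
    metadata$incomplete <- TRUE
  }
  structure(list(compression = compression, expansion = expansion,
                 index = as.integer(index), metadata = metadata),
            class = "hysteresis_cycle")
}

#' @export
print.hysteresis_cycle <- function(x, ...) {
  branches <- c(if (!is.null(x$compression)) "compression",
                if (!is.null(x$expansion)) "expansion")
  flag <- if (isTRUE(x$metadata$incomplete)) " [incomplete]" else ""
  cat(sprintf("<hysteresis_cycle %d: %s%s>\n", x$index,
              paste(branches, collapse = " + "), flag))
  invisible(x)
}

# Internal: monotone rising segment of a compression branch, as a list
# (area, pressure) ordered by increasing pressure. Walks from the pressure
# maximum towards larger areas keeping strictly decreasing pressure, so the
# result is invertible for interpolating A at a target pi.
rising_segment <- function(curve) {
  stopifnot(inherits(curve, "isotherm_curve"))
  o <- order(curve$area, decreasing = TRUE)
  a <- curve$area[o]
  p <- curve$pressure[o]
  i_max <- which.max(p)
  a <- a[seq_len(i_max)]
  p <- p[seq_len(i_max)]
  # scan from the large-area end keeping strictly increasing pressure
  keep <- logical(length(p))
  last <- -Inf
  for (i in seq_along(p)) {
    if (p[i] > last) {
      keep[i] <- TRUE
      last <- p[i]
    }
  }
  list(area = a[keep], pressure = p[keep])
}
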