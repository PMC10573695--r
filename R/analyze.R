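#' Analysis configuration
#'
#' Single source of the thresholds used across the pipeline. All
#' downstream entry points take one of these; [read_analysis_config()]
#' loads overrides from a YAML file.
#'
#' @param liftoff_threshold Lift-off detection threshold, mN/m.
#' @param liftoff_run_length Persistence run length, samples.
#' @param collapse_mode `"pressure_max"` or `"kink"`.
#' @param slope_lower,slope_upper Fractions of the collapse pressure
#'   bounding the dynamic-rise fit region.
#' @param smoothing_window,smoothing_order Local-polynomial smoothing
#'   settings (samples / polynomial degree); `NULL` window means
#'   sample-count adaptive (odd, about n/32, in \[11, 51\]).
#' @param phase_thresholds Threshold table, see [phase_thresholds()].
#' @param boundary_delta LE/LC boundary half-width, mN/m.
#' @param reference_pressure Reference pressure for area-shift
#'   comparisons, mN/m.
#' @param bounds_mode Integration bounds for reversibility:
#'   `"per_loop"` or `"fixed"`.
#' @param fixed_bounds Bounds `c(A_low, A_high)` when
#'   `bounds_mode = "fixed"`.
#' @param qc_threshold Cleanliness bound for blank compressions, mN/m.
#' @param dialect A [trace_dialect()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(liftoff_threshold = 0.5,
                            liftoff_run_length = 5L,
                            collapse_mode = c("pressure_max", "kink"),
                            slope_lower = 0.25, slope_upper = 0.75,
                            smoothing_window = NULL, smoothing_order = 2L,
                            phase_thresholds = langmuir::phase_thresholds(),
                            boundary_delta = 2,
                            reference_pressure = 30,
                            bounds_mode = c("per_loop", "fixed"),
                            fixed_bounds = NULL,
                            qc_threshold = 0.30,
                            dialect = trace_dialect()) {
  collapse_mode <- match.arg(collapse_mode)
  bounds_mode <- match.arg(bounds_mode)
  if (liftoff_threshold <= 0) stop("`liftoff_threshold` must be positive",
                                   call. = FALSE)
  if (!(slope_lower > 0 && slope_lower < slope_upper && slope_upper < 1)) {
    stop("need 0 < slope_lower < slope_upper < 1", call. = FALSE)
  }
  structure(list(liftoff_threshold = liftoff_threshold,
                 liftoff_run_length = as.integer(liftoff_run_length),
                 collapse_mode = collapse_mode,
                 slope_lower = slope_lower, slope_upper = slope_upper,
                 smoothing_window = if (is.null(smoothing_window)) NULL else
                   as.integer(smoothing_window),
                 smoothing_order = as.integer(smoothing_order),
                 phase_thresholds = phase_thresholds,
                 boundary_delta = boundary_delta,
                 reference_pressure = reference_pressure,
                 bounds_mode = bounds_mode, fixed_bounds = fixed_bounds,
                 qc_threshold = qc_threshold,
                 dialect = dialect),
            class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Keys present in the file override the defaults of
#' [analysis_config()]; nested `dialect` keys (`sep`, `dec`, `columns`)
#' build a [trace_dialect()].
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        setdiff(names(formals(analysis_config)),
                                c("dialect", "phase_thresholds")))]
  if (!is.null(raw$dialect)) {
    d <- raw$dialect
    args$dialect <- trace_dialect(
      sep = d$sep %||% ",", dec = d$dec %||% ".",
      columns = unlist(d$columns) %||% character())
  }
  if (!is.null(raw$phase_preset)) {
    args$phase_thresholds <- phase_thresholds(raw$phase_preset)
  }
  do.call(analysis_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a trace and make sure it carries area_per_molecule and
# surface_pressure, applying the Wilhelmy / per-molecule conversions from
# trace metadata where necessary.
prepare_trace <- function(path, config) {
  tr <- read_trace(path, config$dialect)
  meta <- attr(tr, "metadata") %||% list()
  if (!"area_per_molecule" %in% names(tr)) {
    if (is.null(meta$solution_molarity) || is.null(meta$spread_volume)) {
      stop("trace ", path, " has trough_area but no spreading metadata ",
           "(solution_molarity, spread_volume) to convert per molecule",
           call. = FALSE)
    }
    n_mol <- molecules_spread(meta$solution_molarity, meta$spread_volume)
    tr$area_per_molecule <- to_area_per_molecule(tr$trough_area, n_mol)
    tr$trough_area <- NULL
  }
  if (!"surface_pressure" %in% names(tr)) {
    geom <- wire_geometry(
      radius = meta$wire_radius %||% 2.5e-4,
      length = meta$wire_length %||% 1e-2,
      wire_density = meta$wire_density %||% 0,
      contact_angle = meta$contact_angle %||% 0,
      immersion_depth = meta$immersion_depth %||% 0)
    sub <- subphase_props(
      liquid_density = meta$liquid_density %||% 997,
      clean_surface_tension = meta$gamma0 %||% 72.8)
    gamma <- tension_from_force(tr$force, geom, sub)
    tr$surface_pressure <- pressure_from_tension(gamma,
                                                 sub$clean_surface_tension)
    tr$force <- NULL
  }
  tr
}

#' Analyse traces into a descriptor report
#'
#' For each trace file: read, convert to area-per-molecule /
#' surface-pressure, split into cycles, and extract the standard
#' descriptor set from every compression branch. One row per compression
#' branch, in the conventional column order (`A_lift_off`, `A_collapse`,
#' `pi_collapse`, `A_max`, `pi_max`, `Cs1_max`, `chi`, `a_LE_LC`, plus
#' the phase label). Unreadable or degenerate traces are reported in the
#' `errors` attribute and do not stop the remaining files.
#'
#' @param paths Character vector of trace files.
#' @param config An [analysis_config()].
#' @return A data.frame (one row per compression branch) with columns
#'   `file`, `cycle`, the eight descriptors and `phase`; failed files are
#'   listed in `attr(, "errors")`.
#' @export
analyze <- function(paths, config = analysis_config()) {
  rows <- list()
  errors <- character(0)
  for (path in paths) {
    res <- tryCatch({
      tr <- prepare_trace(path, config)
      cycles <- suppressWarnings(split_cycles(
        tr, run_length = config$liftoff_run_length))
      out <- list()
      for (cy in cycles) {
        if (is.null(cy$compression)) next
        feats <- extract_features(cy$compression, config)
        out[[length(out) + 1L]] <- cbind(
          data.frame(file = basename(path), cycle = cy$index,
                     stringsAsFactors = FALSE),
          feats)
      }
      do.call(rbind, out)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- paste0(basename(path), ": ",
                                               conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0))
  attr(report, "errors") <- errors
  attr(report, "config") <- config
  report
}

#' Analyse hysteresis traces into a reversibility table
#'
#' Splits each trace into compression--decompression loops and computes
#' the per-loop reversibility factor plus the loop trend. Incomplete
#' cycles are reported with `Rv = NA` and flagged.
#'
#' @param paths Character vector of trace files.
#' @param config An [analysis_config()].
#' @return A long data.frame: `file`, `loop_index`, `Rv`, bounds,
#'   integrals, `incomplete`; the per-file trend summaries are in
#'   `attr(, "trends")`, failures in `attr(, "errors")`.
#' @export
analyze_hysteresis <- function(paths, config = analysis_config()) {
  rows <- list()
  trends <- list()
  errors <- character(0)
  for (path in paths) {
    tryCatch({
      tr <- prepare_trace(path, config)
      cycles <- suppressWarnings(split_cycles(
        tr, run_length = config$liftoff_run_length))
      res <- list()
      for (cy in cycles) {
        if (is.null(cy$compression) || is.null(cy$expansion)) {
          res[[length(res) + 1L]] <- data.frame(
            loop_index = cy$index, Rv = NA_real_, A_low = NA_real_,
            A_high = NA_real_, compression_integral = NA_real_,
            expansion_integral = NA_real_, clipped = NA, flagged = NA,
            incomplete = TRUE)
          next
        }
        rv <- reversibility_factor(
          cy, bounds = config$bounds_mode,
          fixed_bounds = config$fixed_bounds,
          liftoff_threshold = config$liftoff_threshold,
          liftoff_run = config$liftoff_run_length,
          collapse_mode = config$collapse_mode,
          window = config$smoothing_window,
          order = config$smoothing_order)
        rv$incomplete <- FALSE
        res[[length(res) + 1L]] <- rv
      }
      res <- do.call(rbind, res)
      complete <- res[!res$incomplete & !is.na(res$Rv), , drop = FALSE]
      if (nrow(complete) >= 2L) {
        trends[[basename(path)]] <- loop_trend(complete)
      }
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(file = basename(path), stringsAsFactors = FALSE), res)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- paste0(basename(path), ": ",
                                               conditionMessage(e))
    })
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0))
  attr(report, "trends") <- trends
  attr(report, "errors") <- errors
  report
}

#' Compare test isotherms against a reference at a fixed pressure
#'
#' Computes the percentage change in area per molecule, at the configured
#' reference pressure, of each test trace's first compression branch
#' relative to the reference trace's.
#'
#' @param reference_path Reference trace file.
#' @param test_paths Character vector of test trace files.
#' @param config An [analysis_config()].
#' @return A data.frame: `file`, `area_shift_pct` at
#'   `config$reference_pressure`.
#' @export
compare_traces <- function(reference_path, test_paths,
                           config = analysis_config()) {
  first_compression <- function(path) {
    tr <- prepare_trace(path, config)
    cycles <- suppressWarnings(split_cycles(
      tr, run_length = config$liftoff_run_length))
    for (cy in cycles) if (!is.null(cy$compression)) return(cy$compression)
    stop("no compression branch in ", path, call. = FALSE)
  }
  ref <- first_compression(reference_path)
  shifts <- vapply(test_paths, function(p) {
    area_shift_at_pressure(ref, first_compression(p),
                           pi_ref = config$reference_pressure)
  }, numeric(1))
  data.frame(file = basename(test_paths), area_shift_pct = unname(shifts),
             reference = basename(reference_path),
             reference_pressure = config$reference_pressure,
             stringsAsFactors = FALSE)
}
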