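#' Describe the layout of a delimited trace file
#'
#' Instrument exports differ in delimiter and column naming; a dialect maps
#' a file onto the canonical trace columns. The canonical format is a
#' delimited text file with a header row, '.' decimal separator, optional
#' `#`-prefixed metadata lines (`# key: value`) before the header, and
#' columns named `time`, plus exactly one of `trough_area` (cm^2) /
#' `area_per_molecule` (A^2/molecule) and exactly one of `surface_pressure`
#' (mN/m) / `force` (N).
#'
#' @param sep Field delimiter (default `","`; use `"\t"` for TSV).
#' @param dec Decimal mark (default `"."`).
#' @param columns Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(time = "t_s", surface_pressure = "Pi")`.
#'   Canonical names missing from the map are looked up verbatim.
#'
#' @return A list of class `trace_dialect`.
#' @export
trace_dialect <- function(sep = ",", dec = ".", columns = character()) {
  canonical <- c("time", "trough_area", "area_per_molecule",
                 "surface_pressure", "force")
  if (length(columns)) {
    bad <- setdiff(names(columns), canonical)
    if (length(bad)) {
      stop("unknown canonical column(s) in dialect: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sep = sep, dec = dec, columns = columns,
                 canonical = canonical),
            class = "trace_dialect")
}

#' Read a trough trace from delimited text
#'
#' Reads a time-ordered Langmuir trough record set, applies the dialect's
#' column mapping, and validates the trace invariants: strictly increasing
#' time, exactly one pressure-like column (`surface_pressure` or `force`)
#' and exactly one area-like column (`trough_area` or `area_per_molecule`).
#'
#' @param path Path to a delimited text file.
#' @param dialect A [trace_dialect()].
#'
#' @return A `data.frame` of class `trough_trace` with the canonical
#'   columns present in the file, plus a `metadata` attribute holding any
#'   `# key: value` header lines.
#' @seealso [write_trace()], [split_cycles()]
#' @export
read_trace <- function(path, dialect = trace_dialect()) {
  if (!file.exists(path)) {
    stop("trace file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- parse_meta_lines(meta_lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) {
    stop("trace file has no data rows: ", path, call. = FALSE)
  }
  df <- utils::read.table(text = body, header = TRUE, sep = dialect$sep,
                          dec = dialect$dec, stringsAsFactors = FALSE,
                          check.names = FALSE)
  # apply column mapping: canonical <- file name
  for (canon in names(dialect$columns)) {
    src <- dialect$columns[[canon]]
    if (!src %in% names(df)) {
      stop(sprintf("dialect maps '%s' to column '%s', absent from %s",
                   canon, src, path), call. = FALSE)
    }
    names(df)[names(df) == src] <- canon
  }
  keep <- intersect(dialect$canonical, names(df))
  df <- df[keep]
  validate_trace(df, path)
  attr(df, "metadata") <- metadata
  class(df) <- c("trough_trace", "data.frame")
  df
}

parse_meta_lines <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
    }
  }
  out
}

validate_trace <- function(df, path = "<trace>") {
  if (!"time" %in% names(df)) {
    stop("missing mandatory column 'time' in ", path, call. = FALSE)
  }
  has_p <- "surface_pressure" %in% names(df)
  has_f <- "force" %in% names(df)
  if (has_p == has_f) {
    stop("exactly one of 'surface_pressure' or 'force' must be present in ",
         path, call. = FALSE)
  }
  has_ta <- "trough_area" %in% names(df)
  has_apm <- "area_per_molecule" %in% names(df)
  if (has_ta == has_apm) {
    stop("exactly one of 'trough_area' or 'area_per_molecule' must be ",
         "present in ", path, call. = FALSE)
  }
  if (any(diff(df$time) <= 0)) {
    stop("'time' must be strictly increasing in ", path, call. = FALSE)
  }
  invisible(df)
}

#' Write a trace in the canonical delimited format
#'
#' Values are formatted with 12 significant digits so that
#' `read_trace(write_trace(x))` reproduces `x` to formatting precision.
#'
#' @param trace A `trough_trace` (or plain data.frame with canonical
#'   columns).
#' @param path Output file path.
#' @param metadata Named list written as `# key: value` header lines;
#'   defaults to the trace's own `metadata` attribute.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, metadata = attr(trace, "metadata")) {
  df <- as.data.frame(trace)
  validate_trace(df)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(metadata)) {
    for (key in names(metadata)) {
      writeLines(sprintf("# %s: %s", key, format(metadata[[key]])), con)
    }
  }
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 12, format = "g") else
      as.character(col)
  }, character(nrow(df)))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(matrix(fmt, nrow = nrow(df)), 1L, paste, collapse = ","),
             con)
  invisible(path)
}

#' Number of molecules deposited on the subphase
#'
#' Converts a spreading protocol (solution molarity and spread volume) into
#' a molecule count: n = molarity x volume x N_A, with the volume taken in
#' microlitres.
#'
#' @param molarity Solution concentration in mol/L; must be positive.
#' @param volume_ul Spread volume in microlitres; must be positive.
#' @return Number of molecules (dimensionless count).
#' @examples
#' molecules_spread(2.2e-3, 15)  # ~1.99e16 molecules
#' @export
molecules_spread <- function(molarity, volume_ul) {
  if (any(molarity <= 0) || any(volume_ul <= 0)) {
    stop("`molarity` and `volume_ul` must be positive", call. = FALSE)
  }
  avogadro <- 6.02214076e23
  molarity * (volume_ul * 1e-6) * avogadro
}

#' Convert trough area to area per molecule
#'
#' 1 cm^2 = 1e16 A^2, so the mean molecular area is
#' `trough_area_cm2 * 1e16 / n_molecules` A^2/molecule.
#'
#' @param trough_area_cm2 Trough surface area in cm^2 (vectorised).
#' @param n_molecules Number of molecules in the film; must be positive.
#' @return Area per molecule in A^2/molecule.
#' @examples
#' n <- molecules_spread(2.2e-3, 15)
#' to_area_per_molecule(124, n)
#' @export
to_area_per_molecule <- function(trough_area_cm2, n_molecules) {
  if (any(n_molecules <= 0)) {
    stop("`n_molecules` must be positive", call. = FALSE)
  }
  if (any(trough_area_cm2 < 0)) {
    stop("`trough_area_cm2` must be non-negative", call. = FALSE)
  }
  trough_area_cm2 * 1e16 / n_molecules
}

#' Split a multi-loop trace into hysteresis cycles
#'
#' Detects direction reversals of the area signal from the sign of a
#' smoothed first difference, requiring each direction to persist for at
#' least `run_length` samples so that barrier jitter does not create
#' spurious loops. Each compression branch is paired with the expansion
#' branch that follows it. A trailing (or leading) unpaired branch is kept
#' as an incomplete cycle flagged in its metadata. The cycles partition the
#' input samples: no loss, no duplication.
#'
#' @param trace A `trough_trace` with an area-like and a pressure column
#'   (apply [to_area_per_molecule()] / Wilhelmy conversion first if needed),
#'   or a data.frame with `area_per_molecule` and `surface_pressure`.
#' @param run_length Minimum number of samples a direction must persist
#'   (default 5).
#' @param smooth_window Width of the running-mean smoother applied to the
#'   area differences before taking signs (default 5, odd).
#' @return A list of [hysteresis_cycle()] objects, indices 1..k. If no
#'   reversal is found the list has one compression-only cycle and a
#'   warning is raised.
#' @export
split_cycles <- function(trace, run_length = 5L, smooth_window = 5L) {
  df <- as.data.frame(trace)
  if (!"area_per_molecule" %in% names(df)) {
    stop("trace has no 'area_per_molecule' column; convert trough area first",
         call. = FALSE)
  }
  if (!"surface_pressure" %in% names(df)) {
    stop("trace has no 'surface_pressure' column; convert force first",
         call. = FALSE)
  }
  a <- df$area_per_molecule
  p <- df$surface_pressure
  n <- length(a)
  if (n < 3L) stop("trace too short to split", call. = FALSE)
  d <- diff(a)
  if (smooth_window > 1L) {
    k <- min(as.integer(smooth_window), length(d))
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L) {
      sm <- stats::filter(d, rep(1 / k, k), sides = 2)
      half <- (k - 1L) %/% 2L
      sm[seq_len(half)] <- d[seq_len(half)]
      sm[(length(d) - half + 1L):length(d)] <- d[(length(d) - half + 1L):length(d)]
      d <- as.numeric(sm)
    }
  }
  s <- sign(d)
  s[s == 0] <- NA
  # carry last non-zero sign through flat spots
  for (i in seq_along(s)) if (is.na(s[i]) && i > 1L) s[i] <- s[i - 1L]
  s[is.na(s)] <- -1  # leading flat: assume compression
  r <- rle(s)
  # absorb runs shorter than run_length into the previous run
  while (length(r$lengths) > 1L && any(r$lengths < run_length)) {
    j <- which(r$lengths < run_length)[1L]
    tgt <- if (j == 1L) 2L else j - 1L
    r$lengths[tgt] <- r$lengths[tgt] + r$lengths[j]
    r$lengths <- r$lengths[-j]
    r$values <- r$values[-j]
    r <- rle(inverse.rle(r))
  }
  ends_d <- cumsum(r$lengths)            # run ends in diff index space
  seg_ends <- c(ends_d + 1L)             # sample index closing each segment
  seg_starts <- c(1L, head(seg_ends, -1L) + 1L)
  directions <- ifelse(r$values < 0, "compression", "expansion")

  make_branch <- function(i0, i1, dir) {
    idx <- i0:i1
    aa <- a[idx]
    pp <- p[idx]
    # enforce strict monotonicity by dropping ties/backtracks within branch
    keep <- logical(length(aa))
    keep[1] <- TRUE
    last <- aa[1]
    for (i in seq_along(aa)[-1]) {
      ok <- if (dir == "compression") aa[i] < last else aa[i] > last
      if (ok) {
        keep[i] <- TRUE
        last <- aa[i]
      }
    }
    if (sum(keep) < 3L) return(NULL)
    isotherm_curve(aa[keep], pp[keep], direction = dir,
                   metadata = list(sample_index = range(idx),
                                   n_raw = length(idx),
                                   raw = data.frame(area = aa, pressure = pp)))
  }

  branches <- vector("list", length(seg_starts))
  for (k in seq_along(seg_starts)) {
    branches[[k]] <- list(
      curve = make_branch(seg_starts[k], seg_ends[k], directions[k]),
      dir = directions[k])
  }
  branches <- Filter(function(b) !is.null(b$curve), branches)

  cycles <- list()
  i <- 1L
  loop <- 1L
  while (i <= length(branches)) {
    b <- branches[[i]]
    if (b$dir == "compression") {
      if (i + 1L <= length(branches) && branches[[i + 1L]]$dir == "expansion") {
        cycles[[loop]] <- hysteresis_cycle(b$curve, branches[[i + 1L]]$curve,
                                           index = loop)
        i <- i + 2L
      } else {
        cycles[[loop]] <- hysteresis_cycle(b$curve, NULL, index = loop,
                                           metadata = list(incomplete = TRUE))
        i <- i + 1L
      }
    } else {
      # leading/unpaired expansion
      cycles[[loop]] <- hysteresis_cycle(NULL, b$curve, index = loop,
                                         metadata = list(incomplete = TRUE))
      i <- i + 1L
    }
    loop <- loop + 1L
  }
  if (length(cycles) == 1L && is.null(cycles[[1L]]$expansion)) {
    warning("no direction reversal found; returning one compression-only cycle",
            call. = FALSE)
  }
  cycles
}

#' Summarise a cycle split as a manifest table
#'
#' @param cycles List returned by [split_cycles()].
#' @return A data.frame with one row per branch: cycle index, direction,
#'   sample count and area range.
#' @export
cycle_manifest <- function(cycles) {
  rows <- list()
  for (cy in cycles) {
    for (dir in c("compression", "expansion")) {
      crv <- cy[[dir]]
      if (is.null(crv)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = cy$index, direction = dir, n = length(crv$area),
        area_min = min(crv$area), area_max = max(crv$area),
        incomplete = isTRUE(cy$metadata$incomplete))
    }
  }
  do.call(rbind, rows)
}
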