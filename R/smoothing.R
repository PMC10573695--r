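# Windowed local-polynomial smoothing and differentiation.
#
# On a uniform grid this is the classical Savitzky-Golay filter and is
# delegated to signal::sgolayfilt (which handles the end transients with
# one-sided fits). Non-uniform grids fall back to explicit per-window
# least-squares polynomial fits, evaluated at each sample.

# Default smoothing window for a branch of n samples: an odd window of
# roughly n/32 samples, clamped to [11, 51]. Short windows track the
# LE/LC kink closely; long windows tame derivative noise. n/32 keeps the
# window span small against the feature scale of a full compression
# branch while averaging enough samples for -A dpi/dA at realistic
# pressure noise.
default_window <- function(n) {
  w <- max(11L, min(51L, as.integer(round(n / 32))))
  if (w %% 2L == 0L) w + 1L else w
}

# Resolve a requested window against the branch length: NULL means the
# adaptive default; an explicit window larger than the branch shrinks
# with a warning.
resolve_window <- function(window, n) {
  n_odd <- if (n %% 2L == 1L) n else n - 1L
  if (is.null(window)) {
    w <- min(default_window(n), n_odd)
  } else {
    w <- as.integer(window)
    if (w %% 2L == 0L) w <- w + 1L
    if (w > n) {
      w <- n_odd
      warning(sprintf("smoothing window shrunk to %d (only %d samples)",
                      w, n), call. = FALSE)
    }
  }
  max(w, 3L)
}

is_uniform_grid <- function(x, rel_tol = 1e-8) {
  d <- diff(x)
  if (!length(d)) return(TRUE)
  m <- mean(d)
  if (m == 0) return(FALSE)
  max(abs(d - m)) <= rel_tol * abs(m) + 1e-15
}

# Value (deriv = 0) or first/second derivative (deriv = 1, 2) of y(x),
# estimated by a degree-`order` polynomial fit over a centred window of
# `window` samples (one-sided near the ends). Returns a numeric vector the
# length of y.
local_poly <- function(x, y, window = 11L, order = 2L, deriv = 0L) {
  n <- length(y)
  stopifnot(length(x) == n, n >= 3L)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) {
    window <- if (n %% 2L == 0L) n - 1L else n
    warning(sprintf("smoothing window shrunk to %d (only %d samples)",
                    window, n), call. = FALSE)
  }
  order <- min(as.integer(order), window - 1L)
  if (deriv > order) {
    stop("`deriv` must not exceed the polynomial order", call. = FALSE)
  }
  if (is_uniform_grid(x)) {
    h <- mean(diff(x))
    out <- signal::sgolayfilt(y, p = order, n = window, m = deriv,
                              ts = abs(h))
    # sgolayfilt differentiates against sample index spacing |h|; flip the
    # sign of odd derivatives on a descending grid
    if (deriv %% 2L == 1L && h < 0) out <- -out
    return(out)
  }
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    i0 <- max(1L, min(i - half, n - window + 1L))
    idx <- i0:(i0 + window - 1L)
    xc <- x[idx] - x[i]
    X <- outer(xc, 0:order, `^`)
    beta <- qr.coef(qr(X), y[idx])
    out[i] <- beta[deriv + 1L] * factorial(deriv)
  }
  out
}
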