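# Butterworth filter design (order-2 low-pass and band-pass via the bilinear
# transform) and zero-phase forward-backward filtering with odd-reflection
# padding and steady-state initial conditions.  Hand-rolled because no DSP
# package is available in the target library; the design matches
# scipy.signal.butter / filtfilt, which tests use as an oracle.

#' Design a digital Butterworth filter
#'
#' @param order filter order of the analog prototype (the band-pass digital
#'   filter has twice this order).
#' @param w_hz cutoff in Hz: one value for `type = "low"`, `c(low, high)`
#'   for `type = "pass"`.
#' @param fs_hz sampling frequency in Hz.
#' @param type `"low"` or `"pass"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(order, w_hz, fs_hz, type = c("low", "pass")) {
  type <- match.arg(type)
  if (any(w_hz <= 0) || any(w_hz >= fs_hz / 2)) {
    stopf("cutoff must lie strictly inside (0, Nyquist)")
  }
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z <- complex(0)
  gain <- 1
  fs2 <- 2 * fs_hz
  warp <- function(f) fs2 * tan(pi * f / fs_hz)
  if (type == "low") {
    wc <- warp(w_hz[1])
    p <- p * wc
    gain <- gain * wc^order
  } else {
    if (length(w_hz) != 2L || w_hz[1] >= w_hz[2]) stopf("band must be c(low, high)")
    w1 <- warp(w_hz[1]); w2 <- warp(w_hz[2])
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    # low-pass to band-pass: each pole maps to a conjugate pair
    pb <- c((p * bw + sqrt((p * bw)^2 - 4 * w0^2 + 0i)) / 2,
            (p * bw - sqrt((p * bw)^2 - 4 * w0^2 + 0i)) / 2)
    z <- rep(0 + 0i, order)
    gain <- gain * bw^order
    p <- pb
  }
  # bilinear transform
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  # bilinear maps extra zeros at analog infinity to z = -1
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Steady-state initial filter state (direct form II transposed), as in
# scipy.signal.lfilter_zi.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[-1]
  if (n > 2L) A[cbind(seq_len(n - 2), seq(2, n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - A, B)
}

# Causal IIR filter over a wide matrix (series in rows, time in columns),
# direct form II transposed, vectorized over series.  Column access is
# contiguous, which keeps the per-time-step cost low.
lfilter_wide <- function(b, a, Xw, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(Xw * b[1])
  ns <- nrow(Xw); nt <- ncol(Xw)
  Yw <- matrix(0, ns, nt)
  Z <- if (is.null(zi)) matrix(0, ns, n - 1) else zi
  for (t in seq_len(nt)) {
    xt <- Xw[, t]
    yt <- b[1] * xt + Z[, 1]
    if (n > 2L) {
      for (j in seq_len(n - 2)) {
        Z[, j] <- b[j + 1] * xt + Z[, j + 1] - a[j + 1] * yt
      }
    }
    Z[, n - 1] <- b[n] * xt - a[n] * yt
    Yw[, t] <- yt
  }
  Yw
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-reflection padding of
#' length `3 * (max(length(a), length(b)) - 1)` and steady-state initial
#' conditions, matching the conventional filtfilt recipe.
#'
#' @param b,a filter coefficients from [butter_design()].
#' @param x numeric vector, or a matrix with time down the rows (each
#'   column filtered independently).
#' @return object of the same shape as `x`.
#' @export
filtfilt <- function(b, a, x) {
  vec <- is.null(dim(x))
  Xw <- if (vec) matrix(x, nrow = 1) else t(x)   # series in rows
  Y <- filtfilt_wide(b, a, Xw)
  if (vec) drop(Y) else t(Y)
}

# Zero-phase filtering of a wide matrix (series in rows, time in columns);
# the in-memory layout used for whole-brain voxel filtering.
filtfilt_wide <- function(b, a, Xw) {
  nt <- ncol(Xw)
  pad <- 3L * (max(length(a), length(b)) - 1L)
  if (nt <= pad) stopf("series too short for zero-phase filtering (need > %d)", pad)
  zi <- lfilter_zi(b, a)
  ext <- cbind(2 * Xw[, 1] - Xw[, (pad + 1):2, drop = FALSE],
               Xw,
               2 * Xw[, nt] - Xw[, (nt - 1):(nt - pad), drop = FALSE])
  Y <- lfilter_wide(b, a, ext, zi = outer(ext[, 1], zi))
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y <- lfilter_wide(b, a, Y, zi = outer(Y[, 1], zi))
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y[, (pad + 1):(pad + nt), drop = FALSE]
}

#' Zero-phase low-pass filter of each column
#' @param X matrix (time x series) or vector.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs_hz sampling frequency in Hz.
#' @param order Butterworth order (default 2).
#' @export
lowpass_filtfilt <- function(X, cutoff_hz, fs_hz, order = 2L) {
  d <- butter_design(order, cutoff_hz, fs_hz, "low")
  filtfilt(d$b, d$a, X)
}

#' Zero-phase band-pass filter of each column
#' @inheritParams lowpass_filtfilt
#' @param band_hz `c(low, high)` in Hz.
#' @export
bandpass_filtfilt <- function(X, band_hz, fs_hz, order = 2L) {
  d <- butter_design(order, band_hz, fs_hz, "pass")
  filtfilt(d$b, d$a, X)
}
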