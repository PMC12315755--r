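# Volume-wise isotropic Gaussian smoothing.  Applied separably along each
# spatial axis; never across time.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)  # normalized: interior mass conserved exactly
}

# Convolve a 3D array along one axis with a symmetric kernel (zero padding).
conv_axis <- function(vol, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(vol * kernel)
  out <- array(0, dim(vol))
  for (j in seq_along(kernel)) {
    s <- j - 1L - r
    shift <- c(0L, 0L, 0L); shift[axis] <- s
    out <- out + kernel[j] * shift3d_num(vol, shift[1], shift[2], shift[3])
  }
  out
}

shift3d_num <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

#' Smooth each volume of a BOLD series with an isotropic Gaussian
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2))` in mm, converted to voxel units per
#' axis by the grid's voxel size.  `fwhm_mm = 0` returns the input.
#'
#' @param bold a [bold_series()] (or a 3D array together with `grid`).
#' @param fwhm_mm full width at half maximum in mm (default 4).
#' @param grid required when `bold` is a bare array.
#' @return the smoothed object, same class as the input.
#' @export
smooth_gaussian <- function(bold, fwhm_mm = 4, grid = NULL) {
  if (fwhm_mm < 0) stopf("fwhm must be non-negative")
  fwhm_to_sigma <- 1 / (2 * sqrt(2 * log(2)))
  smooth_vol <- function(vol, vox) {
    for (axis in 1:3) {
      k <- gaussian_kernel_1d(fwhm_mm * fwhm_to_sigma / vox[axis])
      vol <- conv_axis(vol, k, axis)
    }
    vol
  }
  if (is.array(bold) && length(dim(bold)) == 3L) {
    if (is.null(grid)) stopf("grid required for bare arrays")
    if (fwhm_mm == 0) return(bold)
    return(smooth_vol(bold, grid$voxel_size_mm))
  }
  stopifnot(inherits(bold, "bold_series"))
  if (isTRUE(bold$flat)) stopf("smoothing requires array storage; see as_array_bold()")
  if (fwhm_mm == 0) return(bold)
  vox <- bold$grid$voxel_size_mm
  # all volumes at once: the shifts leave the 4th dimension untouched
  out <- bold$data
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(fwhm_mm * fwhm_to_sigma / vox[axis])
    out <- conv_axis4d(out, k, axis)
  }
  bold$data <- out
  bold
}

# Convolve a 4D array along one spatial axis by whole-vector stride shifts
# (zero padding at the axis edges); much cheaper than sliced indexing.
conv_axis4d <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(arr * kernel)
  d <- dim(arr)
  n <- length(arr)
  stride <- prod(d[seq_len(axis - 1L)])
  axlen <- d[axis]
  ax_idx <- rep(rep.int(seq_len(axlen), rep.int(stride, axlen)),
                times = n / (stride * axlen))
  v <- as.vector(arr)
  out <- numeric(n)
  for (j in seq_along(kernel)) {
    s <- j - 1L - r
    off <- s * stride
    if (off == 0L) {
      out <- out + kernel[j] * v
      next
    }
    sv <- numeric(n)
    if (off > 0L) sv[(off + 1L):n] <- v[1:(n - off)]
    else sv[1:(n + off)] <- v[(1L - off):n]
    # zero the positions whose source wrapped across the axis boundary
    if (s > 0L) sv[ax_idx <= s] <- 0 else sv[ax_idx > axlen + s] <- 0
    out <- out + kernel[j] * sv
  }
  dim(out) <- d
  out
}
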