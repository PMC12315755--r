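# Binary 3D morphology on logical arrays: dilation, erosion, connected
# components, centroids.  Implemented with whole-array shifts so the cost is
# (neighbors x voxels) vectorized operations; grids here are small (tens of
# thousands of voxels) so no compiled code is needed.

neighbor_offsets <- function(connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L)) stopf("connectivity must be 6, 18 or 26")
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 `6` = d == 1, `18` = d >= 1 & d <= 2, `26` = d >= 1)
  as.matrix(off[keep, , drop = FALSE])
}

# Shift a 3D logical array by (dx,dy,dz), padding with `fill`.
shift3d <- function(m, dx, dy, dz, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

#' Dilate a binary mask
#'
#' @param mask logical 3D array.
#' @param iterations number of dilation passes (0 returns the input).
#' @param connectivity neighborhood: 6 (faces), 18 (+edges) or 26 (+corners;
#'   default, matching the package-wide convention).
#' @return logical 3D array.
#' @export
dilate_mask <- function(mask, iterations = 1L, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  off <- neighbor_offsets(connectivity)
  for (i in seq_len(iterations)) {
    out <- mask
    for (j in seq_len(nrow(off))) {
      out <- out | shift3d(mask, off[j, 1], off[j, 2], off[j, 3], fill = FALSE)
    }
    mask <- out
  }
  mask
}

#' Erode a binary mask
#'
#' Voxels survive only if all neighbors in the structuring element are in
#' the mask; image borders count as background.  The default element is the
#' 6-connected cross, a conservative choice for tissue-compartment erosion.
#'
#' @inheritParams dilate_mask
#' @export
erode_mask <- function(mask, iterations = 1L, connectivity = 6L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  off <- neighbor_offsets(connectivity)
  for (i in seq_len(iterations)) {
    out <- mask
    for (j in seq_len(nrow(off))) {
      out <- out & shift3d(mask, off[j, 1], off[j, 2], off[j, 3], fill = FALSE)
    }
    mask <- out
  }
  mask
}

#' Label connected components of a binary mask
#'
#' Flood fill over the mask's voxels only, so cost scales with mask size.
#'
#' @inheritParams dilate_mask
#' @return integer 3D array; 0 background, components numbered from 1 in
#'   decreasing size order.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  off <- neighbor_offsets(connectivity)
  # linear-index offsets plus coordinate bookkeeping to avoid wrap-around
  coords <- arrayInd(idx, d)
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  comp <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      vc <- arrayInd(v, d)
      for (j in seq_len(nrow(off))) {
        x <- vc[1] + off[j, 1]; y <- vc[2] + off[j, 2]; z <- vc[3] + off[j, 3]
        if (x < 1L || y < 1L || z < 1L || x > d[1] || y > d[2] || z > d[3]) next
        w <- x + d[1] * ((y - 1L) + d[2] * (z - 1L))
        if (inmask[w] && lab[w] == 0L) {
          lab[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  # renumber by decreasing size (stable: ties keep discovery order)
  sizes <- tabulate(lab[lab > 0L], nbins = comp)
  ord <- order(-sizes, seq_len(comp))
  remap <- integer(comp); remap[ord] <- seq_len(comp)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Centroid of a binary mask in voxel coordinates
#' @param mask logical 3D array.
#' @return numeric length 3 (x, y, z), 1-based voxel units.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) stopf("mask is empty")
  colMeans(arrayInd(idx, dim(mask)))
}

# N grid voxels nearest to `center` (1-based voxel coords); deterministic
# lexicographic tie-break.  Used by the phantom to implant compact nuclei.
ball_mask <- function(shape, center, n_vox) {
  ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
  dx2 <- (ax - center[1])^2
  dy2 <- (ay - center[2])^2
  dz2 <- (az - center[3])^2
  dist <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  ord <- order(as.vector(dist), seq_along(dist))
  m <- array(FALSE, shape)
  m[ord[seq_len(n_vox)]] <- TRUE
  m
}

box_mask <- function(shape, xr, yr, zr) {
  m <- array(FALSE, shape)
  m[xr, yr, zr] <- TRUE
  m
}
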