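# Tissue-compartment nuisance series: WM/CSF (iteratively eroded masks),
# global gray matter, and TSR-local WM.

#' Eroded-compartment mean signal
#'
#' The compartment mask is eroded iteratively, up to `n_erosions_max` times,
#' stopping before any erosion that would leave fewer than two voxels; the
#' returned series is the spatial mean over the final mask at each volume.
#' Intended to be run on unsmoothed data.
#'
#' @param bold a [bold_series()] (unsmoothed).
#' @param labels a [labeled_volume()] on the same grid.
#' @param compartment structure name, e.g. `"white_matter"` or `"csf"`.
#' @param n_erosions_max maximum erosions (default 3).
#' @param connectivity erosion structuring element (default 6, a
#'   face-adjacent cross).
#' @return numeric vector, one value per volume.
#' @export
compartment_signal <- function(bold, labels, compartment, n_erosions_max = 3L,
                               connectivity = 6L) {
  assert_same_grid(bold$grid, labels$grid, "BOLD series")
  mask <- label_mask(labels, compartment)
  if (!any(mask)) stopf("compartment '%s' is empty", compartment)
  mask <- erode_compartment(mask, n_erosions_max, connectivity)
  mask_mean_series(bold, mask)
}

# Erode up to n_max times while the next erosion keeps >= 2 voxels.
erode_compartment <- function(mask, n_max = 3L, connectivity = 6L) {
  for (i in seq_len(n_max)) {
    nxt <- erode_mask(mask, 1L, connectivity)
    if (sum(nxt) < 2L) break
    mask <- nxt
  }
  mask
}

#' Global gray-matter signal
#'
#' Mean over the cortical gray-matter mask eroded once, from unsmoothed data.
#' @inheritParams compartment_signal
#' @export
global_gm_signal <- function(bold, labels, connectivity = 6L) {
  assert_same_grid(bold$grid, labels$grid, "BOLD series")
  gm <- label_mask(labels, "cortical_gm")
  er <- erode_mask(gm, 1L, connectivity)
  if (sum(er) < 2L) er <- gm
  mask_mean_series(bold, er)
}

#' TSR-local white-matter signal
#'
#' Mean over white-matter voxels located between one and five voxels from
#' the search region in any direction (26-neighbor dilation distance),
#' extracted from unsmoothed data.  Falls back to the global eroded WM
#' signal with a warning when the shell contains no WM.
#'
#' @param bold a [bold_series()] (unsmoothed).
#' @param labels a [labeled_volume()].
#' @param tsr_mask logical 3D array (the search region), or a
#'   `thalamic_search_region`.
#' @param max_dist shell outer radius in dilation steps (default 5).
#' @return numeric vector, one value per volume.
#' @export
local_wm_series <- function(bold, labels, tsr_mask, max_dist = 5L) {
  if (inherits(tsr_mask, "thalamic_search_region")) tsr_mask <- tsr_mask$mask
  wm <- label_mask(labels, "white_matter")
  shell <- dilate_mask(tsr_mask, max_dist, 26L) & !tsr_mask
  sel <- wm & shell
  if (!any(sel)) {
    warnf("no white matter within %d voxels of the TSR; using global WM signal",
          max_dist)
    return(compartment_signal(bold, labels, "white_matter"))
  }
  mask_mean_series(bold, sel)
}
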