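# Thalamic search regions (TSRs): participant-specific neighborhoods of the
# segmentation-estimated MGN/LGN in which functional nuclei are sought.
# Built by dilating the segmentation seed (MGN: 3 iterations, LGN: 1),
# removing an exclusion union of surrounding structures, deleting the
# posterior-most two slices, and (MGN only) constraining to at or below the
# inferior-most pulvinar slice.

#' Union of exclusion structures around posterior thalamus
#'
#' Cortical gray matter, parahippocampal WM and hippocampus enter
#' undilated; mediodorsal nucleus, insular WM, choroid plexus, pulvinar,
#' putamen and pallidum are each dilated once before the union.
#'
#' @param labels a [labeled_volume()].
#' @param connectivity dilation neighborhood (default 26).
#' @return logical 3D array.
#' @export
exclusion_union <- function(labels, connectivity = 26L) {
  undilated <- c("cortical_gm", "parahippocampal_wm", "hippocampus")
  dilated <- c("mediodorsal_L", "mediodorsal_R", "insular_wm",
               "choroid_plexus", "pulvinar_L", "pulvinar_R",
               "putamen", "pallidum")
  missing <- setdiff(c(undilated, dilated), names(labels$label_map))
  if (length(missing)) {
    stopf("missing required label(s): %s", paste(missing, collapse = ", "))
  }
  out <- label_mask_union(labels, undilated)
  for (nm in dilated) {
    m <- labels$labels == labels$label_map[[nm]]
    if (any(m)) out <- out | dilate_mask(m, 1L, connectivity)
  }
  out
}

#' Posterior-slice and pulvinar trims of a TSR mask
#'
#' Removes voxels lying in the two posterior-most (smallest-y) slices in
#' which the TSR has any voxels.  For the MGN-TSR only, additionally
#' removes voxels strictly superior to the inferior-most slice of the
#' bilateral pulvinar (z > min pulvinar z; the boundary slice is kept).
#'
#' @param tsr_mask logical 3D array.
#' @param nucleus `"mgn"` or `"lgn"`.
#' @param pulvinar_mask bilateral pulvinar mask (required for mgn).
#' @return trimmed logical array.
#' @export
posterior_and_pulvinar_trim <- function(tsr_mask, nucleus = c("mgn", "lgn"),
                                        pulvinar_mask = NULL) {
  nucleus <- match.arg(nucleus)
  idx <- which(tsr_mask)
  if (!length(idx)) stopf("TSR mask is empty before trimming")
  co <- arrayInd(idx, dim(tsr_mask))
  ys <- sort(unique(co[, 2]))
  drop_y <- ys[seq_len(min(2L, length(ys)))]
  keep <- !(co[, 2] %in% drop_y)
  if (nucleus == "mgn") {
    if (is.null(pulvinar_mask) || !any(pulvinar_mask)) {
      stopf("pulvinar mask required for the MGN-TSR trim")
    }
    zstar <- min(arrayInd(which(pulvinar_mask), dim(pulvinar_mask))[, 3])
    keep <- keep & co[, 3] <= zstar
  }
  out <- array(FALSE, dim(tsr_mask))
  out[idx[keep]] <- TRUE
  if (!any(out)) stopf("TSR empty after posterior/pulvinar trimming (QC failure)")
  out
}

#' Build a hemispheric thalamic search region
#'
#' @param labels a [labeled_volume()] containing the segmentation seeds
#'   (`mgn_seed_L/R`, `lgn_seed_L/R`), the pulvinar and all exclusion
#'   structures.
#' @param nucleus `"mgn"` (seed dilated 3 times) or `"lgn"` (dilated once).
#' @param hemisphere `"L"` or `"R"`.
#' @param dilations override of the dilation count (default per nucleus).
#' @param connectivity dilation neighborhood (default 26).
#' @return An object of class `thalamic_search_region`: `mask`, `nucleus`,
#'   `hemisphere`, and `provenance` (step names with voxel counts).
#' @export
build_tsr <- function(labels, nucleus = c("mgn", "lgn"),
                      hemisphere = c("L", "R"), dilations = NULL,
                      connectivity = 26L) {
  nucleus <- match.arg(nucleus)
  hemisphere <- match.arg(hemisphere)
  if (is.null(dilations)) dilations <- if (nucleus == "mgn") 3L else 1L
  seed_name <- sprintf("%s_seed_%s", nucleus, hemisphere)
  seed <- label_mask(labels, seed_name)
  prov <- list(seed = sum(seed))
  m <- dilate_mask(seed, dilations, connectivity)
  prov$dilated <- sum(m)
  m <- m & !exclusion_union(labels, connectivity)
  prov$after_exclusion <- sum(m)
  if (!any(m)) stopf("TSR empty after exclusion masking (QC failure)")
  pulv <- label_mask_union(labels, c("pulvinar_L", "pulvinar_R"))
  m <- posterior_and_pulvinar_trim(m, nucleus, pulv)
  prov$after_trim <- sum(m)
  structure(list(mask = m, nucleus = nucleus, hemisphere = hemisphere,
                 provenance = prov),
            class = "thalamic_search_region")
}

#' @export
print.thalamic_search_region <- function(x, ...) {
  cat(sprintf("<thalamic_search_region> %s-%s: %d voxels (%s)\n",
              toupper(x$nucleus), x$hemisphere, sum(x$mask),
              paste(sprintf("%s=%d", names(x$provenance),
                            unlist(x$provenance)), collapse = ", ")))
  invisible(x)
}
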