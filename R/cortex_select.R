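# Cortical reference selection: per-hemisphere auditory/visual search masks
# from Brodmann-area labels, rank-based contrast thresholding, connected
# cluster selection, and extraction of the AC/VC reference time series.

#' Cortical search mask for one modality and hemisphere
#'
#' Auditory: union of BA 41 and 42 (the `ba41_42` label); visual: union of
#' BA 17 and 18 (`ba17_18`); dilated once in 3D.
#'
#' @param labels a [labeled_volume()].
#' @param modality `"auditory"` or `"visual"`.
#' @param hemisphere `"L"` or `"R"`.
#' @param connectivity dilation neighborhood (default 26).
#' @return logical 3D array.
#' @export
make_cortex_search_mask <- function(labels, modality = c("auditory", "visual"),
                                    hemisphere = c("L", "R"),
                                    connectivity = 26L) {
  modality <- match.arg(modality)
  hemisphere <- match.arg(hemisphere)
  base <- if (modality == "auditory") "ba41_42" else "ba17_18"
  nm <- paste0(base, "_", hemisphere)
  if (!nm %in% names(labels$label_map)) stopf("missing required label(s): %s", nm)
  m <- labels$labels == labels$label_map[[nm]]
  if (!any(m)) stopf("cortical search label '%s' is empty", nm)
  dilate_mask(m, 1L, connectivity)
}

# Keep the ceil(pct/100 * N) most extreme in-mask voxels; boundary ties are
# all included (stable superset).
rank_threshold_mask <- function(values, mask, tail = c("top", "bottom"),
                                pct = 10) {
  tail <- match.arg(tail)
  idx <- which(mask)
  if (!length(idx)) stopf("threshold mask is empty")
  v <- values[idx]
  k <- ceiling(pct / 100 * length(idx))
  s <- sort(v, decreasing = (tail == "top"))
  cut <- s[k]
  keep <- if (tail == "top") v >= cut else v <= cut
  out <- array(FALSE, dim(mask))
  out[idx[keep]] <- TRUE
  out
}

#' Select the reference cortex cluster for one hemisphere and modality
#'
#' Thresholds the Auditory - Visual contrast inside the search mask to its
#' top (auditory) or bottom (visual) `pct` percent by rank, removes
#' connected components smaller than `min_size` voxels, and returns the
#' surviving component containing the greatest-magnitude peak.  Ties among
#' component peaks go to the larger component, then to the lexicographically
#' smallest peak index.
#'
#' @param contrast a `contrast_map` from [contrast_auditory_minus_visual()].
#' @param mask search mask from [make_cortex_search_mask()].
#' @param tail `"top"` for auditory, `"bottom"` for visual.
#' @param pct rank-percentile retained (default 10).
#' @param min_size minimum cluster size in voxels (default 10).
#' @param connectivity component connectivity (default 26).
#' @return An object of class `cortex_cluster`: `mask`, `peak_value`,
#'   `size`, `tail`.
#' @export
select_cortex_cluster <- function(contrast, mask, tail = c("top", "bottom"),
                                  pct = 10, min_size = 10L,
                                  connectivity = 26L) {
  tail <- match.arg(tail)
  vals <- contrast$values
  thr <- rank_threshold_mask(vals, mask, tail, pct)
  comps <- connected_components(thr, connectivity)
  ncomp <- max(comps)
  if (ncomp == 0L) stopf("no suprathreshold voxels in search mask (QC failure)")
  best <- NULL
  for (ci in seq_len(ncomp)) {
    cm <- comps == ci
    size <- sum(cm)
    if (size < min_size) next
    cidx <- which(cm)
    peak_abs <- max(abs(vals[cidx]))
    peak_idx <- min(cidx[abs(vals[cidx]) == peak_abs])
    cand <- list(mask = cm, size = size, peak_abs = peak_abs,
                 peak_idx = peak_idx, peak_value = vals[peak_idx])
    if (is.null(best) ||
        cand$peak_abs > best$peak_abs ||
        (cand$peak_abs == best$peak_abs &&
         (cand$size > best$size ||
          (cand$size == best$size && cand$peak_idx < best$peak_idx)))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stopf("no cluster of >= %d contiguous voxels survives thresholding (QC failure)",
          min_size)
  }
  structure(list(mask = best$mask, peak_value = best$peak_value,
                 size = best$size, tail = tail),
            class = "cortex_cluster")
}

#' Extract a cortical reference time series
#'
#' Spatial mean within each hemisphere's cluster, then the unweighted mean
#' of the two hemispheric series, yielding one reference series per
#' modality.  Intended to be run on smoothed task data.
#'
#' @param bold a smoothed task [bold_series()].
#' @param cluster_L,cluster_R `cortex_cluster` objects (both required; a
#'   missing hemisphere is a participant QC failure).
#' @return numeric vector, one value per volume.
#' @export
reference_series <- function(bold, cluster_L, cluster_R) {
  if (is.null(cluster_L) || is.null(cluster_R)) {
    stopf("both hemispheres must contribute a cortex cluster (QC failure)")
  }
  sL <- mask_mean_series(bold, cluster_L$mask)
  sR <- mask_mean_series(bold, cluster_R$mask)
  (sL + sR) / 2
}
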