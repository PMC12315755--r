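# Coactivation-based fROI extraction: partial correlation of each TSR voxel
# with the AC and VC reference series, size-adaptive rank thresholding,
# dual-map exclusion, largest-cluster extraction, and QC heuristics.

#' Pearson partial correlation
#'
#' Correlation of the residuals of `x` and `y` after least-squares
#' projection onto an intercept plus the nuisance columns.
#'
#' @param x,y numeric vectors of equal length.
#' @param nuisance numeric matrix (may have zero columns or be NULL).
#' @return correlation in \[-1, 1\].
#' @export
partial_correlation <- function(x, y, nuisance = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  N <- cbind(rep(1, n), nuisance)
  if (n < ncol(N) + 2L) stopf("too few samples for %d nuisance columns", ncol(N) - 1L)
  qrN <- qr(N)
  if (qrN$rank < ncol(N)) stopf("nuisance matrix is rank deficient")
  rx <- qr.resid(qrN, x)
  ry <- qr.resid(qrN, y)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  tol_x <- 1e-8 * sqrt(sum((x - mean(x))^2))
  tol_y <- 1e-8 * sqrt(sum((y - mean(y))^2))
  if (sx <= tol_x || sy <= tol_y) {
    stopf("degenerate signal: zero residual variance in partial correlation")
  }
  sum(rx * ry) / (sx * sy)
}

# Residual-maker applied to a matrix of series (time x k).
residualize <- function(M, qrN) {
  qr.resid(qrN, M)
}

#' Coactivation maps of one TSR
#'
#' Per-voxel partial correlation of the (smoothed) task series inside the
#' search region with the AC and the VC reference series, controlling the
#' nuisance bundle.  Voxels with degenerate residual variance are excluded
#' (NA) with a warning.
#'
#' @param bold a smoothed task [bold_series()], or a time-by-voxel matrix of
#'   TSR voxel series (then `tsr` supplies the voxel order via `which(mask)`).
#' @param tsr a `thalamic_search_region` (or bare logical mask).
#' @param ac_series,vc_series reference series (same length as the run).
#' @param nuisance matrix of nuisance regressors (no intercept column
#'   needed; one is added).
#' @return An object of class `coactivation_result`: `r_ac`, `r_vc`
#'   (3D arrays, NA outside the TSR), `tsr`, and empty `kept_ac`/`kept_vc`
#'   until [threshold_and_exclude()] is applied.
#' @export
coactivation_maps <- function(bold, tsr, ac_series, vc_series, nuisance = NULL) {
  mask <- if (inherits(tsr, "thalamic_search_region")) tsr$mask else tsr
  idx <- which(mask)
  if (!length(idx)) stopf("TSR mask is empty")
  if (inherits(bold, "bold_series")) {
    Y <- t(bold_matrix(bold)[idx, , drop = FALSE])   # time x voxels
  } else {
    Y <- bold
    if (ncol(Y) != length(idx)) stopf("voxel series count does not match TSR size")
  }
  nt <- nrow(Y)
  stopifnot(length(ac_series) == nt, length(vc_series) == nt)
  N <- cbind(rep(1, nt), nuisance)
  qrN <- qr(N)
  if (qrN$rank < ncol(N)) stopf("nuisance matrix is rank deficient")
  rY <- residualize(Y, qrN)
  rac <- residualize(matrix(ac_series), qrN)
  rvc <- residualize(matrix(vc_series), qrN)
  ssY <- sqrt(colSums(rY^2))
  ssa <- sqrt(sum(rac^2)); ssv <- sqrt(sum(rvc^2))
  tol_a <- 1e-8 * sqrt(sum((ac_series - mean(ac_series))^2))
  tol_v <- 1e-8 * sqrt(sum((vc_series - mean(vc_series))^2))
  if (ssa <= tol_a || ssv <= tol_v) {
    stopf("degenerate reference series after nuisance removal")
  }
  good <- ssY > 1e-10 * sqrt(nt)
  if (!all(good)) warnf("%d TSR voxel(s) excluded: degenerate residual variance",
                        sum(!good))
  r_ac_v <- rep(NA_real_, length(idx))
  r_vc_v <- rep(NA_real_, length(idx))
  r_ac_v[good] <- drop(crossprod(rY[, good, drop = FALSE], rac)) / (ssY[good] * ssa)
  r_vc_v[good] <- drop(crossprod(rY[, good, drop = FALSE], rvc)) / (ssY[good] * ssv)
  shape <- dim(mask)
  r_ac <- array(NA_real_, shape); r_ac[idx] <- r_ac_v
  r_vc <- array(NA_real_, shape); r_vc[idx] <- r_vc_v
  structure(list(tsr = tsr, mask = mask, r_ac = r_ac, r_vc = r_vc,
                 kept_ac = NULL, kept_vc = NULL, threshold_fraction = NA_real_),
            class = "coactivation_result")
}

#' Threshold coactivation maps and remove dual-map voxels
#'
#' The retained fraction is `k / mean_tsr_size` with `k = 32` for the MGN
#' and `k = 20` for the LGN (capped at 1), where `mean_tsr_size` is the
#' average voxel count of that nucleus's TSR across hemispheres.  Each map
#' keeps its `ceil(fraction * N)` highest-correlation voxels (boundary ties
#' included); voxels surviving in both the AC and the VC map are then
#' removed from both.
#'
#' @param result a [coactivation_maps()] result.
#' @param nucleus `"mgn"` or `"lgn"`.
#' @param mean_tsr_size average TSR size across hemispheres (voxels).
#' @param k_target target voxel count; defaults to 32 (mgn) / 20 (lgn).
#' @return the result with `kept_ac`, `kept_vc` and `threshold_fraction` set.
#' @export
threshold_and_exclude <- function(result, nucleus = c("mgn", "lgn"),
                                  mean_tsr_size, k_target = NULL) {
  nucleus <- match.arg(nucleus)
  if (is.null(k_target)) k_target <- if (nucleus == "mgn") 32 else 20
  f <- min(k_target / mean_tsr_size, 1)
  keep_top <- function(rmap) {
    idx <- which(!is.na(rmap))
    out <- array(FALSE, dim(rmap))
    if (!length(idx)) return(out)
    k <- ceiling(f * length(idx))
    v <- rmap[idx]
    cut <- sort(v, decreasing = TRUE)[k]
    out[idx[v >= cut]] <- TRUE
    out
  }
  kept_ac <- keep_top(result$r_ac)
  kept_vc <- keep_top(result$r_vc)
  dual <- kept_ac & kept_vc
  result$kept_ac <- kept_ac & !dual
  result$kept_vc <- kept_vc & !dual
  result$threshold_fraction <- f
  result
}

#' Largest connected component of a mask
#'
#' Ties on size are broken by the higher peak value of `tie_r_map` within
#' the component, then by the lexicographically smallest peak index.
#'
#' @param mask logical 3D array.
#' @param tie_r_map numeric array used for tie-breaking (e.g. the
#'   coactivation map); optional.
#' @param connectivity component connectivity (default 26).
#' @return logical 3D array containing exactly one component.
#' @export
largest_cluster <- function(mask, tie_r_map = NULL, connectivity = 26L) {
  if (!any(mask)) stopf("empty coactivation mask: no fROI cluster (QC failure)")
  comps <- connected_components(mask, connectivity)
  sizes <- tabulate(comps[comps > 0L])
  big <- which(sizes == max(sizes))
  pick <- big[1]
  if (length(big) > 1L && !is.null(tie_r_map)) {
    peak <- vapply(big, function(ci) max(tie_r_map[comps == ci], na.rm = TRUE),
                   numeric(1))
    cand <- big[peak == max(peak)]
    if (length(cand) > 1L) {
      first_idx <- vapply(cand, function(ci) min(which(comps == ci)), numeric(1))
      cand <- cand[which.min(first_idx)]
    }
    pick <- cand[1]
  }
  comps == pick
}

#' Anatomical-plausibility QC flags for an fROI set
#'
#' Automated stand-in for manual review: flags an LGN centroid inferior to
#' the same hemisphere's MGN centroid (`LGN_INFERIOR`), an LGN centroid
#' more medial than the MGN's (`LGN_MEDIAL`), and size asymmetry
#' `|ln(size_L / size_R)| > ln(3)` for either nucleus (`ASYMMETRY`).
#' Flags are advisory; exclusion is the caller's decision.
#'
#' @param froi a `froi_set` (see [extract_frois()]).
#' @param midline_x x coordinate of the midsagittal plane in voxel units;
#'   defaults to the volume center.
#' @return character vector of flags (empty when all checks pass).
#' @export
qc_flags <- function(froi, midline_x = NULL) {
  masks <- froi[c("mgn_L", "mgn_R", "lgn_L", "lgn_R")]
  if (any(vapply(masks, function(m) is.null(m) || !any(m), logical(1)))) {
    return("FAILED")
  }
  if (is.null(midline_x)) midline_x <- (dim(froi$mgn_L)[1] + 1) / 2
  flags <- character(0)
  for (h in c("L", "R")) {
    cm <- mask_centroid(froi[[paste0("mgn_", h)]])
    cl <- mask_centroid(froi[[paste0("lgn_", h)]])
    if (cl[3] < cm[3]) flags <- c(flags, "LGN_INFERIOR")
    if (abs(cl[1] - midline_x) < abs(cm[1] - midline_x)) {
      flags <- c(flags, "LGN_MEDIAL")
    }
  }
  for (nuc in c("mgn", "lgn")) {
    sL <- sum(froi[[paste0(nuc, "_L")]]); sR <- sum(froi[[paste0(nuc, "_R")]])
    if (abs(log(sL / sR)) > log(3)) flags <- c(flags, "ASYMMETRY")
  }
  unique(flags)
}
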