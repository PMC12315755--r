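# Shared domain types: acquisition grid, site configuration, labeled anatomy
# and 4D BOLD series.  All images in one analysis share one grid; the
# pipeline never resamples (resampling is preprocessing, not method).

#' Define the common voxel grid
#'
#' Axis convention is fixed right-anterior-superior: x runs left to right,
#' y posterior to anterior, z inferior to superior.  Voxel indices used
#' throughout the package are 1-based in R but reported geometry
#' ("posterior-most slice") always refers to the smallest y index,
#' "inferior-most" to the smallest z index.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size_mm numeric length 3, edge length of a voxel in mm
#'   (default 2 mm isotropic, the acquisition resolution).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stopf("grid shape must be 3 positive integers")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stopf("voxel sizes must be 3 positive numbers (mm)")
  }
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))
}

assert_same_grid <- function(a, b, what = "volume") {
  if (!same_grid(a, b)) stopf("grid mismatch: %s is not on the session grid", what)
  invisible(TRUE)
}

#' Site acquisition configuration
#'
#' Captures the per-site scan timing of the clustered-sparse localizer task:
#' each 12 s trial is gap / 9 s stimulation / gap / acquisition cluster of
#' `n_cluster_vols` volumes, with the gap calibrated so the trial duration
#' is exact (see [calibrate_gap()]).
#'
#' @param name site tag; `"nyspi"` (TR 0.85 s) and `"sbu"` (TR 0.80 s) are
#'   the built-in presets.
#' @param tr_s repetition time in seconds.
#' @param n_cluster_vols volumes per acquisition cluster (default 3).
#' @param stim_dur_s stimulation duration per trial in seconds (default 9).
#' @param trial_dur_s total trial duration in seconds (default 12).
#' @param n_aud_trials,n_vis_trials stimulus trial counts per run (default 8 each).
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (default 4).
#' @param rest_run_dur_s resting-state run duration in seconds (default 458,
#'   i.e. 7 min 38 s).
#' @return An object of class `site_config`.
#' @export
site_config <- function(name = "nyspi",
                        tr_s = if (identical(name, "sbu")) 0.80 else 0.85,
                        n_cluster_vols = 3L,
                        stim_dur_s = 9,
                        trial_dur_s = 12,
                        n_aud_trials = 8L,
                        n_vis_trials = 8L,
                        fwhm_mm = 4,
                        rest_run_dur_s = 458) {
  cfg <- structure(list(
    name = name, tr_s = tr_s, n_cluster_vols = as.integer(n_cluster_vols),
    stim_dur_s = stim_dur_s, trial_dur_s = trial_dur_s,
    n_aud_trials = as.integer(n_aud_trials),
    n_vis_trials = as.integer(n_vis_trials),
    fwhm_mm = fwhm_mm, rest_run_dur_s = rest_run_dur_s
  ), class = "site_config")
  if (cfg$trial_dur_s < cfg$stim_dur_s + cfg$n_cluster_vols * cfg$tr_s) {
    stopf("infeasible site config: trial shorter than stimulation plus cluster")
  }
  cfg
}

#' Structure names every analysis expects in a segmentation volume
#'
#' Seeds and exclusion structures for the thalamic search regions, the
#' cortical parcels for reference selection and alternative ROIs, tissue
#' compartments for nuisance signals, and the brain envelope.
#' @format character vector of structure names.
#' @export
REQUIRED_LABELS <- c(
  "mgn_seed_L", "mgn_seed_R", "lgn_seed_L", "lgn_seed_R",
  "pulvinar_L", "pulvinar_R", "mediodorsal_L", "mediodorsal_R",
  "ba41_42_L", "ba41_42_R", "ba17_18_L", "ba17_18_R",
  "transverse_temporal_L", "transverse_temporal_R",
  "pericalcarine_L", "pericalcarine_R",
  "cortical_gm", "white_matter", "csf", "choroid_plexus",
  "putamen", "pallidum", "hippocampus",
  "parahippocampal_wm", "insular_wm", "brain"
)

#' Construct a labeled segmentation volume
#'
#' A single integer-valued 3D array plus a name-to-integer dictionary.
#' Background is 0.  By convention every non-zero voxel is in-brain, and
#' `label_mask(lv, "brain")` returns the whole non-zero support; the
#' integer mapped to `"brain"` marks otherwise-unlabeled brain tissue.
#'
#' @param grid a [volume_grid()].
#' @param labels 3D integer array with `dim == grid$shape`.
#' @param label_map named integer vector mapping structure names to labels.
#' @param require_all validate that all labels in [REQUIRED_LABELS] are
#'   present (default TRUE).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(grid, labels, label_map, require_all = TRUE) {
  if (!identical(dim(labels), grid$shape)) {
    stopf("label array shape does not match grid shape")
  }
  if (any(labels != round(labels))) stopf("label volume has non-integer voxel values")
  storage.mode(labels) <- "integer"
  label_map <- vapply(label_map, as.integer, integer(1))
  if (require_all) {
    missing <- setdiff(REQUIRED_LABELS, names(label_map))
    if (length(missing)) {
      stopf("missing required label(s): %s", paste(missing, collapse = ", "))
    }
  }
  structure(list(grid = grid, labels = labels, label_map = label_map),
            class = "labeled_volume")
}

#' Binary mask for one named structure
#'
#' @param lv a [labeled_volume()].
#' @param name structure name; `"brain"` returns all non-background voxels.
#' @return logical 3D array.
#' @export
label_mask <- function(lv, name) {
  if (identical(name, "brain")) return(lv$labels != 0L)
  if (!name %in% names(lv$label_map)) stopf("missing required label(s): %s", name)
  m <- lv$labels == lv$label_map[[name]]
  if (!any(m)) stopf("label '%s' maps to an empty mask", name)
  m
}

label_mask_union <- function(lv, names) {
  m <- array(FALSE, lv$grid$shape)
  for (nm in names) m <- m | (lv$labels == lv$label_map[[nm]])
  m
}

#' Construct a 4D BOLD series
#'
#' @param grid a [volume_grid()].
#' @param data 4D numeric array (x, y, z, t) in arbitrary scanner units.
#' @param tr_s repetition time in seconds.
#' @param timestamps_s per-volume acquisition times (strictly increasing).
#'   For continuous data defaults to `(0:(t-1)) * tr_s`; clustered-sparse
#'   task data must supply the true cluster timestamps.
#' @param kind `"task-sparse"` or `"rest-continuous"`.
#' @param site the [site_config()] the run was acquired under.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(grid, data, tr_s, timestamps_s = NULL,
                        kind = c("rest-continuous", "task-sparse"),
                        site = NULL) {
  kind <- match.arg(kind)
  d <- dim(data)
  flat <- length(d) == 2L && !is.null(attr(data, "mask_idx"))
  if (flat) {
    if (nrow(data) != length(attr(data, "mask_idx"))) {
      stopf("flat BOLD data must have one row per mask voxel")
    }
    nt <- d[2]
  } else {
    if (length(d) != 4L || !identical(d[1:3], grid$shape)) {
      stopf("BOLD data must be 4D on the session grid")
    }
    nt <- d[4]
  }
  if (nt < 1L) stopf("BOLD series needs at least one volume")
  if (is.null(timestamps_s)) timestamps_s <- (seq_len(nt) - 1) * tr_s
  if (length(timestamps_s) != nt || any(diff(timestamps_s) <= 0)) {
    stopf("timestamps must be strictly increasing, one per volume")
  }
  structure(list(grid = grid, data = data, tr_s = tr_s,
                 timestamps_s = timestamps_s, kind = kind, site = site,
                 flat = flat),
            class = "bold_series")
}

n_volumes <- function(bold) {
  if (isTRUE(bold$flat)) ncol(bold$data) else dim(bold$data)[4]
}

bold_is_flat <- function(bold) isTRUE(bold$flat)

# Voxels-by-time matrix of a 4D series (copies; prefer bold_submatrix for
# subsets of voxels).  Flat series expand to the full grid with zeros
# outside the stored mask.
bold_matrix <- function(bold) {
  if (bold_is_flat(bold)) {
    out <- matrix(0, prod(bold$grid$shape), ncol(bold$data))
    out[attr(bold$data, "mask_idx"), ] <- bold$data
    return(out)
  }
  d <- dim(bold$data)
  matrix(bold$data, prod(d[1:3]), d[4])
}

# Rows of the implicit voxels-by-time matrix for the given linear voxel
# indices, without materializing the full matrix.
bold_submatrix <- function(bold, idx) {
  nt <- n_volumes(bold)
  if (bold_is_flat(bold)) {
    rows <- match(idx, attr(bold$data, "mask_idx"))
    if (anyNA(rows)) stopf("requested voxels are outside the stored brain mask")
    return(bold$data[rows, , drop = FALSE])
  }
  nvox <- prod(bold$grid$shape)
  # linear indices into the flattened 4D array (as.vector: a matrix index
  # would be misread as coordinates when nt happens to equal 4)
  ivec <- as.vector(outer(as.double(idx), (seq_len(nt) - 1) * nvox, `+`))
  matrix(bold$data[ivec], length(idx), nt)
}

#' Convert a flat (masked-matrix) BOLD series to full 4D array storage
#' @param bold a [bold_series()].
#' @return the same series with a 4D data array (zeros outside the mask).
#' @export
as_array_bold <- function(bold) {
  if (!bold_is_flat(bold)) return(bold)
  M <- bold_matrix(bold)
  dim(M) <- c(bold$grid$shape, ncol(bold$data))
  bold_series(bold$grid, M, bold$tr_s, bold$timestamps_s, bold$kind, bold$site)
}

#' Mean time series over a mask
#'
#' @param bold a [bold_series()].
#' @param mask logical 3D array on the same grid.
#' @return numeric vector, one value per volume.
#' @export
mask_mean_series <- function(bold, mask) {
  stopifnot(identical(dim(mask), bold$grid$shape))
  idx <- which(mask)
  if (!length(idx)) stopf("mask is empty")
  colMeans(bold_submatrix(bold, idx))
}
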