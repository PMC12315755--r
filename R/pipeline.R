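# Participant-level localizer pipeline: smoothing, per-run GLM, cortical
# reference selection, search-region construction, coactivation mapping and
# fROI extraction, with QC flags.

# Coactivation nuisance bundle over concatenated task runs: WM, CSF, global
# GM (eroded cortical GM), TSR-local WM (all from unsmoothed data),
# cluster-volume-2/3 indicators, and per-run intercepts to absorb run
# baselines under concatenation.
coactivation_nuisance <- function(task_runs, schedules, labels, tsr) {
  blocks <- lapply(seq_along(task_runs), function(r) {
    bold <- task_runs[[r]]
    info <- schedule_volume_info(schedules[[r]])
    cbind(wm = compartment_signal(bold, labels, "white_matter"),
          csf = compartment_signal(bold, labels, "csf"),
          gm = global_gm_signal(bold, labels),
          local_wm = local_wm_series(bold, labels, tsr),
          vol2 = as.numeric(info$cluster_pos == 2L),
          vol3 = as.numeric(info$cluster_pos == 3L))
  })
  N <- do.call(rbind, blocks)
  nrun <- length(task_runs)
  if (nrun > 1L) {
    lens <- vapply(task_runs, n_volumes, integer(1))
    run_id <- rep(seq_len(nrun), lens)
    # run intercept contrasts (first run absorbed by the global intercept)
    for (r in 2:nrun) N <- cbind(N, as.numeric(run_id == r))
  }
  N
}

#' Run the full localizer analysis for one participant
#'
#' Smooths each task run, fits the sparse GLM (motion, WM and CSF
#' nuisance), averages the Auditory - Visual contrast over runs, selects
#' per-hemisphere AC and VC reference clusters, builds the MGN and LGN
#' search regions, computes AC/VC coactivation maps over the concatenated
#' task series by partial correlation, applies the size-adaptive thresholds
#' (32 / mean MGN-TSR voxels; 20 / mean LGN-TSR voxels) with dual-map
#' exclusion, extracts the largest clusters as fROIs, and attaches QC
#' flags.
#'
#' @param labels a [labeled_volume()].
#' @param task_runs list of unsmoothed task [bold_series()] (at least two).
#' @param schedules list of matching [trial_schedule()] objects.
#' @param motion list of per-run 6-column motion tables (optional).
#' @param fwhm_mm smoothing kernel (default from the first schedule's site).
#' @param k_mgn,k_lgn coactivation threshold target counts (default 32, 20).
#' @param connectivity morphology neighborhood (default 26).
#' @return list with `froi` (a `froi_set`), `contrast`, `tsr` (per
#'   nucleus/hemisphere), `cortex` (selected clusters), `coactivation`
#'   (per nucleus/hemisphere `coactivation_result`).
#' @export
extract_frois <- function(labels, task_runs, schedules, motion = NULL,
                          fwhm_mm = NULL, k_mgn = 32, k_lgn = 20,
                          connectivity = 26L) {
  stopifnot(length(task_runs) == length(schedules))
  if (length(task_runs) < 2L) stopf("a minimum of two task runs is required")
  if (is.null(fwhm_mm)) fwhm_mm <- schedules[[1]]$site$fwhm_mm
  smoothed <- lapply(task_runs, smooth_gaussian, fwhm_mm = fwhm_mm)
  fits <- lapply(seq_along(task_runs), function(r) {
    wm <- compartment_signal(task_runs[[r]], labels, "white_matter")
    csf <- compartment_signal(task_runs[[r]], labels, "csf")
    mot <- if (is.null(motion)) NULL else motion[[r]]
    X <- build_design(schedules[[r]], motion = mot, wm = wm, csf = csf)
    fit_glm(smoothed[[r]], X)
  })
  contrast <- contrast_auditory_minus_visual(fits)
  cortex <- list()
  for (h in c("L", "R")) {
    am <- make_cortex_search_mask(labels, "auditory", h, connectivity)
    vm <- make_cortex_search_mask(labels, "visual", h, connectivity)
    cortex[[paste0("ac_", h)]] <-
      select_cortex_cluster(contrast, am, "top", connectivity = connectivity)
    cortex[[paste0("vc_", h)]] <-
      select_cortex_cluster(contrast, vm, "bottom", connectivity = connectivity)
  }
  ac_series <- unlist(lapply(smoothed, reference_series,
                             cluster_L = cortex$ac_L, cluster_R = cortex$ac_R))
  vc_series <- unlist(lapply(smoothed, reference_series,
                             cluster_L = cortex$vc_L, cluster_R = cortex$vc_R))
  tsr <- list(); coact <- list(); kept <- list()
  for (nuc in c("mgn", "lgn")) {
    for (h in c("L", "R")) {
      tsr[[paste0(nuc, "_", h)]] <- build_tsr(labels, nuc, h,
                                              connectivity = connectivity)
    }
    mean_size <- mean(c(sum(tsr[[paste0(nuc, "_L")]]$mask),
                        sum(tsr[[paste0(nuc, "_R")]]$mask)))
    k <- if (nuc == "mgn") k_mgn else k_lgn
    for (h in c("L", "R")) {
      key <- paste0(nuc, "_", h)
      N <- coactivation_nuisance(task_runs, schedules, labels, tsr[[key]])
      Y <- do.call(rbind, lapply(smoothed, function(b) {
        t(bold_matrix(b)[which(tsr[[key]]$mask), , drop = FALSE])
      }))
      co <- coactivation_maps(Y, tsr[[key]], ac_series, vc_series, N)
      co <- threshold_and_exclude(co, nuc, mean_size, k_target = k)
      coact[[key]] <- co
      src <- if (nuc == "mgn") co$kept_ac else co$kept_vc
      rmap <- if (nuc == "mgn") co$r_ac else co$r_vc
      kept[[key]] <- largest_cluster(src, rmap, connectivity)
    }
  }
  froi <- froi_set(kept$mgn_L, kept$mgn_R, kept$lgn_L, kept$lgn_R)
  froi$qc_flags <- qc_flags(froi)
  list(froi = froi, contrast = contrast, tsr = tsr, cortex = cortex,
       coactivation = coact)
}

#' Voxelwise frequency map of fROI sets across participants
#'
#' Plumbing utility: the per-voxel fraction of participants whose mask
#' includes the voxel.
#'
#' @param masks list of logical 3D arrays on one grid.
#' @return numeric 3D array in \[0, 1\].
#' @export
froi_frequency_map <- function(masks) {
  stopifnot(length(masks) >= 1L)
  Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks)
}

#' Write an fROI set as NIfTI files
#'
#' One binary file per nucleus/hemisphere plus a combined 4-label file
#' (1 = MGN-L, 2 = MGN-R, 3 = LGN-L, 4 = LGN-R).
#'
#' @param froi a `froi_set`.
#' @param grid the session [volume_grid()].
#' @param out_dir output directory.
#' @param prefix filename prefix (default "froi").
#' @export
write_froi_nifti <- function(froi, grid, out_dir, prefix = "froi") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  combined <- array(0, grid$shape)
  nms <- c("mgn_L", "mgn_R", "lgn_L", "lgn_R")
  for (i in seq_along(nms)) {
    m <- froi[[nms[i]]]
    write_nifti(array(as.numeric(m), dim(m)),
                file.path(out_dir, sprintf("%s_%s.nii.gz", prefix, nms[i])),
                voxel_size_mm = grid$voxel_size_mm, datatype = "int16")
    combined[m] <- i
  }
  write_nifti(combined, file.path(out_dir, sprintf("%s_combined.nii.gz", prefix)),
              voxel_size_mm = grid$voxel_size_mm, datatype = "int16")
  jsonlite::write_json(list(sizes = as.list(froi$sizes),
                            qc_flags = froi$qc_flags),
                       file.path(out_dir, sprintf("%s_qc.json", prefix)),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
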