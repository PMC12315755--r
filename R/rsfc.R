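# Resting-state post-processing and connectivity: mode-1000 normalization,
# linear detrending, interpolation-aware band-pass filtering with edge
# trimming, ROI-pair partial correlations, selectivity contrasts, ROI-set
# benchmarking, and seed maps.
#
# Normalization, detrending and band-pass filtering are linear and applied
# identically to every voxel, so the mean series of an ROI after voxelwise
# processing equals the processed ROI-mean series; ROI analyses therefore
# extract ROI means first and process at series level.

#' Resting-state post-processing configuration
#'
#' @param band_hz band-pass edges in Hz (default 0.009-0.08).
#' @param filter_order Butterworth prototype order (default 2, zero-phase).
#' @param edge_trim_s seconds discarded from each end after filtering
#'   (default 22; 26 volumes at TR 0.85 s, 28 at TR 0.80 s).
#' @param mode_target normalization target for the modal in-brain intensity
#'   (default 1000).
#' @param fisher_z average run-level correlations after Fisher
#'   z-transformation (default FALSE: plain averaging of r).
#' @return an object of class `rsfc_config`.
#' @export
rsfc_config <- function(band_hz = c(0.009, 0.08), filter_order = 2L,
                        edge_trim_s = 22, mode_target = 1000,
                        fisher_z = FALSE) {
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2])) {
    stopf("band must satisfy 0 < low < high")
  }
  structure(list(band_hz = band_hz, filter_order = as.integer(filter_order),
                 edge_trim_s = edge_trim_s, mode_target = mode_target,
                 fisher_z = fisher_z),
            class = "rsfc_config")
}

#' Mode-1000 normalization
#'
#' The modal in-brain intensity is estimated by rounding in-brain values to
#' the nearest integer and taking the most frequent value; every voxel is
#' then scaled by `mode_target / mode`.
#'
#' @param bold a [bold_series()].
#' @param brain_mask logical 3D array.
#' @param mode_target target modal value (default 1000).
#' @return the rescaled [bold_series()], with attribute `"mode"`.
#' @export
mode1000 <- function(bold, brain_mask, mode_target = 1000) {
  mode <- estimate_intensity_mode(bold_submatrix(bold, which(brain_mask)))
  if (mode <= 0) stopf("non-positive modal intensity; cannot normalize")
  bold$data <- bold$data * (mode_target / mode)
  attr(bold, "mode") <- mode
  bold
}

# Most frequent value after rounding to the nearest integer (first value on
# count ties, matching histogram-mode convention).
estimate_intensity_mode <- function(vals) {
  vals <- round(vals)
  shift <- min(vals) - 1
  counts <- tabulate(as.integer(vals - shift))
  which.max(counts) + shift
}

#' Remove linear trend and mean
#'
#' Subtracts the per-series OLS line; the result has zero mean and zero
#' linear trend.
#'
#' @param x numeric vector, or matrix with time down the rows.
#' @return object of the same shape.
#' @export
detrend_center <- function(x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  nt <- nrow(X)
  if (nt < 3L) stopf("need at least 3 time points to detrend")
  tt <- seq_len(nt)
  D <- cbind(1, tt - mean(tt))
  Y <- X - D %*% solve(crossprod(D), crossprod(D, X))
  if (vec) drop(Y) else Y
}

#' Band-pass filter with censored-point interpolation and edge trimming
#'
#' Censored time points are replaced by linear interpolation (edge gaps
#' held at the nearest kept value) before zero-phase band-pass filtering;
#' interpolated points are re-censored afterwards, and
#' `ceil(edge_trim_s / tr_s)` volumes are removed from each end of the
#' retained set.
#'
#' @param x numeric vector or time-by-series matrix.
#' @param keep logical vector (TRUE = retained); NULL keeps everything.
#' @param tr_s repetition time in seconds.
#' @param config an [rsfc_config()].
#' @return list with `series` (filtered, full length), `retained` (logical:
#'   kept, outside censoring, outside the trimmed edges) and `n_trim`.
#' @export
bandpass_with_interpolation <- function(x, keep = NULL, tr_s,
                                        config = rsfc_config()) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  nt <- nrow(X)
  if (is.null(keep)) keep <- rep(TRUE, nt)
  if (sum(keep) < 2L) stopf("fewer than two retained time points")
  if (!all(keep)) {
    ki <- which(keep)
    for (j in seq_len(ncol(X))) {
      X[, j] <- stats::approx(ki, X[ki, j], xout = seq_len(nt), rule = 2)$y
    }
  }
  Y <- bandpass_filtfilt(X, config$band_hz, 1 / tr_s, config$filter_order)
  n_trim <- as.integer(ceiling(config$edge_trim_s / tr_s))
  retained <- keep
  if (n_trim > 0L) {
    lead <- seq_len(min(n_trim, nt))
    tail_i <- seq(max(1L, nt - n_trim + 1L), nt)
    retained[lead] <- FALSE
    retained[tail_i] <- FALSE
  }
  list(series = if (vec) drop(Y) else Y, retained = retained, n_trim = n_trim)
}

# Post-process a bundle of raw series for one run: detrend, interpolate,
# band-pass, trim.  S is time x k.
postprocess_series <- function(S, keep, tr_s, config = rsfc_config()) {
  nms <- colnames(S)
  S <- detrend_center(S)
  out <- bandpass_with_interpolation(S, keep, tr_s, config)
  if (!is.null(nms) && !is.null(dim(out$series))) colnames(out$series) <- nms
  out
}

# RSFC nuisance bundle (time x 28): band-passed MPs, their squares, their
# backward derivatives, squares of the derivatives, WM and CSF signals and
# their derivatives.  `wm` and `csf` must already be post-processed.
rsfc_nuisance <- function(motion, wm, csf, tr_s, config = rsfc_config()) {
  M <- as.matrix(motion)
  if (ncol(M) != 6L) stopf("motion table must have 6 columns")
  Mf <- bandpass_filtfilt(M, config$band_hz, 1 / tr_s, config$filter_order)
  dMf <- apply(Mf, 2, backdiff)
  N <- cbind(Mf, Mf^2, dMf, dMf^2, wm, backdiff(wm), csf, backdiff(csf))
  colnames(N) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_sq"),
                   paste0("dmp", 1:6), paste0("dmp", 1:6, "_sq"),
                   "wm", "dwm", "csf", "dcsf")
  N
}

#' ROI-pair resting-state connectivity for one participant
#'
#' For each run, ROI mean series are extracted from unsmoothed, mode-1000
#' normalized data, post-processed (detrend, censored-point interpolation,
#' band-pass, edge trim), and each geniculo-cortical pair (MGN-AC, MGN-VC,
#' LGN-AC, LGN-VC) is estimated as the mean of the four hemispheric partial
#' correlations (L-L, L-R, R-L, R-R) on retained volumes, controlling the
#' motion/WM/CSF nuisance bundle.  Run values are averaged (plain r, or
#' Fisher z when configured) over valid runs.
#'
#' @param rest_runs list of unsmoothed rest [bold_series()].
#' @param roi_masks named list of logical masks: `mgn_L`, `mgn_R`, `lgn_L`,
#'   `lgn_R`, `ac_L`, `ac_R`, `vc_L`, `vc_R`.
#' @param labels a [labeled_volume()] (for brain mask and WM/CSF signals).
#' @param motion list of per-run 6-column motion tables.
#' @param censor list of per-run `censor_mask` objects (NULL = keep all).
#' @param config an [rsfc_config()].
#' @param censor_cfg a [censor_config()] (for retention rules).
#' @return list with `pairs` (named participant-level values), `runs`
#'   (run-by-pair matrix), `retention`.
#' @export
roi_pair_connectivity <- function(rest_runs, roi_masks, labels, motion,
                                  censor = NULL, config = rsfc_config(),
                                  censor_cfg = censor_config()) {
  need <- c("mgn_L", "mgn_R", "lgn_L", "lgn_R", "ac_L", "ac_R", "vc_L", "vc_R")
  if (!all(need %in% names(roi_masks))) {
    stopf("roi_masks must contain %s", paste(need, collapse = ", "))
  }
  brain <- label_mask(labels, "brain")
  nrun <- length(rest_runs)
  pair_def <- list(mgn_ac = c("mgn", "ac"), mgn_vc = c("mgn", "vc"),
                   lgn_ac = c("lgn", "ac"), lgn_vc = c("lgn", "vc"))
  run_vals <- matrix(NA_real_, nrun, length(pair_def),
                     dimnames = list(NULL, names(pair_def)))
  keep_list <- vector("list", nrun)
  wm_mask <- erode_compartment(label_mask(labels, "white_matter"))
  csf_mask <- erode_compartment(label_mask(labels, "csf"))
  bidx <- which(brain)
  for (r in seq_len(nrun)) {
    bold <- rest_runs[[r]]
    keep <- if (is.null(censor)) rep(TRUE, n_volumes(bold)) else censor[[r]]$keep
    keep_list[[r]] <- structure(list(keep = keep), class = "censor_mask")
    # mode-1000 scaling applied to extracted series (all later steps are
    # linear, so scaling the means equals scaling the volumes)
    sc <- config$mode_target / estimate_intensity_mode(bold_submatrix(bold, bidx))
    roi_S <- vapply(need, function(nm) {
      s <- sc * colMeans(bold_submatrix(bold, which(roi_masks[[nm]])))
      if (stats::sd(s) == 0) stopf("degenerate ROI series: %s", nm)
      s
    }, numeric(n_volumes(bold)))
    wm <- sc * colMeans(bold_submatrix(bold, which(wm_mask)))
    csf <- sc * colMeans(bold_submatrix(bold, which(csf_mask)))
    pp <- postprocess_series(cbind(roi_S, wm = wm, csf = csf), keep,
                             bold$tr_s, config)
    ret <- pp$retained
    S <- pp$series
    N <- rsfc_nuisance(motion[[r]], S[, "wm"], S[, "csf"], bold$tr_s, config)
    # one nuisance projection per run; all pairwise partial correlations
    # come from the residual correlation matrix
    qrN <- qr(cbind(1, N[ret, , drop = FALSE]))
    R <- qr.resid(qrN, S[ret, need, drop = FALSE])
    ss <- sqrt(colSums(R^2))
    if (any(ss < 1e-12)) {
      stopf("degenerate ROI series: %s", paste(need[ss < 1e-12], collapse = ", "))
    }
    C <- crossprod(R) / tcrossprod(ss)
    for (p in names(pair_def)) {
      thal <- pair_def[[p]][1]; ctx <- pair_def[[p]][2]
      combos <- as.matrix(expand.grid(paste0(thal, c("_L", "_R")),
                                      paste0(ctx, c("_L", "_R")),
                                      stringsAsFactors = FALSE))
      run_vals[r, p] <- mean(C[combos])
    }
  }
  retention <- retention_rules(keep_list, rest_runs[[1]]$tr_s, censor_cfg)
  valid <- retention$run_valid
  agg <- function(v) {
    v <- v[valid]
    if (config$fisher_z) tanh(mean(atanh(v))) else mean(v)
  }
  list(pairs = apply(run_vals, 2, agg), runs = run_vals, retention = retention)
}

#' Selectivity contrasts over a participant connectivity table
#'
#' Four within-participant differences — MGN-AC - MGN-VC, MGN-AC - LGN-AC,
#' LGN-VC - LGN-AC, LGN-VC - MGN-VC — each tested against zero with a
#' one-tailed (greater) one-sample t-test, Benjamini-Hochberg corrected
#' across the four tests.
#'
#' @param table data frame with columns `mgn_ac`, `mgn_vc`, `lgn_ac`,
#'   `lgn_vc`, one row per participant.
#' @return data frame with one row per contrast: mean difference, t, df,
#'   one-tailed p, and BH-adjusted p.
#' @export
selectivity_contrasts <- function(table) {
  if (nrow(table) < 2L) stopf("need at least 2 participants for group tests")
  defs <- list(
    mgn_ac_gt_mgn_vc = table$mgn_ac - table$mgn_vc,
    mgn_ac_gt_lgn_ac = table$mgn_ac - table$lgn_ac,
    lgn_vc_gt_lgn_ac = table$lgn_vc - table$lgn_ac,
    lgn_vc_gt_mgn_vc = table$lgn_vc - table$mgn_vc
  )
  rows <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
      stopf("zero variance in contrast %s", nm)
    }
    tt <- stats::t.test(d, alternative = "greater")
    data.frame(contrast = nm, mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Benchmark the localizer fROIs against alternative ROI sets
#'
#' Within-participant differences (primary minus alternative) of MGN-AC and
#' LGN-VC connectivity for every alternative source, with two-tailed
#' one-sample t-tests.
#'
#' @param tables named list of participant tables (as in
#'   [selectivity_contrasts()]), each with a `participant` column; the
#'   first entry (or `primary`) is the localizer-derived set.
#' @param primary name of the primary source (default first element).
#' @return data frame: source, pair, mean difference, t, df, p.
#' @export
benchmark_roi_sets <- function(tables, primary = names(tables)[1]) {
  stopifnot(primary %in% names(tables))
  prim <- tables[[primary]]
  out <- list()
  for (src in setdiff(names(tables), primary)) {
    alt <- tables[[src]]
    if (!identical(sort(prim$participant), sort(alt$participant))) {
      stopf("participant mismatch between '%s' and '%s'", primary, src)
    }
    alt <- alt[match(prim$participant, alt$participant), ]
    for (pair in c("mgn_ac", "lgn_vc")) {
      d <- prim[[pair]] - alt[[pair]]
      if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
        out[[length(out) + 1L]] <- data.frame(
          source = src, pair = pair, mean_diff = mean(d),
          t = NA_real_, df = length(d) - 1, p = NA_real_)
      } else {
        tt <- stats::t.test(d)
        out[[length(out) + 1L]] <- data.frame(
          source = src, pair = pair, mean_diff = mean(d),
          t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
      }
    }
  }
  do.call(rbind, out)
}

#' Whole-brain seed connectivity map
#'
#' Per-voxel partial correlation with each hemisphere's seed series on
#' smoothed, post-processed rest data; run-level maps are averaged over
#' runs, then the left- and right-seed maps are averaged.
#'
#' @param rest_runs list of smoothed rest [bold_series()].
#' @param seed_mask_L,seed_mask_R logical seed masks.
#' @param labels a [labeled_volume()].
#' @param motion list of per-run motion tables.
#' @param censor list of per-run `censor_mask` or NULL.
#' @param config an [rsfc_config()].
#' @return 3D array (NA outside the brain mask).
#' @export
seed_map <- function(rest_runs, seed_mask_L, seed_mask_R, labels, motion,
                     censor = NULL, config = rsfc_config()) {
  brain <- label_mask(labels, "brain")
  bidx <- which(brain)
  acc <- 0
  for (r in seq_along(rest_runs)) {
    bold <- mode1000(rest_runs[[r]], brain, config$mode_target)
    keep <- if (is.null(censor)) rep(TRUE, n_volumes(bold)) else censor[[r]]$keep
    wm <- compartment_signal(bold, labels, "white_matter")
    csf <- compartment_signal(bold, labels, "csf")
    sL <- mask_mean_series(bold, seed_mask_L)
    sR <- mask_mean_series(bold, seed_mask_R)
    Y <- t(bold_submatrix(bold, bidx))
    pp <- postprocess_series(cbind(sL, sR, wm, csf), keep, bold$tr_s, config)
    ppY <- postprocess_series(Y, keep, bold$tr_s, config)
    ret <- pp$retained
    N <- rsfc_nuisance(motion[[r]], pp$series[, "wm"], pp$series[, "csf"],
                       bold$tr_s, config)
    qrN <- qr(cbind(1, N[ret, , drop = FALSE]))
    rY <- qr.resid(qrN, ppY$series[ret, , drop = FALSE])
    ssY <- sqrt(colSums(rY^2))
    run_map <- 0
    for (s in c("sL", "sR")) {
      rs <- qr.resid(qrN, pp$series[ret, s])
      r_v <- drop(crossprod(rY, rs)) / (ssY * sqrt(sum(rs^2)))
      run_map <- run_map + r_v / 2
    }
    acc <- acc + run_map / length(rest_runs)
  }
  out <- array(NA_real_, dim(brain))
  out[bidx] <- acc
  out
}
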