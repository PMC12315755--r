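# Resting-state volume censoring: LPF-FD motion censoring with a study-wide
# threshold, run-wise GEV-DV signal-fluctuation censoring, eye-closure
# censoring, and contiguity/run/participant retention rules.

#' Censoring configuration
#'
#' Defaults are the study-wide values produced by multiband censoring
#' optimization: LPF-FD threshold 0.07587 mm and GEV-DV multiplier 3.105
#' (arbitrary units).  The motion-parameter low-pass cutoff and the GEV
#' threshold functional form (location + d_g * scale) are this package's
#' documented choices and are configurable.
#'
#' @param phi_f_mm LPF-FD censoring threshold in mm.
#' @param d_g GEV-DV multiplier (dimensionless).
#' @param mp_lpf_cutoff_hz low-pass cutoff applied to motion parameters and
#'   voxel series before differencing (default 0.2 Hz).
#' @param rot_radius_mm radius converting rotations to arc-length
#'   displacement (default 50 mm).
#' @param eye_close_min_s minimum eye-closure duration that censors (3 s;
#'   strictly longer closures censor).
#' @param eye_gap_max_s closures closer together than this censor the
#'   intervening volumes (30 s).
#' @param min_segment_s contiguous kept segments shorter than this are
#'   discarded (8 s; a segment of exactly 8 s is kept).
#' @param min_run_s minimum retained data per run (90 s).
#' @param min_participant_s minimum total retained data (300 s).
#' @param min_runs minimum valid runs per participant (2).
#' @return an object of class `censor_config`.
#' @export
censor_config <- function(phi_f_mm = 0.07587, d_g = 3.105,
                          mp_lpf_cutoff_hz = 0.2, rot_radius_mm = 50,
                          eye_close_min_s = 3, eye_gap_max_s = 30,
                          min_segment_s = 8, min_run_s = 90,
                          min_participant_s = 300, min_runs = 2L) {
  cfg <- list(phi_f_mm = phi_f_mm, d_g = d_g,
              mp_lpf_cutoff_hz = mp_lpf_cutoff_hz,
              rot_radius_mm = rot_radius_mm,
              eye_close_min_s = eye_close_min_s,
              eye_gap_max_s = eye_gap_max_s,
              min_segment_s = min_segment_s, min_run_s = min_run_s,
              min_participant_s = min_participant_s,
              min_runs = as.integer(min_runs))
  if (any(unlist(cfg[c("phi_f_mm", "d_g", "mp_lpf_cutoff_hz", "rot_radius_mm",
                       "eye_close_min_s", "eye_gap_max_s", "min_segment_s",
                       "min_run_s", "min_participant_s")]) <= 0)) {
    stopf("censoring thresholds must be positive")
  }
  structure(cfg, class = "censor_config")
}

#' Low-pass-filtered framewise displacement
#'
#' Each of the six motion parameters is low-pass filtered (zero-phase
#' order-2 Butterworth at `mp_lpf_cutoff_hz`; skipped with a warning when
#' the cutoff reaches Nyquist), rotations are converted to arc length at
#' `rot_radius_mm`, and FD is the sum of absolute backward differences of
#' the six traces, with the first volume set to 0.
#'
#' @param motion matrix or data frame with 6 columns (translations in mm,
#'   rotations in radians), one row per volume.
#' @param tr_s repetition time in seconds.
#' @param config a [censor_config()].
#' @return numeric vector of per-volume displacement in mm.
#' @export
lpf_fd <- function(motion, tr_s, config = censor_config()) {
  M <- as.matrix(motion)
  if (ncol(M) != 6L) stopf("motion table must have 6 columns")
  if (nrow(M) < 8L) stopf("need at least 8 volumes for LPF-FD")
  fs <- 1 / tr_s
  if (config$mp_lpf_cutoff_hz >= fs / 2) {
    warnf("motion low-pass cutoff >= Nyquist; skipping filtering")
  } else {
    M <- lowpass_filtfilt(M, config$mp_lpf_cutoff_hz, fs)
  }
  M[, 4:6] <- M[, 4:6] * config$rot_radius_mm
  fd <- rowSums(abs(apply(M, 2, backdiff)))
  fd[1] <- 0
  fd
}

#' Run-wise GEV-DV threshold and per-volume DV
#'
#' DV is the root-mean-square over brain voxels of the backward temporal
#' difference of low-pass-filtered voxel series (first volume 0).  A
#' generalized extreme value distribution is fit to the run's DV values by
#' maximum likelihood; the censoring threshold is `location + d_g * scale`.
#' On fit failure the threshold falls back to `median + d_g * IQR` with a
#' warning.
#'
#' @param bold an unsmoothed, normalized rest [bold_series()].
#' @param brain_mask logical 3D array of in-brain voxels.
#' @param config a [censor_config()].
#' @param max_voxels cap on the number of brain voxels entering the RMS
#'   (default 10000); above it a deterministic stride subsample is used.
#'   The RMS over several thousand voxels estimates the brain-wide value to
#'   well under a percent, at a fraction of the filtering cost.
#' @return list with `dv` (per-volume), `threshold`, `censored` (logical),
#'   and the fitted `gev` parameters (or NULL on fallback).
#' @export
gev_dv_threshold <- function(bold, brain_mask, config = censor_config(),
                             max_voxels = 10000L) {
  nt <- n_volumes(bold)
  if (nt < 30L) stopf("need at least 30 volumes for a stable GEV fit")
  idx <- which(brain_mask)
  if (length(idx) > max_voxels) {
    idx <- idx[seq(1L, length(idx), length.out = max_voxels)]
  }
  Xw <- bold_submatrix(bold, idx)                    # voxels x time
  fs <- 1 / bold$tr_s
  if (config$mp_lpf_cutoff_hz < fs / 2) {
    Xw <- filtfilt_wide(butter_design(2L, config$mp_lpf_cutoff_hz, fs, "low")$b,
                        butter_design(2L, config$mp_lpf_cutoff_hz, fs, "low")$a,
                        Xw)
  }
  D <- Xw[, -1L, drop = FALSE] - Xw[, -nt, drop = FALSE]
  dv <- c(0, sqrt(colMeans(D^2)))
  fit <- fit_gev(dv[-1])
  if (is.null(fit)) {
    warnf("GEV fit failed; falling back to median + d_g * IQR")
    thr <- stats::median(dv[-1]) + config$d_g * stats::IQR(dv[-1])
  } else {
    thr <- fit$loc + config$d_g * fit$scale
  }
  list(dv = dv, threshold = thr, censored = dv > thr, gev = fit)
}

# Maximum-likelihood GEV fit (location/scale/shape); returns NULL on failure.
fit_gev <- function(x) {
  if (stats::sd(x) == 0) return(NULL)
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); xi <- par[3]
    z <- (x - mu) / sigma
    if (abs(xi) < 1e-8) {
      sum(log(sigma) + z + exp(-z))
    } else {
      t1 <- 1 + xi * z
      if (any(t1 <= 0)) return(1e10)
      sum(log(sigma) + (1 + 1 / xi) * log(t1) + t1^(-1 / xi))
    }
  }
  # moment-flavored start: Gumbel approximation
  s0 <- sqrt(6) * stats::sd(x) / pi
  m0 <- mean(x) - 0.5772 * s0
  opt <- try(stats::optim(c(m0, log(s0), 0.1), nll, method = "Nelder-Mead",
                          control = list(maxit = 2000)), silent = TRUE)
  if (inherits(opt, "try-error") || opt$value >= 1e9) return(NULL)
  list(loc = opt$par[1], scale = exp(opt$par[2]), shape = opt$par[3])
}

# Merge possibly-overlapping intervals given as a 2-column matrix.
merge_intervals <- function(onset, end) {
  o <- order(onset)
  onset <- onset[o]; end <- end[o]
  mo <- onset[1]; me <- end[1]
  outs <- list()
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= me) me <- max(me, end[i]) else {
      outs[[length(outs) + 1L]] <- c(mo, me); mo <- onset[i]; me <- end[i]
    }
  }
  outs[[length(outs) + 1L]] <- c(mo, me)
  do.call(rbind, outs)
}

#' Eye-closure censoring
#'
#' Censors volumes acquired during eye closures lasting strictly longer
#' than 3 seconds, and volumes acquired between two such closures whose
#' gap (end of one to start of the next) is under 30 seconds.
#'
#' @param closures data frame with columns `onset` and `duration` (s).
#' @param timestamps_s per-volume acquisition times.
#' @param config a [censor_config()].
#' @return logical vector, TRUE where censored.
#' @export
eye_closure_censor <- function(closures, timestamps_s, config = censor_config()) {
  nt <- length(timestamps_s)
  cens <- rep(FALSE, nt)
  if (is.null(closures) || nrow(closures) == 0L) return(cens)
  iv <- merge_intervals(closures$onset, closures$onset + closures$duration)
  long <- iv[iv[, 2] - iv[, 1] > config$eye_close_min_s, , drop = FALSE]
  if (nrow(long) == 0L) return(cens)
  for (i in seq_len(nrow(long))) {
    cens <- cens | (timestamps_s >= long[i, 1] & timestamps_s <= long[i, 2])
  }
  if (nrow(long) > 1L) {
    for (i in seq_len(nrow(long) - 1L)) {
      gap <- long[i + 1L, 1] - long[i, 2]
      if (gap < config$eye_gap_max_s) {
        cens <- cens | (timestamps_s > long[i, 2] & timestamps_s < long[i + 1L, 1])
      }
    }
  }
  cens
}

#' Combine censoring sources and apply contiguity rules for one run
#'
#' Final keep = not (motion | dv | eyes); contiguous kept segments shorter
#' than `min_segment_s` are then discarded (reason `contiguity`).
#'
#' @param motion_censored,dv_censored,eye_censored logical vectors (any may
#'   be NULL).
#' @param tr_s repetition time in seconds.
#' @param config a [censor_config()].
#' @return an object of class `censor_mask`: `keep` (logical), `reasons`
#'   (list of character vectors), `retained_s`, `retained_vols`.
#' @export
censor_mask <- function(motion_censored = NULL, dv_censored = NULL,
                        eye_censored = NULL, tr_s, config = censor_config()) {
  srcs <- Filter(Negate(is.null),
                 list(motion = motion_censored, dv = dv_censored,
                      eyes = eye_censored))
  if (!length(srcs)) stopf("at least one censoring source is required")
  nt <- unique(vapply(srcs, length, integer(1)))
  if (length(nt) != 1L) stopf("censoring sources disagree in length")
  reasons <- replicate(nt, character(0), simplify = FALSE)
  for (nm in names(srcs)) {
    for (t in which(srcs[[nm]])) reasons[[t]] <- c(reasons[[t]], nm)
  }
  keep <- !Reduce(`|`, srcs)
  r <- rle(keep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] * tr_s < config$min_segment_s) {
      keep[starts[i]:ends[i]] <- FALSE
      for (t in starts[i]:ends[i]) reasons[[t]] <- c(reasons[[t]], "contiguity")
    }
  }
  structure(list(keep = keep, reasons = reasons,
                 retained_s = sum(keep) * tr_s, retained_vols = sum(keep)),
            class = "censor_mask")
}

#' Run and participant retention rules
#'
#' A run is valid when its retained duration is at least `min_run_s`
#' (90 s); a participant is valid with at least `min_runs` valid runs (2)
#' and at least `min_participant_s` (300 s) retained across valid runs.
#'
#' @param masks list of `censor_mask` objects, one per run.
#' @param tr_s repetition time in seconds.
#' @param config a [censor_config()].
#' @return list with `run_valid` (logical vector), `run_retained_s`,
#'   `participant_valid`, `total_retained_s`.
#' @export
retention_rules <- function(masks, tr_s, config = censor_config()) {
  run_s <- vapply(masks, function(m) sum(m$keep) * tr_s, numeric(1))
  run_valid <- run_s >= config$min_run_s
  total <- sum(run_s[run_valid])
  list(run_valid = run_valid, run_retained_s = run_s,
       participant_valid = sum(run_valid) >= config$min_runs &&
         total >= config$min_participant_s,
       total_retained_s = total)
}

#' Full censoring of one rest run
#'
#' @param bold unsmoothed, mode-1000 normalized rest [bold_series()].
#' @param motion 6-column motion table for the run.
#' @param closures eye-closure table (`onset`, `duration`) or NULL.
#' @param brain_mask logical 3D in-brain mask.
#' @param config a [censor_config()].
#' @return a `censor_mask` with attributes `fd`, `dv`, `dv_threshold`.
#' @export
censor_run <- function(bold, motion, closures, brain_mask,
                       config = censor_config()) {
  fd <- lpf_fd(motion, bold$tr_s, config)
  mot <- fd > config$phi_f_mm
  gd <- gev_dv_threshold(bold, brain_mask, config)
  eye <- eye_closure_censor(closures, bold$timestamps_s, config)
  cm <- censor_mask(mot, gd$censored, eye, tr_s = bold$tr_s, config = config)
  attr(cm, "fd") <- fd
  attr(cm, "dv") <- gd$dv
  attr(cm, "dv_threshold") <- gd$threshold
  cm
}
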