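# Synthetic phantom: labeled anatomy with implanted MGN/LGN/AC/VC signal
# sources, clustered-sparse task BOLD with condition-locked amplitudes and
# per-cluster T1-relaxation offsets, band-limited resting-state BOLD with
# seeded thalamocortical coupling, nuisance compartment signals, motion
# traces with injected spikes, and eye-closure logs.
#
# The phantom is a stated world, not a tuning surface: its defaults encode
# the acquisition the method targets (2 mm grid, TR 0.85 s, 4 task + 4 rest
# runs of the documented durations) plus explicit choices for quantities no
# acquisition protocol fixes (amplitudes, noise levels), documented in the
# methods vignette.

#' Phantom configuration
#'
#' @param grid simulation grid (default 40 x 48 x 36 voxels of 2 mm).
#' @param site a [site_config()] (default NYSPI preset, TR 0.85 s).
#' @param truth_mgn_vox,truth_lgn_vox implanted nucleus sizes per
#'   hemisphere (default 20 and 30 voxels).
#' @param task_amplitude_pct percent signal change of condition-locked
#'   responses (default 2).
#' @param t1_offsets additive per-cluster-volume offsets as fractions of
#'   baseline for volumes 1..n_cluster (default 0.05, 0.02, 0): the imprint
#'   of incomplete T1 recovery on the first volumes of each sparse cluster.
#' @param noise_sd task white-noise SD in baseline units (default 10, i.e.
#'   temporal SNR 100 at baseline 1000).
#' @param rest_coupling_r target correlation between geniculate and matching
#'   cortical resting signals (default 0.4).
#' @param rest_fluct_amp SD of the structured resting fluctuation in
#'   baseline units (default 10).
#' @param rest_noise_sd resting white-noise SD per voxel (default 5).
#' @param confound_amp global-signal mixing amplitude (default 3);
#'   `wm_csf_amp` is the compartment-specific amplitude (default 4).
#' @param wm_csf_amp see `confound_amp`.
#' @param drift_amp amplitude of the shared slow scanner drift in task
#'   runs, as a fraction of baseline (default 0.003).
#' @param n_task_runs,n_rest_runs run counts (default 4 and 4).
#' @param motion_spike_rate injected motion spikes per minute (default 2).
#' @param motion_spike_mm spike displacement in mm (default 0.5, safely
#'   above the 0.07587 mm LPF-FD threshold after low-pass filtering).
#' @param eye_closure_rate eye closures per minute during rest (default 0.4).
#' @param seed_jitter_vox offset (voxels, posterior) of the segmentation
#'   seed labels from the implanted nuclei, emulating segmentation-prior
#'   error (default 1; 0 makes seeds equal truth).
#' @param baseline tissue baseline intensity (default 1000 so mode-1000
#'   normalization is near-identity).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid = volume_grid(c(40, 48, 36)),
                           site = site_config("nyspi"),
                           truth_mgn_vox = 20L, truth_lgn_vox = 30L,
                           task_amplitude_pct = 2,
                           t1_offsets = c(0.05, 0.02, 0),
                           noise_sd = 10,
                           rest_coupling_r = 0.4,
                           rest_fluct_amp = 10,
                           rest_noise_sd = 5,
                           confound_amp = 3,
                           wm_csf_amp = 4,
                           drift_amp = 0.003,
                           n_task_runs = 4L, n_rest_runs = 4L,
                           motion_spike_rate = 2,
                           motion_spike_mm = 0.5,
                           eye_closure_rate = 0.4,
                           seed_jitter_vox = 1L,
                           baseline = 1000) {
  if (rest_coupling_r < 0 || rest_coupling_r >= 1) {
    stopf("rest coupling must satisfy 0 <= r < 1")
  }
  if (task_amplitude_pct < 0) stopf("task amplitude must be non-negative")
  if (length(t1_offsets) != site$n_cluster_vols) {
    stopf("t1_offsets must have one entry per cluster volume")
  }
  structure(list(
    grid = grid, site = site,
    truth_mgn_vox = as.integer(truth_mgn_vox),
    truth_lgn_vox = as.integer(truth_lgn_vox),
    task_amplitude_pct = task_amplitude_pct, t1_offsets = t1_offsets,
    noise_sd = noise_sd, rest_coupling_r = rest_coupling_r,
    rest_fluct_amp = rest_fluct_amp, rest_noise_sd = rest_noise_sd,
    confound_amp = confound_amp, wm_csf_amp = wm_csf_amp,
    drift_amp = drift_amp,
    n_task_runs = as.integer(n_task_runs),
    n_rest_runs = as.integer(n_rest_runs),
    motion_spike_rate = motion_spike_rate,
    motion_spike_mm = motion_spike_mm,
    eye_closure_rate = eye_closure_rate,
    seed_jitter_vox = as.integer(seed_jitter_vox),
    baseline = baseline
  ), class = "phantom_config")
}

# Left-hemisphere structure centers (1-based voxel coords on the default
# grid, scaled for other grids); right hemisphere mirrors x.
phantom_geometry <- function(shape) {
  sc <- shape / c(40, 48, 36)
  at <- function(x, y, z) c(x, y, z) * sc
  list(
    truth_mgn = at(14, 20, 14),
    truth_lgn = at(10, 21, 17),     # superior and lateral to the MGN
    pulvinar = at(13, 27, 21),      # superior/posterior... anterior of geniculi
    mediodorsal = at(16, 32, 21),
    putamen = at(5, 25, 14),
    pallidum = at(8, 29, 12),
    hippocampus = at(10, 12, 10),
    parahippocampal_wm = at(16, 11, 8),
    insular_wm = at(7, 34, 20),
    choroid_plexus = at(19, 28, 24)
  )
}

mirror_x <- function(center, shape) c(shape[1] + 1 - center[1], center[2:3])

#' Generate phantom anatomy
#'
#' Builds the labeled segmentation volume (all [REQUIRED_LABELS]) and the
#' ground-truth implanted nuclei.  The truth LGN is superior and lateral to
#' the truth MGN in each hemisphere, so default geometry raises no
#' plausibility flag.  Segmentation-style seed labels are the truth masks
#' shifted `seed_jitter_vox` voxels posterior, emulating prior error while
#' keeping the target inside the dilated, posterior-trimmed search region.
#'
#' @param config a [phantom_config()].
#' @return list with `labels` (a [labeled_volume()]) and `truth` (a
#'   `froi_set` of the implanted nuclei).
#' @export
generate_anatomy <- function(config = phantom_config()) {
  shape <- config$grid$shape
  geo <- phantom_geometry(shape)
  jit <- c(0, -config$seed_jitter_vox, 0)   # posterior offset
  lab <- array(0L, shape)
  codes <- integer(0)
  next_code <- 0L
  paint <- function(name, mask, allow_overlap = FALSE) {
    next_code <<- next_code + 1L
    codes[name] <<- next_code
    if (!allow_overlap && any(lab[mask] != 0L)) {
      stopf("phantom structures collide at label '%s'", name)
    }
    sel <- mask & (lab == 0L)
    if (!any(sel)) stopf("phantom label '%s' is empty after painting", name)
    lab[sel] <<- next_code
    invisible(NULL)
  }
  ball_pair <- function(center, n) {
    list(L = ball_mask(shape, center, n),
         R = ball_mask(shape, mirror_x(center, shape), n))
  }
  truth_mgn <- ball_pair(geo$truth_mgn, config$truth_mgn_vox)
  truth_lgn <- ball_pair(geo$truth_lgn, config$truth_lgn_vox)
  # segmentation-style seeds: truth shifted posterior by the jitter
  seed_mgn <- ball_pair(geo$truth_mgn + jit, config$truth_mgn_vox)
  seed_lgn <- ball_pair(geo$truth_lgn + jit, config$truth_lgn_vox)
  paint("mgn_seed_L", seed_mgn$L); paint("mgn_seed_R", seed_mgn$R)
  paint("lgn_seed_L", seed_lgn$L); paint("lgn_seed_R", seed_lgn$R)
  pulv <- ball_pair(geo$pulvinar, 50L)
  paint("pulvinar_L", pulv$L); paint("pulvinar_R", pulv$R)
  md <- ball_pair(geo$mediodorsal, 40L)
  paint("mediodorsal_L", md$L); paint("mediodorsal_R", md$R)
  bilat <- function(center, n) {
    ball_mask(shape, center, n) | ball_mask(shape, mirror_x(center, shape), n)
  }
  paint("putamen", bilat(geo$putamen, 40L))
  paint("pallidum", bilat(geo$pallidum, 40L))
  paint("hippocampus", bilat(geo$hippocampus, 40L))
  paint("parahippocampal_wm", bilat(geo$parahippocampal_wm, 30L))
  paint("insular_wm", bilat(geo$insular_wm, 30L))
  paint("choroid_plexus", bilat(geo$choroid_plexus, 25L))
  # cortical parcels (boxes; L blocks mirrored to R)
  sc <- shape / c(40, 48, 36)
  bx <- function(xr, yr, zr) {
    box_mask(shape, round(xr[1] * sc[1]):round(xr[2] * sc[1]),
             round(yr[1] * sc[2]):round(yr[2] * sc[2]),
             round(zr[1] * sc[3]):round(zr[2] * sc[3]))
  }
  mirror_box <- function(m) m[rev(seq_len(shape[1])), , , drop = FALSE]
  ba41_L <- bx(c(3, 7), c(14, 22), c(12, 18))
  ba17_L <- bx(c(12, 19), c(3, 8), c(14, 22))
  tt_L <- bx(c(3, 5), c(26, 30), c(17, 19))
  pc_L <- bx(c(14, 17), c(9, 11), c(15, 19))
  paint("ba41_42_L", ba41_L); paint("ba41_42_R", mirror_box(ba41_L))
  paint("ba17_18_L", ba17_L); paint("ba17_18_R", mirror_box(ba17_L))
  paint("transverse_temporal_L", tt_L)
  paint("transverse_temporal_R", mirror_box(tt_L))
  paint("pericalcarine_L", pc_L); paint("pericalcarine_R", mirror_box(pc_L))
  # cerebrum envelope: ellipsoid around everything painted so far
  center <- (shape + 1) / 2
  radii <- shape * c(0.44, 0.46, 0.43)
  ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
  e <- outer(outer(((ax - center[1]) / radii[1])^2,
                   ((ay - center[2]) / radii[2])^2, `+`),
             ((az - center[3]) / radii[3])^2, `+`) <= 1
  envelope <- e | dilate_mask(lab != 0L, 1L, 26L)
  # cortical ribbon: outer shell of the envelope not already labeled
  shell <- envelope & !erode_mask(envelope, 2L, 6L)
  paint("cortical_gm", shell & lab == 0L, allow_overlap = TRUE)
  paint("csf", bx(c(19, 23), c(30, 36), c(20, 26)) & lab == 0L,
        allow_overlap = TRUE)
  # deep white matter: interior envelope at least 2 voxels clear of any
  # structure, so compartment erosion has room
  interior <- erode_mask(envelope, 2L, 6L)
  wm <- interior & lab == 0L & !dilate_mask(lab != 0L, 1L, 26L)
  paint("white_matter", wm, allow_overlap = TRUE)
  paint("brain", envelope & lab == 0L, allow_overlap = TRUE)
  labels <- labeled_volume(config$grid, lab, codes)
  truth <- froi_set(truth_mgn$L, truth_mgn$R, truth_lgn$L, truth_lgn$R)
  excl <- exclusion_union(labels)
  truth_all <- truth$mgn_L | truth$mgn_R | truth$lgn_L | truth$lgn_R
  if (any(excl & truth_all)) {
    stopf("phantom structures collide: exclusion union intersects truth nuclei")
  }
  list(labels = labels, truth = truth)
}

#' Construct an fROI set
#'
#' @param mgn_L,mgn_R,lgn_L,lgn_R logical 3D masks.
#' @param flags optional QC flags.
#' @return an object of class `froi_set` with per-mask `sizes`.
#' @export
froi_set <- function(mgn_L, mgn_R, lgn_L, lgn_R, flags = character(0)) {
  out <- list(mgn_L = mgn_L, mgn_R = mgn_R, lgn_L = lgn_L, lgn_R = lgn_R)
  out$sizes <- vapply(out[1:4], sum, numeric(1))
  out$qc_flags <- flags
  class(out) <- "froi_set"
  out
}

#' @export
print.froi_set <- function(x, ...) {
  cat(sprintf("<froi_set> sizes: %s; flags: %s\n",
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
              if (length(x$qc_flags)) paste(x$qc_flags, collapse = ",") else "none"))
  invisible(x)
}

# Structured-signal masks used by both task and rest generators.
phantom_signal_masks <- function(labels, truth) {
  list(
    auditory_ctx = label_mask_union(labels, c("ba41_42_L", "ba41_42_R",
                                              "transverse_temporal_L",
                                              "transverse_temporal_R")),
    visual_ctx = label_mask_union(labels, c("ba17_18_L", "ba17_18_R",
                                            "pericalcarine_L",
                                            "pericalcarine_R")),
    mgn = truth$mgn_L | truth$mgn_R,
    lgn = truth$lgn_L | truth$lgn_R
  )
}

#' Generate one clustered-sparse task run
#'
#' Only the acquisition-cluster volumes are synthesized (acquisition is
#' sparse).  Voxel value = baseline * (1 + a * c(t) + t1_offset(pos)) +
#' drift + noise, where `a` is the task amplitude for structures matching
#' the trial condition (truth MGN and auditory cortex for auditory trials;
#' truth LGN and visual cortex for visual trials), `c(t)` indicates the
#' cluster following that trial, and `t1_offset` depends only on the
#' within-cluster position.
#'
#' @param labels,truth anatomy from [generate_anatomy()].
#' @param schedule a [trial_schedule()].
#' @param config a [phantom_config()].
#' @param seed RNG seed for noise and drift.
#' @return a task-sparse [bold_series()].
#' @export
generate_task_run <- function(labels, truth, schedule,
                              config = phantom_config(), seed = 1L) {
  shape <- config$grid$shape
  nvox <- prod(shape)
  info <- schedule_volume_info(schedule)
  nvol <- nrow(info)
  brain <- which(label_mask(labels, "brain"))
  sm <- phantom_signal_masks(labels, truth)
  aud <- which(sm$auditory_ctx | sm$mgn)
  vis <- which(sm$visual_ctx | sm$lgn)
  a <- config$task_amplitude_pct / 100
  b <- config$baseline
  M <- matrix(0, nvox, nvol)
  with_seed(seed, {
    drift <- b * config$drift_amp *
      sin(2 * pi * 0.004 * schedule_timestamps(schedule) +
            stats::runif(1, 0, 2 * pi))
    for (t in seq_len(nvol)) {
      col <- numeric(nvox)
      col[brain] <- b * (1 + config$t1_offsets[info$cluster_pos[t]]) + drift[t]
      if (info$trial_type[t] == "auditory") col[aud] <- col[aud] + b * a
      if (info$trial_type[t] == "visual") col[vis] <- col[vis] + b * a
      if (config$noise_sd > 0) {
        col[brain] <- col[brain] + stats::rnorm(length(brain), 0, config$noise_sd)
      }
      M[, t] <- col
    }
  })
  dim(M) <- c(shape, nvol)
  bold_series(config$grid, M, tr_s = config$site$tr_s,
              timestamps_s = schedule_timestamps(schedule),
              kind = "task-sparse", site = config$site)
}

# A unit-variance latent source band-limited to the resting analysis band.
band_limited_source <- function(nt, tr_s, band_hz = c(0.009, 0.08)) {
  x <- stats::rnorm(nt + 200L)
  y <- bandpass_filtfilt(x, band_hz, 1 / tr_s)
  y <- y[101:(100 + nt)]
  y / stats::sd(y)
}

#' Generate one continuous resting-state run
#'
#' Each structure fluctuates with a band-limited (0.009-0.08 Hz) latent
#' source.  Truth MGN voxels share the auditory-cortex source at
#' correlation `rest_coupling_r` (truth LGN the visual-cortex source); the
#' crossed couplings are zero by construction.  A global source is mixed
#' into all brain voxels and compartment-specific sources into WM and CSF,
#' with white noise on top.
#'
#' @inheritParams generate_task_run
#' @param storage `"array"` for full 4D storage (zeros outside the brain),
#'   or `"flat"` for masked-matrix storage (brain voxels by time), which is
#'   substantially cheaper and equivalent for every mask-based analysis.
#' @return a rest-continuous [bold_series()].
#' @export
generate_rest_run <- function(labels, truth, config = phantom_config(),
                              seed = 1L, storage = c("array", "flat")) {
  storage <- match.arg(storage)
  shape <- config$grid$shape
  nvox <- prod(shape)
  tr <- config$site$tr_s
  nt <- as.integer(floor(config$site$rest_run_dur_s / tr))
  brain <- which(label_mask(labels, "brain"))
  sm <- phantom_signal_masks(labels, truth)
  r <- config$rest_coupling_r
  amp <- config$rest_fluct_amp
  nb <- length(brain)
  with_seed(seed, {
    s_ac <- band_limited_source(nt, tr)
    s_vc <- band_limited_source(nt, tr)
    s_mgn <- band_limited_source(nt, tr)
    s_lgn <- band_limited_source(nt, tr)
    g <- band_limited_source(nt, tr)
    s_wm <- band_limited_source(nt, tr)
    s_csf <- band_limited_source(nt, tr)
    B <- matrix(stats::rnorm(nb * nt, 0, config$rest_noise_sd), nb, nt)
    B <- B + config$baseline + rep(config$confound_amp * g, each = nb)
    sources <- list(
      list(mask = sm$auditory_ctx, src = amp * s_ac),
      list(mask = sm$visual_ctx, src = amp * s_vc),
      list(mask = sm$mgn, src = amp * (r * s_ac + sqrt(1 - r^2) * s_mgn)),
      list(mask = sm$lgn, src = amp * (r * s_vc + sqrt(1 - r^2) * s_lgn)),
      list(mask = label_mask(labels, "white_matter"),
           src = config$wm_csf_amp * s_wm),
      list(mask = label_mask(labels, "csf"), src = config$wm_csf_amp * s_csf)
    )
    for (sdef in sources) {
      rows <- match(which(sdef$mask), brain)
      rows <- rows[!is.na(rows)]
      if (length(rows)) {
        B[rows, ] <- B[rows, ] + rep(sdef$src, each = length(rows))
      }
    }
    B
  })
  if (storage == "flat") {
    attr(B, "mask_idx") <- brain
    return(bold_series(config$grid, B, tr_s = tr, kind = "rest-continuous",
                       site = config$site))
  }
  M <- matrix(0, nvox, nt)
  M[brain, ] <- B
  dim(M) <- c(shape, nt)
  bold_series(config$grid, M, tr_s = tr, kind = "rest-continuous",
              site = config$site)
}

#' Generate a motion-parameter table with injected spikes
#'
#' Smooth low-amplitude sinusoidal drift in all six parameters plus
#' Poisson-placed single-volume displacement spikes in a random translation
#' parameter.  Spike magnitude defaults to 0.5 mm so low-pass-filtered
#' framewise displacement exceeds the default censoring threshold only at
#' spike neighborhoods.
#'
#' @param n_vols number of volumes.
#' @param tr_s repetition time in seconds.
#' @param config a [phantom_config()].
#' @param seed RNG seed.
#' @param spikes logical: inject spikes (default TRUE for rest runs).
#' @param drift_mm translation drift amplitude in mm (rotation drift is
#'   `drift_mm / 50` radians); 0 gives all-zero baseline motion.
#' @return list with `motion` (n x 6 data frame; translations mm, rotations
#'   radians) and `spike_volumes` (integer vector).
#' @export
generate_motion <- function(n_vols, tr_s, config = phantom_config(),
                            seed = 1L, spikes = TRUE, drift_mm = 0.01) {
  with_seed(seed, {
    tt <- (seq_len(n_vols) - 1) * tr_s
    M <- sapply(1:6, function(j) {
      a <- if (j <= 3) drift_mm else drift_mm / 50   # mm / radians
      f <- stats::runif(1, 0.005, 0.02)
      # slow drift plus estimation jitter (keeps the 6 traces and their
      # squares linearly independent, as real realignment output is)
      a * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n_vols, 0, a / 5)
    })
    spike_vols <- integer(0)
    if (spikes && config$motion_spike_rate > 0) {
      n_spikes <- stats::rpois(1, config$motion_spike_rate * n_vols * tr_s / 60)
      if (n_spikes > 0) {
        cand <- sample(seq(10L, n_vols - 10L), min(n_spikes, 20L))
        cand <- sort(cand)
        keep <- c(TRUE, diff(cand) >= 10L)
        spike_vols <- cand[keep]
        for (v in spike_vols) {
          j <- sample(1:3, 1)
          M[v, j] <- M[v, j] + config$motion_spike_mm * sample(c(-1, 1), 1)
        }
      }
    }
    colnames(M) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    list(motion = as.data.frame(M), spike_volumes = spike_vols)
  })
}

#' Generate an eye-closure log for one rest run
#'
#' Poisson-placed closure onsets (spaced at least 40 s apart) with
#' durations drawn from a mixture spanning the 3 s censoring boundary.
#'
#' @param run_dur_s run duration in seconds.
#' @param config a [phantom_config()].
#' @param seed RNG seed.
#' @return data frame with columns `onset`, `duration` (possibly 0 rows).
#' @export
generate_eye_closures <- function(run_dur_s, config = phantom_config(),
                                  seed = 1L) {
  with_seed(seed, {
    n <- stats::rpois(1, config$eye_closure_rate * run_dur_s / 60)
    if (n == 0) {
      return(data.frame(onset = numeric(0), duration = numeric(0)))
    }
    onsets <- sort(stats::runif(n, 30, run_dur_s - 30))
    keep <- c(TRUE, diff(onsets) >= 40)
    onsets <- onsets[keep]
    durs <- sample(c(1.5, 2, 4, 6), length(onsets), replace = TRUE)
    data.frame(onset = onsets, duration = durs)
  })
}

#' Generate a full phantom participant
#'
#' @param config a [phantom_config()].
#' @param seed master seed; all runs derive child seeds from it, so a
#'   participant is fully reproducible from `(config, seed)`.
#' @param include_rest generate resting-state runs (default TRUE; disable
#'   for task-only studies to save time and memory).
#' @param rest_storage storage mode for rest runs (see
#'   [generate_rest_run()]); `"flat"` is markedly faster for mask-based
#'   analyses.
#' @return list with `labels`, `truth`, `task` (list of per-run lists with
#'   `bold`, `schedule`, `motion`), `rest` (per-run `bold`, `motion`,
#'   `spike_volumes`, `closures`), and `config`.
#' @export
generate_phantom_subject <- function(config = phantom_config(), seed = 1L,
                                     include_rest = TRUE,
                                     rest_storage = c("array", "flat")) {
  rest_storage <- match.arg(rest_storage)
  anat <- generate_anatomy(config)
  task <- lapply(seq_len(config$n_task_runs), function(r) {
    sch <- build_run_schedule(config$site, seed = child_seed(seed, r))
    bold <- generate_task_run(anat$labels, anat$truth, sch, config,
                              seed = child_seed(seed, 100 + r))
    mot <- generate_motion(n_schedule_volumes(sch), config$site$tr_s, config,
                           seed = child_seed(seed, 200 + r), spikes = FALSE)
    list(bold = bold, schedule = sch, motion = mot$motion)
  })
  rest <- NULL
  if (include_rest) {
    rest <- lapply(seq_len(config$n_rest_runs), function(r) {
      bold <- generate_rest_run(anat$labels, anat$truth, config,
                                seed = child_seed(seed, 300 + r),
                                storage = rest_storage)
      mot <- generate_motion(n_volumes(bold), config$site$tr_s, config,
                             seed = child_seed(seed, 400 + r), spikes = TRUE)
      clo <- generate_eye_closures(config$site$rest_run_dur_s, config,
                                   seed = child_seed(seed, 500 + r))
      list(bold = bold, motion = mot$motion, spike_volumes = mot$spike_volumes,
           closures = clo)
    })
  }
  list(labels = anat$labels, truth = anat$truth, task = task, rest = rest,
       config = config, seed = seed)
}

#' Write a phantom participant as a BIDS-flavored directory
#'
#' `sub-XX/ses-01/anat` holds the label volume; `func` holds task/rest BOLD
#' NIfTI files with events, motion and eye-closure TSV sidecars and a JSON
#' site description.
#'
#' @param subject result of [generate_phantom_subject()].
#' @param out_dir output root.
#' @param sub_id subject identifier (default "01").
#' @return the subject directory, invisibly.
#' @export
write_phantom_bids <- function(subject, out_dir, sub_id = "01") {
  base <- file.path(out_dir, sprintf("sub-%s", sub_id), "ses-01")
  anat_dir <- file.path(base, "anat"); func_dir <- file.path(base, "func")
  dir.create(anat_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(func_dir, recursive = TRUE, showWarnings = FALSE)
  lv <- subject$labels
  write_nifti(array(as.numeric(lv$labels), dim(lv$labels)),
              file.path(anat_dir, sprintf("sub-%s_dseg.nii.gz", sub_id)),
              voxel_size_mm = lv$grid$voxel_size_mm, datatype = "int32")
  jsonlite::write_json(as.list(lv$label_map),
                       file.path(anat_dir, sprintf("sub-%s_dseg.json", sub_id)),
                       auto_unbox = TRUE)
  site <- subject$config$site
  jsonlite::write_json(unclass(site), file.path(base, "site.json"),
                       auto_unbox = TRUE)
  for (r in seq_along(subject$task)) {
    run <- subject$task[[r]]
    stem <- sprintf("sub-%s_task-localizer_run-%02d", sub_id, r)
    write_bold_nifti(run$bold, file.path(func_dir, paste0(stem, "_bold.nii.gz")))
    write_events_tsv(run$schedule, file.path(func_dir, paste0(stem, "_events.tsv")))
    utils::write.table(run$motion,
                       file.path(func_dir, paste0(stem, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (r in seq_along(subject$rest)) {
    run <- subject$rest[[r]]
    stem <- sprintf("sub-%s_task-rest_run-%02d", sub_id, r)
    write_bold_nifti(run$bold, file.path(func_dir, paste0(stem, "_bold.nii.gz")))
    utils::write.table(run$motion,
                       file.path(func_dir, paste0(stem, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$closures,
                       file.path(func_dir, paste0(stem, "_eyeclosure.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dirname(anat_dir))
}
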