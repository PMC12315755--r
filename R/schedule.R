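# Clustered-sparse task schedule: gap calibration, trial ordering, audio
# segment sequencing, and event-table I/O.
#
# Each run is one 12 s fixation trial followed by 16 stimulus trials
# (8 auditory, 8 visual) in a seeded pseudorandom order.  A trial is
# gap / stimulation / gap / acquisition cluster; the gap on each side is
# calibrated so the trial lasts exactly `trial_dur_s`.  Every trial,
# including fixation, is followed by one acquisition cluster, so a default
# run yields 17 clusters x 3 volumes = 51 sparse volumes.

#' Calibrate the per-side silent gap of a clustered-sparse trial
#'
#' Returns `(trial_dur - stim_dur - n_cluster_vols * tr) / 2`, the silence
#' placed symmetrically before and after stimulation so the total trial
#' time is exact.  At TR 0.85 s (3-volume clusters, 9 s stimulation, 12 s
#' trials) this is 0.225 s; at TR 0.80 s it is 0.300 s.
#'
#' @param tr_s repetition time in seconds.
#' @param n_cluster_vols volumes per acquisition cluster.
#' @param stim_dur_s stimulation duration in seconds.
#' @param trial_dur_s total trial duration in seconds.
#' @return gap duration in seconds.
#' @export
calibrate_gap <- function(tr_s, n_cluster_vols, stim_dur_s, trial_dur_s) {
  gap <- (trial_dur_s - stim_dur_s - n_cluster_vols * tr_s) / 2
  if (gap < -1e-12) {
    stopf("infeasible site config: stimulation plus cluster exceeds trial duration")
  }
  max(gap, 0)
}

#' Build one run's trial schedule
#'
#' @param site a [site_config()].
#' @param seed RNG seed for the trial permutation.
#' @param max_consecutive longest allowed run of same-type stimulus trials
#'   (default 3); the pseudorandom order is rejection-sampled until it
#'   complies.
#' @return An object of class `trial_schedule`: list with `site`, `seed`,
#'   `gap_s` and `trials` (data frame with columns `index`, `trial_type`,
#'   `onset_s`, `gap_s`, `stim_dur_s`, `cluster_start` and `cluster_end`,
#'   1-based volume ordinals of the trial's acquisition cluster).
#' @export
build_run_schedule <- function(site, seed = 1L, max_consecutive = 3L) {
  gap <- calibrate_gap(site$tr_s, site$n_cluster_vols, site$stim_dur_s,
                       site$trial_dur_s)
  types <- c(rep("auditory", site$n_aud_trials), rep("visual", site$n_vis_trials))
  order_ok <- function(x) {
    r <- rle(x)
    max(r$lengths) <= max_consecutive
  }
  perm <- with_seed(seed, {
    repeat {
      cand <- sample(types)
      if (order_ok(cand)) break
    }
    cand
  })
  trial_type <- c("fixation", perm)
  n <- length(trial_type)
  ncv <- site$n_cluster_vols
  trials <- data.frame(
    index = seq_len(n),
    trial_type = trial_type,
    onset_s = (seq_len(n) - 1) * site$trial_dur_s,
    gap_s = gap,
    stim_dur_s = site$stim_dur_s,
    cluster_start = (seq_len(n) - 1L) * ncv + 1L,
    cluster_end = seq_len(n) * ncv,
    stringsAsFactors = FALSE
  )
  structure(list(site = site, seed = seed, gap_s = gap, trials = trials),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d trials (%d stimulus), gap %.3f s, %d volumes\n",
              nrow(x$trials), sum(x$trials$trial_type != "fixation"),
              x$gap_s, n_schedule_volumes(x)))
  invisible(x)
}

n_schedule_volumes <- function(schedule) {
  max(schedule$trials$cluster_end)
}

# Acquisition time of each sparse volume: cluster starts after
# gap + stimulation + gap within its trial.
schedule_timestamps <- function(schedule) {
  site <- schedule$site
  tr <- site$tr_s
  ts <- numeric(n_schedule_volumes(schedule))
  for (i in seq_len(nrow(schedule$trials))) {
    tr_row <- schedule$trials[i, ]
    vols <- tr_row$cluster_start:tr_row$cluster_end
    ts[vols] <- tr_row$onset_s + 2 * tr_row$gap_s + tr_row$stim_dur_s +
      (seq_along(vols) - 1) * tr
  }
  ts
}

# Per-volume trial type ("fixation"/"auditory"/"visual") and within-cluster
# position (1..n_cluster_vols).
schedule_volume_info <- function(schedule) {
  nvol <- n_schedule_volumes(schedule)
  type <- character(nvol); pos <- integer(nvol)
  for (i in seq_len(nrow(schedule$trials))) {
    tr_row <- schedule$trials[i, ]
    vols <- tr_row$cluster_start:tr_row$cluster_end
    type[vols] <- tr_row$trial_type
    pos[vols] <- seq_along(vols)
  }
  data.frame(volume = seq_len(nvol), trial_type = type, cluster_pos = pos,
             stringsAsFactors = FALSE)
}

#' Sequence the audio segments of one auditory trial
#'
#' Nine 900 ms music segments, each followed by 100 ms of silence, sampled
#' without replacement from the pool in seeded pseudorandom order (9 s of
#' stimulation in total).
#'
#' @param segment_pool vector of segment identifiers (length >= 9).
#' @param seed RNG seed.
#' @param n_segments segments per trial (default 9).
#' @param segment_dur_s,gap_dur_s segment and trailing-silence durations.
#' @return data frame with columns `segment`, `onset_s`, `dur_s`, `gap_s`.
#' @export
sequence_audio_trial <- function(segment_pool, seed = 1L, n_segments = 9L,
                                 segment_dur_s = 0.9, gap_dur_s = 0.1) {
  if (length(segment_pool) < n_segments) {
    stopf("segment pool too small: %d < %d", length(segment_pool), n_segments)
  }
  picks <- with_seed(seed, sample(segment_pool, n_segments))
  data.frame(
    segment = picks,
    onset_s = (seq_len(n_segments) - 1) * (segment_dur_s + gap_dur_s),
    dur_s = segment_dur_s,
    gap_s = gap_dur_s,
    stringsAsFactors = FALSE
  )
}

#' Normalize audio segments to a common mean amplitude
#'
#' Rescales each waveform so its mean absolute amplitude equals the pool's
#' grand mean absolute amplitude, avoiding loudness jumps between segments.
#'
#' @param waveforms list of numeric vectors (sampled waveforms).
#' @return list of rescaled waveforms.
#' @export
normalize_segments <- function(waveforms) {
  stopifnot(is.list(waveforms), length(waveforms) >= 1L)
  amps <- vapply(waveforms, function(w) mean(abs(w)), numeric(1))
  if (any(amps == 0)) stopf("all-zero waveform cannot be amplitude-normalized")
  target <- mean(amps)
  Map(function(w, a) w * (target / a), waveforms, amps)
}

#' Write a BIDS-style events table for a schedule
#'
#' Columns `onset`, `duration`, `trial_type`; onset is stimulation onset
#' (trial onset plus the leading gap) and duration the stimulation duration.
#' The fixation trial is included with its full trial window.
#'
#' @param schedule a [trial_schedule()].
#' @param path output TSV path.
#' @export
write_events_tsv <- function(schedule, path) {
  tr <- schedule$trials
  ev <- data.frame(
    onset = ifelse(tr$trial_type == "fixation", tr$onset_s,
                   tr$onset_s + tr$gap_s),
    duration = ifelse(tr$trial_type == "fixation",
                      schedule$site$trial_dur_s, tr$stim_dur_s),
    trial_type = tr$trial_type
  )
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events table
#' @param path TSV with columns onset, duration, trial_type.
#' @return data frame.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev))) {
    stopf("events table must have columns %s", paste(need, collapse = ", "))
  }
  ev
}
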