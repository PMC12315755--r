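# Volume censoring: LPF-FD, GEV-DV, eye closures, retention rules.

test_that("LPF-FD follows its arc-length definition", {
  cfg <- censor_config()
  zero <- matrix(0, 100, 6)
  expect_equal(lpf_fd(zero, 0.85, cfg), rep(0, 100))
  # with filtering disabled (cutoff at Nyquist) a 0.1 mm step gives FD 0.1
  cfg_nf <- censor_config(mp_lpf_cutoff_hz = 10)
  step <- zero; step[50:100, 1] <- 0.1
  expect_warning(fd <- lpf_fd(step, 0.85, cfg_nf), "Nyquist")
  expect_equal(fd[50], 0.1)
  expect_equal(fd[c(49, 51)], c(0, 0))
  expect_equal(fd[1], 0)
  # a pure rotation step contributes theta * 50 mm
  rot <- zero; rot[50:100, 5] <- 0.002
  expect_warning(fd_r <- lpf_fd(rot, 0.85, cfg_nf), "Nyquist")
  expect_equal(fd_r[50], 0.002 * 50)
  # low-pass filtering spreads the step over neighbors without growing the
  # peak, and keeps the displacement localized around the step
  fd_f <- lpf_fd(step, 0.85, cfg)
  expect_lt(max(fd_f), 0.1)
  expect_gt(max(fd_f), 0.02)
  expect_lte(abs(which.max(fd_f) - 50), 2)
  expect_lt(max(fd_f[-(44:56)]), 0.01)
})

test_that("GEV-DV finds injected global spikes and is monotone in d_g", {
  g <- volume_grid(c(8, 8, 8))
  nt <- 120
  set.seed(40)
  arr <- array(rnorm(8^3 * nt, 1000, 2), c(8, 8, 8, nt))
  arr[, , , 60] <- arr[, , , 60] + 30                  # one global spike
  bold <- bold_series(g, arr, 0.8)
  brain <- array(TRUE, c(8, 8, 8))
  res <- gev_dv_threshold(bold, brain)
  # the spike dominates DV (the low-pass filter may shift the peak by one)
  expect_lte(abs(which.max(res$dv) - 60), 1)
  expect_true(any(res$censored[59:61]))
  # constant data: zero DV, nothing censored
  bold_c <- bold_series(g, array(5, c(8, 8, 8, nt)), 0.8)
  expect_warning(res_c <- gev_dv_threshold(bold_c, brain), "fall")
  expect_equal(res_c$dv, rep(0, nt))
  expect_equal(sum(res_c$censored), 0)
  # monotonicity: larger d_g never censors more
  n_prev <- Inf
  for (dg in c(1, 2, 3.105, 5)) {
    n_cens <- sum(gev_dv_threshold(bold, brain,
                                   censor_config(d_g = dg))$censored)
    expect_lte(n_cens, n_prev)
    n_prev <- n_cens
  }
})

test_that("the GEV fitter recovers known parameters", {
  qgev <- function(p, loc, scale, shape) {
    loc + scale * ((-log(p))^(-shape) - 1) / shape
  }
  set.seed(41)
  x <- qgev(runif(4000), loc = 2, scale = 0.5, shape = 0.1)
  fit <- thalamloc:::fit_gev(x)
  expect_equal(fit$loc, 2, tolerance = 0.05)
  expect_equal(fit$scale, 0.5, tolerance = 0.1)
  expect_equal(fit$shape, 0.1, tolerance = 0.2)
})

test_that("eye-closure censoring respects the 3 s and 30 s rules", {
  cfg <- censor_config()
  ts <- seq(0, 100, by = 0.8)
  # 2 s closure: below the censoring duration, nothing removed
  none <- eye_closure_censor(data.frame(onset = 10, duration = 2), ts, cfg)
  expect_equal(sum(none), 0)
  # 4 s closure censors exactly the overlapping volumes
  one <- eye_closure_censor(data.frame(onset = 10, duration = 4), ts, cfg)
  expect_identical(one, ts >= 10 & ts <= 14)
  # two long closures 25 s apart censor everything in between
  two <- eye_closure_censor(data.frame(onset = c(16, 45), duration = c(4, 4)),
                            ts, cfg)
  expect_true(all(two[ts >= 16 & ts <= 49]))
  # a 35 s gap leaves the interval untouched
  far <- eye_closure_censor(data.frame(onset = c(10, 49), duration = c(4, 4)),
                            ts, cfg)
  expect_equal(sum(far[ts > 14 & ts < 49]), 0)
  # overlapping intervals are merged before the duration rule
  ov <- eye_closure_censor(data.frame(onset = c(10, 12), duration = c(2, 2)),
                           ts, cfg)
  expect_identical(ov, ts >= 10 & ts <= 14)            # merged 4 s closure
})

test_that("contiguity and retention boundaries are exact", {
  cfg <- censor_config()
  # TR 0.8: a 9-volume segment lasts 7.2 s and is dropped; 10 volumes stay
  keep9 <- c(rep(FALSE, 3), rep(TRUE, 9), rep(FALSE, 110))
  cm9 <- censor_mask(motion_censored = !keep9, tr_s = 0.8, config = cfg)
  expect_equal(sum(cm9$keep), 0)
  expect_true(all(vapply(cm9$reasons[4:12], function(r) "contiguity" %in% r,
                         logical(1))))
  keep10 <- c(rep(FALSE, 3), rep(TRUE, 10), rep(FALSE, 110))
  cm10 <- censor_mask(motion_censored = !keep10, tr_s = 0.8, config = cfg)
  expect_equal(sum(cm10$keep), 10)
  # run validity at exactly 90 s (113 volumes x 0.8 = 90.4 s pass; 112 fail)
  mk_mask <- function(n_keep, n_total = 500) {
    structure(list(keep = c(rep(TRUE, n_keep), rep(FALSE, n_total - n_keep))),
              class = "censor_mask")
  }
  r <- retention_rules(list(mk_mask(113), mk_mask(112)), 0.8, cfg)
  expect_identical(r$run_valid, c(TRUE, FALSE))
  # participant needs >= 2 valid runs and >= 300 s total
  r2 <- retention_rules(list(mk_mask(500), mk_mask(112)), 0.8, cfg)
  expect_false(r2$participant_valid)                   # one valid run only
  r3 <- retention_rules(list(mk_mask(187), mk_mask(187)), 0.8, cfg)
  expect_false(r3$participant_valid)                   # 299.2 s total < 300 s
  expect_true(retention_rules(list(mk_mask(200), mk_mask(200)), 0.8,
                              cfg)$participant_valid)
  # a fully clean 458 s run is valid
  clean <- structure(list(keep = rep(TRUE, 538)), class = "censor_mask")
  expect_true(retention_rules(list(clean, clean), 0.85,
                              cfg)$participant_valid)
})

test_that("censoring sources combine by union with reason attribution", {
  cfg <- censor_config(min_segment_s = 0.1)
  mot <- c(TRUE, rep(FALSE, 59))
  dv <- c(rep(FALSE, 30), TRUE, rep(FALSE, 29))
  eye <- c(rep(FALSE, 59), TRUE)
  cm <- censor_mask(mot, dv, eye, tr_s = 0.8, config = cfg)
  expect_equal(which(!cm$keep), c(1, 31, 60))
  expect_identical(cm$reasons[[1]], "motion")
  expect_identical(cm$reasons[[31]], "dv")
  expect_identical(cm$reasons[[60]], "eyes")
  expect_equal(cm$retained_s, 57 * 0.8)
})

test_that("phantom motion censoring hits exactly the spike neighborhoods", {
  cfg <- phantom_config()
  ccfg <- censor_config()
  for (s in 0:9) {
    mot <- generate_motion(538, 0.85, cfg, seed = s, spikes = TRUE)
    fd <- lpf_fd(mot$motion, 0.85, ccfg)
    cens <- which(fd > ccfg$phi_f_mm)
    if (length(mot$spike_volumes)) {
      near <- unlist(lapply(mot$spike_volumes, function(v) (v - 3):(v + 3)))
      expect_true(all(cens %in% near),
                  label = sprintf("seed %d: censored within spikes +/- 3", s))
      hit <- vapply(mot$spike_volumes,
                    function(v) any(abs(cens - v) <= 3), logical(1))
      expect_true(all(hit), label = sprintf("seed %d: every spike caught", s))
    } else {
      expect_length(cens, 0)
    }
  }
  # spike-free, drift-free motion censors nothing
  quiet <- generate_motion(538, 0.85, phantom_config(motion_spike_rate = 0),
                           seed = 1, spikes = FALSE, drift_mm = 0)
  expect_equal(max(abs(as.matrix(quiet$motion))), 0)
  expect_equal(sum(lpf_fd(quiet$motion, 0.85, ccfg) > ccfg$phi_f_mm), 0)
})
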