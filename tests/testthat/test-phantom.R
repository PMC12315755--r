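# Phantom generator: geometry, closed-form task signal, rest coupling,
# reproducibility, BIDS output.

test_that("anatomy places the truth LGN superior and lateral to the MGN", {
  anat <- tl_test_anatomy()
  mid <- (dim(anat$truth$mgn_L)[1] + 1) / 2
  for (h in c("L", "R")) {
    cm <- mask_centroid(anat$truth[[paste0("mgn_", h)]])
    cl <- mask_centroid(anat$truth[[paste0("lgn_", h)]])
    expect_gt(cl[3], cm[3])                            # superior
    expect_gt(abs(cl[1] - mid), abs(cm[1] - mid))      # lateral
  }
  expect_equal(sum(anat$truth$mgn_L), 20)
  expect_equal(sum(anat$truth$lgn_L), 30)
  # seeds overlap truth; zero jitter makes them identical
  expect_gt(sum(label_mask(anat$labels, "mgn_seed_L") & anat$truth$mgn_L), 0)
  anat0 <- generate_anatomy(phantom_config(seed_jitter_vox = 0))
  expect_identical(label_mask(anat0$labels, "mgn_seed_L"), anat0$truth$mgn_L)
  # exclusion structures never overlap the implanted nuclei
  excl <- exclusion_union(anat$labels)
  truth_all <- anat$truth$mgn_L | anat$truth$mgn_R |
    anat$truth$lgn_L | anat$truth$lgn_R
  expect_equal(sum(excl & truth_all), 0)
})

test_that("noiseless task runs obey the closed-form condition amplitudes", {
  cfg <- phantom_config(noise_sd = 0, drift_amp = 0, t1_offsets = c(0, 0, 0))
  anat <- tl_test_anatomy()
  sch <- build_run_schedule(cfg$site, seed = 3)
  bold <- generate_task_run(anat$labels, anat$truth, sch, cfg, seed = 1)
  info <- thalamloc:::schedule_volume_info(sch)
  ac <- mask_mean_series(bold, label_mask(anat$labels, "ba41_42_L"))
  aud_mean <- mean(ac[info$trial_type == "auditory"])
  vis_mean <- mean(ac[info$trial_type == "visual"])
  expect_equal(aud_mean - vis_mean, 1000 * 0.02, tolerance = 1e-10)
  # truth LGN carries visual-locked signal only: constant across auditory
  # clusters, elevated in visual clusters
  lgn <- mask_mean_series(bold, anat$truth$lgn_L)
  expect_equal(sd(lgn[info$trial_type == "auditory"]), 0, tolerance = 1e-12)
  expect_equal(unique(lgn[info$trial_type == "visual"]) -
                 unique(lgn[info$trial_type == "auditory"]),
               1000 * 0.02, tolerance = 1e-10)
  # truth MGN is auditory-locked only
  mgn <- mask_mean_series(bold, anat$truth$mgn_L)
  expect_equal(sd(mgn[info$trial_type == "visual"]), 0, tolerance = 1e-12)
})

test_that("T1 offsets raise early cluster volumes by the stated fractions", {
  cfg <- phantom_config(noise_sd = 0, drift_amp = 0)
  anat <- tl_test_anatomy()
  sch <- build_run_schedule(cfg$site, seed = 3)
  bold <- generate_task_run(anat$labels, anat$truth, sch, cfg, seed = 1)
  info <- thalamloc:::schedule_volume_info(sch)
  wm <- mask_mean_series(bold, label_mask(anat$labels, "white_matter"))
  v1 <- wm[info$cluster_pos == 1]; v3 <- wm[info$cluster_pos == 3]
  expect_equal(unique(round(v1 - v3, 9)), 1000 * (0.05 - 0.0))
  v2 <- wm[info$cluster_pos == 2]
  expect_equal(unique(round(v2 - v3, 9)), 1000 * (0.02 - 0.0))
})

test_that("phantom output is reproducible from config and seed", {
  cfg <- phantom_config()
  anat <- tl_test_anatomy()
  sch <- build_run_schedule(cfg$site, seed = 5)
  t1 <- generate_task_run(anat$labels, anat$truth, sch, cfg, seed = 9)
  t2 <- generate_task_run(anat$labels, anat$truth, sch, cfg, seed = 9)
  expect_identical(t1$data, t2$data)
  r1 <- generate_rest_run(anat$labels, anat$truth, cfg, seed = 9, storage = "flat")
  r2 <- generate_rest_run(anat$labels, anat$truth, cfg, seed = 9, storage = "flat")
  expect_identical(r1$data, r2$data)
  m1 <- generate_motion(100, 0.85, cfg, seed = 4)
  m2 <- generate_motion(100, 0.85, cfg, seed = 4)
  expect_identical(m1, m2)
  e1 <- generate_eye_closures(458, cfg, seed = 4)
  expect_identical(e1, generate_eye_closures(458, cfg, seed = 4))
  # and the generators do not disturb the session RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(generate_motion(50, 0.85, cfg, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("rest coupling matches its target in the low-noise limit", {
  anat <- tl_test_anatomy()
  cfg <- phantom_config(rest_noise_sd = 0, confound_amp = 0, wm_csf_amp = 0,
                        rest_coupling_r = 0.4)
  both <- function(cfgx, s) {
    b <- generate_rest_run(anat$labels, anat$truth, cfgx, seed = s,
                           storage = "flat")
    c(cor(mask_mean_series(b, anat$truth$mgn_L | anat$truth$mgn_R),
          mask_mean_series(b, label_mask(anat$labels, "ba41_42_L") |
                             label_mask(anat$labels, "ba41_42_R"))),
      cor(mask_mean_series(b, anat$truth$lgn_L | anat$truth$lgn_R),
          mask_mean_series(b, label_mask(anat$labels, "ba17_18_L") |
                             label_mask(anat$labels, "ba17_18_R"))))
  }
  # 10-run Monte Carlo over both geniculo-cortical couplings
  rs <- vapply(1:10, both, numeric(2), cfgx = cfg)
  expect_lt(abs(mean(rs) - 0.4), 0.05)
  # zero coupling leaves the geniculate and cortex sources independent
  cfg0 <- phantom_config(rest_noise_sd = 0, confound_amp = 0, wm_csf_amp = 0,
                         rest_coupling_r = 0)
  rs0 <- vapply(1:10, both, numeric(2), cfgx = cfg0)
  expect_lt(abs(mean(rs0)), 0.05)
})

test_that("partial correlation removes the implanted confounds", {
  anat <- tl_test_anatomy()
  # same seed, confounds on vs off: sources are drawn in the same order
  cfg_on <- phantom_config(rest_noise_sd = 0)
  cfg_off <- phantom_config(rest_noise_sd = 0, confound_amp = 0,
                            wm_csf_amp = 0)
  b_on <- generate_rest_run(anat$labels, anat$truth, cfg_on, seed = 77,
                            storage = "flat")
  b_off <- generate_rest_run(anat$labels, anat$truth, cfg_off, seed = 77,
                             storage = "flat")
  get <- function(b) {
    list(mgn = mask_mean_series(b, anat$truth$mgn_L | anat$truth$mgn_R),
         ac = mask_mean_series(b, label_mask(anat$labels, "ba41_42_L") |
                                 label_mask(anat$labels, "ba41_42_R")),
         wm = compartment_signal(b, anat$labels, "white_matter"),
         csf = compartment_signal(b, anat$labels, "csf"),
         gm = global_gm_signal(b, anat$labels))
  }
  on <- get(b_on); off <- get(b_off)
  r_partial <- partial_correlation(on$mgn, on$ac, cbind(on$wm, on$csf, on$gm))
  r_clean <- cor(off$mgn, off$ac)
  # controlling WM/CSF/global recovers the confound-free correlation up to
  # the in-sample projection of the signals on the compartment sources
  expect_lt(abs(r_partial - r_clean), 0.08)
  # without nuisance control the shared global source inflates the estimate
  expect_gt(cor(on$mgn, on$ac), r_clean)
})

test_that("eye-closure logs span the censoring boundary and stay in-run", {
  cfg <- phantom_config(eye_closure_rate = 2)
  durs <- unlist(lapply(1:20, function(s) {
    cl <- generate_eye_closures(458, cfg, seed = s)
    expect_true(all(cl$onset >= 0 & cl$onset + cl$duration <= 458))
    cl$duration
  }))
  expect_true(any(durs < 3) && any(durs > 3))          # mixture spans 3 s rule
})

test_that("a phantom participant writes a readable BIDS-flavored tree", {
  cfg <- phantom_config(n_task_runs = 2L, n_rest_runs = 0L)
  subj <- generate_phantom_subject(cfg, seed = 11, include_rest = FALSE)
  out <- withr::local_tempdir()
  write_phantom_bids(subj, out, sub_id = "07")
  dseg <- file.path(out, "sub-07", "ses-01", "anat", "sub-07_dseg.nii.gz")
  expect_true(file.exists(dseg))
  lv <- load_labeled_volume(
    dseg, unlist(jsonlite::read_json(sub("\\.nii\\.gz$", ".json", dseg))))
  expect_identical(lv$labels, subj$labels$labels)
  func <- file.path(out, "sub-07", "ses-01", "func")
  expect_true(file.exists(file.path(func,
    "sub-07_task-localizer_run-01_bold.nii.gz")))
  ev <- read_events_tsv(file.path(func, "sub-07_task-localizer_run-01_events.tsv"))
  expect_equal(nrow(ev), 17L)
  mot <- utils::read.delim(file.path(func,
    "sub-07_task-localizer_run-01_motion.tsv"))
  expect_equal(dim(mot), c(51L, 6L))
})
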