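# Resting-state post-processing and connectivity statistics.

test_that("mode-1000 normalization matches a counting oracle", {
  g <- volume_grid(c(6, 6, 4))
  brain <- array(TRUE, c(6, 6, 4))
  b <- bold_series(g, array(500, c(6, 6, 4, 5)), 0.8)
  expect_equal(unique(as.vector(mode1000(b, brain)$data)), 1000)
  b2 <- bold_series(g, array(2000, c(6, 6, 4, 5)), 0.8)
  expect_equal(attr(mode1000(b2, brain), "mode"), 2000)
  expect_equal(unique(as.vector(mode1000(b2, brain)$data)), 1000)
  # mixture with a known integer mode
  set.seed(50)
  vals <- sample(c(rep(800, 400), rep(1200, 300), round(rnorm(20, 1000, 50))))
  arr <- array(vals, c(6, 6, 4, 5))
  b3 <- bold_series(g, arr, 0.8)
  tab <- table(round(as.vector(arr)))
  oracle_mode <- as.numeric(names(tab)[which.max(tab)])
  expect_equal(attr(mode1000(b3, brain), "mode"), oracle_mode)
  b4 <- bold_series(g, array(-5, c(6, 6, 4, 5)), 0.8)
  expect_error(mode1000(b4, brain), "non-positive")
})

test_that("detrending removes lines exactly and recovers superposed signal", {
  t <- 1:200
  expect_equal(detrend_center(3 + 0.5 * t), rep(0, 200), tolerance = 1e-10)
  expect_equal(detrend_center(rep(4, 200)), rep(0, 200), tolerance = 1e-12)
  s <- sin(2 * pi * t / 25)
  y <- 2 - 0.3 * t + s
  got <- detrend_center(y)
  expect_equal(got, unname(resid(lm(y ~ t))), tolerance = 1e-10)  # OLS oracle
  expect_equal(mean(got), 0, tolerance = 1e-12)
  expect_equal(unname(coef(lm(got ~ t))[2]), 0, tolerance = 1e-12)
  # matrix input works column-wise
  M <- cbind(3 + 0.5 * t, s)
  D <- detrend_center(M)
  expect_equal(D[, 1], rep(0, 200), tolerance = 1e-10)
})

test_that("edge trimming removes the per-site volume counts", {
  cfg <- rsfc_config()
  x <- rnorm(538)
  out <- bandpass_with_interpolation(x, NULL, tr_s = 0.85, cfg)
  expect_equal(out$n_trim, 26L)                        # 22 s at TR 0.85
  out2 <- bandpass_with_interpolation(rnorm(572), NULL, tr_s = 0.80, cfg)
  expect_equal(out2$n_trim, 28L)                       # 22 s at TR 0.80
  expect_equal(sum(out$retained), 538 - 2 * 26)
  expect_false(any(out$retained[1:26]))
  expect_false(any(out$retained[513:538]))
})

test_that("band-pass with interpolation re-censors interpolated points", {
  cfg <- rsfc_config()
  t <- (0:537) * 0.85
  x <- sin(2 * pi * 0.04 * t)
  keep <- rep(TRUE, 538); keep[200:215] <- FALSE
  out <- bandpass_with_interpolation(x, keep, 0.85, cfg)
  expect_false(any(out$retained[200:215]))
  # in-band signal survives censoring + interpolation nearly unchanged
  ref <- bandpass_with_interpolation(x, NULL, 0.85, cfg)
  ret <- out$retained
  expect_gt(cor(out$series[ret], ref$series[ret]), 0.99)
  expect_error(bandpass_with_interpolation(x, rep(FALSE, 538), 0.85, cfg),
               "retained")
})

test_that("selectivity contrasts compute one-tailed t-tests with BH", {
  # hand-computed 5-participant sample with variance in every contrast
  tab <- data.frame(mgn_ac = c(.50, .60, .70, .60, .60),
                    mgn_vc = c(.40, .42, .38, .41, .40),
                    lgn_ac = c(.20, .22, .18, .21, .30),
                    lgn_vc = c(.50, .52, .48, .55, .45))
  out <- selectivity_contrasts(tab)
  expect_equal(nrow(out), 4L)
  d <- tab$mgn_ac - tab$mgn_vc
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  row <- out[out$contrast == "mgn_ac_gt_mgn_vc", ]
  expect_equal(row$t, t_ref, tolerance = 1e-12)
  expect_equal(row$df, 4)
  expect_equal(row$p, pt(t_ref, df = 4, lower.tail = FALSE), tolerance = 1e-12)
  # BH step-up on p = (.01,.02,.03,.04): all pass at alpha = .05
  expect_equal(p.adjust(c(.01, .02, .03, .04), "BH"), rep(.04, 4))
  expect_equal(out$p_fdr, p.adjust(out$p, "BH"))
  # identical pairs give zero-variance differences
  tab0 <- data.frame(mgn_ac = 1:4 / 10, mgn_vc = 1:4 / 10,
                     lgn_ac = 1:4 / 10, lgn_vc = 1:4 / 10)
  expect_error(selectivity_contrasts(tab0), "zero variance")
  expect_error(selectivity_contrasts(tab[1, ]), "2 participants")
})

test_that("ROI-set benchmarking differences behave per definition", {
  tl <- data.frame(participant = 1:6, mgn_ac = seq(.3, .55, .05),
                   mgn_vc = .1, lgn_ac = .1, lgn_vc = seq(.4, .65, .05))
  alt <- tl; alt$mgn_ac <- alt$mgn_ac - .1; alt$lgn_vc <- alt$lgn_vc - .05
  out <- benchmark_roi_sets(list(tl = tl, atlas = alt))
  expect_equal(out$mean_diff[out$pair == "mgn_ac"], .1, tolerance = 1e-12)
  expect_equal(out$mean_diff[out$pair == "lgn_vc"], .05, tolerance = 1e-12)
  # identical alternative: zero differences, no test statistic
  same <- benchmark_roi_sets(list(tl = tl, copy = tl))
  expect_equal(same$mean_diff, c(0, 0))
  expect_true(all(is.na(same$t)))
  # participant mismatch is an error
  alt2 <- alt[-1, ]
  expect_error(benchmark_roi_sets(list(tl = tl, atlas = alt2)), "mismatch")
})

test_that("identical thalamic and cortical masks give connectivity one", {
  anat <- tl_test_anatomy()
  cfg <- phantom_config()
  rest <- list(generate_rest_run(anat$labels, anat$truth, cfg, seed = 60,
                                 storage = "flat"),
               generate_rest_run(anat$labels, anat$truth, cfg, seed = 61,
                                 storage = "flat"))
  mot <- lapply(60:61, function(s) generate_motion(538, 0.85, cfg, seed = s,
                                                   spikes = FALSE)$motion)
  m <- label_mask(anat$labels, "ba41_42_L")
  roi <- list(mgn_L = m, mgn_R = m, lgn_L = anat$truth$lgn_L,
              lgn_R = anat$truth$lgn_R, ac_L = m, ac_R = m,
              vc_L = label_mask(anat$labels, "ba17_18_L"),
              vc_R = label_mask(anat$labels, "ba17_18_R"))
  conn <- roi_pair_connectivity(rest, roi, anat$labels, mot)
  expect_equal(unname(conn$pairs[["mgn_ac"]]), 1, tolerance = 1e-10)
  expect_equal(nrow(conn$runs), 2L)
  expect_true(all(abs(conn$runs) <= 1 + 1e-12))
})

test_that("seed maps are high in the seed and track implanted coupling", {
  anat <- tl_test_anatomy()
  cfg <- phantom_config()
  rest <- list(generate_rest_run(anat$labels, anat$truth, cfg, seed = 70))
  mot <- list(generate_motion(538, 0.85, cfg, seed = 70, spikes = FALSE)$motion)
  sm <- seed_map(rest, anat$truth$mgn_L, anat$truth$mgn_R, anat$labels, mot)
  expect_gt(mean(sm[anat$truth$mgn_L], na.rm = TRUE), 0.8)
  ac <- label_mask(anat$labels, "ba41_42_L") | label_mask(anat$labels, "ba41_42_R")
  vc <- label_mask(anat$labels, "ba17_18_L") | label_mask(anat$labels, "ba17_18_R")
  expect_gt(mean(sm[ac], na.rm = TRUE), mean(sm[vc], na.rm = TRUE))
})

test_that("connectivity is invariant to voxel order within masks", {
  set.seed(71)
  x <- rnorm(60); y <- rnorm(60); N <- matrix(rnorm(120), 60, 2)
  expect_equal(partial_correlation(x, y, N), partial_correlation(x, y, N[, 2:1]),
               tolerance = 1e-12)
})
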