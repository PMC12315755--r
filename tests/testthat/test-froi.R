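# Partial correlation, coactivation thresholds, cluster extraction, QC.

test_that("partial correlation equals residual Pearson correlation", {
  set.seed(30)
  x <- rnorm(40); expect_equal(partial_correlation(x, x), 1.0)
  y <- rnorm(40)
  expect_equal(partial_correlation(x, y), cor(x, y), tolerance = 1e-12)
  # regression oracle with 3 nuisance columns
  for (i in 1:5) {
    n <- 50
    N <- matrix(rnorm(n * 3), n, 3)
    x <- rnorm(n) + N %*% rnorm(3)
    y <- rnorm(n) + N %*% rnorm(3)
    rx <- resid(lm(x ~ N)); ry <- resid(lm(y ~ N))
    expect_equal(partial_correlation(x, y, N), cor(rx, ry), tolerance = 1e-12)
  }
  # degenerate inputs
  expect_error(partial_correlation(rnorm(50), N[, 1], N), "degenerate")
  expect_error(partial_correlation(rnorm(5), rnorm(5), matrix(rnorm(20), 5, 4)),
               "too few samples")
})

test_that("coactivation maps recover implanted structure and are exchangeable", {
  # small synthetic TSR: 30 voxels, 60 time points
  set.seed(31)
  nt <- 60
  shape <- c(5, 3, 2)
  mask <- array(TRUE, shape)
  ac <- rnorm(nt); vc <- rnorm(nt)
  N <- cbind(rnorm(nt), rnorm(nt))
  Y <- matrix(rnorm(nt * 30, sd = 0.05), nt, 30)
  Y[, 1:10] <- Y[, 1:10] + outer(ac, rep(1, 10))       # AC-driven voxels
  Y[, 11:15] <- Y[, 11:15] + outer(vc, rep(1, 5))      # VC-driven voxels
  co <- coactivation_maps(Y, mask, ac, vc, N)
  expect_true(all(co$r_ac[1:10] > 0.9))
  expect_true(all(co$r_vc[11:15] > 0.9))
  expect_lt(max(abs(co$r_vc[1:10])), 0.5)
  # permuting volume order identically everywhere leaves the maps unchanged
  p <- sample(nt)
  co_p <- coactivation_maps(Y[p, ], mask, ac[p], vc[p], N[p, ])
  expect_equal(co_p$r_ac, co$r_ac, tolerance = 1e-12)
  expect_equal(co_p$r_vc, co$r_vc, tolerance = 1e-12)
  # a nuisance column equal to the reference makes the reference degenerate
  expect_error(coactivation_maps(Y, mask, ac, vc, cbind(N, ac)),
               "degenerate reference")
  # a constant voxel is excluded with a warning, not an error
  Y2 <- Y; Y2[, 30] <- 7
  expect_warning(co2 <- coactivation_maps(Y2, mask, ac, vc, NULL), "excluded")
  expect_true(is.na(co2$r_ac[30]))
})

test_that("size-adaptive thresholding keeps k-of-mean-size and removes dual voxels", {
  shape <- c(8, 4, 4)
  mask <- array(FALSE, shape); mask[1:64] <- TRUE      # 64-voxel TSR
  r_ac <- array(NA_real_, shape); r_vc <- array(NA_real_, shape)
  set.seed(32)
  r_ac[1:64] <- runif(64); r_vc[1:64] <- runif(64)
  co <- structure(list(tsr = mask, mask = mask, r_ac = r_ac, r_vc = r_vc),
                  class = "coactivation_result")
  out <- threshold_and_exclude(co, "mgn", mean_tsr_size = 64)
  expect_equal(out$threshold_fraction, 0.5)            # 32 / 64
  dual <- sum(out$kept_ac & out$kept_vc)
  expect_equal(dual, 0)                                # disjoint after removal
  # before dual removal each map kept exactly 32: reconstruct via rank oracle
  kept_ac_pre <- r_ac >= sort(r_ac[1:64], decreasing = TRUE)[32]
  kept_ac_pre[is.na(kept_ac_pre)] <- FALSE
  expect_identical(out$kept_ac, kept_ac_pre & !(kept_ac_pre &
                     (r_vc >= sort(r_vc[1:64], decreasing = TRUE)[32]) &
                     !is.na(r_vc)))
  # identical maps annihilate completely
  co_same <- structure(list(tsr = mask, mask = mask, r_ac = r_ac, r_vc = r_ac),
                       class = "coactivation_result")
  out_same <- threshold_and_exclude(co_same, "lgn", 64)
  expect_equal(sum(out_same$kept_ac), 0)
  expect_equal(sum(out_same$kept_vc), 0)
  # disjoint kept maps pass through unchanged
  r_b <- array(NA_real_, shape); r_b[1:64] <- -r_ac[1:64]
  co_dis <- structure(list(tsr = mask, mask = mask, r_ac = r_ac, r_vc = r_b),
                      class = "coactivation_result")
  out_dis <- threshold_and_exclude(co_dis, "lgn", 64)
  expect_equal(sum(out_dis$kept_ac & out_dis$kept_vc), 0)
  expect_equal(sum(out_dis$kept_ac), 20)               # ceil(20/64 * 64)
  # target above the mean size caps the fraction at 1
  out_cap <- threshold_and_exclude(co_dis, "mgn", mean_tsr_size = 16)
  expect_equal(out_cap$threshold_fraction, 1)
})

test_that("largest cluster extraction follows size then peak then index", {
  shape <- c(20, 6, 2)
  m <- array(FALSE, shape)
  m[2:6, 2, 1] <- TRUE                                 # size 5
  m[10:16, 2, 1] <- TRUE                               # size 7
  r <- array(0.5, shape)
  got <- largest_cluster(m, r)
  expect_equal(sum(got), 7)
  expect_true(all(which(got) %in% which(m)))
  expect_identical(got, oracle_components(m) ==
                     oracle_components(m)[10, 2, 1])
  # size tie broken by peak coactivation
  m2 <- array(FALSE, shape)
  m2[2:6, 2, 1] <- TRUE; m2[10:14, 2, 1] <- TRUE
  r2 <- array(0, shape); r2[3, 2, 1] <- 0.6; r2[12, 2, 1] <- 0.8
  got2 <- largest_cluster(m2, r2)
  expect_true(got2[12, 2, 1]); expect_false(got2[3, 2, 1])
  expect_equal(largest_cluster(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2))),
               array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)))
  expect_error(largest_cluster(array(FALSE, c(2, 2, 2))), "QC failure")
})

test_that("QC flags detect implausible geometry and asymmetry", {
  shape <- c(20, 10, 10)
  blob <- function(x, y, z, n = 5) {
    m <- array(FALSE, shape)
    m[cbind(x + seq_len(n) - 1, y, z)] <- TRUE
    m
  }
  good <- froi_set(mgn_L = blob(6, 5, 4), mgn_R = blob(12, 5, 4),
                   lgn_L = blob(3, 5, 6), lgn_R = blob(15, 5, 6))
  expect_length(qc_flags(good), 0)
  # LGN below the MGN
  low <- froi_set(mgn_L = blob(6, 5, 6), mgn_R = blob(12, 5, 6),
                  lgn_L = blob(3, 5, 3), lgn_R = blob(15, 5, 3))
  expect_true("LGN_INFERIOR" %in% qc_flags(low))
  # LGN more medial than the MGN
  med <- froi_set(mgn_L = blob(2, 5, 4), mgn_R = blob(15, 5, 4),
                  lgn_L = blob(9, 5, 6), lgn_R = blob(10, 5, 6))
  expect_true("LGN_MEDIAL" %in% qc_flags(med))
  # 7 vs 2 voxels: ln(3.5) > ln(3)
  asym <- froi_set(mgn_L = blob(2, 5, 4, n = 7), mgn_R = blob(17, 5, 4, n = 2),
                   lgn_L = blob(5, 5, 6), lgn_R = blob(14, 5, 6))
  expect_true("ASYMMETRY" %in% qc_flags(asym))
  # a missing mask fails outright
  broken <- good; broken$mgn_L <- array(FALSE, shape)
  expect_identical(qc_flags(broken), "FAILED")
})

test_that("extracted phantom fROIs satisfy the structural invariants", {
  res <- tl_test_froi_result()
  froi <- res$froi
  for (nuc in c("mgn", "lgn")) {
    for (h in c("L", "R")) {
      m <- froi[[paste0(nuc, "_", h)]]
      expect_equal(max(connected_components(m)), 1L)   # single component
      expect_true(all(res$tsr[[paste0(nuc, "_", h)]]$mask[m]))  # inside TSR
    }
  }
  expect_equal(sum(froi$mgn_L & froi$lgn_L), 0)        # disjoint nuclei
  expect_equal(sum(froi$mgn_R & froi$lgn_R), 0)
  expect_length(froi$qc_flags, 0)
})
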