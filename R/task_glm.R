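# Sparse-acquisition GLM: design matrix assembly, per-voxel OLS, and the
# Auditory - Visual contrast.
#
# The design has, per run: intercept, unconvolved auditory and visual
# indicators (no HRF model is possible with sparse sampling), 6 motion
# parameters and their squares, WM and CSF compartment signals, and
# indicators for the 2nd and 3rd volume of every acquisition cluster (the
# latter absorb T1-relaxation offsets, since clustered-sparse volumes are
# not acquired at steady state).

#' Build the sparse-task design matrix for one run
#'
#' Nuisance columns (motion, squared motion, WM, CSF) are mean-centered so
#' the intercept carries the baseline; constant columns are dropped with a
#' warning.  Task indicator columns cover all volumes of the cluster that
#' follows each stimulus trial; fixation cluster volumes are zero in both.
#'
#' @param schedule a [trial_schedule()].
#' @param motion data frame or matrix with 6 columns (trans_x, trans_y,
#'   trans_z, rot_x, rot_y, rot_z; rotations in radians), one row per
#'   acquired volume, or NULL for none.
#' @param wm,csf compartment nuisance series (one value per volume), or NULL.
#' @return An object of class `design_matrix`: list with `X` (numeric
#'   matrix), `column_names`, and `volume_info`.
#' @export
build_design <- function(schedule, motion = NULL, wm = NULL, csf = NULL) {
  info <- schedule_volume_info(schedule)
  nvol <- nrow(info)
  cols <- list(intercept = rep(1, nvol),
               auditory = as.numeric(info$trial_type == "auditory"),
               visual = as.numeric(info$trial_type == "visual"))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nvol) stopf("motion table has %d rows, expected %d",
                                    nrow(motion), nvol)
    if (ncol(motion) != 6L) stopf("motion table must have 6 columns")
    mp_names <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    for (j in 1:6) cols[[paste0("mp_", mp_names[j])]] <- motion[, j]
    for (j in 1:6) cols[[paste0("mp_", mp_names[j], "_sq")]] <- motion[, j]^2
  }
  if (!is.null(wm)) {
    if (length(wm) != nvol) stopf("wm series length mismatch")
    cols$wm <- wm
  }
  if (!is.null(csf)) {
    if (length(csf) != nvol) stopf("csf series length mismatch")
    cols$csf <- csf
  }
  cols$cluster_vol2 <- as.numeric(info$cluster_pos == 2L)
  cols$cluster_vol3 <- as.numeric(info$cluster_pos == 3L)
  task_cols <- c("intercept", "auditory", "visual",
                 "cluster_vol2", "cluster_vol3")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  # center and unit-scale nuisance columns (stabilizes conditioning; task
  # and intercept betas are unaffected); drop degenerate (constant) ones
  drop <- character(0)
  for (nm in setdiff(colnames(X), task_cols)) {
    v <- X[, nm] - mean(X[, nm])
    s <- stats::sd(v)
    if (s < 1e-12) drop <- c(drop, nm) else X[, nm] <- v / s
  }
  if (length(drop)) {
    warnf("dropping constant design column(s): %s", paste(drop, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  structure(list(X = X, column_names = colnames(X), volume_info = info,
                 schedule = schedule),
            class = "design_matrix")
}

#' Write a design matrix as TSV (audit trail)
#' @param design a [build_design()] result.
#' @param path output path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design$X), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the task GLM voxelwise by ordinary least squares
#'
#' @param bold a smoothed task [bold_series()].
#' @param design a [build_design()] result whose row count matches the run.
#' @return An object of class `glm_fit`: `betas` (voxels x coefficients
#'   matrix), `sigma2` (residual variance per voxel), `column_names`,
#'   `grid`.
#' @export
fit_glm <- function(bold, design) {
  X <- design$X
  if (nrow(X) != n_volumes(bold)) {
    stopf("design has %d rows but run has %d volumes", nrow(X), n_volumes(bold))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  Y <- t(bold_matrix(bold))              # time x voxels
  B <- qr.coef(qrX, Y)                   # coefficients x voxels
  resid <- Y - X %*% B
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / max(dfres, 1L)
  structure(list(betas = t(B), sigma2 = sigma2,
                 column_names = colnames(X), grid = bold$grid),
            class = "glm_fit")
}

beta_volume <- function(fit, name) {
  j <- match(name, fit$column_names)
  if (is.na(j)) stopf("no '%s' column in fitted design", name)
  array(fit$betas[, j], fit$grid$shape)
}

#' Average Auditory - Visual contrast over runs
#'
#' @param fits list of [fit_glm()] results, one per run (at least two).
#' @return An object of class `contrast_map`: `values` (3D array),
#'   `grid`, `runs_used`.
#' @export
contrast_auditory_minus_visual <- function(fits) {
  if (length(fits) < 2L) stopf("a minimum of two task runs is required")
  grids <- lapply(fits, `[[`, "grid")
  for (g in grids[-1]) assert_same_grid(grids[[1]], g, "run betas")
  acc <- 0
  for (f in fits) acc <- acc + (beta_volume(f, "auditory") - beta_volume(f, "visual"))
  structure(list(values = acc / length(fits), grid = grids[[1]],
                 runs_used = length(fits)),
            class = "contrast_map")
}
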