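# Independent brute-force oracles used to cross-check the package's
# morphology and thresholding operations, plus shared small fixtures.

# Direct neighborhood-definition dilation: a voxel is set iff any voxel of
# the input lies within the structuring element around it.
oracle_dilate <- function(mask, iterations = 1L, connectivity = 26L) {
  d <- dim(mask)
  off <- switch(as.character(connectivity),
                `6` = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                            c(0,0,1), c(0,0,-1)),
                `18` = {
                  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  g[rowSums(abs(g)) %in% 1:2, , drop = FALSE]
                },
                `26` = {
                  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  g[rowSums(abs(g)) > 0, , drop = FALSE]
                })
  for (it in seq_len(iterations)) {
    out <- mask
    for (v in which(mask)) {
      co <- arrayInd(v, d)
      for (k in seq_len(nrow(off))) {
        p <- co + off[k, ]
        if (all(p >= 1) && all(p <= d)) out[p[1], p[2], p[3]] <- TRUE
      }
    }
    mask <- out
  }
  mask
}

oracle_erode <- function(mask, iterations = 1L, connectivity = 6L) {
  # erosion of M = complement of dilation of the complement, with the image
  # border treated as background
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    pad <- array(TRUE, d + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- !mask
    pad <- oracle_dilate(pad, 1L, connectivity)
    mask <- !pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  }
  mask
}

# Recursive flood fill over an explicit stack.
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  comp <- 0L
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- switch(as.character(connectivity),
                `6` = off[rowSums(abs(off)) == 1, , drop = FALSE],
                `18` = off[rowSums(abs(off)) %in% 1:2, , drop = FALSE],
                `26` = off[rowSums(abs(off)) > 0, , drop = FALSE])
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    comp <- comp + 1L
    stack <- list(arrayInd(v, d))
    lab[v] <- comp
    while (length(stack)) {
      co <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(off))) {
        p <- co + off[k, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- comp
          stack[[length(stack) + 1L]] <- p
        }
      }
    }
  }
  lab
}

# Cached default phantom anatomy and one fully-analyzed task participant,
# shared across test files to keep the suite fast.
.tl_cache <- new.env(parent = emptyenv())

tl_test_anatomy <- function() {
  if (is.null(.tl_cache$anat)) {
    .tl_cache$anat <- generate_anatomy(phantom_config())
  }
  .tl_cache$anat
}

tl_test_subject <- function() {
  if (is.null(.tl_cache$subj)) {
    .tl_cache$subj <- generate_phantom_subject(phantom_config(), seed = 1L,
                                               include_rest = FALSE)
  }
  .tl_cache$subj
}

tl_test_froi_result <- function() {
  if (is.null(.tl_cache$froi_res)) {
    subj <- tl_test_subject()
    .tl_cache$froi_res <- extract_frois(
      subj$labels, lapply(subj$task, `[[`, "bold"),
      lapply(subj$task, `[[`, "schedule"),
      lapply(subj$task, `[[`, "motion"))
  }
  .tl_cache$froi_res
}

# Minimal labeled volume for search-region unit tests: all required labels
# present in the map; only the structures a test sets are non-empty.
tl_sparse_labels <- function(shape, set = list()) {
  lab <- array(0L, shape)
  codes <- seq_along(REQUIRED_LABELS)
  names(codes) <- REQUIRED_LABELS
  for (nm in names(set)) lab[set[[nm]] & lab == 0L] <- codes[[nm]]
  labeled_volume(volume_grid(shape), lab, codes)
}
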