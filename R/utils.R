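# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never clobbers
#' the session stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct child seed from a base seed; kept below 2^31.
child_seed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Backward difference with a leading zero (length-preserving).
backdiff <- function(x) c(0, diff(x))

#' Dice-Sorensen overlap coefficient between two binary masks
#'
#' @param mask_a,mask_b logical arrays of identical shape.
#' @return `2|A n B| / (|A| + |B|)`; 0 when both masks are empty.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0L) return(0)
  2 * sum(mask_a & mask_b) / (na + nb)
}
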