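# Small grid utilities shared across the pipeline. Grids are plain R
# matrices (row 1 = top of the map); georeferencing is carried separately
# by the ASCII-grid writers in io.R.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `expr`, and restores the caller's RNG state, so
#' seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a stage/year, kept inside 32-bit range.
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Binary disc mask on a pixel grid
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param center numeric length-2 `(row, col)` of the disc centre.
#' @param radius_px disc radius in pixels; pixels whose centre lies within
#'   `radius_px` of `center` are TRUE.
#' @return logical matrix.
#' @keywords internal
disc_mask <- function(nrow, ncol, center, radius_px) {
  if (radius_px <= 0) return(matrix(FALSE, nrow, ncol))
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius_px^2
}

# Shift a logical matrix by (dr, dc) with edge replication, so erosion does
# not eat regions merely because they touch the image border.
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Morphological erosion of a binary mask
#'
#' Erodes with a 3x3 (8-connected) structuring element, `margin` times, so a
#' pixel survives iff every pixel within Chebyshev distance `margin` is TRUE.
#' Pixels outside the grid are treated as replicating the border row/column,
#' so a region touching the image edge is only eroded from its interior side.
#'
#' @param mask logical matrix.
#' @param margin non-negative integer erosion depth in pixels.
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask, margin) {
  stopifnot(is.matrix(mask), margin >= 0)
  m <- mask
  if (margin == 0) return(m)
  for (i in seq_len(margin)) {
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out & shift_replicate(m, dr, dc)
    }
    m <- out
  }
  m
}

# Median over the third dimension of a pixel stack, ignoring NA; thin
# wrapper over the compiled kernel. `stack` is a pixels x layers matrix.
stack_median <- function(stack) {
  .stack_median_cpp(stack)
}
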