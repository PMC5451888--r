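# Histogram of oriented gradients at the detector's fixed configuration:
# 9 unsigned bins over 0-180 degrees, 6x6 px cells, 2x2-cell blocks with
# one-cell overlap, L2-Hys block normalization.

#' HOG descriptor parameters
#'
#' The descriptor configuration is fixed across the detector family: a linear
#' gradient vote into 9 unsigned orientation bins over 0–180°, cells of
#' 6 × 6 px, blocks of 2 × 2 cells, and a 1-cell overlap between adjacent
#' blocks.  On a 40 × 40 object image this yields a 900-dimensional feature
#' vector (6 × 6 cells → 5 × 5 blocks × 4 cells × 9 bins).
#'
#' @param bins number of unsigned orientation bins over `[0°, 180°)`.
#' @param cell_size cell side in pixels.
#' @param block_size block side in cells.
#' @param block_stride stride between blocks, in cells (1 = one-cell overlap
#'   for 2-cell blocks).
#' @param clip L2-Hys clipping ceiling applied after the first block
#'   normalization.
#' @param eps normalization guard added (squared) under the square root so
#'   zero-gradient blocks map to zero vectors.
#' @return A list of class `hog_params`.
#' @export
hog_params <- function(bins = 9L, cell_size = 6L, block_size = 2L,
                       block_stride = 1L, clip = 0.2, eps = 1e-6) {
  bins <- as.integer(bins); cell_size <- as.integer(cell_size)
  block_size <- as.integer(block_size); block_stride <- as.integer(block_stride)
  if (bins < 1L || cell_size < 1L || block_size < 1L)
    stop("bins, cell_size and block_size must be >= 1", call. = FALSE)
  if (block_stride < 1L || block_stride > block_size)
    stop("block_stride must lie in [1, block_size]", call. = FALSE)
  structure(list(bins = bins, cell_size = cell_size, block_size = block_size,
                 block_stride = block_stride, clip = clip, eps = eps),
            class = "hog_params")
}

#' Image gradients by centered differences
#'
#' Applies the `[-1, 0, 1]` kernel along x (columns) and y (rows) with edge
#' replication and no pre-smoothing.  For a 3-channel image the channel with
#' the largest gradient magnitude supplies, per pixel, both the magnitude and
#' the orientation (the standard multi-channel HOG convention).  Orientations
#' are unsigned, folded into `[0°, 180°)`.
#'
#' @param image grayscale matrix or RGB array, at least 3 × 3.
#' @return A list of class `gradient_field` with matrices `magnitude` and
#'   `orientation` (degrees).
#' @export
compute_gradients <- function(image) {
  d <- dim(image)
  if (d[1] < 3L || d[2] < 3L)
    stop("image must be at least 3 x 3 for centered differences", call. = FALSE)
  if (is.matrix(image)) {
    g <- gradients_single(image)
    mag <- g$mag; gx <- g$gx; gy <- g$gy
  } else {
    if (length(d) != 3L || d[3] != 3L)
      stop("image must be a matrix or height x width x 3 array", call. = FALSE)
    gs <- lapply(1:3, function(k) gradients_single(image[, , k]))
    mags <- vapply(gs, `[[`, gs[[1]]$mag, "mag")
    # per pixel, the channel with maximal magnitude wins; ties to the lowest index
    pick <- max.col(matrix(mags, ncol = 3L), ties.method = "first")
    n <- d[1] * d[2]
    sel <- (pick - 1L) * n + seq_len(n)
    gxs <- vapply(gs, `[[`, gs[[1]]$gx, "gx")
    gys <- vapply(gs, `[[`, gs[[1]]$gy, "gy")
    mag <- matrix(matrix(mags, ncol = 3L)[cbind(seq_len(n), pick)], d[1], d[2])
    gx <- matrix(gxs[sel], d[1], d[2])
    gy <- matrix(gys[sel], d[1], d[2])
  }
  ori <- atan2(gy, gx) * 180 / pi
  ori <- ori %% 180            # unsigned: (g) and (-g) share an orientation
  ori[ori >= 180] <- 0         # guard the 180-epsilon fold
  ori[mag == 0] <- 0
  structure(list(magnitude = mag, orientation = ori), class = "gradient_field")
}

gradients_single <- function(v) {
  h <- nrow(v); w <- ncol(v)
  # edge replication: derivative at the border uses the border pixel itself
  right <- v[, c(2:w, w)]; left <- v[, c(1, 1:(w - 1))]
  down  <- v[c(2:h, h), ]; up   <- v[c(1, 1:(h - 1)), ]
  gx <- right - left
  gy <- down - up
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' HOG feature vector
#'
#' Computes the descriptor: per-cell orientation histograms by linear
#' interpolation of each pixel's gradient magnitude between the two nearest
#' bin centers (centers at 10°, 30°, …, 170°, wrapping across 180°), grouped
#' into overlapping blocks, each block L2-Hys-normalized (L2 normalization,
#' clipping at `clip`, renormalization), and concatenated in row-major block
#' order with row-major cells inside each block and ascending bins inside
#' each cell.
#'
#' When the image does not divide into whole cells, the largest centered
#' whole-cell region is used: on a 40 × 40 image with 6-px cells this is the
#' central 36 × 36 px window (a 2-px symmetric crop), keeping the berry
#' center aligned with the descriptor center.
#'
#' @param image grayscale matrix or RGB array (RGB is used by the S2 version,
#'   which skips grayscale conversion).
#' @param params a [hog_params()].
#' @return Numeric feature vector of length
#'   `blocks_x * blocks_y * block_size^2 * bins`.
#' @export
hog_features <- function(image, params = hog_params()) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  cs <- params$cell_size
  if (h < cs * params$block_size || w < cs * params$block_size)
    stop("image smaller than one block (", cs * params$block_size, " px)",
         call. = FALSE)
  cells_y <- h %/% cs; cells_x <- w %/% cs
  off_y <- (h - cells_y * cs) %/% 2L
  off_x <- (w - cells_x * cs) %/% 2L

  g <- compute_gradients(image)
  rows <- off_y + seq_len(cells_y * cs)
  cols <- off_x + seq_len(cells_x * cs)
  mag <- g$magnitude[rows, cols]
  ori <- g$orientation[rows, cols]

  H <- cell_histograms(mag, ori, cells_y, cells_x, cs, params$bins)
  normalize_blocks(H, cells_y, cells_x, params)
}

# 3-d array of per-cell histograms, dim (bins, cells_y, cells_x); the linear
# vote splits each pixel's magnitude between the two nearest bin centers so
# the total vote per cell equals the total magnitude per cell.
cell_histograms <- function(mag, ori, cells_y, cells_x, cs, bins) {
  n <- length(mag)
  width <- 180 / bins
  t <- ori / width - 0.5
  k <- floor(t)
  frac <- t - k
  bin_lo <- (k %% bins) + 1L
  bin_hi <- ((k + 1L) %% bins) + 1L

  ri <- (row(mag) - 1L) %/% cs
  ci <- (col(mag) - 1L) %/% cs
  cell <- ri + cells_y * ci                      # 0-based cell index
  idx_lo <- cell * bins + bin_lo
  idx_hi <- cell * bins + bin_hi

  votes <- rowsum(c(as.vector(mag) * (1 - as.vector(frac)),
                    as.vector(mag) * as.vector(frac)),
                  group = c(as.vector(idx_lo), as.vector(idx_hi)))
  H <- numeric(bins * cells_y * cells_x)
  H[as.integer(rownames(votes))] <- votes
  array(H, dim = c(bins, cells_y, cells_x))
}

normalize_blocks <- function(H, cells_y, cells_x, params) {
  bs <- params$block_size; stride <- params$block_stride
  bins <- params$bins; eps2 <- params$eps^2
  by <- seq(1L, cells_y - bs + 1L, by = stride)
  bx <- seq(1L, cells_x - bs + 1L, by = stride)
  out <- vector("list", length(by) * length(bx))
  k <- 0L
  for (i in by) {          # row-major block order
    for (j in bx) {
      v <- numeric(0)
      for (ci in i:(i + bs - 1L))      # row-major cells inside the block
        for (cj in j:(j + bs - 1L))
          v <- c(v, H[, ci, cj])
      v <- v / sqrt(sum(v^2) + eps2)
      v <- pmin(v, params$clip)
      v <- v / sqrt(sum(v^2) + eps2)
      k <- k + 1L
      out[[k]] <- v
    }
  }
  unlist(out, use.names = FALSE)
}

#' Feature-vector length implied by HOG parameters
#'
#' @param height,width image dimensions in pixels.
#' @param params a [hog_params()].
#' @return Integer length of the descriptor for that image size.
#' @export
hog_length <- function(height, width, params = hog_params()) {
  cells_y <- height %/% params$cell_size
  cells_x <- width %/% params$cell_size
  blocks_y <- (cells_y - params$block_size) %/% params$block_stride + 1L
  blocks_x <- (cells_x - params$block_size) %/% params$block_stride + 1L
  as.integer(blocks_y * blocks_x * params$block_size^2 * params$bins)
}
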