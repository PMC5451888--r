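# Ternary shaded-surface diagrams: a performance measure over the weight
# simplex for fixed (version, kernel, C, sigma).  Axis convention: the red
# weight is read on the left arm and increases downwards, the green weight
# on the bottom arm increasing rightwards, the blue weight on the right arm
# increasing upwards.  With a point-up equilateral triangle this places the
# vertices at wR = 1 bottom-left, wG = 1 bottom-right, wB = 1 top.

TERNARY_VERTICES <- rbind(R = c(0, 0),
                          G = c(1, 0),
                          B = c(0.5, sqrt(3) / 2))

#' Map simplex weights to planar triangle coordinates
#'
#' Affine barycentric map onto the reference equilateral triangle: the
#' point is the weight-weighted mean of the three vertices, so `(1, 0, 0)`
#' lands on the red vertex, `(0, 1, 0)` on the green one, `(0, 0, 1)` on
#' the blue one, and `(1/3, 1/3, 1/3)` on the centroid.
#'
#' @param w a [weight_triple()] or an n × 3 matrix of simplex rows.
#' @return A matrix with columns `x`, `y`.
#' @export
barycentric_to_cartesian <- function(w) {
  if (!is.matrix(w)) w <- matrix(weight_triple(w), 1L)
  xy <- w %*% TERNARY_VERTICES
  colnames(xy) <- c("x", "y")
  xy
}

#' Performance surface over the weight simplex
#'
#' Collects, from sweep records, one measure's score at every weight triple
#' for a fixed `(C, sigma)` — the data behind one ternary diagram.
#'
#' @param records sweep record data frame (version `R`).
#' @param measure `"accuracy"`, `"precision"` or `"recall"`.
#' @param C regularization constant selecting the slice.
#' @param sigma kernel width selecting the slice (`NULL` for the linear
#'   kernel).
#' @return A list of class `ternary_surface`: `w` (members × 3 matrix),
#'   `scores`, `p` (lattice resolution) and the fixed `context`.
#' @export
ternary_surface <- function(records, measure = "accuracy", C, sigma = NULL) {
  measure <- match.arg(measure, c("accuracy", "precision", "recall"))
  rows <- records$C == C &
    (if (is.null(sigma)) is.na(records$sigma) else
       !is.na(records$sigma) & records$sigma == sigma)
  slice <- records[rows, , drop = FALSE]
  if (nrow(slice) == 0L)
    stop("no records at C = ", C,
         if (!is.null(sigma)) paste0(", sigma = ", sigma), call. = FALSE)
  if (anyNA(slice$wR))
    stop("records carry no weight triples (not a version-R sweep)",
         call. = FALSE)
  w <- as.matrix(slice[, c("wR", "wG", "wB")])
  # recover the lattice resolution from the step structure
  p <- as.integer(round(1 / min(diff(sort(unique(c(w)))))))
  structure(list(w = w, scores = slice[[measure]], p = p,
                 context = list(measure = measure, C = C, sigma = sigma,
                                version = attr(records, "version"),
                                kernel = attr(records, "kernel"))),
            class = "ternary_surface")
}

#' Read a surface score at a weight triple
#'
#' Returns the score of the grid member nearest (Euclidean) to `w`;
#' distance ties are broken lexicographically by `(wR, wG, wB)` ascending.
#'
#' @param surface a [ternary_surface()].
#' @param w a weight triple.
#' @return The member's score (possibly `NA`).
#' @export
lookup <- function(surface, w) {
  stopifnot(inherits(surface, "ternary_surface"))
  w <- weight_triple(w)
  if (nrow(surface$w) == 0L) stop("empty surface", call. = FALSE)
  d <- colSums((t(surface$w) - as.numeric(w))^2)
  cand <- which(d <= min(d) + 1e-12)
  if (length(cand) > 1L) {
    m <- surface$w[cand, , drop = FALSE]
    cand <- cand[order(m[, 1], m[, 2], m[, 3])]
  }
  surface$scores[cand[1]]
}

# Barycentric interpolation over the regular simplex lattice: locate the
# micro-triangle containing (a, b, c) * p and mix its three lattice corners.
interp_simplex <- function(score_lookup, p, a, b, c_) {
  f <- c(a, b, c_) * p
  i <- floor(f + 1e-9)
  i <- pmin(i, p)
  r <- f - i
  s <- sum(i)
  if (s >= p) {                       # lattice vertex (numerically)
    return(score_lookup(i[1], i[2]))
  } else if (s == p - 1) {            # upward micro-triangle
    v <- c(score_lookup(i[1] + 1, i[2]),
           score_lookup(i[1], i[2] + 1),
           score_lookup(i[1], i[2]))
    wt <- r
  } else {                            # downward micro-triangle
    v <- c(score_lookup(i[1], i[2] + 1),
           score_lookup(i[1] + 1, i[2]),
           score_lookup(i[1] + 1, i[2] + 1))
    wt <- 1 - r
  }
  if (anyNA(v)) return(NA_real_)
  sum(v * wt) / sum(wt)
}

#' Render a ternary shaded-surface diagram
#'
#' Draws the surface as a barycentrically interpolated shaded triangle with
#' axis labels, a color bar on the measure's scale and a title carrying the
#' fixed context.  Undefined scores render as gaps.  When `file` is given a
#' PNG device is opened (cairo backend), making repeated renders of the
#' same surface byte-identical.
#'
#' @param surface a [ternary_surface()].
#' @param file optional output PNG path; `NULL` draws on the active device.
#' @param resolution raster width in pixels for the shaded field.
#' @param palette colormap name passed to [grDevices::hcl.colors()].
#' @return The output path (or `NULL`), invisibly.
#' @export
render_ternary <- function(surface, file = NULL, resolution = 400,
                           palette = "viridis") {
  stopifnot(inherits(surface, "ternary_surface"))
  p <- surface$p
  idx <- matrix(NA_real_, p + 1, p + 1)
  ii <- as.integer(round(surface$w[, 1] * p))
  jj <- as.integer(round(surface$w[, 2] * p))
  idx[cbind(ii + 1L, jj + 1L)] <- surface$scores
  score_lookup <- function(i, j) {
    if (i < 0 || j < 0 || i + j > p) return(NA_real_)
    idx[i + 1L, j + 1L]
  }

  sc <- surface$scores[!is.na(surface$scores)]
  if (length(sc) == 0L) stop("surface has no defined scores", call. = FALSE)
  rng <- range(sc)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)   # constant field: center bar
  cols <- grDevices::hcl.colors(256, palette)

  nx <- as.integer(resolution)
  ny <- as.integer(round(resolution * sqrt(3) / 2))
  xs <- seq(0, 1, length.out = nx)
  ys <- seq(0, sqrt(3) / 2, length.out = ny)
  ras <- matrix(NA_character_, ny, nx)
  for (iy in seq_len(ny)) {
    wB <- ys[iy] / (sqrt(3) / 2)
    for (ix in seq_len(nx)) {
      wG <- xs[ix] - 0.5 * wB
      wR <- 1 - wG - wB
      if (wG < -1e-9 || wR < -1e-9) next
      val <- interp_simplex(score_lookup, p, max(wR, 0), max(wG, 0), wB)
      if (is.na(val)) next
      k <- 1L + as.integer(round(255 * (val - rng[1]) / diff(rng)))
      ras[ny - iy + 1L, ix] <- cols[min(max(k, 1L), 256L)]
    }
  }

  ctx <- surface$context
  main <- sprintf("%s | version %s, %s kernel, C = %g%s",
                  ctx$measure, ctx$version %||% "R", ctx$kernel %||% "?",
                  ctx$C,
                  if (!is.null(ctx$sigma) && !is.na(ctx$sigma))
                    sprintf(", sigma = %g", ctx$sigma) else "")
  if (!is.null(file))
    grDevices::png(file, width = 760, height = 640, type = "cairo")
  op <- graphics::par(mar = c(2, 2, 3, 6))
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.12, 1.25), ylim = c(-0.1, 0.97),
                        asp = 1)
  graphics::rasterImage(ras, 0, 0, 1, sqrt(3) / 2, interpolate = FALSE)
  tri <- TERNARY_VERTICES[c(1, 2, 3, 1), ]
  graphics::lines(tri[, 1], tri[, 2])
  graphics::text(-0.06, 0.48, "I_R", srt = 0)
  graphics::text(0.5, -0.07, "I_G")
  graphics::text(1.06, 0.48, "I_B")
  # arms annotated at their 0 and 1 ends per the axis convention
  graphics::text(c(0.46, 0.02), c(0.83, 0.05), c("0", "1"), cex = 0.7)
  graphics::text(c(0.05, 0.95), c(-0.04, -0.04), c("0", "1"), cex = 0.7)
  graphics::text(c(0.97, 0.53), c(0.02, 0.80), c("0", "1"), cex = 0.7)
  graphics::title(main = main, cex.main = 0.95)
  # color bar
  nbar <- 100
  ybar <- seq(0.05, 0.82, length.out = nbar + 1)
  graphics::rect(1.16, ybar[-(nbar + 1)], 1.21, ybar[-1],
                 col = cols[round(seq(1, 256, length.out = nbar))],
                 border = NA)
  graphics::rect(1.16, 0.05, 1.21, 0.82)
  ticks <- pretty(rng, 4)
  ticks <- ticks[ticks >= rng[1] & ticks <= rng[2]]
  ty <- 0.05 + (ticks - rng[1]) / diff(rng) * 0.77
  graphics::segments(1.21, ty, 1.23, ty)
  graphics::text(1.24, ty, format(ticks), adj = 0, cex = 0.7)
  invisible(file)
}
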