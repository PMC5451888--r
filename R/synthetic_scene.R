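# Synthetic vineyard-like scenes: Lambertian-shaded circular berries with a
# specular highlight over a low-frequency noise background.  Realism is not
# the goal; the generator provides class-discriminating gradient structure at
# the berry scale, with per-channel control of the berry/background contrast,
# so the detector pipeline can be exercised and tuned end to end.

WINDOW <- 40L   # object-image side in px

#' Parameters of the synthetic scene generator
#'
#' Berry centers are snapped to the half-integer pixel lattice so that a
#' 40 × 40 window can center a berry exactly; positional jitter of extracted
#' positives then maps to exact integer offsets.  The per-channel `contrast`
#' triple scales the berry/background intensity difference in each channel:
#' with contrast confined to one channel, the class signal lives in that
#' channel only, which is what the weight-recovery experiments exploit.
#'
#' @param width,height scene size in px; must leave a 40-px margin around the
#'   berry placement region.
#' @param n_berries number of berries to place.
#' @param diameter_range berry diameter bounds in px, within `[30, 40]`.
#' @param contrast length-3 non-negative triple: berry/background contrast in
#'   the red, green, blue channels.
#' @param bg_level mean background intensity (all channels).
#' @param bg_amplitude amplitude of the smoothed background noise.
#' @param bg_scale spatial scale (px) of the background texture.
#' @param min_gap_factor minimum allowed center distance between two berries,
#'   as a fraction of the sum of their radii (1 = no overlap, smaller values
#'   permit partial occlusion).
#' @param seed integer seed fixing all randomness of the scene.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(width = 320L, height = 320L, n_berries = 8L,
                         diameter_range = c(30, 40),
                         contrast = c(0.45, 0.50, 0.35),
                         bg_level = 0.30, bg_amplitude = 0.12, bg_scale = 8,
                         min_gap_factor = 1.0, seed = 1L) {
  if (diameter_range[1] < 30 || diameter_range[2] > 40 ||
      diameter_range[1] > diameter_range[2])
    stop("diameter_range must lie within [30, 40]", call. = FALSE)
  if (length(contrast) != 3L || any(contrast < 0))
    stop("contrast must be a non-negative triple", call. = FALSE)
  if (n_berries > 0 && (width < 3L * WINDOW || height < 3L * WINDOW))
    stop("scene too small to host berries with a 40-px margin", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_berries = as.integer(n_berries),
                 diameter_range = diameter_range, contrast = contrast,
                 bg_level = bg_level, bg_amplitude = bg_amplitude,
                 bg_scale = bg_scale, min_gap_factor = min_gap_factor,
                 seed = as.integer(seed)),
            class = "scene_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# bilinearly upsampled uniform noise: one smooth texture layer per channel
smooth_noise <- function(height, width, scale, amplitude) {
  gy <- max(2L, ceiling(height / scale) + 1L)
  gx <- max(2L, ceiling(width / scale) + 1L)
  coarse <- matrix(runif(gy * gx, -1, 1), gy, gx)
  ys <- seq(1, gy, length.out = height)
  xs <- seq(1, gx, length.out = width)
  y0 <- pmin(floor(ys), gy - 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), gx - 1L); fx <- xs - x0
  a <- coarse[y0, x0]; b <- coarse[y0, x0 + 1]
  c_ <- coarse[y0 + 1, x0]; d <- coarse[y0 + 1, x0 + 1]
  wy <- matrix(fy, height, width); wx <- matrix(fx, height, width, byrow = TRUE)
  amplitude * ((1 - wy) * ((1 - wx) * a + wx * b) +
               wy * ((1 - wx) * c_ + wx * d))
}

#' Generate a synthetic vineyard scene
#'
#' Renders a textured background with shaded circular berries and returns the
#' RGB image together with exact annotations.  Identical parameters (and
#' hence identical seed) give bit-identical output.
#'
#' @param params a [scene_params()].
#' @return A list of class `grape_scene`: `image` (RGB array) and
#'   `annotations` (data frame with `x`, `y`, `diameter`; `x` is the column
#'   and `y` the row coordinate of the berry center, on the half-integer
#'   lattice).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    h <- params$height; w <- params$width
    img <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3)
      img[, , ch] <- params$bg_level +
        smooth_noise(h, w, params$bg_scale, params$bg_amplitude)

    ann <- data.frame(x = numeric(0), y = numeric(0), diameter = numeric(0))
    if (params$n_berries > 0L) {
      margin <- WINDOW
      attempts <- 0L
      while (nrow(ann) < params$n_berries) {
        attempts <- attempts + 1L
        if (attempts > 10000L)
          stop("could not place ", params$n_berries,
               " berries without exceeding the overlap limit", call. = FALSE)
        d <- runif(1, params$diameter_range[1], params$diameter_range[2])
        cx <- floor(runif(1, margin, w - margin)) + 0.5
        cy <- floor(runif(1, margin, h - margin)) + 0.5
        if (nrow(ann) > 0) {
          mind <- params$min_gap_factor * (d / 2 + ann$diameter / 2)
          if (any(sqrt((ann$x - cx)^2 + (ann$y - cy)^2) < mind)) next
        }
        ann <- rbind(ann, data.frame(x = cx, y = cy, diameter = d))
      }
      for (k in seq_len(nrow(ann)))
        img <- render_berry(img, ann$x[k], ann$y[k], ann$diameter[k],
                            params$contrast)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, annotations = ann, params = params),
              class = "grape_scene")
  })
}

# Lambertian-shaded disc with an off-center highlight, blended over the
# background with a half-pixel anti-aliased rim.  The berry adds
# contrast[ch] * shape to channel ch, so a zero-contrast channel carries no
# berry signal at all.
render_berry <- function(img, cx, cy, diameter, contrast) {
  r <- diameter / 2
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- max(1L, floor(cy - r - 1)); r1 <- min(h, ceiling(cy + r + 1))
  c0 <- max(1L, floor(cx - r - 1)); c1 <- min(w, ceiling(cx + r + 1))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  alpha <- pmin(pmax(r - rho + 0.5, 0), 1)     # soft half-pixel rim
  inside <- alpha > 0
  if (!any(inside)) return(img)
  shade <- sqrt(pmax(1 - (rho / r)^2, 0))
  hx <- cx - 0.3 * r; hy <- cy - 0.3 * r
  highlight <- exp(-(((cols[col(rho)] - hx)^2 + (rows[row(rho)] - hy)^2) /
                      (0.25 * r)^2))
  shape <- 0.25 + 0.75 * shade + 0.5 * highlight
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane <- plane + alpha * contrast[ch] * shape
    img[rows, cols, ch] <- plane
  }
  img
}

# window top-left corner such that the window center coincides with (cx, cy):
# a 40-px window spanning rows r0 .. r0+39 has center r0 + 19.5
aligned_corner <- function(c_half) as.integer(round(c_half - (WINDOW - 1) / 2))

window_in_scene <- function(scene, r0, c0) {
  r0 >= 1L && c0 >= 1L &&
    r0 + WINDOW - 1L <= dim(scene$image)[1] &&
    c0 + WINDOW - 1L <= dim(scene$image)[2]
}

crop_window <- function(scene, r0, c0) {
  scene$image[r0:(r0 + WINDOW - 1L), c0:(c0 + WINDOW - 1L), , drop = FALSE]
}

#' Geometric window classification oracle
#'
#' Independent predicate used to audit extracted samples: a window is
#' "positive" iff some berry of in-range diameter has its center within
#' ±1 px (Chebyshev) of the window center; otherwise it is "negative", of
#' kind `"environment"` when no pixel of the window lies inside any closed
#' berry disc and `"grape"` when some disc is touched.
#'
#' @param annotations scene annotation data frame.
#' @param r0,c0 window top-left corner (row, column, 1-based).
#' @param diameter_range admissible berry diameters.
#' @return A list with `label` (`"positive"`/`"negative"`) and `kind`
#'   (`"environment"`, `"grape"`, or `"none"` for positives).
#' @export
classify_window <- function(annotations, r0, c0, diameter_range = c(30, 40)) {
  ctr_y <- r0 + (WINDOW - 1) / 2
  ctr_x <- c0 + (WINDOW - 1) / 2
  if (nrow(annotations) == 0L)
    return(list(label = "negative", kind = "environment"))
  in_range <- annotations$diameter >= diameter_range[1] &
              annotations$diameter <= diameter_range[2]
  off <- pmax(abs(annotations$x - ctr_x), abs(annotations$y - ctr_y))
  if (any(in_range & off <= 1 + 1e-9))
    return(list(label = "positive", kind = "none"))
  # closed-disc overlap against the pixel-center footprint of the window
  dx <- pmax(c0 - annotations$x, 0, annotations$x - (c0 + WINDOW - 1L))
  dy <- pmax(r0 - annotations$y, 0, annotations$y - (r0 + WINDOW - 1L))
  touches <- sqrt(dx^2 + dy^2) <= annotations$diameter / 2
  list(label = "negative", kind = if (any(touches)) "grape" else "environment")
}

#' Extract a centered positive object image
#'
#' Cuts the 40 × 40 window whose center coincides with the annotated berry
#' center, displaced by an integer `jitter` with Chebyshev norm at most 1 —
#' the class tolerance: a berry off-center by more than 1 px is no longer a
#' positive sample.
#'
#' @param scene a [generate_scene()] result.
#' @param annotation one-row slice of `scene$annotations`.
#' @param jitter integer offset `c(dx, dy)` with `max(abs(jitter)) <= 1`.
#' @return A `labelled_sample` (see [labelled_sample()]).
#' @export
extract_positive <- function(scene, annotation, jitter = c(0L, 0L)) {
  jitter <- as.integer(jitter)
  if (length(jitter) != 2L || max(abs(jitter)) > 1L)
    stop("jitter must be an integer offset with Chebyshev norm <= 1",
         call. = FALSE)
  r0 <- aligned_corner(annotation$y) + jitter[2]
  c0 <- aligned_corner(annotation$x) + jitter[1]
  if (!window_in_scene(scene, r0, c0))
    stop("positive window out of scene bounds", call. = FALSE)
  s <- labelled_sample(crop_window(scene, r0, c0), "positive", kind = "none")
  s$corner <- c(r0 = r0, c0 = c0)   # provenance for geometric audits
  s
}

#' Extract a negative object image
#'
#' Environment-kind negatives share no pixel with any closed berry disc;
#' grape-kind negatives touch a berry disc of in-range diameter while
#' violating the positive criteria (center off by more than 1 px).  Windows
#' are found by rejection sampling from the current RNG stream, capped at
#' `max_attempts`.
#'
#' @param scene a [generate_scene()] result.
#' @param kind `"environment"` or `"grape"`.
#' @param max_attempts rejection-sampling cap.
#' @return A `labelled_sample`.
#' @export
extract_negative <- function(scene, kind = c("environment", "grape"),
                             max_attempts = 10000L) {
  kind <- match.arg(kind)
  ann <- scene$annotations
  h <- dim(scene$image)[1]; w <- dim(scene$image)[2]
  if (kind == "grape" && nrow(ann) == 0L)
    stop("no berries in scene: grape-kind negatives infeasible", call. = FALSE)
  for (i in seq_len(max_attempts)) {
    if (kind == "grape") {
      k <- sample.int(nrow(ann), 1L)
      r0 <- aligned_corner(ann$y[k]) + sample(c(-18:-2, 2:18), 1L)
      c0 <- aligned_corner(ann$x[k]) + sample(c(-18:-2, 2:18), 1L)
    } else {
      r0 <- sample.int(h - WINDOW + 1L, 1L)
      c0 <- sample.int(w - WINDOW + 1L, 1L)
    }
    if (!window_in_scene(scene, r0, c0)) next
    cls <- classify_window(ann, r0, c0)
    if (cls$label == "negative" && cls$kind == kind) {
      s <- labelled_sample(crop_window(scene, r0, c0), "negative",
                           kind = kind)
      s$corner <- c(r0 = r0, c0 = c0)
      return(s)
    }
  }
  stop("no feasible ", kind, "-kind negative window after ",
       max_attempts, " attempts", call. = FALSE)
}
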