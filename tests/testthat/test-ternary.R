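# Barycentric mapping, surface lookup and ternary rendering.

test_that("the barycentric map sends vertices, centroid and axes correctly", {
  vr <- barycentric_to_cartesian(c(1, 0, 0))
  vg <- barycentric_to_cartesian(c(0, 1, 0))
  vb <- barycentric_to_cartesian(c(0, 0, 1))
  expect_equal(as.numeric(vr), c(0, 0))
  expect_equal(as.numeric(vg), c(1, 0))
  expect_equal(as.numeric(vb), c(0.5, sqrt(3) / 2))
  # equilateral: all side lengths equal
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_equal(d(vr, vg), d(vg, vb))
  expect_equal(d(vg, vb), d(vb, vr))

  ctr <- barycentric_to_cartesian(c(1, 1, 1) / 3)
  expect_equal(as.numeric(ctr), as.numeric((vr + vg + vb) / 3))

  # axis convention: wR increases downwards along the left arm,
  # wG rightwards along the bottom, wB upwards along the right arm
  left_lo <- barycentric_to_cartesian(c(0.2, 0, 0.8))
  left_hi <- barycentric_to_cartesian(c(0.8, 0, 0.2))
  expect_lt(left_hi[, "y"], left_lo[, "y"])
  bot_lo <- barycentric_to_cartesian(c(0.8, 0.2, 0))
  bot_hi <- barycentric_to_cartesian(c(0.2, 0.8, 0))
  expect_gt(bot_hi[, "x"], bot_lo[, "x"])
  right_lo <- barycentric_to_cartesian(c(0, 0.8, 0.2))
  right_hi <- barycentric_to_cartesian(c(0, 0.2, 0.8))
  expect_gt(right_hi[, "y"], right_lo[, "y"])
})

test_that("the map is affine: midpoints map to midpoints", {
  set.seed(95)
  for (i in 1:10) {
    a <- diff(c(0, sort(runif(2)), 1))
    b <- diff(c(0, sort(runif(2)), 1))
    mid <- (a + b) / 2
    expect_equal(barycentric_to_cartesian(mid),
                 (barycentric_to_cartesian(a) + barycentric_to_cartesian(b)) / 2)
  }
  # worked auxiliary-line example: the reading point of (0.1, 0.2, 0.7)
  pt <- barycentric_to_cartesian(c(0.1, 0.2, 0.7))
  expect_equal(as.numeric(pt), as.numeric(
    0.1 * barycentric_to_cartesian(c(1, 0, 0)) +
    0.2 * barycentric_to_cartesian(c(0, 1, 0)) +
    0.7 * barycentric_to_cartesian(c(0, 0, 1))))
})

make_surface <- function(scores = NULL, p = 2) {
  W <- simplex_grid(p)$w
  rec <- data.frame(C = 10, sigma = 30, wR = W[, 1], wG = W[, 2], wB = W[, 3])
  rec$accuracy <- scores %||% (80 + 10 * rec$wR)
  rec$recall <- 0.9; rec$precision <- 0.9
  attr(rec, "version") <- "R"; attr(rec, "kernel") <- "rbf"
  ternary_surface(rec, "accuracy", C = 10, sigma = 30)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("surface lookup returns the nearest grid member's score", {
  surf <- make_surface()
  # exact hits
  for (i in seq_len(nrow(surf$w)))
    expect_equal(lookup(surf, surf$w[i, ]), surf$scores[i])
  # off-grid: brute-force nearest member
  set.seed(96)
  for (i in 1:20) {
    w <- diff(c(0, sort(runif(2)), 1))
    d <- colSums((t(surf$w) - w)^2)
    expect_equal(lookup(surf, w), surf$scores[which.min(d)])
  }
  # centroid of a symmetric (constant) surface
  flat <- make_surface(scores = 85)
  expect_equal(lookup(flat, c(1, 1, 1) / 3), 85)
})

test_that("rendering is deterministic and handles constant and patchy fields", {
  surf <- make_surface(p = 4)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_ternary(surf, file = f1, resolution = 160)
  render_ternary(surf, file = f2, resolution = 160)
  expect_true(file.exists(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  flat <- make_surface(scores = 85)
  f3 <- withr::local_tempfile(fileext = ".png")
  render_ternary(flat, file = f3, resolution = 120)
  expect_gt(file.info(f3)$size, 0)

  # chance-level patchwork (the anomaly pattern) renders without error
  W <- simplex_grid(4)$w
  patch <- ifelse(W[, 1] %in% c(0, 1), 95, 50)
  f4 <- withr::local_tempfile(fileext = ".png")
  render_ternary(make_surface(scores = patch, p = 4), file = f4,
                 resolution = 120)
  expect_gt(file.info(f4)$size, 0)
})

test_that("re-sampling the rendered field at members recovers their scores", {
  surf <- make_surface(p = 2)
  # interpolation at lattice points must reproduce the member scores
  idx <- matrix(NA_real_, surf$p + 1, surf$p + 1)
  idx[cbind(round(surf$w[, 1] * surf$p) + 1,
            round(surf$w[, 2] * surf$p) + 1)] <- surf$scores
  sl <- function(i, j) {
    if (i < 0 || j < 0 || i + j > surf$p) return(NA_real_)
    idx[i + 1, j + 1]
  }
  for (k in seq_len(nrow(surf$w)))
    expect_equal(grapedetect:::interp_simplex(sl, surf$p, surf$w[k, 1],
                                              surf$w[k, 2], surf$w[k, 3]),
                 surf$scores[k])
  # and between members it interpolates linearly along an edge
  mid <- grapedetect:::interp_simplex(sl, surf$p, 0.25, 0.75, 0)
  expect_equal(mid, (idx[1 + 0, 1 + 2] + idx[1 + 1, 1 + 1]) / 2)
})
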