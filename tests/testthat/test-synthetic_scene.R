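# Synthetic vineyard scenes and object-image extraction.

test_that("scene generation is deterministic and honours its bounds", {
  p <- scene_params(seed = 5, n_berries = 6)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$annotations, s2$annotations)
  expect_true(all(s1$annotations$diameter >= 30 &
                  s1$annotations$diameter <= 40))
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  empty <- generate_scene(scene_params(seed = 5, n_berries = 0,
                                       width = 100, height = 100))
  expect_equal(nrow(empty$annotations), 0L)
  expect_error(scene_params(width = 100, height = 100, n_berries = 2),
               "margin")
})

test_that("positive extraction centers the berry within the 1 px tolerance", {
  sc <- fixture_scene()
  ann <- sc$annotations[1, ]
  s0 <- extract_positive(sc, ann, jitter = c(0, 0))
  expect_equal(dim(s0$image), c(40L, 40L, 3L))
  expect_equal(s0$label, "positive")
  # centered case: window center coincides with the annotated center
  r0 <- grapedetect:::aligned_corner(ann$y)
  c0 <- grapedetect:::aligned_corner(ann$x)
  expect_equal(c(c0 + 19.5, r0 + 19.5), c(ann$x, ann$y))

  s1 <- extract_positive(sc, ann, jitter = c(1, 0))
  expect_equal(s1$label, "positive")
  expect_error(extract_positive(sc, ann, jitter = c(2, 0)), "Chebyshev")
})

test_that("negative windows satisfy their kind's disc geometry", {
  sc <- fixture_scene()
  ann <- sc$annotations
  # independent disc/window algebra on the recorded window corners
  overlaps <- function(r0, c0) {
    dx <- pmax(c0 - ann$x, 0, ann$x - (c0 + 39))
    dy <- pmax(r0 - ann$y, 0, ann$y - (r0 + 39))
    sqrt(dx^2 + dy^2) <= ann$diameter / 2
  }
  off_center <- function(r0, c0)
    pmax(abs(ann$x - (c0 + 19.5)), abs(ann$y - (r0 + 19.5)))
  set.seed(82)
  for (i in 1:25) {
    env <- extract_negative(sc, "environment")
    expect_false(any(overlaps(env$corner["r0"], env$corner["c0"])))
    grape <- extract_negative(sc, "grape")
    expect_true(any(overlaps(grape$corner["r0"], grape$corner["c0"])))
    expect_true(all(off_center(grape$corner["r0"], grape$corner["c0"]) > 1))
  }
  # a window centered 5 px off a berry center is a valid grape-kind negative
  k <- 1L
  r0 <- grapedetect:::aligned_corner(ann$y[k]) + 5L
  c0 <- grapedetect:::aligned_corner(ann$x[k])
  cls <- classify_window(ann, r0, c0)
  expect_equal(cls$label, "negative")
  expect_equal(cls$kind, "grape")
})

test_that("the labelling oracle agrees with extraction on random windows", {
  sc <- fixture_scene()
  ann <- sc$annotations
  set.seed(83)
  n_checked <- 0L
  for (i in 1:400) {
    r0 <- sample.int(dim(sc$image)[1] - 39, 1)
    c0 <- sample.int(dim(sc$image)[2] - 39, 1)
    cls <- classify_window(ann, r0, c0)
    # independent re-derivation with plain disc algebra
    off <- pmax(abs(ann$x - (c0 + 19.5)), abs(ann$y - (r0 + 19.5)))
    is_pos <- any(off <= 1 & ann$diameter >= 30 & ann$diameter <= 40)
    dx <- pmax(c0 - ann$x, 0, ann$x - (c0 + 39))
    dy <- pmax(r0 - ann$y, 0, ann$y - (r0 + 39))
    touches <- any(sqrt(dx^2 + dy^2) <= ann$diameter / 2)
    expect_equal(cls$label, if (is_pos) "positive" else "negative")
    if (!is_pos)
      expect_equal(cls$kind, if (touches) "grape" else "environment")
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 400L)
})

test_that("infeasible extraction requests fail cleanly", {
  empty <- generate_scene(scene_params(seed = 9, n_berries = 0,
                                       width = 100, height = 100))
  expect_error(extract_negative(empty, "grape"), "infeasible")
  # environment windows are infeasible when discs blanket the scene
  centers <- expand.grid(x = seq(0.5, 120, by = 20),
                         y = seq(0.5, 120, by = 20))
  blanket <- structure(list(
    image = array(0.5, dim = c(120, 120, 3)),
    annotations = data.frame(x = centers$x, y = centers$y, diameter = 40)),
    class = "grape_scene")
  set.seed(84)
  expect_error(extract_negative(blanket, "environment", max_attempts = 200L),
               "no feasible")
})

test_that("channel-confined contrast separates classes most in that channel", {
  pf <- function(s) scene_params(n_berries = 10, contrast = c(0.5, 0, 0),
                                 seed = s)
  pool <- synth_pool(n_pos = 15, n_env = 15, n_grape = 0, seed = 90,
                     params_fn = pf)
  ch_mean <- function(s, ch) mean(s$image[, , ch])
  sep <- vapply(1:3, function(ch) {
    abs(mean(vapply(pool$positives, ch_mean, numeric(1), ch)) -
        mean(vapply(pool$negatives, ch_mean, numeric(1), ch)))
  }, numeric(1))
  expect_equal(which.max(sep), 1L)
  expect_gt(sep[1], 5 * max(sep[2:3]))
})
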