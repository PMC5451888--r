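# Shared fixtures, built once per test run.  All synthetic, all seeded.

.fixtures <- new.env()

# small mixed-contrast pool for generic detector tests
fixture_pool <- function() {
  if (is.null(.fixtures$pool))
    .fixtures$pool <- synth_pool(n_pos = 12, n_env = 8, n_grape = 8, seed = 77)
  .fixtures$pool
}

# one deterministic scene with several berries
fixture_scene <- function() {
  if (is.null(.fixtures$scene))
    .fixtures$scene <- generate_scene(scene_params(seed = 303))
  .fixtures$scene
}

# a random RGB image on the 8-bit grid (so PNG round trips are exact)
random_rgb <- function(h = 40, w = 40, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE) / 255, dim = c(h, w, 3))
}

# tiny disjoint train/tuning sets built from disjoint scene seed ranges
fixture_sets <- function(contrast = c(0.45, 0.5, 0.35), seed = 1000,
                         n_pos = 8, n_neg = 16) {
  pf <- function(s) scene_params(n_berries = 10, contrast = contrast, seed = s)
  tr_pool <- synth_pool(n_pos, n_neg / 2, n_neg / 2, seed = seed,
                        params_fn = pf)
  tu_pool <- synth_pool(n_pos, n_neg / 2, n_neg / 2, seed = seed + 500,
                        params_fn = pf)
  list(
    train = build_set("T", tr_pool$positives,
                      tr_pool$negatives[seq_len(n_pos)], name = "train"),
    tune = build_set("tuning", tu_pool$positives, tu_pool$negatives,
                     name = "tune")
  )
}

# 2-D toy point clouds for classifier contract tests
toy_separable <- function(n = 20, gap = 2, seed = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n, -gap, 0.5), ncol = 2),
             matrix(rnorm(2 * n, gap, 0.5), ncol = 2))
  list(x = x, y = rep(c("negative", "positive"), each = n))
}
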