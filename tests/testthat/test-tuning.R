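# Simplex grid, sweep bookkeeping, anomaly filtering and optimum selection.

# brute-force lattice oracle: all integer triples summing to p
brute_simplex <- function(p) {
  g <- expand.grid(i = 0:p, j = 0:p)
  g <- g[g$i + g$j <= p, ]
  cbind(g$i, g$j, p - g$i - g$j) / p
}

test_that("simplex grid enumerates the lattice exactly", {
  g1 <- simplex_grid(1)
  expect_equal(nrow(g1$w), 3L)
  expect_true(all(apply(g1$w, 1, function(r) any(r == 1))))

  expect_equal(nrow(simplex_grid(2)$w), nrow(brute_simplex(2)))

  for (p in c(3, 7, 12, 20, 30)) {
    g <- simplex_grid(p)
    oracle <- brute_simplex(p)
    expect_equal(nrow(g$w), (p + 1) * (p + 2) / 2)
    expect_equal(nrow(g$w), nrow(oracle))
    # same member set regardless of enumeration order
    expect_setequal(apply(round(g$w * p), 1, paste, collapse = ","),
                    apply(round(oracle * p), 1, paste, collapse = ","))
    expect_true(all(rowSums(g$w) == 1))            # exact, rational build
    expect_false(any(duplicated(g$w)))
  }
  expect_error(simplex_grid(0), "positive integer")
})

test_that("the step-0.05 lattice contains the tuned optimum weights", {
  g <- simplex_grid(20)
  expect_equal(nrow(g$w), 231L)
  expect_true(any(g$w[, 1] == 0.95 & g$w[, 2] == 0.05 & g$w[, 3] == 0))
})

test_that("setting enumeration matches the Cartesian structure", {
  space <- parameter_space(X_C = c(1, 10, 100, 1000),
                           X_sigma = c(1, 10, 20, 30, 40, 100),
                           W = simplex_grid(20))
  th <- enumerate_settings(space, version = "R", kernel = "rbf")
  expect_equal(nrow(th), 4L * 6L * 231L)
  th_s1 <- enumerate_settings(space, version = "S1", kernel = "rbf")
  expect_equal(nrow(th_s1), 4L * 6L)
  th_lin <- enumerate_settings(space, version = "R", kernel = "linear")
  expect_equal(nrow(th_lin), 4L * 231L)
  expect_true(all(is.na(th_lin$sigma)))
})

test_that("sweeps are deterministic, cacheable and leakage-guarded", {
  sets <- fixture_sets()
  space <- parameter_space(X_C = c(1, 10), X_sigma = c(10, 30),
                           W = simplex_grid(1))
  cache <- withr::local_tempdir()
  r1 <- sweep_settings(sets$train, sets$tune, space, version = "R",
                       kernel = "rbf", cache_dir = cache)
  expect_equal(nrow(r1), 2L * 2L * 3L)
  r2 <- sweep_settings(sets$train, sets$tune, space, version = "R",
                       kernel = "rbf", cache_dir = cache)
  expect_equal(r1, r2)
  # scores are recomputable from the stored confusion counts
  for (i in seq_len(nrow(r1))) {
    cc <- list(TP = r1$TP[i], FN = r1$FN[i], FP = r1$FP[i], TN = r1$TN[i])
    expect_equal(r1$accuracy[i], accuracy(cc))
  }

  r3 <- sweep_settings(sets$train, sets$tune, space, version = "S1",
                       kernel = "rbf")
  expect_equal(nrow(r3), 4L)   # degenerate simplex for fixed conversion

  expect_error(sweep_settings(sets$train, sets$train, space), "leakage")
})

# hand-built record table with the full (C, sigma) x W structure
fixture_records <- function() {
  W <- simplex_grid(2)$w
  grid <- expand.grid(iw = seq_len(nrow(W)), sigma = c(1, 10), C = c(1, 10))
  rec <- data.frame(C = grid$C, sigma = grid$sigma,
                    wR = W[grid$iw, 1], wG = W[grid$iw, 2],
                    wB = W[grid$iw, 3])
  # sigma = 1 surfaces: chance level almost everywhere (the anomaly pattern)
  rec$accuracy <- ifelse(rec$sigma == 1,
                         ifelse(rec$wR == 1, 95, 50),
                         85 + 5 * rec$wR)
  # recall peaks with red weight; precision is flat
  rec$recall <- ifelse(rec$sigma == 1, 0.5, 0.80 + 0.1 * rec$wR)
  rec$precision <- 0.97
  rec$TP <- rec$FN <- rec$FP <- rec$TN <- 1L
  rec
}

test_that("chance-level surfaces are eliminated; permissive threshold keeps all", {
  rec <- fixture_records()
  flt <- filter_anomalous(rec, threshold = 0.5)
  expect_equal(sort(unique(flt$eliminated$sigma)), 1)
  expect_equal(sort(unique(flt$records$sigma)), 10)
  expect_gt(min(flt$records$accuracy), 80)

  none <- filter_anomalous(rec, threshold = 1.0)
  expect_equal(nrow(none$records), nrow(rec))

  allbad <- rec; allbad$accuracy <- 50
  expect_error(filter_anomalous(allbad), "eliminated")
  expect_error(filter_anomalous(rec[-1, ]), "Cartesian")
})

test_that("per-measure argmax honours scores, ties and undefined values", {
  rec <- fixture_records()
  flt <- filter_anomalous(rec)$records
  best <- best_per_measure(flt, "accuracy")
  expect_equal(best$wR, 1)
  # peaked fixture mirroring the headline optimum
  rec2 <- expand.grid(C = c(1, 10), sigma = c(10, 30),
                      wR = c(0, 0.95), KEEP.OUT.ATTRS = FALSE)
  rec2$wG <- ifelse(rec2$wR == 0.95, 0.05, 1 - rec2$wR)
  rec2$wB <- 0
  rec2$accuracy <- ifelse(rec2$C == 10 & rec2$sigma == 30 & rec2$wR == 0.95,
                          97.8, 90)
  top <- best_per_measure(rec2, "accuracy")
  expect_equal(unlist(top[c("C", "sigma", "wR", "wG", "wB")]),
               c(C = 10, sigma = 30, wR = 0.95, wG = 0.05, wB = 0))

  # tie broken lexicographically by (C, sigma, w) ascending
  tie <- rec2; tie$accuracy <- 90
  t1 <- best_per_measure(tie, "accuracy")
  expect_equal(unlist(t1[c("C", "sigma", "wR")]), c(C = 1, sigma = 10, wR = 0))

  und <- rec2; und$precision <- NA_real_
  expect_error(best_per_measure(und, "precision"), "undefined")
})

test_that("global selection drops flat measures and resolves by priority", {
  rec <- filter_anomalous(fixture_records())$records
  sel <- select_global(rec, measure_set(c("accuracy", "recall", "precision")))
  expect_false("precision" %in% names(sel$optima))   # flat: abandoned
  expect_true(all(c("accuracy", "recall") %in% names(sel$optima)))
  expect_equal(sel$theta$wR, 1)

  # optima agree on (C, w) but differ in sigma: sigma from the top priority
  rec2 <- expand.grid(C = 10, sigma = c(30, 40), wR = c(0, 0.95),
                      KEEP.OUT.ATTRS = FALSE)
  rec2$wG <- 1 - rec2$wR; rec2$wB <- 0
  rec2$accuracy <- c(90, 90, 97, 96)    # accuracy argmax at sigma = 30
  rec2$recall <- c(0.80, 0.80, 0.90, 0.91)  # recall argmax at sigma = 40
  sel2 <- select_global(rec2, measure_set(c("accuracy", "recall")))
  expect_equal(sel2$theta$sigma, 30)
  expect_equal(sel2$theta$wR, 0.95)
  tr <- sel2$trace
  expect_equal(tr$source[tr$coordinate == "sigma"], "priority:accuracy")
  expect_equal(tr$source[tr$coordinate == "wR"], "agreement")

  # single retained measure: theta* is its optimum
  sel3 <- select_global(rec2, measure_set("recall"))
  expect_equal(sel3$theta$sigma, 40)

  # identical optima for all retained measures
  rec3 <- rec2; rec3$recall <- c(0.80, 0.80, 0.91, 0.90)
  sel4 <- select_global(rec3, measure_set(c("accuracy", "recall")))
  expect_true(all(sel4$trace$source == "agreement"))

  flat <- rec2; flat$accuracy <- 90; flat$recall <- 0.9
  expect_error(select_global(flat, measure_set(c("accuracy", "recall"))),
               "no measure discriminates")
})

test_that("tuning recovers a blue-channel-confined signal (linear kernel)", {
  pf <- function(s) scene_params(n_berries = 10, contrast = c(0, 0, 0.35),
                                 bg_amplitude = 0.25, bg_scale = 4, seed = s)
  tr <- synth_pool(25, 25, 25, seed = 7000, params_fn = pf)
  tu <- synth_pool(25, 25, 25, seed = 7500, params_fn = pf)
  train <- build_set("T", tr$positives, tr$negatives[1:25], name = "blue-train")
  tune <- build_set("tuning", tu$positives, tu$negatives, name = "blue-tune")
  space <- parameter_space(X_C = c(1, 10), X_sigma = NULL, W = simplex_grid(5))
  fit <- tune_detector(train, tune, space, version = "R", kernel = "linear")
  th <- fit$theta_star
  expect_equal(max(c(th$wR, th$wG, th$wB)), th$wB)
  expect_output(print(fit), "theta\\*")
  expect_output(summary(fit), "per-measure optima")
})
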