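# Constrained-grid tuning of the detector: a simplex lattice over the
# conversion weights crossed with grids over C (and sigma for the Gaussian
# kernel), a training-evaluation sweep, elimination of anomalous kernel
# settings, per-measure argmax and priority-based global selection.

#' Simplex lattice over the conversion weights
#'
#' All weight triples whose coordinates are integer multiples of the step
#' `1/p` and sum to one: triples `(i/p, j/p, k/p)` with `i + j + k = p`,
#' enumerated in lexicographic order of `(i, j)`.  The lattice has
#' `(p + 1)(p + 2) / 2` members; coordinates are constructed from the
#' integers, so every member satisfies the simplex constraint exactly.
#'
#' @param p lattice resolution (step `1/p`), a positive integer.
#' @return A list of class `simplex_grid` with `p`, `step`, and `w` (a
#'   members × 3 matrix with columns `wR`, `wG`, `wB`).
#' @examples
#' simplex_grid(1)$w            # the three simplex vertices
#' nrow(simplex_grid(20)$w)     # 231 admissible triples at step 0.05
#' @export
simplex_grid <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    stop("p must be a positive integer", call. = FALSE)
  p <- as.integer(p)
  ij <- do.call(rbind, lapply(0:p, function(i)
    cbind(i = i, j = 0:(p - i))))
  w <- cbind(wR = ij[, "i"] / p, wG = ij[, "j"] / p,
             wB = (p - ij[, "i"] - ij[, "j"]) / p)
  structure(list(p = p, step = 1 / p, w = w), class = "simplex_grid")
}

#' Parameter space for the tuning sweep
#'
#' The Cartesian product of the admissible regularization constants, kernel
#' widths (Gaussian kernel only) and the weight lattice.  Versions other
#' than `R` carry no weights and the linear kernel no sigma; the respective
#' axes collapse when the space is enumerated.
#'
#' @param X_C positive regularization constants.
#' @param X_sigma positive kernel widths (`NULL` for the linear kernel).
#' @param W a [simplex_grid()] (or `p` to build one).
#' @return A list of class `parameter_space`.
#' @export
parameter_space <- function(X_C = c(1, 10, 100, 1000),
                            X_sigma = c(1, 10, 20, 30, 40, 100),
                            W = simplex_grid(20)) {
  if (length(X_C) == 0L || any(X_C <= 0))
    stop("X_C must be non-empty and positive", call. = FALSE)
  if (!is.null(X_sigma) && any(X_sigma <= 0))
    stop("X_sigma must be positive", call. = FALSE)
  if (is.numeric(W) && length(W) == 1L) W <- simplex_grid(W)
  stopifnot(inherits(W, "simplex_grid"))
  structure(list(X_C = X_C, X_sigma = X_sigma, W = W),
            class = "parameter_space")
}

#' Enumerate detector settings theta from a parameter space
#'
#' One row per setting `theta = (C, sigma, w)`: the full Cartesian product
#' for version `R` with the Gaussian kernel, degenerating to `C x sigma` for
#' fixed-conversion versions and to `C` alone for the linear kernel.
#'
#' @param space a [parameter_space()].
#' @param version version tag (`"R"` uses the weight lattice; others ignore
#'   it).
#' @param kernel `"rbf"` or `"linear"` (linear ignores `X_sigma`).
#' @return Data frame with columns `C`, `sigma`, `wR`, `wG`, `wB` (NA where
#'   the axis does not apply).
#' @export
enumerate_settings <- function(space, version = "R", kernel = "rbf") {
  stopifnot(inherits(space, "parameter_space"))
  sig <- if (kernel == "rbf") {
    if (is.null(space$X_sigma) || length(space$X_sigma) == 0L)
      stop("rbf kernel requires a sigma grid", call. = FALSE)
    space$X_sigma
  } else NA_real_
  if (version == "R") {
    wgrid <- space$W$w
  } else {
    wgrid <- matrix(NA_real_, 1L, 3L,
                    dimnames = list(NULL, c("wR", "wG", "wB")))
  }
  grid <- expand.grid(iw = seq_len(nrow(wgrid)), sigma = sig, C = space$X_C,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(C = grid$C, sigma = grid$sigma,
             wR = wgrid[grid$iw, "wR"], wG = wgrid[grid$iw, "wG"],
             wB = wgrid[grid$iw, "wB"])
}

#' Number of performance surfaces a sweep produces
#'
#' One ternary (or degenerate) surface per combination of measure,
#' regularization constant and kernel width: `|M| * |X_C| * |X_sigma|` for
#' the Gaussian kernel and `|M| * |X_C|` for the linear kernel.
#'
#' @param space a [parameter_space()].
#' @param measures a [measure_set()].
#' @param kernel `"rbf"` or `"linear"`.
#' @return Integer surface count.
#' @export
n_surfaces <- function(space, measures, kernel = "rbf") {
  stopifnot(inherits(space, "parameter_space"))
  ns <- if (kernel == "rbf") length(space$X_sigma) else 1L
  as.integer(length(measures) * length(space$X_C) * ns)
}

#' Training-evaluation sweep over a parameter space
#'
#' For every setting theta: preprocess the training images under the
#' version (with theta's weights for version `R`), extract HOG features,
#' train the SVM at `(C, sigma)`, predict the tuning set and record the
#' confusion counts and all measures.  Features are computed once per
#' distinct weight triple and reused across the `(C, sigma)` grid.  Records
#' can be cached on disk (keyed by a content hash of the train/tune sets,
#' version, theta and HOG parameters) so an interrupted sweep resumes.
#'
#' @param train,tune disjoint `sample_set`s (overlap by content is an
#'   error).
#' @param space a [parameter_space()].
#' @param measures a [measure_set()].
#' @param version version tag or [detector_version()] (weights are supplied
#'   by the sweep for version `R`).
#' @param kernel `"rbf"` or `"linear"`.
#' @param hog a [hog_params()].
#' @param cache_dir optional directory for per-theta record caching.
#' @param verbose print progress per weight triple.
#' @return Data frame of evaluation records: theta columns, confusion
#'   counts, and one column per measure.
#' @export
sweep_settings <- function(train, tune, space,
                           measures = measure_set(),
                           version = "R", kernel = c("rbf", "linear"),
                           hog = hog_params(), cache_dir = NULL,
                           verbose = FALSE) {
  kernel <- match.arg(kernel)
  if (inherits(version, "detector_version")) version <- version$tag
  measures <- measure_set(measures)
  assert_disjoint(train, tune)
  thetas <- enumerate_settings(space, version, kernel)
  train_imgs <- set_images(train); train_y <- set_labels(train)
  tune_imgs <- set_images(tune); tune_y <- set_labels(tune)
  cache_base <- if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    list(train = set_ids(train), tune = set_ids(tune), hog = unclass(hog),
         version = version, kernel = kernel)
  }

  wkey <- paste(thetas$wR, thetas$wG, thetas$wB)
  records <- vector("list", nrow(thetas))
  for (wk in unique(wkey)) {
    rows <- which(wkey == wk)
    w <- unlist(thetas[rows[1], c("wR", "wG", "wB")])
    ver <- if (version == "R") detector_version("R", w)
           else detector_version(version)
    ftr <- NULL; fte <- NULL   # lazily computed; skipped on full cache hit
    for (r in rows) {
      th <- thetas[r, ]
      rec <- NULL
      cache_file <- NULL
      if (!is.null(cache_base)) {
        key <- serialize_key(c(cache_base, as.list(th)))
        cache_file <- file.path(cache_dir, paste0(key, ".rds"))
        if (file.exists(cache_file)) rec <- readRDS(cache_file)
      }
      if (is.null(rec)) {
        if (is.null(ftr)) {
          ftr <- detector_features(train_imgs, ver, hog)
          fte <- detector_features(tune_imgs, ver, hog)
        }
        ks <- kernel_spec(kernel, sigma = if (kernel == "rbf") th$sigma)
        fit <- train_svm(ftr, train_y, ks, th$C)
        pred <- predict_svm(fit, fte)
        counts <- confusion(tune_y, pred)
        rec <- cbind(th, TP = counts$TP, FN = counts$FN, FP = counts$FP,
                     TN = counts$TN,
                     accuracy = accuracy(counts),
                     precision = precision(counts),
                     recall = recall(counts))
        if (!is.null(cache_file)) saveRDS(rec, cache_file)
      }
      records[[r]] <- rec
    }
    if (verbose)
      message(sprintf("sweep: w = (%s) done [%d settings]", wk, length(rows)))
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "measures") <- measures
  attr(out, "kernel") <- kernel
  attr(out, "version") <- version
  out
}

# content hash of an arbitrary key object via its serialization
serialize_key <- function(key) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(key, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Eliminate kernel settings with chance-level surfaces
#'
#' Reproducible stand-in for the expert review of the performance diagrams:
#' a `(C, sigma)` pair is eliminated when the fraction of weight triples
#' whose accuracy sits within `band` percentage points of the 50% chance
#' level exceeds `threshold`.  Such surfaces are the degenerate patchworks
#' that small kernel widths produce: near-chance almost everywhere with
#' isolated sharp peaks, useless for a robust setting.
#'
#' @param records sweep record data frame.
#' @param threshold maximal tolerated chance-level fraction (default 0.5).
#' @param band half-width, in accuracy percentage points, of the
#'   chance-level zone.
#' @return A list: `records` (surviving rows), `eliminated` (data frame of
#'   dropped `(C, sigma)` pairs with their chance fractions), `kept` (the
#'   surviving pairs).
#' @export
filter_anomalous <- function(records, threshold = 0.5, band = 0.5) {
  key <- paste(records$C, records$sigma)
  per_w <- table(key)
  if (length(unique(per_w)) != 1L)
    stop("records do not cover the full Cartesian structure", call. = FALSE)
  frac <- tapply(abs(records$accuracy - 50) <= band, key, mean)
  bad <- names(frac)[frac > threshold]
  if (length(bad) == length(frac))
    stop("all (C, sigma) settings eliminated as anomalous", call. = FALSE)
  first <- !duplicated(key)
  pairs <- data.frame(C = records$C[first], sigma = records$sigma[first],
                      chance_fraction = as.numeric(frac[key[first]]))
  list(records = records[!key %in% bad, , drop = FALSE],
       eliminated = pairs[paste(pairs$C, pairs$sigma) %in% bad, , drop = FALSE],
       kept = pairs[!paste(pairs$C, pairs$sigma) %in% bad, , drop = FALSE])
}

#' Best setting for one measure
#'
#' The argmax of the measure over the (restricted) record set.  Ties are
#' broken lexicographically by `(C, sigma, wR, wG, wB)` ascending; records
#' where the measure is undefined are excluded.
#'
#' @param records sweep record data frame (possibly filtered).
#' @param measure `"accuracy"`, `"precision"` or `"recall"`.
#' @return The winning record row (one-row data frame).
#' @export
best_per_measure <- function(records, measure) {
  scores <- records[[measure]]
  if (all(is.na(scores)))
    stop("measure '", measure, "' is undefined on every record", call. = FALSE)
  cand <- records[!is.na(scores) & scores == max(scores, na.rm = TRUE), ,
                  drop = FALSE]
  ord <- order(cand$C, ifelse(is.na(cand$sigma), -Inf, cand$sigma),
               cand$wR, cand$wG, cand$wB)
  cand[ord[1], , drop = FALSE]
}

#' Priority-based global selection among per-measure optima
#'
#' Measures whose score barely varies over the restricted space (range below
#' `flat_tol` on the unit scale; accuracy is compared on its percent range
#' divided by 100) discriminate nothing and are dropped.  Among the retained
#' measures, any theta coordinate on which all optima agree is fixed; the
#' remaining coordinates are taken from the optimum of the highest-priority
#' retained measure.  The decision trace records, per coordinate, whether it
#' was agreed or resolved by priority.
#'
#' @param records (filtered) sweep records.
#' @param measures a [measure_set()] in decreasing priority.
#' @param flat_tol flatness tolerance on the unit scale (default 0.005).
#' @return A list of class `global_selection`: `theta` (one-row data frame),
#'   `optima` (per retained measure), `dropped` (flat measures with their
#'   ranges), `trace` (per-coordinate provenance).
#' @export
select_global <- function(records, measures = measure_set(),
                          flat_tol = 0.005) {
  measures <- measure_set(measures)
  ranges <- vapply(measures, function(m) {
    s <- records[[m]]
    s <- s[!is.na(s)]
    if (length(s) == 0L) return(NA_real_)
    r <- diff(range(s))
    if (m == "accuracy") r / 100 else r
  }, numeric(1))
  retained <- measures[!is.na(ranges) & ranges >= flat_tol]
  dropped <- data.frame(measure = as.character(measures), range = ranges,
                        retained = as.character(measures) %in% retained)
  if (length(retained) == 0L)
    stop("no measure discriminates over the restricted space ",
         "(all ranges below ", flat_tol, ")", call. = FALSE)
  optima <- lapply(retained, function(m) best_per_measure(records, m))
  names(optima) <- retained
  coords <- c("C", "sigma", "wR", "wG", "wB")
  top <- optima[[1]]
  trace <- data.frame(coordinate = coords, value = NA_real_,
                      source = NA_character_)
  theta <- top[, coords]
  for (i in seq_along(coords)) {
    vals <- vapply(optima, function(o) o[[coords[i]]], numeric(1))
    agreed <- length(unique(vals[!is.na(vals)])) <= 1L
    trace$value[i] <- theta[[coords[i]]]
    trace$source[i] <- if (agreed) "agreement"
                       else paste0("priority:", retained[1])
  }
  structure(list(theta = theta, optima = optima, dropped = dropped,
                 trace = trace),
            class = "global_selection")
}

#' Tune a detector with the simplex-grid methodology
#'
#' Runs the full methodology: enumerate the parameter space, perform the
#' training-evaluation sweep, eliminate anomalous `(C, sigma)` settings
#' (version `R` only — fixed-conversion versions skip the diagram review
#' step), take the per-measure argmax and resolve the global optimum by
#' measure priority.
#'
#' @inheritParams sweep_settings
#' @param filter_threshold,filter_band see [filter_anomalous()].
#' @param flat_tol see [select_global()].
#' @param exclusions optional data frame of `(C, sigma)` pairs to eliminate
#'   in addition to the programmatic filter (an explicit expert override).
#' @return An object of class `grape_tuning`: `records`, `filtered`,
#'   `selection`, `theta_star`, plus the sweep context.
#' @export
tune_detector <- function(train, tune, space = parameter_space(),
                          measures = measure_set(),
                          version = "R", kernel = c("rbf", "linear"),
                          hog = hog_params(), cache_dir = NULL,
                          filter_threshold = 0.5, filter_band = 0.5,
                          flat_tol = 0.005, exclusions = NULL,
                          verbose = FALSE) {
  kernel <- match.arg(kernel)
  if (inherits(version, "detector_version")) version <- version$tag
  records <- sweep_settings(train, tune, space, measures, version, kernel,
                            hog, cache_dir, verbose)
  filtered <- NULL
  kept <- records
  if (version == "R") {
    filtered <- filter_anomalous(records, filter_threshold, filter_band)
    kept <- filtered$records
  }
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    drop_key <- paste(exclusions$C, exclusions$sigma)
    kept <- kept[!paste(kept$C, kept$sigma) %in% drop_key, , drop = FALSE]
    if (nrow(kept) == 0L)
      stop("exclusion list removed every setting", call. = FALSE)
  }
  selection <- select_global(kept, measures, flat_tol)
  structure(list(records = records, filtered = filtered, kept = kept,
                 selection = selection, theta_star = selection$theta,
                 measures = measure_set(measures), version = version,
                 kernel = kernel, space = space, hog = hog),
            class = "grape_tuning")
}

#' @export
print.grape_tuning <- function(x, ...) {
  th <- x$theta_star
  cat("simplex-grid tuning (version ", x$version, ", ", x$kernel,
      " kernel): ", nrow(x$records), " settings evaluated\n", sep = "")
  if (!is.null(x$filtered) && nrow(x$filtered$eliminated) > 0L)
    cat("  eliminated as anomalous:",
        paste(sprintf("(C=%g, sigma=%g)", x$filtered$eliminated$C,
                      x$filtered$eliminated$sigma), collapse = " "), "\n")
  cat(sprintf("  theta* : C = %g%s", th$C,
              if (!is.na(th$sigma)) sprintf(", sigma = %g", th$sigma) else ""))
  if (!is.na(th$wR))
    cat(sprintf(", w = (%.2f, %.2f, %.2f)", th$wR, th$wG, th$wB))
  cat("\n")
  invisible(x)
}

#' @export
summary.grape_tuning <- function(object, ...) {
  print(object)
  cat("per-measure optima (after filtering):\n")
  for (m in names(object$selection$optima)) {
    o <- object$selection$optima[[m]]
    cat(sprintf("  %-9s -> C = %g%s%s  score = %.4f\n", m, o$C,
                if (!is.na(o$sigma)) sprintf(", sigma = %g", o$sigma) else "",
                if (!is.na(o$wR)) sprintf(", w = (%.2f, %.2f, %.2f)",
                                          o$wR, o$wG, o$wB) else "",
                o[[m]]))
  }
  drop <- object$selection$dropped
  flat <- drop$measure[!drop$retained]
  if (length(flat) > 0L)
    cat("dropped as non-discriminating:", paste(flat, collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.grape_tuning <- function(x, measure = "accuracy", C = NULL, sigma = NULL,
                              ...) {
  if (x$version != "R")
    stop("ternary surfaces exist only for version R (weighted conversion)",
         call. = FALSE)
  th <- x$theta_star
  surface <- ternary_surface(x$records, measure,
                             C = C %||% th$C,
                             sigma = if (x$kernel == "rbf") sigma %||% th$sigma)
  render_ternary(surface, ...)
}
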