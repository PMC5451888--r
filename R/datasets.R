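# Labelled 40x40 object images and the compositional rules of the training,
# tuning and test sets, including exact 90-degree rotation augmentation of
# positive samples.

#' A labelled 40 x 40 object image
#'
#' The unit the detector classifies: an RGB window of exactly 40 × 40 px with
#' a class label, a negative kind (for negatives), and provenance tracking
#' for rotation-augmented copies.  Intensities are quantized to the 8-bit
#' grid on construction so samples round-trip bit-exactly through PNG
#' manifests.
#'
#' @param image RGB array of dimension 40 × 40 × 3 in `[0, 1]`.
#' @param label `"positive"` or `"negative"`.
#' @param kind negative kind: `"environment"`, `"grape"`, or `"none"` for
#'   positives.
#' @param provenance `"unique"` or `"rotated"`.
#' @param angle rotation angle in degrees, one of 0, 90, 180, 270.
#' @param parent content key of the unique parent for rotated samples.
#' @return A list of class `labelled_sample`; its `id` is a deterministic
#'   content key of the quantized image.
#' @export
labelled_sample <- function(image, label, kind = c("none", "environment", "grape"),
                            provenance = c("unique", "rotated"),
                            angle = 0, parent = NA_character_) {
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)
  if (!label %in% CLASSES)
    stop("label must be 'positive' or 'negative'", call. = FALSE)
  if (label == "positive" && kind != "none")
    stop("positive samples carry kind 'none'", call. = FALSE)
  if (label == "negative" && kind == "none")
    stop("negative samples need kind 'environment' or 'grape'", call. = FALSE)
  d <- dim(image)
  if (length(d) != 3L || d[1] != WINDOW || d[2] != WINDOW || d[3] != 3L)
    stop("object image must be exactly 40 x 40 x 3; got ",
         paste(d, collapse = " x "), call. = FALSE)
  if (!angle %in% c(0, 90, 180, 270))
    stop("angle must be one of 0, 90, 180, 270 degrees", call. = FALSE)
  image <- round(image * 255) / 255
  validate_rgb(image)
  structure(list(image = image, label = label, kind = kind,
                 provenance = provenance, angle = angle, parent = parent,
                 id = content_key(image)),
            class = "labelled_sample")
}

# Deterministic content key: two weighted byte sums with fixed pseudo-random
# weights; stable across sessions, used for ids, duplicate detection and
# train/test leakage checks.
content_key <- function(image) {
  b <- as.integer(round(as.vector(image) * 255))
  n <- length(b)
  w1 <- key_weights(n, 101L)
  w2 <- key_weights(n, 202L)
  sprintf("%013.0f%013.0f",
          sum(b * w1) %% 9007199254740881,
          sum(b * w2) %% 9007199254740881)
}

key_weights <- local({
  cache <- list()
  function(n, seed) {
    key <- paste0(n, ":", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- with_seed(seed, sample.int(2^20, n, replace = TRUE))
    cache[[key]]
  }
})

#' Exact quarter-turn rotation of an object image
#'
#' Rotations by multiples of 90° are pixel permutations, hence lossless.
#'
#' @param image RGB array.
#' @param quarters number of counter-clockwise quarter turns (0–3).
#' @return The rotated array.
#' @export
rotate_quarter <- function(image, quarters) {
  quarters <- as.integer(quarters) %% 4L
  out <- image
  for (i in seq_len(quarters)) {
    d <- dim(out)
    # 90 deg CCW: new[i, j] = old[j, W + 1 - i]
    out <- aperm(out, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  out
}

#' Rotation augmentation of positive samples
#'
#' Expands each unique positive into its four rotations by
#' φ ∈ {0, π/2, π, 3π/2}: the parent itself (φ = 0) plus three exact
#' quarter-turn copies marked `provenance = "rotated"` and referencing the
#' parent's content key.  Output size is exactly four times the input size.
#'
#' @param positives list of unique positive `labelled_sample` objects.
#' @return List of `labelled_sample` objects, length `4 * length(positives)`.
#' @export
rotate_augment <- function(positives) {
  if (length(positives) == 0L)
    stop("no positives to augment", call. = FALSE)
  ok <- vapply(positives, function(s)
    inherits(s, "labelled_sample") && s$label == "positive" &&
      s$provenance == "unique", logical(1))
  if (!all(ok))
    stop("rotate_augment requires unique positive samples", call. = FALSE)
  ids <- vapply(positives, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate positives in augmentation input", call. = FALSE)
  out <- vector("list", 4L * length(positives))
  k <- 0L
  for (s in positives) {
    out[[k + 1L]] <- s
    for (q in 1:3)
      out[[k + 1L + q]] <- labelled_sample(rotate_quarter(s$image, q),
                                           "positive", provenance = "rotated",
                                           angle = 90 * q, parent = s$id)
    k <- k + 4L
  }
  out
}

SET_TYPES <- c("T", "tuning", "E", "G", "EX", "GX", "SX")

#' Assemble a sample set under its type's compositional rules
#'
#' Set types mirror the dataset taxonomy of the study design:
#' \describe{
#'   \item{`T`}{training set: unique positives and negatives, no
#'     augmentation, equal class counts.}
#'   \item{`tuning`}{positives rotation-augmented ×4; negatives split exactly
#'     50/50 between environment and grape kinds.}
#'   \item{`E`, `EX`}{test sets with augmented positives and environment-kind
#'     negatives only.}
#'   \item{`G`, `GX`}{as above with grape-kind negatives only.}
#'   \item{`SX`}{standard test set: unique samples only, untouched by the
#'     rotation distortion.}
#' }
#'
#' @param type one of `r paste0('"', SET_TYPES, '"', collapse = ", ")`.
#' @param positives list of unique positive samples.
#' @param negatives list of negative samples of the kinds the type requires.
#' @param name set name (for reports).
#' @return A list of class `sample_set` with `name`, `type`, `samples`.
#' @export
build_set <- function(type, positives, negatives, name = type) {
  type <- match.arg(type, SET_TYPES)
  kinds <- vapply(negatives, `[[`, character(1), "kind")
  labels <- vapply(negatives, `[[`, character(1), "label")
  if (any(labels != "negative"))
    stop("composition error: non-negative sample in negatives", call. = FALSE)
  if (type %in% c("E", "EX") && any(kinds != "environment"))
    stop("composition error: ", type, " admits environment-kind negatives only",
         call. = FALSE)
  if (type %in% c("G", "GX") && any(kinds != "grape"))
    stop("composition error: ", type, " admits grape-kind negatives only",
         call. = FALSE)
  if (type == "tuning" &&
      sum(kinds == "environment") != sum(kinds == "grape"))
    stop("composition error: tuning set requires equal environment and grape ",
         "negative counts", call. = FALSE)
  pos <- if (type %in% c("tuning", "E", "G", "EX", "GX"))
    rotate_augment(positives) else positives
  if (type %in% c("T", "SX")) {
    prov <- vapply(pos, `[[`, character(1), "provenance")
    if (any(prov != "unique"))
      stop("composition error: ", type, " admits unique samples only",
           call. = FALSE)
  }
  if (type == "T" && length(pos) != length(negatives))
    stop("composition error: training set requires equal class counts",
         call. = FALSE)
  set <- structure(list(name = name, type = type,
                        samples = c(pos, negatives)),
                   class = "sample_set")
  validate_sample_set(set)
  set
}

#' Validate a sample set's composition invariants
#'
#' Re-checks the type rules of [build_set()]; run on build and again on load
#' from a manifest.
#'
#' @param set a `sample_set`.
#' @return The set, invisibly, if valid.
#' @export
validate_sample_set <- function(set) {
  stopifnot(inherits(set, "sample_set"))
  labels <- vapply(set$samples, `[[`, character(1), "label")
  kinds <- vapply(set$samples, `[[`, character(1), "kind")
  prov <- vapply(set$samples, `[[`, character(1), "provenance")
  ids <- vapply(set$samples, `[[`, character(1), "id")
  uniq <- ids[prov == "unique"]
  if (anyDuplicated(uniq))
    stop("duplicate unique samples in set '", set$name, "'", call. = FALSE)
  neg_kinds <- kinds[labels == "negative"]
  bad <- switch(set$type,
    E = , EX = any(neg_kinds != "environment"),
    G = , GX = any(neg_kinds != "grape"),
    tuning = sum(neg_kinds == "environment") != sum(neg_kinds == "grape"),
    T = , SX = any(prov != "unique"),
    FALSE)
  if (isTRUE(bad))
    stop("set '", set$name, "' violates the composition rules of type ",
         set$type, call. = FALSE)
  if (set$type %in% c("tuning", "E", "G", "EX", "GX")) {
    npos <- sum(labels == "positive")
    nuniq <- sum(labels == "positive" & prov == "unique")
    if (npos != 4L * nuniq)
      stop("set '", set$name, "': positives are not a x4 rotation augmentation",
           call. = FALSE)
  }
  invisible(set)
}

set_labels <- function(set) vapply(set$samples, `[[`, character(1), "label")
set_images <- function(set) lapply(set$samples, `[[`, "image")
set_ids <- function(set) vapply(set$samples, `[[`, character(1), "id")

#' @export
print.sample_set <- function(x, ...) {
  labels <- set_labels(x)
  kinds <- vapply(x$samples, `[[`, character(1), "kind")
  cat(sprintf("sample_set '%s' (type %s): %d positive, %d negative (%d environment, %d grape)\n",
              x$name, x$type, sum(labels == "positive"),
              sum(labels == "negative"),
              sum(kinds == "environment"), sum(kinds == "grape")))
  invisible(x)
}

#' Check that two sets share no sample content
#'
#' Training/tuning and test sets must be disjoint; comparison is by content
#' key, so byte-identical windows are caught even across different scenes.
#'
#' @param a,b `sample_set` objects.
#' @return `TRUE` invisibly, or an error naming the overlap size.
#' @export
assert_disjoint <- function(a, b) {
  overlap <- intersect(set_ids(a), set_ids(b))
  if (length(overlap) > 0L)
    stop("leakage: ", length(overlap), " samples shared between '",
         a$name, "' and '", b$name, "'", call. = FALSE)
  invisible(TRUE)
}

#' Write or read a sample set as PNGs plus a manifest
#'
#' The manifest is a tab-separated table with header
#' `file, label, kind, provenance, angle, parent`; images are individual
#' 8-bit PNGs in the same directory.  Write-then-read reproduces the set
#' exactly (images byte-identical, metadata equal).
#'
#' @param set a `sample_set`.
#' @param dir directory to write into (created if missing).
#' @param type set type expected when reading (validated).
#' @param name set name on read.
#' @return `write_manifest()` returns the manifest path invisibly;
#'   `read_manifest()` returns the `sample_set`.
#' @export
write_manifest <- function(set, dir) {
  stopifnot(inherits(set, "sample_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(set$samples), function(i) {
    s <- set$samples[[i]]
    fn <- sprintf("%s_%05d.png", s$label, i)
    write_image_png(s$image, file.path(dir, fn))
    data.frame(file = fn, label = s$label, kind = s$kind,
               provenance = s$provenance, angle = s$angle,
               parent = s$parent, stringsAsFactors = FALSE)
  })
  path <- file.path(dir, "manifest.tsv")
  header <- sprintf("# sample_set\tname=%s\ttype=%s", set$name, set$type)
  writeLines(header, path)
  cols <- c("file", "label", "kind", "provenance", "angle", "parent")
  if (length(rows) == 0L) {
    cat(paste(cols, collapse = "\t"), "\n", sep = "", file = path,
        append = TRUE)
  } else {
    suppressWarnings(utils::write.table(do.call(rbind, rows), path,
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir, type = NULL, name = NULL) {
  path <- file.path(dir, "manifest.tsv")
  if (!file.exists(path))
    stop("no manifest.tsv in ", dir, call. = FALSE)
  header <- readLines(path, n = 1L)
  meta <- strsplit(sub("^# sample_set\t", "", header), "\t")[[1]]
  meta <- strsplit(meta, "=")
  meta <- stats::setNames(vapply(meta, `[`, character(1), 2),
                          vapply(meta, `[`, character(1), 1))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(df) == 0L) {
    warning("empty manifest in ", dir, call. = FALSE)
    return(structure(list(name = name %||% meta[["name"]],
                          type = type %||% meta[["type"]], samples = list()),
                     class = "sample_set"))
  }
  samples <- lapply(seq_len(nrow(df)), function(i) {
    fp <- file.path(dir, df$file[i])
    if (!file.exists(fp))
      stop("manifest row ", i, ": missing image file ", df$file[i],
           call. = FALSE)
    img <- read_image_png(fp)
    if (is.matrix(img) || !all(dim(img) == c(WINDOW, WINDOW, 3L)))
      stop("manifest row ", i, ": image is not 40 x 40 RGB", call. = FALSE)
    tryCatch(
      labelled_sample(img, df$label[i], kind = df$kind[i],
                      provenance = df$provenance[i], angle = df$angle[i],
                      parent = as.character(df$parent[i])),
      error = function(e)
        stop("manifest row ", i, ": ", conditionMessage(e), call. = FALSE))
  })
  set <- structure(list(name = name %||% meta[["name"]],
                        type = type %||% meta[["type"]], samples = samples),
                   class = "sample_set")
  validate_sample_set(set)
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build labelled sample pools from synthetic scenes
#'
#' Convenience generator: renders as many scenes as needed (one berry pool
#' per scene, disjoint seed stream starting at `seed`) and extracts unique
#' positives and negatives of the requested kinds.  Positives receive a
#' uniform integer jitter with Chebyshev norm at most 1, the class tolerance.
#'
#' @param n_pos,n_env,n_grape counts of unique positives and of
#'   environment- and grape-kind negatives.
#' @param seed base seed; scene `k` uses `seed + k - 1`.
#' @param params_fn function `(seed) -> scene_params`, customizing scene
#'   appearance (e.g. the per-channel contrast triple).
#' @return A list with `positives` and `negatives` lists of
#'   `labelled_sample`.
#' @export
synth_pool <- function(n_pos, n_env, n_grape, seed = 1L,
                       params_fn = function(s) scene_params(seed = s)) {
  positives <- list(); env <- list(); grape <- list()
  seen <- new.env(parent = emptyenv())   # content keys across all kinds
  keep <- function(s, bucket) {
    if (is.null(s) || !is.null(seen[[s$id]])) return(bucket)
    seen[[s$id]] <- TRUE
    bucket[[length(bucket) + 1L]] <- s
    bucket
  }
  scene_i <- 0L
  with_seed(seed * 1000L + 7L, {
    while (length(positives) < n_pos || length(env) < n_env ||
           length(grape) < n_grape) {
      scene_i <- scene_i + 1L
      if (scene_i > 1000L)
        stop("synth_pool: scene budget exhausted", call. = FALSE)
      sc <- generate_scene(params_fn(seed + scene_i - 1L))
      ann <- sc$annotations
      for (k in seq_len(nrow(ann))) {
        if (length(positives) >= n_pos) break
        jit <- sample(-1:1, 2L, replace = TRUE)
        s <- tryCatch(extract_positive(sc, ann[k, ], jitter = jit),
                      error = function(e) NULL)
        positives <- keep(s, positives)
      }
      per_scene <- max(nrow(ann), 4L)
      for (k in seq_len(per_scene)) {
        if (length(env) >= n_env) break
        s <- tryCatch(extract_negative(sc, "environment"),
                      error = function(e) NULL)
        env <- keep(s, env)
      }
      for (k in seq_len(per_scene)) {
        if (length(grape) >= n_grape) break
        s <- tryCatch(extract_negative(sc, "grape"), error = function(e) NULL)
        grape <- keep(s, grape)
      }
    }
  })
  list(positives = positives, negatives = c(env, grape))
}
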