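# Soft-margin SVM contract behind the detector: linear and Gaussian kernels,
# regularization constant C, kernel width sigma.  The solver is libsvm (via
# e1071) at a pinned tolerance; the kernel-width convention is
# k(u, v) = exp(-||u - v||^2 / (2 sigma^2)).

SVM_TOLERANCE <- 1e-3

#' Kernel specification
#'
#' @param kind `"linear"` or `"rbf"`.
#' @param sigma kernel width (required, positive, for `"rbf"`; absent for
#'   `"linear"`).
#' @return A list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), sigma = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.null(sigma) || !is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
      stop("rbf kernel requires a single positive sigma", call. = FALSE)
  } else if (!is.null(sigma)) {
    stop("linear kernel takes no sigma", call. = FALSE)
  }
  structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
}

#' Convert a Gaussian kernel width to libsvm's gamma
#'
#' The detector parameterizes the Gaussian kernel as
#' `exp(-||u - v||^2 / (2 sigma^2))`, so the solver's gamma is
#' `1 / (2 sigma^2)`.  Centralized here so the sigma grid maps onto the
#' solver consistently everywhere.
#'
#' @param sigma positive kernel width.
#' @return The gamma value.
#' @export
sigma_to_gamma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  1 / (2 * sigma^2)
}

# Train the SVM on a feature matrix.  Deterministic for a fixed sample order.
train_svm <- function(x, y, kernel, C) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("C must be a single positive number", call. = FALSE)
  if (!is.matrix(x) || nrow(x) != length(y))
    stop("features must be a matrix with one row per label", call. = FALSE)
  y <- factor(as.character(y), levels = CLASSES)
  if (anyNA(y))
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L)
    stop("training requires at least one sample of each class", call. = FALSE)
  if (kernel$kind == "rbf") {
    e1071::svm(x = x, y = y, scale = FALSE, kernel = "radial",
               gamma = sigma_to_gamma(kernel$sigma), cost = C,
               tolerance = SVM_TOLERANCE, cachesize = 200)
  } else {
    e1071::svm(x = x, y = y, scale = FALSE, kernel = "linear", cost = C,
               tolerance = SVM_TOLERANCE, cachesize = 200)
  }
}

# Decision-value prediction with the documented tie rule: a decision score of
# exactly zero maps to "negative" -- the detector does not assert a berry
# without positive evidence.
predict_svm <- function(fit, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(fit$SV))
    stop("feature length ", ncol(x), " does not match training length ",
         ncol(fit$SV), call. = FALSE)
  p <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  sides <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  out <- ifelse(dv[, 1] > 0, sides[1],
                ifelse(dv[, 1] < 0, sides[2], "negative"))
  unname(out)
}

# Features for a list of object images under one preprocessing version.
detector_features <- function(images, version, hog = hog_params()) {
  feats <- lapply(images, function(img)
    hog_features(preprocess_image(img, version), hog))
  do.call(rbind, feats)
}

#' Fit a grape berry detector
#'
#' Trains the full detector on labelled 40 × 40 object images: the version's
#' image preprocessing, HOG feature extraction at the fixed configuration,
#' and a soft-margin SVM on the resulting feature vectors.
#'
#' @param x a `sample_set` (see [build_set()]) or a list of RGB object
#'   images.
#' @param y class labels (`"positive"`/`"negative"`), required when `x` is a
#'   plain image list; taken from the set otherwise.
#' @param version preprocessing version: a [detector_version()] or a tag
#'   (`"R"`, `"O"`, `"S1"`, `"S2"`).
#' @param weights [weight_triple()] for version `"R"` (default is the tuned
#'   optimum `(0.95, 0.05, 0.00)`).
#' @param kernel `"rbf"` or `"linear"`, or a [kernel_spec()].
#' @param C soft-margin regularization constant.
#' @param sigma Gaussian kernel width (rbf only).
#' @param hog descriptor configuration, a [hog_params()].
#' @return An object of class `grape_detector` with `predict`, `print` and
#'   `summary` methods.
#' @examples
#' pool <- synth_pool(n_pos = 10, n_env = 5, n_grape = 5, seed = 42)
#' fit <- grape_detector(c(pool$positives, pool$negatives),
#'                       y = rep(c("positive", "negative"), each = 10),
#'                       version = "S1", kernel = "linear", C = 1)
#' predict(fit, pool$positives[[1]]$image)
#' @export
grape_detector <- function(x, y = NULL, version = "R",
                           weights = c(0.95, 0.05, 0.00),
                           kernel = c("rbf", "linear"), C = 10, sigma = 30,
                           hog = hog_params()) {
  if (is.character(version))
    version <- detector_version(version, weights)
  if (is.character(kernel))
    kernel <- kernel_spec(match.arg(kernel),
                          sigma = if (match.arg(kernel) == "rbf") sigma)
  xs <- as_image_list(x)
  if (is.null(y)) y <- xs$labels
  if (is.null(y))
    stop("labels y are required when x is a plain image list", call. = FALSE)
  if (length(y) != length(xs$images))
    stop("length of y must match the number of images", call. = FALSE)
  feats <- detector_features(xs$images, version, hog)
  fit <- train_svm(feats, y, kernel, C)
  structure(list(svm = fit, version = version, kernel = kernel, C = C,
                 hog = hog, n_train = length(y),
                 class_counts = table(factor(y, levels = CLASSES)),
                 format_version = 1L),
            class = "grape_detector")
}

as_image_list <- function(x) {
  if (inherits(x, "sample_set"))
    return(list(images = set_images(x), labels = set_labels(x)))
  if (is.array(x) && length(dim(x)) == 3L)
    return(list(images = list(x), labels = NULL))
  if (is.list(x)) {
    if (all(vapply(x, inherits, logical(1), "labelled_sample")))
      return(list(images = lapply(x, `[[`, "image"),
                  labels = vapply(x, `[[`, character(1), "label")))
    return(list(images = x, labels = NULL))
  }
  stop("x must be a sample_set, a list of images, or one RGB array",
       call. = FALSE)
}

#' Predict berry classes for object images
#'
#' Applies the trained detector's preprocessing, descriptor and classifier.
#' A decision score of exactly zero is resolved to `"negative"`.
#'
#' @param object a fitted [grape_detector()].
#' @param newdata a `sample_set`, list of images/samples, or one RGB array.
#' @param type `"class"` for labels, `"decision"` for raw SVM decision
#'   scores (positive scores favour the class named first by the solver).
#' @param ... unused.
#' @return Character vector of classes, or numeric decision values.
#' @export
predict.grape_detector <- function(object, newdata, type = c("class", "decision"),
                                   ...) {
  type <- match.arg(type)
  xs <- as_image_list(newdata)
  feats <- detector_features(xs$images, object$version, object$hog)
  if (type == "decision") {
    p <- stats::predict(object$svm, feats, decision.values = TRUE)
    return(unname(attr(p, "decision.values")[, 1]))
  }
  predict_svm(object$svm, feats)
}

#' @export
print.grape_detector <- function(x, ...) {
  w <- x$version$weights
  cat("grape berry detector\n")
  cat("  version:", x$version$tag,
      if (!is.null(w)) sprintf("(w = %.3f, %.3f, %.3f)", w[1], w[2], w[3]) else "",
      "\n")
  cat("  kernel: ", x$kernel$kind,
      if (x$kernel$kind == "rbf") sprintf("(sigma = %g)", x$kernel$sigma) else "",
      " C =", x$C, "\n")
  cat("  trained on", x$n_train, "samples (",
      x$class_counts[["positive"]], "positive /",
      x$class_counts[["negative"]], "negative ),",
      nrow(x$svm$SV), "support vectors\n")
  invisible(x)
}

#' @export
summary.grape_detector <- function(object, ...) {
  print(object)
  cat("  HOG:", object$hog$bins, "bins,", object$hog$cell_size, "px cells,",
      object$hog$block_size, "x", object$hog$block_size, "cell blocks, stride",
      object$hog$block_stride, "\n")
  cat("  feature length:", hog_length(WINDOW, WINDOW, object$hog), "\n")
  invisible(object)
}

#' Evaluate a detector on a labelled sample set
#'
#' @param model a fitted [grape_detector()].
#' @param set a `sample_set` (or list of `labelled_sample`).
#' @return A list of class `detector_evaluation`: confusion `counts` and the
#'   three measures (`accuracy` percent scale, `precision` and `recall` unit
#'   scale; `NA` when undefined).
#' @export
evaluate_detector <- function(model, set) {
  xs <- as_image_list(set)
  if (is.null(xs$labels))
    stop("evaluation requires labelled samples", call. = FALSE)
  pred <- predict(model, set)
  counts <- confusion(xs$labels, pred)
  structure(list(counts = counts, accuracy = accuracy(counts),
                 precision = precision(counts), recall = recall(counts)),
            class = "detector_evaluation")
}

#' @export
print.detector_evaluation <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Save or load a fitted detector
#'
#' Persistence uses a versioned container; loading refuses files written
#' under an incompatible format version.
#'
#' @param model a `grape_detector`.
#' @param path file path (binary, RDS-based).
#' @return `save_detector()` returns `path` invisibly; `load_detector()` the
#'   model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "grape_detector"))
  saveRDS(list(format = "grapedetect-model", format_version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "grapedetect-model"))
    stop("not a grapedetect model file", call. = FALSE)
  if (!identical(obj$format_version, 1L))
    stop("incompatible model format version: ", obj$format_version,
         call. = FALSE)
  obj$model
}
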