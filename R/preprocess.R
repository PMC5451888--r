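# Internal intensity scale is real [0,1]; 8-bit PNG values are divided by 255
# on read and re-quantized on write, so the weighted conversion is scale-free.

BT601 <- c(0.299, 0.587, 0.114)

#' Validate an RGB image array
#'
#' An RGB image is a numeric array of dimension `height x width x 3` with all
#' intensities in `[0, 1]` (red, green, blue planes in that order).
#'
#' @param image object to validate.
#' @return The image, invisibly, if valid; otherwise an error is thrown.
#' @keywords internal
validate_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("RGB image must be a height x width x 3 array", call. = FALSE)
  if (!is.numeric(image) || anyNA(image))
    stop("RGB image must be numeric without missing values", call. = FALSE)
  if (min(image) < 0 || max(image) > 1)
    stop("RGB intensities must lie in [0, 1]", call. = FALSE)
  invisible(image)
}

validate_gray <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || anyNA(image))
    stop("grayscale image must be a numeric matrix without missing values",
         call. = FALSE)
  if (min(image) < 0 || max(image) > 1)
    stop("grayscale intensities must lie in [0, 1]", call. = FALSE)
  invisible(image)
}

#' Construct a weight triple on the unit 2-simplex
#'
#' The triple `w = (w_R, w_G, w_B)` mixes the red, green and blue channels
#' into one grayscale image.  Each weight must lie in `[0, 1]` and the three
#' must sum to one (tolerance `1e-9`).
#'
#' @param w numeric vector of length 3, `(w_R, w_G, w_B)`.
#' @return A validated numeric vector of class `weight_triple`.
#' @examples
#' weight_triple(c(0.95, 0.05, 0))   # the tuned optimum for the robust detector
#' weight_triple(c(0.299, 0.587, 0.114))  # BT.601 luma coefficients
#' @export
weight_triple <- function(w) {
  w <- as.numeric(w)
  if (length(w) != 3L || anyNA(w))
    stop("a weight triple has exactly three finite components", call. = FALSE)
  if (any(w < 0) || any(w > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to 1 (tolerance 1e-9); got ", format(sum(w), digits = 12),
         call. = FALSE)
  names(w) <- c("wR", "wG", "wB")
  class(w) <- "weight_triple"
  w
}

#' Weighted RGB to grayscale conversion
#'
#' Converts an RGB image to grayscale as the per-pixel weighted mean
#' `I* = w_R I_R + w_G I_G + w_B I_B`.  Because the weights are non-negative
#' and sum to one, the output stays in `[0, 1]`.
#'
#' @param image RGB image array (`height x width x 3`, intensities in `[0,1]`).
#' @param w a [weight_triple()] or a numeric vector of length 3 on the simplex.
#' @return A grayscale matrix of the same height and width.
#' @seealso [convert_bt601()], [preprocess_image()]
#' @export
convert_weighted <- function(image, w) {
  validate_rgb(image)
  w <- weight_triple(w)
  out <- w[1] * image[, , 1] + w[2] * image[, , 2] + w[3] * image[, , 3]
  # simplex weights cannot push values outside [0,1]; clamp rounding dust only
  matrix(pmin(pmax(out, 0), 1), dim(image)[1], dim(image)[2])
}

#' BT.601 grayscale conversion
#'
#' Weighted conversion at the ITU-R BT.601 luma coefficients
#' `(0.299, 0.587, 0.114)` — the fixed conversion used by the original (O)
#' and first simplified (S1) detector versions.
#'
#' @inheritParams convert_weighted
#' @return A grayscale matrix.
#' @export
convert_bt601 <- function(image) {
  convert_weighted(image, BT601)
}

#' Linear contrast normalization to [0, 1]
#'
#' Rescales a grayscale image so its minimum maps to 0 and its maximum to 1.
#' A constant image has no contrast to stretch; it is returned as all zeros
#' with a warning, since flat windows legitimately occur in scenes.
#'
#' @param image grayscale matrix with values in `[0, 1]`.
#' @return A grayscale matrix spanning `[0, 1]` (or all zeros if degenerate).
#' @export
contrast_normalize <- function(image) {
  validate_gray(image)
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) {
    warning("constant image: contrast normalization returns all zeros",
            call. = FALSE)
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - lo) / (hi - lo)
}

#' Detector version specification
#'
#' The four image-preprocessing variants of the detector family:
#' \describe{
#'   \item{`"O"`}{BT.601 conversion followed by linear contrast normalization.}
#'   \item{`"S1"`}{BT.601 conversion only.}
#'   \item{`"S2"`}{no preprocessing; the 3-channel image is passed through and
#'     the descriptor takes, per pixel, the channel with maximal gradient
#'     magnitude.}
#'   \item{`"R"`}{generalized weighted conversion with a tunable
#'     [weight_triple()] — the robust detector.}
#' }
#'
#' @param tag one of `"O"`, `"S1"`, `"S2"`, `"R"`.
#' @param weights weight triple; required when `tag == "R"`, ignored (with the
#'   BT.601 triple implied) for `"O"` and `"S1"`, absent for `"S2"`.
#' @return A list of class `detector_version` with elements `tag` and `weights`.
#' @export
detector_version <- function(tag = c("R", "O", "S1", "S2"), weights = NULL) {
  tag <- match.arg(tag)
  if (tag == "R") {
    if (is.null(weights))
      stop("version R requires a weight triple", call. = FALSE)
    weights <- weight_triple(weights)
  } else if (tag %in% c("O", "S1")) {
    weights <- weight_triple(BT601)
  } else {
    weights <- NULL
  }
  structure(list(tag = tag, weights = weights), class = "detector_version")
}

#' Apply a detector version's image preprocessing
#'
#' Dispatches on the version tag: `O` converts with BT.601 and contrast
#' normalizes, `S1` converts only, `S2` passes the RGB image through
#' unchanged, and `R` applies the generalized weighted conversion.
#'
#' @param image RGB image array.
#' @param version a [detector_version()], or a tag string (with `weights`
#'   supplied for `"R"`).
#' @param weights optional weight triple used when `version` is the tag `"R"`.
#' @return A grayscale matrix, except for `S2` where the RGB array is returned.
#' @export
preprocess_image <- function(image, version, weights = NULL) {
  if (is.character(version)) version <- detector_version(version, weights)
  if (!inherits(version, "detector_version"))
    stop("version must be a detector_version or tag string", call. = FALSE)
  validate_rgb(image)
  switch(version$tag,
    O  = contrast_normalize(convert_bt601(image)),
    S1 = convert_bt601(image),
    S2 = image,
    R  = convert_weighted(image, version$weights)
  )
}

#' Read and write images as 8-bit PNG
#'
#' `read_image_png()` reads an 8-bit PNG into the internal `[0, 1]` intensity
#' scale (an alpha channel, if present, is dropped); `write_image_png()`
#' quantizes back to 8 bits and writes.  Grayscale matrices round-trip as
#' single-channel PNGs.
#'
#' @param path file path.
#' @param image RGB array or grayscale matrix in `[0, 1]`.
#' @return `read_image_png()` returns the image; `write_image_png()` returns
#'   `path` invisibly.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
    validate_rgb(img)
  } else {
    if (length(dim(img)) == 3L) img <- img[, , 1]
    validate_gray(img)
  }
  img
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  if (is.matrix(image)) validate_gray(image) else validate_rgb(image)
  png::writePNG(image, target = path)
  invisible(path)
}
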