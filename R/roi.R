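#' Read an eye micrograph as a grayscale-capable matrix
#'
#' Reads 8- or 16-bit PNG/TIFF (1 or 3 channels) via EBImage and returns it
#' in this package's (row, col) orientation: element `[i, j]` is image row
#' `i` (top to bottom) and column `j`. Color images are returned as a
#' `row x col x 3` array.
#'
#' @param path Image file path.
#' @return Numeric matrix (grayscale) or 3-d array (color), values in `[0, 1]`.
#' @export
read_eye_image <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) return(t(img))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) return(aperm(img[, , 1:3], c(2, 1, 3)))
    return(t(img[, , 1]))
  }
  stop("unsupported image dimensionality", call. = FALSE)
}

#' Preprocess a micrograph: luminance conversion and white top-hat
#'
#' Converts color input to luminance (Rec. 709 weights), applies a white
#' top-hat transform with a disk structuring element (the image minus its
#' morphological opening), and rescales to `[0, 1]`. Bright blobs smaller
#' than the structuring element survive; flat or smoothly varying background
#' is suppressed towards zero. A sensible `structuring_radius` is about 1.5
#' times the expected ommatidium radius.
#'
#' @param raw 2-d numeric matrix, `row x col x 3` array, or a file path.
#' @param structuring_radius Disk radius of the structuring element, pixels
#'   (>= 1).
#' @return Numeric matrix in `[0, 1]` (a flat input maps to all zeros).
#' @export
#' @examples
#' eye <- generate_eye_image(lattice_spec(5, 5), degeneration_spec())
#' ph <- preprocess(eye$image, structuring_radius = 8)
preprocess <- function(raw, structuring_radius = 8) {
  if (is.character(raw)) raw <- read_eye_image(raw)
  if (length(raw) == 0) stop("empty image", call. = FALSE)
  if (structuring_radius < 1) stop("structuring_radius must be >= 1", call. = FALSE)
  if (length(dim(raw)) == 3L) {
    raw <- 0.2126 * raw[, , 1] + 0.7152 * raw[, , 2] + 0.0722 * raw[, , 3]
  }
  stopifnot(is.matrix(raw), all(is.finite(raw)))
  kern <- EBImage::makeBrush(2L * floor(structuring_radius) + 1L, shape = "disc")
  th <- EBImage::whiteTopHat(raw, kern)
  mx <- max(th)
  if (mx > 0) th <- th / mx
  th
}

#' Pixel-set constructor
#'
#' A set of distinct integer (row, col) pixel positions within an image of
#' known shape.
#'
#' @param coords Two-column integer matrix of (row, col) positions.
#' @param shape Length-2 integer vector `(height, width)` of the source image.
#' @return An object of class `pixel_set` with elements `coords` and `shape`.
#' @export
pixel_set <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  stopifnot(length(shape) == 2L)
  shape <- as.integer(shape)
  if (nrow(coords) > 0) {
    stopifnot(all(coords[, 1] >= 1), all(coords[, 1] <= shape[1]),
              all(coords[, 2] >= 1), all(coords[, 2] <= shape[2]))
    if (anyDuplicated(coords[, 1] + (coords[, 2] - 1) * shape[1]) > 0) {
      stop("duplicate pixel coordinates", call. = FALSE)
    }
  }
  structure(list(coords = coords, shape = shape), class = "pixel_set")
}

#' @export
print.pixel_set <- function(x, ...) {
  cat(sprintf("pixel_set: %d pixels in a %d x %d image\n",
              nrow(x$coords), x$shape[1], x$shape[2]))
  invisible(x)
}

#' @export
length.pixel_set <- function(x) nrow(x$coords)

#' Detect high-intensity pixels
#'
#' Thresholds a preprocessed image to locate the bright pixels that
#' anchor ROI selection. The default rule is Otsu's method on the image
#' histogram; a fixed-quantile rule is available as an alternative.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param quantile Intensity quantile used when `method = "quantile"`.
#' @return A [pixel_set()] of pixels strictly above the threshold. A flat
#'   image yields an empty set with a warning.
#' @export
detect_bright_pixels <- function(img, method = c("otsu", "quantile"),
                                 quantile = 0.95) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  method <- match.arg(method)
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning("flat image: no bright pixels detected")
    return(pixel_set(matrix(integer(0), ncol = 2), dim(img)))
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(img, range = rng)
  } else {
    stats::quantile(img, quantile, type = 7)
  }
  pixel_set(which(img > thr, arr.ind = TRUE), dim(img))
}

#' Prune pixels by distance to the set centroid
#'
#' Computes the centroid of the pixel set, each pixel's Euclidean distance
#' to it, and the empirical `q` quantile of those distances (linear
#' interpolation between order statistics). Pixels farther than the
#' quantile are discarded; ties at the quantile are retained.
#'
#' @param px A non-empty [pixel_set()].
#' @param q Retention quantile (default 0.8).
#' @return A [pixel_set()] of the retained pixels.
#' @export
prune_by_centroid_distance <- function(px, q = 0.8) {
  stopifnot(inherits(px, "pixel_set"), is_prob(q))
  if (nrow(px$coords) == 0) stop("empty pixel set", call. = FALSE)
  ctr <- colMeans(px$coords)
  d <- sqrt((px$coords[, 1] - ctr[1])^2 + (px$coords[, 2] - ctr[2])^2)
  thr <- stats::quantile(d, q, type = 7, names = FALSE)
  pixel_set(px$coords[d <= thr, , drop = FALSE], px$shape)
}

#' Fit a confidence ellipse to a pixel set
#'
#' The ROI ellipse comes from the sample mean and covariance of the pixel
#' coordinates: semi-axes are the square roots of the covariance
#' eigenvalues scaled by the chi-square(2) quantile at `level`, ordered
#' `a >= b`, with the orientation of the major axis reported in `[0, pi)`
#' (angle from the column axis in the (row, col) plane).
#'
#' @param px A [pixel_set()] with at least 3 non-collinear pixels.
#' @param level Confidence level (default 0.95).
#' @return An object of class `roi_ellipse` with elements `center`
#'   (row, col), `semi_axes` (`a >= b`), `orientation` and `level`.
#' @export
fit_confidence_ellipse <- function(px, level = 0.95) {
  stopifnot(inherits(px, "pixel_set"), is_prob(level), level > 0, level < 1)
  n <- nrow(px$coords)
  if (n < 3) stop("need at least 3 pixels to fit an ellipse", call. = FALSE)
  ctr <- colMeans(px$coords)
  S <- stats::cov(px$coords)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= 1e-10 * max(e$values[1], 1)) {
    stop("rank-deficient pixel covariance (collinear pixels)", call. = FALSE)
  }
  scale <- stats::qchisq(level, df = 2)
  axes <- sqrt(e$values * scale)              # already sorted a >= b
  v <- e$vectors[, 1]                         # major axis direction (row, col)
  theta <- atan2(v[1], v[2]) %% pi
  structure(list(center = stats::setNames(ctr, c("row", "col")),
                 semi_axes = stats::setNames(axes, c("a", "b")),
                 orientation = theta, level = level),
            class = "roi_ellipse")
}

#' @export
print.roi_ellipse <- function(x, ...) {
  cat(sprintf("roi_ellipse: center (%.1f, %.1f), semi-axes %.1f x %.1f, theta %.2f rad, level %.2f\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$orientation, x$level))
  invisible(x)
}

# Ellipse membership test for (row, col) coordinates (matrix or vectors).
roi_contains <- function(roi, rows, cols = NULL) {
  if (is.null(cols)) { cols <- rows[, 2]; rows <- rows[, 1] }
  dr <- rows - roi$center[1]
  dc <- cols - roi$center[2]
  u <- cos(roi$orientation) * dc + sin(roi$orientation) * dr
  v <- -sin(roi$orientation) * dc + cos(roi$orientation) * dr
  (u / roi$semi_axes[1])^2 + (v / roi$semi_axes[2])^2 <= 1
}

#' Mask an image to an elliptical ROI
#'
#' Pixels whose centers fall outside the ellipse are set to 0; pixels inside
#' are unchanged. Masking twice with the same ROI equals masking once.
#'
#' @param img Numeric matrix.
#' @param roi An `roi_ellipse` from [fit_confidence_ellipse()].
#' @return Numeric matrix of the same shape.
#' @export
mask_to_roi <- function(img, roi) {
  stopifnot(is.matrix(img), inherits(roi, "roi_ellipse"))
  rows <- matrix(rep(seq_len(nrow(img)), ncol(img)), nrow = nrow(img))
  cols <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow = nrow(img))
  img * roi_contains(roi, rows, cols)
}

#' Serialize an ROI ellipse to JSON
#' @param roi An `roi_ellipse`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_ellipse"))
  jsonlite::write_json(list(center = unname(roi$center),
                            semi_axes = unname(roi$semi_axes),
                            orientation = roi$orientation,
                            level = roi$level),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
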