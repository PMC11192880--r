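#' @importFrom rlang %||% abort warn hash
#' @importFrom stats rnorm runif setNames median predict
#' @importFrom utils head tail
NULL

# Shared coordinate convention: 0-based pixel centers, origin at the top-left
# corner, x rightward, y downward. All modules use it.

#' Lower median
#'
#' Deterministic median that returns the lower of the two middle order
#' statistics for even-length input (so aggregated coordinates are always
#' values that were actually predicted).
#'
#' @param x Numeric vector (NAs dropped).
#' @return A single number.
#' @export
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  if (length(x) == 0L) return(NA_real_)
  x[[floor((length(x) + 1) / 2)]]
}

# Truncated isotropic Gaussian noise, clipped at 3 SD per axis.
trunc_norm <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  pmin(pmax(rnorm(n, 0, sd), -3 * sd), 3 * sd)
}

#' Resize a grayscale image matrix
#'
#' Bilinear resize of an image stored as a numeric matrix with rows = y and
#' columns = x. Coordinates map between resolutions as
#' `src = (dst + 0.5) * src_size / dst_size - 0.5` (0-based pixel centers);
#' [rescale_coords()] applies the same convention to keypoints.
#'
#' @param img Numeric matrix (H x W), values in `[0, 1]`.
#' @param height,width Target size in pixels.
#' @return A `height` x `width` numeric matrix.
#' @export
resize_image <- function(img, height, width = NULL) {
  stopifnot(is.matrix(img), height >= 1)
  if (is.null(width)) {
    width <- max(1L, round(ncol(img) * height / nrow(img)))
  }
  height <- as.integer(height); width <- as.integer(width)
  if (height == nrow(img) && width == ncol(img)) return(img)
  # area-average antialiasing when downscaling: average k x k bilinear
  # subsamples per target pixel (k = ceiling of the scale factor)
  k <- ceiling(max(nrow(img) / height, ncol(img) / width))
  if (k > 1) {
    acc <- matrix(0, height, width)
    offs <- (seq_len(k) - 0.5) / k - 0.5    # subsample offsets in [-.5,.5)
    for (oy in offs) for (ox in offs) {
      acc <- acc + .bilinear_sample(img, height, width, oy, ox)
    }
    return(acc / k^2)
  }
  .bilinear_sample(img, height, width, 0, 0)
}

# Bilinear sampling of `img` on a height x width grid, with subpixel
# offsets (in target-pixel units) for area-average downscaling.
.bilinear_sample <- function(img, height, width, oy = 0, ox = 0) {
  sy <- nrow(img) / height
  sx <- ncol(img) / width
  yy <- (seq_len(height) - 0.5 + oy) * sy - 0.5   # 0-based source coords
  xx <- (seq_len(width) - 0.5 + ox) * sx - 0.5
  y0 <- pmin(pmax(floor(yy), 0), nrow(img) - 1)
  x0 <- pmin(pmax(floor(xx), 0), ncol(img) - 1)
  y1 <- pmin(y0 + 1, nrow(img) - 1)
  x1 <- pmin(x0 + 1, ncol(img) - 1)
  fy <- pmin(pmax(yy - y0, 0), 1)
  fx <- pmin(pmax(xx - x0, 0), 1)
  a <- img[y0 + 1L, x0 + 1L, drop = FALSE]
  b <- img[y0 + 1L, x1 + 1L, drop = FALSE]
  c_ <- img[y1 + 1L, x0 + 1L, drop = FALSE]
  d <- img[y1 + 1L, x1 + 1L, drop = FALSE]
  top <- a * rep(1 - fx, each = height) + b * rep(fx, each = height)
  bot <- c_ * rep(1 - fx, each = height) + d * rep(fx, each = height)
  top * (1 - fy) + bot * fy
}

#' Map keypoint coordinates between image resolutions
#'
#' @param xy Numeric vector/matrix of coordinates (0-based pixel centers).
#' @param from,to Source and target sizes along the same axis, in pixels.
#' @return Rescaled coordinates.
#' @export
rescale_coords <- function(xy, from, to) {
  (xy + 0.5) * (to / from) - 0.5
}

# Shoelace polygon area (vertices in order, any orientation).
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Convex hull area of a 2-D point set.
hull_area <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  shoelace_area(x[h], y[h])
}

assert_track <- function(track) {
  need <- c("frame", "keypoint", "x", "y")
  if (!all(need %in% names(track))) {
    abort(paste0("a pose track needs columns ",
                 paste(need, collapse = ", ")))
  }
  invisible(track)
}

track_fps <- function(track, fps = NULL) {
  fps <- fps %||% attr(track, "fps")
  if (is.null(fps)) abort("frame rate unknown: pass `fps` or set attr(track, 'fps')")
  fps
}
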