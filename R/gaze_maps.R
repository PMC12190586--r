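#' Gaussian point-spread value of a single fixation
#'
#' Evaluates the Gaussian field-of-view model that turns a point fixation into
#' a spatial gaze area:
#' \deqn{G(x, y) = \frac{1}{\sqrt{2\pi}\,\sigma}
#'   \exp\!\left(-\frac{(x-x_c)^2 + (y-y_c)^2}{2\sigma^2}\right).}
#' The constant uses the one-dimensional normalizer; because rendered gaze maps
#' are max-normalized afterwards (see [render_gaze_map()]) the constant cancels
#' and is immaterial to the supervision signal.
#'
#' @param x,y Pixel coordinates at which to evaluate (0-based, pixel-center
#'   convention, origin top-left). Vectorized.
#' @param center Numeric length-2 vector `c(x_c, y_c)`: the fixation point.
#' @param sigma Standard deviation in pixels; must be positive.
#' @return Strictly positive numeric vector, radially symmetric about `center`.
#' @seealso [effective_sigma()] for calibrating `sigma` from viewing geometry.
#' @export
#' @examples
#' point_spread(0, 0, center = c(0, 0), sigma = 30)  # 1 / (sqrt(2*pi) * 30)
point_spread <- function(x, y, center, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  d2 <- (x - center[1L])^2 + (y - center[2L])^2
  exp(-d2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

#' Viewing geometry of an eye-tracking recording setup
#'
#' Bundles the display and observer parameters that determine how a given
#' angular gaze error maps to a pixel distance on screen.
#'
#' @param screen_w_px,screen_h_px Display resolution in pixels
#'   (defaults 1920 x 1080).
#' @param screen_w_phys,screen_h_phys Physical display extent, in the same
#'   length unit as `eye_distance` (defaults 64 x 48, i.e. centimetres for a
#'   27-inch 16:9 panel).
#' @param eye_distance Eye-to-screen distance `R` (default 50).
#' @param perspective_error_deg Angular gaze error `theta` in degrees, in
#'   (0, 90); default 1.
#' @return An object of class `"viewing_geometry"`.
#' @export
viewing_geometry <- function(screen_w_px = 1920, screen_h_px = 1080,
                             screen_w_phys = 64, screen_h_phys = 48,
                             eye_distance = 50, perspective_error_deg = 1) {
  g <- list(screen_w_px = screen_w_px, screen_h_px = screen_h_px,
            screen_w_phys = screen_w_phys, screen_h_phys = screen_h_phys,
            eye_distance = eye_distance,
            perspective_error_deg = perspective_error_deg)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("viewing_geometry field '%s' must be a single positive number", nm),
           call. = FALSE)
  }
  if (g$perspective_error_deg >= 90)
    stop("'perspective_error_deg' must lie in (0, 90)", call. = FALSE)
  structure(g, class = "viewing_geometry")
}

#' Pixel-scale gaze spread implied by viewing geometry
#'
#' Converts an angular gaze error into a standard deviation in display pixels.
#' A physical error radius of \eqn{\sigma_1 = \pi R \theta / 360} on the screen
#' surface is rescaled to pixels by equating area fractions of the physical and
#' pixel screen extents, giving
#' \deqn{\sigma = \frac{\theta}{360}\,\pi R\,
#'   \sqrt{\frac{H_p W_p}{H W}}.}
#' The value is linear in both `eye_distance` and `perspective_error_deg`, and
#' increasing in the pixel density \eqn{H_p W_p / (H W)}. It is provided as a
#' calibration aid for choosing the `sigma` of [render_gaze_map()]; it is not
#' wired in as a default.
#'
#' @param geom A [viewing_geometry()] object.
#' @return Standard deviation in pixels (single number).
#' @export
#' @examples
#' effective_sigma(viewing_geometry(eye_distance = 50))
effective_sigma <- function(geom) {
  if (!inherits(geom, "viewing_geometry"))
    geom <- do.call(viewing_geometry, as.list(geom))
  (geom$perspective_error_deg / 360) * pi * geom$eye_distance *
    sqrt((geom$screen_h_px * geom$screen_w_px) /
           (geom$screen_h_phys * geom$screen_w_phys))
}

#' Ordered fixation sequence for one image reading
#'
#' @param image_id Identifier of the image being read.
#' @param x_px,y_px Screen-pixel coordinates of each fixation (0-based, origin
#'   top-left).
#' @param timestamp_ms Acquisition times in milliseconds; the sequence is
#'   sorted by timestamp.
#' @param duration_ms Optional fixation durations (default 1 per sample, i.e.
#'   unit weight).
#' @param screen_w_px,screen_h_px Recording-display resolution
#'   (defaults 1920 x 1080).
#' @return An object of class `"fixation_sequence"`: a list with the sorted
#'   per-fixation data frame in `$points`.
#' @export
fixation_sequence <- function(image_id, x_px, y_px, timestamp_ms,
                              duration_ms = NULL,
                              screen_w_px = 1920, screen_h_px = 1080) {
  n <- length(x_px)
  stopifnot(length(y_px) == n, length(timestamp_ms) == n)
  if (is.null(duration_ms)) duration_ms <- rep(1, n)
  stopifnot(length(duration_ms) == n)
  if (n > 0L && (!all(is.finite(x_px)) || !all(is.finite(y_px))))
    stop("fixation coordinates must be finite", call. = FALSE)
  if (any(duration_ms < 0)) stop("'duration_ms' must be >= 0", call. = FALSE)
  if (screen_w_px <= 0 || screen_h_px <= 0)
    stop("screen dimensions must be positive", call. = FALSE)
  o <- order(timestamp_ms)
  structure(list(
    image_id = as.character(image_id),
    points = data.frame(x_px = as.numeric(x_px)[o], y_px = as.numeric(y_px)[o],
                        timestamp_ms = as.numeric(timestamp_ms)[o],
                        duration_ms = as.numeric(duration_ms)[o]),
    screen_w_px = screen_w_px, screen_h_px = screen_h_px),
    class = "fixation_sequence")
}

#' @export
print.fixation_sequence <- function(x, ...) {
  cat(sprintf("<fixation_sequence> image '%s': %d fixations on a %dx%d px screen\n",
              x$image_id, nrow(x$points), x$screen_w_px, x$screen_h_px))
  invisible(x)
}

# 1-D discrete Gaussian taps (odd length), normalized to sum 1.
gaussian_taps <- function(kernel_taps, sigma) {
  m <- (kernel_taps - 1L) %/% 2L
  t <- exp(-((-m:m)^2) / (2 * sigma^2))
  t / sum(t)
}

# Banded convolution matrix applying 1-D taps along a dimension of size n,
# with zero or reflected borders. C[i, j] holds the weight with which source
# row j contributes to destination row i.
conv_matrix <- function(n, taps, border = c("zero", "reflect")) {
  border <- match.arg(border)
  m <- (length(taps) - 1L) %/% 2L
  C <- matrix(0, n, n)
  for (k in -m:m) {
    w <- taps[k + m + 1L]
    j <- seq_len(n) + k           # source index for each destination row
    if (border == "reflect") {    # fold out-of-range indices back in
      j <- ifelse(j < 1L, 2L - j, j)
      j <- ifelse(j > n, 2L * n - j, j)
    }
    keep <- j >= 1L & j <= n
    C[cbind(seq_len(n)[keep], j[keep])] <-
      C[cbind(seq_len(n)[keep], j[keep])] + w
  }
  C
}

#' Render a gaze-attention map from a fixation sequence
#'
#' Converts screen-space fixations into a dense, max-normalized attention map
#' over image pixels: fixations are mapped into image coordinates (the image
#' is assumed displayed centered on the recording screen at native size),
#' off-image fixations are dropped, the remaining fixations are accumulated
#' into an impulse image (unit weight each, or their duration when
#' `weight_by_duration`), the impulse image is smoothed with a separable
#' discrete Gaussian kernel, and the result is rescaled so its maximum is 1.
#'
#' @param fix A [fixation_sequence()].
#' @param img_w,img_h Image size in pixels.
#' @param sigma Gaussian standard deviation in pixels (default 30, the preset
#'   that over-covers the angular-error calibration of [effective_sigma()]).
#' @param kernel_taps Odd kernel length (default 199).
#' @param weight_by_duration Weight each fixation by its `duration_ms` rather
#'   than 1 (default `FALSE`).
#' @param offset Screen-to-image offset `c(dx, dy)` such that
#'   `image_xy = screen_xy - offset`; default centers the image on the screen.
#' @param border Border handling for the smoothing kernel: `"zero"` (default)
#'   or `"reflect"`.
#' @return An object of class `"gaze_attention_map"`: list with `values` (an
#'   `img_h` x `img_w` matrix in \[0, 1\], maximum exactly 1 whenever at least
#'   one fixation fell inside the image, all-zero otherwise) and `image_id`.
#' @export
render_gaze_map <- function(fix, img_w, img_h, sigma = 30, kernel_taps = 199,
                            weight_by_duration = FALSE, offset = NULL,
                            border = c("zero", "reflect")) {
  border <- match.arg(border)
  stopifnot(inherits(fix, "fixation_sequence"))
  if (img_w <= 0 || img_h <= 0) stop("image dimensions must be positive", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (kernel_taps %% 2L != 1L) stop("'kernel_taps' must be odd", call. = FALSE)
  if (is.null(offset))
    offset <- c((fix$screen_w_px - img_w) / 2, (fix$screen_h_px - img_h) / 2)

  pts <- fix$points
  if (nrow(pts) == 0L) {
    warning(sprintf("image '%s': empty fixation list; returning all-zero map",
                    fix$image_id), call. = FALSE)
    return(structure(list(values = matrix(0, img_h, img_w),
                          image_id = fix$image_id),
                     class = "gaze_attention_map"))
  }
  ix <- round(pts$x_px - offset[1L])   # 0-based image column
  iy <- round(pts$y_px - offset[2L])   # 0-based image row
  keep <- ix >= 0 & ix < img_w & iy >= 0 & iy < img_h
  impulse <- matrix(0, img_h, img_w)
  if (any(keep)) {
    w <- if (weight_by_duration) pts$duration_ms[keep] else rep(1, sum(keep))
    idx <- cbind(iy[keep] + 1L, ix[keep] + 1L)
    for (r in seq_len(nrow(idx)))
      impulse[idx[r, 1L], idx[r, 2L]] <- impulse[idx[r, 1L], idx[r, 2L]] + w[r]
  } else {
    warning(sprintf("image '%s': no fixation inside the image; all-zero map",
                    fix$image_id), call. = FALSE)
  }
  taps <- gaussian_taps(kernel_taps, sigma)
  sm <- conv_matrix(img_h, taps, border) %*% impulse %*%
    t(conv_matrix(img_w, taps, border))
  mx <- max(sm)
  if (mx > 0) sm <- sm / mx
  structure(list(values = sm, image_id = fix$image_id),
            class = "gaze_attention_map")
}

#' @export
print.gaze_attention_map <- function(x, ...) {
  cat(sprintf("<gaze_attention_map> image '%s': %d x %d, max %.3f\n",
              x$image_id, nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

# Jet-style colormap: map values in [0,1] to an n x 3 RGB matrix in [0,1].
heat_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                 "red", "#7F0000"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Superimpose a gaze or network attention map on an RGB image
#'
#' Color-maps the attention values (blue = low, red = high) and alpha-blends
#' the result over the image, producing the familiar attention-heatmap
#' overlay.
#'
#' @param image Numeric array `(h, w, 3)` with values in \[0, 1\].
#' @param map A `"gaze_attention_map"`, `"network_attention_map"`, or a plain
#'   matrix of the same spatial size as `image`.
#' @param alpha Blend weight of the colormapped attention in \[0, 1\]
#'   (default 0.5). `alpha = 0` returns the image unchanged.
#' @return Numeric array `(h, w, 3)` in \[0, 1\].
#' @export
overlay_heatmap <- function(image, map, alpha = 0.5) {
  vals <- if (is.matrix(map)) map else map$values
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L)
  if (!identical(dim(image)[1:2], dim(vals)))
    stop("attention map shape does not match image spatial shape", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]", call. = FALSE)
  cm <- heat_colors(as.vector(vals))
  out <- image
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * image[, , ch] +
      alpha * matrix(cm[, ch], nrow(vals), ncol(vals))
  out
}
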