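# Synthetic phantom dataset: elliptical lesions on a textured mucosa-like
# background, with class-specific texture rules chosen so the label is
# perfectly recoverable from the image, plus simulated scanpaths whose
# fixations concentrate on the lesion. Emulates the statistical structure the
# attention-consistency loss assumes (gaze density peaked on the diagnostic
# region), not the pixel statistics of real narrow-band-imaging endoscopy.

#' Phantom image generator settings
#'
#' @param img_size Square image size in pixels (>= 32; default 64).
#' @param n_patients Number of synthetic patients (default 30).
#' @param lesions_per_patient Integer range `c(min, max)` of images per
#'   patient (default 6-10, giving roughly 150/50/50 images across a
#'   60/20/20 patient split at the defaults).
#' @param class_probs Sampling probabilities of the three lesion classes
#'   (default balanced).
#' @param background_noise_sd Pixel noise standard deviation (default 0.03).
#' @return List of class `"phantom_spec"`.
#' @export
phantom_spec <- function(img_size = 64, n_patients = 30,
                         lesions_per_patient = c(6, 10),
                         class_probs = c(1, 1, 1) / 3,
                         background_noise_sd = 0.03) {
  if (img_size < 32) stop("'img_size' must be >= 32", call. = FALSE)
  stopifnot(n_patients >= 1, length(lesions_per_patient) == 2,
            lesions_per_patient[1] >= 1,
            lesions_per_patient[2] >= lesions_per_patient[1],
            length(class_probs) == 3, all(class_probs >= 0))
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("'class_probs' must sum to 1", call. = FALSE)
  structure(list(img_size = img_size, n_patients = n_patients,
                 lesions_per_patient = lesions_per_patient,
                 class_probs = class_probs,
                 background_noise_sd = background_noise_sd),
            class = "phantom_spec")
}

#' Scanpath simulator settings
#'
#' @param n_fixations Integer range of fixations per image (default 20-60).
#' @param on_lesion_prob Probability that a fixation targets the lesion
#'   (default 0.8); the remainder are uniform over the image.
#' @param lesion_sd_frac Isotropic scatter of on-lesion fixations, as a
#'   fraction of the lesion's equivalent radius `sqrt(area/pi)`
#'   (default 0.5).
#' @param screen_w_px,screen_h_px Simulated recording display (default
#'   1920 x 1080); the image is displayed centered at native size.
#' @return List of class `"scanpath_spec"`.
#' @export
scanpath_spec <- function(n_fixations = c(20, 60), on_lesion_prob = 0.8,
                          lesion_sd_frac = 0.5,
                          screen_w_px = 1920, screen_h_px = 1080) {
  stopifnot(length(n_fixations) == 2, n_fixations[1] >= 1,
            n_fixations[2] >= n_fixations[1],
            on_lesion_prob >= 0, on_lesion_prob <= 1, lesion_sd_frac >= 0)
  structure(list(n_fixations = n_fixations, on_lesion_prob = on_lesion_prob,
                 lesion_sd_frac = lesion_sd_frac,
                 screen_w_px = screen_w_px, screen_h_px = screen_h_px),
            class = "scanpath_spec")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate one phantom lesion image
#'
#' Draws an elliptical lesion at a random position/orientation on a noisy
#' mucosa-toned background and renders one of three class-specific textures:
#' class 0 — a smooth, slightly brightened lesion (low vessel density);
#' class 1 — a high-granularity tubular (striped) vessel texture; class 2 — a
#' darkened lesion with a dark irregular core. The texture rule is
#' deterministic given the drawn class, so the label is recoverable from the
#' image by construction. Uses the current RNG state.
#'
#' @param spec A [phantom_spec()].
#' @param label Optional fixed class in 0:2; by default drawn from
#'   `spec$class_probs`.
#' @return List with `image` `(s, s, 3)` in \[0, 1\], logical `mask`
#'   `(s, s)`, integer `label`, and the drawn `params`.
#' @export
make_phantom <- function(spec, label = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$img_size
  if (is.null(label))
    label <- sample(0:2, 1L, prob = spec$class_probs)
  stopifnot(label %in% 0:2)

  # pixel-center coordinate grids, 0-based; x = column, y = row
  x <- matrix(rep(0:(s - 1L), each = s), s, s)
  y <- matrix(rep(0:(s - 1L), times = s), s, s)

  # brightness jitter is shared across channels so lesion hue signatures
  # survive global pooling; per-channel jitter stays small
  base <- c(0.78, 0.55, 0.52) + stats::runif(1, -0.05, 0.05) +
    stats::runif(3, -0.01, 0.01)
  gx <- stats::runif(1, -0.06, 0.06); gy <- stats::runif(1, -0.06, 0.06)
  shade <- gx * (x / s - 0.5) + gy * (y / s - 0.5)   # gentle illumination ramp
  img <- array(NA_real_, c(s, s, 3))
  for (ch in 1:3)
    img[, , ch] <- base[ch] + shade +
      stats::rnorm(s * s, sd = spec$background_noise_sd)

  cx <- stats::runif(1, 0.32, 0.68) * s
  cy <- stats::runif(1, 0.32, 0.68) * s
  a <- stats::runif(1, 0.16, 0.26) * s
  b <- stats::runif(1, 0.12, 0.20) * s
  phi <- stats::runif(1, 0, pi)
  dx <- x - cx; dy <- y - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  rho2 <- u^2 + v^2
  mask <- rho2 <= 1
  edge <- clip01(1.15 - rho2)          # soft rim so the lesion has no hard halo
  edge[!mask] <- 0

  vessel_density <- granularity <- NA_real_
  if (label == 0L) {                   # smooth pale lesion, sparse vessels
    vessel_density <- stats::runif(1, 0, 0.15)
    tint <- c(0.10, 0.10, 0.18)        # whitish-pale: lifts blue most
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tint[ch] * edge
  } else if (label == 1L) {            # tubular high-granularity texture
    vessel_density <- stats::runif(1, 0.7, 1)
    granularity <- stats::runif(1, 3, 5)
    psi <- stats::runif(1, 0, pi)
    stripe <- 0.5 * (1 + sin(2 * pi * (x * cos(psi) + y * sin(psi)) /
                               granularity))
    # brown tubular vessels: green/blue drop sharply, red barely
    img[, , 1] <- img[, , 1] - (0.10 * vessel_density) * stripe * edge
    img[, , 2] <- img[, , 2] - (0.42 * vessel_density) * stripe * edge
    img[, , 3] <- img[, , 3] - (0.34 * vessel_density) * stripe * edge
  } else {                             # dark irregular amorphous core
    vessel_density <- stats::runif(1, 0.2, 0.5)
    th <- atan2(v, u)
    wob <- 0.55 * (1 + 0.25 * sin(3 * th + stats::runif(1, 0, 2 * pi)) +
                     0.15 * sin(5 * th + stats::runif(1, 0, 2 * pi)))
    core <- rho2 <= wob^2
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] - 0.12 * edge
      img[, , ch] <- img[, , ch] - 0.38 * core
    }
  }
  img <- clip01(img)
  list(image = img, mask = mask, label = as.integer(label),
       params = list(cx = cx, cy = cy, a = a, b = b, phi = phi,
                     vessel_density = vessel_density,
                     granularity = granularity))
}

#' Simulate an expert scanpath over a lesion image
#'
#' Draws a fixation count uniformly from the configured range; each fixation
#' lands on the lesion with probability `on_lesion_prob` (lesion centroid
#' plus isotropic Gaussian scatter with standard deviation
#' `lesion_sd_frac * sqrt(area/pi)`, redrawn while off-image) and otherwise
#' uniformly over the image. Timestamps advance at ~90 Hz. Coordinates are
#' reported in screen pixels with the image centered on the simulated
#' display. Uses the current RNG state.
#'
#' @param mask Logical lesion mask `(s, s)`; must be non-empty.
#' @param spec A [scanpath_spec()].
#' @param image_id Identifier stored in the returned sequence.
#' @return A [fixation_sequence()] in screen coordinates.
#' @export
simulate_scanpath <- function(mask, spec, image_id = "img") {
  stopifnot(inherits(spec, "scanpath_spec"), is.matrix(mask))
  if (!any(mask)) stop("lesion mask is empty", call. = FALSE)
  s_h <- nrow(mask); s_w <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1] - 1L); cx <- mean(idx[, 2] - 1L)
  r_eq <- sqrt(sum(mask) / pi)
  sd_px <- spec$lesion_sd_frac * r_eq
  n <- sample(spec$n_fixations[1]:spec$n_fixations[2], 1L)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < spec$on_lesion_prob) {
      repeat {
        px <- cx + stats::rnorm(1, sd = sd_px)
        py <- cy + stats::rnorm(1, sd = sd_px)
        if (px >= 0 && px <= s_w - 1 && py >= 0 && py <= s_h - 1) break
      }
    } else {
      px <- stats::runif(1, 0, s_w - 1)
      py <- stats::runif(1, 0, s_h - 1)
    }
    xs[i] <- px; ys[i] <- py
  }
  dt <- 1000 / 90 + stats::runif(n, -2, 2)
  off_x <- (spec$screen_w_px - s_w) / 2
  off_y <- (spec$screen_h_px - s_h) / 2
  fixation_sequence(image_id,
                    x_px = xs + off_x, y_px = ys + off_y,
                    timestamp_ms = cumsum(dt),
                    duration_ms = stats::runif(n, 100, 400),
                    screen_w_px = spec$screen_w_px,
                    screen_h_px = spec$screen_h_px)
}

#' Patient-level train/validation/test split
#'
#' Randomly partitions patients (not images) according to `fractions` using
#' largest-remainder apportionment of the patient counts; every image
#' inherits its patient's split, so no patient contributes to more than one
#' split. Uses the current RNG state.
#'
#' @param manifest Data frame with a `patient_id` column.
#' @param fractions Length-3 train/val/test fractions summing to 1
#'   (default `c(0.6, 0.2, 0.2)`).
#' @return The manifest with a `split` column.
#' @export
split_by_patient <- function(manifest, fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(is.data.frame(manifest), "patient_id" %in% names(manifest),
            length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  patients <- unique(manifest$patient_id)
  P <- length(patients)
  if (P < sum(fractions > 0))
    stop("fewer patients than non-empty splits", call. = FALSE)
  quota <- fractions * P
  n <- floor(quota)
  rem <- P - sum(n)
  if (rem > 0) {
    extra <- order(quota - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1L
  }
  patients <- sample(patients)
  lab <- rep(c("train", "val", "test"), times = n)
  manifest$split <- lab[match(manifest$patient_id, patients)]
  manifest
}

#' Generate a complete synthetic gaze-classification dataset
#'
#' Produces phantom lesion images, ground-truth masks, labels, simulated
#' fixation sequences, rendered gaze-attention maps, and a patient-level
#' 60/20/20 split — everything [gazecam()] and [evaluate_model()] need, with
#' no eye tracker and no clinical data. The gaze-map smoothing width scales
#' with image size (`sigma = img_size * 30/512` pixels, kernel support ~6.6
#' sigma) so the field-of-view model keeps the same angular extent it has at
#' the native ~512 px working resolution. The whole dataset is a pure
#' function of the specs and `seed`.
#'
#' @param pspec A [phantom_spec()].
#' @param sspec A [scanpath_spec()].
#' @param seed Integer seed (default 1).
#' @param fractions Patient-level split fractions (default `c(.6, .2, .2)`).
#' @param sigma,kernel_taps Gaze-map rendering parameters; defaults scale
#'   with `pspec$img_size` as described above.
#' @param imbalanced Use the reference clinical class imbalance
#'   (0.26/0.70/0.04) instead of `pspec$class_probs` (default `FALSE`).
#' @return An object of class `"polyp_data"`: list with `images`
#'   `(s, s, 3, n)`, `masks` `(s, s, n)`, integer `labels` (0-based),
#'   `patient_id`, `image_id`, `split`, `gaze` (list of
#'   [fixation_sequence()]), `gaze_maps` `(s, s, n)`, and the `manifest`
#'   data frame.
#' @export
synthesize_polyp_data <- function(pspec = phantom_spec(),
                                  sspec = scanpath_spec(), seed = 1L,
                                  fractions = c(0.6, 0.2, 0.2),
                                  sigma = NULL, kernel_taps = NULL,
                                  imbalanced = FALSE) {
  stopifnot(inherits(pspec, "phantom_spec"), inherits(sspec, "scanpath_spec"))
  set.seed(seed)
  if (imbalanced) pspec$class_probs <- c(0.26, 0.70, 0.04)
  s <- pspec$img_size
  if (is.null(sigma)) sigma <- max(2, round(s * 30 / 512))
  if (is.null(kernel_taps)) {
    kernel_taps <- ceiling(sigma * 199 / 30)
    if (kernel_taps %% 2L == 0L) kernel_taps <- kernel_taps + 1L
  }

  n_per <- sample(pspec$lesions_per_patient[1]:pspec$lesions_per_patient[2],
                  pspec$n_patients, replace = TRUE)
  n <- sum(n_per)
  patient_id <- rep(sprintf("P%03d", seq_len(pspec$n_patients)), times = n_per)
  image_id <- sprintf("img%04d", seq_len(n))

  images <- array(NA_real_, c(s, s, 3, n))
  masks <- array(NA, c(s, s, n))
  labels <- integer(n)
  gaze <- vector("list", n); names(gaze) <- image_id
  gaze_maps <- array(NA_real_, c(s, s, n))
  for (i in seq_len(n)) {
    ph <- make_phantom(pspec)
    images[, , , i] <- ph$image
    masks[, , i] <- ph$mask
    labels[i] <- ph$label
    fx <- simulate_scanpath(ph$mask, sspec, image_id[i])
    gaze[[i]] <- fx
    gaze_maps[, , i] <- render_gaze_map(fx, s, s, sigma = sigma,
                                        kernel_taps = kernel_taps)$values
  }
  manifest <- data.frame(image_id = image_id, patient_id = patient_id,
                         label = labels, stringsAsFactors = FALSE)
  manifest <- split_by_patient(manifest, fractions)
  structure(list(images = images, masks = masks, labels = labels,
                 patient_id = patient_id, image_id = image_id,
                 split = manifest$split, gaze = gaze, gaze_maps = gaze_maps,
                 manifest = manifest, img_size = s,
                 sigma = sigma, kernel_taps = kernel_taps, seed = seed),
            class = "polyp_data")
}

#' @export
print.polyp_data <- function(x, ...) {
  cat(sprintf("<polyp_data> %d images (%dx%d px), %d patients\n",
              length(x$labels), x$img_size, x$img_size,
              length(unique(x$patient_id))))
  print(table(split = x$split, class = x$labels))
  invisible(x)
}
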