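#' Load and validate a dataset manifest
#'
#' Reads a CSV manifest with one row per image. Required columns:
#' `image_id`, `patient_id`, `label` (nonnegative integer), `split`
#' (`train`/`val`/`test`). Optional: `image_path`, `mask_path`, `gaze`.
#' Duplicate image ids, unknown split tokens, and (when `check_paths`)
#' unresolvable paths are rejected with row numbers.
#'
#' @param path CSV file path.
#' @param check_paths Verify that `image_path`/`mask_path` entries exist
#'   (default `FALSE`).
#' @return Data frame with a `"summary"` attribute: the split-by-class image
#'   count table (see [manifest_summary()]).
#' @export
load_manifest <- function(path, check_paths = FALSE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "patient_id", "label", "split")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- which(duplicated(m$image_id))
  if (length(dup))
    stop("duplicate image_id at row(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- which(!m$split %in% c("train", "val", "test"))
  if (length(bad))
    stop("unknown split token at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(m$label < 0) || any(m$label != floor(m$label)))
    stop("labels must be nonnegative integers", call. = FALSE)
  for (col in intersect(c("image_path", "mask_path"), names(m))) {
    if (check_paths) {
      gone <- which(!file.exists(m[[col]]))
      if (length(gone))
        stop(sprintf("%s does not resolve at row(s): %s", col,
                     paste(gone, collapse = ", ")), call. = FALSE)
    }
  }
  attr(m, "summary") <- manifest_summary(m)
  m
}

#' Split-by-class image counts of a manifest
#'
#' @param manifest Manifest data frame.
#' @return Count table with splits in rows (train, val, test) and classes in
#'   columns.
#' @export
manifest_summary <- function(manifest) {
  table(split = factor(manifest$split, levels = c("train", "val", "test")),
        class = factor(manifest$label, levels = sort(unique(manifest$label))))
}

#' @rdname load_manifest
#' @param manifest Manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a gaze log CSV into fixation sequences
#'
#' Expects a header with `image_id`, `timestamp_ms`, `x_px`, `y_px`,
#' `duration_ms`, one row per gaze sample. Rows are grouped by image and
#' sorted by timestamp. A sampling-interval sanity check against the nominal
#' 90 Hz recording rate logs a warning (never an error) when the median
#' interval is off by more than half.
#'
#' @param path CSV file path.
#' @param screen_w_px,screen_h_px Recording display resolution attached to
#'   every sequence (defaults 1920 x 1080).
#' @return Named list of [fixation_sequence()] objects, one per image id.
#' @export
load_gaze_log <- function(path, screen_w_px = 1920, screen_h_px = 1080) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  req <- c("image_id", "timestamp_ms", "x_px", "y_px", "duration_ms")
  miss <- setdiff(req, names(g))
  if (length(miss))
    stop("gaze log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(g) == 0L) return(structure(list(), names = character()))
  num <- c("timestamp_ms", "x_px", "y_px", "duration_ms")
  for (col in num) {
    v <- suppressWarnings(as.numeric(g[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric '%s' at row(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    g[[col]] <- v
  }
  out <- lapply(split(g, g$image_id), function(d) {
    fs <- fixation_sequence(d$image_id[1L], d$x_px, d$y_px, d$timestamp_ms,
                            d$duration_ms, screen_w_px, screen_h_px)
    dt <- diff(fs$points$timestamp_ms)
    if (length(dt) > 2) {
      md <- stats::median(dt)
      if (is.finite(md) && (md < 0.5 * 1000 / 90 || md > 2 * 1000 / 90))
        warning(sprintf(
          "image '%s': median sample interval %.1f ms deviates from the nominal 90 Hz",
          d$image_id[1L], md), call. = FALSE)
    }
    fs
  })
  out[unique(g$image_id)]
}

#' @rdname load_gaze_log
#' @param gaze Named list of fixation sequences to write.
#' @export
write_gaze_log <- function(gaze, path) {
  rows <- do.call(rbind, lapply(gaze, function(fs)
    cbind(data.frame(image_id = fs$image_id, stringsAsFactors = FALSE),
          fs$points[c("timestamp_ms", "x_px", "y_px", "duration_ms")])))
  rownames(rows) <- NULL
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a gaze-attention map losslessly
#'
#' Writes the map as 16-bit grayscale TIFF (integer value 65535 represents
#' 1.0) and, optionally, as a plain-text CSV array for tool-agnostic reuse.
#'
#' @param map `"gaze_attention_map"`, `"network_attention_map"`, or matrix
#'   with values in \[0, 1\].
#' @param path Output TIFF path.
#' @param csv_path Optional CSV array path.
#' @return `path`, invisibly.
#' @export
write_gaze_map <- function(map, path, csv_path = NULL) {
  v <- if (is.list(map)) map$values else map
  stopifnot(all(v >= 0), all(v <= 1))
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  if (!is.null(csv_path))
    utils::write.table(v, csv_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_map
#' @export
read_gaze_map <- function(path) {
  v <- tiff::readTIFF(path)
  structure(list(values = v, image_id = basename(path)),
            class = "gaze_attention_map")
}

#' Write a synthetic dataset to disk
#'
#' Materializes a [synthesize_polyp_data()] object as `images/*.png` (8-bit
#' RGB), `masks/*.png` (binary), `gaze.csv` (the gaze-log format of
#' [load_gaze_log()]), and `manifest.csv`.
#'
#' @param data A `"polyp_data"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_polyp_data <- function(data, dir) {
  stopifnot(inherits(data, "polyp_data"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- length(data$labels)
  man <- data$manifest
  man$image_path <- file.path("images", paste0(data$image_id, ".png"))
  man$mask_path <- file.path("masks", paste0(data$image_id, ".png"))
  for (i in seq_len(n)) {
    png::writePNG(data$images[, , , i], file.path(dir, man$image_path[i]))
    png::writePNG(data$masks[, , i] * 1.0, file.path(dir, man$mask_path[i]))
  }
  write_gaze_log(data$gaze, file.path(dir, "gaze.csv"))
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Save a CAM overlay image
#'
#' Exports the attention-heatmap overlay of [overlay_heatmap()] as an 8-bit
#' RGB PNG — the standard qualitative check of where the model looks.
#'
#' @param image RGB array `(h, w, 3)` in \[0, 1\].
#' @param map Attention map (matrix or map object).
#' @param path Output PNG path.
#' @param alpha Blend weight (default 0.5).
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, map, path, alpha = 0.5) {
  png::writePNG(overlay_heatmap(image, map, alpha), path)
  invisible(path)
}

run_config_defaults <- function() {
  list(img_size = 64L, sigma = 30, kernel_taps = 199L,
       lr = 0.001, lr_min = 0, t0 = 10L, t_mult = 2,
       batch_train = 8L, batch_val = 16L, max_epochs = 150L,
       lambda_gaze = 1, seed = 1L,
       flip_lr = TRUE, flip_ud = TRUE, rotate = TRUE,
       cam_class = "predicted", relu_on = "weights", average = "macro")
}

#' Validated run configuration
#'
#' A flat key-value configuration covering the gaze-map, training, and
#' evaluation parameters, validated against a fixed schema with explicit
#' defaults; unknown keys are rejected.
#'
#' @param ... Key = value overrides of the defaults (see
#'   `gazecam:::run_config_defaults()`).
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  ov <- list(...)
  cfg <- run_config_defaults()
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of flat key-value pairs.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg A `"run_config"` to write.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
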