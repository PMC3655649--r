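## Readers and writers: marker-track CSV (global or raw stage+camera
## columns), calibration YAML, results CSV/JSON.

#' Read a marker-track CSV
#'
#' One row per marker observation. Two column layouts are accepted:
#' pre-fused global coordinates (`x_mm`, `y_mm`, or already `x`, `y`), or
#' raw stage + camera columns (`stage_x_mm`, `stage_y_mm`, `cam_x_px`,
#' `cam_y_px`), which require a calibration to fuse via [to_global()]. The
#' camera y-axis is flipped to the mathematical convention at ingest when
#' the calibration says so (image rows usually increase downward).
#'
#' @param path CSV file with header; columns `marker_id`, `step_id` plus one
#'   of the coordinate layouts above.
#' @param calibration A [calibration_params()]; required for the raw layout.
#' @return Tibble with `step_id`, `marker_id`, `x`, `y` (mm) plus any raw
#'   columns that were present.
#' @export
read_marker_tracks <- function(path, calibration = NULL) {
  if (!file.exists(path)) {
    qp_abort(sprintf("input file not found: %s", path), "qp_error_schema")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("marker_id", "step_id") %in% names(df))) {
    qp_abort("track CSV needs marker_id and step_id columns", "qp_error_schema")
  }
  if (all(c("x_mm", "y_mm") %in% names(df))) {
    df <- rename(df, x = "x_mm", y = "y_mm")
  }
  if (all(c("x", "y") %in% names(df))) {
    stopifnot_finite(cbind(df$x, df$y), "global coordinates")
    return(as_tibble(df))
  }
  raw <- c("stage_x_mm", "stage_y_mm", "cam_x_px", "cam_y_px")
  if (!all(raw %in% names(df))) {
    qp_abort("track CSV needs either x_mm/y_mm or stage_x_mm/stage_y_mm/cam_x_px/cam_y_px columns",
             "qp_error_schema")
  }
  if (is.null(calibration)) {
    qp_abort("raw stage+camera tracks require a calibration", "qp_error_calibration")
  }
  if (isTRUE(calibration$flip_camera_y)) df$cam_y_px <- -df$cam_y_px
  to_global(df, calibration)
}

#' Write a marker-track table as CSV
#' @param tracks Tibble from [simulate_tracks()] or compatible.
#' @param path Output CSV path.
#' @export
write_marker_tracks <- function(tracks, path) {
  readr::write_csv(as_tibble(tracks), path)
  invisible(path)
}

#' Read / write calibration files
#'
#' Flat YAML with keys `theta_s_c_deg`, `pixel_scale_mm_per_px`,
#' `flip_camera_y` and optionally `camera_origin_offset_mm` (2 numbers).
#'
#' @param path YAML file path.
#' @return `read_calibration()`: a [calibration_params()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    qp_abort(sprintf("calibration file not found: %s", path),
             "qp_error_calibration")
  }
  y <- yaml::read_yaml(path)
  calibration_params(
    theta_s_c_deg = y$theta_s_c_deg %||% 0,
    pixel_scale = y$pixel_scale_mm_per_px %||% 1,
    camera_origin_offset = unlist(y$camera_origin_offset_mm) %||% c(0, 0),
    flip_camera_y = y$flip_camera_y %||% TRUE)
}

#' @rdname read_calibration
#' @param calib A [calibration_params()].
#' @export
write_calibration <- function(calib, path) {
  yaml::write_yaml(list(
    theta_s_c_deg = rad2deg(calib$theta_s_c),
    pixel_scale_mm_per_px = calib$pixel_scale,
    camera_origin_offset_mm = as.numeric(calib$camera_origin_offset),
    flip_camera_y = calib$flip_camera_y), path)
  invisible(path)
}

#' Write per-step results
#'
#' CSV values are rounded to 4 decimal places for human consumption; the
#' JSON sidecar keeps full precision plus the run configuration.
#'
#' @param fit A `qp_fit` from [qp_evaluate()], or its results tibble.
#' @param csv_path Output CSV; `NULL` to skip.
#' @param json_path Optional JSON output with full-precision diagnostics.
#' @export
write_results <- function(fit, csv_path, json_path = NULL) {
  results <- if (inherits(fit, "qp_fit")) fit$results else as_tibble(fit)
  if (!is.null(csv_path)) {
    out <- results
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round, digits = 4)
    readr::write_csv(out, csv_path)
  }
  if (!is.null(json_path)) {
    payload <- list(results = results,
                    config = if (inherits(fit, "qp_fit")) fit$config)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(results)
}

#' Write a grayscale image as 16-bit PNG
#' @param image Numeric matrix of grey levels.
#' @param path Output path.
#' @param max_level Full-scale grey level (default: image maximum).
#' @export
write_spot_image <- function(image, path, max_level = max(image)) {
  if (!requireNamespace("png", quietly = TRUE)) {
    qp_abort("the 'png' package is required to write images", "qp_error_config")
  }
  img <- pmin(pmax(image / max_level, 0), 1)
  png::writePNG(img, path, dpi = NULL)
  invisible(path)
}
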