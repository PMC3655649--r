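## Stage-camera coordinate fusion: a marker's global position combines the
## micro X-Y stage reading (mm) with its in-image position (px), after
## correcting the rotational offset theta_s_c between the two coordinate
## frames and scaling pixels to mm.

#' Stage-camera calibration parameters
#'
#' @param theta_s_c_deg Rotational offset between the camera-image frame and
#'   the stage frame, degrees (stored internally in radians; normalized to
#'   (-180, 180]).
#' @param pixel_scale mm per pixel; must be > 0.
#' @param camera_origin_offset 2-vector (mm) added to every global position.
#'   Defaults to c(0, 0): the method only uses differences of global
#'   positions, which are offset-invariant.
#' @param flip_camera_y Image row coordinates typically increase downward;
#'   when `TRUE` (default) readers flip the camera y-axis to the
#'   mathematical (upward) convention at ingest, before any rotation.
#' @return A `calibration_params` object.
#' @export
calibration_params <- function(theta_s_c_deg = 0, pixel_scale = 1,
                               camera_origin_offset = c(0, 0),
                               flip_camera_y = TRUE) {
  stopifnot_finite(c(theta_s_c_deg, pixel_scale, camera_origin_offset),
                   "calibration parameters")
  if (pixel_scale <= 0) {
    qp_abort("pixel_scale must be > 0 mm/px", "qp_error_calibration")
  }
  th <- deg2rad(theta_s_c_deg)
  th <- atan2(sin(th), cos(th))  # wrap to (-pi, pi]
  structure(list(theta_s_c = th, pixel_scale = pixel_scale,
                 camera_origin_offset = as.numeric(camera_origin_offset),
                 flip_camera_y = isTRUE(flip_camera_y)),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "<calibration_params> theta_s_c = %.4f deg, pixel_scale = %g mm/px, offset = (%g, %g), flip_camera_y = %s\n",
    rad2deg(x$theta_s_c), x$pixel_scale,
    x$camera_origin_offset[1], x$camera_origin_offset[2], x$flip_camera_y))
  invisible(x)
}

#' Fuse stage and camera observations into global coordinates
#'
#' global = stage + offset + pixel_scale * R(theta_s_c) * camera, with R the
#' counterclockwise 2D rotation. The transform is exact (no fitting) and
#' affine in the camera position. Camera coordinates are expected in the
#' mathematical (y-up) convention; readers apply the y-flip before calling
#' this (see [read_marker_tracks()]).
#'
#' @param obs Data frame with columns `stage_x_mm`, `stage_y_mm`,
#'   `cam_x_px`, `cam_y_px` (other columns pass through).
#' @param calib A [calibration_params()].
#' @return The input as a tibble with global `x`, `y` columns (mm) added.
#' @export
to_global <- function(obs, calib) {
  obs <- as_tibble(obs)
  need <- c("stage_x_mm", "stage_y_mm", "cam_x_px", "cam_y_px")
  if (!all(need %in% names(obs))) {
    qp_abort(sprintf("observations need columns %s",
                     paste(need, collapse = ", ")), "qp_error_schema")
  }
  stopifnot_finite(as.matrix(obs[need]), "stage/camera observations")
  R <- rot2(calib$theta_s_c)
  cam <- rbind(obs$cam_x_px, obs$cam_y_px)
  g <- calib$pixel_scale * (R %*% cam)
  obs$x <- obs$stage_x_mm + calib$camera_origin_offset[1] + g[1, ]
  obs$y <- obs$stage_y_mm + calib$camera_origin_offset[2] + g[2, ]
  obs
}

#' Estimate the stage-camera angle from an axis sweep
#'
#' The stage is driven along one of its axes while a stationary marker is
#' imaged; the marker's apparent track in the image is a straight line whose
#' direction, compared with the declared stage axis, gives theta_s_c. The
#' line is fitted by total least squares (the principal direction of the
#' camera positions), which treats both camera coordinates symmetrically
#' since neither is error-free.
#'
#' @param track Data frame with columns `cam_x_px`, `cam_y_px`: >= 2
#'   observations of one marker during a single-axis sweep.
#' @param declared_axis Which stage axis was driven: `"x"` or `"y"`.
#' @return List with `theta` (radians, in (-pi/2, pi/2]), `theta_deg`, `n`,
#'   and `rms_residual_px` (orthogonal scatter about the fitted line).
#' @export
estimate_theta <- function(track, declared_axis = c("x", "y")) {
  declared_axis <- match.arg(declared_axis)
  track <- as_tibble(track)
  if (!all(c("cam_x_px", "cam_y_px") %in% names(track))) {
    qp_abort("track needs columns cam_x_px, cam_y_px", "qp_error_schema")
  }
  P <- cbind(track$cam_x_px, track$cam_y_px)
  stopifnot_finite(P, "camera track")
  if (nrow(P) < 2L) {
    qp_abort("need at least 2 observations to estimate theta_s_c",
             "qp_error_calibration")
  }
  Pc <- sweep(P, 2, colMeans(P))
  if (max(abs(Pc)) == 0) {
    qp_abort("camera positions are all identical; cannot estimate theta_s_c",
             "qp_error_calibration")
  }
  sv <- svd(Pc)
  v <- sv$v[, 1]
  ang <- atan2(v[2], v[1])
  if (declared_axis == "y") ang <- ang - pi / 2
  ang <- normalize_half_angle(ang)
  rms <- if (nrow(P) > 2L || sv$d[2] > 0) sv$d[2] / sqrt(nrow(P)) else 0
  list(theta = ang, theta_deg = rad2deg(ang), n = nrow(P),
       rms_residual_px = rms)
}

#' Estimate stage-camera calibration from one or two axis sweeps
#'
#' Tidy front end to [estimate_theta()]. If `obs` has a `stage_axis` column
#' with values `"x"`/`"y"`, each axis sweep is fitted separately (grouped by
#' `marker_id` if present) and the per-axis angle estimates are averaged;
#' otherwise the whole table is treated as one sweep along `declared_axis`.
#'
#' @param obs Observation data frame with `cam_x_px`, `cam_y_px` and
#'   optionally `stage_axis`, `marker_id`.
#' @param declared_axis Axis used when `obs` has no `stage_axis` column.
#' @param pixel_scale mm per pixel, from a user-supplied reference distance
#'   (the angle fit cannot determine it).
#' @param flip_camera_y Whether raw image rows increase downward; applied to
#'   `cam_y_px` before fitting so the estimated angle refers to the
#'   mathematical convention used by [to_global()].
#' @return A [calibration_params()] with attribute `"fits"` holding the
#'   per-sweep fit summaries.
#' @export
qp_calibrate <- function(obs, declared_axis = c("x", "y"), pixel_scale = 1,
                         flip_camera_y = TRUE) {
  obs <- as_tibble(obs)
  if (isTRUE(flip_camera_y) && "cam_y_px" %in% names(obs)) {
    obs$cam_y_px <- -obs$cam_y_px
  }
  sweeps <- if ("stage_axis" %in% names(obs)) {
    split(obs, obs$stage_axis)
  } else {
    setNames(list(obs), match.arg(declared_axis))
  }
  fits <- imap(sweeps, function(d, ax) {
    if (!ax %in% c("x", "y")) {
      qp_abort(sprintf("stage_axis must be 'x' or 'y', got '%s'", ax),
               "qp_error_schema")
    }
    estimate_theta(d, declared_axis = ax)
  })
  theta_deg <- mean(map_dbl(fits, "theta_deg"))
  calib <- calibration_params(theta_s_c_deg = theta_deg,
                              pixel_scale = pixel_scale,
                              flip_camera_y = flip_camera_y)
  attr(calib, "fits") <- fits
  calib
}
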