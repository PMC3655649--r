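## Optional image layer of the synthetic module: render ink-spot markers as
## Gaussian blobs on a grayscale image and recover their subpixel centroids,
## emulating the CCD imaging + spot-detection front end of the optical
## measurement.

#' Parameters for synthetic marker-spot images
#'
#' @param image_size c(rows, cols) in pixels.
#' @param spot_sigma Gaussian spot radius, pixels (> 0).
#' @param peak_intensity Spot peak above zero, grey levels; must exceed
#'   `background`.
#' @param background Constant background grey level.
#' @param photon_noise_sd Additive Gaussian noise, grey levels.
#' @param pixel_scale mm per pixel used to map marker mm coordinates onto
#'   the image (origin at the image centre, y up).
#' @export
spot_image_params <- function(image_size = c(256, 256), spot_sigma = 3,
                              peak_intensity = 1000, background = 100,
                              photon_noise_sd = 0, pixel_scale = 0.05) {
  if (spot_sigma <= 0) qp_abort("spot_sigma must be > 0", "qp_error_config")
  if (peak_intensity <= background) {
    qp_abort("peak_intensity must exceed background", "qp_error_config")
  }
  if (pixel_scale <= 0) qp_abort("pixel_scale must be > 0", "qp_error_config")
  structure(list(image_size = as.integer(image_size), spot_sigma = spot_sigma,
                 peak_intensity = peak_intensity, background = background,
                 photon_noise_sd = photon_noise_sd,
                 pixel_scale = pixel_scale),
            class = "spot_image_params")
}

## mm -> px: column/row coordinates with origin at the image centre, y up
mm_to_px <- function(x, y, p) {
  list(col = x / p$pixel_scale + (p$image_size[2] + 1) / 2,
       row = (p$image_size[1] + 1) / 2 - y / p$pixel_scale)
}

px_to_mm <- function(row, col, p) {
  list(x = (col - (p$image_size[2] + 1) / 2) * p$pixel_scale,
       y = ((p$image_size[1] + 1) / 2 - row) * p$pixel_scale)
}

#' Render marker spots as a grayscale image
#'
#' image = background + sum of isotropic Gaussian spots centred at the
#' marker positions, plus optional Gaussian noise. Deterministic for a
#' given seed.
#'
#' @param markers Data frame with `x`, `y` (mm).
#' @param p A [spot_image_params()].
#' @param seed Optional seed for the photon noise.
#' @return Numeric matrix (rows x cols) of grey levels.
#' @export
render_spots <- function(markers, p = spot_image_params(), seed = NULL) {
  markers <- as_tibble(markers)
  px <- mm_to_px(markers$x, markers$y, p)
  margin <- 3 * p$spot_sigma
  if (any(px$col < 1 + margin | px$col > p$image_size[2] - margin |
            px$row < 1 + margin | px$row > p$image_size[1] - margin)) {
    qp_abort("marker outside the field of view (3 sigma margin required)",
             "qp_error_fov")
  }
  rows <- seq_len(p$image_size[1]); cols <- seq_len(p$image_size[2])
  img <- matrix(p$background, p$image_size[1], p$image_size[2])
  for (k in seq_len(nrow(markers))) {
    gr <- exp(-(rows - px$row[k])^2 / (2 * p$spot_sigma^2))
    gc <- exp(-(cols - px$col[k])^2 / (2 * p$spot_sigma^2))
    img <- img + (p$peak_intensity - p$background) * outer(gr, gc)
  }
  if (p$photon_noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(rnorm(length(img), sd = p$photon_noise_sd),
                        nrow(img), ncol(img))
  }
  img
}

#' Detect marker spots and their subpixel centroids
#'
#' Thresholds the image at background + `threshold_frac` * (max -
#' background), labels 8-connected components, and returns the
#' intensity-weighted centroid of each component in mm. The quality score is
#' the minor/major axis ratio of the component's second-moment ellipse
#' (1 for a round isolated spot; low values flag elongated blobs such as two
#' merged spots).
#'
#' @param image Numeric matrix from [render_spots()] or a real frame.
#' @param threshold_frac Fraction in (0, 1) of the background-to-peak range.
#' @param p A [spot_image_params()] supplying the mm/px mapping; the
#'   background is re-estimated from the image median so real frames work.
#' @return Tibble sorted by component size (descending): `x`, `y` (mm),
#'   `size_px`, `quality`.
#' @export
detect_centroids <- function(image, threshold_frac = 0.5,
                             p = spot_image_params(image_size = dim(image))) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    qp_abort("threshold_frac must be in (0, 1)", "qp_error_config")
  }
  bg <- median(image)
  thr <- bg + threshold_frac * (max(image) - bg)
  mask <- image > thr
  if (!any(mask)) qp_abort("no marker spots above threshold", "qp_error_nomarker")
  lab <- EBImage::bwlabel(mask)
  ids <- seq_len(max(lab))
  rows <- row(image); cols <- col(image)
  out <- map(ids, function(i) {
    sel <- lab == i
    w <- pmax(image[sel] - bg, 0)
    if (sum(w) == 0) w <- rep(1, sum(sel))
    r <- sum(rows[sel] * w) / sum(w)
    c0 <- sum(cols[sel] * w) / sum(w)
    # second moments of the component footprint
    dr <- rows[sel] - r; dc <- cols[sel] - c0
    M <- matrix(c(sum(w * dr^2), sum(w * dr * dc),
                  sum(w * dr * dc), sum(w * dc^2)), 2, 2) / sum(w)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    q <- if (ev[1] <= 0) 1 else sqrt(max(ev[2], 0) / ev[1])
    mm <- px_to_mm(r, c0, p)
    tibble(x = mm$x, y = mm$y, size_px = sum(sel), quality = q)
  })
  list_rbind(out) |> arrange(desc(.data$size_px))
}
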