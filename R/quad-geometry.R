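## Marker quadrilaterals: construction, validation, canonical ordering.

#' Build a four-marker quadrilateral
#'
#' A `marker_quad` holds the global coordinates (mm) of four surface markers
#' that form the vertices of one quadrilateral element. Vertices are
#' re-ordered into counterclockwise order starting from the lexicographically
#' smallest vertex, so results downstream do not depend on the order markers
#' appear in the input.
#'
#' @param data Data frame with columns `marker_id` (or `marker`), `x`, `y`
#'   (mm). Exactly four rows.
#' @return A `marker_quad`: list with `xy` (4x2 matrix, counterclockwise) and
#'   `labels` (character, matching rows of `xy`).
#' @examples
#' q <- marker_quad(data.frame(marker_id = letters[1:4],
#'                             x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' quad_area(q)
#' @export
marker_quad <- function(data) {
  if (inherits(data, "marker_quad")) return(data)
  df <- as.data.frame(data)
  if (!"marker_id" %in% names(df) && "marker" %in% names(df)) {
    df$marker_id <- df$marker
  }
  need <- c("marker_id", "x", "y")
  if (!all(need %in% names(df))) {
    qp_abort(sprintf("marker_quad input needs columns %s",
                     paste(need, collapse = ", ")), "qp_error_schema")
  }
  if (nrow(df) != 4L) {
    qp_abort(sprintf("a quadrilateral needs exactly 4 markers, got %d",
                     nrow(df)), "qp_error_schema")
  }
  xy <- cbind(as.numeric(df$x), as.numeric(df$y))
  stopifnot_finite(xy, "marker coordinates")
  labels <- as.character(df$marker_id)
  if (anyDuplicated(labels)) {
    qp_abort("duplicated marker labels in quadrilateral", "qp_error_schema")
  }
  d <- as.matrix(stats::dist(xy))
  if (min(d[upper.tri(d)]) <= 1e-12 * max(1, max(abs(xy)))) {
    qp_abort("coincident marker positions in quadrilateral", "qp_error_schema")
  }
  ord <- canonical_order(xy)
  if (is.null(ord)) {
    qp_abort("markers do not form a simple (non-self-intersecting) quadrilateral",
             "qp_error_schema")
  }
  structure(list(xy = xy[ord, , drop = FALSE], labels = labels[ord]),
            class = "marker_quad")
}

## Find a counterclockwise simple ordering of 4 points, starting from the
## lexicographically smallest vertex. Prefers the cyclic order the caller
## supplied (so non-convex quads keep their boundary); falls back to angular
## order about the centroid. Returns NULL if no simple ordering is found.
canonical_order <- function(xy) {
  try_order <- function(idx) {
    p <- xy[idx, , drop = FALSE]
    if (!is_simple_quad(p)) return(NULL)
    if (signed_area(p) < 0) idx <- idx[c(1L, 4L, 3L, 2L)]
    p <- xy[idx, , drop = FALSE]
    if (signed_area(p) <= 0) return(NULL)
    start <- idx[lex_min_pos(p)]
    k <- which(idx == start)
    idx[((seq_len(4L) + k - 2L) %% 4L) + 1L]
  }
  ord <- try_order(1:4)
  if (!is.null(ord)) return(ord)
  ctr <- colMeans(xy)
  ang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
  try_order(order(ang))
}

lex_min_pos <- function(p) {
  order(p[, 1], p[, 2])[1L]
}

signed_area <- function(p) {
  i2 <- c(2L, 3L, 4L, 1L)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

## proper segment intersection (shared endpoints of adjacent edges excluded
## by construction: only opposite edge pairs are tested)
segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_simple_quad <- function(p) {
  !segments_cross(p[1, ], p[2, ], p[3, ], p[4, ]) &&
    !segments_cross(p[2, ], p[3, ], p[4, ], p[1, ])
}

#' Signed area of a marker quadrilateral (mm^2)
#' @param quad A [marker_quad()].
#' @export
quad_area <- function(quad) signed_area(marker_quad(quad)$xy)

#' @export
print.marker_quad <- function(x, ...) {
  cat("<marker_quad>", paste(x$labels, collapse = " "), "\n")
  print(round(x$xy, 6))
  invisible(x)
}

#' @method as_tibble marker_quad
#' @export
as_tibble.marker_quad <- function(x, ...) {
  quad <- x
  tibble(marker_id = quad$labels, x = quad$xy[, 1], y = quad$xy[, 2])
}

#' Pair the initial and deformed configurations of one marker set
#'
#' The initial quad fixes the canonical vertex order; the deformed
#' configuration is matched to it by marker label, so both quads describe the
#' same four physical markers in the same order.
#'
#' @param initial,deformed Data frames acceptable to [marker_quad()], with
#'   identical label sets.
#' @return A `deformation_pair`: list with `initial` and `deformed`
#'   `marker_quad`s in label-consistent order.
#' @export
deformation_pair <- function(initial, deformed) {
  if (inherits(initial, "deformation_pair")) return(initial)
  qi <- marker_quad(initial)
  qd0 <- if (inherits(deformed, "marker_quad")) as_tibble(deformed) else deformed
  df <- as.data.frame(qd0)
  if (!"marker_id" %in% names(df) && "marker" %in% names(df)) {
    df$marker_id <- df$marker
  }
  if (!setequal(df$marker_id, qi$labels) || nrow(df) != 4L) {
    qp_abort("initial and deformed marker label sets differ", "qp_error_schema")
  }
  idx <- match(qi$labels, df$marker_id)
  xy <- cbind(as.numeric(df$x), as.numeric(df$y))[idx, , drop = FALSE]
  stopifnot_finite(xy, "deformed marker coordinates")
  if (!is_simple_quad(xy) || signed_area(xy) <= 0) {
    qp_abort("deformed markers do not form a valid counterclockwise quadrilateral",
             "qp_error_schema")
  }
  qd <- structure(list(xy = xy, labels = qi$labels), class = "marker_quad")
  structure(list(initial = qi, deformed = qd), class = "deformation_pair")
}

#' @export
print.deformation_pair <- function(x, ...) {
  cat("<deformation_pair>\n initial:\n")
  print(x$initial)
  cat(" deformed:\n")
  print(x$deformed)
  invisible(x)
}
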