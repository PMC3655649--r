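## First-order isoparametric quadrilateral kinematics: bilinear shape
## functions on the reference square [-1,1]^2, deformation gradient from the
## initial/deformed vertex coordinates, and small / Green-Lagrange / Biot
## strain measures.

#' Bilinear shape functions of the 4-node quadrilateral
#'
#' Returns the four weights N_k(xi, eta) = (1 + xi_k xi)(1 + eta_k eta)/4 for
#' corner signs (-1,-1), (1,-1), (1,1), (-1,1), matching the counterclockwise
#' vertex order of a [marker_quad()]. The weights are a partition of unity
#' and reproduce any affine field exactly.
#'
#' @param xi,eta Natural coordinates, both in \[-1, 1\].
#' @return Numeric vector of 4 weights summing to 1.
#' @examples
#' shape_functions(0, 0)       # centroid: all 1/4
#' shape_functions(-1, -1)     # node 1
#' @export
shape_functions <- function(xi, eta) {
  check_natural_coords(xi, eta)
  0.25 * c((1 - xi) * (1 - eta),
           (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta),
           (1 - xi) * (1 + eta))
}

check_natural_coords <- function(xi, eta) {
  if (!is.finite(xi) || !is.finite(eta) || abs(xi) > 1 || abs(eta) > 1) {
    qp_abort(sprintf("natural coordinates (%.3g, %.3g) outside [-1,1]^2",
                     xi, eta), "qp_error_domain")
  }
}

## 4x2 matrix of shape-function gradients wrt (xi, eta)
shape_function_grad <- function(xi, eta) {
  check_natural_coords(xi, eta)
  0.25 * cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
               c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)))
}

#' Deformation gradient of a marker quadrilateral
#'
#' Computes F = dx/dX at natural coordinates (xi, eta): the bilinear
#' interpolations of the initial and deformed vertex coordinates are
#' differentiated with respect to (xi, eta) and chained through the inverse
#' Jacobian of the initial configuration. For an affine map between the two
#' quads, F equals that map's linear part everywhere in the element.
#'
#' @param pair A [deformation_pair()].
#' @param xi,eta Natural coordinates in \[-1, 1\] (default: element centroid).
#' @return 2x2 matrix F.
#' @export
deformation_gradient_at <- function(pair, xi = 0, eta = 0) {
  pair <- deformation_pair(pair)
  G <- shape_function_grad(xi, eta)
  J0 <- t(pair$initial$xy) %*% G   # dX/d(xi,eta), initial configuration
  detJ0 <- J0[1, 1] * J0[2, 2] - J0[1, 2] * J0[2, 1]
  if (!is.finite(detJ0) || detJ0 <= 0) {
    qp_abort(sprintf(
      "degenerate element: non-positive Jacobian determinant %.3g at (xi, eta) = (%.3g, %.3g)",
      detJ0, xi, eta), "qp_error_degenerate")
  }
  Jd <- t(pair$deformed$xy) %*% G
  Jd %*% solve(J0)
}

#' In-plane strain tensor at a point of the element
#'
#' @param pair A [deformation_pair()].
#' @param xi,eta Natural coordinates in \[-1, 1\].
#' @param measure Strain measure: `"small"` (infinitesimal, sym(F) - I),
#'   `"green_lagrange"` ((F'F - I)/2, invariant to rigid rotation of the
#'   deformed configuration) or `"biot"` (sqrt(F'F) - I, principal values are
#'   stretch - 1).
#' @return A `strain_tensor_2d`: list with `exx`, `eyy`, `exy` (tensor shear,
#'   half the engineering shear) and `measure`.
#' @export
strain_at <- function(pair, xi = 0, eta = 0,
                      measure = c("small", "green_lagrange", "biot")) {
  measure <- match_measure(measure)
  F <- deformation_gradient_at(pair, xi, eta)
  E <- switch(measure,
    small = {
      (F + t(F)) / 2 - diag(2)
    },
    green_lagrange = {
      (t(F) %*% F - diag(2)) / 2
    },
    biot = {
      C <- t(F) %*% F
      es <- eigen((C + t(C)) / 2, symmetric = TRUE)
      U <- es$vectors %*% diag(sqrt(pmax(es$values, 0))) %*% t(es$vectors)
      U - diag(2)
    })
  strain_tensor_2d(E[1, 1], E[2, 2], (E[1, 2] + E[2, 1]) / 2, measure)
}

match_measure <- function(measure) {
  measure <- measure[1]
  ok <- c("small", "green_lagrange", "biot")
  if (!measure %in% ok) {
    qp_abort(sprintf("unknown strain measure '%s' (use %s)",
                     measure, paste(ok, collapse = ", ")), "qp_error_config")
  }
  measure
}

#' Construct a symmetric 2D strain tensor
#' @param exx,eyy,exy Strain components (dimensionless; `exy` is the tensor
#'   shear, half the engineering shear).
#' @param measure Strain measure label.
#' @export
strain_tensor_2d <- function(exx, eyy, exy, measure = "small") {
  stopifnot_finite(c(exx, eyy, exy), "strain components")
  structure(list(exx = exx, eyy = eyy, exy = exy,
                 measure = match_measure(measure)),
            class = "strain_tensor_2d")
}

#' @export
print.strain_tensor_2d <- function(x, ...) {
  cat(sprintf("<strain_tensor_2d (%s)> exx=%.6g eyy=%.6g exy=%.6g\n",
              x$measure, x$exx, x$eyy, x$exy))
  invisible(x)
}

as_matrix_strain <- function(t) {
  matrix(c(t$exx, t$exy, t$exy, t$eyy), 2L, 2L)
}

#' Single strain tensor for the whole element, with heterogeneity score
#'
#' `mode = "centroid"` evaluates the strain at (xi, eta) = (0, 0);
#' `mode = "gauss_mean"` averages the four 2x2 Gauss points (+-1/sqrt(3)).
#' The heterogeneity score is the maximum Frobenius distance between any
#' Gauss-point tensor and the centroid tensor; it is exactly zero for an
#' affine (homogeneous) deformation and grows with hourglass-type
#' non-uniformity, making it a quality-control diagnostic for the
#' homogeneous-deformation assumption.
#'
#' @inheritParams strain_at
#' @param mode `"centroid"` or `"gauss_mean"`.
#' @return List with `strain` (a `strain_tensor_2d`) and `heterogeneity`.
#' @export
element_strain <- function(pair, mode = c("centroid", "gauss_mean"),
                           measure = c("small", "green_lagrange", "biot")) {
  mode <- mode[1]
  if (!mode %in% c("centroid", "gauss_mean")) {
    qp_abort(sprintf("unknown evaluation mode '%s'", mode), "qp_error_config")
  }
  measure <- match_measure(measure)
  pair <- deformation_pair(pair)
  g <- 1 / sqrt(3)
  gauss <- list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  centroid <- strain_at(pair, 0, 0, measure)
  gpts <- map(gauss, function(p) strain_at(pair, p[1], p[2], measure))
  het <- max(map_dbl(gpts, function(t) {
    norm(as_matrix_strain(t) - as_matrix_strain(centroid), "F")
  }))
  strain <- if (mode == "centroid") {
    centroid
  } else {
    strain_tensor_2d(mean(map_dbl(gpts, "exx")),
                     mean(map_dbl(gpts, "eyy")),
                     mean(map_dbl(gpts, "exy")), measure)
  }
  list(strain = strain, heterogeneity = het)
}
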