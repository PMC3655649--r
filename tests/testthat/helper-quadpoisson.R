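# Shared fixtures and independent oracles for the test suite.

# rotate the coordinates of a marker data frame counterclockwise by `deg`
rotate_df <- function(df, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m <- t(R %*% t(cbind(df$x, df$y)))
  df$x <- m[, 1]
  df$y <- m[, 2]
  df
}

quad_df <- function(quad) tibble::as_tibble(quad)

# apply a 2x2 linear map A (plus translation) to a marker data frame
map_df_lin <- function(df, A, t = c(0, 0)) {
  m <- t(A %*% t(cbind(df$x, df$y)))
  df$x <- m[, 1] + t[1]
  df$y <- m[, 2] + t[2]
  df
}

unit_square_df <- function() {
  tibble::tibble(marker_id = paste0("m", 1:4),
                 x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
}

# the worked tension case: axis-aligned stretch, axial strain 0.4,
# transverse strain -0.08 (nu = 0.2)
worked_pair <- function() {
  q <- make_quad("rectangle", 10, 0.3)
  apply_deformation(q, deformation_scenario(0.4, nu_true = 0.2))
}

# Independent finite-difference oracle for the deformation gradient:
# differentiates the bilinear interpolations of initial and deformed vertex
# coordinates in natural coordinates (using only shape_functions) and chains
# through the initial Jacobian. Central differences, step h.
fd_deformation_gradient <- function(pair, xi, eta, h = 1e-6) {
  interp <- function(xy, a, b) as.numeric(t(xy) %*% shape_functions(a, b))
  dcols <- function(xy) cbind(
    (interp(xy, xi + h, eta) - interp(xy, xi - h, eta)) / (2 * h),
    (interp(xy, xi, eta + h) - interp(xy, xi, eta - h)) / (2 * h))
  dcols(pair$deformed$xy) %*% solve(dcols(pair$initial$xy))
}

expect_tensor_equal <- function(t1, t2, tol = 1e-10) {
  expect_equal(c(t1$exx, t1$eyy, t1$exy), c(t2$exx, t2$eyy, t2$exy),
               tolerance = tol)
}
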