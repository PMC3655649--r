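test_that("shape functions hit the nodes and the centroid", {
  expect_equal(shape_functions(0, 0), rep(0.25, 4))
  expect_equal(shape_functions(-1, -1), c(1, 0, 0, 0))
  expect_equal(shape_functions(1, -1), c(0, 1, 0, 0))
  expect_equal(shape_functions(1, 1), c(0, 0, 1, 0))
  expect_equal(shape_functions(-1, 1), c(0, 0, 0, 1))
  expect_error(shape_functions(1.01, 0), class = "qp_error_domain")
})

test_that("shape functions are a partition of unity and linearly complete", {
  corners <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  set.seed(1)
  err_pou <- err_lin <- 0
  for (i in seq_len(1e4)) {
    xi <- runif(1, -1, 1); eta <- runif(1, -1, 1)
    N <- shape_functions(xi, eta)
    err_pou <- max(err_pou, abs(sum(N) - 1))
    # linear completeness: reproduces (xi, eta) applied to the corners
    err_lin <- max(err_lin, abs(as.numeric(t(corners) %*% N) - c(xi, eta)))
  }
  expect_lt(err_pou, 1e-14)
  expect_lt(err_lin, 1e-13)
})

test_that("marker quads are canonically ordered and invalid ones rejected", {
  # shuffled input: canonical order is counterclockwise from the
  # lexicographically smallest vertex
  q <- marker_quad(tibble::tibble(marker_id = c("c", "a", "d", "b"),
                                  x = c(1, 0, 0, 1), y = c(1, 0, 1, 0)))
  expect_equal(q$xy[1, ], c(0, 0))
  expect_gt(quad_area(q), 0)
  expect_equal(sort(q$labels), c("a", "b", "c", "d"))

  expect_error(marker_quad(tibble::tibble(marker_id = 1:3,
                                          x = 1:3, y = 1:3)),
               class = "qp_error_schema")
  expect_error(marker_quad(tibble::tibble(marker_id = 1:4,
                                          x = c(0, 0, 1, 1),
                                          y = c(0, 0, 0, 1))),
               class = "qp_error_schema")  # coincident vertices
  # collinear points can never bound a positive area
  expect_error(marker_quad(tibble::tibble(marker_id = 1:4,
                                          x = 0:3, y = 0:3)),
               class = "qp_error_schema")
})

test_that("deformation pairs align the deformed quad by marker label", {
  init <- unit_square_df()
  def <- init[c(3, 1, 4, 2), ]
  def$x <- def$x * 1.2 + 5
  def$y <- def$y * 0.9 - 2
  pair <- deformation_pair(init, def)
  expect_equal(pair$initial$labels, pair$deformed$labels)
  i <- match(pair$initial$labels, init$marker_id)
  expect_equal(pair$deformed$xy[, 1], init$x[i] * 1.2 + 5)
  bad <- def
  bad$marker_id[1] <- "zz"
  expect_error(deformation_pair(init, bad), class = "qp_error_schema")
})

test_that("deformation gradient equals the linear part of an affine map", {
  # prescribed diagonal stretch on the unit square
  pair <- deformation_pair(unit_square_df(),
                           map_df_lin(unit_square_df(), diag(c(0.92, 1.4))))
  for (pt in list(c(0, 0), c(0.5, -0.5), c(-0.99, 0.7))) {
    expect_equal(deformation_gradient_at(pair, pt[1], pt[2]),
                 diag(c(0.92, 1.4)), tolerance = 1e-12)
  }
  # pure rigid rotation: F = R(25 deg)
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pr <- deformation_pair(unit_square_df(), map_df_lin(unit_square_df(), R))
  expect_equal(deformation_gradient_at(pr, 0, 0), R, tolerance = 1e-12)
})

test_that("deformation gradient matches the affine oracle on random quads", {
  set.seed(21)
  for (i in 1:20) {
    q <- make_quad("random_simple", size = 8)
    A <- matrix(rnorm(4, sd = 0.4), 2, 2) + diag(2)
    if (det(A) <= 0.05) next
    pair <- deformation_pair(q, map_df_lin(quad_df(q), A, t = rnorm(2)))
    checked <- 0
    for (j in 1:20) {
      pt <- runif(2, -0.95, 0.95)
      # non-convex quads have regions with a non-positive Jacobian where
      # the element map is not invertible; only valid points are checked
      F <- tryCatch(deformation_gradient_at(pair, pt[1], pt[2]),
                    qp_error_degenerate = function(e) NULL)
      if (is.null(F)) next
      expect_equal(F, A, tolerance = 1e-10)
      checked <- checked + 1
      if (checked >= 5) break
    }
    expect_gte(checked, 1)
  }
})

test_that("non-affine (hourglass) fields match the finite-difference oracle", {
  init <- unit_square_df()
  def <- init
  def$x[3] <- def$x[3] + 0.01  # one vertex displaced: bilinear mode
  pair <- deformation_pair(init, def)
  pts <- list(c(0, 0), c(1, 1) / sqrt(3), c(-1, 1) / sqrt(3),
              c(0.4, -0.8))
  for (pt in pts) {
    expect_equal(deformation_gradient_at(pair, pt[1], pt[2]),
                 fd_deformation_gradient(pair, pt[1], pt[2]),
                 tolerance = 1e-8)
  }
})

test_that("degenerate elements raise an informative error", {
  # fold the square into a zero-area configuration via the deformed quad
  init <- unit_square_df()
  expect_error(deformation_pair(init,
                                tibble::tibble(marker_id = init$marker_id,
                                               x = c(0, 1, 0.5, 0.5),
                                               y = c(0, 0, 0, 0))),
               class = "qp_error_schema")
  # strongly non-convex quad: Jacobian flips sign near the reflex corner
  reflex <- tibble::tibble(marker_id = paste0("m", 1:4),
                           x = c(0, 1, 0.1, 0), y = c(0, 0, 0.1, 1))
  pr <- deformation_pair(reflex, reflex |>
                           dplyr::mutate(x = x * 1.1, y = y * 1.1))
  expect_error(deformation_gradient_at(pr, 1, 1),
               class = "qp_error_degenerate")
  # but the centroid is always valid for a positive-area simple quad
  expect_silent(deformation_gradient_at(pr, 0, 0))
})

test_that("strain measures reproduce their closed forms", {
  # axis-aligned stretch: axial 0.4, transverse -0.08
  pair <- worked_pair()
  s <- strain_at(pair, 0, 0, "small")
  expect_equal(c(s$exx, s$eyy, s$exy), c(-0.08, 0.40, 0), tolerance = 1e-12)

  # pure rigid rotation: Green-Lagrange strain vanishes, small does not
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pr <- deformation_pair(unit_square_df(), map_df_lin(unit_square_df(), R))
  gl <- strain_at(pr, 0, 0, "green_lagrange")
  expect_equal(c(gl$exx, gl$eyy, gl$exy), c(0, 0, 0), tolerance = 1e-12)

  # uniaxial stretch lambda = 1.4: E_yy = (lambda^2 - 1)/2
  pl <- deformation_pair(unit_square_df(),
                         map_df_lin(unit_square_df(), diag(c(1, 1.4))))
  expect_equal(strain_at(pl, 0, 0, "green_lagrange")$eyy, (1.4^2 - 1) / 2,
               tolerance = 1e-12)
  # Biot strain on principal axes equals stretch - 1
  expect_equal(strain_at(pl, 0, 0, "biot")$eyy, 0.4, tolerance = 1e-12)
  expect_error(strain_at(pl, 0, 0, "cauchy"), class = "qp_error_config")
})

test_that("rotating only the deformed quad leaves finite-strain measures unchanged", {
  pair <- worked_pair()
  rot_pair <- deformation_pair(quad_df(pair$initial),
                               rotate_df(quad_df(pair$deformed), 25))
  for (m in c("green_lagrange", "biot")) {
    expect_tensor_equal(strain_at(rot_pair, 0, 0, m), strain_at(pair, 0, 0, m),
                        tol = 1e-10)
  }
  # the small-strain measure is corrupted by the rotation
  s0 <- strain_at(pair, 0, 0, "small")
  s1 <- strain_at(rot_pair, 0, 0, "small")
  expect_gt(abs(s1$eyy - s0$eyy), 0.01)
})

test_that("strains are invariant to co-rotation, translation and scaling", {
  pair <- worked_pair()
  p0 <- principal_strains(strain_at(pair, 0, 0, "small"))
  set.seed(5)
  for (i in 1:25) {
    ang <- runif(1, -180, 180)
    shift <- rnorm(2, sd = 20)
    scl <- runif(1, 0.1, 10)
    tr <- function(df) {
      df <- rotate_df(df, ang)
      df$x <- scl * (df$x + shift[1]); df$y <- scl * (df$y + shift[2])
      df
    }
    p <- principal_strains(strain_at(
      deformation_pair(tr(quad_df(pair$initial)), tr(quad_df(pair$deformed))),
      0, 0, "small"))
    expect_equal(c(p$eps1, p$eps2), c(p0$eps1, p0$eps2), tolerance = 1e-10)
  }
})

test_that("element_strain modes agree for affine fields and flag hourglass ones", {
  pair <- worked_pair()
  ec <- element_strain(pair, "centroid")
  eg <- element_strain(pair, "gauss_mean")
  expect_tensor_equal(ec$strain, eg$strain, tol = 1e-12)
  expect_equal(ec$heterogeneity, 0, tolerance = 1e-12)

  init <- unit_square_df()
  def <- init
  def$x[3] <- def$x[3] + 0.01
  hp <- deformation_pair(init, def)
  eh <- element_strain(hp, "gauss_mean")
  expect_gt(eh$heterogeneity, 1e-4)
  # gauss mean of the oracle tensors matches the reported mean
  g <- 1 / sqrt(3)
  oracle <- lapply(list(c(-g, -g), c(g, -g), c(g, g), c(-g, g)), function(pt) {
    F <- fd_deformation_gradient(hp, pt[1], pt[2])
    (F + t(F)) / 2 - diag(2)
  })
  mean_or <- Reduce(`+`, oracle) / 4
  expect_equal(c(eh$strain$exx, eh$strain$eyy, eh$strain$exy),
               c(mean_or[1, 1], mean_or[2, 2], mean_or[1, 2]),
               tolerance = 1e-8)
})
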