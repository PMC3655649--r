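## Principal strains, the Poisson's ratio formula nu = -eps2/eps1, the naive
## axis-aligned baseline, and the stepwise-elongation evaluation loop.

#' Principal strains of a 2D strain tensor
#'
#' Closed-form eigendecomposition (Mohr's circle): with center
#' m = (exx + eyy)/2 and radius r = sqrt(((exx - eyy)/2)^2 + exy^2),
#' eps1 = m + r, eps2 = m - r, and the direction of eps1 is
#' angle = atan2(2 exy, exx - eyy)/2, counterclockwise from the global
#' x-axis, in (-pi/2, pi/2].
#'
#' @param t A [strain_tensor_2d()].
#' @return List with `eps1` (maximum), `eps2` (minimum), `angle` (radians).
#' @examples
#' principal_strains(strain_tensor_2d(-0.08, 0.40, 0))
#' @export
principal_strains <- function(t) {
  stopifnot_finite(c(t$exx, t$eyy, t$exy), "strain tensor")
  m <- (t$exx + t$eyy) / 2
  r <- sqrt(((t$exx - t$eyy) / 2)^2 + t$exy^2)
  angle <- normalize_half_angle(atan2(2 * t$exy, t$exx - t$eyy) / 2)
  list(eps1 = m + r, eps2 = m - r, angle = angle)
}

#' Poisson's ratio from principal strains
#'
#' nu = -eps2/eps1, the negative ratio of minimum to maximum principal
#' strain. Under uniaxial stretch the maximum principal strain is the axial
#' strain and the minimum the transverse one, so this reduces to the
#' textbook definition while being independent of how the specimen is
#' oriented with respect to the measurement axes.
#'
#' @param p List with `eps1`, `eps2` as returned by [principal_strains()].
#' @param tol Smallest `|eps1|` regarded as a real deformation (default
#'   1e-6, dimensionless strain); below it the specimen is treated as
#'   undeformed and an error is raised.
#' @return Poisson's ratio (dimensionless scalar).
#' @export
poisson_ratio <- function(p, tol = 1e-6) {
  if (!is.finite(p$eps1) || !is.finite(p$eps2)) {
    qp_abort("non-finite principal strains", "qp_error_compute")
  }
  if (abs(p$eps1) <= tol) {
    qp_abort(sprintf(
      "specimen undeformed: |eps1| = %.3g <= tol = %.3g, Poisson's ratio undefined",
      abs(p$eps1), tol), "qp_error_undeformed")
  }
  if (abs(p$eps1 - p$eps2) <= tol * max(1, abs(p$eps1))) {
    warn("equibiaxial strain state (eps1 = eps2): nu = -1 and the principal direction is undefined",
         class = "qp_warning_equibiaxial")
  }
  -p$eps2 / p$eps1
}

## one PoissonResult row
result_row <- function(step_id, method, eps1 = NA_real_, eps2 = NA_real_,
                       angle = NA_real_, nu = NA_real_,
                       elongation_pct = NA_real_, heterogeneity = NA_real_,
                       misalignment_deg = NA_real_, status = "ok") {
  tibble(step_id = as.character(step_id), method = method,
         eps1 = eps1, eps2 = eps2,
         principal_angle_deg = rad2deg(angle),
         nu = nu, elongation_pct = elongation_pct,
         heterogeneity = heterogeneity,
         misalignment_deg = misalignment_deg, status = status)
}

#' Evaluate one deformation step with the element method
#'
#' Chains [element_strain()] -> [principal_strains()] -> [poisson_ratio()].
#' Elongation is reported as 100 * eps1 (the maximum principal strain),
#' which coincides with grip-to-grip engineering strain for an aligned
#' specimen but stays meaningful under misalignment. The misalignment
#' diagnostic is the deviation of the major principal direction from the
#' global y-axis (the nominal loading axis), in degrees.
#'
#' @param pair A [deformation_pair()].
#' @param measure,mode Passed to [element_strain()].
#' @param tol Passed to [poisson_ratio()].
#' @param step_id Label copied into the result.
#' @return One-row tibble: `step_id`, `method`, `eps1`, `eps2`,
#'   `principal_angle_deg`, `nu`, `elongation_pct`, `heterogeneity`,
#'   `misalignment_deg`, `status`.
#' @export
evaluate_step <- function(pair, measure = "small", mode = "centroid",
                          tol = 1e-6, step_id = "step") {
  pair <- deformation_pair(pair)
  es <- element_strain(pair, mode = mode, measure = measure)
  p <- principal_strains(es$strain)
  nu <- poisson_ratio(p, tol = tol)
  mis <- rad2deg(normalize_half_angle(p$angle - pi / 2))
  result_row(step_id, "element", p$eps1, p$eps2, p$angle, nu,
             elongation_pct = 100 * p$eps1,
             heterogeneity = es$heterogeneity, misalignment_deg = mis)
}

#' Naive axis-aligned Poisson's ratio (baseline)
#'
#' The classical estimator that assumes the loading axis is the global
#' y-axis and the specimen is aligned with it: per marker k,
#' eps_y^(k) = y_f/y_i - 1 and x_f/x_i = 1 - eps_y * nu, with coordinates
#' measured from the loading-axis origin. Per-marker estimates are averaged
#' arithmetically. The estimator is exact for an aligned specimen and
#' intentionally reproduces the bias that misalignment induces, serving as
#' the comparison baseline for the element method.
#'
#' @inheritParams evaluate_step
#' @return One-row tibble as in [evaluate_step()] with `method = "naive"`
#'   (principal-strain columns are `NA`; `elongation_pct` is 100 * eps_y).
#' @export
naive_poisson <- function(pair, tol = 1e-6, step_id = "step") {
  pair <- deformation_pair(pair)
  xi <- pair$initial$xy[, 1]; yi <- pair$initial$xy[, 2]
  xf <- pair$deformed$xy[, 1]; yf <- pair$deformed$xy[, 2]
  if (any(abs(xi) <= tol) || any(abs(yi) <= tol)) {
    qp_abort("naive method inapplicable: a marker lies on a coordinate axis (initial coordinate ~ 0 in a denominator)",
             "qp_error_naive")
  }
  eps_y_k <- yf / yi - 1
  eps_y <- mean(eps_y_k)
  if (abs(eps_y) <= tol) {
    qp_abort(sprintf(
      "specimen undeformed: |mean axial strain| = %.3g <= tol = %.3g",
      abs(eps_y), tol), "qp_error_undeformed")
  }
  nu <- mean((1 - xf / xi) / eps_y)
  result_row(step_id, "naive", nu = nu, elongation_pct = 100 * eps_y)
}

#' Poisson's ratio over a stepwise elongation sequence
#'
#' Each deformed configuration is compared against the original initial
#' quadrilateral (total strain, not step-to-step increments), mirroring a
#' stepwise tension experiment in which the same four markers are re-imaged
#' at every elongation. Per-step failures (for instance an undeformed first
#' step) are recorded in the `status` column without aborting the sweep.
#'
#' @param initial A [marker_quad()] (or data frame) for the reference state.
#' @param deformed_steps Named list of quads (or data frames), one per step,
#'   label-consistent with `initial`; list names become `step_id`s.
#' @param method `"element"`, `"naive"`, or `"both"`.
#' @inheritParams evaluate_step
#' @return Tibble with one row per step (and per method), columns as in
#'   [evaluate_step()].
#' @export
evaluate_sequence <- function(initial, deformed_steps, method = "element",
                              measure = "small", mode = "centroid",
                              tol = 1e-6) {
  if (length(deformed_steps) < 1L) {
    qp_abort("no deformed steps supplied", "qp_error_schema")
  }
  initial <- marker_quad(initial)
  ids <- names(deformed_steps) %||% as.character(seq_along(deformed_steps))
  ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
  methods <- if (method == "both") c("element", "naive") else method
  rows <- list()
  for (i in seq_along(deformed_steps)) {
    for (m in methods) {
      rows[[length(rows) + 1L]] <- tryCatch({
        pair <- deformation_pair(initial, deformed_steps[[i]])
        if (m == "element") {
          evaluate_step(pair, measure, mode, tol, step_id = ids[i])
        } else {
          naive_poisson(pair, tol, step_id = ids[i])
        }
      }, qp_error = function(e) {
        result_row(ids[i], m, status = conditionMessage(e))
      })
    }
  }
  list_rbind(rows)
}
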