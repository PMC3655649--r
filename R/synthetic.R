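## Ground-truth generator: marker quadrilaterals under parameterized
## homogeneous deformations with material-axis misalignment, rigid motion
## and coordinate noise. Stands in for the physical tension experiment and
## makes every downstream stage testable.

#' Describe a homogeneous deformation scenario
#'
#' The deformation applied to each marker v is
#' R(post_rotation) \[R(theta) diag(1 - nu_true * eps_a, 1 + eps_a)
#' R(theta)'\] v + translation + noise, where theta = `material_axis_deg`
#' tilts the stretch axis away from the global y-axis (specimen
#' misalignment), `post_rotation_deg` is a rigid rotation acquired during
#' deformation, and the noise is iid Gaussian per coordinate (mm),
#' representing marker-centroiding error. With zero noise and zero
#' post-rotation, the small-strain principal values of the generated
#' deformation are exactly (eps_a, -nu_true * eps_a).
#'
#' @param axial_strain eps_a, engineering strain along the material stretch
#'   axis; must exceed -1.
#' @param nu_true Ground-truth Poisson's ratio coupling the transverse
#'   strain as -nu_true * eps_a.
#' @param material_axis_deg Misalignment of the stretch axis from the global
#'   y-axis, degrees.
#' @param post_rotation_deg Rigid rotation applied after stretching, degrees.
#' @param translation 2-vector, mm.
#' @param noise_sd Standard deviation of the additive coordinate noise, mm.
#' @param seed Optional integer seed used when noise is drawn.
#' @export
deformation_scenario <- function(axial_strain, nu_true = 0.44,
                                 material_axis_deg = 0,
                                 post_rotation_deg = 0,
                                 translation = c(0, 0),
                                 noise_sd = 0, seed = NULL) {
  stopifnot_finite(c(axial_strain, nu_true, material_axis_deg,
                     post_rotation_deg, translation, noise_sd), "scenario")
  if (axial_strain <= -1) {
    qp_abort("axial_strain must be > -1", "qp_error_config")
  }
  if (noise_sd < 0) qp_abort("noise_sd must be >= 0", "qp_error_config")
  structure(list(axial_strain = axial_strain, nu_true = nu_true,
                 material_axis_deg = material_axis_deg,
                 post_rotation_deg = post_rotation_deg,
                 translation = as.numeric(translation),
                 noise_sd = noise_sd, seed = seed),
            class = "deformation_scenario")
}

## linear part of the scenario's deformation map
scenario_matrix <- function(s) {
  th <- deg2rad(s$material_axis_deg)
  U <- rot2(th) %*% diag(c(1 - s$nu_true * s$axial_strain,
                           1 + s$axial_strain)) %*% t(rot2(th))
  rot2(deg2rad(s$post_rotation_deg)) %*% U
}

#' Generate a marker quadrilateral
#'
#' @param shape `"rectangle"` (axis-aligned, centred on the origin: the
#'   footprint of a rectangular specimen) or `"random_simple"` (four points
#'   drawn uniformly in the bounding square, resampled until they form a
#'   valid simple quadrilateral).
#' @param size Width of the quad / bounding square, mm.
#' @param aspect Height/width ratio for `"rectangle"` (default 0.3: a
#'   10 x 3 mm specimen footprint at `size = 10`).
#' @param seed Optional integer seed for `"random_simple"`.
#' @param max_tries Retry budget for rejection sampling.
#' @return A [marker_quad()] labelled m1..m4.
#' @export
make_quad <- function(shape = c("rectangle", "random_simple"), size = 10,
                      aspect = 0.3, seed = NULL, max_tries = 100L) {
  shape <- match.arg(shape)
  if (size <= 0) qp_abort("size must be > 0 mm", "qp_error_config")
  if (shape == "rectangle") {
    w <- size / 2; h <- size * aspect / 2
    return(marker_quad(tibble(marker_id = paste0("m", 1:4),
                              x = c(-w, w, w, -w), y = c(-h, -h, h, h))))
  }
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    xy <- matrix(stats::runif(8, -size / 2, size / 2), 4L, 2L)
    q <- tryCatch(
      marker_quad(tibble(marker_id = paste0("m", 1:4),
                         x = xy[, 1], y = xy[, 2])),
      qp_error = function(e) NULL)
    # reject slivers: keep elements with a usable interior
    if (!is.null(q) && quad_area(q) > 0.05 * size^2) return(q)
  }
  qp_abort(sprintf("could not generate a valid random quad in %d tries",
                   max_tries), "qp_error_generation")
}

#' Apply a deformation scenario to a quadrilateral
#'
#' @param quad A [marker_quad()] (initial configuration).
#' @param s A [deformation_scenario()].
#' @return A [deformation_pair()].
#' @export
apply_deformation <- function(quad, s) {
  quad <- marker_quad(quad)
  A <- scenario_matrix(s)
  xy <- t(A %*% t(quad$xy)) +
    matrix(s$translation, nrow(quad$xy), 2L, byrow = TRUE)
  if (s$noise_sd > 0) {
    if (!is.null(s$seed)) set.seed(s$seed)
    xy <- xy + matrix(rnorm(8, sd = s$noise_sd), 4L, 2L)
  }
  deformation_pair(quad, tibble(marker_id = quad$labels,
                                x = xy[, 1], y = xy[, 2]))
}

#' Simulate a marker-track table over a stepwise elongation sweep
#'
#' Produces the same tidy track schema the readers ingest: one row per
#' marker per step, with an `"initial"` reference step followed by one step
#' per requested axial strain. All steps share the scenario's misalignment,
#' rigid motion and noise level; noise is drawn independently per step from
#' the stream seeded once by `seed`.
#'
#' @param axial_strains Numeric vector of per-step axial strains.
#' @param quad Initial [marker_quad()] (default: 10 x 3 mm rectangle).
#' @param step_ids Optional step labels (default step1, step2, ...).
#' @inheritParams deformation_scenario
#' @return Tibble with columns `step_id`, `marker_id`, `x`, `y` (mm).
#' @export
simulate_tracks <- function(axial_strains, nu_true = 0.44,
                            material_axis_deg = 0, post_rotation_deg = 0,
                            translation = c(0, 0), noise_sd = 0,
                            seed = NULL, quad = make_quad("rectangle"),
                            step_ids = NULL) {
  if (length(axial_strains) < 1L) {
    qp_abort("need at least one axial strain", "qp_error_config")
  }
  quad <- marker_quad(quad)
  step_ids <- step_ids %||% paste0("step", seq_along(axial_strains))
  if (!is.null(seed)) set.seed(seed)
  steps <- map2(axial_strains, step_ids, function(ea, id) {
    s <- deformation_scenario(ea, nu_true, material_axis_deg,
                              post_rotation_deg, translation,
                              noise_sd, seed = NULL)
    pair <- apply_deformation(quad, s)
    as_tibble(pair$deformed) |> mutate(step_id = id, .before = 1)
  })
  bind_rows(as_tibble(quad) |> mutate(step_id = "initial", .before = 1),
            list_rbind(steps))
}

#' Bias and RMSE of recovered Poisson's ratio over a scenario grid
#'
#' Monte-Carlo parameter-recovery experiment: for every scenario row,
#' `n_reps` noisy replicates are generated, Poisson's ratio is estimated by
#' the element method and the naive baseline, and the estimator's mean,
#' bias, RMSE and standard error are summarized. With zero noise the
#' element method is exact (bias = RMSE = 0) at any misalignment, while the
#' naive baseline is biased as soon as the stretch axis is tilted.
#'
#' @param scenarios Data frame with any subset of the columns
#'   `axial_strain`, `nu_true`, `material_axis_deg`, `post_rotation_deg`,
#'   `noise_sd` (missing columns take [deformation_scenario()] defaults).
#' @param n_reps Replicates per scenario (>= 2).
#' @param seed Integer seed for the whole experiment.
#' @param quad Initial quadrilateral shared by all scenarios.
#' @param measure Strain measure for the element method.
#' @return Tibble of class `qp_recovery`: one row per scenario x method with
#'   `mean_nu`, `bias`, `rmse`, `se`, `n_ok`.
#' @export
recovery_experiment <- function(scenarios, n_reps = 100, seed = 1,
                                quad = make_quad("rectangle"),
                                measure = "small") {
  if (n_reps < 2) qp_abort("n_reps must be >= 2", "qp_error_config")
  scenarios <- as_tibble(scenarios)
  defaults <- list(axial_strain = 0.2, nu_true = 0.44,
                   material_axis_deg = 0, post_rotation_deg = 0,
                   noise_sd = 0)
  for (nm in names(defaults)) {
    if (!nm %in% names(scenarios)) scenarios[[nm]] <- defaults[[nm]]
  }
  quad <- marker_quad(quad)
  set.seed(seed)
  out <- pmap(scenarios[names(defaults)], function(axial_strain, nu_true,
                                                   material_axis_deg,
                                                   post_rotation_deg,
                                                   noise_sd) {
    s <- deformation_scenario(axial_strain, nu_true, material_axis_deg,
                              post_rotation_deg, noise_sd = noise_sd)
    est <- map(seq_len(n_reps), function(r) {
      pair <- apply_deformation(quad, s)
      el <- tryCatch(evaluate_step(pair, measure = measure)$nu,
                     qp_error = function(e) NA_real_)
      nv <- tryCatch(naive_poisson(pair)$nu,
                     qp_error = function(e) NA_real_)
      c(element = el, naive = nv)
    })
    nus <- do.call(rbind, est)
    list_rbind(map(c("element", "naive"), function(m) {
      v <- nus[, m]; v <- v[is.finite(v)]
      tibble(axial_strain, nu_true, material_axis_deg, post_rotation_deg,
             noise_sd, method = m, n_ok = length(v),
             mean_nu = mean(v), bias = mean(v) - nu_true,
             rmse = sqrt(mean((v - nu_true)^2)),
             se = sd(v) / sqrt(length(v)))
    }))
  })
  structure(list_rbind(out), class = c("qp_recovery", class(tibble())))
}
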