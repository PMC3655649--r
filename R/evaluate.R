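## Tidy front end: marker-track table in, per-step Poisson's ratio table out.

#' Poisson's ratio from a marker-track table
#'
#' The main entry point. Takes a tidy track table (one row per marker per
#' step), builds the quadrilateral element from the `initial` step, and
#' evaluates Poisson's ratio for every other step against that reference
#' (total strain per step, as in a stepwise tension experiment).
#'
#' @param tracks Data frame with columns `step_id`, `marker_id`, `x`, `y`
#'   (mm), e.g. from [simulate_tracks()] or [read_marker_tracks()]. Exactly
#'   four markers per step.
#' @param initial_step Label of the reference step (default `"initial"`).
#' @param method `"element"` (principal-strain method), `"naive"`
#'   (axis-aligned baseline) or `"both"`.
#' @param measure,mode,tol Passed to [evaluate_step()].
#' @return A `qp_fit` object; its `$results` tibble has one row per step
#'   (and method) with the principal strains, Poisson's ratio, elongation
#'   and diagnostics. Use [tidy()], [glance()] and `autoplot()` on it.
#' @examples
#' simulate_tracks(c(0.1, 0.2, 0.3), nu_true = 0.44) |> qp_evaluate() |> tidy()
#' @export
qp_evaluate <- function(tracks, initial_step = "initial",
                        method = c("element", "naive", "both"),
                        measure = "small", mode = "centroid", tol = 1e-6) {
  method <- match.arg(method)
  tracks <- as_tibble(tracks)
  need <- c("step_id", "marker_id", "x", "y")
  if (!all(need %in% names(tracks))) {
    qp_abort(sprintf("track table needs columns %s",
                     paste(need, collapse = ", ")), "qp_error_schema")
  }
  steps <- split(tracks, factor(tracks$step_id,
                                levels = unique(tracks$step_id)))
  if (!initial_step %in% names(steps)) {
    qp_abort(sprintf("no step labelled '%s' in track table", initial_step),
             "qp_error_schema")
  }
  bad <- names(steps)[map_dbl(steps, nrow) != 4]
  if (length(bad)) {
    qp_abort(sprintf("steps without exactly 4 markers: %s",
                     paste(bad, collapse = ", ")), "qp_error_schema")
  }
  initial <- marker_quad(steps[[initial_step]])
  deformed <- steps[setdiff(names(steps), initial_step)]
  results <- evaluate_sequence(initial, deformed, method = method,
                               measure = measure, mode = mode, tol = tol)
  structure(list(results = results, initial = initial,
                 config = list(initial_step = initial_step, method = method,
                               measure = measure, mode = mode, tol = tol)),
            class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("<qp_fit> %s method, %s strain, %s evaluation\n",
              x$config$method, x$config$measure, x$config$mode))
  print(x$results)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-step results of a Poisson's ratio fit
#' @param x A `qp_fit`.
#' @param ... Unused.
#' @return The per-step results tibble.
#' @export
tidy.qp_fit <- function(x, ...) x$results

#' Summary of a Poisson's ratio fit
#' @param x A `qp_fit`.
#' @param ... Unused.
#' @return Tibble with one row per method: number of steps, mean and sd of
#'   nu, the elongation range covered, and the worst heterogeneity
#'   diagnostic.
#' @export
glance.qp_fit <- function(x, ...) {
  x$results |>
    group_by(.data$method) |>
    summarise(n_steps = sum(.data$status == "ok"),
              n_failed = sum(.data$status != "ok"),
              mean_nu = mean(.data$nu[.data$status == "ok"]),
              sd_nu = sd(.data$nu[.data$status == "ok"]),
              min_elongation_pct = min(.data$elongation_pct, na.rm = TRUE),
              max_elongation_pct = max(.data$elongation_pct, na.rm = TRUE),
              max_heterogeneity = if (all(is.na(.data$heterogeneity))) {
                NA_real_
              } else {
                max(.data$heterogeneity, na.rm = TRUE)
              },
              .groups = "drop")
}

#' Plot Poisson's ratio against elongation
#'
#' @param object A `qp_fit`.
#' @param ... Unused.
#' @return A ggplot: nu versus percent elongation, one point per step,
#'   coloured by method when both are present.
#' @method autoplot qp_fit
#' @export
autoplot.qp_fit <- function(object, ...) {
  ok <- filter(object$results, .data$status == "ok")
  ggplot2::ggplot(ok, ggplot2::aes(.data$elongation_pct, .data$nu,
                                   colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "elongation (%)", y = "Poisson's ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot recovery-experiment bias by scenario
#'
#' @param object A `qp_recovery` from [recovery_experiment()].
#' @param ... Unused.
#' @return A ggplot of estimator bias against misalignment angle, one line
#'   per method, faceted by noise level.
#' @method autoplot qp_recovery
#' @export
autoplot.qp_recovery <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$material_axis_deg, .data$bias,
                               colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~noise_sd, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "misalignment of stretch axis (deg)",
                  y = "bias of estimated Poisson's ratio", colour = NULL) +
    ggplot2::theme_minimal()
}
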