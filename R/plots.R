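# ggplot2 diagnostics for models, fits, optimizations and scans.

#' Axial-projection plot of a model
#'
#' Projects CA atoms onto the plane perpendicular to the z (super-helical)
#' axis — the "wheel" view of the bundle — colored by chain.
#'
#' @param object A `coilr_model` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coilr_model <- function(object, ...) {
  ca <- object[object$atom == "CA", ]
  ggplot2::ggplot(ca, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$chain)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = "Axial projection (CA trace)") +
    ggplot2::theme_minimal()
}

#' Energy trace of a Metropolis optimization
#'
#' @param object A `coilr_optimization`.
#' @param ... Unused.
#' @return A ggplot object showing current and best-so-far energy per step.
#' @export
autoplot.coilr_optimization <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    object$trace[, c("step", "energy", "best_energy")],
    -"step", names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "MC step", y = "interaction energy (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-helix energy across oligomeric states
#'
#' @param object A `coilr_scan` from [scan_oligomer_states()].
#' @param ... Unused.
#' @return A ggplot object; the predicted state is highlighted.
#' @export
autoplot.coilr_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$energy_per_helix)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$predicted), size = 2.5) +
    ggplot2::scale_x_continuous(breaks = df$n) +
    ggplot2::labs(x = "oligomeric state", y = "best energy / helix (a.u.)",
                  colour = "predicted") +
    ggplot2::theme_minimal()
}

#' Crick-angle profile of a parameter fit
#'
#' Plots the per-residue Crick angles implied by a [measure_parameters()]
#' fit, wrapping at the heptad period.
#'
#' @param fit A `coilr_fit`.
#' @return A ggplot object.
#' @export
plot_crick_angles <- function(fit) {
  ca <- attr(fit, "crick_angles")
  if (is.null(ca) || nrow(ca) == 0) {
    abort_analysis("fit carries no Crick angles (uncoiled model?)")
  }
  ggplot2::ggplot(ca, ggplot2::aes(x = .data$res_num, y = .data$crick_angle,
                                   colour = .data$chain)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "residue", y = "Crick angle (deg)") +
    ggplot2::theme_minimal()
}
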