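#' Plot a radial distribution function
#'
#' Shows g(r) with the random-packing (dashed) and directional (shaded)
#' windows of the designability fingerprint.
#'
#' @param object A [radial_distribution()].
#' @param windows Optional list of `random` / `directional` windows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_distribution <- function(object, windows = list(
    random = c(1.9, 2.6), directional = c(2.7, 3.5)), ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::annotate("rect", xmin = windows$directional[1],
                      xmax = windows$directional[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.15) +
    ggplot2::geom_vline(xintercept = windows$random,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (bead radii)", y = "g(r)") +
    ggplot2::theme_minimal()
}

#' Plot free-energy profiles
#'
#' @param object A [free_energy_profile()] or a list of them (one per
#'   temperature).
#' @param ... Unused.
#' @return A ggplot object, faceted by temperature for lists.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$F)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$F - .data$err,
                                      ymax = .data$F + .data$err),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DRMSD (bead radii)", y = "F (kT)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.free_energy_profile
#' @export
autoplot.fold_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~temperature, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "DRMSD (bead radii)", y = "F (kT)") +
    ggplot2::theme_minimal()
}

#' Plot a designability diagram
#'
#' @param object A data frame with columns `n_patches`, `q`,
#'   `designable`.
#' @param ... Unused.
#' @return A ggplot tile plot over (alphabet size, patch count).
#' @export
plot_designability_diagram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$q),
                               y = factor(.data$n_patches),
                               fill = .data$designable)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#3B6FB6",
                                          `FALSE` = "#E8C547")) +
    ggplot2::labs(x = "alphabet size q", y = "patches per monomer",
                  fill = "designable") +
    ggplot2::theme_minimal()
}

#' Plot replica-exchange energy traces
#'
#' @param object An [run_mc()] trajectory.
#' @param ... Unused.
#' @return A ggplot of per-temperature energy traces.
#' @export
autoplot.mc_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$step, y = .data$energy,
                               colour = factor(.data$temperature))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "sweep", y = "energy (kT)", colour = "T") +
    ggplot2::theme_minimal()
}
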