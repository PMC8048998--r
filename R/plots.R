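# ggplot2 layers for the main result types. These are thin views over the
# tidy tables; all numbers come from the corresponding compute functions.

#' Plot a total-chick trajectory with optional event overlay
#'
#' Posterior mean of total chicks per day with a one-standard-deviation
#' ribbon; precipitation events are drawn as vertical lines (dashed for
#' magnitude 2, solid for magnitude 3).
#'
#' @param z_summary Tibble from [total_chicks()] (`t`, `Z_mean`, `Z_sd`).
#' @param precip Optional event table with columns `day`, `kind`,
#'   `magnitude`.
#' @param first_chick_day Optional day of the first chick sighting, drawn
#'   as a dashed vertical line marking the start of the observation window.
#' @returns A ggplot object.
#' @export
plot_trajectory <- function(z_summary, precip = NULL, first_chick_day = NULL) {
  p <- ggplot2::ggplot(z_summary, ggplot2::aes(.data$t, .data$Z_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$Z_mean - .data$Z_sd,
                                      ymax = .data$Z_mean + .data$Z_sd),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "day of modelled season", y = "total chicks alive")
  if (!is.null(first_chick_day)) {
    p <- p + ggplot2::geom_vline(xintercept = first_chick_day,
                                 linetype = "dashed", colour = "blue")
  }
  if (!is.null(precip) && nrow(precip) > 0) {
    ev <- precip[precip$magnitude >= 2, , drop = FALSE]
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_vline(
        xintercept = ev$day,
        linetype = ifelse(ev$magnitude >= 3, "solid", "dashed"),
        colour = "red")
    }
  }
  p
}

#' Density plot of phase-specific mortality rates across site/years
#'
#' @param phases Tibble from [phase_mortality_fit()].
#' @returns A ggplot object.
#' @export
plot_phase_mortality <- function(phases) {
  long <- tidyr::pivot_longer(
    phases[, c("egg_rate", "young_rate", "old_rate")],
    cols = dplyr::everything(),
    names_to = "phase", values_to = "rate")
  long$phase <- factor(long$phase, levels = c("egg_rate", "young_rate",
                                              "old_rate"),
                       labels = c("egg", "young chick", "old chick"))
  ggplot2::ggplot(long, ggplot2::aes(.data$rate, colour = .data$phase)) +
    ggplot2::geom_density() +
    ggplot2::scale_colour_manual(values = c(egg = "red",
                                            `young chick` = "goldenrod",
                                            `old chick` = "blue")) +
    ggplot2::labs(x = "chicks lost per day", y = "density", colour = "phase")
}

#' @describeIn fit_driver_regression Scatter of breeding success against
#'   the driver with the posterior-median fit line and 95% credible
#'   ribbon.
#' @param object A `camcr_reg`.
#' @param ... Unused.
#' @export
autoplot.camcr_reg <- function(object, ...) {
  d <- object$data
  grid <- seq(min(d$x), max(d$x), length.out = 80)
  mu <- object$draws[, "alpha"] %o% rep(1, 80) +
    object$draws[, "beta"] %o% grid
  band <- apply(mu, 2, quantile, probs = c(0.025, 0.5, 0.975))
  fitline <- tibble::tibble(x = grid, lo = band[1, ], mid = band[2, ],
                            hi = band[3, ])
  xlab <- if (object$log_transformed) paste0("log(", object$covariate, ")")
  else object$covariate
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$bs_obs)) +
    ggplot2::geom_ribbon(data = fitline,
                         ggplot2::aes(x = .data$x, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(data = fitline,
                       ggplot2::aes(.data$x, .data$mid), colour = "red") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$bs_obs - .data$sigma_bs,
                                          ymax = .data$bs_obs + .data$sigma_bs)) +
    ggplot2::labs(x = xlab, y = "breeding success (chicks per pair)")
}
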