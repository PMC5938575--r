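#' Plot a simulated duet's expectation trajectories
#'
#' Fast- and slow-level order-0 expectations for both agents over time,
#' faceted by level and state variable.
#'
#' @param object a [simulate_duet()] result.
#' @param levels hierarchy levels to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.duet_sim <- function(object, levels = c(1, 2), ...) {
  d <- tidy(object, levels = levels)
  d$level_lab <- ifelse(d$level == 1, "level 1 (fast, HVC)",
                        "level 2 (slow, area X)")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$value,
                                  colour = .data$agent)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(.data$variable ~ .data$level_lab, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "posterior expectation",
                  colour = "agent",
                  title = sprintf("%s duet, seed %s", object$mode,
                                  format(object$seed))) +
    ggplot2::theme_minimal()
}

#' Synchronization-manifold scatter for a duet
#'
#' Plots one agent's expectations against the other's, per state variable;
#' identical synchrony collapses the scatter onto the diagonal.
#'
#' @param sim a [simulate_duet()] result.
#' @param level hierarchy level (default 1).
#' @param final_fraction use only this final fraction of ticks.
#' @return A ggplot object.
#' @export
plot_sync_manifold <- function(sim, level = 1, final_fraction = 0.25) {
  A <- expectation_trajectory(sim, sim$ids[1], level = level)
  B <- expectation_trajectory(sim, sim$ids[2], level = level)
  n <- nrow(A)
  idx <- seq.int(floor(n * (1 - final_fraction)) + 1L, n)
  d <- dplyr::bind_rows(lapply(seq_len(ncol(A)), function(j) {
    tibble::tibble(variable = colnames(A)[j], a = A[idx, j], b = B[idx, j])
  }))
  ggplot2::ggplot(d, ggplot2::aes(.data$a, .data$b,
                                  colour = .data$variable)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(
      x = sprintf("%s expectations", sim$ids[1]),
      y = sprintf("%s expectations", sim$ids[2]),
      colour = "state",
      title = sprintf("synchronization manifold (%s, level %d)",
                      sim$mode, level)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sonogram
#'
#' @param object a [sonogram()].
#' @param ... unused.
#' @return A ggplot object (spectral power as a raster over time and
#'   frequency).
#' @export
autoplot.sonogram <- function(object, ...) {
  d <- tibble::tibble(
    time_s = rep(attr(object, "time_s"), each = nrow(object)),
    freq_hz = rep(attr(object, "freq_hz"), ncol(object)),
    power = as.vector(unclass(object))
  )
  d <- d[d$freq_hz <= 6000, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$freq_hz,
                                  fill = log1p(.data$power))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "log power", title = "sonogram") +
    ggplot2::theme_minimal()
}

#' Plot order-parameter learning trajectories
#'
#' Per-epoch posterior means with 90% confidence ribbons for both agents,
#' optionally for coupled and uncoupled runs side by side.
#'
#' @param theta a theta tibble from [run_precision_asymmetry()] (columns
#'   `run`, `epoch`, `agent`, `theta`, `ci_low`, `ci_high`) or from a
#'   `duet_sim` (`sim$theta`).
#' @return A ggplot object.
#' @export
plot_theta_trajectories <- function(theta) {
  if (!"run" %in% names(theta)) theta$run <- "coupled"
  ggplot2::ggplot(theta, ggplot2::aes(.data$epoch, .data$theta,
                                      colour = .data$agent,
                                      fill = .data$agent)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$run) +
    ggplot2::labs(x = "epoch", y = "order parameter (posterior mean, 90% CI)",
                  title = "order-parameter learning") +
    ggplot2::theme_minimal()
}

#' Plot the complementarity trend across inheritance trials
#'
#' @param trials the `trials` tibble from [run_niche_inheritance()].
#' @return A ggplot object.
#' @export
plot_inheritance_trend <- function(trials) {
  ggplot2::ggplot(trials, ggplot2::aes(.data$trial, .data$joint_F)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "trial (organism generation)",
                  y = "trial-mean joint free energy (nats)",
                  title = "ecological inheritance: organism-niche complementarity") +
    ggplot2::theme_minimal()
}
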