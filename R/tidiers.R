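#' Tidy a simulated duet into a long tibble of expectations
#'
#' One row per tick, agent, level and state variable (order-0 values in
#' natural units).
#'
#' @param x a [simulate_duet()] result.
#' @param levels hierarchy levels to include.
#' @param ... unused.
#' @return A tibble with columns `tick`, `time_s`, `epoch`, `agent`,
#'   `level`, `variable`, `value`.
#' @export
tidy.duet_sim <- function(x, levels = c(1, 2), ...) {
  dplyr::bind_rows(lapply(x$ids, function(id) {
    dplyr::bind_rows(lapply(levels, function(lv) {
      M <- expectation_trajectory(x, id, level = lv, orders = 0)
      tibble::tibble(
        tick = rep(seq_len(nrow(M)), 3L),
        time_s = rep(seq_len(nrow(M)) * x$dt, 3L),
        epoch = rep(x$epoch_of, 3L),
        agent = id, level = lv,
        variable = rep(colnames(M), each = nrow(M)),
        value = as.vector(M)
      )
    }))
  }))
}

#' One-row summary of a simulated duet
#'
#' @param x a [simulate_duet()] result.
#' @param ... unused.
#' @return A one-row tibble: mode, epochs, final-quarter synchrony scores at
#'   the fast level, and the final-epoch mean joint free energy.
#' @export
glance.duet_sim <- function(x, ...) {
  r <- synchrony_report(x, level = 1)
  tibble::tibble(
    mode = x$mode,
    n_epochs = x$schedule$n_epochs,
    epoch_seconds = x$schedule$epoch_seconds,
    seed = x$seed,
    identical_deviation_final = r$final$identical_deviation,
    generalized_r2_final = r$final$generalized_r2,
    joint_F_final_epoch = utils::tail(r$complementarity$per_epoch$joint_F, 1)
  )
}

#' @export
tidy.synchrony_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$full, window = "full", .before = 1),
    dplyr::mutate(x$final, window = "final", .before = 1),
    dplyr::mutate(x$per_epoch, window = paste0("epoch_", .data$epoch),
                  .before = 1)[, c("window", "identical_deviation",
                                   "generalized_r2")]
  )
}

#' @export
glance.synchrony_report <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, level = x$level, seed = x$seed,
    identical_deviation_final = x$final$identical_deviation,
    generalized_r2_final = x$final$generalized_r2
  )
}
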