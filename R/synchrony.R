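#' Deviation from the identical-synchrony manifold
#'
#' Identical synchrony between two trajectories puts every sample on the
#' diagonal of their joint state space. The score is the RMS of the
#' pointwise difference over ticks and dimensions, divided by the pooled
#' (population) standard deviation of the concatenated trajectories:
#' 0 for identical trajectories, about sqrt(2) for independent ones with
#' equal variance, and 2 for perfectly anti-correlated zero-mean ones.
#'
#' @param traj_A,traj_B numeric matrices (ticks by dimensions) of matched
#'   trajectories.
#' @return A single non-negative score; degenerate (zero pooled variance)
#'   input yields `NaN` with a warning.
#' @export
identical_sync_deviation <- function(traj_A, traj_B) {
  traj_A <- as.matrix(traj_A); traj_B <- as.matrix(traj_B)
  if (!all(dim(traj_A) == dim(traj_B))) {
    stop("trajectories must have matching dimensions", call. = FALSE)
  }
  rms <- sqrt(mean((traj_A - traj_B)^2))
  pooled <- c(traj_A, traj_B)
  sd_pop <- sqrt(mean((pooled - mean(pooled))^2))
  if (sd_pop == 0) {
    warning("zero pooled variance: degenerate synchrony score")
    return(NaN)
  }
  rms / sd_pop
}

#' Generalized-synchrony score (R-squared of the optimal affine map)
#'
#' Generalized synchrony means one system's trajectory determines the
#' other's through some mapping. The score fits, by least squares, an affine
#' map from A's expectations (optionally including their temporal
#' derivatives) to each dimension of B, and returns the coefficient of
#' determination `1 - RSS/TSS` averaged over B's dimensions. 1 under any
#' exact affine relation; near 0 for independent signals.
#'
#' @param traj_A,traj_B numeric matrices (ticks by dimensions).
#' @param deriv_A optional matrix of A's temporal derivatives (same tick
#'   count) appended to the design when `include_derivatives` is `TRUE`.
#' @param include_derivatives include the derivative mixture in the map.
#' @param ridge ridge scale used as fallback for rank-deficient designs.
#' @param holdout_fraction if positive, the affine map is fitted on the
#'   first `1 - holdout_fraction` of the ticks and the score evaluated on
#'   the held-out remainder. Out-of-sample scoring is what distinguishes a
#'   genuine synchronization map from an in-sample fit of two smooth but
#'   unrelated trajectories; 0 (default) scores in sample.
#' @return R-squared in \[0, 1\].
#' @export
generalized_sync_score <- function(traj_A, traj_B, deriv_A = NULL,
                                   include_derivatives = FALSE,
                                   ridge = 1e-8, holdout_fraction = 0) {
  traj_A <- as.matrix(traj_A); traj_B <- as.matrix(traj_B)
  if (nrow(traj_A) != nrow(traj_B)) {
    stop("trajectories must have equal length", call. = FALSE)
  }
  X <- traj_A
  if (include_derivatives) {
    if (is.null(deriv_A)) {
      stop("`deriv_A` required when include_derivatives = TRUE", call. = FALSE)
    }
    X <- cbind(X, as.matrix(deriv_A))
  }
  n <- nrow(X)
  fit_idx <- seq_len(n)
  eval_idx <- seq_len(n)
  if (holdout_fraction > 0) {
    n_fit <- max(ncol(X) + 2L, floor(n * (1 - holdout_fraction)))
    fit_idx <- seq_len(n_fit)
    eval_idx <- seq.int(n_fit + 1L, n)
  }
  # standardize columns on the fit window so the ridge penalty (and any
  # fallback) treats value and derivative channels on a common scale
  mu_x <- colMeans(X[fit_idx, , drop = FALSE])
  sd_x <- apply(X[fit_idx, , drop = FALSE], 2, stats::sd)
  sd_x[sd_x < 1e-12] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, mu_x), 2, sd_x, "/"))
  XtX <- crossprod(Xs[fit_idx, , drop = FALSE])
  Xty <- crossprod(Xs[fit_idx, , drop = FALSE],
                   traj_B[fit_idx, , drop = FALSE])
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta)) {
    lambda <- ridge * mean(diag(XtX))
    beta <- solve(XtX + lambda * diag(ncol(Xs)), Xty)
    message("rank-deficient design: ridge fallback used")
  }
  Be <- traj_B[eval_idx, , drop = FALSE]
  res <- Be - Xs[eval_idx, , drop = FALSE] %*% beta
  r2 <- vapply(seq_len(ncol(Be)), function(j) {
    tss <- sum((Be[, j] - mean(Be[, j]))^2)
    if (tss == 0) return(NA_real_)
    max(0, min(1, 1 - sum(res[, j]^2) / tss))
  }, numeric(1))
  mean(r2, na.rm = TRUE)
}

#' Organism-niche complementarity: summed free energy
#'
#' Free energies are extensive, so the attunement of two coupled parties is
#' scored by the pointwise sum of their free-energy traces; lower values
#' mean greater complementarity. Returns the tick-level trace and per-epoch
#' means.
#'
#' @param F_trace_A,F_trace_B numeric free-energy traces (nats), aligned.
#' @param epoch optional integer vector of epoch labels per tick.
#' @return A list with `trace` (nats per tick), `per_epoch` (tibble of epoch
#'   means, when `epoch` is given), and the sign convention note.
#' @export
complementarity <- function(F_trace_A, F_trace_B, epoch = NULL) {
  if (length(F_trace_A) != length(F_trace_B)) {
    stop("free-energy traces are not aligned", call. = FALSE)
  }
  tr <- F_trace_A + F_trace_B
  per_epoch <- NULL
  if (!is.null(epoch)) {
    if (length(epoch) != length(tr)) {
      stop("`epoch` labels are not aligned with the traces", call. = FALSE)
    }
    per_epoch <- tibble::tibble(epoch = epoch, joint_F = tr) |>
      dplyr::group_by(.data$epoch) |>
      dplyr::summarise(joint_F = mean(.data$joint_F), .groups = "drop")
  }
  list(trace = tr, per_epoch = per_epoch,
       convention = "lower joint free energy = greater complementarity")
}

#' Synchrony report for a simulated duet
#'
#' Convenience wrapper computing, from a `duet_sim`: the identical-synchrony
#' deviation and generalized-synchrony R-squared between the two agents'
#' expectations (slow, "area X" level by default), both over the full run
#' and over the final quarter of ticks (reported as `*_final`); per-epoch
#' values of both; and the complementarity trace.
#'
#' @param sim a [simulate_duet()] result.
#' @param level hierarchy level compared (default 2, the slow level).
#' @param include_derivatives include first temporal derivatives in the
#'   generalized-synchrony mixture.
#' @param final_fraction fraction of final ticks used for the `*_final`
#'   scores (default 0.25).
#' @param holdout_fraction holdout fraction passed to
#'   [generalized_sync_score()] (fit on the early part of each window,
#'   score on the rest).
#' @return An object of class `synchrony_report` (a list of tibbles and
#'   scalars).
#' @export
synchrony_report <- function(sim, level = 2, include_derivatives = TRUE,
                             final_fraction = 0.25,
                             holdout_fraction = 0) {
  stopifnot(inherits(sim, "duet_sim"))
  ids <- sim$ids
  A <- expectation_trajectory(sim, ids[1], level = level, orders = 0)
  B <- expectation_trajectory(sim, ids[2], level = level, orders = 0)
  dA <- expectation_trajectory(sim, ids[1], level = level, orders = 1)
  n <- nrow(A)
  fin <- seq.int(floor(n * (1 - final_fraction)) + 1L, n)
  score <- function(idx) {
    tibble::tibble(
      identical_deviation = identical_sync_deviation(A[idx, , drop = FALSE],
                                                     B[idx, , drop = FALSE]),
      generalized_r2 = generalized_sync_score(
        A[idx, , drop = FALSE], B[idx, , drop = FALSE],
        deriv_A = dA[idx, , drop = FALSE],
        include_derivatives = include_derivatives,
        holdout_fraction = holdout_fraction
      )
    )
  }
  per_epoch <- dplyr::bind_rows(lapply(seq_len(sim$schedule$n_epochs),
    function(ep) {
      idx <- which(sim$epoch_of == ep)
      dplyr::mutate(score(idx), epoch = ep, .before = 1)
    }))
  fe <- sim$fe
  FA <- fe$F[fe$agent == ids[1]]
  FB <- fe$F[fe$agent == ids[2]]
  comp <- complementarity(FA, FB, epoch = sim$epoch_of)
  structure(
    list(
      full = score(seq_len(n)),
      final = score(fin),
      per_epoch = per_epoch,
      complementarity = comp,
      level = level, final_fraction = final_fraction,
      mode = sim$mode, seed = sim$seed
    ),
    class = "synchrony_report"
  )
}

#' @export
print.synchrony_report <- function(x, ...) {
  cat(sprintf("<synchrony_report (%s run, level %d expectations)>\n",
              x$mode, x$level))
  cat(sprintf("  full run   : deviation %.3f, generalized R2 %.3f\n",
              x$full$identical_deviation, x$full$generalized_r2))
  cat(sprintf("  final %2.0f%%  : deviation %.3f, generalized R2 %.3f\n",
              100 * x$final_fraction,
              x$final$identical_deviation, x$final$generalized_r2))
  cat(sprintf("  final-epoch mean joint F: %.2f nats (lower = more attuned)\n",
              utils::tail(x$complementarity$per_epoch$joint_F, 1)))
  invisible(x)
}

#' Per-epoch distance between the two agents' expectations
#'
#' Mean Euclidean distance per tick between matched expectations, by epoch;
#' uncoupled duets show this growing across epochs (chaotic divergence),
#' coupled duets shrink it.
#'
#' @inheritParams synchrony_report
#' @return A tibble with `epoch` and `distance`.
#' @export
epoch_distances <- function(sim, level = 2) {
  ids <- sim$ids
  A <- expectation_trajectory(sim, ids[1], level = level, orders = 0)
  B <- expectation_trajectory(sim, ids[2], level = level, orders = 0)
  d <- sqrt(rowSums((A - B)^2))
  tibble::tibble(epoch = sim$epoch_of, d = d) |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(distance = mean(.data$d), .groups = "drop")
}

#' Short-time spectral sonogram of a song
#'
#' Synthesizes a waveform as an amplitude-modulated sinusoid at the
#' instantaneous frequency, then computes short-time spectral power with a
#' Hann-tapered windowed transform.
#'
#' @param amplitude,frequency per-tick song channels (amplitude in arbitrary
#'   units, frequency in Hz), sampled at `1/dt`.
#' @param dt sampling interval of the channels, seconds.
#' @param window,hop STFT window and hop lengths in seconds.
#' @param sample_rate waveform synthesis rate, Hz.
#' @return An object of class `sonogram`: a non-negative power matrix
#'   (frequency bins by time frames) with `freq_hz` and `time_s` attributes.
#' @export
sonogram <- function(amplitude, frequency, dt = 1 / 256,
                     window = 0.064, hop = 0.016, sample_rate = 16000) {
  stopifnot(length(amplitude) == length(frequency))
  n_w <- round(window * sample_rate)
  if (n_w < 2) stop("window shorter than 2 samples", call. = FALSE)
  n_h <- max(1L, round(hop * sample_rate))
  # upsample channels to the waveform rate (piecewise linear)
  t_chan <- seq_along(amplitude) * dt
  t_wav <- seq(dt, max(t_chan), by = 1 / sample_rate)
  amp <- stats::approx(t_chan, amplitude, xout = t_wav, rule = 2)$y
  frq <- stats::approx(t_chan, frequency, xout = t_wav, rule = 2)$y
  phase <- 2 * pi * cumsum(frq) / sample_rate
  wav <- amp * sin(phase)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_w) / (n_w + 1))
  starts <- seq(1L, length(wav) - n_w + 1L, by = n_h)
  pow <- vapply(starts, function(s) {
    seg <- wav[s:(s + n_w - 1L)] * hann
    Mod(stats::fft(seg)[seq_len(n_w %/% 2)])^2
  }, numeric(n_w %/% 2))
  structure(
    pow,
    freq_hz = (seq_len(n_w %/% 2) - 1L) * sample_rate / n_w,
    time_s = (starts + n_w / 2) / sample_rate,
    window = window, hop = hop,
    class = c("sonogram", "matrix")
  )
}

#' @export
print.sonogram <- function(x, ...) {
  cat(sprintf("<sonogram: %d frequency bins x %d frames, window %gs, hop %gs>\n",
              nrow(x), ncol(x), attr(x, "window"), attr(x, "hop")))
  invisible(x)
}
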