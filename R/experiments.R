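#' Experiment configuration
#'
#' Builds and validates the configuration for one of the three packaged
#' experiments. Every model and agent default can be overridden; unknown
#' keys are rejected (fail fast).
#'
#' @param experiment `"duet"`, `"precision_asymmetry"` or
#'   `"niche_inheritance"`.
#' @param ... overrides of the experiment's defaults (see Details).
#' @details Common fields: `n_epochs`, `epoch_seconds`, `dt`, `k_mu`,
#' `eta_theta`, `learn_burnin`, `model` (a named list of
#' [birdsong_model()] arguments applied to both agents), `with_uncoupled`
#' (also run the matched uncoupled control). Per-agent priors:
#' `theta_prior_A`, `theta_prior_B` (each `list(mean, log_precision)`).
#' Inheritance only: `n_trials`, `trial_epochs`, `niche_learning_scale`,
#' `niche_theta_prior`, `organism_theta_prior`, `niche_gamma_z`.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment = c("duet", "precision_asymmetry",
                                             "niche_inheritance"), ...) {
  experiment <- match.arg(experiment)
  base <- list(
    epoch_seconds = 2, dt = 1 / 256, k_mu = 2, eta_theta = 1,
    learn_burnin = 2, model = list(), with_uncoupled = TRUE
  )
  defaults <- switch(experiment,
    duet = c(base, list(
      n_epochs = 8,
      theta_prior_A = list(mean = 24, log_precision = 8),
      theta_prior_B = list(mean = 24, log_precision = 8)
    )),
    precision_asymmetry = c(base, list(
      n_epochs = 24, eta_theta = 2,
      theta_prior_A = list(mean = 24, log_precision = 8),  # teacher
      theta_prior_B = list(mean = 16, log_precision = 0)   # learner
    )),
    niche_inheritance = c(base, list(
      n_epochs = 8, n_trials = 10, trial_epochs = 16, eta_theta = 2,
      niche_learning_scale = 0.2,
      niche_theta_prior = list(mean = 32, log_precision = 0),
      organism_theta_prior = list(mean = 24, log_precision = 8),
      niche_gamma_z = 4
    ))
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  cfg$experiment <- experiment
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file with an `experiment` field and any overrides
#'   accepted by [experiment_config()].
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$experiment)) stop("config must name an `experiment`",
                                  call. = FALSE)
  exp <- y$experiment
  y$experiment <- NULL
  do.call(experiment_config, c(list(experiment = exp), y))
}

cfg_model <- function(cfg, prior, extra = list()) {
  args <- utils::modifyList(cfg$model, extra)
  args$theta_prior_mean <- prior$mean
  args$theta_prior_log_precision <- prior$log_precision
  do.call(birdsong_model, args)
}

cfg_agent <- function(cfg, prior, id, extra_model = list()) {
  ns_agent(cfg_model(cfg, prior, extra_model),
           k_mu = cfg$k_mu, eta_theta = cfg$eta_theta, id = id)
}

cfg_schedule <- function(cfg, n_epochs = cfg$n_epochs, turn = "A") {
  epoch_schedule(epoch_seconds = cfg$epoch_seconds, n_epochs = n_epochs,
                 turn_order = turn, dt = cfg$dt)
}

#' Run the duet experiment
#'
#' Simulates the coupled duet (two agents with the same generative model but
#' different initial expectations singing in 2-s turns), the matched
#' uncoupled control, and a chaotic-divergence control from adjacent initial
#' conditions. Synchrony is quantified at the fast ("HVC") level over the
#' final quarter of ticks; slow-level ("area X") scores are reported
#' alongside.
#'
#' @param config an [experiment_config()] (experiment `"duet"`).
#' @param seed master seed.
#' @param out optional output directory; artifacts are written as delimited
#'   text plus structured metric files (see [write_experiment()]).
#' @return A list with the simulations, `synchrony` tibble, `divergence`
#'   tibble, per-mode sonograms, and a `metrics` list.
#' @export
run_duet <- function(config = experiment_config("duet"), seed = 1,
                     out = NULL) {
  stopifnot(identical(config$experiment, "duet"))
  mk <- function(mode) {
    couple(cfg_agent(config, config$theta_prior_A, "A"),
           cfg_agent(config, config$theta_prior_B, "B"),
           mode = mode, schedule = cfg_schedule(config))
  }
  sims <- list(coupled = simulate_duet(mk("coupled"), seed,
                                       learn_burnin = config$learn_burnin))
  if (isTRUE(config$with_uncoupled)) {
    sims$uncoupled <- simulate_duet(mk("uncoupled"), seed,
                                    learn_burnin = config$learn_burnin)
    sims$divergence <- simulate_duet(mk("uncoupled"), seed, init = "perturb",
                                     learn_burnin = config$learn_burnin)
  }
  syn <- dplyr::bind_rows(lapply(names(sims), function(nm) {
    s <- sims[[nm]]
    dplyr::bind_rows(lapply(c(1, 2), function(lv) {
      r <- synchrony_report(s, level = lv)
      tibble::tibble(
        run = nm, level = lv,
        identical_deviation_final = r$final$identical_deviation,
        generalized_r2_final = r$final$generalized_r2,
        identical_deviation_full = r$full$identical_deviation,
        generalized_r2_full = r$full$generalized_r2,
        joint_F_final_epoch = utils::tail(r$complementarity$per_epoch$joint_F, 1)
      )
    }))
  }))
  divergence <- dplyr::bind_rows(lapply(names(sims), function(nm) {
    dplyr::mutate(epoch_distances(sims[[nm]], level = 1), run = nm,
                  .before = 1)
  }))
  sonograms <- lapply(sims[c("coupled", "uncoupled")], function(s) {
    if (is.null(s)) return(NULL)
    sonogram(s$song$amplitude, s$song$frequency, dt = s$dt)
  })
  lvl1 <- syn[syn$level == 1, ]
  pick <- function(col, run) {
    v <- lvl1[[col]][lvl1$run == run]
    if (length(v)) v else NULL
  }
  metrics <- Filter(Negate(is.null), list(
    seed = seed,
    coupled_r2_final = pick("generalized_r2_final", "coupled"),
    uncoupled_r2_final = pick("generalized_r2_final", "uncoupled"),
    coupled_deviation_final = pick("identical_deviation_final", "coupled"),
    uncoupled_deviation_final = pick("identical_deviation_final", "uncoupled"),
    coupled_joint_F_final = pick("joint_F_final_epoch", "coupled"),
    uncoupled_joint_F_final = pick("joint_F_final_epoch", "uncoupled")
  ))
  res <- list(sims = sims, synchrony = syn, divergence = divergence,
              sonograms = sonograms, metrics = metrics,
              config = config, seed = seed)
  class(res) <- c("duet_experiment", class(res))
  if (!is.null(out)) write_experiment(res, out)
  res
}

#' Run the teacher-learner (precision asymmetry) experiment
#'
#' Agent A (the teacher) holds precise prior beliefs about its order
#' parameter; agent B (the learner) imprecise ones, with a different prior
#' mean. In the coupled duet the learner's parameter converges toward the
#' teacher's while the teacher barely moves; the uncoupled control retains
#' the initial gap. Per-epoch posterior means and 90% confidence intervals
#' are recorded for both agents.
#'
#' @param config an [experiment_config()] (experiment
#'   `"precision_asymmetry"`).
#' @inheritParams run_duet
#' @return A list with the simulations, the `theta` tibble (both runs), and
#'   a `metrics` list (displacements, final gap, interval monotonicity).
#' @export
run_precision_asymmetry <- function(
    config = experiment_config("precision_asymmetry"), seed = 1,
    out = NULL) {
  stopifnot(identical(config$experiment, "precision_asymmetry"))
  mk <- function(mode) {
    couple(cfg_agent(config, config$theta_prior_A, "A"),
           cfg_agent(config, config$theta_prior_B, "B"),
           mode = mode, schedule = cfg_schedule(config, turn = "A"))
  }
  sims <- list(coupled = simulate_duet(mk("coupled"), seed,
                                       learn_burnin = config$learn_burnin))
  if (isTRUE(config$with_uncoupled)) {
    sims$uncoupled <- simulate_duet(mk("uncoupled"), seed,
                                    learn_burnin = config$learn_burnin)
  }
  theta <- dplyr::bind_rows(lapply(names(sims), function(nm) {
    dplyr::mutate(sims[[nm]]$theta, run = nm, .before = 1)
  }))
  fin <- function(s, a) {
    th <- s$theta
    utils::tail(th$theta[th$agent == a], 1)
  }
  gap0 <- abs(config$theta_prior_A$mean - config$theta_prior_B$mean)
  dA <- abs(fin(sims$coupled, "A") - config$theta_prior_A$mean)
  dB <- abs(fin(sims$coupled, "B") - config$theta_prior_B$mean)
  wl <- subset(sims$coupled$theta, agent == "B")
  widths <- wl$ci_high - wl$ci_low
  metrics <- list(
    seed = seed, initial_gap = gap0,
    teacher_displacement = dA, learner_displacement = dB,
    displacement_ratio = dB / max(dA, 1e-9),
    final_gap = abs(fin(sims$coupled, "A") - fin(sims$coupled, "B")),
    final_gap_fraction =
      abs(fin(sims$coupled, "A") - fin(sims$coupled, "B")) / gap0,
    uncoupled_final_gap = if (is.null(sims$uncoupled)) NA_real_ else
      abs(fin(sims$uncoupled, "A") - fin(sims$uncoupled, "B")),
    learner_ci_monotone = all(diff(widths) <= 1e-9)
  )
  res <- list(sims = sims, theta = theta, metrics = metrics,
              config = config, seed = seed)
  class(res) <- c("asymmetry_experiment", class(res))
  if (!is.null(out)) write_experiment(res, out)
  res
}

#' Run the niche-inheritance experiment
#'
#' Agent `N` plays the role of a constructed niche: its learned order
#' parameter and posterior precision persist across trials while a fresh
#' organism (`O`, precise priors) is drawn each trial and duets with it.
#' The niche learns slowly (`niche_learning_scale` < 1 scales both its
#' gradient steps and its precision accrual; 0 freezes it). Trial-mean
#' joint free energy (organism-niche complementarity) is recorded per
#' trial; as the niche's parameter is shaped by successive organisms, later
#' organisms find a better-attuned niche and the joint free energy falls.
#'
#' @param config an [experiment_config()] (experiment
#'   `"niche_inheritance"`).
#' @inheritParams run_duet
#' @return A list with the per-trial tibble `trials` (niche theta, its
#'   precision, trial-mean joint F), the last trial's simulation, and a
#'   `metrics` list.
#' @export
run_niche_inheritance <- function(
    config = experiment_config("niche_inheritance"), seed = 1,
    out = NULL) {
  stopifnot(identical(config$experiment, "niche_inheritance"))
  if (config$n_trials < 3) stop("`n_trials` must be >= 3", call. = FALSE)
  niche_state <- list(theta = config$niche_theta_prior$mean,
                      lp = config$niche_theta_prior$log_precision)
  rows <- vector("list", config$n_trials)
  last_sim <- NULL
  for (tr in seq_len(config$n_trials)) {
    niche <- cfg_agent(config, config$niche_theta_prior, "N",
                       extra_model = list(gamma_z = config$niche_gamma_z))
    niche$theta_mean <- niche_state$theta
    niche$theta_log_precision <- niche_state$lp
    niche$lr_scale <- config$niche_learning_scale
    organism <- cfg_agent(config, config$organism_theta_prior, "O")
    sys <- couple(organism, niche, mode = "coupled",
                  schedule = cfg_schedule(config,
                                          n_epochs = config$trial_epochs,
                                          turn = "O"))
    trial_seed <- substream_seed(seed, paste0("trial_", tr))
    sim <- simulate_duet(sys, trial_seed,
                         learn_burnin = config$learn_burnin)
    fe <- sim$fe
    post <- fe$epoch > config$learn_burnin  # entrainment burn-in excluded
    # robust trial complementarity: 20%-trimmed mean of the joint trace
    # (filter transients at chaotic transitions produce heavy right tails)
    joint <- mean(fe$F[post & fe$agent == "O"] +
                    fe$F[post & fe$agent == "N"], trim = 0.2)
    niche_after <- sim$agents[["N"]]
    rows[[tr]] <- tibble::tibble(
      trial = tr,
      niche_theta = niche_after$theta_mean,
      niche_log_precision = niche_after$theta_log_precision,
      joint_F = joint
    )
    niche_state <- list(theta = niche_after$theta_mean,
                        lp = niche_after$theta_log_precision)
    last_sim <- sim
  }
  trials <- dplyr::bind_rows(rows)
  djf <- diff(trials$joint_F)
  metrics <- list(
    seed = seed,
    n_trials = config$n_trials,
    niche_learning_scale = config$niche_learning_scale,
    niche_theta_first = trials$niche_theta[1],
    niche_theta_final = utils::tail(trials$niche_theta, 1),
    joint_F_first = trials$joint_F[1],
    joint_F_final = utils::tail(trials$joint_F, 1),
    joint_F_decrease = trials$joint_F[1] - utils::tail(trials$joint_F, 1),
    trend_violations = sum(djf > 0)
  )
  res <- list(trials = trials, last_sim = last_sim, metrics = metrics,
              config = config, seed = seed)
  class(res) <- c("inheritance_experiment", class(res))
  if (!is.null(out)) write_experiment(res, out)
  res
}
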