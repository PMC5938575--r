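#' Seeded named substreams
#'
#' One master seed spawns independent named substreams (`init_A`, `noise_B`,
#' `trials`, ...) so that toggling one randomness source never shifts the
#' draws of another.
#'
#' @param master master seed (integer).
#' @param name substream name.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(master, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u) * 1009)
  as.integer((abs(as.numeric(master)) * 69069 + h) %% 2147483629)
}

#' Epoch schedule for a duet
#'
#' @param epoch_seconds epoch duration in seconds (the birds sing for 2 s and
#'   then listen).
#' @param n_epochs number of alternating epochs.
#' @param turn_order which agent sings first (`"A"` or `"B"` slot id).
#' @param dt integration step in seconds.
#' @return An object of class `epoch_schedule`.
#' @export
epoch_schedule <- function(epoch_seconds = 2, n_epochs = 8,
                           turn_order = "A", dt = 1 / 256) {
  ticks <- epoch_seconds / dt
  if (abs(ticks - round(ticks)) > 1e-9 || round(ticks) < 2) {
    stop("`epoch_seconds`/`dt` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(epoch_seconds = epoch_seconds, n_epochs = as.integer(n_epochs),
         turn_order = turn_order, dt = dt,
         ticks_per_epoch = as.integer(round(ticks))),
    class = "epoch_schedule"
  )
}

#' Couple two agents through a shared Markov blanket
#'
#' Builds a two-agent system in which the only cross-agent data path is the
#' emission buffer: each agent's active states (its emitted song) are the
#' other's sensory states. In `"uncoupled"` mode the cross wiring is severed
#' (the birds are too far apart): each agent hears only its own emission,
#' which for a silent (listening) agent is the zero-amplitude sample.
#'
#' @param agent_A,agent_B two [ns_agent()]s with matching sensory dimensions.
#' @param mode `"coupled"` or `"uncoupled"`.
#' @param schedule an [epoch_schedule()].
#' @param attention_drop optional reduction of the sensory log-precision
#'   applied by a listener attending to the severed channel (default 0: the
#'   zero-amplitude sample is heard at full precision, so silence is
#'   surprising when the model predicts song).
#' @return An object of class `blanket_system`.
#' @export
couple <- function(agent_A, agent_B, mode = c("coupled", "uncoupled"),
                   schedule = epoch_schedule(), attention_drop = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(agent_A, "ns_agent"), inherits(agent_B, "ns_agent"))
  if (agent_A$model$sensory_dim != agent_B$model$sensory_dim) {
    stop("agents' sensory dimensions do not match", call. = FALSE)
  }
  if (agent_A$model$n_hidden != agent_B$model$n_hidden) {
    stop("agents' sensory embedding orders do not match", call. = FALSE)
  }
  if (identical(agent_A$id, agent_B$id)) {
    stop("agents must have distinct ids", call. = FALSE)
  }
  # declared update-graph wiring: every data path each update consumes
  wiring <- wiring_edges(agent_A$id, agent_B$id, mode)
  structure(
    list(agents = list(agent_A, agent_B),
         mode = mode, schedule = schedule,
         attention_drop = attention_drop, wiring = wiring),
    class = "blanket_system"
  )
}

# The update graph: nodes are {internal, emission, sensory, noise} per agent;
# edges say which buffers each computed quantity reads.
wiring_edges <- function(id_a, id_b, mode) {
  own <- function(id, other) {
    tibble::tibble(
      from = c(paste0("internal_", id), paste0("sensory_", id),
               paste0("noise_", id)),
      to = c(paste0("emission_", id), paste0("internal_", id),
             paste0("sensory_", id))
    )
  }
  cross <- if (mode == "coupled") {
    tibble::tibble(
      from = c(paste0("emission_", id_a), paste0("emission_", id_b)),
      to = c(paste0("sensory_", id_b), paste0("sensory_", id_a))
    )
  } else {
    tibble::tibble(
      from = c(paste0("emission_", id_a), paste0("emission_", id_b)),
      to = c(paste0("sensory_", id_a), paste0("sensory_", id_b))
    )
  }
  dplyr::bind_rows(own(id_a, id_b), own(id_b, id_a), cross)
}

#' @export
print.blanket_system <- function(x, ...) {
  cat(sprintf("<blanket_system: %s, agents '%s' + '%s', %d epochs x %gs>\n",
              x$mode, x$agents[[1]]$id, x$agents[[2]]$id,
              x$schedule$n_epochs, x$schedule$epoch_seconds))
  invisible(x)
}

#' Simulate a duet
#'
#' Runs the alternating sing/listen schedule: in each epoch the singer voices
#' its predictions tick by tick and hears itself (noiselessly); the listener
#' perceives the incoming samples (the singer's emission plus seeded sensory
#' noise when coupled; the zero-amplitude sample, attended with attenuated
#' precision, when uncoupled). Both agents update their order parameter at
#' every epoch boundary. Expectations persist across epochs; only roles
#' switch. The result is fully determined by `(system, seed)`.
#'
#' @param system a [couple()]d `blanket_system`.
#' @param seed master seed; spawns substreams `init_<id>` and `noise_<id>`.
#' @param init `"random"` draws each agent's initial order-0 expectations
#'   uniformly from \[-8, 8\]^3 per level from its `init` substream;
#'   `"perturb"` gives the second agent the first agent's draw displaced by
#'   `1e-6` (for demonstrating chaotic divergence from adjacent starts);
#'   `"keep"` uses the expectations the agents were built with.
#' @param learn_burnin number of initial epochs during which no learning
#'   step is applied (the first exchange entrains the listeners; gradients
#'   collected before entrainment are unreliable).
#' @return A `duet_sim` object; see [tidy.duet_sim()].
#' @examples
#' \donttest{
#' sys <- couple(ns_agent(birdsong_model(), id = "A"),
#'               ns_agent(birdsong_model(), id = "B"),
#'               schedule = epoch_schedule(n_epochs = 2))
#' sim <- simulate_duet(sys, seed = 1)
#' }
#' @export
simulate_duet <- function(system, seed, init = c("random", "perturb", "keep"),
                          learn_burnin = 2L) {
  stopifnot(inherits(system, "blanket_system"))
  init <- match.arg(init)
  sch <- system$schedule
  dt <- sch$dt
  Tpe <- sch$ticks_per_epoch
  Ttot <- Tpe * sch$n_epochs
  agents <- system$agents
  ids <- vapply(agents, function(a) a$id, character(1))

  if (init != "keep") {
    draws <- lapply(1:2, function(i) {
      set.seed(substream_seed(seed, paste0("init_", ids[i])))
      list(x1 = stats::runif(3, -8, 8), x2 = stats::runif(3, -8, 8),
           eps = stats::rnorm(6))
    })
    if (init == "perturb") {
      draws[[2]]$x1 <- draws[[1]]$x1 + 1e-6 * draws[[2]]$eps[1:3]
      draws[[2]]$x2 <- draws[[1]]$x2 + 1e-6 * draws[[2]]$eps[4:6]
    }
    for (i in 1:2) {
      old <- agents[[i]]
      agents[[i]] <- ns_agent(
        old$model, init_x1 = draws[[i]]$x1, init_x2 = draws[[i]]$x2,
        k_mu = old$k_mu, eta_theta = old$eta_theta, id = ids[i]
      )
      # re-initialization refreshes expectations only: learned parameter
      # posteriors (and learning-rate scaling) carry over
      agents[[i]]$lr_scale <- old$lr_scale
      agents[[i]]$theta_step_cap <- old$theta_step_cap
      agents[[i]]$theta_mean <- old$theta_mean
      agents[[i]]$theta_log_precision <- old$theta_log_precision
    }
  }
  init_values <- lapply(agents, function(a) {
    list(x1 = a$expectations$x1$values[, 1], x2 = a$expectations$x2$values[, 1])
  })

  # pre-drawn sensory noise, indexed by tick so that severing the coupling
  # does not shift any other stream
  nh1 <- agents[[1]]$model$n_hidden + 1L
  noise <- lapply(1:2, function(i) {
    set.seed(substream_seed(seed, paste0("noise_", ids[i])))
    matrix(stats::rnorm(2L * nh1 * Ttot), 2L * nh1, Ttot)
  })

  n_mu <- 3L * nh1 + (agents[[1]]$model$n_cause + 1L) + 3L * nh1
  MU <- lapply(1:2, function(i) matrix(NA_real_, n_mu, Ttot))
  HEARD <- lapply(1:2, function(i) matrix(NA_real_, 2L * nh1, Ttot))
  GZEFF <- lapply(1:2, function(i) numeric(Ttot))
  FE <- lapply(1:2, function(i) {
    list(F = numeric(Ttot), accuracy = numeric(Ttot),
         complexity = numeric(Ttot))
  })
  song <- matrix(NA_real_, 2, Ttot)  # audible channel heard at each tick
  theta_rows <- list(theta_row(agents, epoch = 0L))
  lr_scales <- vapply(agents, function(a) {
    if (is.null(a$lr_scale)) 1 else a$lr_scale
  }, numeric(1))

  first <- match(sch$turn_order, ids)
  if (is.na(first)) first <- 1L
  for (ep in seq_len(sch$n_epochs)) {
    s_i <- if (ep %% 2L == 1L) first else 3L - first
    l_i <- 3L - s_i
    cols <- (ep - 1L) * Tpe + seq_len(Tpe)
    singer <- agents[[s_i]]; listener <- agents[[l_i]]
    singer$role <- "singing"; listener$role <- "listening"

    sp <- core_pars(singer, gamma_z_eff = singer$model$gamma_z, dt = dt)
    so <- .sing_epoch_core(agent_mu(singer), singer$theta_mean, sp, Tpe)
    if (system$mode == "coupled") {
      # the listener filters the heard song (emission plus seeded noise)
      lm <- listener$model
      dec <- if (is.null(lm$gamma_z_decay)) 2 else lm$gamma_z_decay
      ords <- rep(0:(nh1 - 1L), each = 2L)
      sdz <- exp(-(lm$gamma_z - ords * dec) / 2)
      Yl <- so$emission + sdz * noise[[l_i]][, cols, drop = FALSE]
      gz_l <- listener$model$gamma_z
      lp <- core_pars(listener, gamma_z_eff = gz_l, dt = dt)
      lo <- .epoch_core(agent_mu(listener), Yl, listener$theta_mean, lp, FALSE)
    } else {
      # severed channel: the non-voicing agent hears the zero-amplitude
      # sample. With no usable signal its expectations follow the prior
      # prediction (its own generative flow); its free energy is evaluated
      # against the silence it hears, at full precision (attention_drop can
      # attenuate it), so unanswered song remains surprising.
      Yl <- matrix(0, 2L * nh1, Tpe)
      gz_l <- listener$model$gamma_z - system$attention_drop
      lp <- core_pars(listener, gamma_z_eff = gz_l, dt = dt)
      lo <- .sing_epoch_core(agent_mu(listener), listener$theta_mean, lp, Tpe)
      fe_l <- .fe_trace_core(lo$mu, Yl, listener$theta_mean, lp)
      lo$F <- fe_l$F; lo$accuracy <- fe_l$accuracy
      lo$complexity <- fe_l$complexity
      lo$gtheta <- fe_l$gtheta; lo$htheta <- fe_l$htheta
      lo$emission <- matrix(0, 2L * nh1, Tpe)  # it does not voice
    }

    MU[[s_i]][, cols] <- so$mu; MU[[l_i]][, cols] <- lo$mu
    HEARD[[s_i]][, cols] <- so$emission  # self-audition
    HEARD[[l_i]][, cols] <- Yl
    GZEFF[[s_i]][cols] <- sp$gamma_z_eff; GZEFF[[l_i]][cols] <- gz_l
    for (nm in c("F", "accuracy", "complexity")) {
      FE[[s_i]][[nm]][cols] <- so[[nm]]; FE[[l_i]][[nm]][cols] <- lo[[nm]]
    }
    song[, cols] <- present_song(so$emission, singer$model)

    singer <- agent_set_mu(singer, so$mu_final)
    listener <- agent_set_mu(listener, lo$mu_final)
    tr_s <- theta_trace(so$mu, singer$model, sch$epoch_seconds)
    tr_l <- theta_trace(lo$mu, listener$model, sch$epoch_seconds)
    if (ep > learn_burnin) {
      singer <- learning_step(singer, tr_s, lr_scale = lr_scales[s_i])
      listener <- learning_step(listener, tr_l, lr_scale = lr_scales[l_i])
    }
    agents[[s_i]] <- singer; agents[[l_i]] <- listener
    theta_rows[[ep + 1L]] <- theta_row(agents, epoch = ep)
  }

  epoch_of <- rep(seq_len(sch$n_epochs), each = Tpe)
  singer_of <- ids[ifelse(epoch_of %% 2L == 1L, first, 3L - first)]
  structure(
    list(
      mu = stats::setNames(MU, ids),
      heard = stats::setNames(HEARD, ids),
      gz_eff = stats::setNames(GZEFF, ids),
      fe = fe_tibble(FE, ids, dt, epoch_of),
      song = tibble::tibble(
        tick = seq_len(Ttot), time_s = seq_len(Ttot) * dt,
        epoch = epoch_of, singer = singer_of,
        amplitude = song[1, ], frequency = song[2, ]
      ),
      theta = dplyr::bind_rows(theta_rows),
      agents = stats::setNames(agents, ids),
      init_values = stats::setNames(init_values, ids),
      learn_burnin = learn_burnin,
      mode = system$mode, schedule = sch, wiring = system$wiring,
      attention_drop = system$attention_drop,
      seed = seed, dt = dt, ids = ids,
      epoch_of = epoch_of, singer_of = singer_of
    ),
    class = "duet_sim"
  )
}

# Learning trace from the cause's equilibrium displacement. Theta and the
# cause act on the fast flow through the same lever
# (rho = theta + cap * tanh(v / cap)), so at the cause's equilibrium
# dF/dtheta = -Pi_v (v - P x2) / dsat exactly; this form is robust to the
# tracking lag that biases the raw tick-wise product gradient, and vanishes
# for a self-consistent singer (v = P x2 by construction).
theta_trace <- function(MU, model, epoch_seconds) {
  nh1 <- model$n_hidden + 1L
  o_v <- 3L * nh1 + 1L
  o_x2 <- 3L * nh1 + model$n_cause + 1L
  v <- MU[o_v, ]
  P <- model$levels[[2]]$output_map
  Px2 <- as.vector(P %*% MU[o_x2 + c(1L, 2L, 3L), , drop = FALSE])
  cap <- model$rho_mod_cap
  th <- tanh(v / cap)
  dsat <- pmax(1 - th^2, 0.1)
  pv <- exp(model$gamma_v)
  list(gtheta = -pv * (v - Px2) / dsat,
       htheta = pv / dsat^2,
       epoch_seconds = epoch_seconds)
}

theta_row <- function(agents, epoch) {
  dplyr::bind_rows(lapply(agents, function(a) {
    ci <- confidence_interval(a, 0.90)
    tibble::tibble(
      epoch = epoch, agent = a$id, theta = a$theta_mean,
      theta_log_precision = a$theta_log_precision,
      ci_low = ci[["low"]], ci_high = ci[["high"]]
    )
  }))
}

fe_tibble <- function(FE, ids, dt, epoch_of) {
  dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    tibble::tibble(
      tick = seq_along(FE[[i]]$F), time_s = seq_along(FE[[i]]$F) * dt,
      epoch = epoch_of, agent = ids[i],
      F = FE[[i]]$F, energy = FE[[i]]$F, entropy = 0,
      complexity = FE[[i]]$complexity, accuracy = FE[[i]]$accuracy
    )
  }))
}

# emission (normalized linear channels) -> audible (amplitude, Hz)
present_song <- function(emission, model) {
  amp <- softplus(model$amp_a0 + model$amp_a1 * emission[1, ])
  freq <- model$f_mid + model$f_gain * emission[2, ]
  freq <- pmin(pmax(freq, model$freq_range[1]), model$freq_range[2])
  rbind(amp, freq)
}

#' @export
print.duet_sim <- function(x, ...) {
  cat(sprintf(
    "<duet_sim: %s, %d epochs x %gs, agents %s; seed %s>\n",
    x$mode, x$schedule$n_epochs, x$schedule$epoch_seconds,
    paste(x$ids, collapse = " + "), format(x$seed)
  ))
  invisible(x)
}

#' Extract an agent's expectation trajectory
#'
#' @param sim a `duet_sim`.
#' @param agent agent id.
#' @param level 1 (fast, "HVC") or 2 (slow, "area X").
#' @param orders derivative orders to include (0 = values only). Derivative
#'   orders are returned in natural units (per second), unscaled from the
#'   internal dimensionless-time convention.
#' @return Numeric matrix, ticks by (3 x length(orders)) columns.
#' @export
expectation_trajectory <- function(sim, agent, level = 2, orders = 0) {
  stopifnot(inherits(sim, "duet_sim"))
  M <- sim$mu[[agent]]
  if (is.null(M)) stop("unknown agent id", call. = FALSE)
  m <- sim$agents[[agent]]$model
  nh1 <- m$n_hidden + 1L
  off <- if (level == 1) 0L else 3L * nh1 + (m$n_cause + 1L)
  rate <- if (level == 1) m$rate1 else m$rate2
  out <- do.call(cbind, lapply(orders, function(k) {
    t(M[off + 3L * k + 1:3, , drop = FALSE]) * rate^k
  }))
  colnames(out) <- unlist(lapply(orders, function(k) {
    paste0("x", 1:3, if (k > 0) paste0("_d", k) else "")
  }))
  out
}

#' Structural and dynamic audit of the Markov blanket
#'
#' Checks the conditional-independence contract two ways. Structurally, it
#' walks the declared update graph and verifies that the only edges leaving
#' one agent's side reach the other through the emission buffer (internal
#' states never feed the partner's update directly, and external states
#' never feed the partner's active states). Dynamically, it replays each
#' agent's whole trajectory from its own initial state plus the recorded
#' heard buffer alone and requires bitwise-equal expectations, proving that
#' the realized update consumed nothing else.
#'
#' @param system a `blanket_system`.
#' @param seed seed for the dynamic replay.
#' @param sim optionally, an existing `simulate_duet(system, seed)` result.
#' @return A list with `structural_ok`, `replay_ok`, `ok` and the audited
#'   `graph`.
#' @export
audit_blanket <- function(system, seed = 1, sim = NULL) {
  stopifnot(inherits(system, "blanket_system"))
  ids <- vapply(system$agents, function(a) a$id, character(1))
  g <- system$wiring
  side <- function(node) sub("^[a-z]+_", "", node)
  kind <- function(node) sub("_.*$", "", node)
  cross <- g[side(g$from) != side(g$to), , drop = FALSE]
  structural_ok <- all(kind(cross$from) == "emission" &
                         kind(cross$to) == "sensory") &&
    !any(kind(g$from) == "internal" & side(g$from) != side(g$to)) &&
    !any(kind(g$to) == "internal" & side(g$from) != side(g$to))

  if (is.null(sim)) sim <- simulate_duet(system, seed)
  replay_ok <- all(vapply(ids, function(id) {
    replay_matches(sim, id)
  }, logical(1)))
  list(structural_ok = structural_ok, replay_ok = replay_ok,
       ok = structural_ok && replay_ok, graph = g)
}

# re-run one agent against its recorded heard buffer only; must reproduce
# its recorded trajectory exactly
replay_matches <- function(sim, id) {
  sch <- sim$schedule
  Tpe <- sch$ticks_per_epoch
  agent0 <- sim$agents[[id]]
  # rebuild the initial agent from the recorded initial expectations
  iv <- sim$init_values[[id]]
  ag <- ns_agent(agent0$model, init_x1 = iv$x1, init_x2 = iv$x2,
                 k_mu = agent0$k_mu, eta_theta = agent0$eta_theta, id = id)
  ag$lr_scale <- agent0$lr_scale
  ag$theta_step_cap <- agent0$theta_step_cap
  th0 <- sim$theta[sim$theta$epoch == 0L & sim$theta$agent == id, ]
  ag$theta_mean <- th0$theta
  ag$theta_log_precision <- th0$theta_log_precision
  lr <- if (is.null(agent0$lr_scale)) 1 else agent0$lr_scale
  ok <- TRUE
  for (ep in seq_len(sch$n_epochs)) {
    cols <- (ep - 1L) * Tpe + seq_len(Tpe)
    pars <- core_pars(ag, gamma_z_eff = sim$gz_eff[[id]][cols[1]],
                      dt = sch$dt)
    singing <- identical(sim$singer_of[cols[1]], id)
    out <- if (singing || sim$mode == "uncoupled") {
      .sing_epoch_core(agent_mu(ag), ag$theta_mean, pars, Tpe)
    } else {
      .epoch_core(agent_mu(ag), sim$heard[[id]][, cols, drop = FALSE],
                  ag$theta_mean, pars, FALSE)
    }
    ok <- ok && identical(out$mu, sim$mu[[id]][, cols, drop = FALSE])
    ag <- agent_set_mu(ag, out$mu_final)
    if (ep > sim$learn_burnin) {
      ag <- learning_step(ag, theta_trace(out$mu, ag$model,
                                          sch$epoch_seconds),
                          lr_scale = lr)
    }
  }
  ok
}

#' Swap the labels of the two agents in a system
#'
#' Relabelling antisymmetry: because the Markov blanket's conditional
#' independencies are symmetric under exchanging (internal, external) and
#' (sensory, active) labels, swapping the two agents (and the turn order)
#' must yield the mirror-identical simulation under the same seed.
#'
#' @param system a `blanket_system`.
#' @return The relabelled system.
#' @export
relabel_system <- function(system) {
  sch <- system$schedule
  ids <- vapply(system$agents, function(a) a$id, character(1))
  sch$turn_order <- if (identical(sch$turn_order, ids[1])) ids[1] else ids[2]
  couple(system$agents[[2]], system$agents[[1]],
         mode = system$mode, schedule = sch,
         attention_drop = system$attention_drop)
}
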