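#' Construct an active-inference agent
#'
#' An agent holds posterior expectations over its model's hidden states and
#' cause in generalized coordinates, the posterior mean and log-precision of
#' its learnable order parameter (the fast level's base `rho`), the fixed priors
#' those started from, and a role flag.
#'
#' @param model a [birdsong_model()] or [gauss_model()].
#' @param init_x1,init_x2 3-vectors of initial order-0 expectations for the
#'   fast and slow level (birdsong models). Higher orders start at zero.
#' @param init_mean initial posterior mean ([gauss_model()] agents).
#' @param role one of `"singing"`, `"listening"`, `"silent"`.
#' @param k_mu perception step-size gain (default 2; the gradient flow is
#'   `mu_dot = D mu - k_mu dF/dmu`).
#' @param eta_theta learning-rate gain for the order parameter.
#' @param id agent identifier (used to key the agent's random substreams).
#' @return An object of class `ns_agent`.
#' @examples
#' a <- ns_agent(birdsong_model(), init_x1 = c(1, 1, 25), init_x2 = c(1, 1, 25))
#' @export
ns_agent <- function(model, init_x1 = c(1, 1, 25), init_x2 = c(1, 1, 25),
                     init_mean = 0, role = "silent",
                     k_mu = 2, eta_theta = 1, id = "A") {
  role <- match.arg(role, c("singing", "listening", "silent"))
  if (inherits(model, "birdsong_model")) {
    expectations <- flow_consistent_expectations(model, init_x1, init_x2)
    theta_mean <- model$theta_prior_mean
    theta_lp <- model$theta_prior_log_precision
  } else if (inherits(model, "gauss_model")) {
    expectations <- list(mu = init_mean)
    theta_mean <- NA_real_
    theta_lp <- NA_real_
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  structure(
    list(
      model = model,
      expectations = expectations,
      theta_mean = theta_mean,
      theta_log_precision = theta_lp,
      prior_theta_mean = theta_mean,
      prior_theta_log_precision = theta_lp,
      role = role, k_mu = k_mu, eta_theta = eta_theta, id = id
    ),
    class = "ns_agent"
  )
}

#' @export
print.ns_agent <- function(x, ...) {
  cat(sprintf("<ns_agent '%s' (%s), model: %s>\n", x$id, x$role,
              class(x$model)[1]))
  if (inherits(x$model, "birdsong_model")) {
    cat(sprintf("  theta: %.4f (log-precision %.3f; prior %.4f @ %.3f)\n",
                x$theta_mean, x$theta_log_precision,
                x$prior_theta_mean, x$prior_theta_log_precision))
  }
  invisible(x)
}

#' Flow-consistent initial expectations
#'
#' Seeds the derivative orders of the expectations from the model's own flow
#' (scaled order k+1 set to `T` times the generalized flow at order k), so
#' the initial state errors vanish exactly and the filter starts on the
#' generalized-coordinate manifold of its dynamics rather than jumping to a
#' fixed point from an inconsistent start. Blocks follow the scaled
#' convention of [prediction_errors()].
#'
#' @param model a [birdsong_model()].
#' @param x1_0,x2_0 order-0 values for the fast and slow level.
#' @param theta order parameter used for the slow flow.
#' @return List of [gen_state()]s `x1`, `v`, `x2`.
#' @export
flow_consistent_expectations <- function(model, x1_0, x2_0,
                                         theta = model$theta_prior_mean) {
  nh1 <- model$n_hidden + 1L
  nc1 <- model$n_cause + 1L
  p1 <- model$levels[[1]]$flow_params
  p2 <- model$levels[[2]]$flow_params
  P <- model$levels[[2]]$output_map
  T1 <- 1 / model$rate1
  T2 <- 1 / model$rate2
  rconv <- T1 / T2

  X2 <- matrix(0, 3, nh1)
  X2[, 1] <- x2_0
  J2 <- lorenz_jacobian(x2_0, p2$sigma, model$rho2, p2$beta, p2$tau)
  for (k in 2:nh1) {
    X2[, k] <- T2 * if (k == 2) {
      lorenz_flow(x2_0, p2$sigma, model$rho2, p2$beta, p2$tau)
    } else {
      J2 %*% X2[, k - 1L]
    }
  }
  V <- matrix(P, nrow = 1) %*% X2[, seq_len(nc1), drop = FALSE]

  X1 <- matrix(0, 3, nh1)
  X1[, 1] <- x1_0
  cap <- model$rho_mod_cap
  th <- tanh(V[1] / cap)
  rho1 <- theta + cap * th
  J1 <- lorenz_jacobian(x1_0, p1$sigma, rho1, p1$beta, p1$tau)
  dfdv <- (1 - th^2) * c(0, x1_0[1], 0) / p1$tau
  vv <- c(as.vector(V) * rconv^(seq_len(nc1) - 1L), rep(0, nh1 - nc1))
  for (k in 2:nh1) {
    X1[, k] <- T1 * if (k == 2) {
      lorenz_flow(x1_0, p1$sigma, rho1, p1$beta, p1$tau)
    } else {
      J1 %*% X1[, k - 1L] + dfdv * vv[k - 1L]
    }
  }
  list(x1 = gen_state(X1), x2 = gen_state(X2), v = gen_state(V))
}

# flatten expectations to the core's mu layout and back
agent_mu <- function(agent) {
  e <- agent$expectations
  c(as.vector(e$x1$values), as.vector(e$v$values), as.vector(e$x2$values))
}

agent_set_mu <- function(agent, mu) {
  m <- agent$model
  nh1 <- m$n_hidden + 1L
  nc1 <- m$n_cause + 1L
  agent$expectations$x1$values <- matrix(mu[seq_len(3 * nh1)], 3, nh1)
  agent$expectations$v$values <- matrix(mu[3 * nh1 + seq_len(nc1)], 1, nc1)
  agent$expectations$x2$values <- matrix(mu[3 * nh1 + nc1 + seq_len(3 * nh1)],
                                         3, nh1)
  agent
}

# parameter list handed to the compiled core
core_pars <- function(agent, gamma_z_eff = NULL, dt = 1 / 256) {
  m <- agent$model
  p1 <- m$levels[[1]]$flow_params
  p2 <- m$levels[[2]]$flow_params
  list(
    sigma1 = p1$sigma, beta1 = p1$beta, tau1 = p1$tau,
    rho1_base = agent$prior_theta_mean,
    sigma2 = p2$sigma, beta2 = p2$beta, tau2 = p2$tau,
    rho2 = m$rho2,
    output_map = m$levels[[2]]$output_map,
    amp_a0 = m$amp_a0, amp_a1 = m$amp_a1, f_ref = m$f_ref,
    gamma_z_eff = if (is.null(gamma_z_eff)) m$gamma_z else gamma_z_eff,
    gamma_w = m$gamma_w, gamma_v = m$gamma_v,
    gamma_z_decay = if (is.null(m$gamma_z_decay)) 2 else m$gamma_z_decay,
    rate1 = m$rate1, rate2 = m$rate2,
    theta_prior_mean = agent$prior_theta_mean,
    theta_prior_log_precision = agent$prior_theta_log_precision,
    k_mu = agent$k_mu, dt = dt,
    n_hidden = m$n_hidden, n_cause = m$n_cause,
    n_substeps = if (is.null(m$n_substeps)) 4L else m$n_substeps,
    rho_mod_cap = if (is.null(m$rho_mod_cap)) 8 else m$rho_mod_cap,
    max_step = if (is.null(m$max_step)) 10 else m$max_step
  )
}

#' One perception step: gradient flow of expectations on free energy
#'
#' Advances the agent's expectations one step of size `dt` along
#' `mu_dot = D mu - k_mu dF/dmu` using local linearization, where `D` is the
#' generalized shift operator and the free-energy gradient is assembled from
#' finite differences through the prediction errors. For [gauss_model()]
#' agents there are no dynamics (`D = 0`) and the flow is plain free-energy
#' descent on the posterior mean.
#'
#' @param agent an [ns_agent()].
#' @param sensory a [gen_state()] of normalized sensory channels (birdsong)
#'   or a numeric observation (static Gaussian).
#' @param dt step size in seconds.
#' @param gamma_z_eff effective (attention-weighted) sensory log-precision.
#' @return The updated agent, with attributes `F`, `accuracy`, `complexity`,
#'   `gtheta`, `htheta` describing the step.
#' @export
perception_step <- function(agent, sensory, dt = 1 / 256,
                            gamma_z_eff = NULL) {
  stopifnot(inherits(agent, "ns_agent"))
  if (inherits(agent$model, "gauss_model")) {
    return(perception_step_gauss(agent, sensory, dt))
  }
  y <- if (inherits(sensory, "gen_state")) {
    as.vector(sensory$values)
  } else {
    as.numeric(sensory)
  }
  out <- .tick_core(agent_mu(agent), y, agent$theta_mean,
                    core_pars(agent, gamma_z_eff, dt))
  agent <- agent_set_mu(agent, out$mu)
  attr(agent, "F") <- out$F
  attr(agent, "accuracy") <- out$accuracy
  attr(agent, "complexity") <- out$complexity
  attr(agent, "gtheta") <- out$gtheta
  attr(agent, "htheta") <- out$htheta
  agent
}

perception_step_gauss <- function(agent, s, dt) {
  m <- agent$model
  mu <- agent$expectations$mu
  grad <- function(x) (x - s) / m$obs_var + (x - m$prior_mean) / m$prior_var
  # linear flow: exact local-linearization step
  flow <- function(x) -agent$k_mu * grad(x)
  agent$expectations$mu <- integrate_flow(flow, mu, dt)
  rep <- free_energy_gaussian(m, s, gauss_beliefs(agent$expectations$mu,
                                                  log(1 / m$obs_var + 1 / m$prior_var)))
  attr(agent, "F") <- rep$F
  agent
}

#' Emit a song sample (action as voiced prediction)
#'
#' A singing agent voices its proprioceptive predictions: the song sample is
#' [song_observation()] evaluated at its current fast-level expectations. A
#' silent agent emits the zero-amplitude sample. Calling this on a listening
#' agent is a contract violation.
#'
#' @param agent an [ns_agent()] with role `"singing"` or `"silent"`.
#' @return Named numeric vector `c(amplitude, frequency)`.
#' @export
action_step <- function(agent) {
  stopifnot(inherits(agent, "ns_agent"))
  if (agent$role == "listening") {
    stop("action_step called on a listening agent", call. = FALSE)
  }
  if (agent$role == "silent") {
    return(c(amplitude = 0, frequency = agent$model$f_mid))
  }
  song_observation(agent$expectations$x1$values[, 1], agent$model)
}

# full generalized emission in normalized channels (2 x (n_hidden+1))
agent_emission <- function(agent, dt = 1 / 256) {
  e <- .emission_core(agent_mu(agent), core_pars(agent, dt = dt))
  matrix(e, nrow = 2)
}

silent_emission <- function(model) {
  matrix(0, 2, model$n_hidden + 1L)
}

#' One learning step of the order parameter from an epoch trace
#'
#' Learning is the slow counterpart of perception: a gradient step on the
#' epoch-averaged free energy. The posterior precision of the order
#' parameter first accrues the epoch's information — the epoch-mean
#' curvature of F in theta, floored at zero, times the epoch duration,
#' discounted by the state precision `exp(-gamma_w)` (the precision-weighted
#' curvature counts every tick's inferred states as data; the discount makes
#' an epoch contribute order-one information about a quasi-static
#' parameter). Then the mean gradient — including the prior term, counted
#' once — is applied scaled by the inverse updated posterior precision.
#' Posterior precision never decreases, so confidence intervals shrink
#' monotonically across epochs.
#'
#' @param agent an [ns_agent()].
#' @param epoch_trace list with numeric vectors `gtheta` (per-tick data-part
#'   dF/dtheta) and `htheta` (per-tick curvature), and `epoch_seconds`.
#' @param lr_scale extra learning-rate scale (1 for organisms; < 1 for a
#'   slow-learning niche; 0 freezes the parameter).
#' @return The updated agent.
#' @export
learning_step <- function(agent, epoch_trace, lr_scale = 1) {
  stopifnot(inherits(agent, "ns_agent"))
  if (!length(epoch_trace$gtheta)) {
    stop("empty epoch trace", call. = FALSE)
  }
  acc_scale <- if (!is.null(agent$model$gamma_v)) {
    exp(-agent$model$gamma_v)
  } else {
    1
  }
  info <- max(0, stats::median(epoch_trace$htheta)) *
    epoch_trace$epoch_seconds * acc_scale
  prec_new <- exp(agent$theta_log_precision) + lr_scale * info
  lp_new <- log(prec_new)
  pi_prior <- exp(agent$prior_theta_log_precision)
  g_mean <- mean(epoch_trace$gtheta, trim = 0.2) +
    pi_prior * (agent$theta_mean - agent$prior_theta_mean)
  step <- -agent$eta_theta * lr_scale * g_mean / prec_new
  cap <- if (is.null(agent$theta_step_cap)) 2 else agent$theta_step_cap
  cap <- cap * lr_scale  # a slow learner's bounded move is slow too
  step <- max(-cap, min(cap, step))  # one epoch moves theta a bounded amount
  agent$theta_mean <- agent$theta_mean + step
  agent$theta_log_precision <- max(lp_new, agent$prior_theta_log_precision)
  agent
}

#' Bayesian confidence interval for the order parameter
#'
#' @param agent an [ns_agent()].
#' @param level coverage probability (default 0.90, the convention used for
#'   the reported learning trajectories).
#' @return Numeric vector `c(low, high)`.
#' @export
confidence_interval <- function(agent, level = 0.90) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd <- exp(-agent$theta_log_precision / 2)
  c(low = agent$theta_mean - z * sd, high = agent$theta_mean + z * sd)
}
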