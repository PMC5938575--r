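#' Lorenz equations of motion with a time constant
#'
#' Returns `(sigma (x2 - x1), x1 (rho - x3) - x2, x1 x2 - beta x3) / tau`.
#' Both levels of the birdsong model use this chaotic flow; the level's time
#' constant `tau` sets its speed.
#'
#' @param x numeric 3-vector of hidden states.
#' @param sigma,rho,beta Lorenz parameters.
#' @param tau time constant in seconds.
#' @return Numeric 3-vector, the state derivative.
#' @examples
#' lorenz_flow(c(1, 1, 1), sigma = 10, rho = 28, beta = 8 / 3)
#' @export
lorenz_flow <- function(x, sigma = 10, rho = 28, beta = 8 / 3, tau = 1) {
  if (!all(is.finite(c(x, sigma, rho, beta, tau)))) {
    stop("lorenz_flow requires finite inputs", call. = FALSE)
  }
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  c(sigma * (x[2] - x[1]),
    x[1] * (rho - x[3]) - x[2],
    x[1] * x[2] - beta * x[3]) / tau
}

# Jacobian of lorenz_flow in x
lorenz_jacobian <- function(x, sigma, rho, beta, tau) {
  matrix(c(-sigma, sigma, 0,
           rho - x[3], -1, -x[1],
           x[2], x[1], -beta),
         nrow = 3, byrow = TRUE) / tau
}

#' Specify one level of a hierarchical dynamic model
#'
#' @param flow_params named list of equation-of-motion parameters
#'   (`sigma`, `rho`, `beta`, `tau` for Lorenz levels).
#' @param output_map numeric vector (or matrix) mapping the level's hidden
#'   states to its outgoing cause(s).
#' @param log_precision_states log-precision (gamma_w) of the state noise.
#' @param log_precision_output log-precision (gamma_z) of the level's output
#'   (sensory noise at level 1, cause noise above).
#' @return An object of class `level_spec`.
#' @export
level_spec <- function(flow_params, output_map,
                       log_precision_states = 8,
                       log_precision_output = 4) {
  if (!is.null(flow_params$tau) && flow_params$tau <= 0) {
    stop("`tau` must be positive", call. = FALSE)
  }
  if (!all(is.finite(c(log_precision_states, log_precision_output)))) {
    stop("log-precisions must be finite", call. = FALSE)
  }
  structure(
    list(flow_params = flow_params,
         output_map = output_map,
         log_precision_states = log_precision_states,
         log_precision_output = log_precision_output),
    class = "level_spec"
  )
}

#' Two-level chaotic birdsong generative model
#'
#' The model a synthetic songbird entertains about its sensorium. A slow
#' Lorenz system ("area X", time constant `tau2`, fixed `rho2`) modulates,
#' through a linear output map, the `rho` parameter of a fast Lorenz system
#' ("HVC", time constant `tau1`), whose states map to a two-channel sonogram
#' (amplitude, frequency). The fast level's base `rho` is the learnable
#' order parameter `theta` shaping the song's chaotic structure: the
#' effective song rho is `theta + cap * tanh(v / cap)` with `v` the slow
#' level's output cause.
#'
#' Hidden states carry embedding order `n_hidden` (default 4); the
#' inter-level cause carries `n_cause` (default 2). Sensory precisions are
#' defined on normalized channels: amplitude in its native units and
#' frequency in hidden-state units `phi = x3 - f_ref`; the mapping to Hz is
#' `freq = f_mid + f_gain * phi`, clipped to `freq_range`.
#'
#' @param theta_prior_mean prior mean of the order parameter (the fast
#'   level's base rho).
#' @param theta_prior_log_precision prior log-precision of the order parameter.
#' @param sigma1,beta1,tau1 fast-level Lorenz parameters.
#' @param sigma2,beta2,tau2,rho2 slow-level Lorenz parameters (`rho2` fixed).
#' @param output_map linear map from slow hidden states to the cause `v`.
#'   The default reads the slow z-state, keeping the fast level inside its
#'   chaotic regime in every epoch and making the order parameter audible
#'   as the song's mean regime (`z̄ ~ theta - 1`).
#' @param gamma_z,gamma_w,gamma_v log-precisions of sensory noise, state
#'   noise, and the inter-level cause noise.
#' @param gamma_z_decay sensory log-precision decrement per derivative
#'   order: hearing conveys the value and low derivatives of a song
#'   reliably, not high ones.
#' @param amp_a0,amp_a1 amplitude map `softplus(a0 + a1 * x2)`.
#' @param f_mid,f_gain,f_ref,freq_range frequency presentation map (Hz).
#' @param n_hidden,n_cause embedding orders.
#' @param rate1,rate2 characteristic rates (1/s) of the fast and slow level
#'   (defaults `sigma/tau`). Internally, generalized coordinates carry
#'   derivatives in the level's dimensionless time `T = 1/rate`, which keeps
#'   every order well scaled and is equivalent to sensory/state precisions
#'   decaying with derivative order at the level's speed.
#' @param rho_mod_cap bound of the cause's modulation of the fast `rho`:
#'   `rho1 = theta + cap * tanh(v / cap)`, keeping the song regime inside a
#'   bounded band around the learnable base for any inferred cause.
#' @param n_substeps local-linearization substeps per sample tick.
#' @param max_step trust-region cap (L2 norm) on one substep's update.
#' @return An object of class `birdsong_model`.
#' @examples
#' m <- birdsong_model()
#' @export
birdsong_model <- function(theta_prior_mean = 24,
                           theta_prior_log_precision = 8,
                           sigma1 = 10, beta1 = 8 / 3, tau1 = 0.25,
                           sigma2 = 10, beta2 = 8 / 3, tau2 = 8, rho2 = 28,
                           output_map = c(0, 0, 0.2),
                           gamma_z = 4, gamma_w = 8, gamma_v = 6,
                           gamma_z_decay = 2,
                           amp_a0 = 0, amp_a1 = 0.3,
                           f_mid = 3500, f_gain = 60, f_ref = 25,
                           freq_range = c(2000, 5000),
                           n_hidden = 4L, n_cause = 2L,
                           rate1 = sigma1 / tau1, rate2 = sigma2 / tau2,
                           rho_mod_cap = 8, n_substeps = 4L,
                           max_step = 10) {
  stopifnot(tau1 > 0, tau2 > 0, length(output_map) == 3L)
  if (!all(is.finite(c(gamma_z, gamma_w, gamma_v,
                       theta_prior_log_precision)))) {
    stop("log-precisions must be finite", call. = FALSE)
  }
  structure(
    list(
      levels = list(
        level_spec(list(sigma = sigma1, rho = theta_prior_mean, beta = beta1,
                        tau = tau1),
                   output_map = NULL,
                   log_precision_states = gamma_w,
                   log_precision_output = gamma_z),
        level_spec(list(sigma = sigma2, rho = rho2, beta = beta2,
                        tau = tau2),
                   output_map = output_map,
                   log_precision_states = gamma_w,
                   log_precision_output = gamma_v)
      ),
      theta_prior_mean = theta_prior_mean,
      theta_prior_log_precision = theta_prior_log_precision,
      rho2 = rho2,
      gamma_z = gamma_z, gamma_w = gamma_w, gamma_v = gamma_v,
      gamma_z_decay = gamma_z_decay,
      amp_a0 = amp_a0, amp_a1 = amp_a1,
      f_mid = f_mid, f_gain = f_gain, f_ref = f_ref,
      freq_range = freq_range,
      sensory_dim = 2L,
      n_hidden = as.integer(n_hidden), n_cause = as.integer(n_cause),
      rate1 = rate1, rate2 = rate2,
      rho_mod_cap = rho_mod_cap,
      n_substeps = as.integer(n_substeps), max_step = max_step
    ),
    class = c("birdsong_model", "ns_model")
  )
}

#' @export
print.birdsong_model <- function(x, ...) {
  cat("<birdsong_model: two-level Lorenz hierarchy>\n")
  cat(sprintf("  fast level : sigma=%g beta=%g tau=%gs rho = theta + mod (theta prior %g, log-prec %g)\n",
              x$levels[[1]]$flow_params$sigma, x$levels[[1]]$flow_params$beta,
              x$levels[[1]]$flow_params$tau, x$theta_prior_mean,
              x$theta_prior_log_precision))
  cat(sprintf("  slow level : sigma=%g beta=%g tau=%gs rho2 = %g\n",
              x$levels[[2]]$flow_params$sigma, x$levels[[2]]$flow_params$beta,
              x$levels[[2]]$flow_params$tau, x$rho2))
  cat(sprintf("  log-precisions: gamma_z=%g gamma_w=%g gamma_v=%g\n",
              x$gamma_z, x$gamma_w, x$gamma_v))
  invisible(x)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Map fast hidden states to a song sample
#'
#' Amplitude is `softplus(a0 + a1 * x2)` (arbitrary units, non-negative);
#' frequency is `f_mid + f_gain * (x3 - f_ref)` Hz, clipped to the model's
#' frequency range.
#'
#' @param x1 fast-level hidden 3-vector (order 0).
#' @param model a [birdsong_model()].
#' @return Named numeric vector `c(amplitude, frequency)`.
#' @export
song_observation <- function(x1, model = birdsong_model()) {
  stopifnot(length(x1) == 3L, all(is.finite(x1)))
  amp <- softplus(model$amp_a0 + model$amp_a1 * x1[2])
  freq <- model$f_mid + model$f_gain * (x1[3] - model$f_ref)
  freq <- min(max(freq, model$freq_range[1]), model$freq_range[2])
  c(amplitude = amp, frequency = freq)
}

# normalized sensory channels are linear in the fast states: (y, z - f_ref);
# the softplus amplitude / Hz maps are the audible presentation layer only
song_pred_norm <- function(x1, model) {
  c(x1[2], x1[3] - model$f_ref)
}

song_pred_jac <- function(x1, model) {
  matrix(c(0, 1, 0,
           0, 0, 1), nrow = 2, byrow = TRUE)
}

#' Hidden-state flow of the hierarchical model
#'
#' Evaluates the order-0 equations of motion at the current expectations: the
#' slow level runs its own Lorenz flow with fixed `rho2`; its output cause
#' `v = output_map . x2` shifts the fast level's `rho` to
#' `theta + cap * tanh(v / cap)` (bounded modulation of the learnable base).
#'
#' @param model a [birdsong_model()].
#' @param hidden list with 3-vectors `x1`, `x2` (order-0 values) and scalar
#'   cause `v` (if `NULL`, computed from `x2`).
#' @param theta current value of the order parameter (level-2 rho);
#'   defaults to the model's prior mean.
#' @return List with derivatives `x1`, `x2` and the cause prediction `v`.
#' @export
model_flow <- function(model, hidden, theta = model$theta_prior_mean) {
  stopifnot(inherits(model, "birdsong_model"))
  x1 <- hidden$x1; x2 <- hidden$x2
  if (length(x1) != 3L || length(x2) != 3L) {
    stop("`hidden` must carry 3-vectors x1 and x2", call. = FALSE)
  }
  p1 <- model$levels[[1]]$flow_params
  p2 <- model$levels[[2]]$flow_params
  v <- if (is.null(hidden$v)) {
    sum(model$levels[[2]]$output_map * x2)
  } else {
    hidden$v
  }
  cap <- model$rho_mod_cap
  rho_eff <- theta + cap * tanh(v / cap)
  list(
    x1 = lorenz_flow(x1, p1$sigma, rho_eff, p1$beta, p1$tau),
    x2 = lorenz_flow(x2, p2$sigma, model$rho2, p2$beta, p2$tau),
    v = sum(model$levels[[2]]$output_map * x2)
  )
}

# generalized flow of one Lorenz level: order 0 exact, orders >= 1 linearized
# X: 3 x (n+1); v: cause orders (vector, recycled with zeros); rho modulation
# saturates at +/- mod_cap (rho = rho0 + cap * tanh(v / cap)) when a cause is
# present; returns 3 x (n+1)
gen_lorenz_flow <- function(X, sigma, rho0, beta, tau, v_orders = NULL,
                            mod_cap = 8) {
  n1 <- ncol(X)
  vv <- rep(0, n1)
  if (!is.null(v_orders)) vv[seq_along(v_orders)] <- v_orders
  x0 <- X[, 1]
  if (is.null(v_orders)) {
    rho <- rho0
    dsat <- 1
  } else {
    th <- tanh(vv[1] / mod_cap)
    rho <- rho0 + mod_cap * th
    dsat <- 1 - th^2
  }
  f <- matrix(0, 3, n1)
  f[, 1] <- lorenz_flow(x0, sigma, rho, beta, tau)
  if (n1 > 1) {
    J <- lorenz_jacobian(x0, sigma, rho, beta, tau)
    dfdv <- dsat * c(0, x0[1], 0) / tau  # d f / d v through the saturation
    for (k in 2:n1) f[, k] <- J %*% X[, k] + dfdv * vv[k]
  }
  f
}

#' Hierarchical prediction errors in generalized coordinates
#'
#' Computes the precision-weighted error structure of the birdsong model in
#' scaled generalized coordinates (order `k` of a block stores
#' `T^k d^k x/dt^k`, `T = tau/sigma` of the generating level): sensory
#' errors `eta_z = sensory - prediction` (all orders), state errors
#' `eta_w^(k) = x^(k+1)/T - f^(k)(x)` for orders `0..n-1` (each order of
#' motion against its shifted partner), and cause errors
#' `eta_v = v - output_map . x2`. Order 0 uses the exact nonlinear maps;
#' higher orders use the maps linearized at the order-0 values, the
#' standard generalized-filtering convention.
#'
#' @param model a [birdsong_model()].
#' @param expectations list of [gen_state()]s `x1` (3 x n_hidden+1),
#'   `x2` (3 x n_hidden+1) and `v` (1 x n_cause+1), scaled convention.
#' @param sensory a [gen_state()] (2 x n_hidden+1), normalized channels in
#'   the fast level's scaled convention.
#' @param theta current order-parameter value.
#' @return Named list of error matrices `z`, `w1`, `v`, `w2`.
#' @export
prediction_errors <- function(model, expectations, sensory,
                              theta = model$theta_prior_mean) {
  stopifnot(inherits(model, "birdsong_model"))
  X1 <- expectations$x1$values
  X2 <- expectations$x2$values
  V <- expectations$v$values
  S <- sensory$values
  n1 <- model$n_hidden + 1L
  if (ncol(X1) != n1 || ncol(S) != n1) {
    stop("embedding order mismatch between expectations and sensory input",
         call. = FALSE)
  }
  p1 <- model$levels[[1]]$flow_params
  p2 <- model$levels[[2]]$flow_params
  P <- model$levels[[2]]$output_map
  T1 <- 1 / model$rate1
  T2 <- 1 / model$rate2
  rconv <- T1 / T2  # converts the cause's scaled orders to T1 scaling

  # sensory errors: order 0 nonlinear, higher orders linearized
  g0 <- song_pred_norm(X1[, 1], model)
  G <- song_pred_jac(X1[, 1], model)
  pred <- cbind(g0, G %*% X1[, -1, drop = FALSE])
  eps_z <- S - pred

  # fast-level state errors, orders 0..n-1: x^(k+1)/T1 - f^(k). The top
  # order has no shifted partner and is excluded, so that every
  # flow-consistent trajectory (not just fixed points) solves the
  # generalized constraint.
  nv <- ncol(V)
  v_conv <- as.vector(V) * rconv^(seq_len(nv) - 1L)
  f1 <- gen_lorenz_flow(X1, p1$sigma, theta, p1$beta, p1$tau,
                        v_orders = v_conv, mod_cap = model$rho_mod_cap)
  eps_w1 <- X1[, -1, drop = FALSE] / T1 - f1[, -n1, drop = FALSE]

  # cause errors: v - P x2 (linear, exact at all cause orders)
  eps_v <- V - matrix(P, nrow = 1) %*% X2[, seq_len(nv), drop = FALSE]

  # slow-level state errors, same convention (fixed rho2)
  f2 <- gen_lorenz_flow(X2, p2$sigma, model$rho2, p2$beta, p2$tau)
  eps_w2 <- X2[, -1, drop = FALSE] / T2 - f2[, -n1, drop = FALSE]

  list(z = eps_z, w1 = eps_w1, v = eps_v, w2 = eps_w2)
}

#' Per-element log-precisions of the birdsong error structure
#'
#' Uniform per block in the scaled-error parametrization. In natural units
#' this is equivalent to precision decaying with derivative order at the
#' generating level's characteristic rate (the roughness weighting of
#' generalized filtering); order-0 precisions equal the block values.
#'
#' @inheritParams birdsong_free_energy
#' @return Named list of matrices shaped like [prediction_errors()] output.
#' @export
model_log_precisions <- function(model, gamma_z_eff = model$gamma_z) {
  nh1 <- model$n_hidden + 1L
  nc1 <- model$n_cause + 1L
  dec <- if (is.null(model$gamma_z_decay)) 2 else model$gamma_z_decay
  list(
    z = matrix(rep(gamma_z_eff - (seq_len(nh1) - 1L) * dec, each = 2L),
               2L, nh1),
    w1 = matrix(model$gamma_w, 3L, nh1 - 1L),
    v = matrix(model$gamma_v, 1L, nc1),
    w2 = matrix(model$gamma_w, 3L, nh1 - 1L)
  )
}

#' Free energy of a birdsong-model configuration
#'
#' Convenience wrapper: [prediction_errors()] followed by
#' [laplace_free_energy()] with the model's (order-weighted) precisions and
#' the order parameter's prior deviation.
#'
#' @inheritParams prediction_errors
#' @param gamma_z_eff effective sensory log-precision (attention); defaults
#'   to the model's `gamma_z`.
#' @return A [fe_report()].
#' @export
birdsong_free_energy <- function(model, expectations, sensory,
                                 theta = model$theta_prior_mean,
                                 gamma_z_eff = model$gamma_z) {
  errs <- prediction_errors(model, expectations, sensory, theta)
  laplace_free_energy(
    errors = errs,
    log_precisions = model_log_precisions(model, gamma_z_eff),
    param_deviation = theta - model$theta_prior_mean,
    param_log_precision = model$theta_prior_log_precision
  )
}
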