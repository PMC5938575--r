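# Independent straight-line oracles, written against the model equations
# directly (not via the package's vectorized/compiled paths).

# classic RK4 on an autonomous vector field
rk4_path <- function(f, x0, dt, n) {
  out <- matrix(NA_real_, n + 1L, length(x0))
  out[1, ] <- x0
  x <- x0
  for (i in seq_len(n)) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- x
  }
  out
}

# naive re-implementation of the birdsong prediction errors: plain loops,
# one scalar at a time, mirroring the declared error conventions
naive_errors <- function(model, ex, sensory, theta) {
  X1 <- ex$x1$values; X2 <- ex$x2$values; V <- as.vector(ex$v$values)
  S <- sensory$values
  nh1 <- ncol(X1); nc1 <- length(V)
  T1 <- 1 / model$rate1; T2 <- 1 / model$rate2
  rconv <- T1 / T2
  cap <- model$rho_mod_cap
  P <- model$levels[[2]]$output_map
  s1 <- model$levels[[1]]$flow_params$sigma
  b1 <- model$levels[[1]]$flow_params$beta
  t1 <- model$levels[[1]]$flow_params$tau
  s2 <- model$levels[[2]]$flow_params$sigma
  b2 <- model$levels[[2]]$flow_params$beta
  t2 <- model$levels[[2]]$flow_params$tau

  eps_z <- matrix(NA_real_, 2, nh1)
  for (k in seq_len(nh1)) {
    pred_a <- X1[2, k]
    pred_f <- X1[3, k] - if (k == 1) model$f_ref else 0
    eps_z[1, k] <- S[1, k] - pred_a
    eps_z[2, k] <- S[2, k] - pred_f
  }

  th <- tanh(V[1] / cap)
  rho <- theta + cap * th
  dsat <- 1 - th^2
  lor <- function(x, sg, rh, bt, tu) {
    c(sg * (x[2] - x[1]), x[1] * (rh - x[3]) - x[2],
      x[1] * x[2] - bt * x[3]) / tu
  }
  jac <- function(x, sg, rh, bt, tu) {
    rbind(c(-sg, sg, 0), c(rh - x[3], -1, -x[1]), c(x[2], x[1], -bt)) / tu
  }
  J1 <- jac(X1[, 1], s1, rho, b1, t1)
  eps_w1 <- matrix(NA_real_, 3, nh1 - 1L)
  for (k in seq_len(nh1 - 1L)) {
    fk <- if (k == 1) {
      lor(X1[, 1], s1, rho, b1, t1)
    } else {
      vk <- if (k <= nc1) V[k] * rconv^(k - 1L) else 0
      as.vector(J1 %*% X1[, k]) + dsat * c(0, X1[1, 1], 0) / t1 * vk
    }
    eps_w1[, k] <- X1[, k + 1L] / T1 - fk
  }

  eps_v <- numeric(nc1)
  for (k in seq_len(nc1)) eps_v[k] <- V[k] - sum(P * X2[, k])

  J2 <- jac(X2[, 1], s2, model$rho2, b2, t2)
  eps_w2 <- matrix(NA_real_, 3, nh1 - 1L)
  for (k in seq_len(nh1 - 1L)) {
    fk <- if (k == 1) lor(X2[, 1], s2, model$rho2, b2, t2)
          else as.vector(J2 %*% X2[, k])
    eps_w2[, k] <- X2[, k + 1L] / T2 - fk
  }
  list(z = eps_z, w1 = eps_w1, v = eps_v, w2 = eps_w2)
}

# naive sum-of-terms free energy from an error set and log-precisions
naive_laplace_F <- function(errors, log_precisions, dev = numeric(0),
                            dev_lp = numeric(0)) {
  tot <- 0
  for (nm in names(errors)) {
    e <- as.numeric(errors[[nm]])
    lp <- as.numeric(log_precisions[[nm]])
    if (length(lp) == 1L) lp <- rep(lp, length(e))
    for (i in seq_along(e)) {
      tot <- tot + 0.5 * (exp(lp[i]) * e[i]^2 - lp[i] + log(2 * pi))
    }
  }
  if (length(dev)) {
    tot <- tot + 0.5 * (exp(dev_lp) * dev^2 - dev_lp + log(2 * pi))
  }
  tot
}

# random scaled-coordinate expectations and matching sensory input
random_instance <- function(model, seed) {
  set.seed(seed)
  ex <- flow_consistent_expectations(model,
                                     stats::runif(3, -8, 8),
                                     stats::runif(3, -8, 8))
  ex$x1$values <- ex$x1$values + matrix(stats::rnorm(15, 0, 0.5), 3, 5)
  ex$x2$values <- ex$x2$values + matrix(stats::rnorm(15, 0, 0.5), 3, 5)
  ex$v$values <- ex$v$values + matrix(stats::rnorm(3, 0, 0.5), 1, 3)
  sens <- gen_state(matrix(stats::rnorm(10, 0, 3), 2, 5))
  list(ex = ex, sens = sens)
}

tiny_duet <- function(mode = "coupled", n_epochs = 2, seed = 1, ...) {
  sys <- couple(ns_agent(birdsong_model(...), id = "A"),
                ns_agent(birdsong_model(...), id = "B"),
                mode = mode,
                schedule = epoch_schedule(n_epochs = n_epochs))
  simulate_duet(sys, seed = seed)
}
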