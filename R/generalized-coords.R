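#' Generalized-coordinate state blocks
#'
#' A `gen_state` holds a block of variables in generalized coordinates of
#' motion: a numeric matrix of size `d x (n + 1)` whose first column is the
#' variables' values and whose column `k + 1` is their k-th temporal
#' derivative. The shift (derivative) operator maps each order onto the next
#' and annihilates the block after `n + 1` applications.
#'
#' @param values numeric matrix (`d` variables by `n + 1` orders) or a numeric
#'   vector (interpreted as a single variable's orders).
#' @param dt sampling interval in seconds.
#' @return An object of class `gen_state`.
#' @examples
#' g <- gen_state(matrix(c(1, 0.5, 0), nrow = 1), dt = 1 / 256)
#' gen_shift(g)
#' @export
gen_state <- function(values, dt = 1 / 256) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (variables x orders)", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("gen_state values must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, dt = dt), class = "gen_state")
}

#' @export
print.gen_state <- function(x, ...) {
  cat(sprintf(
    "<gen_state: %d variable(s), embedding order %d, dt = %g s>\n",
    nrow(x$values), ncol(x$values) - 1L, x$dt
  ))
  print(x$values)
  invisible(x)
}

#' Embedding order of a generalized state
#' @param state a `gen_state`.
#' @return Integer embedding order `n` (the state holds `n + 1` orders).
#' @export
gen_order <- function(state) ncol(state$values) - 1L

#' Shift matrix of the generalized-coordinate derivative operator
#'
#' Returns the nilpotent `(n + 1) x (n + 1)` matrix `D` with ones on the
#' first superdiagonal, so that right-multiplying an orders-in-columns block
#' by `t(D)` (or applying [gen_shift()]) moves each derivative down one order.
#'
#' @param n embedding order.
#' @return A numeric matrix.
#' @export
gen_shift_matrix <- function(n) {
  D <- matrix(0, n + 1L, n + 1L)
  if (n >= 1L) D[cbind(seq_len(n), seq_len(n) + 1L)] <- 1
  D
}

#' Apply the shift (derivative) operator to a generalized state
#'
#' Order `k` of the result equals order `k + 1` of the input; the top order is
#' set to zero. Applying the operator `n + 1` times yields the zero block.
#'
#' @param state a `gen_state`.
#' @return A `gen_state` of the same shape.
#' @export
gen_shift <- function(state) {
  stopifnot(inherits(state, "gen_state"))
  v <- state$values
  n1 <- ncol(v)
  out <- cbind(v[, -1L, drop = FALSE], 0)
  gen_state(out, dt = state$dt)
}

#' Embed a uniformly sampled time series in generalized coordinates
#'
#' Estimates the value and temporal derivatives (up to order `n`) of a signal
#' at its final sample, using backward finite differences of increasing order.
#'
#' @param samples numeric vector or matrix (rows = time, columns = variables)
#'   of uniformly spaced samples.
#' @param order embedding order `n` (number of derivatives to estimate).
#' @param dt sampling interval in seconds.
#' @param times optional sample times; if supplied they must be uniform.
#' @return A `gen_state` with `d` variables and `n + 1` orders.
#' @examples
#' t <- seq(0, 1, by = 1 / 256)
#' g <- gen_embed(sin(2 * pi * t), order = 2, dt = 1 / 256)
#' @export
gen_embed <- function(samples, order, dt, times = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  n_t <- nrow(samples)
  if (n_t < order + 1L) {
    stop(sprintf(
      "need at least %d samples to embed at order %d, got %d",
      order + 1L, order, n_t
    ), call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!is.null(times)) {
    gaps <- diff(times)
    if (max(abs(gaps - mean(gaps))) > 1e-9 * max(abs(gaps))) {
      stop("`times` must be uniformly spaced", call. = FALSE)
    }
  }
  # backward differences at the final sample: k-th derivative ~ Delta^k / dt^k
  out <- matrix(0, ncol(samples), order + 1L)
  for (j in seq_len(ncol(samples))) {
    x <- samples[, j]
    for (k in 0:order) {
      d <- x
      if (k > 0) for (i in seq_len(k)) d <- diff(d)
      out[j, k + 1L] <- d[length(d)] / dt^k
    }
  }
  gen_state(out, dt = dt)
}

#' One local-linearization integration step of a flow
#'
#' Advances a state one step of size `dt` under the flow `f`, using local
#' linearization: with Jacobian `J` of the flow at the current state, the
#' update is `dx = (expm(J dt) - I) J^{-1} f(x)`, which is exact for linear
#' flows. When `J` is singular beyond tolerance (condition number above
#' `cond_tol`) the step falls back to explicit Euler.
#'
#' @param flow a function mapping a numeric vector to its derivative vector,
#'   or a function of a `gen_state` returning a `gen_state`-shaped derivative.
#' @param state numeric vector or `gen_state`.
#' @param dt step size in seconds.
#' @param cond_tol condition-number threshold for the Euler fallback.
#' @param jac_eps relative perturbation for the finite-difference Jacobian.
#' @return The advanced state, same type as the input.
#' @examples
#' # exponential decay: one step of xdot = -x from 1 matches exp(-dt)
#' integrate_flow(function(x) -x, 1, dt = 0.1)
#' @export
integrate_flow <- function(flow, state, dt, cond_tol = 1e10, jac_eps = 1e-6) {
  is_gs <- inherits(state, "gen_state")
  x0 <- if (is_gs) as.vector(state$values) else as.numeric(state)
  f_vec <- if (is_gs) {
    function(x) {
      s <- gen_state(matrix(x, nrow(state$values), ncol(state$values)), state$dt)
      out <- flow(s)
      if (inherits(out, "gen_state")) as.vector(out$values) else as.numeric(out)
    }
  } else {
    function(x) as.numeric(flow(x))
  }
  fx <- f_vec(x0)
  if (!all(is.finite(fx))) {
    stop("flow returned non-finite values at the current state", call. = FALSE)
  }
  d <- length(x0)
  J <- matrix(0, d, d)
  for (i in seq_len(d)) {
    h <- jac_eps * max(1, abs(x0[i]))
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    J[, i] <- (f_vec(xp) - f_vec(xm)) / (2 * h)
  }
  dx <- ll_step(J, fx, dt, cond_tol = cond_tol)
  x1 <- x0 + dx
  if (is_gs) {
    gen_state(matrix(x1, nrow(state$values), ncol(state$values)), state$dt)
  } else {
    x1
  }
}

# local-linearization increment (expm(J dt) - I) J^{-1} f, Euler fallback
ll_step <- function(J, fx, dt, cond_tol = 1e10) {
  d <- length(fx)
  ok <- all(is.finite(J))
  if (ok) {
    cn <- tryCatch(kappa(J, exact = FALSE), error = function(e) Inf)
    ok <- is.finite(cn) && cn < cond_tol
  }
  if (!ok) return(dt * fx)
  E <- as.matrix(Matrix::expm(J * dt)) - diag(d)
  sol <- tryCatch(solve(J, fx), error = function(e) NULL)
  if (is.null(sol)) return(dt * fx)
  as.vector(E %*% sol)
}
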