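test_that("embedding recovers derivatives of simple signals", {
  # constant: all derivatives vanish
  g <- gen_embed(rep(3.5, 10), order = 3, dt = 0.1)
  expect_equal(as.vector(g$values), c(3.5, 0, 0, 0))

  # ramp b*t at t = 0..4: value b*4, slope b, curvature 0
  b <- 1.7
  g <- gen_embed(b * (0:4), order = 2, dt = 1)
  expect_equal(as.vector(g$values), c(4 * b, b, 0))

  # densely sampled sinusoid: matches analytic derivatives
  # backward differences have O(dt) error at order k scaled by om^(k+1)
  om <- 2 * pi
  dt <- 1e-4
  t <- seq(0, 0.4, by = dt)
  g <- gen_embed(sin(om * t), order = 2, dt = dt)
  t_end <- t[length(t)]
  expect_equal(g$values[1, 1], sin(om * t_end), tolerance = 1e-6)
  expect_lt(abs(g$values[1, 2] - om * cos(om * t_end)), 1e-2)
  expect_lt(abs(g$values[1, 3] + om^2 * sin(om * t_end)), 5e-2)
})

test_that("embedding validates its inputs", {
  expect_error(gen_embed(1:3, order = 3, dt = 0.1), "at least 4 samples")
  expect_error(gen_embed(1:10, order = 2, dt = 0.1,
                         times = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10.5)),
               "uniformly spaced")
})

test_that("the shift operator moves orders down and is nilpotent", {
  g <- gen_state(matrix(c(1, 2, 3), nrow = 1), dt = 0.1)
  expect_equal(as.vector(gen_shift(g)$values), c(2, 3, 0))
  expect_equal(as.vector(gen_shift(gen_state(c(5, 0, 0)))$values), c(0, 0, 0))

  # shift^(n+1) annihilates any state; oracle: power of the shift matrix
  set.seed(1)
  for (n in 2:4) {
    D <- gen_shift_matrix(n)
    Dp <- diag(n + 1)
    for (i in seq_len(n + 1)) Dp <- Dp %*% D
    expect_equal(Dp, matrix(0, n + 1, n + 1))
    g <- gen_state(matrix(rnorm(2 * (n + 1)), nrow = 2))
    for (i in seq_len(n + 1)) g <- gen_shift(g)
    expect_equal(g$values, matrix(0, 2, n + 1))
  }
})

test_that("local-linearization integration is exact on linear flows", {
  # fixed point: state unchanged
  x <- c(1.2, -0.7)
  expect_equal(integrate_flow(function(z) c(0, 0), x, dt = 0.3), x)

  # exponential decay matches the closed form
  x1 <- integrate_flow(function(z) -z, 1, dt = 0.1)
  expect_equal(x1, exp(-0.1), tolerance = 1e-6)

  # any linear system: one LL step equals the exact matrix exponential
  set.seed(42)
  A <- matrix(rnorm(9), 3, 3)
  x0 <- rnorm(3)
  x1 <- integrate_flow(function(z) as.vector(A %*% z), x0, dt = 0.05)
  exact <- as.vector(Matrix::expm(A * 0.05) %*% x0)
  expect_equal(x1, exact, tolerance = 1e-8)
})

test_that("local linearization tracks a chaotic flow against an RK4 reference", {
  f <- function(x) lorenz_flow(x, 10, 28, 8 / 3, tau = 1)
  dt <- 1 / 256
  n <- 100
  x <- c(1, 1, 20)
  path <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    x <- integrate_flow(f, x, dt)
    path[i, ] <- x
  }
  ref <- rk4_path(f, c(1, 1, 20), dt / 20, n * 20)
  ref <- ref[seq(21, nrow(ref), by = 20), ]
  expect_lt(sqrt(mean((path - ref)^2)), 1e-2)
})

test_that("integration is deterministic and rejects bad input", {
  f <- function(x) lorenz_flow(x, 10, 28, 8 / 3)
  a <- integrate_flow(f, c(1, 2, 3), 1 / 256)
  b <- integrate_flow(f, c(1, 2, 3), 1 / 256)
  expect_identical(a, b)
  expect_error(integrate_flow(function(x) c(NaN, 0, 0), c(1, 2, 3), 0.1),
               "non-finite")
  expect_error(gen_state(matrix(c(1, Inf), 1, 2)), "finite")
})
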