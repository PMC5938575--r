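test_that("identical-synchrony deviation follows its definition", {
  set.seed(2)
  A <- matrix(rnorm(300), 100, 3)
  expect_equal(identical_sync_deviation(A, A), 0)

  # anti-correlated zero-mean trajectories score 2 after normalization
  Az <- sweep(A, 2, colMeans(A))
  expect_equal(identical_sync_deviation(Az, -Az), 2, tolerance = 1e-2)

  # two independent chaotic runs sit far from the diagonal manifold
  f <- function(x) lorenz_flow(x, 10, 28, 8 / 3)
  r1 <- rk4_path(f, c(1, 1, 20), 0.01, 400)
  r2 <- rk4_path(f, c(-3, 2, 30), 0.01, 400)
  expect_gt(identical_sync_deviation(r1, r2), 0.5)

  expect_error(identical_sync_deviation(A, A[1:10, ]), "matching")
  expect_warning(identical_sync_deviation(matrix(1, 5, 2), matrix(1, 5, 2)),
                 "degenerate")
})

test_that("the generalized-synchrony score is affine-invariant and honest on noise", {
  set.seed(4)
  A <- matrix(rnorm(1536), 512, 3)
  expect_equal(generalized_sync_score(A, A), 1)
  expect_equal(generalized_sync_score(A, 2 * A + 1), 1)

  # independent white noise: no affine map helps (null over several seeds)
  null_scores <- vapply(1:10, function(s) {
    set.seed(100 + s)
    generalized_sync_score(matrix(rnorm(1536), 512, 3),
                           matrix(rnorm(1536), 512, 3))
  }, numeric(1))
  expect_lt(mean(null_scores), 0.2)

  # optimality: the fitted map can never do worse than a fixed identity map
  B <- A + matrix(rnorm(1536, 0, 0.5), 512, 3)
  r2_fit <- generalized_sync_score(A, B)
  rss_id <- colSums((B - A)^2)
  tss <- colSums(sweep(B, 2, colMeans(B))^2)
  r2_id <- mean(pmax(0, 1 - rss_id / tss))
  expect_gte(r2_fit + 1e-10, r2_id)

  # rank-deficient design falls back to ridge with a notice
  Ac <- cbind(A[, 1], A[, 1], A[, 1])
  expect_message(generalized_sync_score(Ac, B), "ridge")
})

test_that("complementarity is additive, symmetric and epoch-aware", {
  fa <- c(1, 2, 3, 4)
  fb <- c(0.5, 0.5, 1, 1)
  expect_equal(complementarity(fa, rep(0, 4))$trace, fa)
  expect_equal(complementarity(fa, fb)$trace, complementarity(fb, fa)$trace)
  pe <- complementarity(fa, fb, epoch = c(1, 1, 2, 2))$per_epoch
  expect_equal(pe$joint_F, c(mean(fa[1:2] + fb[1:2]), mean(fa[3:4] + fb[3:4])))
  expect_error(complementarity(fa, fb[1:3]), "aligned")
})

test_that("sonograms localize spectral power correctly", {
  dt <- 1 / 256
  n <- 512
  # constant 3 kHz tone: every frame peaks at ~3 kHz
  son <- sonogram(rep(1, n), rep(3000, n), dt = dt)
  peaks <- attr(son, "freq_hz")[apply(unclass(son), 2, which.max)]
  expect_true(all(abs(peaks - 3000) < 100))

  # silence: the all-zero matrix
  son0 <- sonogram(rep(0, n), rep(3000, n), dt = dt)
  expect_true(all(unclass(son0) == 0))

  # linear chirp 2 -> 5 kHz: the per-frame peak rises monotonically
  sonc <- sonogram(rep(1, n), seq(2000, 5000, length.out = n), dt = dt)
  peaks <- attr(sonc, "freq_hz")[apply(unclass(sonc), 2, which.max)]
  expect_true(all(diff(peaks) >= 0))
  expect_error(sonogram(1:10, 1:10, window = 1e-5), "window")
})

test_that("duet synchrony reports expose the coupled/uncoupled contrast", {
  sc <- tiny_duet("coupled", n_epochs = 4, seed = 2)
  su <- tiny_duet("uncoupled", n_epochs = 4, seed = 2)
  rc <- synchrony_report(sc, level = 1)
  ru <- synchrony_report(su, level = 1)
  expect_lt(rc$final$identical_deviation, ru$final$identical_deviation)
  expect_true(all(rc$per_epoch$generalized_r2 >= 0 &
                    rc$per_epoch$generalized_r2 <= 1))
  # identical synchrony implies generalized synchrony on the same data
  expect_gt(rc$final$generalized_r2, ru$final$generalized_r2 - 1e-9)
  # complementarity equals the verified sum of the two traces
  FA <- sc$fe$F[sc$fe$agent == "A"]
  FB <- sc$fe$F[sc$fe$agent == "B"]
  expect_equal(rc$complementarity$trace, FA + FB)
})
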