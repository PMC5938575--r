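test_that("coupling validates agents and schedules", {
  a <- ns_agent(birdsong_model(), id = "A")
  b <- ns_agent(birdsong_model(), id = "B")
  expect_s3_class(couple(a, b), "blanket_system")
  expect_error(couple(a, a), "distinct")
  b2 <- ns_agent(birdsong_model(n_hidden = 3L), id = "B")
  expect_error(couple(a, b2), "orders")
  expect_error(epoch_schedule(epoch_seconds = 0.003, dt = 1 / 256), ">= 2")
})

test_that("the wiring severs cross-agent hearing in uncoupled mode", {
  sim_u <- tiny_duet("uncoupled", n_epochs = 2, seed = 2)
  # epoch 1: A sings, B hears only the zero-amplitude sample
  idx <- which(sim_u$epoch_of == 1)
  expect_true(all(sim_u$heard[["B"]][, idx] == 0))
  # the singer hears its own emission (voiced from its current state)
  expect_equal(sim_u$heard[["A"]][, idx[5]],
               as.vector(nichesync:::.emission_core(
                 sim_u$mu[["A"]][, idx[5]],
                 nichesync:::core_pars(sim_u$agents[["A"]]))),
               tolerance = 1e-12)

  # coupled: the listener's sample is the singer's emission plus noise of
  # the declared scale on the value channels
  sim_c <- tiny_duet("coupled", n_epochs = 2, seed = 2)
  idx <- which(sim_c$epoch_of == 1)
  emitA <- vapply(idx, function(t) {
    nichesync:::.emission_core(sim_c$mu[["A"]][, t],
                               nichesync:::core_pars(sim_c$agents[["A"]]))[1]
  }, numeric(1))
  resid <- sim_c$heard[["B"]][1, idx] - emitA
  expect_lt(abs(sd(resid) - exp(-4 / 2)), 0.03)
})

test_that("a duet is bitwise-reproducible from (config, seed)", {
  s1 <- tiny_duet("coupled", n_epochs = 2, seed = 9)
  s2 <- tiny_duet("coupled", n_epochs = 2, seed = 9)
  expect_identical(s1$mu, s2$mu)
  expect_identical(s1$fe, s2$fe)
  expect_identical(s1$theta, s2$theta)
  s3 <- tiny_duet("coupled", n_epochs = 2, seed = 10)
  expect_false(identical(s1$mu, s3$mu))
})

test_that("the blanket audit passes structurally and dynamically", {
  sys <- couple(ns_agent(birdsong_model(), id = "A"),
                ns_agent(birdsong_model(), id = "B"),
                schedule = epoch_schedule(n_epochs = 2))
  aud <- audit_blanket(sys, seed = 4)
  expect_true(aud$structural_ok)
  expect_true(aud$replay_ok)
  expect_true(aud$ok)
  # the declared graph has no internal-to-internal cross edge
  g <- aud$graph
  cross_internal <- grepl("^internal", g$from) & grepl("^internal", g$to) &
    sub(".*_", "", g$from) != sub(".*_", "", g$to)
  expect_false(any(cross_internal))
})

test_that("relabelling the two agents yields mirror-identical trajectories", {
  mk <- function(swapped) {
    a <- ns_agent(birdsong_model(), id = "A")
    b <- ns_agent(birdsong_model(), id = "B")
    sch <- epoch_schedule(n_epochs = 2, turn_order = "A")
    if (swapped) relabel_system(couple(a, b, schedule = sch))
    else couple(a, b, schedule = sch)
  }
  s1 <- simulate_duet(mk(FALSE), seed = 6)
  s2 <- simulate_duet(mk(TRUE), seed = 6)
  expect_identical(s1$mu[["A"]], s2$mu[["A"]])
  expect_identical(s1$mu[["B"]], s2$mu[["B"]])
  expect_identical(s1$singer_of, s2$singer_of)
})

test_that("expectations persist across epoch boundaries", {
  sim <- tiny_duet("coupled", n_epochs = 2, seed = 1)
  Tpe <- sim$schedule$ticks_per_epoch
  for (id in sim$ids) {
    # the state entering epoch 2 is the state leaving epoch 1 (no reset);
    # one tick of motion separates the recorded columns
    d <- sim$mu[[id]][, Tpe + 1] - sim$mu[[id]][, Tpe]
    expect_lt(max(abs(d)), 5)  # continuous motion, not a re-draw
  }
})
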