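test_that("configurations validate their keys", {
  cfg <- experiment_config("duet", n_epochs = 4)
  expect_equal(cfg$n_epochs, 4)
  expect_error(experiment_config("duet", nonsense_key = 1), "unknown")
  expect_error(run_niche_inheritance(
    experiment_config("niche_inheritance", n_trials = 2)), "n_trials")
  # YAML round trip
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(experiment = "duet", n_epochs = 4), p)
  cfg2 <- read_experiment_config(p)
  expect_equal(cfg2$n_epochs, 4)
  expect_equal(cfg2$experiment, "duet")
})

test_that("experiment artifacts are written and summaries regenerate identically", {
  dir <- tempfile("nsx")
  cfg <- experiment_config("duet", n_epochs = 2, with_uncoupled = FALSE)
  res <- run_duet(cfg, seed = 3, out = dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "metrics.json")))
  expect_true(file.exists(file.path(dir, "summary.md")))
  expect_true(file.exists(file.path(dir, "coupled_fe.tsv")))

  # regenerating the summary is byte-identical
  s1 <- readBin(file.path(dir, "summary.md"), "raw",
                file.size(file.path(dir, "summary.md")))
  render_report(dir)
  s2 <- readBin(file.path(dir, "summary.md"), "raw",
                file.size(file.path(dir, "summary.md")))
  expect_identical(s1, s2)

  # the summary includes the seed and a config hash, and its numbers equal
  # the metric file's
  txt <- readLines(file.path(dir, "summary.md"))
  expect_true(any(grepl("^- seed: 3$", txt)))
  expect_true(any(grepl("config hash: [0-9a-f]{8}", txt)))
  met <- jsonlite::read_json(file.path(dir, "metrics.json"),
                             simplifyVector = TRUE)
  r2line <- txt[grepl("^- coupled_r2_final:", txt)]
  expect_equal(as.numeric(sub(".*: ", "", r2line)),
               met$coupled_r2_final, tolerance = 1e-9)

  # missing files give an itemized error
  unlink(file.path(dir, "metrics.json"))
  expect_error(render_report(dir), "metrics.json")
})

test_that("epoch boundaries fall on exact multiples of the epoch length", {
  sim <- tiny_duet("coupled", n_epochs = 2, seed = 1)
  b <- sim$song$time_s[which(diff(sim$song$epoch) == 1)]
  expect_equal(b %% 2, rep(0, length(b)), tolerance = 1e-12)
  expect_equal(max(sim$song$time_s), 4)
})

test_that("tidiers and plots return well-formed objects", {
  sim <- tiny_duet("coupled", n_epochs = 2, seed = 1)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$agent), c("A", "B"))
  expect_equal(nrow(td), 2 * 2 * 3 * 1024)
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_sync_manifold(sim), "ggplot")
  son <- sonogram(sim$song$amplitude, sim$song$frequency, dt = sim$dt)
  expect_s3_class(autoplot(son), "ggplot")
  expect_s3_class(plot_theta_trajectories(sim$theta), "ggplot")
})
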