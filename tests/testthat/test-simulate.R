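test_that("simulation is fully determined by its seed", {
  a <- simulate_dataset(sim_config(n_sequences = 10, seed = 7))
  b <- simulate_dataset(sim_config(n_sequences = 10, seed = 7))
  expect_identical(a, b)
  c <- simulate_dataset(sim_config(n_sequences = 10, seed = 8))
  expect_false(identical(a, c))
})

test_that("generated MoRFs and traces respect the configured regime", {
  ds <- simulate_dataset(sim_config(n_sequences = 40, seed = 11))
  for (d in ds) {
    lab <- d$sequence$labels
    n <- length(lab)
    expect_true(n >= 60 && n <= 600)
    expect_equal(nrow(d$trace$values), n)          # trace alignment
    runs <- trimorf:::label_runs(lab)
    expect_equal(nrow(runs), 1L)                   # one MoRF per sequence
    len <- runs$end - runs$start + 1
    expect_true(len >= 5 && len <= 25)
    expect_setequal(d$trace$channels, MORF_CHANNELS)
    ss <- d$trace$values[, c("SS_H", "SS_E", "SS_C")]
    expect_true(all(abs(rowSums(ss) - 1) < 0.01))
  }
})

test_that("the signal channel carries the configured mean shift", {
  cfg <- sim_config(n_sequences = 120, seed = 13)
  ds <- simulate_dataset(cfg)
  # the noise is autocorrelated by design, so the honest standard error
  # treats each sequence as one cluster
  per_seq <- vapply(ds, function(d) {
    sig <- d$trace$values[, "HSEa_up"]
    lab <- d$sequence$labels
    mean(sig[lab]) - mean(sig[!lab])
  }, numeric(1))
  expected <- cfg$effect_size * cfg$background_sd
  se <- sd(per_seq) / sqrt(length(per_seq))
  expect_lt(abs(mean(per_seq) - expected), 3 * se)
  # neighbouring residues are autocorrelated by construction
  acs <- sapply(ds[1:20], function(d) {
    x <- d$trace$values[, "HSEa_up"]
    cor(x[-1], x[-length(x)])
  })
  expect_gt(mean(acs), 0.3)
})

test_that("a zero effect size severs the label/signal link", {
  cfg <- sim_config(n_sequences = 100, effect_size = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  sig <- unlist(lapply(ds, function(d) d$trace$values[, "HSEa_up"]))
  lab <- unlist(lapply(ds, function(d) d$sequence$labels))
  diff_means <- mean(sig[lab]) - mean(sig[!lab])
  se <- sqrt(var(sig[lab]) / sum(lab) + var(sig[!lab]) / sum(!lab))
  expect_lt(abs(diff_means), 4 * se)
})

test_that("terminal placement probability is honoured at the extremes", {
  ds1 <- simulate_dataset(sim_config(n_sequences = 25,
                                     terminal_placement_prob = 1, seed = 19))
  s1 <- dataset_summary(ds1)
  expect_equal(s1$n_morfs_touching_terminal, s1$n_morfs)

  ds0 <- simulate_dataset(sim_config(n_sequences = 25,
                                     terminal_placement_prob = 0,
                                     length_range = c(100, 300), seed = 23))
  expect_equal(dataset_summary(ds0)$n_morfs_touching_terminal, 0L)
})

test_that("dataset summaries conserve residue and MoRF counts", {
  ds <- simulate_dataset(sim_config(n_sequences = 15, seed = 29))
  s <- dataset_summary(ds)
  expect_equal(s$n_sequences, 15L)
  expect_equal(s$morf_residues + s$non_morf_residues, s$total_residues)
  expect_equal(sum(s$morf_residues_by_zone), s$morf_residues)
  expect_equal(sum(s$morf_length_histogram), s$n_morfs)
  hist_lens <- as.integer(names(s$morf_length_histogram))
  expect_equal(sum(hist_lens * as.integer(s$morf_length_histogram)),
               s$morf_residues)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(n_sequences = 5, length_range = c(10, 20),
                          morf_length_range = c(15, 25)),
               class = "trimorf_validation_error")
  expect_error(sim_config(background_sd = 0),
               class = "trimorf_validation_error")
  expect_error(sim_config(terminal_placement_prob = 1.2),
               class = "trimorf_validation_error")
})
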