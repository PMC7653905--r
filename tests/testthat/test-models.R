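test_that("zone dispatch routes terminal and middle residues correctly", {
  b <- stub_bundle(terminal_value = 1, middle_value = 0)
  tr <- make_trace(rnorm(100, 12, 3), seq_id = "q")
  track <- score_sequence(b, 100, tr)
  expect_equal(sum(track$scores == 1), 40L)
  expect_equal(which(track$scores == 1), c(1:20, 81:100))
  expect_equal(which(track$scores == 0), 21:80)
  expect_equal(track$stage, "raw")
})

test_that("short sequences are scored entirely by the terminal model", {
  b <- stub_bundle(terminal_value = 0.8, middle_value = 0.1)
  tr <- make_trace(rnorm(30, 12, 3), seq_id = "s")
  track <- score_sequence(b, 30, tr)
  expect_true(all(track$scores == 0.8))
})

test_that("training is reproducible and scores stay in [0, 1]", {
  ds <- small_dataset(n = 25, seed = 31, terminal_placement_prob = 0.5)
  b1 <- train_bundle(ds, seed = 5)
  b2 <- train_bundle(ds, seed = 5)
  expect_identical(b1$manifest, b2$manifest)
  probe <- small_dataset(n = 2, seed = 99)[[1]]
  s1 <- score_sequence(b1, probe$sequence, probe$trace)$scores
  s2 <- score_sequence(b2, probe$sequence, probe$trace)$scores
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("per-model positive and negative counts are balanced", {
  # long sequences so every negative placement is feasible
  ds <- small_dataset(n = 25, seed = 37, length_range = c(300, 500),
                      terminal_placement_prob = 0.5)
  expect_no_warning(b <- train_bundle(ds, seed = 7))
  counts <- b$manifest$counts
  expect_equal(counts$n_pos, counts$n_neg)
  expect_true(all(counts$n_pos >= 1))
})

test_that("a zone with no positive segments aborts training with its name", {
  ds <- small_dataset(n = 20, seed = 41, terminal_placement_prob = 0)
  expect_error(suppressWarnings(train_bundle(ds, seed = 1)),
               "terminal", class = "trimorf_training_error")
})

test_that("trace/sequence length mismatches are rejected", {
  ds <- small_dataset(n = 2, seed = 43, length_range = c(60, 80))
  b <- stub_bundle()
  expect_error(score_sequence(b, 999, ds[[1]]$trace),
               class = "trimorf_validation_error")
})

test_that("bundles survive a save/load round trip", {
  ds <- small_dataset(n = 15, seed = 47, terminal_placement_prob = 0.5)
  b <- suppressWarnings(train_bundle(ds, seed = 3))
  p <- withr::local_tempfile(fileext = ".rds")
  save_bundle(b, p)
  b2 <- load_bundle(p)
  probe <- small_dataset(n = 1, seed = 48)[[1]]
  expect_equal(score_sequence(b2, probe$sequence, probe$trace)$scores,
               score_sequence(b, probe$sequence, probe$trace)$scores)
})

test_that("the trained pipeline separates MoRF from background residues", {
  train <- small_dataset(n = 60, seed = 51, terminal_placement_prob = 0.4)
  held <- small_dataset(n = 30, seed = 52, terminal_placement_prob = 0.4)
  b <- suppressWarnings(train_bundle(train, seed = 1))
  tracks <- score_dataset(b, held)
  ev <- evaluate_tracks(tracks, annotations_of(held))
  expect_gt(ev$auc, 0.8)
})

test_that("signal-free channels train markedly worse than the HSE channel", {
  train <- small_dataset(n = 40, seed = 61, terminal_placement_prob = 0.4)
  held <- small_dataset(n = 25, seed = 62, terminal_placement_prob = 0.4)
  b_hse <- suppressWarnings(train_bundle(train, seed = 2))
  b_ss <- suppressWarnings(train_bundle(
    train, features = feature_config(channels = c("SS_H", "SS_E", "SS_C")),
    seed = 2))
  auc_hse <- evaluate_tracks(score_dataset(b_hse, held),
                             annotations_of(held))$auc
  auc_ss <- evaluate_tracks(score_dataset(b_ss, held),
                            annotations_of(held))$auc
  expect_gt(auc_hse, auc_ss)
})
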