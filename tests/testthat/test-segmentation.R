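test_that("zone boundaries follow the trisection inequalities", {
  expect_equal(zone_of(20, 100), "terminal")
  expect_equal(zone_of(21, 100), "middle")
  expect_equal(zone_of(80, 100), "middle")
  expect_equal(zone_of(81, 100), "terminal")
  # no middle zone exists for length <= 2*flank
  expect_equal(zone_of(25, 40), "terminal")
  expect_true(all(zone_of(1:40, 40) == "terminal"))
  expect_error(zone_of(0, 10), class = "trimorf_validation_error")
  expect_error(zone_of(11, 10), class = "trimorf_validation_error")
})

test_that("query windows match the literal three-branch rule", {
  for (L in c(1, 5, 40, 41, 100, 500)) {
    qs <- enumerate_query_samples(L, 20)
    expect_equal(nrow(qs), L)
    expect_equal(qs$position, seq_len(L))
    for (j in seq_len(L)) {
      expect_equal(c(qs$start[j], qs$end[j]), window_oracle(j, L, 20),
                   info = sprintf("L=%d j=%d", L, j))
    }
  }
  qs <- enumerate_query_samples(100, 20)
  expect_equal(c(qs$start[1], qs$end[1]), c(1, 21))
  expect_equal(c(qs$start[50], qs$end[50]), c(30, 70))
  expect_equal(c(qs$start[100], qs$end[100]), c(80, 100))
  q41 <- enumerate_query_samples(41, 20)
  full <- which(q41$end - q41$start + 1 == 41)
  expect_equal(full, 21L)
})

test_that("window lengths and terminal counts hold for arbitrary flanks", {
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(1:300, 1)
    f <- sample(1:30, 1)
    qs <- enumerate_query_samples(L, f)
    expect_equal(qs$end - qs$start + 1,
                 pmin(L, qs$position + f) - pmax(1, qs$position - f) + 1)
    expect_true(all(qs$end - qs$start + 1 <= 2 * f + 1))
    n_term <- sum(qs$zone == "terminal")
    expect_equal(n_term, if (L > 2 * f) 2 * f else L)
    term_pos <- qs$position[qs$zone == "terminal"]
    expect_equal(term_pos,
                 sort(unique(c(seq_len(min(f, L)),
                               seq.int(max(1, L - f + 1), L)))))
  }
})

test_that("positive segments are the clipped flanked extents of MoRF runs", {
  lab <- rep(FALSE, 100); lab[40:50] <- TRUE
  s <- annotated_sequence("a", strrep("A", 100), lab)
  # the 51-residue extent leaves no room for a negative here; that path
  # is asserted separately below
  segs <- suppressWarnings(extract_training_segments(s, rng_seed = 1))
  pos <- segs[segs$polarity == "positive", ]
  expect_equal(nrow(pos), 1L)
  expect_equal(c(pos$start, pos$end), c(20, 70))
  expect_equal(pos$zone, "middle")

  lab <- rep(FALSE, 100); lab[3:10] <- TRUE
  s <- annotated_sequence("b", strrep("A", 100), lab)
  segs <- extract_training_segments(s, rng_seed = 1)
  pos <- segs[segs$polarity == "positive", ]
  expect_equal(c(pos$start, pos$end), c(1, 30))
  expect_equal(pos$zone, "terminal")

  s <- annotated_sequence("c", strrep("A", 50))
  expect_equal(nrow(extract_training_segments(s)), 0L)
})

test_that("a run straddling both zones feeds both training pools", {
  lab <- rep(FALSE, 200); lab[15:25] <- TRUE
  s <- annotated_sequence("d", strrep("A", 200), lab)
  segs <- extract_training_segments(s, rng_seed = 2)
  pos <- segs[segs$polarity == "positive", ]
  expect_setequal(pos$zone, c("terminal", "middle"))
  expect_equal(nrow(pos), 2L)
  # both copies cover the same flanked extent
  expect_true(all(pos$start == 1 & pos$end == 45))
})

test_that("negative segments are balanced, zone-matched and leakage-free", {
  set.seed(9)
  for (rep in 1:15) {
    n <- sample(150:400, 1)
    m <- sample(5:25, 1)
    st <- sample(n - m + 1, 1)
    lab <- rep(FALSE, n); lab[st:(st + m - 1)] <- TRUE
    s <- annotated_sequence("p", strrep("A", n), lab)
    warned <- FALSE
    segs <- withCallingHandlers(
      extract_training_segments(s, rng_seed = rep),
      trimorf_placement_warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    pos <- segs[segs$polarity == "positive", ]
    neg <- segs[segs$polarity == "negative", ]
    if (!warned) expect_equal(nrow(neg), nrow(pos))
    for (i in seq_len(nrow(neg))) {
      expect_false(any(lab[neg$start[i]:neg$end[i]]))
      # disjoint from every flanked extent, not just the run
      ext <- c(max(1, st - 20), min(n, st + m - 1 + 20))
      expect_true(neg$end[i] < ext[1] || neg$start[i] > ext[2])
      # same length and zone as some positive
      match_pos <- pos[pos$zone == neg$zone[i], ]
      expect_true(any(match_pos$end - match_pos$start ==
                      neg$end[i] - neg$start[i]))
      # zone-matching: the negative window touches its declared zone
      zs <- zone_of(neg$start[i]:neg$end[i], n, 20)
      expect_true(neg$zone[i] %in% zs)
    }
  }
})

test_that("negative placement is reproducible under a seed", {
  lab <- rep(FALSE, 300); lab[100:110] <- TRUE
  s <- annotated_sequence("r", strrep("A", 300), lab)
  a <- extract_training_segments(s, rng_seed = 7)
  b <- extract_training_segments(s, rng_seed = 7)
  expect_identical(a, b)
  draws <- unique(sapply(1:20, function(k)
    extract_training_segments(s, rng_seed = k)$start[2]))
  expect_gt(length(draws), 1L)  # the placement really is random
})

test_that("an unplaceable negative keeps the positive and warns", {
  lab <- rep(FALSE, 60); lab[20:40] <- TRUE  # flanked extent covers all 60
  s <- annotated_sequence("w", strrep("A", 60), lab)
  msgs <- capture_warnings(segs <- extract_training_segments(s, rng_seed = 1))
  expect_gte(length(msgs), 1L)
  expect_true(all(grepl("no feasible negative placement", msgs)))
  expect_true(all(segs$polarity == "positive"))
})
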