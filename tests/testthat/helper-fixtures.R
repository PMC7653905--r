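# Shared fixtures: everything is generated in code at test time.

# A minimal trace carrying one channel (default HSEa_up) with given values.
make_trace <- function(values, seq_id = "t1", channel = "HSEa_up") {
  m <- matrix(as.numeric(values), ncol = 1)
  colnames(m) <- channel
  structural_trace(seq_id, m)
}

# A small simulated dataset; longer default sequences keep negative
# placements feasible.
small_dataset <- function(n = 30, seed = 1, length_range = c(200, 400), ...) {
  simulate_dataset(sim_config(n_sequences = n, seed = seed,
                              length_range = length_range, ...))
}

# Bundle whose two models return fixed normalized scores; exercises zone
# dispatch independently of any SVM.
stub_bundle <- function(terminal_value = 1, middle_value = 0, flank = 20L) {
  structure(list(terminal_model = trimorf:::constant_model(terminal_value),
                 middle_model = trimorf:::constant_model(middle_value),
                 feature_config = feature_config(),
                 svm_config = svm_config(),
                 flank = as.integer(flank), trisect = TRUE,
                 manifest = list(), version = 1L),
            class = "morf_bundle")
}

# Score all held-out sequences with a bundle and smooth each track.
score_dataset <- function(bundle, dataset, window_flank = 12) {
  lapply(dataset, function(d) {
    tr <- score_sequence(bundle, d$sequence, d$trace)
    if (window_flank > 0) tr <- process_track(tr, window_flank)
    tr
  })
}

annotations_of <- function(dataset) lapply(dataset, `[[`, "sequence")

# Independent brute-force oracles -------------------------------------

# Literal double-loop transcription of the lagged second-moment feature.
ac_oracle <- function(M, df) {
  M <- as.matrix(M)
  l <- nrow(M); u <- ncol(M)
  out <- matrix(0, df, u)
  for (k in seq_len(df)) {
    for (j in seq_len(u)) {
      s <- 0
      i <- 1
      while (i <= l - k) {
        s <- s + M[i, j] * M[i + k, j]
        i <- i + 1
      }
      out[k, j] <- s / l
    }
  }
  as.vector(out)
}

# Literal three-branch query-window rule (clipped to the sequence).
window_oracle <- function(j, L, flank) {
  b <- if (j <= flank) c(1, j + flank)
       else if (j > L - flank) c(j - flank, L)
       else c(j - flank, j + flank)
  c(max(1, b[1]), min(L, b[2]))
}

# Brute-force sliding-window (max + median)/2 smoother.
smooth_oracle <- function(s, w) {
  L <- length(s)
  sapply(seq_len(L), function(j) {
    win <- s[max(1, j - w):min(L, j + w)]
    (max(win) + median(win)) / 2
  })
}

# Rank-based Mann-Whitney AUC with half credit for ties.
mw_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}
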