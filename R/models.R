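# The two zone models (terminal / middle) and their training.

#' SVM configuration
#'
#' RBF-kernel support vector classifier settings. The defaults
#' `C = 1000`, `gamma = 0.0038` are the values the method was developed
#' with; they assume z-scored auto-covariance features.
#'
#' @param C Soft-margin cost (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return A list of class `svm_config` (kernel is fixed to RBF).
#' @export
svm_config <- function(C = 1000, gamma = 0.0038) {
  if (C <= 0 || gamma <= 0)
    morf_stop("trimorf_validation_error", "C and gamma must be positive")
  structure(list(kernel = "RBF", C = C, gamma = gamma),
            class = "svm_config")
}

# Fit one zone model: z-score scaler + RBF SVM + decision-value
# normalization bounds. Decision values are oriented so that larger means
# more MoRF-like, then min-max normalized over the training set.
fit_zone_model <- function(X, polarity, svm_cfg) {
  pos <- polarity == "positive"
  if (!any(pos) || !all(c(TRUE, FALSE) %in% pos))
    morf_stop("trimorf_training_error",
              "need at least one positive and one negative sample")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  y <- factor(ifelse(pos, "positive", "negative"),
              levels = c("negative", "positive"))
  fit <- e1071::svm(Xs, y, type = "C-classification", kernel = "radial",
                    cost = svm_cfg$C, gamma = svm_cfg$gamma, scale = FALSE)
  dv <- attr(predict(fit, Xs, decision.values = TRUE),
             "decision.values")[, 1L]
  flip <- mean(dv[pos]) < mean(dv[!pos])
  if (flip) dv <- -dv
  low <- min(dv); high <- max(dv)
  if (!(low < high))
    morf_stop("trimorf_training_error",
              "degenerate decision values: all training samples score %.6f",
              low)
  structure(list(fit = fit, center = center, scale = scale, flip = flip,
                 low = low, high = high,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = c("morf_svm_model", "morf_model"))
}

# Stub model returning a fixed normalized score; used for dispatch checks
# and pipeline diagnostics.
constant_model <- function(value) {
  structure(list(value = value, low = 0, high = 1, n_pos = 1L, n_neg = 1L),
            class = c("morf_constant_model", "morf_model"))
}

# Oriented raw decision values for a feature matrix.
raw_decision <- function(model, X) UseMethod("raw_decision")

#' @export
raw_decision.morf_svm_model <- function(model, X) {
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  dv <- attr(predict(model$fit, Xs, decision.values = TRUE),
             "decision.values")[, 1L]
  if (model$flip) -dv else dv
}

#' @export
raw_decision.morf_constant_model <- function(model, X) {
  rep(model$value, nrow(X))
}

normalized_score <- function(model, X) {
  dv <- raw_decision(model, X)
  pmin(1, pmax(0, (dv - model$low) / (model$high - model$low)))
}

#' Train the two-model bundle
#'
#' Extracts balanced positive/negative training segments from every
#' annotated sequence, routes them by zone, featurizes them, and fits one
#' RBF SVM per zone (terminal and middle). Each model stores its z-score
#' feature scaler and the min/max of its training decision values, used to
#' map scores onto `[0, 1]`. With `trisect = FALSE` a single model is
#' trained on all segments and used for every residue (the baseline the
#' trisection is compared against).
#'
#' @param dataset List of `list(sequence = annotated_sequence,
#'   trace = structural_trace)` pairs (the shape returned by
#'   [simulate_dataset()]).
#' @param svm An [svm_config()].
#' @param features A [feature_config()].
#' @param flank Zone/segment flank size (default 20).
#' @param seed Integer seed controlling negative-segment placement.
#' @param trisect Train separate terminal/middle models (default) or one
#'   pooled model.
#' @return A list of class `morf_bundle` with fields `terminal_model`,
#'   `middle_model`, `feature_config`, `svm_config`, `flank`, `trisect`
#'   and a `manifest` recording the seed, per-model sample counts and a
#'   dataset fingerprint.
#' @export
train_bundle <- function(dataset, svm = svm_config(),
                         features = feature_config(), flank = 20L,
                         seed = 1L, trisect = TRUE) {
  if (!length(dataset))
    morf_stop("trimorf_training_error", "empty training dataset")
  for (d in dataset) {
    if (!inherits(d$sequence, "annotated_sequence") ||
        !inherits(d$trace, "structural_trace"))
      morf_stop("trimorf_validation_error",
                "dataset entries must be list(sequence=, trace=)")
    if (nrow(d$trace$values) != length(d$sequence$labels))
      morf_stop("trimorf_validation_error",
                "trace/sequence length mismatch for '%s'", d$sequence$id)
  }
  segs <- with_seed(seed, {
    do.call(rbind, lapply(dataset, function(d)
      extract_training_segments(d$sequence, flank = flank)))
  })
  if (is.null(segs) || !nrow(segs))
    morf_stop("trimorf_training_error",
              "no MoRF-bearing sequences in the training set")
  traces <- setNames(lapply(dataset, `[[`, "trace"),
                     vapply(dataset, function(d) d$sequence$id, character(1)))
  feats <- vapply(seq_len(nrow(segs)), function(i)
    featurize(traces[[segs$seq_id[i]]], segs[i, ], features)$values,
    numeric(features$df * length(features$channels)))
  X <- if (is.matrix(feats)) t(feats) else matrix(feats, ncol = 1L)

  fit_pool <- function(idx, what) {
    if (!any(segs$polarity[idx] == "positive"))
      morf_stop("trimorf_training_error",
                "no positive training segments for the %s model", what)
    if (!any(segs$polarity[idx] == "negative"))
      morf_stop("trimorf_training_error",
                "no negative training segments for the %s model", what)
    fit_zone_model(X[idx, , drop = FALSE], segs$polarity[idx], svm)
  }

  if (trisect) {
    t_idx <- which(segs$zone == "terminal")
    m_idx <- which(segs$zone == "middle")
    terminal_model <- fit_pool(t_idx, "terminal")
    middle_model <- fit_pool(m_idx, "middle")
    counts <- data.frame(
      model = c("terminal", "middle"),
      n_pos = c(terminal_model$n_pos, middle_model$n_pos),
      n_neg = c(terminal_model$n_neg, middle_model$n_neg))
  } else {
    terminal_model <- middle_model <- fit_pool(seq_len(nrow(segs)), "pooled")
    counts <- data.frame(model = "pooled",
                         n_pos = terminal_model$n_pos,
                         n_neg = terminal_model$n_neg)
  }
  total_res <- sum(vapply(dataset, function(d) length(d$sequence$labels),
                          integer(1)))
  morf_res <- sum(vapply(dataset, function(d) sum(d$sequence$labels),
                         integer(1)))
  manifest <- list(seed = seed, flank = as.integer(flank),
                   trisect = trisect, counts = counts,
                   feature_config = unclass(features),
                   svm_config = unclass(svm),
                   fingerprint = list(n_sequences = length(dataset),
                                      total_residues = total_res,
                                      morf_residues = morf_res))
  structure(list(terminal_model = terminal_model,
                 middle_model = middle_model,
                 feature_config = features, svm_config = svm,
                 flank = as.integer(flank), trisect = trisect,
                 manifest = manifest, version = 1L),
            class = "morf_bundle")
}

#' @export
print.morf_bundle <- function(x, ...) {
  cat(sprintf("<morf_bundle v%d> flank %d, %s\n", x$version, x$flank,
              if (x$trisect) "terminal + middle models" else "single model"))
  print(x$manifest$counts)
  invisible(x)
}

#' Score every residue of a query sequence
#'
#' Enumerates the per-residue query windows, featurizes them against the
#' trace, scores terminal-zone positions with the terminal model and
#' middle-zone positions with the middle model, and maps each model's
#' decision values through its stored normalization onto `[0, 1]`
#' (clipping outside the training bounds). Sequences of length
#' `<= 2*flank` have no middle zone and are scored entirely by the
#' terminal model.
#'
#' @param bundle A [train_bundle()] result.
#' @param seq An [annotated_sequence()], a plain amino-acid string, or a
#'   sequence length (labels are not consulted).
#' @param trace The matching [structural_trace()].
#' @return A [score_track()] with `stage = "raw"`.
#' @export
score_sequence <- function(bundle, seq, trace) {
  stopifnot(inherits(bundle, "morf_bundle"),
            inherits(trace, "structural_trace"))
  n <- if (inherits(seq, "annotated_sequence")) length(seq$labels)
       else if (is.character(seq)) nchar(seq)
       else as.integer(seq)
  if (nrow(trace$values) != n)
    morf_stop("trimorf_validation_error",
              "trace '%s' has %d rows but sequence has %d residues",
              trace$seq_id, nrow(trace$values), n)
  samples <- enumerate_query_samples(n, bundle$flank)
  X <- ac_window_features(trace, samples$start, samples$end,
                          bundle$feature_config)
  scores <- numeric(n)
  if (bundle$trisect) {
    t_idx <- samples$zone == "terminal"
    if (any(t_idx))
      scores[t_idx] <- normalized_score(bundle$terminal_model,
                                        X[t_idx, , drop = FALSE])
    if (any(!t_idx))
      scores[!t_idx] <- normalized_score(bundle$middle_model,
                                         X[!t_idx, , drop = FALSE])
  } else {
    scores <- normalized_score(bundle$terminal_model, X)
  }
  score_track(trace$seq_id, scores, "raw")
}

#' Save / load a model bundle
#'
#' The bundle (models, scalers, normalization bounds, manifest) is stored
#' as a single versioned RDS archive.
#'
#' @param bundle A `morf_bundle`.
#' @param path File path.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "morf_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path))
    morf_stop("trimorf_parse_error", "bundle file not found: %s", path)
  bundle <- readRDS(path)
  if (!inherits(bundle, "morf_bundle"))
    morf_stop("trimorf_parse_error", "'%s' is not a model bundle", path)
  bundle
}
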