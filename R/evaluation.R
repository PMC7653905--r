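# Per-residue ROC/AUC evaluation.

#' ROC curve and AUC for pooled per-residue scores
#'
#' Builds the ROC curve from every distinct score threshold and computes
#' the AUC as the trapezoidal area, which with grouped ties equals the
#' Mann-Whitney statistic with half credit for ties (the standard
#' estimator). Residues are pooled across sequences before calling this,
#' giving one global curve — the convention under which MoRF predictors
#' are benchmarked.
#'
#' @param scores Numeric vector of per-residue scores.
#' @param labels Logical (or 0/1) vector; `TRUE` = MoRF residue.
#' @return A list of class `roc_result` with fields `auc`, `thresholds`,
#'   `tpr`, `fpr` (aligned, starting at the (0, 0) corner), `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    morf_stop("trimorf_eval_error",
              "scores and labels must be equal-length and non-missing")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1L || n_neg < 1L)
    morf_stop("trimorf_eval_error",
              "need at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # last index of each tie group = the curve points
  idx <- c(which(diff(s) < 0), length(s))
  tpr <- cumsum(l)[idx] / n_pos
  fpr <- cumsum(!l)[idx] / n_neg
  thresholds <- c(Inf, s[idx])
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(auc = auc, thresholds = thresholds, tpr = tpr, fpr = fpr,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positives, %d negatives, %d curve points)\n",
              x$auc, x$n_pos, x$n_neg, length(x$tpr)))
  invisible(x)
}

#' FPR at a given TPR
#'
#' Smallest FPR among ROC curve points whose TPR reaches `target_tpr`
#' (conservative, interpolation-free convention).
#'
#' @param result A [roc_auc()] result.
#' @param target_tpr Target true-positive rate in `(0, 1]`.
#' @return The FPR as a single number.
#' @export
fpr_at_tpr <- function(result, target_tpr) {
  stopifnot(inherits(result, "roc_result"))
  if (!is.numeric(target_tpr) || target_tpr <= 0 || target_tpr > 1)
    morf_stop("trimorf_eval_error", "target_tpr must be in (0, 1]")
  ok <- result$tpr >= target_tpr - 1e-12
  if (!any(ok))
    morf_stop("trimorf_eval_error",
              "TPR %.3f unreachable (max %.3f)", target_tpr,
              max(result$tpr))
  min(result$fpr[ok])
}

#' Evaluate score tracks against MoRF annotations
#'
#' Pools per-residue scores and labels across all sequences (matching
#' tracks to sequences by `seq_id`) into one global ROC curve, with an
#' FPR-at-TPR summary over a TPR grid. Optionally the pool is restricted
#' to terminal- or middle-zone residues, or broken out per sequence.
#'
#' @param tracks List of [score_track()]s.
#' @param annotated List of [annotated_sequence()]s covering every track's
#'   `seq_id`.
#' @param tpr_grid TPR values for the FPR summary (default 0.2..0.9).
#' @param zone `"all"` (default), `"terminal"` or `"middle"`: which
#'   residues enter the pool.
#' @param flank Zone flank used when `zone != "all"` (default 20).
#' @param per_sequence Also return a per-sequence AUC table (sequences
#'   with a single class are reported as `NA`).
#' @return A list with `auc`, `n_pos`, `n_neg`, `fpr_at_tpr` (named
#'   vector; `NA` where unreachable), `roc`, and optionally
#'   `per_sequence`.
#' @export
evaluate_tracks <- function(tracks, annotated,
                            tpr_grid = seq(0.2, 0.9, by = 0.1),
                            zone = c("all", "terminal", "middle"),
                            flank = 20L, per_sequence = FALSE) {
  zone <- match.arg(zone)
  ann <- setNames(annotated,
                  vapply(annotated, `[[`, character(1), "id"))
  pool_s <- list(); pool_l <- list()
  per <- list()
  for (t in tracks) {
    a <- ann[[t$seq_id]]
    if (is.null(a))
      morf_stop("trimorf_eval_error",
                "no annotation for sequence '%s'", t$seq_id)
    n <- length(a$labels)
    if (length(t$scores) != n)
      morf_stop("trimorf_eval_error",
                "track/annotation length mismatch for '%s'", t$seq_id)
    keep <- if (zone == "all") rep(TRUE, n)
            else zone_of(seq_len(n), n, flank) == zone
    pool_s[[t$seq_id]] <- t$scores[keep]
    pool_l[[t$seq_id]] <- a$labels[keep]
    if (per_sequence) {
      lab <- a$labels[keep]
      per[[t$seq_id]] <- if (length(unique(lab)) == 2L)
        roc_auc(t$scores[keep], lab)$auc else NA_real_
    }
  }
  scores <- unlist(pool_s, use.names = FALSE)
  labels <- unlist(pool_l, use.names = FALSE)
  roc <- roc_auc(scores, labels)
  fat <- vapply(tpr_grid, function(tt)
    tryCatch(fpr_at_tpr(roc, tt), trimorf_eval_error = function(e) NA_real_),
    numeric(1))
  out <- list(auc = roc$auc, n_pos = roc$n_pos, n_neg = roc$n_neg,
              fpr_at_tpr = setNames(fat, sprintf("tpr_%.1f", tpr_grid)),
              roc = roc)
  if (per_sequence)
    out$per_sequence <- data.frame(seq_id = names(per),
                                   auc = unlist(per), row.names = NULL)
  out
}
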