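# Score post-processing and track fusion.

#' Smooth a score track with the windowed (max + median)/2 rule
#'
#' For each residue `j` the window is
#' `scores[max(1, j - w) .. min(L, j + w)]` (truncated at the termini) and
#' the output is `(max(window) + median(window)) / 2`. The median of an
#' even-length window is the mean of the two central order statistics.
#' This rewards residues whose neighbourhood scores high, reflecting that
#' a true MoRF residue sits inside a region of at least 5 residues.
#' `window_flank = 0` is the identity.
#'
#' @param track A [score_track()].
#' @param window_flank Half-width `w` of the smoothing window. The
#'   defaults used in the pipeline are 12 for the structural model's own
#'   track, 4 and 15 for MoRFpred-plus- and MoRFchibi-style external
#'   tracks, and 8 for the combined track.
#' @return A [score_track()] with `stage = "processed"`.
#' @export
process_track <- function(track, window_flank = 12L) {
  stopifnot(inherits(track, "score_track"))
  w <- as.integer(window_flank)
  if (w < 0L)
    morf_stop("trimorf_validation_error", "window_flank must be >= 0")
  s <- track$scores
  L <- length(s)
  out <- numeric(L)
  for (j in seq_len(L)) {
    win <- s[max(1L, j - w):min(L, j + w)]
    out[j] <- (max(win) + stats::median(win)) / 2
  }
  score_track(track$seq_id, out, "processed")
}

#' Fuse score tracks by averaging
#'
#' Element-wise arithmetic mean of two or more tracks for the same
#' sequence; the common averaging rule used to combine predictors.
#'
#' @param tracks Non-empty list of [score_track()]s with identical
#'   `seq_id` and length.
#' @return A [score_track()] with `stage = "combined"`.
#' @export
combine_tracks <- function(tracks) {
  if (!length(tracks))
    morf_stop("trimorf_validation_error", "no tracks to combine")
  for (t in tracks) stopifnot(inherits(t, "score_track"))
  ids <- unique(vapply(tracks, `[[`, character(1), "seq_id"))
  if (length(ids) != 1L)
    morf_stop("trimorf_mismatch_error",
              "tracks belong to different sequences: %s",
              paste(ids, collapse = ", "))
  lens <- unique(vapply(tracks, function(t) length(t$scores), integer(1)))
  if (length(lens) != 1L)
    morf_stop("trimorf_mismatch_error",
              "tracks have different lengths: %s",
              paste(lens, collapse = ", "))
  mean_scores <- Reduce(`+`, lapply(tracks, `[[`, "scores")) / length(tracks)
  score_track(ids, mean_scores, "combined")
}

#' Run the combined scoring pipeline for one sequence
#'
#' Scores the sequence with the bundle, smooths the raw track with
#' `own_flank`, smooths each external predictor track with its own flank
#' (tracks whose `window_flank` is `NULL` are averaged unprocessed),
#' averages all tracks, and optionally re-smooths the averaged track with
#' `combined_flank`.
#'
#' @param bundle A [train_bundle()] result.
#' @param seq Sequence (see [score_sequence()]).
#' @param trace The matching [structural_trace()].
#' @param external_tracks List of `list(track = score_track,
#'   window_flank = integer or NULL)` entries for external predictors.
#' @param own_flank Smoothing flank for the bundle's own track (default 12).
#' @param combined_flank Smoothing flank for the averaged track (default 8).
#' @param reprocess_combined Re-smooth the averaged track (default `TRUE`).
#' @return A [score_track()] with `stage = "combined"`.
#' @export
run_combined_pipeline <- function(bundle, seq, trace,
                                  external_tracks = list(),
                                  own_flank = 12L, combined_flank = 8L,
                                  reprocess_combined = TRUE) {
  own <- process_track(score_sequence(bundle, seq, trace), own_flank)
  ext <- lapply(external_tracks, function(e) {
    stopifnot(inherits(e$track, "score_track"))
    if (is.null(e$window_flank)) e$track
    else process_track(e$track, e$window_flank)
  })
  fused <- combine_tracks(c(list(own), ext))
  if (reprocess_combined) {
    smoothed <- process_track(fused, combined_flank)
    fused <- score_track(smoothed$seq_id, smoothed$scores, "combined")
  }
  fused
}
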