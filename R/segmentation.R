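# Trisection of sequences into terminal/middle zones, training-segment
# extraction and per-residue query-sample enumeration.

#' Zone of a residue position
#'
#' A position `j` of a length-`n` sequence is *terminal* iff
#' `j <= flank` or `j > n - flank`, and *middle* otherwise. For sequences
#' of length `<= 2*flank` every position is terminal (the middle zone is
#' empty).
#'
#' @param position 1-based residue index (vectorised).
#' @param length Sequence length.
#' @param flank Zone flank size in residues (default 20).
#' @return Character vector of `"terminal"` / `"middle"`.
#' @export
zone_of <- function(position, length, flank = 20L) {
  stopifnot(length >= 1L, flank >= 1L)
  if (any(position < 1L | position > length))
    morf_stop("trimorf_validation_error",
              "position out of range 1..%d", length)
  ifelse(position <= flank | position > length - flank, "terminal", "middle")
}

#' Enumerate per-residue query samples
#'
#' One sample per residue `j`, spanning the window
#' `[max(1, j - flank), min(L, j + flank)]` (truncated at the termini, full
#' width `2*flank + 1` elsewhere), plus the zone that decides which model
#' scores it.
#'
#' @param length Sequence length `L`.
#' @param flank Window flank size (default 20, i.e. window 41).
#' @return Data frame with columns `position`, `start`, `end`, `zone`.
#' @export
enumerate_query_samples <- function(length, flank = 20L) {
  stopifnot(length >= 1L, flank >= 1L)
  j <- seq_len(length)
  data.frame(position = j,
             start = pmax(1L, j - as.integer(flank)),
             end = pmin(as.integer(length), j + as.integer(flank)),
             zone = zone_of(j, length, flank),
             stringsAsFactors = FALSE)
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end)
label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

#' Extract balanced training segments from one annotated sequence
#'
#' For each maximal MoRF run the flanked extent
#' `[run_start - flank, run_end + flank]` (clipped to the sequence) becomes
#' a positive segment. Its zone is terminal if any run residue is terminal
#' and middle if any run residue is middle; a run straddling both zones
#' contributes one segment to each zone's pool. For every positive segment
#' a negative segment of identical length is drawn uniformly at random
#' among placements that (i) stay inside the sequence, (ii) share no
#' residue with any MoRF run's flanked extent, and (iii) touch the same
#' zone. When no such placement exists the positive segment is kept alone
#' and a warning is raised.
#'
#' @param seq An [annotated_sequence()].
#' @param flank Flank size (default 20).
#' @param rng_seed Integer seed for negative placement; `NULL` uses the
#'   current RNG stream.
#' @return Data frame with columns `seq_id`, `start`, `end`, `polarity`
#'   (`"positive"`/`"negative"`), `zone`. Sequences with no MoRF residues
#'   yield zero rows.
#' @export
extract_training_segments <- function(seq, flank = 20L, rng_seed = NULL) {
  stopifnot(inherits(seq, "annotated_sequence"))
  n <- length(seq$labels)
  runs <- label_runs(seq$labels)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), polarity = character(),
                      zone = character(), stringsAsFactors = FALSE)
  if (nrow(runs) == 0L) return(empty)
  with_seed(rng_seed, {
    # residues blocked for negative placement: union of flanked extents
    ext_start <- pmax(1L, runs$start - flank)
    ext_end <- pmin(n, runs$end + flank)
    blocked <- rep(FALSE, n)
    for (r in seq_len(nrow(runs))) blocked[ext_start[r]:ext_end[r]] <- TRUE
    cblock <- c(0L, cumsum(blocked))

    out <- list()
    for (r in seq_len(nrow(runs))) {
      zones <- unique(zone_of(runs$start[r]:runs$end[r], n, flank))
      for (z in zones) {
        ps <- ext_start[r]; pe <- ext_end[r]
        len <- pe - ps + 1L
        out[[length(out) + 1L]] <-
          data.frame(seq_id = seq$id, start = ps, end = pe,
                     polarity = "positive", zone = z,
                     stringsAsFactors = FALSE)
        if (len > n) next
        starts <- seq_len(n - len + 1L)
        free <- (cblock[starts + len] - cblock[starts]) == 0L
        zone_ok <- if (z == "terminal")
          starts <= flank | (starts + len - 1L) > n - flank
        else
          (starts + len - 1L) > flank & starts <= n - flank
        feasible <- starts[free & zone_ok]
        if (length(feasible)) {
          s <- if (length(feasible) == 1L) feasible
               else feasible[sample.int(length(feasible), 1L)]
          out[[length(out) + 1L]] <-
            data.frame(seq_id = seq$id, start = s, end = s + len - 1L,
                       polarity = "negative", zone = z,
                       stringsAsFactors = FALSE)
        } else {
          morf_warn("trimorf_placement_warning",
                    "sequence '%s': no feasible negative placement for %s segment [%d,%d]",
                    seq$id, z, ps, pe)
        }
      }
    }
    do.call(rbind, out)
  })
}
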