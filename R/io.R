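# I/O for sequences, MoRF annotations, structural-attribute tables and
# score tracks.  All file formats use 1-based inclusive residue coordinates.

#' Construct an annotated sequence
#'
#' Bundles a protein sequence with its per-residue MoRF labels.
#'
#' @param id Sequence identifier (non-empty string).
#' @param residues Amino-acid string over the 20-letter alphabet plus `X`.
#' @param labels Logical vector, one element per residue; `TRUE` marks a
#'   MoRF residue. Defaults to all `FALSE`.
#' @return An object of class `annotated_sequence` with fields `id`,
#'   `residues` and `labels`.
#' @export
annotated_sequence <- function(id, residues, labels = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  n <- nchar(residues)
  if (n < 1L)
    morf_stop("trimorf_validation_error", "sequence '%s' is empty", id)
  bad <- regexpr(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")),
                 toupper(residues))
  if (bad > 0L)
    morf_stop("trimorf_validation_error",
              "sequence '%s': invalid residue '%s' at position %d",
              id, substr(residues, bad, bad), bad)
  if (is.null(labels)) labels <- rep(FALSE, n)
  labels <- as.logical(labels)
  if (length(labels) != n || anyNA(labels))
    morf_stop("trimorf_validation_error",
              "sequence '%s': labels must be %d non-missing logicals", id, n)
  structure(list(id = id, residues = toupper(residues), labels = labels),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("<annotated_sequence> %s: %d residues, %d MoRF\n",
              x$id, nchar(x$residues), sum(x$labels)))
  invisible(x)
}

#' Construct a structural trace
#'
#' A per-residue matrix of named structural-attribute channels aligned to
#' one sequence. When all three secondary-structure probability channels
#' are present each row must lie in `[0,1]` per channel and sum to 1
#' (tolerance 0.01).
#'
#' @param seq_id Sequence identifier.
#' @param values Numeric matrix, rows = residues, columns = channels.
#' @param channels Channel names (subset of [MORF_CHANNELS]); defaults to
#'   `colnames(values)`.
#' @return An object of class `structural_trace`.
#' @export
structural_trace <- function(seq_id, values, channels = colnames(values)) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channels) || length(channels) != ncol(values))
    morf_stop("trimorf_validation_error",
              "trace '%s': channel names missing or wrong length", seq_id)
  unknown <- setdiff(channels, MORF_CHANNELS)
  if (length(unknown))
    morf_stop("trimorf_validation_error",
              "trace '%s': unknown channel(s) %s", seq_id,
              paste(unknown, collapse = ", "))
  if (anyDuplicated(channels))
    morf_stop("trimorf_validation_error",
              "trace '%s': duplicated channel names", seq_id)
  if (nrow(values) < 1L || anyNA(values) || any(!is.finite(values)))
    morf_stop("trimorf_validation_error",
              "trace '%s': values must be a non-empty finite matrix", seq_id)
  colnames(values) <- channels
  ss <- c("SS_H", "SS_E", "SS_C")
  if (all(ss %in% channels)) {
    p <- values[, ss, drop = FALSE]
    if (any(p < 0 | p > 1))
      morf_stop("trimorf_validation_error",
                "trace '%s': SS probabilities outside [0,1]", seq_id)
    rs <- rowSums(p)
    if (any(rs < 0.99 | rs > 1.01))
      morf_stop("trimorf_validation_error",
                "trace '%s': SS probabilities do not sum to 1 (row %d)",
                seq_id, which(rs < 0.99 | rs > 1.01)[1L])
  }
  structure(list(seq_id = seq_id, channels = channels, values = values),
            class = "structural_trace")
}

#' @export
print.structural_trace <- function(x, ...) {
  cat(sprintf("<structural_trace> %s: %d residues x %d channels (%s)\n",
              x$seq_id, nrow(x$values), length(x$channels),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Construct a per-residue score track
#'
#' @param seq_id Sequence identifier.
#' @param scores Numeric vector of per-residue propensity scores.
#' @param stage One of `"raw"`, `"processed"`, `"combined"`.
#' @return An object of class `score_track`.
#' @export
score_track <- function(seq_id, scores, stage = c("raw", "processed", "combined")) {
  stage <- match.arg(stage)
  stopifnot(is.character(seq_id), length(seq_id) == 1L)
  scores <- as.numeric(scores)
  if (length(scores) < 1L)
    morf_stop("trimorf_validation_error",
              "track '%s': zero-length score tracks are invalid", seq_id)
  if (anyNA(scores) || any(!is.finite(scores)))
    morf_stop("trimorf_validation_error",
              "track '%s': scores must be finite", seq_id)
  structure(list(seq_id = seq_id, scores = scores, stage = stage),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %s [%s]: %d residues, range [%.3f, %.3f]\n",
              x$seq_id, x$stage, length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order with wrapped lines concatenated,
#' whitespace stripped and letters upper-cased. Identifiers are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    morf_stop("trimorf_parse_error", "FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    morf_stop("trimorf_parse_error",
                              "cannot parse FASTA '%s': %s",
                              path, conditionMessage(e)))
  if (length(set) == 0L)
    morf_stop("trimorf_parse_error", "FASTA file '%s' contains no records",
              path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    morf_stop("trimorf_parse_error",
              "FASTA file '%s': duplicate id '%s'", path,
              ids[duplicated(ids)][1L])
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")),
                   seqs[i])
    if (bad > 0L)
      morf_stop("trimorf_parse_error",
                "FASTA record '%s': invalid residue '%s' at position %d",
                ids[i], substr(seqs[i], bad, bad), bad)
    if (!nzchar(seqs[i]))
      morf_stop("trimorf_parse_error", "FASTA record '%s' is empty", ids[i])
  }
  data.frame(id = ids, residues = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Data frame with columns `id`, `residues` (as returned
#'   by [read_fasta()]) or a list of `annotated_sequence` objects.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.list(sequences) && !is.data.frame(sequences)) {
    sequences <- data.frame(
      id = vapply(sequences, function(s) s$id, character(1)),
      residues = vapply(sequences, function(s) s$residues, character(1)),
      stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(setNames(sequences$residues, sequences$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read per-residue MoRF annotations
#'
#' The annotation table is a headered TSV with columns `seq_id`, `start`,
#' `end` giving 1-based inclusive MoRF intervals. Sequences without any
#' row receive all-`FALSE` labels. Intervals may not overlap.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Data frame with `id`, `residues` columns ([read_fasta()]).
#' @return A list of [annotated_sequence()] objects in `sequences` order.
#' @export
read_morf_annotations <- function(path, sequences) {
  if (!file.exists(path))
    morf_stop("trimorf_parse_error", "annotation file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(tab)))
    morf_stop("trimorf_parse_error",
              "annotation file '%s' must have columns seq_id, start, end",
              path)
  if (nrow(tab) && (!is.numeric(tab$start) || !is.numeric(tab$end)))
    morf_stop("trimorf_parse_error",
              "annotation file '%s': start/end must be numeric", path)
  lens <- setNames(nchar(sequences$residues), sequences$id)
  unknown <- setdiff(tab$seq_id, sequences$id)
  if (length(unknown))
    morf_stop("trimorf_validation_error",
              "annotation references unknown seq_id '%s'", unknown[1L])
  out <- vector("list", nrow(sequences))
  for (i in seq_len(nrow(sequences))) {
    id <- sequences$id[i]
    n <- lens[[id]]
    labels <- rep(FALSE, n)
    rows <- tab[tab$seq_id == id, , drop = FALSE]
    if (nrow(rows)) {
      if (any(rows$start < 1 | rows$end > n | rows$start > rows$end))
        morf_stop("trimorf_validation_error",
                  "annotation for '%s': interval out of bounds (length %d)",
                  id, n)
      rows <- rows[order(rows$start), , drop = FALSE]
      if (nrow(rows) > 1L && any(rows$start[-1L] <= rows$end[-nrow(rows)]))
        morf_stop("trimorf_validation_error",
                  "annotation for '%s': overlapping intervals", id)
      for (r in seq_len(nrow(rows)))
        labels[rows$start[r]:rows$end[r]] <- TRUE
    }
    out[[i]] <- annotated_sequence(id, sequences$residues[i], labels)
  }
  out
}

#' Write MoRF annotations as an interval TSV
#'
#' @param annotated List of `annotated_sequence` objects.
#' @param path Output path.
#' @export
write_morf_annotations <- function(annotated, path) {
  rows <- list()
  for (s in annotated) {
    r <- rle(s$labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      rows[[length(rows) + 1L]] <-
        data.frame(seq_id = s$id, start = starts[k], end = ends[k])
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(seq_id = character(), start = integer(),
                         end = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# SPIDER2-style column aliases -> canonical channel names.  Best effort:
# the exact set of columns depends on which SPIDER2 output files were
# concatenated; categorical columns (SS letter) are skipped.
SPIDER2_ALIASES <- c(
  "P(C)" = "SS_C", "P(H)" = "SS_H", "P(E)" = "SS_E",
  "PC" = "SS_C", "PH" = "SS_H", "PE" = "SS_E",
  "ASA" = "ASA",
  "PHI" = "PHI", "PSI" = "PSI",
  "THETA" = "THETA", "THETA(I-1=>I+1)" = "THETA",
  "TAU" = "TAU", "TAU(I-2=>I+2)" = "TAU",
  "HSEA_UP" = "HSEa_up", "HSEA_DOWN" = "HSEa_dn", "HSEA_DN" = "HSEa_dn",
  "HSEAU" = "HSEa_up", "HSEAD" = "HSEa_dn",
  "HSEB_UP" = "HSEb_up", "HSEB_DOWN" = "HSEb_dn", "HSEB_DN" = "HSEb_dn",
  "HSEBU" = "HSEb_up", "HSEBD" = "HSEb_dn",
  "CN" = "CN", "CN13" = "CN")

#' Read a per-residue structural-attribute table
#'
#' Two dialects are supported. `native` is a headered TSV with columns
#' `seq_id`, `pos`, `residue` and one column per structural channel (names
#' from [MORF_CHANNELS]), as written by [write_structural_table()].
#' `spider2` is a best-effort reader for SPIDER2-style whitespace-delimited
#' output with a `#`-prefixed header line; recognised column names are
#' mapped onto canonical channels and unrecognised or categorical columns
#' (e.g. the SS letter) are skipped.
#'
#' @param path Path to the table.
#' @param dialect `"native"` or `"spider2"`.
#' @param sequence Optional amino-acid string; when given, the file's
#'   residue column is cross-checked against it (positions where the file
#'   records `X` are exempt).
#' @param seq_id Identifier to assign when the file itself carries none
#'   (spider2 dialect); defaults to the file name without extension.
#' @return A [structural_trace()].
#' @export
read_structural_table <- function(path, dialect = c("native", "spider2"),
                                  sequence = NULL, seq_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    morf_stop("trimorf_parse_error", "structural table not found: %s", path)
  if (dialect == "native") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c("seq_id", "pos", "residue")
    if (!all(need %in% names(tab)))
      morf_stop("trimorf_parse_error",
                "'%s': native structural table needs seq_id/pos/residue",
                path)
    chans <- setdiff(names(tab), need)
    chans <- chans[chans %in% MORF_CHANNELS]
    if (!length(chans))
      morf_stop("trimorf_parse_error",
                "'%s': no recognised structural channels", path)
    id <- unique(tab$seq_id)
    if (length(id) != 1L)
      morf_stop("trimorf_parse_error",
                "'%s': expected a single seq_id, found %d", path, length(id))
    vals <- as.matrix(tab[, chans, drop = FALSE])
    residues <- tab$residue
  } else {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    if (!length(hdr))
      morf_stop("trimorf_parse_error",
                "'%s': spider2 table has no '#' header line", path)
    fields <- strsplit(sub("^#\\s*", "", hdr[1L]), "\\s+")[[1L]]
    tab <- tryCatch(
      utils::read.table(path, comment.char = "#", stringsAsFactors = FALSE),
      error = function(e)
        morf_stop("trimorf_parse_error", "'%s': %s", path,
                  conditionMessage(e)))
    if (ncol(tab) != length(fields))
      morf_stop("trimorf_parse_error",
                "'%s': header names %d columns but rows have %d",
                path, length(fields), ncol(tab))
    names(tab) <- fields
    mapped <- SPIDER2_ALIASES[toupper(fields)]
    chans <- unname(mapped[!is.na(mapped)])
    src <- fields[!is.na(mapped)]
    if (!length(chans))
      morf_stop("trimorf_parse_error",
                "'%s': no recognised SPIDER2 columns (saw: %s)", path,
                paste(fields, collapse = ", "))
    vals <- as.matrix(tab[, src, drop = FALSE])
    colnames(vals) <- chans
    residues <- if ("AA" %in% toupper(fields))
      as.character(tab[[which(toupper(fields) == "AA")[1L]]]) else NULL
    id <- seq_id %||% sub("\\.[^.]*$", "", basename(path))
  }
  if (!is.numeric(vals)) {
    badcol <- which(!vapply(as.data.frame(vals), is.numeric, logical(1)))[1L]
    suppressWarnings(num <- as.numeric(vals[, badcol]))
    morf_stop("trimorf_parse_error",
              "'%s': non-numeric value in channel '%s' at row %d",
              path, colnames(vals)[badcol], which(is.na(num))[1L])
  }
  if (!is.null(sequence)) {
    if (nrow(vals) != nchar(sequence))
      morf_stop("trimorf_validation_error",
                "'%s': %d rows but declared sequence has %d residues",
                path, nrow(vals), nchar(sequence))
    if (!is.null(residues)) {
      want <- strsplit(toupper(sequence), "")[[1L]]
      got <- toupper(residues)
      bad <- which(got != want & got != "X")
      if (length(bad))
        morf_stop("trimorf_validation_error",
                  "'%s': amino acid mismatch at row %d ('%s' vs '%s')",
                  path, bad[1L], got[bad[1L]], want[bad[1L]])
    }
  }
  structural_trace(id, vals)
}

#' Write a structural trace as a native TSV
#'
#' Values are written with 6 decimals; [read_structural_table()] with
#' `dialect = "native"` inverts this to that precision.
#'
#' @param trace A [structural_trace()].
#' @param path Output path.
#' @param residues Optional amino-acid string recorded in the `residue`
#'   column (defaults to `X` placeholders).
#' @export
write_structural_table <- function(trace, path, residues = NULL) {
  stopifnot(inherits(trace, "structural_trace"))
  n <- nrow(trace$values)
  res <- if (is.null(residues)) rep("X", n) else strsplit(residues, "")[[1L]]
  if (length(res) != n)
    morf_stop("trimorf_validation_error",
              "residues length %d does not match trace rows %d",
              length(res), n)
  tab <- data.frame(seq_id = trace$seq_id, pos = seq_len(n), residue = res,
                    stringsAsFactors = FALSE)
  for (ch in trace$channels) tab[[ch]] <- sprintf("%.6f", trace$values[, ch])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score track as a TSV
#'
#' Columns: `seq_id`, `position` (1-based), `residue`, `score` (6 decimals),
#' `stage`. [read_score_track()] inverts it.
#'
#' @param track A [score_track()].
#' @param path Output path.
#' @param residues Optional amino-acid string for the `residue` column.
#' @param append Append to an existing multi-sequence file.
#' @export
write_score_track <- function(track, path, residues = NULL, append = FALSE) {
  stopifnot(inherits(track, "score_track"))
  n <- length(track$scores)
  res <- if (is.null(residues)) rep("X", n) else strsplit(residues, "")[[1L]]
  if (length(res) != n)
    morf_stop("trimorf_validation_error",
              "residues length %d does not match track length %d",
              length(res), n)
  tab <- data.frame(seq_id = track$seq_id, position = seq_len(n),
                    residue = res, score = sprintf("%.6f", track$scores),
                    stage = track$stage, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append, append = append)
  invisible(path)
}

#' Read score tracks from a TSV
#'
#' @param path Path written by [write_score_track()] (may hold several
#'   sequences).
#' @return A list of [score_track()] objects, one per `seq_id`, in first
#'   appearance order.
#' @export
read_score_tracks <- function(path) {
  if (!file.exists(path))
    morf_stop("trimorf_parse_error", "score track file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "position", "score", "stage")
  if (!all(need %in% names(tab)))
    morf_stop("trimorf_parse_error",
              "'%s': score track needs columns %s", path,
              paste(need, collapse = ", "))
  ids <- unique(tab$seq_id)
  lapply(ids, function(id) {
    rows <- tab[tab$seq_id == id, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    if (!identical(as.integer(rows$position), seq_len(nrow(rows))))
      morf_stop("trimorf_parse_error",
                "'%s': positions for '%s' are not contiguous from 1",
                path, id)
    st <- unique(rows$stage)
    if (length(st) != 1L)
      morf_stop("trimorf_parse_error",
                "'%s': mixed stages for '%s'", path, id)
    score_track(id, rows$score, st)
  })
}

#' Read a single score track
#'
#' @inheritParams read_score_tracks
#' @return A [score_track()]; errors if the file holds more than one
#'   sequence.
#' @export
read_score_track <- function(path) {
  tracks <- read_score_tracks(path)
  if (length(tracks) != 1L)
    morf_stop("trimorf_parse_error",
              "'%s': expected one sequence, found %d", path, length(tracks))
  tracks[[1L]]
}
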