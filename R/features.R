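# Structural matrices and auto-covariance features.
#
# For a segment of length l and u selected channels, the structural matrix
# M is the l x u slice of the trace. The auto-covariance descriptor is
#
#   AC(k, j) = (1/l) * sum_{i = 1..l-k} M(i, j) * M(i+k, j)
#
# for lags k = 1..DF and channels j = 1..u. Note the divisor is l (not
# l - k) and the channel is NOT mean-centred: this is a raw lagged second
# moment, which differs from the textbook auto-covariance. When l <= k the
# sum is empty and AC(k, j) = 0, so the descriptor length DF * u is fixed
# regardless of segment length.

#' Feature configuration
#'
#' @param channels Structural channels used for featurization. Default is
#'   `HSEa_up` alone (upper-sphere half-sphere exposure, alpha variant),
#'   the single channel that carries the predictive signal.
#' @param df Distance factor: number of auto-covariance lags (default 10).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(channels = "HSEa_up", df = 10L) {
  df <- as.integer(df)
  if (df < 1L)
    morf_stop("trimorf_validation_error", "df must be >= 1")
  unknown <- setdiff(channels, MORF_CHANNELS)
  if (length(unknown))
    morf_stop("trimorf_validation_error", "unknown channel(s): %s",
              paste(unknown, collapse = ", "))
  structure(list(channels = channels, df = df), class = "feature_config")
}

#' Build the structural matrix for a segment
#'
#' Slices rows `start..end` and the requested channels (in the requested
#' order) out of a structural trace.
#'
#' @param trace A [structural_trace()].
#' @param start,end 1-based inclusive residue bounds.
#' @param channels Channel names to select.
#' @return A list of class `structural_matrix` with fields `values`
#'   (l x u matrix) and `channel_names`.
#' @export
build_matrix <- function(trace, start, end, channels) {
  stopifnot(inherits(trace, "structural_trace"))
  n <- nrow(trace$values)
  if (start < 1L || end > n || start > end)
    morf_stop("trimorf_validation_error",
              "bad bounds [%d,%d] for trace of %d rows", start, end, n)
  missing <- setdiff(channels, trace$channels)
  if (length(missing))
    morf_stop("trimorf_validation_error",
              "trace '%s' lacks channel(s): %s", trace$seq_id,
              paste(missing, collapse = ", "))
  structure(list(values = trace$values[start:end, channels, drop = FALSE],
                 channel_names = channels),
            class = "structural_matrix")
}

#' Auto-covariance feature vector of a structural matrix
#'
#' Computes `AC(k, j) = (1/l) * sum_i M(i,j) M(i+k,j)` for lags `k = 1..df`
#' and every channel, flattening channel-major (all `df` lags of channel 1,
#' then channel 2, ...). Lags with an empty sum (`k >= l`) are 0.
#'
#' @param matrix A [build_matrix()] result or a plain numeric matrix.
#' @param df Number of lags (default 10).
#' @return A list of class `feature_vector` with fields `values`
#'   (length `df * u`), `df`, `channel_names`.
#' @export
autocovariance <- function(matrix, df = 10L) {
  df <- as.integer(df)
  if (df < 1L)
    morf_stop("trimorf_validation_error", "df must be >= 1")
  chans <- NULL
  if (inherits(matrix, "structural_matrix")) {
    chans <- matrix$channel_names
    matrix <- matrix$values
  }
  M <- as.matrix(matrix)
  l <- nrow(M); u <- ncol(M)
  ac <- base::matrix(0, nrow = df, ncol = u)
  for (k in seq_len(df)) {
    if (k < l)
      ac[k, ] <- colSums(M[seq_len(l - k), , drop = FALSE] *
                         M[seq_len(l - k) + k, , drop = FALSE]) / l
  }
  structure(list(values = as.vector(ac), df = df,
                 channel_names = chans %||% colnames(M)),
            class = "feature_vector")
}

#' Featurize one segment or query sample
#'
#' Composes [build_matrix()] and [autocovariance()] under a
#' [feature_config()]; the identical code path serves training segments and
#' query windows.
#'
#' @param trace A [structural_trace()].
#' @param segment Anything with `start` and `end` fields (a row of
#'   [extract_training_segments()] or [enumerate_query_samples()] output, or
#'   a list).
#' @param config A [feature_config()].
#' @return A `feature_vector`.
#' @export
featurize <- function(trace, segment, config = feature_config()) {
  autocovariance(build_matrix(trace, segment$start, segment$end,
                              config$channels),
                 df = config$df)
}

# Batch featurization of many windows over one trace, O(L * df) per
# channel via cumulative sums of lagged products. Returns an
# n_windows x (df * u) matrix whose column order matches autocovariance().
ac_window_features <- function(trace, starts, ends, config) {
  stopifnot(length(starts) == length(ends))
  df <- config$df
  u <- length(config$channels)
  lens <- ends - starts + 1
  X <- base::matrix(0, nrow = length(starts), ncol = df * u)
  for (j in seq_len(u)) {
    x <- trace$values[, config$channels[j]]
    L <- length(x)
    for (k in seq_len(df)) {
      col <- (j - 1L) * df + k
      if (k >= L) next
      cp <- c(0, cumsum(x[seq_len(L - k)] * x[seq_len(L - k) + k]))
      hi <- pmax(ends - k, starts - 1L)  # empty sum when window length <= k
      X[, col] <- (cp[hi + 1L] - cp[starts]) / lens
    }
  }
  X
}
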