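#' Construct a labeled fixed-rate signal record
#'
#' @param samples Numeric vector of at least two samples.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param label Class label of the record (character or NA).
#' @param record_id Free-text identifier.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, sampling_rate, label = NA_character_,
                          record_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a signal record needs at least 2 samples")
  if (anyNA(samples)) stop("signal samples must not contain NA")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be positive")
  }
  structure(list(samples = samples,
                 sampling_rate = as.numeric(sampling_rate),
                 label = as.character(label),
                 record_id = as.character(record_id)),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("Signal record '%s': %d samples @ %g Hz (%.3f s), label %s\n",
              x$record_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$label))
  invisible(x)
}

#' Cut a signal record into fixed-length segments
#'
#' Produces consecutive, non-overlapping segments of
#' `floor(segment_seconds * sampling_rate)` samples; any trailing remainder
#' shorter than one segment is discarded. Segments inherit the record's label.
#' A 23.6 s record cut into 2.95 s segments yields 8 segments.
#'
#' @param rec A [signal_record()].
#' @param segment_seconds Segment duration in seconds; must not exceed the
#'   record duration.
#' @return List of `signal_record` segments.
#' @export
segment_signal <- function(rec, segment_seconds) {
  stopifnot(inherits(rec, "signal_record"))
  if (!is.numeric(segment_seconds) || segment_seconds <= 0) {
    stop("'segment_seconds' must be positive")
  }
  n_seg <- floor(segment_seconds * rec$sampling_rate)
  if (n_seg < 2L) stop("segment too short: fewer than 2 samples")
  if (n_seg > length(rec$samples)) {
    stop("segment length (", n_seg, " samples) exceeds record length (",
         length(rec$samples), ")")
  }
  k <- length(rec$samples) %/% n_seg
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * n_seg + 1L):(i * n_seg)
    signal_record(rec$samples[idx], rec$sampling_rate, rec$label,
                  sprintf("%s_seg%03d", rec$record_id, i))
  })
}

#' Segment every record of a signal set
#'
#' @param records List of [signal_record()] objects.
#' @param segment_seconds Segment duration in seconds.
#' @return Flat list of segment `signal_record`s.
#' @export
segment_signals <- function(records, segment_seconds) {
  unlist(lapply(records, segment_signal, segment_seconds = segment_seconds),
         recursive = FALSE)
}

#' FFT magnitude-spectrum features of equal-length segments
#'
#' Computes the discrete Fourier transform of each segment (rectangular
#' window by default; no detrending) and returns the magnitude spectrum as
#' one feature row per segment. The one-sided spectrum keeps bins
#' `0 .. floor(N/2)`; feature names carry the bin frequencies in Hz. For a
#' constant signal `c` only the DC bin is nonzero and equals `c * N`.
#'
#' @param segments List of equal-length, equal-rate [signal_record()]s.
#' @param window `"rectangular"` (default, keeps pure-tone examples exact) or
#'   `"hann"`.
#' @param two_sided If `TRUE`, return all `N` magnitude bins (useful for
#'   Parseval checks). Default `FALSE`.
#' @return An object of class `feature_set`: list with `values` (`K x s`
#'   matrix), `feature_names` and `labels`.
#' @export
fft_features <- function(segments, window = c("rectangular", "hann"),
                         two_sided = FALSE) {
  window <- match.arg(window)
  if (length(segments) < 1L) stop("no segments supplied")
  lens <- vapply(segments, function(s) length(s$samples), integer(1))
  rates <- vapply(segments, `[[`, numeric(1), "sampling_rate")
  if (length(unique(lens)) != 1L) stop("segments have mixed lengths")
  if (length(unique(rates)) != 1L) stop("segments have mixed sampling rates")
  n <- lens[1L]
  rate <- rates[1L]
  X <- vapply(segments, `[[`, numeric(n), "samples")  # n x K
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n - 1L) / (n - 1L))
    w <- c(0.5 - 0.5 * cos(0), w)  # standard symmetric Hann over 0..n-1
    X <- X * w
  }
  spec <- Mod(stats::mvfft(X))
  keep <- if (two_sided) seq_len(n) else seq_len(floor(n / 2) + 1L)
  freqs <- (keep - 1L) * rate / n
  feature_set(t(spec[keep, , drop = FALSE]),
              feature_names = sprintf("f_%.4gHz", freqs),
              labels = vapply(segments, `[[`, character(1), "label"))
}

#' Construct a feature set (samples by features with class labels)
#'
#' @param values Numeric `K x s` matrix without missing values.
#' @param feature_names Character vector of `s` feature labels.
#' @param labels Character vector of `K` class labels.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(values, feature_names = colnames(values), labels) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  if (ncol(values) < 1L) stop("need at least one feature")
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(ncol(values)))
  stopifnot(length(feature_names) == ncol(values),
            length(labels) == nrow(values))
  colnames(values) <- feature_names
  structure(list(values = values,
                 feature_names = as.character(feature_names),
                 labels = as.character(labels)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' @export
`[.feature_set` <- function(x, i, ...) {
  feature_set(x$values[i, , drop = FALSE], x$feature_names, x$labels[i])
}
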