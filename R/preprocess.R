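# Preprocessing: dropout excision, zero-phase bandpass, resampling.

# Split a signal at runs of >= run_min consecutive exact zeros (hardware
# dropouts). Isolated zeros are legitimate samples and retained. Returns the
# kept chunks so no analysis window ever spans a splice.
split_zero_runs <- function(x, run_min = 3) {
  is_zero <- x == 0
  if (!any(is_zero)) return(list(chunks = list(x), n_dropped = 0L))
  r <- rle(is_zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop <- r$values & r$lengths >= run_min
  keep_mask <- rep(TRUE, length(x))
  for (i in which(drop)) keep_mask[starts[i]:ends[i]] <- FALSE
  kr <- rle(keep_mask)
  ke <- cumsum(kr$lengths)
  ks <- ke - kr$lengths + 1L
  chunks <- lapply(which(kr$values), function(i) x[ks[i]:ke[i]])
  list(chunks = chunks, n_dropped = sum(!keep_mask))
}

#' Preprocess one channel
#'
#' Excises exact-zero dropout runs (splitting the signal so no analysis
#' window spans the splice), applies a zero-phase Butterworth bandpass, and
#' polyphase-resamples to the common analysis rate.
#'
#' @param x Numeric samples.
#' @param fs Input sampling rate in Hz; must be at least twice the upper
#'   band edge.
#' @param bandpass Band edges in Hz (default `c(0.5, 80)`).
#' @param resample_to Target rate in Hz (default 200).
#' @param filter_order Butterworth order (default 4).
#' @param zero_run_min Minimum zero-run length treated as a dropout.
#' @return A list of class `bisca_preprocessed`: `chunks` (list of numeric
#'   vectors at the target rate), `fs`, `n_dropped_zero`.
#' @export
preprocess <- function(x, fs, bandpass = c(0.5, 80), resample_to = 200,
                       filter_order = 4, zero_run_min = 3) {
  check_finite_numeric(x)
  if (fs < 2 * bandpass[2]) {
    abort("`fs` must be at least twice the upper bandpass edge.")
  }
  sp <- split_zero_runs(x, zero_run_min)
  if (length(sp$chunks) == 0 || all(lengths(sp$chunks) == 0)) {
    abort("nothing left after removing zero-run dropouts.")
  }
  bf <- signal::butter(filter_order, bandpass / (fs / 2), type = "pass")
  min_len <- 3 * (filter_order * 3 + 1) # filtfilt edge requirement
  chunks <- lapply(sp$chunks, function(ch) {
    if (length(ch) < min_len) return(NULL)
    y <- signal::filtfilt(bf, ch)
    if (resample_to != fs) {
      frac <- rational_ratio(resample_to, fs)
      y <- as.numeric(signal::resample(y, frac[1], frac[2]))
    }
    y
  })
  chunks <- chunks[!vapply(chunks, is.null, logical(1))]
  if (length(chunks) == 0) {
    abort("all chunks are too short after dropout removal.")
  }
  structure(list(chunks = chunks, fs = resample_to,
                 n_dropped_zero = sp$n_dropped),
            class = "bisca_preprocessed")
}

rational_ratio <- function(p, q) {
  pi_ <- round(p * 1000)
  qi <- round(q * 1000)
  g <- gcd_int(pi_, qi)
  c(pi_ / g, qi / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Segment a preprocessed channel
#'
#' Applies [segment_signal()] to every contiguous chunk and pools the
#' segments, so windows never span a dropout splice. Chunks shorter than one
#' window are skipped.
#'
#' @param pp A [preprocess()] result (or numeric vector).
#' @inheritParams segment_signal
#' @return A `bisca_segments` object.
#' @export
segment_preprocessed <- function(pp, window_samples = 300,
                                 overlap_fraction = 0.75, channel_id = "x") {
  if (is.numeric(pp)) {
    return(segment_signal(pp, attr(pp, "fs") %||%
                            abort("numeric input needs an `fs` attribute"),
                          window_samples, overlap_fraction, channel_id))
  }
  stopifnot(inherits(pp, "bisca_preprocessed"))
  usable <- pp$chunks[lengths(pp$chunks) >= window_samples]
  if (length(usable) == 0) {
    abort("no chunk is long enough for a single analysis window.")
  }
  parts <- lapply(usable, segment_signal, fs = pp$fs,
                  window_samples = window_samples,
                  overlap_fraction = overlap_fraction,
                  channel_id = channel_id)
  segs <- do.call(rbind, lapply(parts, function(s) s$segments))
  out <- parts[[1]]
  out$segments <- segs
  out$n_segments <- nrow(segs)
  out
}

#' Average-reference a multichannel recording
#'
#' Subtracts the instantaneous mean across channels (common scalp-EEG
#' referencing); requires equal channel lengths. Off by default in the
#' pipeline and unsuitable for single-channel input.
#'
#' @param recording A `bisca_recording`.
#' @return The recording with re-referenced signals.
#' @export
average_reference <- function(recording) {
  stopifnot(inherits(recording, "bisca_recording"))
  lens <- lengths(recording$signals)
  if (length(unique(lens)) != 1) {
    abort("average referencing needs equal channel lengths.")
  }
  mat <- do.call(cbind, recording$signals)
  mat <- mat - rowMeans(mat)
  recording$signals <- setNames(
    lapply(seq_len(ncol(mat)), function(i) mat[, i]), recording$labels)
  recording
}
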