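## Fluorescence-trace preprocessing: F/F0 normalisation with automatic
## baseline-window selection, and a simple threshold-crossing spike
## extractor. Spike tables remain the primary input of the package; the
## extractor is a documented convenience front end, not a calibrated
## detector.

#' Normalise a fluorescence trace (F/F0)
#'
#' Divides the trace by the baseline F0, defined as the mean over the
#' sliding window of length `baseline_len` with minimum standard deviation
#' among all windows contained in `[0, search_end]` (the pre-stimulus
#' segment).
#'
#' @param trace numeric fluorescence values, uniformly sampled.
#' @param time sample times in seconds (uniform, strictly increasing).
#' @param baseline_len baseline window length in seconds (default 25).
#' @param search_end end of the search range in seconds (default 120).
#' @return The normalised trace, with the selected window `c(start, end)`
#'   in attribute `"baseline_window"` and F0 in `"F0"`.
#' @export
normalize_trace <- function(trace, time, baseline_len = 25, search_end = 120) {
  stopifnot(length(trace) == length(time), length(trace) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    stop("time base must be uniform and strictly increasing")
  dt <- dt[1L]
  if (max(time) < search_end - 1e-9)
    stop("trace must cover the search range [0, search_end]")
  w <- max(2L, as.integer(round(baseline_len / dt)))
  last_start <- max(which(time <= search_end - baseline_len + 1e-9))
  starts <- seq_len(last_start)
  sds <- vapply(starts, function(i) stats::sd(trace[i:(i + w - 1L)]),
                numeric(1L))
  i0 <- starts[which.min(sds)]
  F0 <- mean(trace[i0:(i0 + w - 1L)])
  if (F0 <= 0) stop("baseline mean is non-positive; cannot normalise")
  out <- trace / F0
  attr(out, "baseline_window") <- c(time[i0], time[i0 + w - 1L])
  attr(out, "F0") <- F0
  out
}

#' Extract spike times from a normalised trace
#'
#' Marks one spike per super-threshold excursion at the time of the local
#' maximum, then enforces a refractory separation; deterministic given its
#' parameters, which must be supplied explicitly (there are no calibrated
#' defaults).
#'
#' @param trace normalised (F/F0) trace.
#' @param time sample times in seconds.
#' @param threshold detection threshold in F/F0 units (> 1).
#' @param refractory minimum separation between spikes in seconds.
#' @param cell_id label for the returned sequence.
#' @return A [spike_seq()] with `t_end = max(time)` and `delta` equal to the
#'   frame interval.
#' @export
extract_spikes <- function(trace, time, threshold, refractory,
                           cell_id = "cell") {
  stopifnot(length(trace) == length(time), threshold > 1, refractory >= 0)
  dt <- diff(time)[1L]
  above <- trace > threshold
  peaks <- numeric(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    peaks <- c(peaks, time[seg[which.max(trace[seg])]])
  }
  keep <- numeric(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= max(refractory, dt)) { keep <- c(keep, p); last <- p }
  }
  keep <- keep[keep > 0]
  spike_seq(keep, t_end = max(time), delta = dt, cell_id = cell_id)
}
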