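#' Fixed-length epoch set
#'
#' Segments of a recording arranged as an `epoch x channel x sample` array
#' with a per-epoch condition label (`"REST"`, `"EC"` or `"EO"`), a
#' rejection mask, and the source start sample of each epoch.
#'
#' @param epochs numeric array `n_epochs x n_channels x n_samples`.
#' @param fs sampling rate (Hz).
#' @param channel_labels channel labels along the second dimension.
#' @param condition character vector of per-epoch labels.
#' @param rejected logical mask, `TRUE` = excluded from analysis.
#' @param start_sample 1-based source sample at which each epoch begins.
#' @return object of class `bcg_epoch_set`.
#' @export
epoch_set <- function(epochs, fs, channel_labels,
                      condition = rep("REST", dim(epochs)[1]),
                      rejected = rep(FALSE, dim(epochs)[1]),
                      start_sample = NULL) {
  stopifnot(length(dim(epochs)) == 3L,
            dim(epochs)[2] == length(channel_labels),
            dim(epochs)[1] == length(condition),
            dim(epochs)[1] == length(rejected))
  structure(list(epochs = epochs, fs = fs,
                 channel_labels = as.character(channel_labels),
                 condition = as.character(condition),
                 rejected = as.logical(rejected),
                 start_sample = start_sample),
            class = "bcg_epoch_set")
}

#' @export
print.bcg_epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<bcg_epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  conditions:", paste(sprintf("%s:%d", names(table(x$condition)),
                                     table(x$condition)), collapse = " "),
      "| rejected:", sum(x$rejected), "\n")
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) IIR filtering: a 2nd-order Butterworth
#' high-pass cascaded with a 4th-order Butterworth low-pass, each applied
#' with `signal::filtfilt`. The cascade is numerically robust for the very
#' low normalized high-pass edge (1 Hz at 1000 Hz sampling) and meets a
#' >= 20 dB attenuation one octave outside the band.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @return filtered [recording()].
#' @export
bandpass <- function(rec, low = 1, high = 50) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  out <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  with_data(rec, out)
}

#' Segment a recording into consecutive non-overlapping epochs
#'
#' When the recording carries `EC_ONSET`/`EO_ONSET` block events, every
#' epoch is labelled with its block's condition; epochs that would straddle
#' a block boundary are dropped (with a message). Without block events all
#' epochs are labelled `"REST"`.
#'
#' @param rec a [recording()].
#' @param length_s epoch length in seconds (default 2).
#' @param channels channels to keep (default: all non-ECG channels).
#' @return an [epoch_set()].
#' @export
epoch_recording <- function(rec, length_s = 2,
                            channels = setdiff(rec$channel_labels, "ECG")) {
  len <- round(length_s * rec$fs)
  n <- n_samples(rec)
  if (n < len) stop("recording shorter than one epoch", call. = FALSE)
  starts <- seq(1L, n - len + 1L, by = len)
  onsets <- sort(c(get_events(rec, "EC_ONSET"), get_events(rec, "EO_ONSET")))
  labels <- c(rep("EC", length(get_events(rec, "EC_ONSET"))),
              rep("EO", length(get_events(rec, "EO_ONSET"))))
  labels <- labels[order(c(get_events(rec, "EC_ONSET"),
                           get_events(rec, "EO_ONSET")))]
  cond <- rep("REST", length(starts))
  keep <- rep(TRUE, length(starts))
  if (length(onsets)) {
    for (i in seq_along(starts)) {
      s <- starts[i]; e <- s + len - 1L
      straddle <- any(onsets > s & onsets <= e)
      if (straddle) { keep[i] <- FALSE; next }
      prev <- which(onsets <= s)
      cond[i] <- if (length(prev)) labels[max(prev)] else NA_character_
    }
    keep <- keep & !is.na(cond)
    if (any(!keep))
      message(sum(!keep), " epoch(s) dropped at block boundaries")
  }
  starts <- starts[keep]; cond <- cond[keep]
  ci <- match(channels, rec$channel_labels)
  arr <- array(0, dim = c(length(starts), length(channels), len))
  for (i in seq_along(starts))
    arr[i, , ] <- rec$data[ci, starts[i]:(starts[i] + len - 1L)]
  epoch_set(arr, rec$fs, channels, condition = cond,
            start_sample = starts)
}

#' Reject epochs on a peak-to-peak amplitude criterion
#'
#' An epoch is rejected iff any channel's peak-to-peak amplitude exceeds
#' the threshold. The data are untouched; only the mask changes.
#'
#' @param epochs an [epoch_set()].
#' @param threshold_uv peak-to-peak threshold in microvolts (default 150).
#' @return the epoch set with an updated `rejected` mask.
#' @export
reject_epochs <- function(epochs, threshold_uv = 150) {
  stopifnot(threshold_uv > 0)
  p2p <- apply(epochs$epochs, c(1, 2), function(x) max(x) - min(x))
  epochs$rejected <- apply(p2p, 1, max) > threshold_uv
  if (all(epochs$rejected))
    warning("all epochs exceed the rejection threshold", call. = FALSE)
  epochs
}

#' Energy-based QRS detection
#'
#' Pan-Tompkins-style detector: 5-15 Hz zero-phase band-pass, squared
#' derivative, 150-ms moving-window integration, adaptive thresholding of
#' the integrated energy with a refractory period, and refinement of each
#' detection to the nearest absolute maximum of the band-passed ECG. The
#' detector is invariant to amplitude scaling and polarity of the ECG.
#'
#' @param ecg single-channel [recording()] (`fs >= 250` Hz).
#' @param refractory_s minimum separation between detections (s).
#' @return integer vector of detected R-peak samples (1-based), possibly
#'   empty (with a warning) for flat input.
#' @export
detect_qrs <- function(ecg, refractory_s = 0.3) {
  stopifnot(nrow(ecg$data) == 1L)
  fs <- ecg$fs
  if (fs < 250) stop("QRS detection requires fs >= 250 Hz", call. = FALSE)
  x <- as.numeric(ecg$data[1, ])
  if (stats::sd(x) == 0) {
    warning("flat ECG signal: no QRS complexes detected", call. = FALSE)
    return(integer(0))
  }
  bp <- signal::filtfilt(signal::butter(3, c(5, 15) / (fs / 2), type = "pass"),
                         x)
  en <- c(0, diff(bp))^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(en, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  # candidate peaks: maxima of contiguous supra-threshold runs
  thr <- 0.1 * as.numeric(stats::quantile(integ, 0.99))
  runs <- rle(integ > thr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  if (!length(sel)) {
    warning("no QRS candidates above threshold", call. = FALSE)
    return(integer(0))
  }
  cand <- vapply(sel, function(j)
    starts[j] - 1L + which.max(integ[starts[j]:ends[j]]), integer(1))
  # adaptive acceptance: candidate must reach a fraction of the running
  # signal-peak level; refractory period enforced greedily
  level <- stats::median(integ[cand])
  ref_n <- round(refractory_s * fs)
  accepted <- integer(0)
  for (p in cand) {
    if (integ[p] < 0.3 * level) next
    if (length(accepted) && p - accepted[length(accepted)] < ref_n) {
      if (integ[p] > integ[accepted[length(accepted)]])
        accepted[length(accepted)] <- p
      next
    }
    accepted <- c(accepted, p)
    level <- 0.875 * level + 0.125 * integ[p]
  }
  # refine each detection to the absolute band-passed maximum nearby
  half <- round(0.1 * fs)
  n <- length(x)
  peaks <- vapply(accepted, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo - 1L + which.max(abs(bp[lo:hi])))
  }, integer(1))
  sort(unique(peaks))
}
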