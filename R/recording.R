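#' Continuous multichannel recording
#'
#' A `bcg_recording` bundles a channels x samples data matrix (microvolts for
#' EEG channels, millivolts for ECG), its sampling rate, labelled event
#' trains, and free-form provenance notes. It is the common currency of every
#' pipeline stage: the simulator produces one, the readers produce one, and
#' every correction method maps one to another of identical shape.
#'
#' Event sample indices are stored 1-based (first sample is 1); file formats
#' that count from zero or in seconds are converted at the I/O boundary.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (scalar > 0).
#' @param channel_labels character vector, one unique label per row of
#'   `data`. 10-20 names (`"O1"`, `"Fz"`, ...) plus optionally `"ECG"`.
#' @param events named list of integer vectors: event trains keyed by label
#'   (`"TR"`, `"RPEAK"`, `"EC_ONSET"`, `"EO_ONSET"`, ...), each strictly
#'   increasing, values in `[1, n_samples]`.
#' @param reference optional name of the (removed) reference electrode,
#'   stored as metadata only.
#' @param meta free-form list of provenance notes.
#' @return An object of class `bcg_recording`.
#' @export
recording <- function(data, fs, channel_labels = rownames(data),
                      events = list(), reference = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row is required", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  rownames(data) <- channel_labels
  events <- lapply(events, function(x) as.integer(round(x)))
  rec <- structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         events = events, reference = reference, meta = meta),
    class = "bcg_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording's invariants
#'
#' Checks unique labels, positive sampling rate, event indices within
#' `[1, n_samples]` and strict monotonicity of every event train.
#'
#' @param rec a [recording()].
#' @return `rec`, invisibly; errors on violation.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "bcg_recording"))
  n <- ncol(rec$data)
  if (anyDuplicated(rec$channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  if (rec$fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  for (lab in names(rec$events)) {
    ev <- rec$events[[lab]]
    if (!nzchar(lab)) stop("event label must be nonempty", call. = FALSE)
    if (length(ev)) {
      if (any(ev < 1L) || any(ev > n))
        stop(sprintf("event '%s' has indices outside [1, %d]", lab, n),
             call. = FALSE)
      if (any(diff(ev) <= 0L))
        stop(sprintf("event '%s' must be strictly increasing", lab),
             call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf("<bcg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (length(x$events))
    cat("  events:  ",
        paste(sprintf("%s[%d]", names(x$events),
                      lengths(x$events)), collapse = " "), "\n")
  if (!is.null(x$reference)) cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec a [recording()].
#' @return integer sample count or duration in seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Extract one event train
#'
#' @param rec a [recording()].
#' @param label event label, e.g. `"RPEAK"`.
#' @param required error (rather than return `integer(0)`) when absent.
#' @return integer vector of 1-based sample indices.
#' @export
get_events <- function(rec, label, required = FALSE) {
  ev <- rec$events[[label]]
  if (is.null(ev)) {
    if (required) stop(sprintf("recording has no '%s' events", label),
                       call. = FALSE)
    return(integer(0))
  }
  ev
}

#' Subset channels of a recording
#'
#' @param rec a [recording()].
#' @param channels character vector of labels to keep (order preserved).
#' @return a [recording()] with the selected rows; events untouched.
#' @export
select_channels <- function(rec, channels) {
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing))
    stop("unknown channels: ", paste(missing, collapse = ", "), call. = FALSE)
  recording(rec$data[channels, , drop = FALSE], rec$fs, channels,
            events = rec$events, reference = rec$reference, meta = rec$meta)
}

#' Replace the data matrix, keeping everything else
#' @param rec a [recording()].
#' @param data replacement matrix of identical dimensions.
#' @return a [recording()].
#' @export
with_data <- function(rec, data) {
  stopifnot(identical(dim(data), dim(rec$data)))
  recording(data, rec$fs, rec$channel_labels, events = rec$events,
            reference = rec$reference, meta = rec$meta)
}

#' The 18 analysed 10-20 scalp channels
#'
#' Standard montage analysed throughout: the eighteen 10-20 electrodes
#' (Cz serves as reference and carries no data row).
#' @return character vector of length 18.
#' @export
standard_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4",
    "P3", "P4", "Pz", "T3", "T4", "T5", "T6", "O1", "O2")
}

#' Posterior channels used for alpha topography checks
#' @return character vector.
#' @export
posterior_channels <- function() c("P3", "P4", "Pz", "T5", "T6", "O1", "O2")

# left/right and anterior/posterior mirror pairs of the 18-channel montage,
# used by component topography scoring
lr_pairs <- function() {
  cbind(left  = c("Fp1", "F3", "F7", "C3", "P3", "T3", "T5", "O1"),
        right = c("Fp2", "F4", "F8", "C4", "P4", "T4", "T6", "O2"))
}

ap_pairs <- function() {
  cbind(front = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
        back  = c("O1", "O2", "P3", "P4", "T5", "T6", "Pz"))
}
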