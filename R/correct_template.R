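# ---- shared epoch geometry for cardiac-locked template corrections -------

# Artifact epochs span R + delay - 0.25*RRmed .. R + delay + 0.75*RRmed
# (RRmed = median RR interval). Overlapping neighbours are truncated at the
# midpoint of the overlap, so every sample is corrected at most once.
bcg_epoch_geometry <- function(rpeaks, delay_n, fs, n) {
  if (length(rpeaks) < 2L)
    stop("at least 2 R peaks are required", call. = FALSE)
  rr_med <- stats::median(diff(rpeaks))
  L <- as.integer(round(rr_med))
  offset <- as.integer(round(0.25 * rr_med))
  starts <- as.integer(rpeaks + delay_n - offset)
  ends <- starts + L - 1L
  k <- length(starts)
  cut_lo <- starts; cut_hi <- ends
  if (k > 1L) {
    ov_prev <- which(ends[-k] >= starts[-1L])  # i overlaps i+1
    mids <- (ends[ov_prev] + starts[ov_prev + 1L]) %/% 2L
    cut_hi[ov_prev] <- mids
    cut_lo[ov_prev + 1L] <- mids + 1L
  }
  valid <- starts >= 1L & ends <= n
  list(starts = starts, ends = ends, cut_lo = pmax(cut_lo, 1L),
       cut_hi = pmin(cut_hi, n), valid = valid, L = L, rr_med = rr_med)
}

# epochs x L matrix of one channel at the given geometry (valid cycles only)
extract_cycles <- function(x, geo) {
  idx <- outer(geo$starts[geo$valid], 0:(geo$L - 1L), "+")
  matrix(x[idx], nrow = sum(geo$valid))
}

# sliding centered mean over the rows of E, window w (truncated at edges)
sliding_row_mean <- function(E, w) {
  k <- nrow(E)
  half <- (w - 1L) %/% 2L
  cs <- rbind(0, apply(E, 2, cumsum))
  t(vapply(seq_len(k), function(i) {
    lo <- max(1L, i - half); hi <- min(k, i + half)
    (cs[hi + 1L, ] - cs[lo, ]) / (hi - lo + 1L)
  }, numeric(ncol(E))))
}

# standard report skeleton shared by all correction methods
correction_report <- function(method, params, before, after, fs,
                              rpeaks = NULL, warnings = character(0)) {
  rep_ <- list(method = method, params = params, warnings = warnings)
  if (!is.null(rpeaks) && length(rpeaks) > 2L) {
    f0 <- fs / stats::median(diff(rpeaks))
    rep_$cardiac_power_reduction <- vapply(seq_len(nrow(before)), function(i) {
      pb <- harmonic_band_power(before[i, ], fs, f0)
      pa <- harmonic_band_power(after[i, ], fs, f0)
      if (pb > 0) 1 - pa / pb else NA_real_
    }, numeric(1))
    names(rep_$cardiac_power_reduction) <- rownames(before)
  }
  rep_$rms_reduction <- 1 - sqrt(rowMeans(after^2)) / sqrt(rowMeans(before^2))
  class(rep_) <- "bcg_correction_report"
  rep_
}

#' @export
print.bcg_correction_report <- function(x, ...) {
  cat("<correction report>", x$method, "\n")
  if (!is.null(x$cardiac_power_reduction))
    cat(sprintf("  cardiac-harmonic power reduction: median %.1f%%\n",
                100 * stats::median(x$cardiac_power_reduction, na.rm = TRUE)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# periodogram mass near the cardiac fundamental and its first harmonics
harmonic_band_power <- function(x, fs, f0, harmonics = 1:4, bw = 0.25) {
  sp <- epoch_spectrum(x, fs)
  sum(vapply(harmonics, function(h)
    sum(sp$power[abs(sp$freq - h * f0) <= bw * f0]), numeric(1)))
}

# rows of a recording to which EEG corrections apply
eeg_rows <- function(rec) which(rec$channel_labels != "ECG")

# ---- gradient artifact: sliding-window AAS -------------------------------

#' Gradient-artifact removal by sliding-window average subtraction
#'
#' For each TR segment the artifact template is the mean of the
#' `window_volumes` nearest segments (centered window, truncated at the
#' record edges), subtracted per channel. A strictly TR-periodic artifact
#' is cancelled exactly.
#'
#' @param rec a [recording()] with `TR` events (or pass `tr_events`).
#' @param tr_events integer TR onsets; defaults to the recording's events.
#' @param window_volumes sliding-window width in volumes (default 5).
#' @return list: `recording` (corrected), `report`.
#' @export
ga_aas <- function(rec, tr_events = get_events(rec, "TR", required = TRUE),
                   window_volumes = 5L) {
  n <- n_samples(rec)
  if (length(tr_events) < 2L)
    stop("at least 2 TR events are required", call. = FALSE)
  sp <- diff(tr_events)
  if (max(sp) - min(sp) > 1L)
    stop("irregular TR spacing: AAS alignment impossible", call. = FALSE)
  warns <- character(0)
  if (length(tr_events) < window_volumes)
    warns <- c(warns, sprintf(
      "only %d TR segments for a %d-volume window: windows edge-truncated",
      length(tr_events), window_volumes))
  L <- as.integer(stats::median(sp))
  full <- tr_events + L - 1L <= n
  starts_f <- tr_events[full]
  out <- rec$data
  rows <- eeg_rows(rec)
  idx <- outer(starts_f, 0:(L - 1L), "+")
  for (r in rows) {
    E <- matrix(rec$data[r, idx], nrow = length(starts_f))
    Tm <- sliding_row_mean(E, window_volumes)
    out[r, t(idx)] <- t(E - Tm)
    # truncated final segment (if any): reuse the last template
    if (any(!full)) {
      s <- tr_events[!full][1L]
      len <- n - s + 1L
      out[r, s:n] <- rec$data[r, s:n] - Tm[nrow(Tm), seq_len(len)]
    }
  }
  corrected <- with_data(rec, out)
  rep_ <- correction_report(
    "ga_aas", list(window_volumes = window_volumes),
    rec$data[rows, , drop = FALSE], out[rows, , drop = FALSE], rec$fs,
    warnings = warns)
  for (w in warns) warning(w, call. = FALSE)
  list(recording = corrected, report = rep_)
}

# ---- BCG: average artifact subtraction -----------------------------------

#' BCG correction by sliding-window average artifact subtraction
#'
#' Cardiac artifact epochs are extracted around `R + delay` spanning the
#' median RR interval; each cycle's template is the unweighted mean of the
#' `window_cycles` nearest cycles (centered window) and is subtracted over
#' the cycle's (overlap-truncated) span. Samples outside artifact epochs
#' are untouched. With `scale = TRUE` the template is least-squares scaled
#' to each cycle before subtraction; the default unweighted subtraction
#' makes the operator linear in the data, so it commutes exactly with
#' channel mixing (the property [projic()] relies on).
#'
#' @param rec a [recording()].
#' @param rpeaks integer R-peak train.
#' @param delay_s delay from R peak to the main BCG peak (default 0.21 s).
#' @param window_cycles sliding-window width in cardiac cycles (default 21).
#' @param scale least-squares scale the template per cycle.
#' @return list: `recording`, `report`.
#' @export
bcg_aas <- function(rec, rpeaks = get_events(rec, "RPEAK", required = TRUE),
                    delay_s = 0.21, window_cycles = 21L, scale = FALSE) {
  n <- n_samples(rec)
  if (length(rpeaks) < 2L) stop("need at least 2 R peaks", call. = FALSE)
  if (length(rpeaks) < window_cycles)
    warning("fewer cardiac cycles than the window width; window truncated",
            call. = FALSE)
  geo <- bcg_epoch_geometry(rpeaks, round(delay_s * rec$fs), rec$fs, n)
  out <- rec$data
  rows <- eeg_rows(rec)
  vi <- which(geo$valid)
  for (r in rows) {
    E <- extract_cycles(rec$data[r, ], geo)
    Tm <- sliding_row_mean(E, window_cycles)
    for (j in seq_along(vi)) {
      i <- vi[j]
      lo <- geo$cut_lo[i]; hi <- geo$cut_hi[i]
      if (hi < lo) next
      toff <- (lo - geo$starts[i] + 1L):(hi - geo$starts[i] + 1L)
      tmpl <- Tm[j, toff]
      a <- if (scale && sum(tmpl^2) > 0)
        sum(out[r, lo:hi] * tmpl) / sum(tmpl^2) else 1
      out[r, lo:hi] <- out[r, lo:hi] - a * tmpl
    }
  }
  corrected <- with_data(rec, out)
  rep_ <- correction_report(
    "bcg_aas",
    list(delay_s = delay_s, window_cycles = window_cycles, scale = scale),
    rec$data[rows, , drop = FALSE], out[rows, , drop = FALSE], rec$fs,
    rpeaks = rpeaks)
  list(recording = corrected, report = rep_)
}

# ---- BCG: optimal basis set ----------------------------------------------

#' BCG correction by optimal basis set regression
#'
#' Per channel, the matrix of aligned artifact epochs is decomposed by PCA;
#' the epoch-mean waveform plus the leading `n_pcs` principal components
#' form the basis, whose least-squares fit is subtracted from every epoch.
#' Artifact epochs drawn from a rank-`n_pcs` family are suppressed
#' essentially completely. `n_pcs = 0` is the identity transform.
#'
#' @inheritParams bcg_aas
#' @param n_pcs number of principal components (default 4).
#' @return list: `recording`, `report`.
#' @export
bcg_obs <- function(rec, rpeaks = get_events(rec, "RPEAK", required = TRUE),
                    delay_s = 0.21, n_pcs = 4L) {
  n_pcs <- as.integer(n_pcs)
  if (n_pcs == 0L) {
    rows <- eeg_rows(rec)
    return(list(recording = rec,
                report = correction_report(
                  "bcg_obs", list(delay_s = delay_s, n_pcs = 0L),
                  rec$data[rows, , drop = FALSE],
                  rec$data[rows, , drop = FALSE], rec$fs)))
  }
  n <- n_samples(rec)
  geo <- bcg_epoch_geometry(rpeaks, round(delay_s * rec$fs), rec$fs, n)
  if (sum(geo$valid) < n_pcs + 1L)
    stop("fewer cardiac cycles than principal components", call. = FALSE)
  out <- rec$data
  rows <- eeg_rows(rec)
  vi <- which(geo$valid)
  for (r in rows) {
    E <- extract_cycles(rec$data[r, ], geo)
    m <- colMeans(E)
    Ec <- sweep(E, 2, m)
    sv <- svd(Ec, nu = 0, nv = min(n_pcs, min(dim(Ec))))
    B <- cbind(m, sv$v)                    # L x (n_pcs + 1)
    # least-squares via pseudo-inverse: the mean column may lie inside the
    # PC span (exactly rank-limited artifact families), so plain QR would
    # be rank-deficient
    bs <- svd(B)
    keep <- bs$d > max(bs$d) * 1e-10
    fit <- t(B %*% (bs$v[, keep, drop = FALSE] %*%
                      (t(bs$u[, keep, drop = FALSE]) %*% t(E) /
                         bs$d[keep])))     # epochs x L
    for (j in seq_along(vi)) {
      i <- vi[j]
      lo <- geo$cut_lo[i]; hi <- geo$cut_hi[i]
      if (hi < lo) next
      toff <- (lo - geo$starts[i] + 1L):(hi - geo$starts[i] + 1L)
      out[r, lo:hi] <- out[r, lo:hi] - fit[j, toff]
    }
  }
  corrected <- with_data(rec, out)
  rep_ <- correction_report(
    "bcg_obs", list(delay_s = delay_s, n_pcs = n_pcs),
    rec$data[rows, , drop = FALSE], out[rows, , drop = FALSE], rec$fs,
    rpeaks = rpeaks)
  list(recording = corrected, report = rep_)
}
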