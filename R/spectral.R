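#' Frequency band scheme
#'
#' The six classical EEG bands, realised as contiguous half-open intervals
#' `[low, high)` (the last band includes its upper edge) so that every
#' 0.5-Hz FFT bin between the printed integer edges is assigned
#' deterministically and relative powers sum to exactly 1:
#' delta `[1,4)`, theta `[4,8)`, alpha `[8,13)`, slow beta `[13,18)`,
#' fast beta `[18,31)`, gamma `[31,50]` Hz.
#'
#' @param name,low,high parallel vectors defining custom bands.
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
band_scheme <- function(name = c("delta", "theta", "alpha", "slow_beta",
                                 "fast_beta", "gamma"),
                        low = c(1, 4, 8, 13, 18, 31),
                        high = c(4, 8, 13, 18, 31, 50)) {
  stopifnot(length(name) == length(low), length(low) == length(high))
  ord <- order(low)
  name <- as.character(name)[ord]; low <- low[ord]; high <- high[ord]
  if (any(high <= low)) stop("band edges must increase", call. = FALSE)
  if (length(low) > 1 && any(abs(low[-1] - high[-length(high)]) > 1e-9))
    stop("bands must be contiguous and non-overlapping", call. = FALSE)
  data.frame(name = name, low = low, high = high,
             stringsAsFactors = FALSE)
}

#' One-sided power spectrum of a single epoch
#'
#' Rectangular-window FFT power spectrum, scaled so that the sum of all
#' spectral bins equals the mean squared amplitude of the input (Parseval
#' consistency). A 2-s epoch therefore yields 0.5-Hz resolution.
#'
#' @param x numeric vector, one channel of one epoch.
#' @param fs sampling rate (Hz).
#' @param window `"rect"` (default, plain FFT) or `"hann"`.
#' @return data.frame with columns `freq` (Hz) and `power` (uV^2 per bin).
#' @export
epoch_spectrum <- function(x, fs, window = c("rect", "hann")) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 2L) stop("epoch too short for a spectrum", call. = FALSE)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w / sqrt(mean(w^2))  # preserve total power on average
  }
  X <- stats::fft(x)
  nyq <- n %/% 2L
  k <- 0:nyq
  p <- Mod(X[k + 1L])^2 / n^2
  # fold negative frequencies onto positive ones (not DC; not Nyquist if even n)
  interior <- k > 0L & !(n %% 2L == 0L & k == nyq)
  p[interior] <- 2 * p[interior]
  data.frame(freq = k * fs / n, power = p)
}

#' Average spectrum over the retained epochs of one channel
#'
#' @param epochs an [epoch_set()].
#' @param channel channel label.
#' @param window passed to [epoch_spectrum()].
#' @return data.frame `freq`, `power` (mean over non-rejected epochs).
#' @export
average_spectrum <- function(epochs, channel, window = "rect") {
  idx <- which(!epochs$rejected)
  if (!length(idx)) stop("all epochs rejected", call. = FALSE)
  ci <- match(channel, epochs$channel_labels)
  if (is.na(ci)) stop("unknown channel: ", channel, call. = FALSE)
  specs <- lapply(idx, function(i)
    epoch_spectrum(epochs$epochs[i, ci, ], epochs$fs, window = window)$power)
  ref <- epoch_spectrum(epochs$epochs[idx[1L], ci, ], epochs$fs,
                        window = window)
  data.frame(freq = ref$freq, power = Reduce(`+`, specs) / length(specs))
}

#' Absolute and relative band power
#'
#' Bins are assigned to the band whose half-open interval `[low, high)`
#' contains them; the final band also takes its upper edge. Relative power
#' is the band's share of the total over the scheme's full range.
#'
#' @param spectrum data.frame from [epoch_spectrum()].
#' @param scheme a [band_scheme()].
#' @return data.frame `band`, `low`, `high`, `absolute`, `relative`.
#' @export
band_powers <- function(spectrum, scheme = band_scheme()) {
  nb <- nrow(scheme)
  absolute <- vapply(seq_len(nb), function(b) {
    hi_ok <- if (b == nb) spectrum$freq <= scheme$high[b] + 1e-9
             else spectrum$freq < scheme$high[b] - 1e-9
    sum(spectrum$power[spectrum$freq >= scheme$low[b] - 1e-9 & hi_ok])
  }, numeric(1))
  total <- sum(absolute)
  data.frame(band = scheme$name, low = scheme$low, high = scheme$high,
             absolute = absolute,
             relative = if (total > 0) absolute / total else rep(NA_real_, nb),
             stringsAsFactors = FALSE)
}

#' Percent change of power relative to a reference
#'
#' `(p_inside / p_outside) * 100 - 100`: the percentage change of power
#' measured inside the scanner relative to the outside-scanner reference.
#'
#' @param p_inside,p_outside positive powers.
#' @return percent change; `NA` (flagged undefined) when `p_outside` is 0.
#' @export
percent_change <- function(p_inside, p_outside) {
  out <- (p_inside / p_outside) * 100 - 100
  out[p_outside == 0] <- NA_real_
  out
}

#' Eyes-closed / eyes-open alpha power ratio
#'
#' Mean alpha-band absolute power over the eyes-closed epochs of the listed
#' (occipital) channels, divided by the same quantity over the eyes-open
#' epochs. Only non-rejected epochs enter; at most `max_epochs` per
#' condition are used (the first available ones), mirroring the fixed
#' epoch budget of the reference analysis.
#'
#' @param epochs an [epoch_set()] with `"EC"`/`"EO"` condition labels.
#' @param channels channel labels, default `c("O1", "O2")`.
#' @param scheme a [band_scheme()]; the band named `"alpha"` is used.
#' @param max_epochs cap per condition (default 20; `Inf` for all).
#' @return scalar ratio.
#' @export
ec_eo_alpha_ratio <- function(epochs, channels = c("O1", "O2"),
                              scheme = band_scheme(), max_epochs = 20) {
  ci <- match(channels, epochs$channel_labels)
  if (anyNA(ci)) stop("requested channels not present", call. = FALSE)
  cond_power <- function(cond) {
    idx <- which(epochs$condition == cond & !epochs$rejected)
    if (!length(idx)) stop("no usable '", cond, "' epochs", call. = FALSE)
    idx <- utils::head(idx, max_epochs)
    p <- vapply(idx, function(i) mean(vapply(ci, function(ch) {
      sp <- epoch_spectrum(epochs$epochs[i, ch, ], epochs$fs)
      band_powers(sp, scheme)$absolute[scheme$name == "alpha"]
    }, numeric(1))), numeric(1))
    mean(p)
  }
  cond_power("EC") / cond_power("EO")
}

#' Individual alpha peak frequency and center of gravity
#'
#' The spectrum is smoothed with a Savitzky-Golay filter (default frame
#' width 11, polynomial order 5) and searched for an interior local maximum
#' within the alpha range (default 7-13 Hz) whose height exceeds the
#' smoothed spectrum at both range endpoints. The center of gravity is the
#' power-weighted mean frequency of the smoothed spectrum over the range.
#' When no qualifying local maximum exists, both estimates are `NA` and the
#' quality flag is set.
#'
#' @param spectrum data.frame `freq`, `power` covering at least 1-40 Hz.
#' @param frame odd Savitzky-Golay frame width (bins).
#' @param order polynomial order, must be `< frame`.
#' @param range two-element numeric search range in Hz.
#' @return list with `peak_hz`, `cog_hz`, `ok` (logical quality flag).
#' @export
alpha_peak_cog <- function(spectrum, frame = 11L, order = 5L,
                           range = c(7, 13)) {
  frame <- as.integer(frame); order <- as.integer(order)
  if (frame %% 2L == 0L || frame <= order)
    stop("Savitzky-Golay frame must be odd and exceed the order",
         call. = FALSE)
  if (max(spectrum$freq) < 40 || min(spectrum$freq) > 1)
    stop("spectrum must cover 1-40 Hz", call. = FALSE)
  sm <- signal::sgolayfilt(spectrum$power, p = order, n = frame)
  f <- spectrum$freq
  inr <- which(f >= range[1] & f <= range[2])
  if (length(inr) < 3L)
    stop("search range too narrow for the spectral resolution",
         call. = FALSE)
  lo <- sm[inr[1L]]; hi <- sm[inr[length(inr)]]
  interior <- inr[-c(1L, length(inr))]
  is_max <- vapply(interior, function(i)
    sm[i] >= sm[i - 1L] && sm[i] >= sm[i + 1L] &&
      sm[i] > lo && sm[i] > hi, logical(1))
  if (!any(is_max))
    return(list(peak_hz = NA_real_, cog_hz = NA_real_, ok = FALSE))
  cand <- interior[is_max]
  peak <- f[cand[which.max(sm[cand])]]
  w <- pmax(sm[inr], 0)
  cog <- sum(f[inr] * w) / sum(w)
  list(peak_hz = peak, cog_hz = cog, ok = TRUE)
}
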