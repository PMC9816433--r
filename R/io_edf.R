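# ---- minimal EDF+ reader/writer ------------------------------------------
# European Data Format: 256-byte ASCII main header, 256 ASCII bytes per
# signal (stored field-major), then 16-bit little-endian data records.
# Events travel in an "EDF Annotations" signal as TALs
# ("+onset\x14label\x14\x00"). Only the subset needed for EEG round-trips
# is implemented: one sampling rate for all signals, 1-s data records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, width - 2), width = -width, format = "fg")
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

# round x outward (floor/ceiling) at the highest decimal precision that
# still fits the 8-character header field, so every sample lies inside
# the stored physical range and the stored value parses back exactly
edf_num_outward <- function(x, width, up) {
  int_chars <- nchar(sprintf("%d", trunc(x))) + (x < 0 && trunc(x) == 0)
  d <- max(0L, width - int_chars - 1L)
  repeat {
    v <- if (up) ceiling(x * 10^d) / 10^d else floor(x * 10^d) / 10^d
    s <- formatC(v, format = "f", digits = d)
    s <- sub("0+$", "", s); s <- sub("\\.$", "", s)
    if (nchar(s) <= width) return(s)
    d <- d - 1L
  }
}

# TAL byte strings per 1-s record for the given events (0-based seconds)
edf_annotation_records <- function(events, fs, n_records) {
  onset_tal <- function(t, label = NULL) {
    body <- if (is.null(label)) "\x14\x14" else paste0("\x14", label, "\x14")
    paste0(sprintf("+%g", t), body)
  }
  recs <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    tals <- onset_tal(r - 1)
    for (lab in names(events)) {
      ev <- events[[lab]]
      sec <- (ev - 1) / fs
      hit <- sec >= (r - 1) & sec < r
      if (any(hit))
        tals <- c(tals, vapply(sec[hit], onset_tal, "", label = lab))
    }
    # each TAL is NUL-terminated; raw assembly since R strings cannot
    # carry NUL bytes
    recs[[r]] <- do.call(c, lapply(tals, function(s)
      c(charToRaw(s), as.raw(0))))
  }
  recs
}

#' Write a recording to an EDF+ file
#'
#' 16-bit EDF+C with 1-s data records; channel units are microvolts except
#' a channel labelled `"ECG"`, written as millivolts. Events are stored in
#' an `EDF Annotations` signal. Recordings whose length is not a whole
#' number of seconds are zero-padded to the next full record.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  n <- n_samples(rec)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  data <- rec$data
  if (pad > 0) data <- cbind(data, matrix(0, nrow(data), pad))
  nchan <- nrow(data)
  ann <- edf_annotation_records(rec$events, fs, n_rec)
  ann_bytes <- max(16L, max(vapply(ann, length, integer(1))) + 2L)
  if (ann_bytes %% 2L) ann_bytes <- ann_bytes + 1L
  ns <- nchan + 1L
  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  same <- pmax - pmin < 1e-12
  pmax[same] <- pmin[same] + 1
  # digitize against the header-rounded limits (rounded outward) so the
  # round trip is exact to 16-bit quantization
  pmin_str <- vapply(pmin, edf_num_outward, "", width = 8, up = FALSE)
  pmax_str <- vapply(pmax, edf_num_outward, "", width = 8, up = TRUE)
  pmin <- as.numeric(pmin_str); pmax <- as.numeric(pmax_str)
  units <- ifelse(rec$channel_labels == "ECG", "mV", "uV")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad((ns + 1L) * 256L, 8))
  wr(edf_pad("EDF+C", 44))
  wr(edf_pad(n_rec, 8)); wr(edf_pad(1, 8)); wr(edf_pad(ns, 4))
  field <- function(vals, width)
    for (v in vals) wr(edf_pad(v, width))
  field(c(rec$channel_labels, "EDF Annotations"), 16)
  field(rep("", ns), 80)
  field(c(units, ""), 8)
  field(c(pmin_str, "-1"), 8)
  field(c(pmax_str, "1"), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(c(rep(fs, nchan), ann_bytes / 2L), 8)
  field(rep("", ns), 32)
  scale <- (pmax - pmin) / 65535
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round((data[, cols, drop = FALSE] - pmin) / scale) - 32768
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
    a <- ann[[r]]
    writeBin(c(a, raw(ann_bytes - length(a))), con)
  }
  invisible(path)
}

# split raw annotation bytes into (onset seconds, label) pairs
parse_tals <- function(bytes) {
  chunks <- split(bytes, cumsum(bytes == as.raw(0)))
  out <- list()
  for (ch in chunks) {
    ch <- ch[ch != as.raw(0)]
    if (!length(ch)) next
    parts <- strsplit(rawToChar(ch), "\x14")[[1]]
    if (length(parts) < 2L) next        # bare record timestamp
    onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[1])))
    for (lab in parts[-1])
      if (nzchar(lab) && is.finite(onset))
        out[[length(out) + 1L]] <- list(onset = onset, label = lab)
  }
  out
}

#' Read an EDF/EDF+ file into a recording
#'
#' Supports the subset produced by [write_edf()] (common to most EEG EDF
#' exports): identical sampling rate across ordinary signals, 16-bit
#' samples, optional `EDF Annotations` signal whose TAL labels become event
#' trains.
#'
#' @param path EDF file path.
#' @return a [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (sz < 256) stop("not an EDF file (truncated header): ", path,
                     call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  readChar(con, 8)                       # version
  readChar(con, 160); readChar(con, 16)  # ids, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || sz < header_bytes)
    stop("corrupt EDF header: ", path, call. = FALSE)
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16); fld(80)
  units <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  is_ann <- labels == "EDF Annotations"
  expected <- header_bytes + 2 * sum(spr) * n_rec
  if (sz < expected)
    stop("truncated EDF data section: ", path, call. = FALSE)
  sig <- which(!is_ann)
  if (length(unique(spr[sig])) > 1L)
    stop("mixed sampling rates are not supported", call. = FALSE)
  fs <- spr[sig][1] / rec_dur
  if (!length(fs) || !is.finite(fs))
    stop("missing sampling rate metadata", call. = FALSE)
  data <- matrix(0, length(sig), n_rec * spr[sig][1])
  tals <- list()
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      if (is_ann[j]) {
        bytes <- readBin(con, "raw", 2 * spr[j])
        tals <- c(tals, parse_tals(bytes))
      } else {
        dig <- readBin(con, "integer", spr[j], size = 2, endian = "little")
        jj <- match(j, sig)
        cols <- ((r - 1L) * spr[j] + 1L):(r * spr[j])
        data[jj, cols] <- (dig - dmin[j]) / (dmax[j] - dmin[j]) *
          (pmax[j] - pmin[j]) + pmin[j]
      }
    }
  }
  events <- list()
  for (tl in tals) {
    s <- as.integer(round(tl$onset * fs)) + 1L
    events[[tl$label]] <- c(events[[tl$label]], s)
  }
  events <- lapply(events, function(x) sort(unique(x)))
  recording(data, fs, labels[sig], events = events,
            meta = list(path = path, units = units[sig]))
}
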