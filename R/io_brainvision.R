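# ---- BrainVision (.vhdr / .vmrk / .eeg) reader/writer --------------------
# Text header + text marker file + raw binary data (IEEE float32,
# multiplexed). Marker descriptions carry the event labels.

#' Write a recording as a BrainVision file triplet
#'
#' Produces `<stem>.vhdr` (header), `<stem>.vmrk` (markers; one marker per
#' event, description = event label, 1-based positions) and `<stem>.eeg`
#' (32-bit IEEE float, multiplexed channels, microvolt resolution 1).
#'
#' @param rec a [recording()].
#' @param path path of the `.vhdr` file (companion files are placed next
#'   to it).
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stem <- sub("\\.vhdr$", "", path)
  base <- basename(stem)
  vhdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    vapply(seq_len(nrow(rec$data)), function(i)
      sprintf("Ch%d=%s,,1,%s", i, rec$channel_labels[i],
              if (rec$channel_labels[i] == "ECG") "mV" else "µV"), ""))
  writeLines(vhdr, paste0(stem, ".vhdr"))
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  i <- 1L
  for (lab in names(rec$events))
    for (s in rec$events[[lab]]) {
      i <- i + 1L
      mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0", i, lab, s))
    }
  writeLines(mk, paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(paste0(stem, ".vhdr"))
}

# parse "key=value" lines of one INI section
bv_section <- function(lines, name) {
  start <- grep(sprintf("^\\[%s\\]", name), lines)
  if (!length(start)) return(character(0))
  rest <- lines[(start[1] + 1L):length(lines)]
  stop_at <- grep("^\\[", rest)
  if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1L)]
  rest[grepl("=", rest, fixed = TRUE)]
}

bv_value <- function(kv, key) {
  hit <- grep(paste0("^", key, "="), kv, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision file triplet into a recording
#'
#' Supports multiplexed binary data in IEEE float32 or signed 16-bit
#' format, with markers read from the companion `.vmrk` file
#' (marker description = event label).
#'
#' @param path path of the `.vhdr` header file.
#' @return a [recording()].
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("Brain Vision", lines[1], fixed = TRUE))
    stop("not a BrainVision header: ", path, call. = FALSE)
  common <- bv_section(lines, "Common Infos")
  nchan <- as.integer(bv_value(common, "NumberOfChannels"))
  si <- as.numeric(bv_value(common, "SamplingInterval"))
  if (is.na(si)) stop("missing sampling rate metadata", call. = FALSE)
  fs <- 1e6 / si
  fmt <- bv_value(bv_section(lines, "Binary Infos"), "BinaryFormat")
  chinfo <- bv_section(lines, "Channel Infos")
  labels <- vapply(seq_len(nchan), function(i) {
    v <- bv_value(chinfo, sprintf("Ch%d", i))
    strsplit(v, ",")[[1]][1]
  }, "")
  res <- vapply(seq_len(nchan), function(i) {
    v <- strsplit(bv_value(chinfo, sprintf("Ch%d", i)), ",")[[1]]
    if (length(v) >= 3 && nzchar(v[3])) as.numeric(v[3]) else 1
  }, numeric(1))
  dir <- dirname(path)
  data_file <- file.path(dir, bv_value(common, "DataFile"))
  if (!file.exists(data_file))
    stop("missing data file: ", data_file, call. = FALSE)
  sz <- file.info(data_file)$size
  bytes <- if (identical(fmt, "INT_16")) 2L else 4L
  n <- as.integer(sz / bytes / nchan)
  if (n < 1L) stop("truncated BrainVision data file", call. = FALSE)
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw_vals <- if (bytes == 2L)
    readBin(con, "integer", n * nchan, size = 2, endian = "little")
  else readBin(con, "numeric", n * nchan, size = 4, endian = "little")
  data <- matrix(raw_vals, nrow = nchan) * res
  events <- list()
  marker_file <- file.path(dir, bv_value(common, "MarkerFile"))
  if (!is.na(marker_file) && file.exists(marker_file)) {
    mk <- bv_section(readLines(marker_file, warn = FALSE), "Marker Infos")
    for (m in mk) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", m), ",")[[1]]
      if (length(parts) >= 3 && nzchar(parts[2]))
        events[[parts[2]]] <- c(events[[parts[2]]],
                                as.integer(parts[3]))
    }
    events <- lapply(events, function(x) sort(unique(x)))
  }
  recording(data, fs, labels, events = events, meta = list(path = path))
}

#' Read or write a recording in a named dialect
#'
#' Thin dispatchers over [read_edf()]/[write_edf()] and
#' [read_brainvision()]/[write_brainvision()]; the dialect defaults to the
#' file extension (`.edf` or `.vhdr`).
#'
#' @param path file path.
#' @param rec a [recording()] (writer only).
#' @param dialect `"EDF"` or `"BrainVision"`.
#' @return `read_recording()`: a [recording()]; `write_recording()`: the
#'   path, invisibly.
#' @export
read_recording <- function(path, dialect = c("auto", "EDF", "BrainVision")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vhdr$", path, ignore.case = TRUE))
      "BrainVision" else "EDF"
  switch(dialect, EDF = read_edf(path), BrainVision = read_brainvision(path))
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path,
                            dialect = c("auto", "EDF", "BrainVision")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vhdr$", path, ignore.case = TRUE))
      "BrainVision" else "EDF"
  switch(dialect,
         EDF = write_edf(rec, path),
         BrainVision = write_brainvision(rec, path))
}
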