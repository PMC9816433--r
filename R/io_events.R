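#' Read / write event trains as TSV
#'
#' Events travel as a two-column tab-separated file `label`, `sample`.
#' On disk samples are 0-based (the convention of most event-file formats);
#' in memory they are 1-based. Duplicated (label, sample) rows are
#' deduplicated with a warning; rows are sorted per label.
#'
#' @param path TSV file path.
#' @param events named list of integer event trains (1-based).
#' @return `read_events()`: named list of sorted integer trains;
#'   `write_events()`: `path`, invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "sample") %in% names(df)))
    stop("event file must have 'label' and 'sample' columns", call. = FALSE)
  bad <- suppressWarnings(abs(as.numeric(df$sample) -
                                round(as.numeric(df$sample))) > 1e-9)
  if (anyNA(as.numeric(df$sample)) || any(bad, na.rm = TRUE))
    stop("non-integer sample index in event file", call. = FALSE)
  out <- lapply(split(as.integer(df$sample) + 1L, df$label), function(x) {
    if (anyDuplicated(x))
      warning("duplicated event samples deduplicated", call. = FALSE)
    sort(unique(x))
  })
  out
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  df <- do.call(rbind, lapply(names(events), function(lab)
    data.frame(label = lab, sample = as.integer(events[[lab]]) - 1L,
               stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(label = character(0),
                                    sample = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
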