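#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis pipeline in one flat
#' list. Defaults reproduce the standard settings of the workflow: 1-50 Hz
#' band-pass, 2-s epochs, a 210-ms delay between the R peak and the main BCG
#' deflection, a 5-volume sliding window for gradient-artifact AAS, a
#' 21-cycle window for BCG AAS, 4 principal components for OBS,
#' Savitzky-Golay frame 11 / order 5 with a 7-13 Hz alpha search range, a
#' gamma HRF peaking at 6 s, and a 150 uV peak-to-peak epoch rejection
#' threshold.
#'
#' @param epoch_s epoch length in seconds.
#' @param filter_low,filter_high band-pass edges in Hz.
#' @param bcg_delay_s delay from R peak to main BCG peak, seconds.
#' @param ga_window_volumes sliding-window width (TR volumes) for GA AAS.
#' @param bcg_window_cycles sliding-window width (cardiac cycles) for BCG AAS.
#' @param obs_n_pcs number of principal components removed by OBS.
#' @param sg_frame,sg_order Savitzky-Golay frame width (odd) and polynomial
#'   order for alpha-peak estimation.
#' @param alpha_range two-element search range (Hz) for the alpha peak.
#' @param hrf_peak_s,hrf_sd_s gamma HRF mode and dispersion (seconds).
#' @param reject_uv peak-to-peak epoch rejection threshold (microvolts).
#' @param bands band scheme, see [band_scheme()].
#' @param seed integer random seed used by seeded stages.
#' @return a list of class `bcg_config`.
#' @export
pipeline_config <- function(epoch_s = 2, filter_low = 1, filter_high = 50,
                            bcg_delay_s = 0.21, ga_window_volumes = 5L,
                            bcg_window_cycles = 21L, obs_n_pcs = 4L,
                            sg_frame = 11L, sg_order = 5L,
                            alpha_range = c(7, 13),
                            hrf_peak_s = 6, hrf_sd_s = 3,
                            reject_uv = 150, bands = band_scheme(),
                            seed = 1L) {
  cfg <- list(epoch_s = epoch_s, filter_low = filter_low,
              filter_high = filter_high, bcg_delay_s = bcg_delay_s,
              ga_window_volumes = as.integer(ga_window_volumes),
              bcg_window_cycles = as.integer(bcg_window_cycles),
              obs_n_pcs = as.integer(obs_n_pcs),
              sg_frame = as.integer(sg_frame),
              sg_order = as.integer(sg_order),
              alpha_range = as.numeric(alpha_range),
              hrf_peak_s = hrf_peak_s, hrf_sd_s = hrf_sd_s,
              reject_uv = reject_uv, bands = bands, seed = as.integer(seed))
  class(cfg) <- "bcg_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$epoch_s <= 0) stop("epoch length must be positive", call. = FALSE)
  if (cfg$filter_low >= cfg$filter_high)
    stop("filter low edge must be below high edge", call. = FALSE)
  counts <- c(cfg$ga_window_volumes, cfg$bcg_window_cycles, cfg$sg_frame)
  if (any(counts < 1L)) stop("window counts must be >= 1", call. = FALSE)
  if (cfg$obs_n_pcs < 0L) stop("obs_n_pcs must be >= 0", call. = FALSE)
  if (length(cfg$alpha_range) != 2L || diff(cfg$alpha_range) <= 0)
    stop("alpha_range must be an increasing pair of frequencies",
         call. = FALSE)
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as flat YAML (or JSON) key-value files; the band
#' scheme is stored as parallel `band_names` / `band_low` / `band_high`
#' vectors.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg a [pipeline_config()].
#' @return `read_config()` returns a `bcg_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  bands <- if (!is.null(raw$band_names))
    band_scheme(raw$band_names, raw$band_low, raw$band_high)
  else band_scheme()
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, c(raw[keep], list(bands = bands)))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  flat <- cfg[setdiff(names(cfg), "bands")]
  flat$band_names <- cfg$bands$name
  flat$band_low <- cfg$bands$low
  flat$band_high <- cfg$bands$high
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(flat, path)
  invisible(path)
}
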