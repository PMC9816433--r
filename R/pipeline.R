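#' Apply one BCG correction method by name
#'
#' Dispatcher over the eight BCG handling strategies (plus `"none"`):
#' `"aas"`, `"obs"`, `"ica"`, `"obs-ica"`, `"aas-ica"`, `"projic-aas"`,
#' `"projic-obs"` and `"ife"`. ICA-based methods accept a pre-fitted,
#' scored decomposition through `ica` to avoid refitting.
#'
#' @param rec a GA-corrected, band-passed [recording()].
#' @param method method name (see above).
#' @param rpeaks integer R-peak train (default: the recording's `RPEAK`).
#' @param cfg a [pipeline_config()].
#' @param ica optional scored [fit_ica()] decomposition of `rec`.
#' @param seed seed for ICA fits.
#' @param thin ICA thinning factor (see [fit_ica()]).
#' @return list: `recording`, `report` (and `ica` where one was fitted).
#' @export
correct_bcg <- function(rec, method,
                        rpeaks = get_events(rec, "RPEAK", required = TRUE),
                        cfg = pipeline_config(), ica = NULL, seed = 1L,
                        thin = 1L) {
  need_ica <- method %in% c("ica", "projic-aas", "projic-obs", "ife")
  if (need_ica && is.null(ica)) {
    ica <- fit_ica(rec, n_components = min(8L, sum(eeg_rows(rec) > 0)),
                   thin = thin, seed = seed)
    ica <- score_bcg_components(ica, rpeaks, seed = seed)
  }
  switch(method,
    "none" = list(recording = rec,
                  report = list(method = "none", params = list())),
    "aas" = bcg_aas(rec, rpeaks, cfg$bcg_delay_s, cfg$bcg_window_cycles),
    "obs" = bcg_obs(rec, rpeaks, cfg$bcg_delay_s, cfg$obs_n_pcs),
    "ica" = {
      sel <- ica$selected$bcg
      corrected <- remove_components(ica, sel)
      list(recording = corrected, ica = ica,
           report = list(method = "ica", params = list(removed = sel)))
    },
    "obs-ica" = bcg_combined(rec, rpeaks, "OBS", cfg$bcg_delay_s,
                             cfg$bcg_window_cycles, cfg$obs_n_pcs,
                             n_components = 8L, seed = seed),
    "aas-ica" = bcg_combined(rec, rpeaks, "AAS", cfg$bcg_delay_s,
                             cfg$bcg_window_cycles, cfg$obs_n_pcs,
                             n_components = 8L, seed = seed),
    "projic-aas" = c(projic(rec, ica, inner = "AAS", rpeaks = rpeaks,
                            delay_s = cfg$bcg_delay_s,
                            window_cycles = cfg$bcg_window_cycles),
                     list(ica = ica)),
    "projic-obs" = c(projic(rec, ica, inner = "OBS", rpeaks = rpeaks,
                            delay_s = cfg$bcg_delay_s,
                            n_pcs = cfg$obs_n_pcs),
                     list(ica = ica)),
    "ife" = c(ife_alpha(ica), list(ica = ica)),
    stop("unknown correction method: ", method, call. = FALSE))
}

# band-power table of one epoched recording: one row per channel x band
subject_band_table <- function(epochs, scheme) {
  rows <- lapply(epochs$channel_labels, function(ch) {
    bp <- band_powers(average_spectrum(epochs, ch), scheme)
    data.frame(channel = ch, band = bp$band, absolute = bp$absolute,
               relative = bp$relative, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full simulated-cohort evaluation
#'
#' For each simulated subject: gradient-artifact AAS, 1-50 Hz band-pass,
#' QRS detection from the simulated ECG, every requested BCG correction
#' method, band-power and EC-EO reactivity metrics, and an alpha-predictor
#' GLM against the subject's synthetic BOLD grid. Across subjects:
#' repeated-measures ANOVAs (with Bonferroni post-hocs against the clean
#' outside-scanner reference) on log absolute power, relative power and the
#' EC-EO ratio. All tables are written as CSV under `out_dir` together with
#' a JSON run manifest; per-subject tables are cached so a re-run with
#' existing outputs skips completed subjects and reproduces identical
#' final tables.
#'
#' @param cfg a [sim_config()] describing the cohort's study conditions.
#' @param n_subjects cohort size.
#' @param methods subset of
#'   `c("none","aas","obs","ica","obs-ica","aas-ica","projic-aas",
#'   "projic-obs","ife")`.
#' @param out_dir output directory (created if needed).
#' @param pcfg a [pipeline_config()].
#' @param glm_methods methods for which the EEG-informed GLM is run
#'   (default: all requested methods).
#' @param resume reuse cached per-subject tables when present.
#' @param thin ICA thinning factor used by ICA-based methods.
#' @return the run manifest (list), invisibly; side effect: CSV/JSON files
#'   under `out_dir`.
#' @export
run_cohort <- function(cfg = sim_config(), n_subjects = 3,
                       methods = c("none", "aas", "obs", "ica", "ife"),
                       out_dir, pcfg = pipeline_config(),
                       glm_methods = methods, resume = TRUE, thin = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subj_dir <- file.path(out_dir, "subjects")
  dir.create(subj_dir, showWarnings = FALSE)
  scheme <- pcfg$bands
  cfgs <- cohort_configs(cfg, n_subjects)
  warnings_log <- character(0)
  per_subject <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cache <- file.path(subj_dir, sprintf("subject_%02d.csv", i))
    cache_r <- file.path(subj_dir, sprintf("subject_%02d_summary.csv", i))
    if (resume && file.exists(cache) && file.exists(cache_r)) {
      per_subject[[i]] <- list(
        bands = utils::read.csv(cache, stringsAsFactors = FALSE),
        summary = utils::read.csv(cache_r, stringsAsFactors = FALSE))
      next
    }
    sub <- assemble_subject(cfgs[[i]])
    ga <- ga_aas(sub$recording, window_volumes = pcfg$ga_window_volumes)
    bp <- bandpass(ga$recording, pcfg$filter_low, pcfg$filter_high)
    rpeaks <- detect_qrs(select_channels(bp, "ECG"))
    eeg <- select_channels(bp, setdiff(bp$channel_labels, "ECG"))
    # outside-scanner reference: the clean component of the simulation
    block_ev <- sub$recording$events[intersect(
      names(sub$recording$events), c("EC_ONSET", "EO_ONSET"))]
    outside <- bandpass(recording(sub$truth$clean, cfg$fs,
                                  rownames(sub$truth$clean),
                                  events = block_ev),
                        pcfg$filter_low, pcfg$filter_high)
    shared_ica <- NULL
    bands_rows <- list(); summary_rows <- list()
    for (m in c("outside", methods)) {
      rec_m <- if (m == "outside") outside else {
        res <- correct_bcg(eeg, m, rpeaks, pcfg, ica = shared_ica,
                           seed = pcfg$seed, thin = thin)
        if (!is.null(res$ica)) shared_ica <- res$ica
        res$recording
      }
      ep <- reject_epochs(epoch_recording(rec_m, pcfg$epoch_s),
                          pcfg$reject_uv)
      bt <- subject_band_table(ep, scheme)
      bt$subject <- i; bt$method <- m
      bands_rows[[m]] <- bt
      ratio <- tryCatch(ec_eo_alpha_ratio(ep, scheme = scheme),
                        error = function(e) NA_real_)
      glm_sens <- glm_fpr <- NA_real_
      if (m %in% glm_methods || m == "outside") {
        nv <- ncol(sub$truth$bold)
        pred <- tryCatch(
          build_predictor(ep, "auto", scheme, n_volumes = nv,
                          tr_s = cfg$ga_tr_s, peak_s = pcfg$hrf_peak_s,
                          sd_s = pcfg$hrf_sd_s),
          error = function(e) NULL)
        if (!is.null(pred)) {
          fit <- glm_fit(sub$truth$bold, pred$predictor)
          glm_sens <- mean(fit$mask[sub$truth$coupled])
          glm_fpr <- mean(fit$mask[!sub$truth$coupled])
        }
      }
      summary_rows[[m]] <- data.frame(
        subject = i, method = m, ec_eo_ratio = ratio,
        true_ratio = sub$truth$true_ratio,
        n_rejected = sum(ep$rejected),
        glm_sensitivity = glm_sens, glm_fpr = glm_fpr,
        stringsAsFactors = FALSE)
    }
    per_subject[[i]] <- list(bands = do.call(rbind, bands_rows),
                             summary = do.call(rbind, summary_rows))
    utils::write.csv(per_subject[[i]]$bands, cache, row.names = FALSE)
    utils::write.csv(per_subject[[i]]$summary, cache_r, row.names = FALSE)
  }
  bands <- do.call(rbind, lapply(per_subject, `[[`, "bands"))
  summary <- do.call(rbind, lapply(per_subject, `[[`, "summary"))
  rownames(bands) <- rownames(summary) <- NULL
  # percent change vs the outside reference, per subject/channel/band
  outside_abs <- bands[bands$method == "outside",
                       c("subject", "channel", "band", "absolute")]
  names(outside_abs)[4] <- "outside_absolute"
  pc <- merge(bands[bands$method != "outside", ], outside_abs,
              by = c("subject", "channel", "band"))
  pc$percent_change <- percent_change(pc$absolute, pc$outside_absolute)
  # repeated-measures inference per band: log10 absolute / relative power
  conds <- c("outside", methods)
  anova_table <- function(value_col, transform = identity) {
    do.call(rbind, lapply(scheme$name, function(b) {
      sub_b <- bands[bands$band == b, ]
      agg <- stats::aggregate(sub_b[[value_col]],
                              by = list(subject = sub_b$subject,
                                        method = sub_b$method), FUN = mean)
      y <- matrix(NA_real_, n_subjects, length(conds),
                  dimnames = list(NULL, conds))
      for (r in seq_len(nrow(agg)))
        y[agg$subject[r], agg$method[r]] <- transform(agg$x[r])
      res <- rm_anova(y)
      ph <- bonferroni_posthoc(y, "outside")
      data.frame(band = b, F = res$F, df1 = res$df1, df2 = res$df2,
                 epsilon = res$epsilon, p = res$p,
                 method = ph$condition, p_adjusted = ph$p_adjusted,
                 stringsAsFactors = FALSE)
    }))
  }
  rm_abs <- if (n_subjects >= 3) anova_table("absolute", log10) else NULL
  rm_rel <- if (n_subjects >= 3) anova_table("relative") else NULL
  ratio_anova <- NULL
  if (n_subjects >= 3) {
    ym <- matrix(NA_real_, n_subjects, length(conds),
                 dimnames = list(NULL, conds))
    for (r in seq_len(nrow(summary)))
      ym[summary$subject[r], summary$method[r]] <- summary$ec_eo_ratio[r]
    if (!anyNA(ym)) {
      res <- rm_anova(ym)
      ph <- bonferroni_posthoc(ym, "outside")
      ratio_anova <- data.frame(F = res$F, df1 = res$df1, df2 = res$df2,
                                epsilon = res$epsilon, p = res$p,
                                method = ph$condition,
                                p_adjusted = ph$p_adjusted,
                                stringsAsFactors = FALSE)
    }
  }
  outputs <- list(spectral = "spectral.csv",
                  percent_change = "percent_change.csv",
                  summary = "summary.csv")
  utils::write.csv(bands, file.path(out_dir, "spectral.csv"),
                   row.names = FALSE)
  utils::write.csv(pc, file.path(out_dir, "percent_change.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(rm_abs)) {
    utils::write.csv(rm_abs, file.path(out_dir, "rm_anova_absolute.csv"),
                     row.names = FALSE)
    outputs$rm_anova_absolute <- "rm_anova_absolute.csv"
  }
  if (!is.null(rm_rel)) {
    utils::write.csv(rm_rel, file.path(out_dir, "rm_anova_relative.csv"),
                     row.names = FALSE)
    outputs$rm_anova_relative <- "rm_anova_relative.csv"
  }
  if (!is.null(ratio_anova)) {
    utils::write.csv(ratio_anova, file.path(out_dir, "ratio_anova.csv"),
                     row.names = FALSE)
    outputs$ratio_anova <- "ratio_anova.csv"
  }
  manifest <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("bcgpreserve")),
      error = function(e) "devel"),
    seeds = vapply(cfgs, `[[`, integer(1), "seed"),
    n_subjects = n_subjects, methods = methods,
    sim_config = cfg[setdiff(names(cfg),
                             c("alpha_topography", "bcg_topography"))],
    outputs = lapply(outputs, function(f) file.path(out_dir, f)),
    warnings = warnings_log)
  missing_out <- !vapply(manifest$outputs, file.exists, logical(1))
  if (any(missing_out))
    stop("declared outputs missing: ",
         paste(unlist(manifest$outputs)[missing_out], collapse = ", "),
         call. = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
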