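#' Simulation configuration
#'
#' Parameters of the synthetic EEG-fMRI subject generator. The defaults
#' emulate the acquisition this package targets: an 18-channel 10-20 montage
#' sampled at 1000 Hz, a 1/f background, a 10-Hz posterior alpha rhythm
#' whose amplitude follows alternating 20-s eyes-closed / eyes-open blocks
#' (eyes-closed amplitude sqrt(3) times eyes-open, i.e. a true EC/EO power
#' ratio of 3), an ECG channel with jittered RR intervals around 0.9 s, a
#' cardiac-locked BCG artifact starting 210 ms after each R peak built from
#' damped harmonics of the cardiac fundamental (power concentrated in
#' 1-15 Hz, left-right polarity inversion across the scalp), a TR-locked
#' gradient artifact (TR = 2 s) dwarfing the EEG, and a BOLD grid whose
#' coupled voxels follow the HRF-convolved alpha power with negative sign.
#'
#' @param seed integer seed; `assemble_subject()` seeds the RNG with it.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz).
#' @param channels EEG channel labels (default the 18 10-20 electrodes).
#' @param background_exponent spectral exponent of the 1/f background.
#' @param background_rms_uv RMS amplitude of the background per channel (uV).
#' @param alpha_freq_hz alpha oscillation frequency (7-13 Hz).
#' @param alpha_ec_uv,alpha_eo_uv alpha amplitude (uV) during EC / EO blocks
#'   at a topography weight of 1.
#' @param alpha_phase_diffusion phase random-walk diffusion of the alpha
#'   oscillator (rad^2 per second). Real alpha keeps phase coherence only
#'   over a few cycles; a non-zero diffusion ensures the oscillation is not
#'   spuriously phase-locked to the TR or cardiac grids, while leaving the
#'   instantaneous band power (`amplitude^2 / 2`) exact.
#' @param alpha_topography named channel weights of the alpha source.
#' @param block_s block length of the EC-EO task (s).
#' @param start_condition `"EC"` or `"EO"`; first block's condition.
#' @param task if `FALSE` the whole recording is eyes-closed rest.
#' @param rr_mean_s,rr_jitter_s mean RR interval and its uniform jitter (s).
#' @param bcg_delay_s delay from R peak to BCG onset (s).
#' @param bcg_cycle_s duration of one BCG cycle waveform (s).
#' @param bcg_amp_uv peak amplitude of the BCG waveform (uV) at weight 1.
#' @param bcg_harmonics multiples of the cardiac fundamental composing the
#'   BCG waveform.
#' @param bcg_harmonic_amps relative amplitude of each harmonic. The
#'   default emphasises the theta and slow-beta region and carries a
#'   strong 10-Hz component, reproducing the artifact's hallmark of
#'   masking occipital alpha reactivity.
#' @param bcg_damping_s exponential damping time constant of each cycle (s).
#' @param bcg_amp_jitter fractional cycle-to-cycle amplitude jitter in
#'   `[0, 1]`.
#' @param bcg_topography named channel weights (antisymmetric left-right).
#' @param ga_tr_s fMRI repetition time (s).
#' @param ga_slices slices per TR (sets the slice-harmonic comb frequency).
#' @param ga_scale gradient-artifact RMS as a multiple of the clean-EEG RMS
#'   (0 disables the GA).
#' @param bold_dim integer length-3 grid dimensions of the synthetic BOLD.
#' @param bold_n_volumes number of volumes (one per TR).
#' @param bold_coupled_frac fraction of voxels coupled to alpha power.
#' @param bold_coupled_seed optional separate seed for drawing the coupled
#'   voxel set; give every subject of a cohort the same value to share one
#'   coupled mask (required for group-level inference on the grid).
#' @param bold_beta coupling coefficient (negative: alpha suppresses BOLD).
#' @param bold_ar AR(1) coefficient of the BOLD noise.
#' @param bold_sd innovation SD of the BOLD noise.
#' @return list of class `bcg_sim_config`.
#' @export
sim_config <- function(seed = 1L, duration_s = 240, fs = 1000,
                       channels = standard_channels(),
                       background_exponent = 1, background_rms_uv = 5,
                       alpha_freq_hz = 10,
                       alpha_ec_uv = 10 * sqrt(3), alpha_eo_uv = 10,
                       alpha_phase_diffusion = 2,
                       alpha_topography = default_alpha_topography(channels),
                       block_s = 20, start_condition = "EC", task = TRUE,
                       rr_mean_s = 0.9, rr_jitter_s = 0.05,
                       bcg_delay_s = 0.21, bcg_cycle_s = 0.6,
                       bcg_amp_uv = 80,
                       bcg_harmonics = c(5, 6, 7, 9, 12),
                       bcg_harmonic_amps = c(1, 1, 1, 2, 1),
                       bcg_damping_s = 0.25, bcg_amp_jitter = 0.1,
                       bcg_topography = default_bcg_topography(channels),
                       ga_tr_s = 2, ga_slices = 30, ga_scale = 50,
                       bold_dim = c(10, 10, 10), bold_n_volumes = 120,
                       bold_coupled_frac = 0.1, bold_coupled_seed = NULL,
                       bold_beta = -1, bold_ar = 0.3, bold_sd = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "bcg_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  amp <- c(cfg$background_rms_uv, cfg$alpha_ec_uv, cfg$alpha_eo_uv,
           cfg$bcg_amp_uv, cfg$ga_scale, cfg$bold_sd)
  if (any(amp < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (cfg$bcg_amp_jitter < 0 || cfg$bcg_amp_jitter > 1)
    stop("bcg_amp_jitter must lie in [0, 1]", call. = FALSE)
  if (cfg$alpha_freq_hz < 7 || cfg$alpha_freq_hz > 13)
    stop("alpha_freq_hz must lie within 7-13 Hz", call. = FALSE)
  if (cfg$rr_mean_s <= cfg$bcg_delay_s)
    stop("mean RR interval must exceed the BCG onset delay", call. = FALSE)
  if (cfg$rr_jitter_s >= cfg$rr_mean_s)
    stop("RR jitter must be smaller than the mean RR interval",
         call. = FALSE)
  if (cfg$duration_s <= 0 || cfg$fs <= 0)
    stop("duration and sampling rate must be positive", call. = FALSE)
  invisible(cfg)
}

#' Default source topographies
#'
#' `default_alpha_topography()` weights posterior electrodes heavily
#' (occipital 1.0 tapering to near 0 frontally); `default_bcg_topography()`
#' encodes the left-right polarity inversion characteristic of the BCG
#' artifact (mirror-image electrodes carry opposite signs, midline
#' electrodes near 0).
#'
#' @param channels channel labels; unknown labels get a small default
#'   weight (alpha) or 0 (BCG).
#' @return named numeric vector over `channels`.
#' @export
default_alpha_topography <- function(channels = standard_channels()) {
  w <- c(Fp1 = 0.05, Fp2 = 0.05, F3 = 0.1, F4 = 0.1, F7 = 0.1, F8 = 0.1,
         Fz = 0.1, C3 = 0.2, C4 = 0.2, P3 = 0.7, P4 = 0.7, Pz = 0.8,
         T3 = 0.2, T4 = 0.2, T5 = 0.6, T6 = 0.6, O1 = 1, O2 = 1)
  out <- w[channels]
  out[is.na(out)] <- 0.1
  names(out) <- channels
  out
}

#' @rdname default_alpha_topography
#' @export
default_bcg_topography <- function(channels = standard_channels()) {
  w <- c(Fp1 = 0.7, Fp2 = -0.7, F3 = 0.8, F4 = -0.8, F7 = 0.9, F8 = -0.9,
         Fz = 0.05, C3 = 0.85, C4 = -0.85, P3 = 0.9, P4 = -0.9, Pz = -0.1,
         T3 = 1, T4 = -1, T5 = 0.95, T6 = -0.95, O1 = 0.8, O2 = -0.8)
  out <- w[channels]
  out[is.na(out)] <- 0
  names(out) <- channels
  out
}

# 1/f^exponent noise: random-phase spectral shaping of white noise,
# rescaled to the requested RMS
one_over_f_noise <- function(n, fs, exponent = 1, rms = 1) {
  nf <- (n - 1L) %/% 2L
  f <- (1:nf) * fs / n
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 1L)] <- Conj(spec)
  if (n %% 2L == 0L)  # real-valued Nyquist line
    full[n / 2L + 1L] <- complex(real = (fs / 2)^(-exponent / 2))
  x <- Re(stats::fft(full, inverse = TRUE))
  x * rms / stats::sd(x)
}

# per-sample condition vector and block-onset events for the EC-EO design
block_design <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  if (!cfg$task)
    return(list(condition = rep("EC", n),
                events = list(EC_ONSET = 1L)))
  block_n <- round(cfg$block_s * cfg$fs)
  if (n < block_n)
    stop("duration must cover at least one task block", call. = FALSE)
  starts <- seq(1L, n, by = block_n)
  conds <- rep(c(cfg$start_condition,
                 setdiff(c("EC", "EO"), cfg$start_condition)),
               length.out = length(starts))
  condition <- rep(conds, times = diff(c(starts, n + 1L)))
  list(condition = condition,
       events = list(EC_ONSET = starts[conds == "EC"],
                     EO_ONSET = starts[conds == "EO"]))
}

#' Generate clean (artifact-free) task EEG
#'
#' Each channel is an independent 1/f background plus a shared alpha source
#' `envelope(t) * sin(2 pi f t)` scaled by the channel's topography weight,
#' where the envelope takes the EC amplitude during eyes-closed blocks and
#' the EO amplitude during eyes-open blocks. Block-onset events are
#' attached. The true EC/EO alpha band-power ratio of the pure source is
#' `(alpha_ec_uv / alpha_eo_uv)^2`.
#'
#' Uses the current RNG state; seed beforehand (or via
#' [assemble_subject()]) for reproducibility.
#'
#' @param cfg a [sim_config()].
#' @return list: `recording` (EEG channels only), `alpha_source` (length-n
#'   vector at weight 1), `condition` (per-sample label), `true_ratio`.
#' @export
gen_clean_eeg <- function(cfg) {
  validate_sim_config(cfg)
  n <- round(cfg$duration_s * cfg$fs)
  des <- block_design(cfg)
  amp <- ifelse(des$condition == "EC", cfg$alpha_ec_uv, cfg$alpha_eo_uv)
  t <- (seq_len(n) - 1L) / cfg$fs
  phi <- if (cfg$alpha_phase_diffusion > 0)
    cumsum(stats::rnorm(n, 0, sqrt(cfg$alpha_phase_diffusion / cfg$fs)))
  else 0
  alpha_source <- amp * sin(2 * pi * cfg$alpha_freq_hz * t + phi)
  topo <- cfg$alpha_topography[cfg$channels]
  data <- matrix(0, length(cfg$channels), n,
                 dimnames = list(cfg$channels, NULL))
  for (i in seq_along(cfg$channels))
    data[i, ] <- topo[i] * alpha_source +
      one_over_f_noise(n, cfg$fs, cfg$background_exponent,
                       cfg$background_rms_uv)
  rec <- recording(data, cfg$fs, cfg$channels, events = des$events,
                   reference = "Cz", meta = list(source = "simulated clean"))
  list(recording = rec, alpha_source = alpha_source,
       condition = des$condition,
       true_ratio = (cfg$alpha_ec_uv / cfg$alpha_eo_uv)^2)
}

# one QRS-like complex (Q, R, S deflections plus T wave), peak exactly at 0;
# t in seconds, output in millivolts
qrs_waveform <- function(t) {
  g <- function(mu, sd) exp(-((t - mu)^2) / (2 * sd^2))
  1.0 * g(0, 0.01) - 0.15 * g(-0.025, 0.008) - 0.25 * g(0.03, 0.01) +
    0.2 * g(0.25, 0.05)
}

#' Generate a synthetic ECG channel with ground-truth R peaks
#'
#' R times are laid down with RR intervals drawn uniformly from
#' `rr_mean_s +/- rr_jitter_s`; a QRS-like waveform (sharp R deflection,
#' small Q/S troughs, broad T wave; millivolts) is placed at each R time
#' over a small amount of white measurement noise.
#'
#' @param cfg a [sim_config()].
#' @return list: `recording` (single `"ECG"` channel, mV) and `rpeaks`
#'   (integer ground-truth train).
#' @export
gen_ecg <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$rr_mean_s <= 0.3)
    stop("mean RR interval must exceed 0.3 s", call. = FALSE)
  n <- round(cfg$duration_s * cfg$fs)
  t_max <- cfg$duration_s
  times <- c()
  t_cur <- 0.5
  while (t_cur < t_max - 0.5) {
    times <- c(times, t_cur)
    t_cur <- t_cur + cfg$rr_mean_s +
      stats::runif(1, -cfg$rr_jitter_s, cfg$rr_jitter_s)
  }
  rpeaks <- as.integer(round(times * cfg$fs)) + 1L
  x <- stats::rnorm(n, 0, 0.02)
  half <- round(0.4 * cfg$fs)
  rel_t <- (-half:half) / cfg$fs
  w <- qrs_waveform(rel_t)
  for (r in rpeaks) {
    idx <- (r - half):(r + half)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + w[ok]
  }
  rec <- recording(matrix(x, 1, n, dimnames = list("ECG", NULL)), cfg$fs,
                   "ECG", events = list(RPEAK = rpeaks),
                   meta = list(units = "mV"))
  list(recording = rec, rpeaks = rpeaks)
}

# unit-peak BCG cycle waveform: damped sum of harmonics of the cardiac
# fundamental, zero at onset
bcg_cycle_waveform <- function(cfg) {
  L <- round(cfg$bcg_cycle_s * cfg$fs)
  t <- (seq_len(L) - 1L) / cfg$fs
  f0 <- 1 / cfg$rr_mean_s
  amps <- cfg$bcg_harmonic_amps
  if (is.null(amps)) amps <- rep(1, length(cfg$bcg_harmonics))
  w <- rowSums(mapply(function(h, a) a * sin(2 * pi * h * f0 * t),
                      cfg$bcg_harmonics, amps)) *
    exp(-t / cfg$bcg_damping_s)
  w / max(abs(w))
}

#' Generate the ballistocardiographic artifact
#'
#' Each cardiac cycle contributes the same damped multi-harmonic waveform
#' starting `bcg_delay_s` after the R peak, multiplied per cycle by
#' `1 + U(-jitter, jitter)` and per channel by the (left-right
#' antisymmetric) BCG topography. With the default harmonics essentially
#' all artifact power lies within 1-15 Hz.
#'
#' @param cfg a [sim_config()].
#' @param rpeaks integer R-peak train (1-based samples).
#' @param n_samples total length of the output.
#' @return channels x n_samples artifact matrix (uV).
#' @export
gen_bcg_artifact <- function(cfg, rpeaks, n_samples) {
  validate_sim_config(cfg)
  if (length(rpeaks) && (min(rpeaks) < 1L || max(rpeaks) > n_samples))
    stop("R peaks outside the recording", call. = FALSE)
  w <- bcg_cycle_waveform(cfg) * cfg$bcg_amp_uv
  L <- length(w)
  delay <- round(cfg$bcg_delay_s * cfg$fs)
  topo <- cfg$bcg_topography[cfg$channels]
  src <- numeric(n_samples)
  for (r in rpeaks) {
    a <- 1 + (if (cfg$bcg_amp_jitter > 0)
      stats::runif(1, -cfg$bcg_amp_jitter, cfg$bcg_amp_jitter) else 0)
    idx <- (r + delay):(r + delay + L - 1L)
    ok <- idx >= 1L & idx <= n_samples
    src[idx[ok]] <- src[idx[ok]] + a * w[ok]
  }
  out <- outer(as.numeric(topo), src)
  rownames(out) <- cfg$channels
  out
}

#' Generate the gradient artifact
#'
#' A deterministic slice-harmonic comb (harmonics of the slice repetition
#' frequency `ga_slices / ga_tr_s`) repeated identically every TR, scaled so
#' its RMS is `ga_scale` times `clean_rms`, with a fixed per-channel gain
#' profile.
#'
#' @param cfg a [sim_config()].
#' @param tr_events integer TR-onset train (regular spacing).
#' @param n_samples total output length.
#' @param clean_rms reference RMS of the clean EEG (uV).
#' @return channels x n_samples artifact matrix (uV).
#' @export
gen_gradient_artifact <- function(cfg, tr_events, n_samples,
                                  clean_rms = cfg$background_rms_uv) {
  validate_sim_config(cfg)
  if (cfg$ga_scale == 0)
    return(matrix(0, length(cfg$channels), n_samples,
                  dimnames = list(cfg$channels, NULL)))
  if (length(tr_events) > 1L) {
    sp <- diff(tr_events)
    if (max(sp) - min(sp) > 1L)
      stop("TR markers must be regularly spaced", call. = FALSE)
  }
  L <- round(cfg$ga_tr_s * cfg$fs)
  t <- (seq_len(L) - 1L) / cfg$fs
  f_slice <- cfg$ga_slices / cfg$ga_tr_s
  seg <- rowSums(sapply(1:5, function(k) sin(2 * pi * k * f_slice * t) / k))
  seg <- seg * cfg$ga_scale * clean_rms / sqrt(mean(seg^2))
  src <- numeric(n_samples)
  for (s in tr_events) {
    idx <- s:(s + L - 1L)
    ok <- idx <= n_samples
    src[idx[ok]] <- seg[ok]
  }
  gains <- 1 + 0.2 * sin(seq_along(cfg$channels))  # fixed channel profile
  out <- outer(gains, src)
  rownames(out) <- cfg$channels
  out
}

#' Generate alpha-coupled synthetic BOLD data
#'
#' Coupled voxels follow `beta * z(HRF-convolved alpha power sampled at TR)`
#' plus AR(1) noise (`beta < 0` by default: alpha suppresses BOLD);
#' uncoupled voxels carry noise only.
#'
#' @param cfg a [sim_config()].
#' @param alpha_series per-epoch (= per-volume) alpha power values, length
#'   `bold_n_volumes`.
#' @return list: `bold` (voxels x volumes matrix), `coupled` (logical mask),
#'   `predictor` (the noiseless coupled time course at unit scale).
#' @export
gen_bold <- function(cfg, alpha_series) {
  validate_sim_config(cfg)
  nv <- cfg$bold_n_volumes
  if (length(alpha_series) != nv)
    stop("alpha_series length must equal the number of volumes",
         call. = FALSE)
  hrf <- gamma_hrf(cfg$ga_tr_s, peak_s = 6, sd_s = 3)
  conv <- stats::convolve(alpha_series, rev(hrf), type = "open")[seq_len(nv)]
  pred <- as.numeric(scale(conv))
  n_vox <- prod(cfg$bold_dim)
  n_coupled <- round(cfg$bold_coupled_frac * n_vox)
  coupled <- rep(FALSE, n_vox)
  if (n_coupled > 0 && cfg$bold_beta != 0) {
    idx <- if (!is.null(cfg$bold_coupled_seed)) {
      state <- get0(".Random.seed", envir = globalenv())
      set.seed(cfg$bold_coupled_seed)
      i <- sample.int(n_vox, n_coupled)
      if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
      i
    } else sample.int(n_vox, n_coupled)
    coupled[idx] <- TRUE
  }
  noise <- matrix(stats::rnorm(n_vox * nv, 0, cfg$bold_sd), n_vox, nv)
  if (cfg$bold_ar != 0)
    for (j in 2:nv) noise[, j] <- noise[, j] + cfg$bold_ar * noise[, j - 1L]
  bold <- noise
  if (any(coupled))
    bold[coupled, ] <- bold[coupled, ] +
      matrix(cfg$bold_beta * pred, sum(coupled), nv, byrow = TRUE)
  list(bold = bold, coupled = coupled, predictor = pred)
}

#' Assemble one fully contaminated synthetic subject
#'
#' Seeds the RNG with `cfg$seed`, then composes clean EEG, ECG with
#' ground-truth R peaks, the BCG artifact, the gradient artifact and the
#' alpha-coupled BOLD grid. The contaminated EEG equals
#' `clean + BCG + GA` sample-wise, which the returned ground-truth ledger
#' preserves exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (contaminated EEG + `"ECG"` row; events
#'   `TR`, `RPEAK`, `EC_ONSET`/`EO_ONSET`) and `truth`, a ledger holding
#'   `clean`, `bcg`, `ga` (matrices), `alpha_source`, `condition`,
#'   `rpeaks`, `true_ratio`, `epoch_alpha` (true per-epoch alpha power of
#'   the pure source at weight 1), `bold`, `coupled`, `beta`.
#' @export
assemble_subject <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  clean <- gen_clean_eeg(cfg)
  ecg <- gen_ecg(cfg)
  bcg <- gen_bcg_artifact(cfg, ecg$rpeaks, n)
  tr_events <- seq(1L, n, by = round(cfg$ga_tr_s * cfg$fs))
  clean_rms <- sqrt(mean(clean$recording$data^2))
  ga <- gen_gradient_artifact(cfg, tr_events, n, clean_rms)
  contaminated <- clean$recording$data + bcg + ga
  data <- rbind(contaminated, ECG = ecg$recording$data[1, ])
  events <- c(clean$recording$events,
              list(RPEAK = ecg$rpeaks, TR = tr_events))
  rec <- recording(data, cfg$fs, c(cfg$channels, "ECG"), events = events,
                   reference = "Cz",
                   meta = list(source = "simulated subject",
                               seed = cfg$seed))
  # true per-epoch alpha power of the pure alpha source at topography 1
  epoch_n <- round(2 * cfg$fs)
  n_epochs <- n %/% epoch_n
  epoch_cond <- clean$condition[(seq_len(n_epochs) - 1L) * epoch_n + 1L]
  epoch_alpha <- ifelse(epoch_cond == "EC",
                        cfg$alpha_ec_uv^2 / 2, cfg$alpha_eo_uv^2 / 2)
  n_vol <- min(cfg$bold_n_volumes, n_epochs)
  cfg_b <- cfg; cfg_b$bold_n_volumes <- n_vol
  bold <- gen_bold(cfg_b, epoch_alpha[seq_len(n_vol)])
  list(recording = rec,
       truth = list(clean = clean$recording$data, bcg = bcg, ga = ga,
                    alpha_source = clean$alpha_source,
                    condition = clean$condition,
                    epoch_condition = epoch_cond,
                    rpeaks = ecg$rpeaks, true_ratio = clean$true_ratio,
                    epoch_alpha = epoch_alpha,
                    bold = bold$bold, coupled = bold$coupled,
                    bold_predictor = bold$predictor, beta = cfg$bold_beta))
}

#' Per-subject configurations for a simulated cohort
#'
#' Returns `n_subjects` copies of `cfg` whose seeds are
#' `cfg$seed * 1000 + 1:n`, so subjects are distinct but the cohort is
#' reproducible from one master seed.
#'
#' @param cfg a [sim_config()].
#' @param n_subjects cohort size.
#' @return list of `bcg_sim_config`.
#' @export
cohort_configs <- function(cfg, n_subjects) {
  lapply(seq_len(n_subjects), function(i) {
    ci <- cfg
    ci$seed <- as.integer(cfg$seed * 1000L + i)
    ci
  })
}
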