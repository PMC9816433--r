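# Oracles for the sliding-window template methods: strictly periodic
# artifacts must be cancelled (the window mean of identical segments is the
# segment), and rank-limited artifact families must be absorbed by the OBS
# basis.

test_that("GA AAS cancels a strictly periodic artifact and spares the EEG", {
  cfg <- artifact_only_cfg(seed = 30, duration_s = 60, fs = 500)
  n <- 30000L
  tr <- seq(1L, n, by = 1000L)
  ga <- gen_gradient_artifact(cfg, tr, n, clean_rms = 5)
  rec <- recording(ga, 500, cfg$channels, events = list(TR = tr))
  out <- ga_aas(rec)
  core <- 3001:27000
  expect_lt(sqrt(mean(out$recording$data[, core]^2)) /
              sqrt(mean(ga[, core]^2)), 1e-8)
  # with EEG present the only error is EEG leakage into the template: an
  # unweighted w-segment mean leaves exactly 1/sqrt(w) of the clean RMS
  cfg2 <- sim_config(seed = 31, duration_s = 60, fs = 500,
                     bcg_amp_uv = 0)
  sub <- assemble_subject(cfg2)
  out2 <- ga_aas(sub$recording)
  err <- out2$recording$data[1:18, core] - sub$truth$clean[, core]
  expect_equal(sqrt(mean(err^2)) / sqrt(mean(sub$truth$clean[, core]^2)),
               1 / sqrt(5), tolerance = 0.15)
  # edge truncation with fewer volumes than the window
  short <- recording(ga[, 1:3000], 500, cfg$channels,
                     events = list(TR = tr[1:3]))
  expect_warning(ga_aas(short), "edge-truncated")
  expect_error(ga_aas(recording(ga, 500, cfg$channels,
                                events = list(TR = c(1L, 900L, 2100L)))),
               "irregular")
})

test_that("BCG AAS cancels a jitter-free artifact and suppresses the fundamental", {
  fs <- 500; n <- 120 * fs
  cfg <- artifact_only_cfg(seed = 32, fs = fs, rr_jitter_s = 0,
                           bcg_amp_jitter = 0)
  rpeaks <- seq(250L, n - 500L, by = 450L)
  art <- gen_bcg_artifact(cfg, rpeaks, n)
  rec <- recording(art, fs, cfg$channels, events = list(RPEAK = rpeaks))
  out <- bcg_aas(rec)
  core <- (5 * 450):(n - 5 * 450)
  expect_lt(sqrt(mean(out$recording$data[, core]^2)) /
              sqrt(mean(art[, core]^2)), 0.01)
  # 10% amplitude jitter: power at the cardiac fundamental drops >= 80%
  cfg_j <- artifact_only_cfg(seed = 33, fs = fs, rr_jitter_s = 0,
                             bcg_amp_jitter = 0.1)
  set.seed(33)
  art_j <- gen_bcg_artifact(cfg_j, rpeaks, n)
  rec_j <- recording(art_j, fs, cfg_j$channels,
                     events = list(RPEAK = rpeaks))
  out_j <- bcg_aas(rec_j)
  f0 <- fs / 450
  before <- bcgpreserve:::harmonic_band_power(art_j["T3", ], fs, f0)
  after <- bcgpreserve:::harmonic_band_power(out_j$recording$data["T3", ],
                                             fs, f0)
  expect_lt(after / before, 0.2)
  expect_error(bcg_aas(recording(art, fs, cfg$channels,
                                 events = list(RPEAK = 100L))), "2 R peaks")
})

test_that("BCG AAS restores per-epoch alpha power toward the clean signal", {
  cfg <- sim_config(seed = 34, duration_s = 120, fs = 500, ga_scale = 0,
                    bold_n_volumes = 60)
  sub <- assemble_subject(cfg)
  eeg <- select_channels(bandpass(sub$recording), standard_channels())
  out <- bcg_aas(eeg, sub$truth$rpeaks)
  clean <- bandpass(recording(sub$truth$clean, cfg$fs,
                              standard_channels()))
  per_epoch_alpha <- function(rec) {
    ep <- epoch_recording(rec, channels = "O1")
    vapply(seq_len(dim(ep$epochs)[1]), function(i) {
      sp <- epoch_spectrum(ep$epochs[i, 1, ], cfg$fs)
      sum(sp$power[sp$freq >= 8 & sp$freq < 13])
    }, numeric(1))
  }
  a_clean <- per_epoch_alpha(clean)
  a_dirty <- per_epoch_alpha(eeg)
  a_corr <- per_epoch_alpha(out$recording)
  # correction reduces the aggregate per-epoch alpha-power error and helps
  # in the majority of epochs (template leakage keeps it from helping in
  # every single epoch)
  expect_lt(mean(abs(a_corr - a_clean)), mean(abs(a_dirty - a_clean)))
  expect_gt(mean(abs(a_corr - a_clean) < abs(a_dirty - a_clean)), 0.5)
})

test_that("OBS absorbs artifact epochs drawn from a fixed rank-4 basis", {
  fs <- 500; n <- 200 * 450L
  rpeaks <- seq(100L, n - 500L, by = 450L)
  L <- 200L
  t <- seq_len(L) / fs
  basis <- rbind(sin(2 * pi * 3 * t), cos(2 * pi * 5 * t),
                 sin(2 * pi * 8 * t) * exp(-t / 0.1), t / max(t))
  set.seed(35)
  x <- numeric(n)
  delay <- round(0.21 * fs)
  for (r in rpeaks) {
    coefs <- rnorm(4, sd = c(30, 20, 25, 10))
    x[(r + delay):(r + delay + L - 1L)] <- colSums(coefs * basis)
  }
  rec <- recording(matrix(x, 1), fs, "O1", events = list(RPEAK = rpeaks))
  out <- bcg_obs(rec, n_pcs = 4)
  expect_lt(mean(out$recording$data^2) / mean(x^2), 0.01)
  # rank-1 artifact with n_pcs = 4: also fully absorbed
  x1 <- numeric(n)
  for (r in rpeaks)
    x1[(r + delay):(r + delay + L - 1L)] <- rnorm(1, sd = 30) * basis[1, ]
  rec1 <- recording(matrix(x1, 1), fs, "O1", events = list(RPEAK = rpeaks))
  out1 <- bcg_obs(rec1, n_pcs = 4)
  expect_lt(mean(out1$recording$data^2) / mean(x1^2), 0.01)
  # n_pcs = 0 is the identity
  out0 <- bcg_obs(rec, n_pcs = 0)
  expect_identical(out0$recording$data, rec$data)
  expect_error(bcg_obs(recording(matrix(x[1:2000], 1), fs, "O1",
                                 events = list(RPEAK = c(100L, 550L))),
                       n_pcs = 4), "fewer")
})

test_that("corrections preserve shape and never amplify the cardiac fundamental", {
  cfg <- quick_cfg(seed = 36, ga_scale = 0)
  sub <- assemble_subject(cfg)
  eeg <- select_channels(bandpass(sub$recording), standard_channels())
  f0 <- cfg$fs / stats::median(diff(sub$truth$rpeaks))
  p_before <- vapply(seq_len(18), function(i)
    bcgpreserve:::harmonic_band_power(eeg$data[i, ], cfg$fs, f0),
    numeric(1))
  for (fn in list(function(r) bcg_aas(r, sub$truth$rpeaks),
                  function(r) bcg_obs(r, sub$truth$rpeaks))) {
    out <- fn(eeg)
    expect_identical(dim(out$recording$data), dim(eeg$data))
    expect_identical(out$recording$channel_labels, eeg$channel_labels)
    p_after <- vapply(seq_len(18), function(i)
      bcgpreserve:::harmonic_band_power(out$recording$data[i, ], cfg$fs,
                                        f0), numeric(1))
    expect_true(all(p_after <= p_before * (1 + 1e-9)))
    expect_true(all(is.finite(out$report$rms_reduction)))
  }
})
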