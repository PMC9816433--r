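test_that("simulation config rejects inconsistent parameters", {
  expect_error(sim_config(alpha_freq_hz = 20), "7-13")
  expect_error(sim_config(bcg_amp_jitter = 2), "jitter")
  expect_error(sim_config(rr_mean_s = 0.5, rr_jitter_s = 0.6), "jitter")
  expect_error(sim_config(rr_mean_s = 0.2), "delay")
  expect_error(sim_config(background_rms_uv = -1), "amplitudes")
})

test_that("clean EEG reproduces the configured EC/EO alpha power contrast", {
  # equal amplitudes: perfectly symmetric conditions
  cfg <- quick_cfg(alpha_ec_uv = 8, alpha_eo_uv = 8)
  expect_equal(within_tol <- {
    set.seed(1); gen_clean_eeg(cfg)$true_ratio
  }, 1)
  # EC = sqrt(3) x EO: empirical occipital band-power ratio 3.0 +/- 10%
  cfg <- sim_config(seed = 2, duration_s = 240)
  set.seed(2)
  clean <- gen_clean_eeg(cfg)
  ep <- epoch_recording(clean$recording)
  ratio <- ec_eo_alpha_ratio(ep, max_epochs = Inf)
  expect_equal(ratio, 3, tolerance = 0.1)
  # a channel with zero topography weight carries background-only alpha
  cfg0 <- quick_cfg(seed = 3)
  cfg0$alpha_topography["Fp1"] <- 0
  set.seed(3); low <- gen_clean_eeg(cfg0)
  cfg_bg <- quick_cfg(seed = 3, alpha_ec_uv = 0, alpha_eo_uv = 0)
  set.seed(3); bg <- gen_clean_eeg(cfg_bg)
  p_low <- mean(epoch_spectrum(low$recording$data["Fp1", 1:1000],
                               500)$power)
  p_bg <- mean(epoch_spectrum(bg$recording$data["Fp1", 1:1000],
                              500)$power)
  expect_equal(p_low, p_bg, tolerance = 1e-6)
  expect_error(gen_clean_eeg(sim_config(duration_s = 10)), "block")
})

test_that("synthetic ECG has the requested RR statistics and exact ground truth", {
  cfg <- sim_config(seed = 4, duration_s = 60, rr_jitter_s = 0)
  set.seed(4)
  e <- gen_ecg(cfg)
  expect_true(abs(length(e$rpeaks) - 60 / 0.9) <= 2)
  expect_true(all(diff(diff(e$rpeaks)) == 0))  # perfectly periodic
  cfg2 <- sim_config(seed = 5, duration_s = 600, rr_mean_s = 0.9,
                     rr_jitter_s = 0.1)
  set.seed(5)
  e2 <- gen_ecg(cfg2)
  expect_lt(abs(mean(diff(e2$rpeaks)) / cfg2$fs - 0.9), 0.02)
  cfg_bad <- sim_config(rr_mean_s = 0.31, rr_jitter_s = 0.005,
                        bcg_delay_s = 0.21, bcg_cycle_s = 0.05)
  cfg_bad$rr_mean_s <- 0.25   # bypass constructor to hit gen_ecg's check
  expect_error(gen_ecg(cfg_bad), "0.3")
})

test_that("BCG artifact is cardiac-locked with power concentrated in 1-15 Hz", {
  cfg <- sim_config(seed = 6, duration_s = 120, rr_jitter_s = 0,
                    bcg_amp_jitter = 0)
  set.seed(6)
  rpeaks <- seq(1000L, 119000L, by = 900L)
  art <- gen_bcg_artifact(cfg, rpeaks, 120000L)
  # jitter-free constant RR: consecutive cycles identical
  one <- art["T3", 1210:2109]; two <- art["T3", 2110:3009]
  expect_equal(one, two)
  sp <- epoch_spectrum(art["T3", ], cfg$fs)
  frac <- sum(sp$power[sp$freq >= 1 & sp$freq <= 15]) /
    sum(sp$power[sp$freq > 0])
  expect_gte(frac, 0.9)
  # cross-correlation with the R train peaks near the 210-ms delay
  rtrain <- numeric(120000); rtrain[rpeaks] <- 1
  cc <- stats::ccf(art["T3", ], rtrain, lag.max = 500, plot = FALSE)
  lag_max <- cc$lag[which.max(abs(cc$acf))]
  expect_gte(lag_max, 210)
  expect_lte(lag_max, 310)   # within one cycle-rise time of the delay
  # left-right polarity inversion of the topography
  expect_equal(art["T4", ], -art["T3", ])
})

test_that("gradient artifact is TR-periodic with the configured amplitude ratio", {
  cfg <- quick_cfg(seed = 7)
  tr <- seq(1L, 40000L, by = 1000L)
  ga <- gen_gradient_artifact(cfg, tr, 40000L, clean_rms = 5)
  expect_identical(ga[, 1:1000], ga[, 1001:2000])  # bitwise periodic
  expect_equal(sqrt(mean(ga[1, ]^2)) / 5 / (1 + 0.2 * sin(1)),
               cfg$ga_scale, tolerance = 0.1)
  ga0 <- gen_gradient_artifact(quick_cfg(ga_scale = 0), tr, 40000L)
  expect_true(all(ga0 == 0))
  expect_error(gen_gradient_artifact(cfg, c(1L, 500L, 1500L), 4000L),
               "regular")
})

test_that("coupled BOLD voxels follow the negated convolved alpha regressor", {
  cfg <- quick_cfg(seed = 8, bold_sd = 0, bold_ar = 0)
  alpha <- rep(c(150, 50), each = 10, length.out = 40)
  set.seed(8)
  b <- gen_bold(cfg, alpha)
  v <- which(b$coupled)[1]
  expect_equal(b$bold[v, ], cfg$bold_beta * b$predictor, tolerance = 1e-12)
  # beta = 0: no voxel is flagged coupled
  set.seed(8)
  b0 <- gen_bold(quick_cfg(bold_beta = 0), alpha)
  expect_false(any(b0$coupled))
  # at the default SNR coupled voxels separate from the null distribution
  cfg2 <- quick_cfg(seed = 9)
  set.seed(9)
  b2 <- gen_bold(cfg2, alpha)
  r <- abs(apply(b2$bold, 1, stats::cor, y = b2$predictor))
  thr <- stats::quantile(r[!b2$coupled], 0.95)
  expect_gt(mean(r[b2$coupled] > thr), 0.9)
  expect_error(gen_bold(cfg, alpha[1:10]), "length")
})

test_that("assembled subjects are additive, deterministic and seed-distinct", {
  cfg <- quick_cfg(seed = 10)
  s1 <- assemble_subject(cfg)
  expect_identical(s1$recording$data[seq_len(18), ],
                   s1$truth$clean + s1$truth$bcg + s1$truth$ga)
  s2 <- assemble_subject(cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  cfgs <- cohort_configs(cfg, 3)
  recs <- lapply(cfgs, function(ci) assemble_subject(ci)$recording$data)
  expect_false(identical(recs[[1]], recs[[2]]))
  expect_false(identical(recs[[2]], recs[[3]]))
  expect_true(all(c("RPEAK", "TR", "EC_ONSET", "EO_ONSET") %in%
                    names(s1$recording$events)))
})

test_that("clean-EEG band power matches the analytic ground truth within 10%", {
  cfg <- sim_config(seed = 11, duration_s = 240)
  set.seed(11)
  clean <- gen_clean_eeg(cfg)
  ep <- epoch_recording(clean$recording)
  scheme <- band_scheme()
  ec <- which(ep$condition == "EC")
  p_alpha <- mean(vapply(ec, function(i) {
    sp <- epoch_spectrum(ep$epochs[i, match("O1", ep$channel_labels), ],
                         cfg$fs)
    band_powers(sp, scheme)$absolute[scheme$name == "alpha"]
  }, numeric(1)))
  # analytic: alpha source power + 1/f background mass in [8, 13) Hz
  p_src <- cfg$alpha_ec_uv^2 / 2 * cfg$alpha_topography[["O1"]]^2
  nf <- 240 * cfg$fs; f <- (1:(nf %/% 2)) * cfg$fs / nf
  shape <- f^(-cfg$background_exponent)
  p_bg <- cfg$background_rms_uv^2 * sum(shape[f >= 8 & f < 13]) / sum(shape)
  expect_equal(p_alpha, p_src + p_bg, tolerance = 0.1)
})
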