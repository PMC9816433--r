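test_that("rejected-epoch interpolation follows the nearest-neighbour-mean rule", {
  expect_equal(interpolate_rejected(c(1, 99, 3), c(FALSE, TRUE, FALSE)),
               c(1, 2, 3))
  expect_equal(interpolate_rejected(c(99, 4, 5), c(TRUE, FALSE, FALSE)),
               c(4, 4, 5))
  expect_equal(interpolate_rejected(c(2, 0, 0, 8), c(FALSE, TRUE, TRUE,
                                                     FALSE)),
               c(2, 5, 5, 8))
  expect_equal(interpolate_rejected(c(1, 2, 9), c(FALSE, FALSE, TRUE)),
               c(1, 2, 2))
  expect_error(interpolate_rejected(c(1, 2), c(TRUE, TRUE)), "all epochs")
})

test_that("gamma HRF has unit mass, the configured mode, and refines stably", {
  k <- gamma_hrf(dt = 0.1)
  expect_equal(sum(k), 1, tolerance = 1e-9)
  t <- seq(0, 32, by = 0.1)
  expect_equal(t[which.max(k)], 6, tolerance = 0.1 + 1e-9)
  expect_true(all(k >= 0))
  # Riemann refinement: halving dt converges to the same density shape
  k1 <- gamma_hrf(dt = 0.2) / 0.2
  k2 <- gamma_hrf(dt = 0.1) / 0.1
  expect_lt(max(abs(k2[seq(1, length(k2), by = 2)] - k1)), 0.01)
  expect_error(gamma_hrf(dt = -1), "positive")
  expect_error(gamma_hrf(dt = 0.1, peak_s = 0), "positive")
})

test_that("the alpha predictor tracks a block design through the HRF", {
  cfg <- sim_config(seed = 80, duration_s = 240)
  set.seed(80)
  clean <- gen_clean_eeg(cfg)
  ep <- epoch_recording(clean$recording)
  pred <- build_predictor(ep, "O1", n_volumes = 120)
  expect_length(pred$predictor, 120)
  expect_equal(mean(pred$predictor), 0, tolerance = 1e-9)
  # reference: block design convolved with the same kernel
  block <- ifelse(clean$condition[seq(1, by = 2000, length.out = 120)] ==
                    "EC", 1, 0)
  hrf <- gamma_hrf(dt = 2)
  padded <- c(rep(block[1], length(hrf) - 1), block)
  ref <- stats::convolve(padded, rev(hrf),
                         type = "open")[length(hrf) - 1 + 1:120]
  expect_gt(stats::cor(pred$predictor, ref), 0.95)
  # constant alpha: flat predictor after centering
  arr <- array(rep(sin(2 * pi * 10 * (0:999) / 500), each = 12),
               dim = c(12, 1, 1000))
  for (i in 1:12) arr[i, 1, ] <- sin(2 * pi * 10 * (0:999) / 500)
  ep_c <- epoch_set(arr, 500, "O1")
  pc <- build_predictor(ep_c, "O1", n_volumes = 12)
  expect_lt(max(abs(pc$predictor)), 1e-9)
  # automatic channel choice picks the stronger reactivity channel
  expect_true(pred$channel %in% c("O1", "O2"))
  expect_error(build_predictor(ep, "O1", n_volumes = 500), "span")
})

test_that("the GLM estimates noiseless couplings exactly and is calibrated", {
  set.seed(81)
  nv <- 120
  reg <- as.numeric(scale(stats::filter(rnorm(nv), rep(1, 5),
                                        circular = TRUE)))
  # noiseless coupled voxel: beta recovered exactly
  bold1 <- matrix(-1 * reg + 5, 1)
  fit1 <- glm_fit(bold1, reg)
  expect_equal(unname(fit1$beta), -1, tolerance = 1e-6)
  # scaling the regressor scales beta reciprocally, t unchanged
  bold <- matrix(rnorm(50 * nv), 50)
  f1 <- glm_fit(bold, reg)
  f2 <- glm_fit(bold, reg * 4)
  expect_equal(f2$beta, f1$beta / 4, tolerance = 1e-9)
  expect_equal(f2$t, f1$t, tolerance = 1e-9)
  # null calibration: white-noise voxels reject at the nominal rate
  set.seed(82)
  null_bold <- matrix(rnorm(2000 * nv), 2000)
  fn <- glm_fit(null_bold, reg)
  expect_lt(abs(mean(fn$p < 0.05) - 0.05), 0.02)
  expect_error(glm_fit(bold, reg[1:10]), "length")
  expect_error(glm_fit(bold, rep(1, nv)), "collinear")
})

test_that("sign-flip permutation controls FWE and matches exhaustive enumeration", {
  set.seed(83)
  betas <- matrix(rnorm(8 * 60), 8, 60)
  betas[, 1] <- betas[, 1] - 4        # one strongly negative voxel
  res <- group_permutation(betas, n_perm = 300)
  expect_true(res$exhaustive)          # 2^8 = 256 <= 300
  expect_true(res$mask[1])
  expect_equal(res$n_perm, 256)
  # exhaustive p equals a brute-force oracle enumeration
  tstat <- function(m) apply(m, 2, function(v)
    mean(v) / (stats::sd(v) / sqrt(length(v))))
  t_obs <- tstat(betas)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 8)))
  null_min <- apply(signs, 1, function(s) min(tstat(betas * s)))
  p_oracle <- vapply(t_obs, function(tv) mean(null_min <= tv), numeric(1))
  expect_equal(res$p_corrected, p_oracle, tolerance = 1e-12)
  # null betas: familywise error under control across repeated runs
  set.seed(84)
  fwe <- vapply(1:60, function(r) {
    b <- matrix(rnorm(8 * 40), 8, 40)
    any(group_permutation(b, n_perm = 256)$mask)
  }, logical(1))
  expect_lte(mean(fwe), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  expect_error(group_permutation(betas[1:4, ]), "6 subjects")
  expect_warning(group_permutation(betas[, 1:5], n_perm = 50), "coarse")
})

test_that("IFE-derived predictors track the BOLD coupling at least as well as uncorrected", {
  # operate at a noise level where detection is not saturated, so the
  # comparison between predictors is informative
  wins <- logical(4)
  for (r in seq_along(wins)) {
    cfg <- sim_config(seed = 90 + r, duration_s = 120, bold_n_volumes = 60,
                      bold_sd = 3, bold_ar = 0)
    sub <- assemble_subject(cfg)
    eeg <- select_channels(bandpass(ga_aas(sub$recording)$recording),
                           standard_channels())
    nv <- ncol(sub$truth$bold)
    sens_at_matched_spec <- function(rec) {
      ep <- epoch_recording(rec)
      pred <- build_predictor(ep, "auto", n_volumes = nv)
      fit <- glm_fit(sub$truth$bold, pred$predictor)
      thr <- stats::quantile(fit$p[!sub$truth$coupled], 0.05)
      mean(fit$p[sub$truth$coupled] <= thr)
    }
    ica <- fit_ica(eeg, n_components = 6, thin = 3, seed = 1)
    ife <- ife_alpha(ica)
    wins[r] <- sens_at_matched_spec(ife$recording) >=
      sens_at_matched_spec(eeg)
  }
  expect_gte(mean(wins), 0.75)
})
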