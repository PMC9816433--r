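test_that("ICA recovers a 3-source mixture up to permutation and sign", {
  toy <- toy_mixture(seed = 42)
  ica <- fit_ica(toy$X, seed = 3)
  expect_gte(matched_correlations(ica$sources, toy$S), 0.95)
  # unmixing-mixing consistency on the retained subspace
  expect_equal(ica$W %*% ica$A, diag(3), tolerance = 1e-8)
  # determinism under a fixed seed
  ica2 <- fit_ica(toy$X, seed = 3)
  expect_identical(ica$W, ica2$W)
  expect_false(isTRUE(all.equal(ica$W, fit_ica(toy$X, seed = 9)$W)))
})

test_that("component removal reproduces or zeroes the input as expected", {
  toy <- toy_mixture(seed = 43)
  ica <- fit_ica(toy$X, fs = toy$fs, seed = 1)
  r0 <- remove_components(ica, integer(0))
  expect_lt(max(abs(r0$data - toy$X)) / max(abs(toy$X)), 1e-6)
  rall <- remove_components(ica, 1:3)
  expect_lt(max(abs(rall$data - rowMeans(toy$X))) / max(abs(toy$X)), 1e-6)
  expect_error(remove_components(ica, 7), "out of range")
  # removing the artifact component leaves the other sources intact
  which_bcg <- which.max(abs(stats::cor(t(ica$sources), toy$S[2, ])))
  r1 <- remove_components(ica, which_bcg)
  proj <- abs(stats::cor(r1$data[1, ], toy$S[2, ]))
  expect_lt(proj, 0.3)   # artifact contribution largely gone
  expect_gt(abs(stats::cor(r1$data[1, ],
                           (toy$A[, -2] %*% toy$S[-2, ])[1, ])), 0.95)
})

test_that("rank-deficient input reduces the component count with a warning", {
  set.seed(44)
  S <- matrix(rnorm(2 * 8000), 2)
  A <- matrix(rnorm(8), 4, 2)
  X <- A %*% S   # 4 channels, rank 2
  expect_warning(ica <- fit_ica(X, seed = 1), "rank-deficient")
  expect_equal(ica$n_components, 2)
})

test_that("BCG scoring selects the artifact source and spares the alpha source", {
  cfg <- sim_config(seed = 50, duration_s = 120, ga_scale = 0,
                    bold_n_volumes = 60)
  sub <- assemble_subject(cfg)
  eeg <- select_channels(bandpass(sub$recording), standard_channels())
  ica <- fit_ica(eeg, n_components = 6, thin = 3, seed = 1)
  ica <- score_bcg_components(ica, sub$truth$rpeaks)
  which_bcg <- which.max(abs(stats::cor(t(ica$sources),
                                        sub$truth$bcg["T3", ])))
  which_alpha <- which.max(abs(stats::cor(t(ica$sources),
                                          sub$truth$alpha_source)))
  expect_true(which_bcg %in% ica$selected$bcg)
  expect_false(which_alpha %in% ica$selected$bcg)
  sc <- ica$scores
  expect_lt(sc$cardiac_p[which_bcg], 0.01)
  expect_gt(sc$harmonic_ratio[which_bcg], 2)
  expect_gt(sc$topo_antisym[which_bcg], 0.5)
  expect_gt(sc$cardiac_p[which_alpha], 0.01)
  # scoring against a shuffled R train: the cardiac-locking criterion
  # loses significance for the true BCG component
  set.seed(99)
  fake <- sort(sample.int(ncol(ica$sources) - 1000L,
                          length(sub$truth$rpeaks)))
  ica_fake <- score_bcg_components(ica, fake, seed = 7)
  expect_gt(ica_fake$scores$cardiac_p[which_bcg], 0.01)
})

test_that("IFE retains exactly the alpha component on a simulated subject", {
  cfg <- sim_config(seed = 51, duration_s = 120, ga_scale = 0,
                    bold_n_volumes = 60)
  sub <- assemble_subject(cfg)
  eeg <- select_channels(bandpass(sub$recording), standard_channels())
  ica <- fit_ica(eeg, n_components = 6, thin = 3, seed = 1)
  ife <- ife_alpha(ica)
  which_alpha <- which.max(abs(stats::cor(t(ica$sources),
                                          sub$truth$alpha_source)))
  which_bcg <- which.max(abs(stats::cor(t(ica$sources),
                                        sub$truth$bcg["T3", ])))
  expect_identical(ife$report$components_retained, which_alpha)
  sc <- ife$scores
  expect_false(sc$retained[which_bcg])
  expect_lt(sc$ec_eo_ratio[which_bcg], 2)   # criterion (a) fails for BCG
  # impossible thresholds raise the advisory error
  expect_error(ife_alpha(ica, ratio_thresh = 1e6), "threshold")
})

test_that("combined corrections compose and report both stages", {
  cfg <- sim_config(seed = 52, duration_s = 120, ga_scale = 0,
                    bold_n_volumes = 60)
  sub <- assemble_subject(cfg)
  eeg <- select_channels(bandpass(sub$recording), standard_channels())
  comb <- bcg_combined(eeg, sub$truth$rpeaks, "AAS", n_components = 6,
                       thin = 3)
  expect_named(comb$report$params, c("stage1", "stage2"))
  expect_identical(dim(comb$recording$data), dim(eeg$data))
  # with impossible selection thresholds no ICs are removed and the
  # combination equals the template stage alone
  comb0 <- bcg_combined(eeg, sub$truth$rpeaks, "AAS", n_components = 6,
                        thin = 3, p_thresh = 0, harmonic_thresh = Inf)
  aas_only <- bcg_aas(eeg, sub$truth$rpeaks)
  expect_equal(comb0$recording$data, aas_only$recording$data,
               tolerance = 1e-12)
})

test_that("PROJIC corrects only the selected sources and commutes with mixing", {
  cfg <- sim_config(seed = 53, duration_s = 120, ga_scale = 0,
                    bold_n_volumes = 60)
  sub <- assemble_subject(cfg)
  eeg <- select_channels(bandpass(sub$recording), standard_channels())
  ica <- fit_ica(eeg, n_components = 6, thin = 3, seed = 1)
  ica <- score_bcg_components(ica, sub$truth$rpeaks)
  # selected = all components of a full-rank decomposition, inner AAS ==
  # channel-space AAS (the unweighted template operator is linear in time,
  # so it commutes with channel mixing). ICA centers the data, so the
  # identity is exact on a zero-mean recording; otherwise the two paths
  # differ by the (tiny) DC content of the channels inside artifact spans.
  eeg_dm <- with_data(eeg, eeg$data - rowMeans(eeg$data))
  ica_full <- fit_ica(eeg_dm, n_components = 18, thin = 3, seed = 1)
  pr_all <- projic(eeg_dm, ica_full, selected = seq_len(18), inner = "AAS",
                   rpeaks = sub$truth$rpeaks)
  ch_aas <- bcg_aas(eeg_dm, sub$truth$rpeaks)
  expect_lt(max(abs(pr_all$recording$data - ch_aas$recording$data)) /
              max(abs(eeg_dm$data)), 1e-6)
  # unselected sources pass through bit-identically
  sel <- ica$selected$bcg
  pr <- projic(eeg, ica, inner = "AAS", rpeaks = sub$truth$rpeaks)
  src_after <- ica$W %*% (pr$recording$data[ica$channel_labels, ] -
                            ica$means)
  keep <- setdiff(seq_len(6), sel)
  expect_equal(src_after[keep, ], ica$sources[keep, ], tolerance = 1e-6)
  expect_warning(pr0 <- projic(eeg, ica, selected = integer(0),
                               inner = "AAS", rpeaks = sub$truth$rpeaks),
                 "identity")
  expect_identical(pr0$recording$data, eeg$data)
})
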