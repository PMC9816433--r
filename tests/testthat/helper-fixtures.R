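# Shared fixtures: all synthetic, built in code at test time.

# small, fast subject configuration (halved sampling rate, 2 task cycles)
quick_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, duration_s = 80, fs = 500, bold_n_volumes = 40,
             ...)
}

# artifact-free configurations for the template-method oracles
artifact_only_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, background_rms_uv = 0, alpha_ec_uv = 0,
             alpha_eo_uv = 0, ...)
}

# a toy 3-source mixture: modulated alpha burst, cardiac-locked artifact
# train, 1/f noise
toy_mixture <- function(seed = 42, n = 20000, fs = 1000) {
  set.seed(seed)
  t <- (1:n) / fs
  s1 <- sin(2 * pi * 10 * t) *
    rep(c(2, 0.5), each = n %/% 4, length.out = n)
  w <- bcgpreserve:::bcg_cycle_waveform(sim_config())
  s2 <- numeric(n)
  for (r in seq(500, n - length(w), by = 900))
    s2[r:(r + length(w) - 1L)] <- w
  s3 <- bcgpreserve:::one_over_f_noise(n, fs, 1, 1)
  S <- rbind(s1, s2, s3)
  A <- matrix(rnorm(9), 3)
  list(S = S, A = A, X = A %*% S, fs = fs)
}

# best source-to-truth assignment over all permutations (exact for k <= 4)
matched_correlations <- function(est, truth) {
  cc <- abs(stats::cor(t(est), t(truth)))
  k <- ncol(cc)
  perms <- matrix(unlist(combinat_perms(seq_len(k))), ncol = k,
                  byrow = TRUE)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    v <- mean(cc[cbind(perms[i, ], seq_len(k))])
    if (v > best) best <- v
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}
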