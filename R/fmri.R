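#' Interpolate rejected epochs of a per-epoch series
#'
#' Each rejected value is replaced by the mean of the nearest preceding and
#' following non-rejected values; at the boundaries the single nearest
#' non-rejected value is used.
#'
#' @param series numeric per-epoch values.
#' @param mask logical, `TRUE` = rejected.
#' @return numeric series with no missing epochs.
#' @export
interpolate_rejected <- function(series, mask) {
  stopifnot(length(series) == length(mask))
  if (all(mask)) stop("all epochs rejected: nothing to interpolate from",
                      call. = FALSE)
  good <- which(!mask)
  out <- series
  for (i in which(mask)) {
    prev <- good[good < i]
    nxt <- good[good > i]
    vals <- c(if (length(prev)) series[max(prev)],
              if (length(nxt)) series[min(nxt)])
    out[i] <- mean(vals)
  }
  out
}

#' Gamma hemodynamic response kernel
#'
#' Unit-sum gamma-density kernel parameterised by its mode (`peak_s`) and
#' dispersion (`sd_s`); defaults place the peak at 6 s with a 3-s spread.
#' The underlying shape/rate solve `mode = (shape-1)/rate` and
#' `sd^2 = shape/rate^2`.
#'
#' @param dt sampling step of the kernel (s).
#' @param peak_s mode of the response (s).
#' @param sd_s dispersion (s).
#' @param duration_s kernel support (s), default 32.
#' @return numeric kernel summing to 1.
#' @export
gamma_hrf <- function(dt, peak_s = 6, sd_s = 3, duration_s = 32) {
  if (dt <= 0 || peak_s <= 0 || sd_s <= 0 || duration_s <= 0)
    stop("HRF parameters must be positive", call. = FALSE)
  rate <- (peak_s + sqrt(peak_s^2 + 4 * sd_s^2)) / (2 * sd_s^2)
  shape <- 1 + peak_s * rate
  t <- seq(0, duration_s, by = dt)
  k <- stats::dgamma(t, shape = shape, rate = rate)
  k / sum(k)
}

#' Build an alpha-power BOLD predictor from epoched EEG
#'
#' Computes the alpha-band absolute power of every epoch on an occipital
#' channel, interpolates rejected epochs ([interpolate_rejected()]),
#' convolves with the gamma HRF sampled at the epoch step, truncates to the
#' number of volumes and mean-centers. With 2-s epochs and TR = 2 s the
#' epoch grid coincides with the volume grid.
#'
#' @param epochs an [epoch_set()].
#' @param channel `"O1"`, `"O2"` or `"auto"` (pick the channel with the
#'   larger EC/EO alpha ratio).
#' @param scheme a [band_scheme()].
#' @param n_volumes number of BOLD volumes the predictor must span.
#' @param tr_s repetition time (s); must equal the epoch length.
#' @param peak_s,sd_s gamma HRF parameters.
#' @return list: `predictor` (mean-centered, length `n_volumes`), `raw`
#'   (per-epoch alpha power), `interpolated` (logical), `channel`.
#' @export
build_predictor <- function(epochs, channel = "auto",
                            scheme = band_scheme(), n_volumes,
                            tr_s = 2, peak_s = 6, sd_s = 3) {
  epoch_s <- dim(epochs$epochs)[3] / epochs$fs
  if (abs(epoch_s - tr_s) > 1e-9)
    stop("epoch length must equal the TR for the predictor grid",
         call. = FALSE)
  if (channel == "auto") {
    cand <- intersect(c("O1", "O2"), epochs$channel_labels)
    if (!length(cand)) stop("no occipital channel available", call. = FALSE)
    ratios <- vapply(cand, function(ch)
      tryCatch(ec_eo_alpha_ratio(epochs, ch, scheme), error = function(e) NA),
      numeric(1))
    channel <- if (all(is.na(ratios))) cand[1] else cand[which.max(ratios)]
  }
  ci <- match(channel, epochs$channel_labels)
  if (is.na(ci)) stop("channel not present: ", channel, call. = FALSE)
  n_epochs <- dim(epochs$epochs)[1]
  if (n_epochs < n_volumes)
    stop("epochs do not cover the volume span", call. = FALSE)
  alpha <- vapply(seq_len(n_epochs), function(i) {
    sp <- epoch_spectrum(epochs$epochs[i, ci, ], epochs$fs)
    band_powers(sp, scheme)$absolute[scheme$name == "alpha"]
  }, numeric(1))
  filled <- interpolate_rejected(alpha, epochs$rejected)
  hrf <- gamma_hrf(dt = tr_s, peak_s = peak_s, sd_s = sd_s)
  # steady-state padding: assume the pre-scan alpha level equalled the
  # first epoch's, so a constant series maps to a constant predictor
  padded <- c(rep(filled[1L], length(hrf) - 1L), filled)
  conv <- stats::convolve(padded, rev(hrf),
                          type = "open")[length(hrf) - 1L + seq_len(n_volumes)]
  list(predictor = conv - mean(conv), raw = alpha,
       interpolated = epochs$rejected, channel = channel)
}

#' Voxelwise first-level GLM with a negative alpha contrast
#'
#' Ordinary least squares of every voxel's time series on an intercept,
#' polynomial drift columns and the alpha predictor. The contrast tests
#' `beta < 0` (one-sided), the hypothesised negative alpha-BOLD coupling.
#'
#' @param bold voxels x volumes matrix.
#' @param regressor predictor of length `ncol(bold)`.
#' @param drift_order polynomial drift order (default 2: linear +
#'   quadratic).
#' @param correction multiplicity correction for the significance mask
#'   (any method of [stats::p.adjust()], default `"bonferroni"`).
#' @param alpha_level significance level of the mask.
#' @return list: `beta`, `t`, `p` (one-sided, beta < 0), `p_corrected`,
#'   `mask`, `df`.
#' @export
glm_fit <- function(bold, regressor, drift_order = 2,
                    correction = "bonferroni", alpha_level = 0.05) {
  nt <- ncol(bold)
  if (length(regressor) != nt)
    stop("regressor length must match the number of volumes", call. = FALSE)
  drift <- if (drift_order > 0)
    stats::poly(seq_len(nt), degree = drift_order) else NULL
  X <- cbind(intercept = 1, drift, alpha = regressor)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- nt - ncol(X)
  coefs <- qr.coef(qrX, t(bold))           # p x voxels
  fitted <- X %*% coefs
  rss <- colSums((t(bold) - fitted)^2)
  XtX_inv <- chol2inv(qr.R(qrX))
  j <- ncol(X)                             # alpha column (unpivoted qr)
  se <- sqrt(pmax(rss / df * XtX_inv[j, j], 0))
  beta <- coefs[j, ]
  tval <- ifelse(se > 0, beta / se, 0)
  p <- stats::pt(tval, df)                 # one-sided: beta < 0
  p_corr <- stats::p.adjust(p, method = correction)
  list(beta = beta, t = tval, p = p, p_corrected = p_corr,
       mask = p_corr < alpha_level, df = df)
}

#' Group-level sign-flip permutation test with max-statistic correction
#'
#' One-sample test of the per-subject effect sizes against zero
#' (`alternative = "less"`: negative coupling). The null is generated by
#' flipping subject signs; familywise error is controlled by comparing
#' each voxel's t statistic with the permutation distribution of the
#' extreme (most negative) statistic over all voxels. When `2^n_subjects`
#' does not exceed `n_perm`, the full enumeration of sign flips is used and
#' the p-values are exact.
#'
#' @param subject_betas subjects x voxels matrix of first-level effects.
#' @param n_perm permutation budget (default 1000).
#' @param alpha_level significance level of the corrected mask.
#' @return list: `t` (observed), `p_corrected`, `mask`, `n_perm`,
#'   `exhaustive`.
#' @export
group_permutation <- function(subject_betas, n_perm = 1000,
                              alpha_level = 0.05) {
  n <- nrow(subject_betas)
  if (n < 6) stop("at least 6 subjects are required", call. = FALSE)
  if (n_perm < 100)
    warning("fewer than 100 permutations: p-values will be coarse",
            call. = FALSE)
  tstat <- function(mat) {
    m <- colMeans(mat)
    s <- sqrt(colSums(sweep(mat, 2, m)^2) / (n - 1))
    ifelse(s > 0, m / (s / sqrt(n)), 0)
  }
  t_obs <- tstat(subject_betas)
  exhaustive <- 2^n <= n_perm
  flips <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n_perm, n)
  }
  null_min <- apply(flips, 1, function(s) min(tstat(subject_betas * s)))
  if (exhaustive) {
    p_corr <- vapply(t_obs, function(tv) mean(null_min <= tv), numeric(1))
  } else {
    p_corr <- vapply(t_obs, function(tv)
      (1 + sum(null_min <= tv)) / (nrow(flips) + 1), numeric(1))
  }
  list(t = t_obs, p_corrected = p_corr, mask = p_corr < alpha_level,
       n_perm = nrow(flips), exhaustive = exhaustive)
}
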