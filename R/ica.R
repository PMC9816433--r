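#' Independent component analysis of a recording
#'
#' Symmetric fixed-point ICA after PCA whitening: a deterministic,
#' seed-controlled unmixing estimator maximizing statistical independence of
#' the sources. The default contrast is the kurtosis (`"cube"`)
#' nonlinearity, which separates mixtures of sub- and super-Gaussian
#' sources (amplitude-modulated oscillations are sub-Gaussian); `"logcosh"`
#' is available as the more outlier-robust alternative. Rank-deficient data
#' reduce the component count with a warning.
#'
#' @param x a [recording()], an [epoch_set()] (non-rejected epochs are
#'   concatenated) or a channels x samples matrix.
#' @param n_components number of components (default: number of channels).
#' @param fs sampling rate; taken from `x` when it carries one.
#' @param fun contrast nonlinearity, `"cube"` (default) or `"logcosh"`.
#' @param max_iter,tol fixed-point iteration controls. When the symmetric
#'   update cycles without reaching `tol` (which happens when some retained
#'   components are near-Gaussian noise), the iterate closest to a fixed
#'   point is kept; the result is still fully determined by the seed.
#' @param thin use every `thin`-th sample when estimating the unmixing
#'   matrix (the sources are always computed from all samples). Thinning
#'   speeds up long high-rate recordings with negligible effect on the
#'   estimate.
#' @param seed integer seed for the random orthonormal initialisation.
#' @return object of class `bcg_ica` with unmixing `W` (components x
#'   channels), mixing `A` (channels x components, `A %*% W` = identity on
#'   the retained subspace), `sources` (components x samples), channel
#'   means, labels and sampling rate.
#' @export
fit_ica <- function(x, n_components = NULL, fs = NULL,
                    fun = c("cube", "logcosh"), max_iter = 200L,
                    tol = 1e-6, thin = 1L, seed = 1L) {
  fun <- match.arg(fun)
  proto <- NULL
  if (inherits(x, "bcg_recording")) {
    proto <- x; fs <- x$fs
    X <- x$data[eeg_rows(x), , drop = FALSE]
  } else if (inherits(x, "bcg_epoch_set")) {
    fs <- x$fs
    keep <- which(!x$rejected)
    X <- do.call(cbind, lapply(keep, function(i) x$epochs[i, , ]))
    rownames(X) <- x$channel_labels
  } else {
    X <- as.matrix(x)
  }
  nc <- nrow(X); ns <- ncol(X)
  if (is.null(n_components)) n_components <- nc
  if (ns < 20 * nc^2)
    warning("few samples relative to channels^2: ICA may be unstable",
            call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ns
  eg <- eigen(C, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(pos) < n_components) {
    warning(sprintf("rank-deficient data: reducing components to %d",
                    sum(pos)), call. = FALSE)
    n_components <- sum(pos)
  }
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  d <- eg$values[seq_len(n_components)]
  K <- diag(1 / sqrt(d), n_components) %*% t(E)     # whitening, comp x chan
  Z <- K %*% Xc
  Zt <- if (thin > 1L) Z[, seq(1L, ns, by = as.integer(thin)),
                         drop = FALSE] else Z
  nt <- ncol(Zt)
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n_components^2), n_components)))
  sym_decorrelate <- function(M) {
    s <- svd(M)
    s$u %*% t(s$v)
  }
  best <- list(W = W, delta = Inf)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Zt
    if (fun == "cube") {
      W1 <- (WZ^3 %*% t(Zt)) / nt - 3 * W
    } else {
      G <- tanh(WZ)
      W1 <- (G %*% t(Zt)) / nt - diag(rowMeans(1 - G^2)) %*% W
    }
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < best$delta) best <- list(W = W, delta = delta)
    if (delta < tol) break
  }
  if (best$delta >= tol) W <- best$W
  W_full <- W %*% K                                  # comp x chan
  A <- E %*% diag(sqrt(d), n_components) %*% t(W)    # chan x comp (pinv)
  S <- W_full %*% Xc
  structure(list(W = W_full, A = A, sources = S, means = mu,
                 channel_labels = rownames(X), fs = fs,
                 n_components = n_components, iterations = it,
                 proto = proto, X = if (is.null(proto)) X else NULL,
                 scores = NULL, selected = list()),
            class = "bcg_ica")
}

#' @export
print.bcg_ica <- function(x, ...) {
  cat(sprintf("<bcg_ica> %d components over %d channels (%d samples)\n",
              x$n_components, length(x$channel_labels), ncol(x$sources)))
  if (!is.null(x$scores)) print(x$scores)
  invisible(x)
}

# original (unreduced) data matrix the decomposition was fitted to
ica_input <- function(ica) {
  if (!is.null(ica$proto))
    ica$proto$data[ica$channel_labels, , drop = FALSE]
  else ica$X
}

# wrap a channels x samples matrix back into a recording shaped like the
# decomposition's source recording (ECG and events pass through)
as_ica_recording <- function(ica, X) {
  rownames(X) <- ica$channel_labels
  if (!is.null(ica$proto)) {
    out <- ica$proto
    out$data[ica$channel_labels, ] <- X
    validate_recording(out)
    out
  } else {
    recording(X, if (is.null(ica$fs)) 1 else ica$fs, ica$channel_labels)
  }
}

# reconstruction from the listed components only (+ channel means)
reconstruct_from <- function(ica, keep) {
  X <- if (length(keep))
    ica$A[, keep, drop = FALSE] %*% ica$sources[keep, , drop = FALSE] +
      ica$means
  else matrix(ica$means, length(ica$means), ncol(ica$sources))
  as_ica_recording(ica, X)
}

#' Reconstruct a recording with selected components removed
#'
#' The removed components' contribution `A[, idx] %*% S[idx, ]` is
#' subtracted from the original data, so with an empty index set the input
#' is reproduced exactly even when the decomposition was rank-reduced.
#'
#' @param ica a [fit_ica()] decomposition.
#' @param indices integer component indices to remove (may be empty).
#' @return a [recording()]; the ECG channel of the source recording, if
#'   any, passes through untouched.
#' @export
remove_components <- function(ica, indices) {
  indices <- as.integer(indices)
  if (length(indices) &&
      (min(indices) < 1L || max(indices) > ica$n_components))
    stop("component index out of range", call. = FALSE)
  X <- ica_input(ica)
  if (length(indices))
    X <- X - ica$A[, indices, drop = FALSE] %*%
      ica$sources[indices, , drop = FALSE]
  as_ica_recording(ica, X)
}

#' Score components for BCG-artifact character
#'
#' Three automated criteria mirror the classical visual selection rules for
#' cardiac artifact components:
#' \enumerate{
#'   \item \emph{cardiac locking}: RMS of the R-locked source average,
#'     tested against a null of randomly repositioned R trains
#'     (permutation p-value);
#'   \item \emph{harmonic spectrum}: periodogram mass at the low cardiac
#'     harmonics (1-6 x the fundamental, below the alpha range) relative to
#'     the neighbouring half-harmonic bands;
#'   \item \emph{topography polarity}: left-right or anterior-posterior
#'     antisymmetry of the mixing column (negated correlation of
#'     mirror-electrode weights).
#' }
#' A component is selected as BCG iff all three exceed their thresholds.
#'
#' @param ica a [fit_ica()] decomposition.
#' @param rpeaks integer R-peak train on the same clock as the sources.
#' @param fs sampling rate (Hz); defaults to the decomposition's.
#' @param n_perm permutations for the cardiac-locking null.
#' @param p_thresh criterion-1 threshold (default 0.01).
#' @param harmonic_thresh criterion-2 mass ratio threshold (default 2).
#' @param topo_thresh criterion-3 antisymmetry threshold (default 0.5).
#' @param seed seed for the permutation null.
#' @return the decomposition with `$scores` (data.frame) and
#'   `$selected$bcg` (integer indices) filled in.
#' @export
score_bcg_components <- function(ica, rpeaks, fs = ica$fs, n_perm = 199L,
                                 p_thresh = 0.01, harmonic_thresh = 2,
                                 topo_thresh = 0.5, seed = 1L) {
  ns <- ncol(ica$sources)
  rr_med <- stats::median(diff(rpeaks))
  f0 <- fs / rr_med
  win <- as.integer(round(0.8 * rr_med))
  locked_rms <- function(src, peaks) {
    ok <- peaks >= 1L & peaks + win - 1L <= ns
    if (sum(ok) < 2L) return(0)
    idx <- outer(as.integer(peaks[ok]), 0:(win - 1L), "+")
    avg <- colMeans(matrix(src[idx], nrow = sum(ok)))
    sqrt(mean(avg^2))
  }
  set.seed(seed)
  null_peaks <- lapply(seq_len(n_perm), function(p)
    sort(sample.int(ns - win, length(rpeaks))))
  scores <- lapply(seq_len(ica$n_components), function(j) {
    src <- ica$sources[j, ]
    obs <- locked_rms(src, rpeaks)
    null <- vapply(null_peaks, function(p) locked_rms(src, p), numeric(1))
    p1 <- (1 + sum(null >= obs)) / (n_perm + 1)
    harm <- harmonic_band_power(src, fs, f0, harmonics = 1:6)
    neigh <- harmonic_band_power(src, fs, f0, harmonics = 1:6 + 0.5)
    ratio <- if (neigh > 0) harm / neigh else Inf
    a <- stats::setNames(ica$A[, j], ica$channel_labels)
    anti <- function(pairs) {
      i1 <- match(pairs[, 1], names(a)); i2 <- match(pairs[, 2], names(a))
      ok <- !is.na(i1) & !is.na(i2)
      if (sum(ok) < 3L) return(NA_real_)
      -suppressWarnings(stats::cor(a[i1[ok]], a[i2[ok]]))
    }
    topo <- max(anti(lr_pairs()), anti(ap_pairs()), na.rm = TRUE)
    c(cardiac_p = p1, harmonic_ratio = ratio, topo_antisym = topo)
  })
  sc <- as.data.frame(do.call(rbind, scores))
  sc$component <- seq_len(ica$n_components)
  sc$selected <- sc$cardiac_p < p_thresh &
    sc$harmonic_ratio > harmonic_thresh & sc$topo_antisym > topo_thresh
  ica$scores <- sc[, c("component", "cardiac_p", "harmonic_ratio",
                       "topo_antisym", "selected")]
  ica$selected$bcg <- sc$component[sc$selected]
  ica
}

#' BCG correction by ICA component removal
#'
#' Fits (or reuses) an ICA decomposition, scores components with
#' [score_bcg_components()] and reconstructs the recording without the
#' selected BCG components.
#'
#' @param rec a [recording()].
#' @param rpeaks integer R-peak train.
#' @param n_components,seed,thin passed to [fit_ica()].
#' @param ... passed to [score_bcg_components()].
#' @return list: `recording`, `report`, `ica`.
#' @export
bcg_ica <- function(rec, rpeaks = get_events(rec, "RPEAK", required = TRUE),
                    n_components = NULL, seed = 1L, thin = 1L, ...) {
  ica <- fit_ica(rec, n_components = n_components, thin = thin,
                 seed = seed)
  ica <- score_bcg_components(ica, rpeaks, ...)
  sel <- ica$selected$bcg
  corrected <- remove_components(ica, sel)
  rows <- eeg_rows(rec)
  rep_ <- correction_report(
    "bcg_ica",
    list(n_components = ica$n_components, removed = sel, seed = seed),
    rec$data[rows, , drop = FALSE],
    corrected$data[rows, , drop = FALSE], rec$fs, rpeaks = rpeaks)
  rep_$components_removed <- sel
  list(recording = corrected, report = rep_, ica = ica)
}

#' Combined template-then-ICA correction (OBS-ICA, AAS-ICA)
#'
#' Applies [bcg_aas()] or [bcg_obs()] first, then ICA component removal on
#' the residual. The report concatenates both stages' parameters.
#'
#' @param rec a [recording()].
#' @param rpeaks integer R-peak train.
#' @param first `"AAS"` or `"OBS"`.
#' @param delay_s,window_cycles,n_pcs template-stage parameters.
#' @param n_components,seed,thin,... ICA-stage parameters.
#' @return list: `recording`, `report`, `ica`.
#' @export
bcg_combined <- function(rec,
                         rpeaks = get_events(rec, "RPEAK", required = TRUE),
                         first = c("AAS", "OBS"), delay_s = 0.21,
                         window_cycles = 21L, n_pcs = 4L,
                         n_components = NULL, seed = 1L, thin = 1L, ...) {
  first <- match.arg(first)
  stage1 <- if (first == "AAS")
    bcg_aas(rec, rpeaks, delay_s, window_cycles)
  else bcg_obs(rec, rpeaks, delay_s, n_pcs)
  stage2 <- bcg_ica(stage1$recording, rpeaks, n_components = n_components,
                    seed = seed, thin = thin, ...)
  rep_ <- stage2$report
  rep_$method <- paste0(tolower(first), "-ica")
  rep_$params <- list(stage1 = stage1$report$params,
                      stage2 = stage2$report$params)
  rows <- eeg_rows(rec)
  rep_$rms_reduction <- 1 -
    sqrt(rowMeans(stage2$recording$data[rows, , drop = FALSE]^2)) /
    sqrt(rowMeans(rec$data[rows, , drop = FALSE]^2))
  list(recording = stage2$recording, report = rep_, ica = stage2$ica)
}

#' PROJIC: template correction applied in component space
#'
#' Applies AAS or OBS to the \emph{selected} independent-component time
#' series only, then remixes all sources back to channel space through the
#' mixing matrix. Unselected sources pass through bit-identically.
#'
#' @param rec a [recording()] (used for events/shape of the output).
#' @param ica a scored [fit_ica()] decomposition.
#' @param selected integer component indices to correct; defaults to the
#'   decomposition's `$selected$bcg`.
#' @param inner `"AAS"` or `"OBS"`.
#' @param rpeaks integer R-peak train.
#' @param delay_s,window_cycles,n_pcs inner-correction parameters.
#' @return list: `recording`, `report`.
#' @export
projic <- function(rec, ica, selected = ica$selected$bcg,
                   inner = c("AAS", "OBS"),
                   rpeaks = get_events(rec, "RPEAK", required = TRUE),
                   delay_s = 0.21, window_cycles = 21L, n_pcs = 4L) {
  inner <- match.arg(inner)
  if (!length(selected)) {
    warning("empty component selection: PROJIC is the identity",
            call. = FALSE)
    rows <- eeg_rows(rec)
    return(list(recording = rec,
                report = correction_report(
                  paste0("projic-", tolower(inner)),
                  list(selected = integer(0)),
                  rec$data[rows, , drop = FALSE],
                  rec$data[rows, , drop = FALSE], rec$fs)))
  }
  src_rec <- recording(ica$sources[selected, , drop = FALSE], ica$fs,
                       paste0("IC", selected))
  corr <- if (inner == "AAS")
    bcg_aas(src_rec, rpeaks, delay_s, window_cycles)
  else bcg_obs(src_rec, rpeaks, delay_s, n_pcs)
  # subtract the removed artifact contribution in channel space, keeping
  # unselected sources (and any PCA-reduction residual) bit-identical
  delta <- ica$sources[selected, , drop = FALSE] - corr$recording$data
  corrected <- as_ica_recording(
    ica, ica_input(ica) - ica$A[, selected, drop = FALSE] %*% delta)
  rows <- eeg_rows(rec)
  rep_ <- correction_report(
    paste0("projic-", tolower(inner)),
    list(selected = selected, inner = corr$report$params),
    rec$data[rows, , drop = FALSE],
    corrected$data[rows, , drop = FALSE], rec$fs, rpeaks = rpeaks)
  list(recording = corrected, report = rep_)
}

#' ICA feature extraction of alpha activity (IFE)
#'
#' Instead of removing artifact components, retain only the components that
#' carry task-reactive alpha: (a) eyes-closed/eyes-open alpha power ratio of
#' the source time series above `ratio_thresh`, (b) dominant spectral peak
#' within 8-12 Hz, and (c) posterior share of the absolute mixing weights
#' above `posterior_thresh`. The recording is reconstructed from the
#' retained components only.
#'
#' @param ica a [fit_ica()] decomposition whose source recording carried
#'   `EC_ONSET`/`EO_ONSET` events (or pass `block_events`).
#' @param block_events named list with `EC_ONSET`, `EO_ONSET` sample
#'   vectors.
#' @param fs sampling rate (defaults to the decomposition's).
#' @param ratio_thresh threshold on the source EC/EO alpha ratio.
#' @param peak_range frequency window the spectral peak must fall in.
#' @param posterior_thresh threshold on the posterior weight share.
#' @return list: `recording` (retained-alpha reconstruction), `report`
#'   (with `components_retained`), `scores`.
#' @export
ife_alpha <- function(ica, block_events = NULL, fs = ica$fs,
                      ratio_thresh = 2, peak_range = c(8, 12),
                      posterior_thresh = 0.5) {
  if (is.null(block_events)) {
    if (is.null(ica$proto))
      stop("EC/EO block events are required", call. = FALSE)
    block_events <- list(EC_ONSET = get_events(ica$proto, "EC_ONSET"),
                         EO_ONSET = get_events(ica$proto, "EO_ONSET"))
  }
  if (!length(block_events$EC_ONSET) || !length(block_events$EO_ONSET))
    stop("both EC and EO block events are required", call. = FALSE)
  ns <- ncol(ica$sources)
  onsets <- sort(c(block_events$EC_ONSET, block_events$EO_ONSET))
  labels <- c(rep("EC", length(block_events$EC_ONSET)),
              rep("EO", length(block_events$EO_ONSET)))
  labels <- labels[order(c(block_events$EC_ONSET, block_events$EO_ONSET))]
  cond <- rep(labels[1L], ns)
  for (i in seq_along(onsets))
    cond[onsets[i]:ns] <- labels[i]
  epoch_n <- as.integer(round(2 * fs))
  n_ep <- ns %/% epoch_n
  post <- posterior_channels()
  scheme <- band_scheme()
  scores <- lapply(seq_len(ica$n_components), function(j) {
    src <- ica$sources[j, ]
    pw <- vapply(seq_len(n_ep), function(i) {
      s <- (i - 1L) * epoch_n + 1L
      sp <- epoch_spectrum(src[s:(s + epoch_n - 1L)], fs)
      band_powers(sp, scheme)$absolute[scheme$name == "alpha"]
    }, numeric(1))
    ep_cond <- cond[(seq_len(n_ep) - 1L) * epoch_n + 1L]
    ratio <- mean(pw[ep_cond == "EC"]) / mean(pw[ep_cond == "EO"])
    sp_all <- epoch_spectrum(src[seq_len(n_ep * epoch_n)], fs)
    inr <- sp_all$freq >= 2 & sp_all$freq <= 40
    peak_f <- sp_all$freq[inr][which.max(sp_all$power[inr])]
    a <- abs(stats::setNames(ica$A[, j], ica$channel_labels))
    share <- sum(a[intersect(post, names(a))]) / sum(a)
    c(ec_eo_ratio = ratio, peak_hz = peak_f, posterior_share = share)
  })
  sc <- as.data.frame(do.call(rbind, scores))
  sc$component <- seq_len(ica$n_components)
  sc$retained <- sc$ec_eo_ratio > ratio_thresh &
    sc$peak_hz >= peak_range[1] & sc$peak_hz <= peak_range[2] &
    sc$posterior_share > posterior_thresh
  retained <- sc$component[sc$retained]
  if (!length(retained))
    stop(paste("no component met the alpha-retention criteria;",
               "review ratio/posterior thresholds"), call. = FALSE)
  corrected <- reconstruct_from(ica, retained)
  rows <- which(corrected$channel_labels != "ECG")
  rep_ <- correction_report(
    "ife", list(ratio_thresh = ratio_thresh, peak_range = peak_range,
                posterior_thresh = posterior_thresh),
    corrected$data[rows, , drop = FALSE],
    corrected$data[rows, , drop = FALSE], fs)
  rep_$components_retained <- retained
  list(recording = corrected, report = rep_,
       scores = sc[, c("component", "ec_eo_ratio", "peak_hz",
                       "posterior_share", "retained")])
}
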