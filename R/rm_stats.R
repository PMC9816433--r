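#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Classical partitioned sums of squares for a complete subjects x
#' conditions design: the condition effect is tested against the
#' subject-by-condition interaction (`F = MS_cond / MS_error`), with
#' degrees of freedom scaled by the Greenhouse-Geisser epsilon computed
#' from the double-centered condition covariance (Huynh-Feldt available
#' via `correction`). With two conditions the test is equivalent to the
#' squared paired t statistic and epsilon is 1.
#'
#' @param y numeric subjects x conditions matrix (complete, no missing
#'   cells; column names are the condition names).
#' @param correction `"greenhouse-geisser"` (default), `"huynh-feldt"` or
#'   `"none"`.
#' @return list of class `bcg_rm_anova`: `F`, `df1`, `df2` (corrected),
#'   `epsilon`, `p`, `ss` (component sums of squares), `n_subjects`,
#'   `conditions`.
#' @export
rm_anova <- function(y, correction = c("greenhouse-geisser", "huynh-feldt",
                                       "none")) {
  correction <- match.arg(correction)
  y <- as.matrix(y)
  if (anyNA(y)) stop("incomplete design: missing cells are not imputed",
                     call. = FALSE)
  n <- nrow(y); k <- ncol(y)
  if (k < 2L || n < 3L)
    stop("need >= 2 conditions and >= 3 subjects", call. = FALSE)
  grand <- mean(y)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_cond <- k - 1
  df_err <- (k - 1) * (n - 1)
  Fval <- if (ss_cond <= .Machine$double.eps * ss_tot) 0
          else if (ss_err <= .Machine$double.eps * ss_tot) Inf
          else (ss_cond / df_cond) / (ss_err / df_err)
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(y)
  Cc <- S - outer(rowMeans(S), colMeans(S), function(a, b) a + b) + mean(S)
  eps_gg <- if (sum(Cc^2) <= .Machine$double.eps) 1
            else sum(diag(Cc))^2 / ((k - 1) * sum(Cc^2))
  eps <- switch(correction,
    "greenhouse-geisser" = eps_gg,
    "huynh-feldt" = min(1, (n * (k - 1) * eps_gg - 2) /
                           ((k - 1) * (n - 1 - (k - 1) * eps_gg))),
    "none" = 1)
  eps <- min(max(eps, 1 / (k - 1)), 1)
  p <- stats::pf(Fval, eps * df_cond, eps * df_err, lower.tail = FALSE)
  structure(list(F = Fval, df1 = eps * df_cond, df2 = eps * df_err,
                 epsilon = eps, p = p,
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err, total = ss_tot),
                 n_subjects = n,
                 conditions = colnames(y)),
            class = "bcg_rm_anova")
}

#' @export
print.bcg_rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g (epsilon %.3f)\n",
              x$df1, x$df2, x$F, x$p, x$epsilon))
  invisible(x)
}

#' Bonferroni-adjusted post-hoc contrasts against a reference condition
#'
#' Paired t-tests of every non-reference condition against the reference,
#' with p-values multiplied by the number of contrasts (capped at 1) —
#' the comparison scheme used when several corrected versions of a
#' measurement are each compared with an outside-scanner reference.
#'
#' @param y subjects x conditions matrix with column names.
#' @param reference name of the reference condition.
#' @return data.frame: `condition`, `mean_diff`, `t`, `p_raw`,
#'   `p_adjusted`, `significant` (adjusted p < 0.05).
#' @export
bonferroni_posthoc <- function(y, reference) {
  y <- as.matrix(y)
  if (!reference %in% colnames(y))
    stop("reference condition not found: ", reference, call. = FALSE)
  others <- setdiff(colnames(y), reference)
  m <- length(others)
  rows <- lapply(others, function(cond) {
    tt <- stats::t.test(y[, cond], y[, reference], paired = TRUE)
    data.frame(condition = cond,
               mean_diff = mean(y[, cond] - y[, reference]),
               t = unname(tt$statistic), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$significant <- out$p_adjusted < 0.05
  out
}
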