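#' Two-way ANOVA mean squares for paired registrations
#'
#' Each dual registration is a subject measured once by each of the two
#' methods (pharmacy, ward): a subjects x methods layout with subjects
#' random and method fixed, one observation per cell. Mean squares are
#' computed from explicit sums of squares:
#' \deqn{MS_s = \frac{k \sum_i (\bar y_{i.} - \bar y)^2}{n - 1}, \quad
#'       MS_m = \frac{n \sum_j (\bar y_{.j} - \bar y)^2}{k - 1}, \quad
#'       MS_e = \frac{\sum_{ij} (y_{ij} - \bar y_{i.} - \bar y_{.j} + \bar y)^2}
#'                   {(n-1)(k-1)}}
#' with \eqn{k = 2} raters.
#'
#' @param pairs tibble with columns `pharmacy_ddd` and `ward_ddd`, as from
#'   [build_paired_registrations()].
#' @return list with `ms_subjects`, `ms_method`, `ms_error`, the degrees of
#'   freedom `df_subjects`/`df_error`, `n`, `k` and a `degenerate` flag
#'   (TRUE when the data carry no variance at all, e.g. all-zero pairs).
#' @export
anova_mean_squares <- function(pairs) {
  pairs <- as_tibble(pairs)
  check_columns(pairs, c("pharmacy_ddd", "ward_ddd"), "paired registrations")
  y <- cbind(pairs$pharmacy_ddd, pairs$ward_ddd)
  if (any(!is.finite(y))) {
    abort("paired values must be finite", class = "abxflow_error_validation")
  }
  n <- nrow(y)
  k <- ncol(y)
  if (n < 3) {
    abort("at least 3 paired registrations are needed for the ANOVA",
      class = "abxflow_error_insufficient"
    )
  }
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ss_total <- sum((y - grand)^2)
  ss_subjects <- k * sum((row_means - grand)^2)
  ss_method <- n * sum((col_means - grand)^2)
  ss_error <- ss_total - ss_subjects - ss_method
  list(
    ms_subjects = ss_subjects / (n - 1),
    ms_method = ss_method / (k - 1),
    ms_error = max(ss_error, 0) / ((n - 1) * (k - 1)),
    df_subjects = n - 1,
    df_error = (n - 1) * (k - 1),
    n = n,
    k = k,
    degenerate = ss_total <= 1e-12 * max(1, grand^2)
  )
}

new_icc <- function(fields) {
  structure(fields, class = "abx_icc")
}

#' Intraclass correlation from ANOVA mean squares
#'
#' The consistency, single-measures ICC for a two-way layout with subjects
#' random and methods fixed:
#' \deqn{ICC = \frac{MS_s - MS_e}{MS_s + (k - 1) MS_e}
#'           = \frac{\sigma_s^2}{\sigma_s^2 + \sigma_e^2}}
#' where \eqn{\sigma_s^2 = (MS_s - MS_e)/k} is the between-subject and
#' \eqn{\sigma_e^2 = MS_e} the within-subject variance component. The 95%
#' confidence bounds come from the exact F ratio \eqn{MS_s / MS_e} with
#' \eqn{(n-1, (n-1)(k-1))} degrees of freedom, transformed through the same
#' formula. Consistency is the right variant here because a systematic
#' level shift between methods is the object of the separate Bland-Altman
#' analysis; an absolute-agreement variant is available via [icc()].
#'
#' @param ms_subjects,ms_error mean squares from [anova_mean_squares()].
#' @param n number of subjects (paired registrations).
#' @param k number of methods/raters (2).
#' @param conf_level confidence level for the interval.
#' @param ms_method optional method mean square (carried through for
#'   reporting).
#' @param degenerate set TRUE to mark the ICC undefined (no variance).
#' @return an `abx_icc` object; see [tidy.abx_icc()] and
#'   [glance.abx_icc()].
#' @export
icc_from_anova <- function(ms_subjects, ms_error, n, k = 2,
                           conf_level = 0.95, ms_method = NA_real_,
                           degenerate = FALSE) {
  if (degenerate || (ms_subjects <= 0 && ms_error <= 0)) {
    return(new_icc(list(
      icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      n_subjects = n, k = k, type = "consistency",
      conf_level = conf_level,
      sigma_s2 = NA_real_, sigma_e2 = NA_real_,
      ms_subjects = ms_subjects, ms_error = ms_error,
      ms_method = ms_method,
      degenerate = TRUE, reason = "no variance in the paired data"
    )))
  }
  est <- (ms_subjects - ms_error) / (ms_subjects + (k - 1) * ms_error)
  alpha <- 1 - conf_level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  if (ms_error > 0) {
    f0 <- ms_subjects / ms_error
    fl <- f0 / qf(1 - alpha / 2, df1, df2)
    fu <- f0 * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    ci <- c(1, 1) # perfect within-subject agreement
  }
  new_icc(list(
    icc = est, ci_low = ci[1], ci_high = ci[2],
    n_subjects = n, k = k, type = "consistency", conf_level = conf_level,
    sigma_s2 = max((ms_subjects - ms_error) / k, 0),
    sigma_e2 = ms_error,
    ms_subjects = ms_subjects, ms_error = ms_error, ms_method = ms_method,
    degenerate = FALSE, reason = NA_character_
  ))
}

#' Intraclass correlation between pharmacy and ward registrations
#'
#' Convenience wrapper: runs [anova_mean_squares()] on the pairs and
#' transforms the mean squares into an ICC. `type = "consistency"` (the
#' default, see [icc_from_anova()]) ignores a constant offset between the
#' methods; `type = "agreement"` (ICC(A,1), two-way random/mixed absolute
#' agreement) penalises it, with the McGraw & Wong confidence interval
#' using Satterthwaite degrees of freedom.
#'
#' @inheritParams anova_mean_squares
#' @param type ICC variant.
#' @param conf_level confidence level.
#' @return an `abx_icc` object.
#' @export
icc <- function(pairs, type = c("consistency", "agreement"),
                conf_level = 0.95) {
  type <- match.arg(type)
  ms <- anova_mean_squares(pairs)
  if (type == "consistency") {
    return(icc_from_anova(
      ms$ms_subjects, ms$ms_error,
      n = ms$n, k = ms$k,
      conf_level = conf_level, ms_method = ms$ms_method,
      degenerate = ms$degenerate
    ))
  }
  # absolute agreement, single measures
  n <- ms$n
  k <- ms$k
  if (ms$degenerate) {
    out <- icc_from_anova(ms$ms_subjects, ms$ms_error,
      n = n, k = k,
      conf_level = conf_level, degenerate = TRUE
    )
    out$type <- "agreement"
    return(out)
  }
  msr <- ms$ms_subjects
  msc <- ms$ms_method
  mse <- ms$ms_error
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  est <- (msr - mse) / denom
  alpha <- 1 - conf_level
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_star1 <- qf(1 - alpha / 2, n - 1, v)
  f_star2 <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_star1 * mse) /
    (f_star1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_star2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_star2 * msr)
  new_icc(list(
    icc = est, ci_low = lower, ci_high = upper,
    n_subjects = n, k = k, type = "agreement", conf_level = conf_level,
    sigma_s2 = max((msr - mse) / k, 0), sigma_e2 = mse,
    ms_subjects = msr, ms_error = mse, ms_method = msc,
    degenerate = FALSE, reason = NA_character_
  ))
}

#' @export
print.abx_icc <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("ICC (", x$type, "): undefined -- ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "ICC (%s, single measures): %.3f  [%g%% CI %.3f - %.3f], n = %d\n",
    x$type, x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n_subjects
  ))
  cat(sprintf(
    "  variance components: sigma_s2 = %.4g, sigma_e2 = %.4g\n",
    x$sigma_s2, x$sigma_e2
  ))
  invisible(x)
}

#' @rdname icc
#' @param x an `abx_icc` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.abx_icc <- function(x, ...) {
  tibble(
    type = x$type, icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    conf_level = x$conf_level, n_subjects = x$n_subjects, k = x$k,
    sigma_s2 = x$sigma_s2, sigma_e2 = x$sigma_e2
  )
}

#' @rdname icc
#' @exportS3Method generics::glance
glance.abx_icc <- function(x, ...) {
  tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    n_subjects = x$n_subjects, ms_subjects = x$ms_subjects,
    ms_method = x$ms_method, ms_error = x$ms_error,
    degenerate = x$degenerate
  )
}

#' Is the measurement reliable enough?
#'
#' Applies the conventional sufficiency threshold for reliability
#' (ICC >= 0.7, inclusive at the boundary).
#'
#' @param icc an `abx_icc` object.
#' @param threshold sufficiency cut-off.
#' @return a one-row tibble: `sufficient` (logical, `NA` when the ICC is
#'   undefined), `verdict` label carrying the CI, `icc`, `threshold`.
#' @export
reliability_verdict <- function(icc, threshold = 0.7) {
  stopifnot(inherits(icc, "abx_icc"))
  if (isTRUE(icc$degenerate) || is.na(icc$icc)) {
    return(tibble(
      sufficient = NA, verdict = "indeterminate (ICC undefined)",
      icc = NA_real_, threshold = threshold
    ))
  }
  ok <- icc$icc >= threshold
  tibble(
    sufficient = ok,
    verdict = sprintf(
      "%s (ICC %.2f, %g%% CI %.2f - %.2f)",
      if (ok) "sufficient" else "insufficient",
      icc$icc, 100 * icc$conf_level, icc$ci_low, icc$ci_high
    ),
    icc = icc$icc,
    threshold = threshold
  )
}

#' Bland-Altman analysis of paired registrations
#'
#' Differences `pharmacy - ward` are summarised by their mean (the
#' systematic bias), sample standard deviation (n - 1 denominator) and
#' limits of agreement `mean +/- 1.96 * sd` (the conventional normal-range
#' multiplier, not a t quantile).
#'
#' @inheritParams anova_mean_squares
#' @param loa_multiplier multiplier for the limits of agreement.
#' @return an `abx_bland_altman` object with `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `n_pairs`, `mean_of_means`,
#'   and `$data` (per-pair averages and differences, for plotting).
#' @export
bland_altman <- function(pairs, loa_multiplier = 1.96) {
  pairs <- as_tibble(pairs)
  check_columns(pairs, c("pharmacy_ddd", "ward_ddd"), "paired registrations")
  n <- nrow(pairs)
  if (n < 2) {
    abort("at least 2 pairs are needed for Bland-Altman statistics",
      class = "abxflow_error_insufficient"
    )
  }
  d <- pairs$pharmacy_ddd - pairs$ward_ddd
  a <- (pairs$pharmacy_ddd + pairs$ward_ddd) / 2
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      mean_difference = m, sd_difference = s,
      loa_low = m - loa_multiplier * s, loa_high = m + loa_multiplier * s,
      loa_multiplier = loa_multiplier,
      n_pairs = n, mean_of_means = mean(a),
      data = tibble(average = a, difference = d)
    ),
    class = "abx_bland_altman"
  )
}

#' @export
print.abx_bland_altman <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Bland-Altman (pharmacy - ward), n = %d pairs\n",
      "  mean difference %.4g, sd %.4g\n",
      "  limits of agreement %.4g to %.4g\n"
    ),
    x$n_pairs, x$mean_difference, x$sd_difference, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @param x an `abx_bland_altman` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.abx_bland_altman <- function(x, ...) {
  x$data
}

#' @rdname bland_altman
#' @exportS3Method generics::glance
glance.abx_bland_altman <- function(x, ...) {
  tibble(
    mean_difference = x$mean_difference, sd_difference = x$sd_difference,
    loa_low = x$loa_low, loa_high = x$loa_high, n_pairs = x$n_pairs,
    mean_of_means = x$mean_of_means
  )
}

#' Average interval-level DDD use across the two methods
#'
#' The average of the two methods' grand totals over retained weeks,
#' divided by the number of `k`-week intervals: the "mean use" a pair-level
#' limit of agreement is judged against.
#'
#' @inheritParams build_paired_registrations
#' @return a single DDD value per interval.
#' @export
mean_interval_use <- function(pharm, ward, k, omit_weeks = integer()) {
  pharm <- as_tibble(pharm)
  ward <- as_tibble(ward)
  k <- as.integer(k)
  retained <- sort(setdiff(unique(c(pharm$week, ward$week)), omit_weeks))
  n_int <- length(retained) %/% k
  if (n_int == 0 || length(retained) %% k != 0) {
    abort(
      paste0(
        length(retained), " retained weeks do not form complete intervals",
        " of k = ", k, " weeks"
      ),
      class = "abxflow_error_config"
    )
  }
  p_tot <- sum(pharm$ddd[pharm$week %in% retained])
  w_tot <- sum(ward$ddd[ward$week %in% retained])
  ((p_tot + w_tot) / 2) / n_int
}

#' Convert pair-level limits of agreement to an interval-level use range
#'
#' A Bland-Altman limit applies to a single ward x agent registration; an
#' interval's total use sums `n_cells_per_interval` such registrations
#' (wards x agents in the stratum). Scaling the limits by the cell count
#' and anchoring at the mean interval use expresses agreement as the DDD
#' range an interval total could plausibly span, and as percent deviations
#' from the mean use. This linear scaling treats the per-cell bias bound as
#' if it applied jointly to all cells, a deliberately conservative reading.
#'
#' @param ba an [bland_altman()] result.
#' @param n_cells_per_interval registrations summed per interval (>= 1).
#' @param mean_interval_use positive mean interval use in DDDs, from
#'   [mean_interval_use()].
#' @return one-row tibble: `mean_interval_use`, `range_low`, `range_high`,
#'   `percent_low`, `percent_high`, `n_cells`.
#' @export
loa_to_use_range <- function(ba, n_cells_per_interval, mean_interval_use) {
  stopifnot(inherits(ba, "abx_bland_altman"), n_cells_per_interval >= 1)
  if (mean_interval_use <= 0) {
    abort("mean_interval_use must be positive",
      class = "abxflow_error_validation"
    )
  }
  lo <- mean_interval_use + n_cells_per_interval * ba$loa_low
  hi <- mean_interval_use + n_cells_per_interval * ba$loa_high
  tibble(
    mean_interval_use = mean_interval_use,
    range_low = lo, range_high = hi,
    percent_low = 100 * abs(lo - mean_interval_use) / mean_interval_use,
    percent_high = 100 * abs(hi - mean_interval_use) / mean_interval_use,
    n_cells = n_cells_per_interval
  )
}
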