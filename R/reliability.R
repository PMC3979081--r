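# Inter-reader reliability statistics: single-measure absolute-agreement
# ICC from a two-way model (patient random, observer fixed), Bland-Altman
# limits of agreement at configurable coverage, smallest detectable change,
# descriptives, cumulative-probability plot data, interval-stratified
# reliability, and change-score discrepancy adjudication.

#' Qualitative ICC band
#'
#' Bands an ICC estimate: below 0.4 fair; 0.4 to below 0.6 moderate; 0.6 to
#' below 0.8 good; 0.8 to below 0.9 very good; 0.9 and above excellent.
#'
#' @param estimate Numeric vector of ICC estimates.
#' @return Character vector of bands (`NA` for non-finite estimates).
#' @export
#' @examples
#' band_of(c(0.96, 0.86, 0.39999))
band_of <- function(estimate) {
  cut_pts <- c(-Inf, 0.4, 0.6, 0.8, 0.9, Inf)
  labels <- c("fair", "moderate", "good", "very_good", "excellent")
  out <- labels[findInterval(estimate, cut_pts, left.open = FALSE)]
  out[!is.finite(estimate)] <- NA_character_
  out
}

#' Single-measure absolute-agreement intraclass correlation
#'
#' ICC from a two-way model with subjects (patients) as the random factor
#' and readers as the fixed factor, single measures, absolute agreement
#' (ICC(A,1) in the McGraw-Wong taxonomy):
#'
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#'
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the two-way ANOVA mean
#' squares for rows (subjects), columns (readers) and error. The
#' confidence interval uses the F-distribution method for this ICC form
#' (Satterthwaite degrees of freedom for the denominator). Absolute
#' agreement penalises systematic between-reader offsets, unlike
#' consistency ICCs.
#'
#' A matrix with zero total variance (all cells identical) has no defined
#' ICC; the result is returned with `degenerate = TRUE` and an `NA`
#' estimate rather than an error, so batch stratified analyses complete.
#'
#' @param values An `n x k` numeric matrix: `n` subjects (rows) by `k`
#'   readers (columns), no missing cells. A data frame is coerced.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `fasss_icc`: list with `estimate`, `ci_low`,
#'   `ci_high`, `band`, `n_subjects`, `k_readers`, `conf_level`,
#'   `ms` (the three mean squares) and `degenerate`.
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 3, 5, 7), r2 = c(2, 4, 6, 8))
#' icc_a1(m)
icc_a1 <- function(values, conf_level = 0.95) {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 readers", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  # summation-order residue: error SS is zero up to rounding when the
  # readers agree cell-for-cell
  if (abs(ss_err) < 1e-12 * max(ss_tot, 1)) ss_err <- 0
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  degenerate <- ss_tot < .Machine$double.eps * max(1, abs(grand))^2 * n * k
  if (degenerate) {
    res <- list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                band = NA_character_, n_subjects = n, k_readers = k,
                conf_level = conf_level,
                ms = c(rows = msr, cols = msc, error = mse),
                degenerate = TRUE)
    class(res) <- "fasss_icc"
    return(res)
  }

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  est <- (msr - mse) / denom

  # F-based CI for ICC(A,1), Satterthwaite df for the denominator.
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (mse > 0) {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  } else if (isTRUE(all.equal(est, 1))) {
    ci <- c(1, 1)  # identical columns: perfect absolute agreement
  }

  res <- list(
    estimate = est,
    ci_low = if (is.finite(ci[1])) min(ci[1], est) else NA_real_,
    ci_high = if (is.finite(ci[2])) max(ci[2], est) else NA_real_,
    band = band_of(est),
    n_subjects = n, k_readers = k,
    conf_level = conf_level,
    ms = c(rows = msr, cols = msc, error = mse),
    degenerate = FALSE
  )
  class(res) <- "fasss_icc"
  res
}

#' @export
print.fasss_icc <- function(x, digits = 4, ...) {
  if (x$degenerate) {
    cat(sprintf(
      "ICC(A,1): undefined (zero total variance), n = %d, k = %d\n",
      x$n_subjects, x$k_readers))
    return(invisible(x))
  }
  cat(sprintf(
    "ICC(A,1) = %.*f, %d%% CI (%.*f to %.*f), %s; n = %d subjects, k = %d readers\n",
    digits, x$estimate, round(100 * x$conf_level), digits, x$ci_low,
    digits, x$ci_high, gsub("_", " ", x$band), x$n_subjects, x$k_readers
  ))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y` between two readers' paired scores, with limits
#' of agreement `mean(d) +/- z * sd(d)` where `z` is the standard-normal
#' quantile at `(1 + coverage)/2`. The default coverage of 0.80
#' (`z = 1.2816`) follows the convention used for smallest-detectable-change
#' estimation in imaging scores. Also returns the (pair mean, difference)
#' points for plotting.
#'
#' @param x,y Equal-length numeric vectors, paired by subject.
#' @param coverage Fraction of differences the limits should contain
#'   (default 0.80).
#' @return Object of class `fasss_ba`: list with `mean_diff`, `sd_diff`
#'   (sample SD, denominator n-1), `z`, `coverage`, `loa_low`, `loa_high`,
#'   `n` and `points` (data frame with columns `mean` and `diff`).
#' @export
#' @examples
#' ba <- bland_altman(c(1, 2, 3, 4), c(2, 2, 2, 5))
#' ba$loa_low; ba$loa_high
bland_altman <- function(x, y, coverage = 0.80) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  stopifnot(coverage > 0, coverage < 1)
  d <- x - y
  z <- stats::qnorm((1 + coverage) / 2)
  m <- mean(d)
  s <- stats::sd(d)
  res <- list(
    mean_diff = m, sd_diff = s, z = z, coverage = coverage,
    loa_low = m - z * s, loa_high = m + z * s, n = length(d),
    points = data.frame(mean = (x + y) / 2, diff = d)
  )
  class(res) <- "fasss_ba"
  res
}

#' @export
print.fasss_ba <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean diff %.*f, SD %.*f, %d%% LoA (%.*f to %.*f)\n",
    x$n, digits, x$mean_diff, digits, x$sd_diff,
    round(100 * x$coverage), digits, x$loa_low, digits, x$loa_high
  ))
  invisible(x)
}

#' @export
plot.fasss_ba <- function(x, xlab = "Mean of readers",
                          ylab = "Difference between readers", ...) {
  graphics::plot(x$points$mean, x$points$diff, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Smallest detectable change
#'
#' The smallest change in score distinguishable from inter-reader
#' measurement error at the individual-patient level, derived from the
#' Bland-Altman limits of agreement of the two readers' change scores:
#'
#' \deqn{SDC = \frac{z \cdot SD(d)}{\sqrt{2}}, \quad d = \Delta_1 - \Delta_2}
#'
#' with `z` the standard-normal quantile at `(1 + coverage)/2`
#' (1.2816 for the default 80% coverage) and the `sqrt(2)` divisor
#' accounting for the difference of `k = 2` readings. All components are
#' returned so alternative conventions can be audited.
#'
#' @param change_r1,change_r2 Paired change-score vectors, one per reader.
#' @param coverage Coverage for the limits of agreement (default 0.80).
#' @param k Number of readings entering the difference (default 2).
#' @return Object of class `fasss_sdc`: list with `sdc`, `z`, `coverage`,
#'   `sd_diff`, `mean_diff`, `k`, `n`.
#' @export
#' @examples
#' sdc(c(0, 2, 5, 1), c(1, 2, 4, 0))$sdc
sdc <- function(change_r1, change_r2, coverage = 0.80, k = 2) {
  if (length(change_r1) != length(change_r2)) {
    stop("change vectors must have equal length", call. = FALSE)
  }
  if (length(change_r1) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- change_r1 - change_r2
  z <- stats::qnorm((1 + coverage) / 2)
  s <- stats::sd(d)
  res <- list(
    sdc = z * s / sqrt(k), z = z, coverage = coverage,
    sd_diff = s, mean_diff = mean(d), k = k, n = length(d)
  )
  class(res) <- "fasss_sdc"
  res
}

#' @export
print.fasss_sdc <- function(x, digits = 4, ...) {
  cat(sprintf(
    "SDC = %.*f (z = %.4f at %d%% coverage, SD(diff) = %.*f, n = %d)\n",
    digits, x$sdc, x$z, round(100 * x$coverage), digits, x$sd_diff, x$n
  ))
  invisible(x)
}

#' Descriptive statistics
#'
#' Mean, sample SD (denominator n-1), median, interquartile range and range,
#' the descriptives used to summarise total and segmental scores. Quartiles
#' use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values Non-empty numeric vector.
#' @return Named list: `n`, `mean`, `sd`, `median`, `iqr_low`, `iqr_high`,
#'   `min`, `max`.
#' @export
descriptives <- function(values) {
  if (length(values) < 1L) stop("empty vector", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    median = q[2],
    iqr_low = q[1], iqr_high = q[3],
    min = min(values), max = max(values)
  )
}

#' Cumulative probability plot coordinates
#'
#' Sorts the values ascending and assigns rank `i` (1-based) the plotting
#' position `(i - 0.5)/n`; ties keep their individual points. This is the
#' coordinate set behind cumulative probability plots of status and change
#' scores.
#'
#' @param values Non-empty numeric vector.
#' @return Data frame with columns `prob` (strictly increasing) and `value`
#'   (ascending).
#' @export
#' @examples
#' cumulative_probability_points(c(5, 1, 3))
cumulative_probability_points <- function(values) {
  if (length(values) < 1L) stop("empty vector", call. = FALSE)
  n <- length(values)
  data.frame(prob = (seq_len(n) - 0.5) / n, value = sort(values))
}

#' Default inter-scan interval strata
#'
#' Four strata on the interval between MRI scans: at most 1.0 years; more
#' than 1.0 up to 1.5; more than 1.5 up to 2.0; more than 2.0 years. Lower
#' bounds are exclusive, upper bounds inclusive.
#'
#' @return Data frame with columns `label`, `lower` (exclusive) and
#'   `upper` (inclusive).
#' @export
default_strata <- function() {
  data.frame(
    label = c("<=1.0y", ">1.0-1.5y", ">1.5-2.0y", ">2.0y"),
    lower = c(0, 1.0, 1.5, 2.0),
    upper = c(1.0, 1.5, 2.0, Inf),
    stringsAsFactors = FALSE
  )
}

#' Assign intervals to strata
#'
#' @param interval_years Positive numeric vector.
#' @param strata Stratum table as from [default_strata()].
#' @return Integer vector of stratum indices; errors listing any record
#'   matching no stratum.
#' @keywords internal
assign_stratum <- function(interval_years, strata = default_strata()) {
  idx <- rep(NA_integer_, length(interval_years))
  for (s in seq_len(nrow(strata))) {
    hit <- interval_years > strata$lower[s] & interval_years <= strata$upper[s]
    idx[hit & is.na(idx)] <- s
  }
  if (anyNA(idx)) {
    stop("interval(s) matching no stratum: ",
         paste(interval_years[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Reliability stratified by inter-scan interval
#'
#' Splits paired two-reader records by the time interval between scans and
#' computes, per stratum: the number of pairs, descriptives of each
#' reader's baseline and change scores, the baseline ICC, the change-score
#' ICC and the smallest detectable change. Strata too small for a statistic
#' return it as a degenerate/`NA` result rather than failing the batch.
#'
#' @param pairs Data frame with one row per patient and columns
#'   `patient_id`, `interval_years`, `baseline_r1`, `baseline_r2`,
#'   `delta_r1`, `delta_r2`.
#' @param strata Stratum table as from [default_strata()].
#' @param coverage Coverage for the SDC (default 0.80).
#' @return Object of class `fasss_strat`: a list of per-stratum results
#'   plus the stratum table.
#' @export
stratified_reliability <- function(pairs, strata = default_strata(),
                                   coverage = 0.80) {
  need <- c("patient_id", "interval_years", "baseline_r1", "baseline_r2",
            "delta_r1", "delta_r2")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0L) {
    stop("pairs lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(pairs$interval_years <= 0)) {
    stop("interval_years must be positive for all records", call. = FALSE)
  }
  idx <- assign_stratum(pairs$interval_years, strata)
  per_stratum <- lapply(seq_len(nrow(strata)), function(s) {
    g <- pairs[idx == s, , drop = FALSE]
    if (nrow(g) < 2L) {
      return(list(label = strata$label[s], n = nrow(g),
                  baseline_icc = NULL, change_icc = NULL, sdc = NULL,
                  descriptives = NULL, degenerate = TRUE))
    }
    list(
      label = strata$label[s],
      n = nrow(g),
      descriptives = list(
        baseline_r1 = descriptives(g$baseline_r1),
        baseline_r2 = descriptives(g$baseline_r2),
        change_r1 = descriptives(g$delta_r1),
        change_r2 = descriptives(g$delta_r2)
      ),
      baseline_icc = icc_a1(cbind(g$baseline_r1, g$baseline_r2)),
      change_icc = icc_a1(cbind(g$delta_r1, g$delta_r2)),
      sdc = sdc(g$delta_r1, g$delta_r2, coverage = coverage),
      degenerate = FALSE
    )
  })
  structure(list(strata = strata, results = per_stratum),
            class = "fasss_strat")
}

#' @export
print.fasss_strat <- function(x, digits = 3, ...) {
  cat("Reliability stratified by inter-scan interval\n")
  for (r in x$results) {
    cat(sprintf("  %s: n = %d", r$label, r$n))
    if (isTRUE(r$degenerate)) {
      cat("  (too few pairs; statistics undefined)\n")
      next
    }
    fmt_icc <- function(ic) {
      if (ic$degenerate) "ICC undefined" else {
        sprintf("%.*f (%.*f to %.*f)", digits, ic$estimate, digits,
                ic$ci_low, digits, ic$ci_high)
      }
    }
    cat(sprintf("  baseline ICC %s, change ICC %s, SDC %.*f\n",
                fmt_icc(r$baseline_icc), fmt_icc(r$change_icc),
                digits, r$sdc$sdc))
  }
  invisible(x)
}

#' Flag discrepant change-score pairs
#'
#' Applies the pre-specified adjudication rules for inter-reader change
#' scores:
#' \describe{
#'   \item{A}{absolute difference in change scores of at least 10 AND a
#'     relative difference exceeding 100% of the pair's mean change score,
#'     i.e. `|d1 - d2| > |(d1 + d2)/2|` (a zero mean with a nonzero
#'     difference satisfies the relative criterion).}
#'   \item{B}{change scores in opposite directions with one at or below -2
#'     and the other at or above 2.}
#'   \item{C}{one reader scored no change (0) while the other's change has
#'     magnitude at least 3.}
#' }
#' A patient is flagged iff any rule fires; all fired rules are listed.
#'
#' @param delta_r1,delta_r2 Paired change-score vectors.
#' @param ids Patient identifiers (defaults to indices).
#' @return Data frame of flagged patients: `patient_id`, `rules_fired`
#'   (e.g. `"A;C"`), `delta_r1`, `delta_r2`. Zero rows when nothing fires.
#' @export
#' @examples
#' flag_discrepant(c(10, 3, 1), c(0, -3, 2), ids = c("a", "b", "c"))
flag_discrepant <- function(delta_r1, delta_r2,
                            ids = seq_along(delta_r1)) {
  if (length(delta_r1) != length(delta_r2)) {
    stop("change vectors must have equal length", call. = FALSE)
  }
  d1 <- delta_r1
  d2 <- delta_r2
  diff_abs <- abs(d1 - d2)
  rule_a <- diff_abs >= 10 & (2 * diff_abs > abs(d1 + d2))
  rule_b <- (pmin(d1, d2) <= -2) & (pmax(d1, d2) >= 2)
  rule_c <- xor(d1 == 0, d2 == 0) &
    pmax(abs(d1), abs(d2)) >= 3
  fired <- rule_a | rule_b | rule_c
  rules <- vapply(seq_along(d1), function(i) {
    paste(c("A", "B", "C")[c(rule_a[i], rule_b[i], rule_c[i])],
          collapse = ";")
  }, character(1))
  out <- data.frame(
    patient_id = as.character(ids)[fired],
    rules_fired = rules[fired],
    delta_r1 = d1[fired],
    delta_r2 = d2[fired],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
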