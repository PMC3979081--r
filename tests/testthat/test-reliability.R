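test_that("ICC(A,1) matches the ANOVA oracle on the toy matrix", {
  m <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  res <- icc_a1(m)
  # hand computation: MSR = 40/3, MSC = 2, MSE = 0 -> 40/43
  expect_equal(res$estimate, 40 / 43, tolerance = 1e-12)
  expect_equal(res$estimate, icc_a1_oracle(m), tolerance = 1e-12)
})

test_that("ICC(A,1) equals the ANOVA oracle across random small matrices", {
  set.seed(11)
  for (n in 2:6) {
    for (k in 2:3) {
      for (rep in 1:5) {
        m <- matrix(rnorm(n * k, sd = 3), n, k) +
          rnorm(n)  # add subject effects so estimates vary
        expect_equal(icc_a1(m)$estimate, icc_a1_oracle(m),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("identical reader columns give ICC exactly 1; offsets lower it", {
  m <- cbind(c(2, 5, 9, 14), c(2, 5, 9, 14))
  res <- icc_a1(m)
  expect_identical(res$estimate, 1)
  expect_equal(res$ci_low, 1)
  # absolute agreement penalises a systematic offset
  m_off <- m
  m_off[, 2] <- m_off[, 2] + 3
  expect_lt(icc_a1(m_off)$estimate, 1)
  expect_lt(icc_a1(m_off)$estimate, icc_a1(m)$estimate)
})

test_that("ICC is invariant under a common affine transform", {
  set.seed(12)
  m <- matrix(rpois(10 * 2, 20), 10, 2) + rnorm(10)
  base <- icc_a1(m)$estimate
  expect_equal(icc_a1(2.5 * m + 7)$estimate, base, tolerance = 1e-12)
  expect_equal(icc_a1(-1.5 * m + 2)$estimate, base, tolerance = 1e-12)
})

test_that("degenerate zero-variance input is flagged, not raised", {
  m <- matrix(5, 4, 2)
  res <- icc_a1(m)
  expect_true(res$degenerate)
  expect_true(is.na(res$estimate))
  expect_output(print(res), "undefined")
})

test_that("confidence bounds bracket the estimate", {
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(rnorm(8 * 2, sd = 2), 8, 2) + 3 * rnorm(8)
    res <- icc_a1(m)
    expect_true(res$ci_low <= res$estimate)
    expect_true(res$ci_high >= res$estimate)
  }
})

test_that("ICC banding uses the published thresholds", {
  expect_equal(band_of(c(0.96, 0.86, 0.39999, 0.75, 0.45)),
               c("excellent", "very_good", "fair", "good", "moderate"))
  # boundaries belong to the upper band
  expect_equal(band_of(c(0.4, 0.6, 0.8, 0.9)),
               c("moderate", "good", "very_good", "excellent"))
  expect_true(is.na(band_of(NA_real_)))
})

test_that("Bland-Altman limits follow mean +/- z * sd", {
  d <- c(-2, -1, 0, 1, 2)
  ba <- bland_altman(d, rep(0, 5))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sd(d))
  z80 <- qnorm(0.9)
  expect_equal(ba$loa_high, z80 * sd(d))
  expect_equal(ba$loa_low, -z80 * sd(d))
  expect_equal(round(bland_altman(d, rep(0, 5), coverage = 0.95)$z, 4),
               1.9600)
  # identical vectors collapse the limits
  ba0 <- bland_altman(1:4, 1:4)
  expect_equal(c(ba0$mean_diff, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  expect_error(bland_altman(1:3, 1:4), "equal length")
  # plotting points are (pair mean, difference)
  ba2 <- bland_altman(c(4, 6), c(2, 2))
  expect_equal(ba2$points$mean, c(3, 4))
  expect_equal(ba2$points$diff, c(2, 4))
})

test_that("SDC is z * SD(d) / sqrt(2) with auditable components", {
  # engineered differences (-1, 1): SD(d) = sqrt(2), so SDC = z exactly
  r1 <- c(0, 1) + 5
  r2 <- c(1, 0) + 5
  d <- r1 - r2
  expect_equal(sd(d), sqrt(2), tolerance = 1e-12)
  res <- sdc(r1, r2)
  expect_equal(res$sdc, qnorm(0.9), tolerance = 1e-12)
  # SD(d) = 1 gives the 0.9062 constant
  expect_equal(round(qnorm(0.9) / sqrt(2), 4), 0.9062)
  expect_equal(sdc(c(0, 1, 2), c(1, 2, 3))$sdc, 0)  # constant shift
  expect_equal(sdc(c(1, 5, 2), c(1, 5, 2))$sdc, 0)
  # linearity in scale
  a <- c(0, 3, 8, -2); b <- c(1, 2, 9, 0)
  expect_equal(sdc(3 * a, 3 * b)$sdc, 3 * sdc(a, b)$sdc)
  expect_error(sdc(1, 1), "at least 2")
})

test_that("descriptives use sample SD and interpolated quartiles", {
  d <- descriptives(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  expect_equal(d$sd, 1)
  dc <- descriptives(rep(4, 6))
  expect_equal(dc$sd, 0)
  expect_equal(dc$iqr_high - dc$iqr_low, 0)
  set.seed(14)
  x <- rpois(30, 8)
  dx <- descriptives(x)
  expect_true(dx$min <= dx$iqr_low && dx$iqr_low <= dx$median &&
                dx$median <= dx$iqr_high && dx$iqr_high <= dx$max)
  expect_equal(dx$iqr_low, unname(quantile(x, 0.25)))
  expect_error(descriptives(numeric(0)), "empty")
})

test_that("cumulative probability points use (i - 0.5)/n on sorted values", {
  p1 <- cumulative_probability_points(7)
  expect_equal(p1$prob, 0.5)
  p3 <- cumulative_probability_points(c(5, 1, 3))
  expect_equal(p3$value, c(1, 3, 5))
  expect_equal(p3$prob, c(0.5, 1.5, 2.5) / 3)
  expect_true(all(diff(p3$prob) > 0))
  # ties keep individual points
  pt <- cumulative_probability_points(c(2, 2, 2))
  expect_equal(nrow(pt), 3L)
})

test_that("interval strata reproduce the published boundaries", {
  s <- default_strata()
  expect_equal(assign_stratum(1.0, s), 1L)    # inclusive upper bound
  expect_equal(assign_stratum(1.01, s), 2L)
  expect_equal(assign_stratum(1.5, s), 2L)
  expect_equal(assign_stratum(2.0, s), 3L)
  expect_equal(assign_stratum(2.0001, s), 4L)
  expect_equal(assign_stratum(10, s), 4L)
  expect_error(assign_stratum(0, s), "no stratum")
})

test_that("stratified reliability computes per-stratum ICC and SDC", {
  set.seed(15)
  n <- 60
  truth <- rpois(n, 12)
  pairs <- data.frame(
    patient_id = sprintf("p%02d", 1:n),
    interval_years = runif(n, 0.6, 2.8),
    baseline_r1 = truth + rpois(n, 2),
    baseline_r2 = truth + rpois(n, 2),
    delta_r1 = rpois(n, 4),
    delta_r2 = rpois(n, 4)
  )
  res <- stratified_reliability(pairs)
  expect_s3_class(res, "fasss_strat")
  ns <- vapply(res$results, function(r) r$n, numeric(1))
  expect_equal(sum(ns), n)  # each record in exactly one stratum
  idx <- assign_stratum(pairs$interval_years)
  for (s in 1:4) {
    r <- res$results[[s]]
    expect_equal(r$n, sum(idx == s))
    if (r$n >= 2) {
      g <- pairs[idx == s, ]
      expect_equal(r$baseline_icc$estimate,
                   icc_a1(cbind(g$baseline_r1, g$baseline_r2))$estimate)
      expect_equal(r$sdc$sdc, sdc(g$delta_r1, g$delta_r2)$sdc)
    }
  }
  # an empty stratum is reported, not an error
  near <- pairs
  near$interval_years <- runif(n, 0.6, 0.9)
  res2 <- stratified_reliability(near)
  expect_equal(res2$results[[4]]$n, 0)
  expect_true(res2$results[[4]]$degenerate)
})

test_that("discrepancy flags match the printed rule examples", {
  f <- flag_discrepant(c(10, 3, 1), c(0, -3, 2), ids = c("a", "b", "c"))
  expect_equal(f$patient_id, c("a", "b"))
  expect_equal(f$rules_fired, c("A;C", "B"))
  # d1 = 1, d2 = 2 fires nothing
  expect_equal(nrow(flag_discrepant(1, 2)), 0L)
  # opposite-direction boundary: exactly -2 and 2
  expect_equal(flag_discrepant(-2, 2)$rules_fired, "B")
  # one reader zero, |other| >= 3
  expect_equal(flag_discrepant(0, 3)$rules_fired, "C")
  expect_equal(nrow(flag_discrepant(0, 2)), 0L)
  # both zero: rule C needs exactly one zero
  expect_equal(nrow(flag_discrepant(0, 0)), 0L)
})

test_that("discrepancy flags agree with direct rule evaluation on a grid", {
  grid <- expand.grid(d1 = -15:15, d2 = -15:15)
  flags <- flag_discrepant(grid$d1, grid$d2,
                           ids = seq_len(nrow(grid)))
  direct <- lapply(seq_len(nrow(grid)),
                   function(i) discrepancy_rules_direct(grid$d1[i],
                                                        grid$d2[i]))
  fired_direct <- vapply(direct, function(r) length(r) > 0, logical(1))
  expect_equal(sort(as.integer(flags$patient_id)), which(fired_direct))
  got <- setNames(flags$rules_fired, flags$patient_id)
  for (i in which(fired_direct)) {
    expect_equal(got[[as.character(i)]],
                 paste(direct[[i]], collapse = ";"))
  }
})
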