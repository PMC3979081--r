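# Shared fixture builders for the test suite.

# One lesion annotation row.
lesion_row <- function(dvu, endplate, region,
                       slice_domain = "central",
                       size_grade = "present_small",
                       cortex_large = NA_integer_,
                       midpoint_large = NA_integer_) {
  data.frame(
    dvu = dvu, endplate = endplate, region = region,
    slice_domain = slice_domain, size_grade = size_grade,
    cortex_large = cortex_large, midpoint_large = midpoint_large,
    stringsAsFactors = FALSE
  )
}

# The published worked single-slice example: small anterior corner lesions
# at the upper endplates of T12, L1, L2 and L3, plus one large anterior
# corner lesion at the lower endplate of L2. (The upper endplate of a
# vertebra is the caudal endplate of the DVU above it; the lower endplate
# is the cranial endplate of the DVU below.)
worked_example_exam <- function() {
  fasss_exam(rbind(
    lesion_row("T11/T12", "caudal", "anterior_corner"),
    lesion_row("T12/L1", "caudal", "anterior_corner"),
    lesion_row("L1/L2", "caudal", "anterior_corner"),
    lesion_row("L2/L3", "caudal", "anterior_corner"),
    lesion_row("L2/L3", "cranial", "anterior_corner",
               size_grade = "present_large")
  ), patient_id = "example")
}

# Random schema-valid exam: each site annotated independently with
# probability p at a uniformly drawn legal grade.
random_valid_exam <- function(p = 0.15, patient_id = "p1") {
  sites <- fasss_all_sites()
  keep <- runif(nrow(sites)) < p
  ss <- sites[keep, , drop = FALSE]
  if (nrow(ss) == 0L) return(fasss_exam(patient_id = patient_id))
  grades <- vapply(seq_len(nrow(ss)), function(i) {
    ok <- if (ss$segment[i] == "cervical" || ss$slice_domain[i] != "central") {
      "present"
    } else if (ss$region[i] == "noncorner") {
      c("present_small", "present_large")
    } else {
      c("present_small", "present_large", "present_combined")
    }
    sample(ok, 1L)
  }, character(1))
  les <- data.frame(
    dvu = ss$dvu, endplate = ss$endplate, region = ss$region,
    slice_domain = ss$slice_domain, size_grade = grades,
    cortex_large = sample(c(0L, 1L), nrow(ss), replace = TRUE),
    midpoint_large = sample(c(0L, 1L), nrow(ss), replace = TRUE),
    stringsAsFactors = FALSE
  )
  fasss_exam(les, patient_id = patient_id)
}

# Independent ICC(A,1) oracle: mean squares from stats::anova on the
# two-way fixed-effects fit, then the single-measure absolute-agreement
# formula.
icc_a1_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- anova(lm(y ~ subj + rater, data = d))
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Direct, literal evaluation of the three discrepancy adjudication rules
# for a single pair of change scores.
discrepancy_rules_direct <- function(d1, d2) {
  fired <- character(0)
  if (abs(d1 - d2) >= 10 && abs(d1 - d2) > abs((d1 + d2) / 2)) {
    fired <- c(fired, "A")
  }
  if ((d1 <= -2 && d2 >= 2) || (d2 <= -2 && d1 >= 2)) {
    fired <- c(fired, "B")
  }
  if ((d1 == 0 && d2 != 0 && abs(d2) >= 3) ||
      (d2 == 0 && d1 != 0 && abs(d1) >= 3)) {
    fired <- c(fired, "C")
  }
  fired
}
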