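test_that("single-site scores follow the published weights", {
  # thoracolumbar central corners: 1, +1 if large
  expect_equal(score_site(lesion_row("L2/L3", "cranial", "anterior_corner")),
               1L)
  expect_equal(score_site(lesion_row("L2/L3", "cranial", "anterior_corner",
                                     size_grade = "present_large")), 2L)
  # lateral corners: presence only, score 1
  expect_equal(score_site(lesion_row("T5/T6", "caudal", "posterior_corner",
                                     slice_domain = "lateral_left",
                                     size_grade = "present")), 1L)
  # noncorner: 2, +2 if large
  expect_equal(score_site(lesion_row("T5/T6", "caudal", "noncorner")), 2L)
  expect_equal(score_site(lesion_row("T5/T6", "caudal", "noncorner",
                                     size_grade = "present_large")), 4L)
  # cervical: presence only; corner 1, noncorner 2
  expect_equal(score_site(lesion_row("C3/C4", "cranial", "anterior_corner",
                                     size_grade = "present")), 1L)
  expect_equal(score_site(lesion_row("C3/C4", "cranial", "noncorner",
                                     size_grade = "present")), 2L)
  # combined corner: corner component 1 + cortex addition
  expect_equal(score_site(lesion_row("L1/L2", "caudal", "anterior_corner",
                                     size_grade = "present_combined",
                                     cortex_large = 0L)), 1L)
  expect_equal(score_site(lesion_row("L1/L2", "caudal", "anterior_corner",
                                     size_grade = "present_combined",
                                     cortex_large = 1L)), 2L)
})

test_that("illegal size grades for a site class are rejected", {
  expect_error(score_site(lesion_row("C3/C4", "cranial", "anterior_corner",
                                     size_grade = "present_large")),
               "not allowed")
  expect_error(score_site(lesion_row("T5/T6", "caudal", "noncorner",
                                     size_grade = "present_combined")),
               "not allowed")
  expect_error(score_site(lesion_row("T5/T6", "caudal", "anterior_corner",
                                     slice_domain = "lateral_left",
                                     size_grade = "present_large")),
               "not allowed")
})

test_that("DVU scores saturate at the published maxima", {
  sat <- saturated_exam()
  expect_equal(score_dvu(sat, "L2/L3"), 24L)
  expect_equal(score_dvu(sat, "T7/T8"), 24L)
  expect_equal(score_dvu(sat, "C4/C5"), 8L)
  # central-only saturation of a thoracolumbar DVU: 16
  central <- fasss_sites("L2/L3")
  central <- central[central$slice_domain == "central", ]
  ex <- fasss_exam(data.frame(
    dvu = central$dvu, endplate = central$endplate,
    region = central$region, slice_domain = central$slice_domain,
    size_grade = "present_large",
    cortex_large = NA_integer_, midpoint_large = NA_integer_
  ))
  expect_equal(score_dvu(ex, "L2/L3"), 16L)
  # lateral-only saturation: 8
  lat <- fasss_sites("L2/L3")
  lat <- lat[lat$slice_domain != "central", ]
  ex_lat <- fasss_exam(data.frame(
    dvu = lat$dvu, endplate = lat$endplate, region = lat$region,
    slice_domain = lat$slice_domain, size_grade = "present",
    cortex_large = NA_integer_, midpoint_large = NA_integer_
  ))
  expect_equal(score_dvu(ex_lat, "L2/L3"), 8L)
})

test_that("the worked single-slice example scores 1,1,1,3 with sum 6", {
  sheet <- score_exam(worked_example_exam())
  got <- sheet$per_dvu[c("T11/T12", "T12/L1", "L1/L2", "L2/L3")]
  expect_equal(unname(got), c(1L, 1L, 1L, 3L))
  expect_equal(sum(got), 6L)
  expect_equal(sheet$total, 6L)
  expect_equal(score_dvu(worked_example_exam(), "L2/L3"), 3L)
})

test_that("combined lesions credit the noncorner site once, largest credit wins", {
  # combined corner alone: corner 1 + noncorner credit 2
  ex1 <- fasss_exam(lesion_row("L1/L2", "caudal", "anterior_corner",
                               size_grade = "present_combined"))
  expect_equal(score_dvu(ex1, "L1/L2"), 3L)
  # both additions: corner 2 + noncorner credit 4
  ex2 <- fasss_exam(lesion_row("L1/L2", "caudal", "anterior_corner",
                               size_grade = "present_combined",
                               cortex_large = 1L, midpoint_large = 1L))
  expect_equal(score_dvu(ex2, "L1/L2"), 6L)
  # combined (midpoint large, credit 4) + direct small noncorner (credit 2):
  # the larger credit wins, no double count
  ex3 <- fasss_exam(rbind(
    lesion_row("L1/L2", "caudal", "anterior_corner",
               size_grade = "present_combined", cortex_large = 0L,
               midpoint_large = 1L),
    lesion_row("L1/L2", "caudal", "noncorner")
  ))
  expect_equal(score_dvu(ex3, "L1/L2"), 1L + 4L)
  # direct large noncorner (4) beats a combined credit of 2
  ex4 <- fasss_exam(rbind(
    lesion_row("L1/L2", "caudal", "anterior_corner",
               size_grade = "present_combined", midpoint_large = 0L),
    lesion_row("L1/L2", "caudal", "noncorner",
               size_grade = "present_large")
  ))
  expect_equal(score_dvu(ex4, "L1/L2"), 1L + 4L)
  # credits on different endplates do not interact
  ex5 <- fasss_exam(rbind(
    lesion_row("L1/L2", "caudal", "anterior_corner",
               size_grade = "present_combined"),
    lesion_row("L1/L2", "cranial", "noncorner",
               size_grade = "present_large")
  ))
  expect_equal(score_dvu(ex5, "L1/L2"), 1L + 2L + 4L)
})

test_that("exam scoring is additive over DVUs and partitions into segments", {
  set.seed(101)
  for (i in 1:10) {
    ex <- random_valid_exam(p = 0.12)
    sheet <- score_exam(ex)
    expect_equal(sheet$total, sum(sheet$per_dvu))
    expect_equal(sheet$total, sheet$cervical + sheet$thoracic + sheet$lumbar)
    dvus <- fasss_dvus()
    expect_equal(sheet$cervical,
                 sum(sheet$per_dvu[dvus$segment == "cervical"]))
    # vectorised exam scorer agrees with the per-DVU reference path
    ref <- vapply(dvus$dvu, function(d) score_dvu(ex, d), integer(1))
    expect_equal(sheet$per_dvu, ref)
    # cap property
    expect_true(all(sheet$per_dvu <= max_dvu_score(dvus$dvu)))
    expect_true(all(sheet$per_dvu >= 0L))
  }
})

test_that("adding one valid annotation never decreases any score component", {
  set.seed(202)
  sites <- fasss_all_sites()
  for (i in 1:15) {
    ex <- random_valid_exam(p = 0.08)
    taken <- with(ex$lesions,
                  paste(dvu, endplate, region, slice_domain))
    open <- sites[!paste(sites$dvu, sites$endplate, sites$region,
                         sites$slice_domain) %in% taken, , drop = FALSE]
    pick <- open[sample(nrow(open), 1L), , drop = FALSE]
    grade <- if (pick$segment == "cervical" ||
                 pick$slice_domain != "central") {
      "present"
    } else if (pick$region == "noncorner") "present_large" else {
      sample(c("present_small", "present_large", "present_combined"), 1L)
    }
    les2 <- rbind(ex$lesions,
                  lesion_row(pick$dvu, pick$endplate, pick$region,
                             pick$slice_domain, grade,
                             cortex_large = 1L, midpoint_large = 1L))
    ex2 <- fasss_exam(les2)
    s1 <- score_exam(ex)
    s2 <- score_exam(ex2)
    expect_true(s2$total >= s1$total)
    expect_true(all(s2$per_dvu >= s1$per_dvu))
    expect_true(s2$cervical >= s1$cervical &&
                  s2$thoracic >= s1$thoracic && s2$lumbar >= s1$lumbar)
  }
})

test_that("saturated exam reaches 456 with segmental totals 48/288/120", {
  sheet <- score_exam(saturated_exam())
  expect_equal(sheet$total, 456L)
  expect_equal(sheet$cervical, 48L)
  expect_equal(sheet$thoracic, 288L)
  expect_equal(sheet$lumbar, 120L)
  expect_equal(score_exam(fasss_exam())$total, 0L)
})

test_that("excluded DVUs score zero and reject annotations", {
  sat <- saturated_exam()
  sat$excluded_dvus <- "L2/L3"
  expect_equal(score_dvu(sat, "L2/L3"), 0L)
  expect_gt(nrow(validate_annotations(sat)), 0L)
  expect_error(score_exam(sat), "violation")
  # exclusion without annotations is fine and visibly flagged
  ex <- fasss_exam(lesion_row("T5/T6", "cranial", "anterior_corner"),
                   excluded_dvus = "L2/L3")
  sheet <- score_exam(ex)
  expect_equal(sheet$per_dvu[["L2/L3"]], 0L)
  expect_equal(sheet$excluded_dvus, "L2/L3")
})

test_that("duplicate annotations are reported by validation", {
  ex <- fasss_exam(rbind(
    lesion_row("T5/T6", "cranial", "anterior_corner"),
    lesion_row("T5/T6", "cranial", "anterior_corner",
               size_grade = "present_large")
  ))
  v <- validate_annotations(ex)
  expect_equal(sum(v$problem == "duplicate annotation for site"), 1L)
  expect_error(score_exam(ex), "duplicate")
})

test_that("change scores are follow-up minus baseline and antisymmetric", {
  b <- score_exam(worked_example_exam())
  f <- score_exam(saturated_exam(patient_id = "example"))
  ch <- change_score(b, f, interval_years = 1.5)
  expect_equal(ch$delta_total, 456L - 6L)
  expect_equal(ch$interval_years, 1.5)
  rev <- change_score(f, b, interval_years = 1.5)
  expect_equal(rev$delta_total, -ch$delta_total)
  expect_equal(rev$delta_thoracic, -ch$delta_thoracic)
  same <- change_score(b, b, interval_years = 1)
  expect_equal(same$delta_total, 0L)
  # pairing contract
  other <- score_exam(saturated_exam(patient_id = "someone_else"))
  expect_error(change_score(b, other), "different patients")
  expect_error(change_score(b, f, interval_years = 0), "positive")
})

test_that("validation returns violations as data and clean sets score", {
  # lateral cervical site
  ex <- fasss_exam(lesion_row("C3/C4", "cranial", "anterior_corner",
                              slice_domain = "lateral_left",
                              size_grade = "present"))
  v <- validate_annotations(ex)
  expect_equal(nrow(v), 1L)
  expect_match(v$problem, "cervical")
  expect_equal(nrow(validate_annotations(worked_example_exam())), 0L)
  expect_silent(score_exam(worked_example_exam()))
})
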