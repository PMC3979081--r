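# FASSS scoring engine.
#
# Input is sparse: one row per observed lesion (absent sites are simply not
# annotated). The annotation table uses the long CSV dialect:
#   record_type {lesion|dvu_exclusion}, patient_id, exam_time_years,
#   reader_id, dvu, endplate {cranial|caudal},
#   region {anterior_corner|posterior_corner|noncorner},
#   slice_domain {central|lateral_left|lateral_right},
#   size_grade {present|present_small|present_large|present_combined},
#   cortex_large {0|1|NA}, midpoint_large {0|1|NA}.

.annotation_cols <- c(
  "record_type", "patient_id", "exam_time_years", "reader_id", "dvu",
  "endplate", "region", "slice_domain", "size_grade",
  "cortex_large", "midpoint_large"
)

#' Construct a single-exam annotation set
#'
#' Bundles one reader's lesion annotations for one exam with the set of
#' excluded DVUs (DVUs whose disc height is unequivocally reduced by at
#' least 50% are not assessed, since fat there may be degenerative).
#'
#' @param lesions Data frame of lesion rows with columns `dvu`, `endplate`,
#'   `region`, `slice_domain`, `size_grade` and optionally `cortex_large`,
#'   `midpoint_large` (0/1, used only for `present_combined`). A zero-row
#'   data frame (or `NULL`) is an exam without lesions.
#' @param excluded_dvus Character vector of excluded DVU codes.
#' @param patient_id,exam_time_years,reader_id Exam identity.
#' @return An object of class `fasss_exam`.
#' @export
fasss_exam <- function(lesions = NULL, excluded_dvus = character(),
                       patient_id = "p1", exam_time_years = 0,
                       reader_id = "r1") {
  if (is.null(lesions)) {
    lesions <- data.frame(
      dvu = character(), endplate = character(), region = character(),
      slice_domain = character(), size_grade = character(),
      cortex_large = integer(), midpoint_large = integer(),
      stringsAsFactors = FALSE
    )
  }
  lesions <- as.data.frame(lesions, stringsAsFactors = FALSE)
  if (is.null(lesions$cortex_large)) lesions$cortex_large <- NA_integer_
  if (is.null(lesions$midpoint_large)) lesions$midpoint_large <- NA_integer_
  if (length(excluded_dvus) > 0L) check_dvu(excluded_dvus)
  if (nrow(lesions) > 0L) check_dvu(lesions$dvu)
  structure(
    list(
      patient_id = patient_id,
      exam_time_years = exam_time_years,
      reader_id = reader_id,
      lesions = lesions,
      excluded_dvus = unique(as.character(excluded_dvus))
    ),
    class = "fasss_exam"
  )
}

#' @export
print.fasss_exam <- function(x, ...) {
  cat(sprintf(
    "<fasss_exam> patient %s, t = %s y, reader %s: %d lesion(s), %d excluded DVU(s)\n",
    x$patient_id, format(x$exam_time_years), x$reader_id,
    nrow(x$lesions), length(x$excluded_dvus)
  ))
  invisible(x)
}

# Size-grade vocabulary by site class:
#  - cervical (any region) and lateral corners: "present" only
#  - thoracolumbar central corner: present_small / present_large /
#    present_combined
#  - thoracolumbar central noncorner: present_small / present_large
.allowed_grades <- function(segment, region, slice_domain) {
  if (segment == "cervical" || slice_domain != "central") return("present")
  if (region == "noncorner") return(c("present_small", "present_large"))
  c("present_small", "present_large", "present_combined")
}

#' Validate an exam's annotations
#'
#' Checks every lesion row against the anatomy and the size-grade
#' vocabulary. Violations are returned as data, not raised, so batch
#' pipelines can report all problems at once; an exam is scoreable iff the
#' returned frame has zero rows.
#'
#' Checked: the site must exist (known DVU; lateral slice domains only in
#' the thoracic/lumbar spine; noncorner only on central slices); the size
#' grade must be legal for the site class; no annotation may reference an
#' excluded DVU; at most one annotation per site.
#'
#' @param exam A [fasss_exam()].
#' @return Data frame with columns `row` (index into `exam$lesions`),
#'   `site_id` and `problem`.
#' @export
validate_annotations <- function(exam) {
  stopifnot(inherits(exam, "fasss_exam"))
  les <- exam$lesions
  empty <- data.frame(row = integer(), site_id = character(),
                      problem = character(), stringsAsFactors = FALSE)
  if (nrow(les) == 0L) return(empty)
  n <- nrow(les)
  seg <- dvu_segment(les$dvu)
  ids <- site_id(les$dvu, les$endplate, les$region, les$slice_domain)

  rows <- integer(0)
  probs <- character(0)
  flag <- function(hit, problem) {
    rows <<- c(rows, which(hit))
    probs <<- c(probs, rep_len(problem, sum(hit)))
  }

  bad_ep <- !les$endplate %in% c("cranial", "caudal")
  bad_reg <- !les$region %in% c("anterior_corner", "posterior_corner",
                                "noncorner")
  bad_sl <- !les$slice_domain %in% c("central", "lateral_left",
                                     "lateral_right")
  flag(bad_ep, "unknown endplate")
  flag(!bad_ep & bad_reg, "unknown region")
  flag(!bad_ep & !bad_reg & bad_sl, "unknown slice domain")

  well_formed <- !(bad_ep | bad_reg | bad_sl)
  cerv_lat <- well_formed & seg == "cervical" & les$slice_domain != "central"
  flag(cerv_lat, "lateral slice domain in cervical spine")
  nc_lat <- well_formed & !cerv_lat & les$region == "noncorner" &
    les$slice_domain != "central"
  flag(nc_lat, "noncorner lesion outside central slices")

  site_ok <- well_formed & !cerv_lat & !nc_lat
  # legal grades: "present" iff cervical or lateral; otherwise the graded
  # vocabulary, with present_combined reserved for corners
  sizeless <- seg == "cervical" | les$slice_domain != "central"
  grade_ok <- ifelse(
    sizeless,
    les$size_grade == "present",
    les$size_grade %in% c("present_small", "present_large") |
      (les$size_grade == "present_combined" & les$region != "noncorner")
  )
  bad_grade <- site_ok & !grade_ok
  if (any(bad_grade)) {
    for (i in which(bad_grade)) {
      ok <- .allowed_grades(seg[i], les$region[i], les$slice_domain[i])
      rows <- c(rows, i)
      probs <- c(probs, sprintf(
        "size grade '%s' not allowed for this site (allowed: %s)",
        les$size_grade[i], paste(ok, collapse = "/")))
    }
  }
  flag(site_ok & les$dvu %in% exam$excluded_dvus,
       "annotation on excluded DVU")
  flag(duplicated(ids), "duplicate annotation for site")

  if (length(rows) == 0L) return(empty)
  data.frame(row = rows, site_id = ids[rows], problem = probs,
             stringsAsFactors = FALSE)
}

.is_large <- function(x) !is.na(x) & x != 0

#' Score a single lesion annotation
#'
#' Corner fat lesions (central or lateral) score 1 when present; in the
#' thoracic and lumbar spine a central corner lesion scores +1 when large
#' (involving at least 25% of the endplate's anterior-posterior diameter or
#' the vertebral body height). Noncorner lesions (central slices only)
#' score 2, +2 when large. Cervical lesions are not graded for size.
#' A combined corner-and-noncorner lesion (a central corner lesion spanning
#' more than 50% of the anterior-posterior diameter) scores its corner
#' component here -- base 1, +1 if large at the anterior/posterior cortex --
#' while its noncorner credit (2, +2 if large at the endplate midpoint) is
#' attributed to the endplate's noncorner site by [score_dvu()], which
#' deduplicates that credit against any direct noncorner annotation.
#'
#' @param annotation One-row data frame (or list) with fields `dvu`,
#'   `endplate`, `region`, `slice_domain`, `size_grade`, `cortex_large`,
#'   `midpoint_large`.
#' @return Integer site score (the corner component for combined lesions).
#' @export
#' @examples
#' score_site(list(dvu = "L2/L3", endplate = "cranial",
#'                 region = "anterior_corner", slice_domain = "central",
#'                 size_grade = "present_large"))
score_site <- function(annotation) {
  a <- as.list(annotation)
  seg <- dvu_segment(a$dvu)
  ok <- .allowed_grades(seg, a$region, a$slice_domain)
  if (!a$size_grade %in% ok) {
    stop(sprintf("size grade '%s' not allowed at %s (allowed: %s)",
                 a$size_grade,
                 site_id(a$dvu, a$endplate, a$region, a$slice_domain),
                 paste(ok, collapse = "/")), call. = FALSE)
  }
  if (a$size_grade == "present") {
    return(if (a$region == "noncorner") 2L else 1L)
  }
  if (a$region == "noncorner") {
    return(if (a$size_grade == "present_large") 4L else 2L)
  }
  switch(a$size_grade,
    present_small = 1L,
    present_large = 2L,
    present_combined = 1L + as.integer(.is_large(a$cortex_large))
  )
}

# Noncorner credit a combined corner lesion contributes to its endplate.
.combined_noncorner_credit <- function(midpoint_large) {
  2L + 2L * as.integer(.is_large(midpoint_large))
}

#' Score one disco-vertebral unit
#'
#' Sums the site scores of one DVU, counting the noncorner component of
#' each endplate at most once: a direct noncorner annotation and the
#' noncorner credit carried by any combined corner lesion on the same
#' endplate do not double-count -- the largest credit wins. An excluded DVU
#' scores 0.
#'
#' @param exam A validated [fasss_exam()].
#' @param dvu A single DVU code.
#' @return Integer DVU score in `[0, max_dvu_score(dvu)]`.
#' @export
score_dvu <- function(exam, dvu) {
  stopifnot(inherits(exam, "fasss_exam"), length(dvu) == 1L)
  check_dvu(dvu)
  if (dvu %in% exam$excluded_dvus) return(0L)
  les <- exam$lesions
  les <- les[les$dvu == dvu, , drop = FALSE]
  if (nrow(les) == 0L) return(0L)
  total <- 0L
  for (ep in c("cranial", "caudal")) {
    rows <- les[les$endplate == ep, , drop = FALSE]
    if (nrow(rows) == 0L) next
    noncorner_credits <- 0L
    for (i in seq_len(nrow(rows))) {
      if (rows$region[i] == "noncorner") {
        noncorner_credits <- c(noncorner_credits,
                               score_site(rows[i, , drop = FALSE]))
      } else {
        total <- total + score_site(rows[i, , drop = FALSE])
        if (identical(rows$size_grade[i], "present_combined")) {
          noncorner_credits <- c(
            noncorner_credits,
            .combined_noncorner_credit(rows$midpoint_large[i])
          )
        }
      }
    }
    total <- total + max(noncorner_credits)
  }
  as.integer(total)
}

# Vectorised scorer for all 23 DVUs of a validated exam; agrees with
# score_dvu applied per DVU (asserted in the test suite).
.score_all_dvus <- function(exam) {
  dvus <- fasss_dvus()$dvu
  per_dvu <- setNames(integer(length(dvus)), dvus)
  les <- exam$lesions
  if (length(exam$excluded_dvus) > 0L) {
    les <- les[!les$dvu %in% exam$excluded_dvus, , drop = FALSE]
  }
  if (nrow(les) == 0L) return(per_dvu)

  is_nc <- les$region == "noncorner"
  grade <- les$size_grade
  corner_score <- ifelse(
    grade %in% c("present", "present_small"), 1L,
    ifelse(grade == "present_large", 2L,
           1L + as.integer(.is_large(les$cortex_large))))
  nc_credit <- ifelse(grade %in% c("present", "present_small"), 2L, 4L)

  corner_rows <- !is_nc
  corner_sum <- tapply(corner_score[corner_rows], les$dvu[corner_rows], sum)
  per_dvu[names(corner_sum)] <- per_dvu[names(corner_sum)] +
    as.integer(corner_sum)

  # per-endplate noncorner credit: direct annotations and combined-corner
  # carries compete; the maximum wins
  credit <- integer(0)
  key <- character(0)
  if (any(is_nc)) {
    credit <- c(credit, nc_credit[is_nc])
    key <- c(key, paste(les$dvu[is_nc], les$endplate[is_nc]))
  }
  comb <- grade == "present_combined"
  if (any(comb)) {
    credit <- c(credit, .combined_noncorner_credit(les$midpoint_large[comb]))
    key <- c(key, paste(les$dvu[comb], les$endplate[comb]))
  }
  if (length(credit) > 0L) {
    ep_max <- tapply(credit, key, max)
    ep_dvu <- sub(" (cranial|caudal)$", "", names(ep_max))
    dvu_nc <- tapply(as.integer(ep_max), ep_dvu, sum)
    per_dvu[names(dvu_nc)] <- per_dvu[names(dvu_nc)] + as.integer(dvu_nc)
  }
  per_dvu
}

#' Score an exam
#'
#' Computes the per-DVU scores over all 23 DVUs, the segmental sums
#' (cervical, thoracic, lumbar) and the total FASSS (range 0-456) for one
#' reader's annotations of one exam. The exam must pass
#' [validate_annotations()]; otherwise an error lists the offending sites.
#'
#' @param exam A [fasss_exam()].
#' @return An object of class `fasss_scoresheet`: a list with `per_dvu`
#'   (named integer vector, 23 entries), `cervical`, `thoracic`, `lumbar`,
#'   `total`, `excluded_dvus`, and the exam identity fields.
#' @export
#' @examples
#' score_exam(fasss_exam())$total  # empty exam scores 0
score_exam <- function(exam) {
  stopifnot(inherits(exam, "fasss_exam"))
  viol <- validate_annotations(exam)
  if (nrow(viol) > 0L) {
    stop("exam has ", nrow(viol), " annotation violation(s):\n  ",
         paste(sprintf("row %d [%s]: %s", viol$row, viol$site_id,
                       viol$problem), collapse = "\n  "),
         call. = FALSE)
  }
  dvus <- fasss_dvus()
  per_dvu <- .score_all_dvus(exam)
  seg_sum <- function(s) as.integer(sum(per_dvu[dvus$segment == s]))
  structure(
    list(
      patient_id = exam$patient_id,
      exam_time_years = exam$exam_time_years,
      reader_id = exam$reader_id,
      per_dvu = per_dvu,
      cervical = seg_sum("cervical"),
      thoracic = seg_sum("thoracic"),
      lumbar = seg_sum("lumbar"),
      total = as.integer(sum(per_dvu)),
      excluded_dvus = exam$excluded_dvus
    ),
    class = "fasss_scoresheet"
  )
}

#' @export
print.fasss_scoresheet <- function(x, ...) {
  cat(sprintf(
    "FASSS score sheet: patient %s, t = %s y, reader %s\n",
    x$patient_id, format(x$exam_time_years), x$reader_id
  ))
  cat(sprintf("  total %d (cervical %d, thoracic %d, lumbar %d)\n",
              x$total, x$cervical, x$thoracic, x$lumbar))
  nz <- x$per_dvu[x$per_dvu > 0L]
  if (length(nz) > 0L) {
    cat("  nonzero DVUs: ",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$excluded_dvus) > 0L) {
    cat("  excluded DVUs:", paste(x$excluded_dvus, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Change score between two timepoints
#'
#' Follow-up minus baseline, for the total and each segment; change scores
#' may be negative (fat lesions can regress). Both sheets must belong to
#' the same patient and reader.
#'
#' @param baseline,followup `fasss_scoresheet` objects.
#' @param interval_years Positive inter-scan interval in years. Defaults to
#'   the difference of the sheets' `exam_time_years`.
#' @return An object of class `fasss_change`: a list with `patient_id`,
#'   `reader_id`, `interval_years`, `delta_total`, `delta_cervical`,
#'   `delta_thoracic`, `delta_lumbar` and `delta_per_dvu`.
#' @export
change_score <- function(baseline, followup, interval_years = NULL) {
  stopifnot(inherits(baseline, "fasss_scoresheet"),
            inherits(followup, "fasss_scoresheet"))
  if (!identical(baseline$patient_id, followup$patient_id)) {
    stop("baseline and follow-up belong to different patients", call. = FALSE)
  }
  if (!identical(baseline$reader_id, followup$reader_id)) {
    stop("baseline and follow-up belong to different readers", call. = FALSE)
  }
  if (is.null(interval_years)) {
    interval_years <- followup$exam_time_years - baseline$exam_time_years
  }
  if (!is.finite(interval_years) || interval_years <= 0) {
    stop("interval_years must be positive", call. = FALSE)
  }
  structure(
    list(
      patient_id = baseline$patient_id,
      reader_id = baseline$reader_id,
      interval_years = interval_years,
      delta_total = followup$total - baseline$total,
      delta_cervical = followup$cervical - baseline$cervical,
      delta_thoracic = followup$thoracic - baseline$thoracic,
      delta_lumbar = followup$lumbar - baseline$lumbar,
      delta_per_dvu = followup$per_dvu - baseline$per_dvu
    ),
    class = "fasss_change"
  )
}

#' @export
print.fasss_change <- function(x, ...) {
  cat(sprintf(
    "FASSS change: patient %s, reader %s, interval %.2f y\n  delta total %+d (cervical %+d, thoracic %+d, lumbar %+d)\n",
    x$patient_id, x$reader_id, x$interval_years, x$delta_total,
    x$delta_cervical, x$delta_thoracic, x$delta_lumbar
  ))
  invisible(x)
}

#' Fully saturated exam
#'
#' Annotates every scoreable site of every DVU at its maximal grade:
#' thoracolumbar central corners and noncorners `present_large`, lateral
#' corners `present`, all cervical sites `present`. Scoring it yields the
#' FASSS ceiling of 456 (cervical 48, thoracic 288, lumbar 120).
#'
#' @param patient_id,exam_time_years,reader_id Exam identity.
#' @return A [fasss_exam()].
#' @export
#' @examples
#' score_exam(saturated_exam())$total  # 456
saturated_exam <- function(patient_id = "pmax", exam_time_years = 0,
                           reader_id = "r1") {
  sites <- fasss_all_sites()
  grade <- ifelse(
    sites$segment == "cervical" | sites$slice_domain != "central",
    "present", "present_large"
  )
  lesions <- data.frame(
    dvu = sites$dvu, endplate = sites$endplate, region = sites$region,
    slice_domain = sites$slice_domain, size_grade = grade,
    cortex_large = NA_integer_, midpoint_large = NA_integer_,
    stringsAsFactors = FALSE
  )
  fasss_exam(lesions, character(), patient_id, exam_time_years, reader_id)
}

#' Score every exam in an annotation table
#'
#' Splits a long-format annotation table (the CSV dialect of
#' [read_annotations()]) into exams by `(patient_id, exam_time_years,
#' reader_id)` and scores each.
#'
#' Annotation input is sparse (absent sites are simply not annotated), so
#' an exam with no lesions and no exclusions has no rows at all. Supplying
#' `exam_grid` scores such exams as 0 instead of dropping them, which keeps
#' longitudinal pairing complete.
#'
#' @param annotations Data frame in the annotation dialect, or a list of
#'   [fasss_exam()] objects.
#' @param exam_grid Optional data frame (`patient_id`, `exam_time_years`,
#'   `reader_id`) listing every exam that was read; exams absent from
#'   `annotations` are scored as empty.
#' @return Data frame with one row per exam: identity columns, `total`,
#'   `cervical`, `thoracic`, `lumbar`, one column per DVU code, and
#'   `excluded_dvus` (semicolon-joined codes).
#' @export
fasss_score <- function(annotations, exam_grid = NULL) {
  exams <- if (is.data.frame(annotations)) {
    annotations_to_exams(annotations, exam_grid)
  } else {
    annotations
  }
  sheets <- lapply(exams, score_exam)
  do.call(rbind, lapply(sheets, as.data.frame))
}

#' @export
as.data.frame.fasss_scoresheet <- function(x, ...) {
  out <- data.frame(
    patient_id = x$patient_id,
    exam_time_years = x$exam_time_years,
    reader_id = x$reader_id,
    total = x$total,
    cervical = x$cervical,
    thoracic = x$thoracic,
    lumbar = x$lumbar,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  dvu_cols <- as.data.frame(as.list(x$per_dvu), check.names = FALSE)
  out <- cbind(out, dvu_cols)
  out$excluded_dvus <- paste(x$excluded_dvus, collapse = ";")
  out
}

#' Group an annotation table into exams
#'
#' @param annotations Data frame in the long annotation dialect, including
#'   `record_type` (`"lesion"` rows carry sites, `"dvu_exclusion"` rows
#'   carry only `dvu`).
#' @param exam_grid Optional roster of exams (see [fasss_score()]).
#' @return List of [fasss_exam()] objects, ordered by patient, time, reader.
#' @export
annotations_to_exams <- function(annotations, exam_grid = NULL) {
  need <- c("record_type", "patient_id", "exam_time_years", "reader_id",
            "dvu")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0L) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(annotations$cortex_large)) {
    annotations$cortex_large <- NA_integer_
  }
  if (is.null(annotations$midpoint_large)) {
    annotations$midpoint_large <- NA_integer_
  }
  key <- interaction(annotations$patient_id, annotations$exam_time_years,
                     annotations$reader_id, drop = TRUE, lex.order = TRUE)
  exams <- lapply(split(annotations, key), function(g) {
    les <- g[g$record_type == "lesion", , drop = FALSE]
    exc <- g$dvu[g$record_type == "dvu_exclusion"]
    fasss_exam(
      lesions = les[, c("dvu", "endplate", "region", "slice_domain",
                        "size_grade", "cortex_large", "midpoint_large")],
      excluded_dvus = exc,
      patient_id = as.character(g$patient_id[1]),
      exam_time_years = g$exam_time_years[1],
      reader_id = as.character(g$reader_id[1])
    )
  })
  if (!is.null(exam_grid)) {
    have <- vapply(exams, function(e) {
      paste(e$patient_id, as.character(e$exam_time_years), e$reader_id,
            sep = "\r")
    }, character(1))
    want <- paste(exam_grid$patient_id,
                  as.character(exam_grid$exam_time_years),
                  exam_grid$reader_id, sep = "\r")
    for (j in which(!(want %in% have))) {
      exams[[length(exams) + 1L]] <- fasss_exam(
        patient_id = as.character(exam_grid$patient_id[j]),
        exam_time_years = exam_grid$exam_time_years[j],
        reader_id = as.character(exam_grid$reader_id[j])
      )
    }
  }
  exams
}

#' Pairwise change scores from a score-sheet table
#'
#' For every `(patient_id, reader_id)` with exactly two timepoints, the
#' earlier exam is the baseline and the later the follow-up; the interval
#' is computed from `exam_time_years`.
#'
#' @param sheets Score-sheet data frame from [fasss_score()].
#' @return Data frame with `patient_id`, `reader_id`, `interval_years`,
#'   `baseline_total`, `followup_total`, `delta_total`, `delta_cervical`,
#'   `delta_thoracic`, `delta_lumbar`.
#' @export
fasss_change_table <- function(sheets) {
  key <- interaction(sheets$patient_id, sheets$reader_id, drop = TRUE,
                     lex.order = TRUE)
  rows <- lapply(split(sheets, key), function(g) {
    if (nrow(g) != 2L) {
      stop("patient ", g$patient_id[1], ", reader ", g$reader_id[1],
           ": expected exactly 2 timepoints, found ", nrow(g),
           call. = FALSE)
    }
    g <- g[order(g$exam_time_years), , drop = FALSE]
    data.frame(
      patient_id = g$patient_id[1],
      reader_id = g$reader_id[1],
      interval_years = g$exam_time_years[2] - g$exam_time_years[1],
      baseline_total = g$total[1],
      followup_total = g$total[2],
      delta_total = g$total[2] - g$total[1],
      delta_cervical = g$cervical[2] - g$cervical[1],
      delta_thoracic = g$thoracic[2] - g$thoracic[1],
      delta_lumbar = g$lumbar[2] - g$lumbar[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
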