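# Readers/writers for the annotation and score-sheet CSV dialects, the
# reliability report (JSON + tidy CSV point sets), and simulation configs
# (YAML or JSON mirroring cohort_params/reader_error_params fields).

#' Read an annotation CSV
#'
#' Long format, one row per observed lesion or per DVU exclusion. Required
#' header: `record_type, patient_id, exam_time_years, reader_id, dvu,
#' endplate, region, slice_domain, size_grade, cortex_large,
#' midpoint_large`. Rows are grouped into exams by
#' `(patient_id, exam_time_years, reader_id)` and each exam is validated;
#' malformed rows are reported with their file line numbers.
#'
#' @param path CSV file path.
#' @return List of [fasss_exam()] objects (empty list for a header-only
#'   file).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(.annotation_cols, names(raw))
  if (length(miss) > 0L) {
    stop(path, ": header lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) return(list())
  raw$.line <- seq_len(nrow(raw)) + 1L  # header is line 1

  bad_type <- !raw$record_type %in% c("lesion", "dvu_exclusion")
  if (any(bad_type)) {
    stop(path, ": unknown record_type at line(s) ",
         paste(raw$.line[bad_type], collapse = ", "), call. = FALSE)
  }
  known <- fasss_dvus()$dvu
  bad_dvu <- !raw$dvu %in% known
  if (any(bad_dvu)) {
    stop(path, ": unknown DVU code at line(s) ",
         paste(sprintf("%d ('%s')", raw$.line[bad_dvu],
                       raw$dvu[bad_dvu]), collapse = ", "), call. = FALSE)
  }

  ann <- data.frame(
    record_type = raw$record_type,
    patient_id = raw$patient_id,
    exam_time_years = as.numeric(raw$exam_time_years),
    reader_id = raw$reader_id,
    dvu = raw$dvu,
    endplate = raw$endplate,
    region = raw$region,
    slice_domain = raw$slice_domain,
    size_grade = raw$size_grade,
    cortex_large = suppressWarnings(as.integer(raw$cortex_large)),
    midpoint_large = suppressWarnings(as.integer(raw$midpoint_large)),
    stringsAsFactors = FALSE
  )
  exams <- annotations_to_exams(ann)
  lines <- split(raw$.line[ann$record_type == "lesion"],
                 interaction(ann$patient_id, ann$exam_time_years,
                             ann$reader_id, drop = TRUE,
                             lex.order = TRUE)[ann$record_type == "lesion"])
  msgs <- character()
  for (nm in names(exams)) {
    viol <- validate_annotations(exams[[nm]])
    if (nrow(viol) > 0L) {
      ln <- lines[[nm]][viol$row]
      msgs <- c(msgs, sprintf("line %d [%s]: %s", ln, viol$site_id,
                              viol$problem))
    }
  }
  if (length(msgs) > 0L) {
    stop(path, ": invalid annotations:\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  unname(exams)
}

#' Write an annotation table
#'
#' @param annotations Annotation data frame in the long dialect (as
#'   produced by [simulate_reader()]), or a list of [fasss_exam()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (!is.data.frame(annotations)) {
    annotations <- do.call(rbind, lapply(annotations, exam_to_rows))
  }
  out <- annotations[, .annotation_cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @keywords internal
exam_to_rows <- function(exam) {
  les <- exam$lesions
  n <- nrow(les)
  ne <- length(exam$excluded_dvus)
  data.frame(
    record_type = c(rep("lesion", n), rep("dvu_exclusion", ne)),
    patient_id = exam$patient_id,
    exam_time_years = exam$exam_time_years,
    reader_id = exam$reader_id,
    dvu = c(les$dvu, exam$excluded_dvus),
    endplate = c(les$endplate, rep(NA_character_, ne)),
    region = c(les$region, rep(NA_character_, ne)),
    slice_domain = c(les$slice_domain, rep(NA_character_, ne)),
    size_grade = c(les$size_grade, rep(NA_character_, ne)),
    cortex_large = c(les$cortex_large, rep(NA_integer_, ne)),
    midpoint_large = c(les$midpoint_large, rep(NA_integer_, ne)),
    stringsAsFactors = FALSE
  )
}

#' Write and read score-sheet CSVs
#'
#' Columns: `patient_id, exam_time_years, reader_id, total, cervical,
#' thoracic, lumbar`, then the 23 per-DVU columns named by DVU code, then
#' `excluded_dvus` (semicolon-joined codes).
#'
#' @param sheets Score-sheet data frame from [fasss_score()].
#' @param path CSV path.
#' @return `path` (write) or the score-sheet data frame (read).
#' @export
write_scoresheets <- function(sheets, path) {
  utils::write.csv(sheets, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scoresheets
#' @export
read_scoresheets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "exam_time_years", "reader_id", "total",
            "cervical", "thoracic", "lumbar")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0L) {
    stop(path, ": header lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out$patient_id <- as.character(out$patient_id)
  out$reader_id <- as.character(out$reader_id)
  if (is.null(out$excluded_dvus)) out$excluded_dvus <- ""
  out$excluded_dvus[is.na(out$excluded_dvus)] <- ""
  out
}

#' Full two-reader reliability report
#'
#' Computes the analysis block the reading-exercise workflow reports:
#' descriptives of both readers' baseline and change scores, baseline and
#' change-score ICC with CI and band, Bland-Altman limits for baseline and
#' change, the smallest detectable change, cumulative-probability points,
#' and (optionally) the interval-stratified reliability.
#'
#' @param pairs Paired two-reader table as from [reader_pairs()].
#' @param coverage Coverage for limits of agreement and SDC (default 0.80).
#' @param strata Stratum table as from [default_strata()], or `NULL` to
#'   skip stratification.
#' @return Object of class `fasss_report` (nested list).
#' @export
reliability_report <- function(pairs, coverage = 0.80,
                               strata = default_strata()) {
  rep_list <- list(
    n = nrow(pairs),
    coverage = coverage,
    descriptives = list(
      baseline_r1 = descriptives(pairs$baseline_r1),
      baseline_r2 = descriptives(pairs$baseline_r2),
      change_r1 = descriptives(pairs$delta_r1),
      change_r2 = descriptives(pairs$delta_r2)
    ),
    icc_baseline = icc_a1(cbind(pairs$baseline_r1, pairs$baseline_r2)),
    icc_change = icc_a1(cbind(pairs$delta_r1, pairs$delta_r2)),
    ba_baseline = bland_altman(pairs$baseline_r1, pairs$baseline_r2,
                               coverage = coverage),
    ba_change = bland_altman(pairs$delta_r1, pairs$delta_r2,
                             coverage = coverage),
    sdc = sdc(pairs$delta_r1, pairs$delta_r2, coverage = coverage),
    cumprob_baseline = list(
      r1 = cumulative_probability_points(pairs$baseline_r1),
      r2 = cumulative_probability_points(pairs$baseline_r2)
    ),
    cumprob_change = list(
      r1 = cumulative_probability_points(pairs$delta_r1),
      r2 = cumulative_probability_points(pairs$delta_r2)
    ),
    stratified = if (!is.null(strata)) {
      stratified_reliability(pairs, strata, coverage = coverage)
    }
  )
  class(rep_list) <- "fasss_report"
  rep_list
}

#' @export
print.fasss_report <- function(x, ...) {
  cat(sprintf("Two-reader reliability report (n = %d pairs)\n", x$n))
  cat("  baseline: "); print(x$icc_baseline)
  cat("  change:   "); print(x$icc_change)
  cat("  "); print(x$sdc)
  if (!is.null(x$stratified)) print(x$stratified)
  invisible(x)
}

.icc_block <- function(population, ic) {
  list(population = population, n = ic$n_subjects, statistic = "icc_a1",
       estimate = .round4(ic$estimate), ci_low = .round4(ic$ci_low),
       ci_high = .round4(ic$ci_high), band = ic$band,
       degenerate = ic$degenerate)
}

.round4 <- function(x) {
  if (is.null(x) || !is.numeric(x)) return(x)
  round(x, 4)
}

#' Serialise a reliability report
#'
#' Writes the report as JSON (estimates at 4 decimal places) and the
#' Bland-Altman / cumulative-probability point sets as tidy CSVs for
#' external plotting.
#'
#' @param report A [reliability_report()].
#' @param json_path Output JSON path, or `NULL` to skip.
#' @param points_dir Directory for the point-set CSVs, or `NULL` to skip.
#' @return The JSON-ready list, invisibly.
#' @export
write_reliability_report <- function(report, json_path = NULL,
                                     points_dir = NULL) {
  desc4 <- function(d) lapply(d, .round4)
  blocks <- list(
    n = report$n,
    coverage = report$coverage,
    descriptives = lapply(report$descriptives, desc4),
    icc = list(
      .icc_block("baseline", report$icc_baseline),
      .icc_block("change", report$icc_change)
    ),
    bland_altman = lapply(
      list(baseline = report$ba_baseline, change = report$ba_change),
      function(b) list(mean_diff = .round4(b$mean_diff),
                       sd_diff = .round4(b$sd_diff),
                       coverage = b$coverage, z = .round4(b$z),
                       loa_low = .round4(b$loa_low),
                       loa_high = .round4(b$loa_high), n = b$n)
    ),
    sdc = list(value = .round4(report$sdc$sdc), z = .round4(report$sdc$z),
               coverage = report$sdc$coverage,
               sd_diff = .round4(report$sdc$sd_diff), k = report$sdc$k,
               n = report$sdc$n)
  )
  if (!is.null(report$stratified)) {
    blocks$stratified <- lapply(report$stratified$results, function(r) {
      if (isTRUE(r$degenerate)) {
        return(list(label = r$label, n = r$n, degenerate = TRUE))
      }
      list(label = r$label, n = r$n,
           icc_baseline = .icc_block(r$label, r$baseline_icc),
           icc_change = .icc_block(r$label, r$change_icc),
           sdc = .round4(r$sdc$sdc))
    })
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(blocks, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  if (!is.null(points_dir)) {
    dir.create(points_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, nm) {
      utils::write.csv(df, file.path(points_dir, nm), row.names = FALSE,
                       quote = FALSE)
    }
    wr(report$ba_baseline$points, "bland_altman_baseline.csv")
    wr(report$ba_change$points, "bland_altman_change.csv")
    wr(report$cumprob_baseline$r1, "cumprob_baseline_r1.csv")
    wr(report$cumprob_baseline$r2, "cumprob_baseline_r2.csv")
    wr(report$cumprob_change$r1, "cumprob_change_r1.csv")
    wr(report$cumprob_change$r2, "cumprob_change_r2.csv")
  }
  invisible(blocks)
}

#' Read a simulation configuration
#'
#' YAML or JSON document with optional top-level blocks `cohort`,
#' `reader1`, `reader2` whose fields mirror [cohort_params()] and
#' [reader_error_params()] arguments. Unknown fields are an error;
#' omitted fields keep their defaults.
#'
#' @param path Config file (`.yml`/`.yaml`/`.json`).
#' @return List with validated `cohort`, `reader1`, `reader2` entries.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(block, fun) {
    if (is.null(block)) return(fun())
    if (!is.null(block$segment_weights)) {
      block$segment_weights <- unlist(block$segment_weights)
    }
    if (!is.null(block$site_type_weights)) {
      block$site_type_weights <- unlist(block$site_type_weights)
    }
    bad <- setdiff(names(block), names(formals(fun)))
    if (length(bad) > 0L) {
      stop(path, ": unknown config field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(fun, block)
  }
  list(
    cohort = build(cfg$cohort, cohort_params),
    reader1 = build(cfg$reader1, reader_error_params),
    reader2 = {
      r2 <- build(cfg$reader2, reader_error_params)
      if (is.null(cfg$reader2$seed_offset)) r2$seed_offset <- 2L
      r2
    }
  )
}
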