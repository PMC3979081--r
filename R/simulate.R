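# Synthetic two-reader longitudinal cohort generator.
#
# Truth model: each patient carries a latent severity s ~ log-normal; a
# scoreable site is prevalent at baseline with probability
# 1 - exp(-s * w_segment * w_site_type). Segment weights default to the
# observed ordering thoracic > lumbar > cervical. At follow-up each true
# lesion persists unless it regresses (probability p_regress) and a
# Poisson number of new lesions accrues over the inter-scan interval,
# allocated to empty sites by the same weights. Readers observe the truth
# through a per-site Bernoulli error channel (sensitivity, false-positive
# rate, size misgrading).

#' Cohort generative parameters
#'
#' Settings for [simulate_truth()]. Defaults are calibrated so that a
#' default cohort's baseline totals have a mean in the low tens with an SD
#' of comparable magnitude, a heavy right skew, and segment means ordered
#' thoracic > lumbar > cervical.
#'
#' @param n_patients Number of patients.
#' @param severity_meanlog,severity_sdlog Location and scale of the
#'   per-patient log-normal latent severity.
#' @param segment_weights Named relative prevalence multipliers for
#'   `cervical`, `thoracic`, `lumbar`.
#' @param site_type_weights Named relative multipliers for `corner`
#'   (central corners), `noncorner` and `lateral` sites.
#' @param p_large Probability a prevalent thoracolumbar central lesion is
#'   large.
#' @param p_combined Probability a large thoracolumbar central corner
#'   lesion is combined (extends past 50% of the anterior-posterior
#'   diameter); combined lesions carry independent cortex/midpoint
#'   largeness flags.
#' @param accrual_rate Expected new lesions per patient per year (scaled by
#'   the patient's relative severity).
#' @param p_regress Probability an existing lesion has disappeared at
#'   follow-up.
#' @param interval_min,interval_max Uniform bounds (years) of the
#'   inter-scan interval.
#' @param p_excluded_dvu Per-DVU probability of degenerative exclusion
#'   (disc height reduced by half or more), fixed across timepoints.
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @return Object of class `cohort_params` (validated list).
#' @export
cohort_params <- function(n_patients = 135L,
                          severity_meanlog = log(0.045),
                          severity_sdlog = 1.3,
                          segment_weights = c(cervical = 0.5,
                                              thoracic = 1.0,
                                              lumbar = 0.9),
                          site_type_weights = c(corner = 1.0,
                                                noncorner = 0.5,
                                                lateral = 0.7),
                          p_large = 0.3,
                          p_combined = 0.15,
                          accrual_rate = 2.0,
                          p_regress = 0.05,
                          interval_min = 0.5,
                          interval_max = 3.0,
                          p_excluded_dvu = 0.01,
                          seed = 1L) {
  p <- list(
    n_patients = as.integer(n_patients),
    severity_meanlog = severity_meanlog,
    severity_sdlog = severity_sdlog,
    segment_weights = segment_weights,
    site_type_weights = site_type_weights,
    p_large = p_large, p_combined = p_combined,
    accrual_rate = accrual_rate, p_regress = p_regress,
    interval_min = interval_min, interval_max = interval_max,
    p_excluded_dvu = p_excluded_dvu,
    seed = as.integer(seed)
  )
  probs <- c(p$p_large, p$p_combined, p$p_regress, p$p_excluded_dvu)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (p$accrual_rate < 0) stop("accrual_rate must be >= 0", call. = FALSE)
  if (p$severity_sdlog < 0) stop("severity_sdlog must be >= 0", call. = FALSE)
  if (!all(c("cervical", "thoracic", "lumbar") %in%
           names(p$segment_weights))) {
    stop("segment_weights needs cervical/thoracic/lumbar", call. = FALSE)
  }
  if (!all(c("corner", "noncorner", "lateral") %in%
           names(p$site_type_weights))) {
    stop("site_type_weights needs corner/noncorner/lateral", call. = FALSE)
  }
  if (any(p$segment_weights < 0) || any(p$site_type_weights < 0)) {
    stop("weights must be >= 0", call. = FALSE)
  }
  if (p$interval_min <= 0 || p$interval_max < p$interval_min) {
    stop("need 0 < interval_min <= interval_max", call. = FALSE)
  }
  class(p) <- "cohort_params"
  p
}

#' Reader error-channel parameters
#'
#' @param sensitivity Per-site probability a true lesion is recorded.
#' @param false_positive_rate Per-site probability a lesion is recorded at
#'   an empty site (recorded at the minimal grade for the site class).
#' @param p_size_misgrade Probability a recorded small/large central
#'   thoracolumbar lesion has its size flipped.
#' @param seed_offset Integer offset added to the cohort seed so readers'
#'   error draws are independent conditional on the truth.
#' @return Object of class `reader_error_params`.
#' @export
reader_error_params <- function(sensitivity = 1.0,
                                false_positive_rate = 0.0,
                                p_size_misgrade = 0.0,
                                seed_offset = 1L) {
  p <- list(
    sensitivity = sensitivity,
    false_positive_rate = false_positive_rate,
    p_size_misgrade = p_size_misgrade,
    seed_offset = as.integer(seed_offset)
  )
  probs <- c(p$sensitivity, p$false_positive_rate, p$p_size_misgrade)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  class(p) <- "reader_error_params"
  p
}

# Weight of each site under (segment_weights, site_type_weights).
.site_weights <- function(sites, params) {
  type <- ifelse(sites$region == "noncorner", "noncorner",
                 ifelse(sites$slice_domain == "central", "corner",
                        "lateral"))
  unname(params$segment_weights[sites$segment] *
           params$site_type_weights[type])
}

# Draw size attributes for newly prevalent lesions, vectorised over sites.
.draw_sizes <- function(sites, params) {
  n <- nrow(sites)
  sizeable <- sites$segment != "cervical" & sites$slice_domain == "central"
  grade <- ifelse(sizeable, "present_small", "present")
  cortex <- rep(NA_integer_, n)
  midpoint <- rep(NA_integer_, n)
  if (any(sizeable)) {
    large <- sizeable & stats::runif(n) < params$p_large
    grade[large] <- "present_large"
    comb <- large & sites$region != "noncorner" &
      stats::runif(n) < params$p_combined
    grade[comb] <- "present_combined"
    cortex[comb] <- as.integer(stats::runif(n)[comb] < 0.5)
    midpoint[comb] <- as.integer(stats::runif(n)[comb] < 0.5)
  }
  data.frame(size_grade = grade, cortex_large = cortex,
             midpoint_large = midpoint, stringsAsFactors = FALSE)
}

#' Simulate ground-truth lesion states
#'
#' Draws each patient's latent severity, excluded DVUs, inter-scan
#' interval, baseline lesion set, and follow-up lesion set (persistence
#' minus regression plus Poisson accrual). Excluded DVUs never host
#' lesions and are fixed across timepoints.
#'
#' @param params A [cohort_params()].
#' @return Object of class `fasss_truth`: list with `patients` (data frame:
#'   `patient_id`, `severity`, `interval_years`), `exclusions` (data frame:
#'   `patient_id`, `dvu`) and `lesions` (data frame: `patient_id`,
#'   `timepoint` in `{baseline, followup}`, site columns, `size_grade`,
#'   `cortex_large`, `midpoint_large`).
#' @export
simulate_truth <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  sites <- fasss_all_sites()
  n_sites <- nrow(sites)
  w <- .site_weights(sites, params)
  dvus <- fasss_dvus()$dvu

  n <- params$n_patients
  ids <- sprintf("p%03d", seq_len(n))
  severity <- stats::rlnorm(n, params$severity_meanlog, params$severity_sdlog)
  interval <- stats::runif(n, params$interval_min, params$interval_max)
  mean_sev <- exp(params$severity_meanlog + params$severity_sdlog^2 / 2)

  excl_list <- lapply(seq_len(n), function(i) {
    dvus[stats::runif(length(dvus)) < params$p_excluded_dvu]
  })

  lesion_rows <- vector("list", n)
  for (i in seq_len(n)) {
    excluded <- sites$dvu %in% excl_list[[i]]
    p_base <- 1 - exp(-severity[i] * w)
    base_on <- stats::runif(n_sites) < p_base & !excluded

    # follow-up: persistence, regression, then severity-scaled accrual
    keep <- base_on & stats::runif(n_sites) >= params$p_regress
    lambda <- params$accrual_rate * interval[i] * severity[i] / mean_sev
    n_new <- stats::rpois(1L, lambda)
    fu_on <- keep
    empty <- which(!base_on & !excluded)
    if (n_new > 0L && length(empty) > 0L) {
      n_new <- min(n_new, length(empty))
      pick <- sample(empty, n_new, prob = w[empty])
      fu_on[pick] <- TRUE
    }

    base_sites <- sites[base_on, , drop = FALSE]
    base_attrs <- .draw_sizes(base_sites, params)
    new_idx <- which(fu_on & !base_on)
    new_sites <- sites[new_idx, , drop = FALSE]
    new_attrs <- .draw_sizes(new_sites, params)

    mk <- function(s, a, tp) {
      if (nrow(s) == 0L) return(NULL)
      data.frame(patient_id = ids[i], timepoint = tp,
                 s[, c("dvu", "segment", "endplate", "region",
                       "slice_domain", "site_id")],
                 a, stringsAsFactors = FALSE)
    }
    persist <- keep[base_on]  # among baseline rows
    lesion_rows[[i]] <- rbind(
      mk(base_sites, base_attrs, "baseline"),
      mk(base_sites[persist, , drop = FALSE],
         base_attrs[persist, , drop = FALSE], "followup"),
      mk(new_sites, new_attrs, "followup")
    )
  }

  lesions <- do.call(rbind, lesion_rows)
  if (is.null(lesions)) {
    lesions <- data.frame(patient_id = character(), timepoint = character(),
                          dvu = character(), segment = character(),
                          endplate = character(), region = character(),
                          slice_domain = character(),
                          size_grade = character(),
                          cortex_large = integer(),
                          midpoint_large = integer(),
                          stringsAsFactors = FALSE)
  }
  rownames(lesions) <- NULL
  exclusions <- data.frame(
    patient_id = rep(ids, lengths(excl_list)),
    dvu = unlist(excl_list),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      patients = data.frame(patient_id = ids, severity = severity,
                            interval_years = interval,
                            stringsAsFactors = FALSE),
      exclusions = exclusions,
      lesions = lesions,
      params = params
    ),
    class = "fasss_truth"
  )
}

#' @export
print.fasss_truth <- function(x, ...) {
  cat(sprintf(
    "<fasss_truth> %d patients, %d true lesion records, %d excluded DVU(s)\n",
    nrow(x$patients), nrow(x$lesions), nrow(x$exclusions)
  ))
  invisible(x)
}

#' Simulate one reader's annotations of a truth cohort
#'
#' Each true lesion is recorded with probability `sensitivity`; each empty
#' (non-excluded) site is annotated with probability
#' `false_positive_rate` at the minimal grade for its site class; recorded
#' small/large central thoracolumbar lesions have their size flipped with
#' probability `p_size_misgrade`. Error draws are independent across
#' sites, exams and readers. Outputs always pass [validate_annotations()].
#'
#' @param truth A [simulate_truth()] result.
#' @param reader A [reader_error_params()].
#' @param reader_id Identifier written into the annotations.
#' @return Annotation data frame in the long CSV dialect (lesion rows plus
#'   `dvu_exclusion` rows), both timepoints, one reader.
#' @export
simulate_reader <- function(truth, reader = reader_error_params(),
                            reader_id = "r1") {
  stopifnot(inherits(truth, "fasss_truth"),
            inherits(reader, "reader_error_params"))
  set.seed(truth$params$seed + reader$seed_offset)
  sites <- fasss_all_sites()
  pat <- truth$patients

  out <- vector("list", nrow(pat) * 2L)
  k <- 0L
  for (i in seq_len(nrow(pat))) {
    pid <- pat$patient_id[i]
    excl <- truth$exclusions$dvu[truth$exclusions$patient_id == pid]
    t_of <- c(baseline = 0, followup = pat$interval_years[i])
    for (tp in c("baseline", "followup")) {
      true_l <- truth$lesions[truth$lesions$patient_id == pid &
                                truth$lesions$timepoint == tp, ,
                              drop = FALSE]
      seen <- true_l[stats::runif(nrow(true_l)) < reader$sensitivity, ,
                     drop = FALSE]
      # size misgrading on gradable recorded lesions
      if (nrow(seen) > 0L && reader$p_size_misgrade > 0) {
        gradable <- seen$size_grade %in% c("present_small", "present_large")
        flip <- gradable & stats::runif(nrow(seen)) < reader$p_size_misgrade
        seen$size_grade[flip] <- ifelse(
          seen$size_grade[flip] == "present_small",
          "present_large", "present_small")
      }
      # false positives at empty, non-excluded sites
      fp <- NULL
      if (reader$false_positive_rate > 0) {
        open <- !(sites$site_id %in% true_l$site_id) &
          !(sites$dvu %in% excl)
        hit <- open & stats::runif(nrow(sites)) < reader$false_positive_rate
        if (any(hit)) {
          fp_sites <- sites[hit, , drop = FALSE]
          sizeable <- fp_sites$segment != "cervical" &
            fp_sites$slice_domain == "central"
          fp <- data.frame(
            fp_sites[, c("dvu", "endplate", "region", "slice_domain")],
            size_grade = ifelse(sizeable, "present_small", "present"),
            cortex_large = NA_integer_, midpoint_large = NA_integer_,
            stringsAsFactors = FALSE
          )
        }
      }
      les <- rbind(
        if (nrow(seen) > 0L) {
          seen[, c("dvu", "endplate", "region", "slice_domain",
                   "size_grade", "cortex_large", "midpoint_large")]
        },
        fp
      )
      n_les <- if (is.null(les)) 0L else nrow(les)
      if (n_les + length(excl) == 0L) next  # exam with nothing to record
      rows <- data.frame(
        record_type = c(rep("lesion", n_les),
                        rep("dvu_exclusion", length(excl))),
        patient_id = pid,
        exam_time_years = unname(t_of[tp]),
        reader_id = reader_id,
        dvu = c(if (n_les > 0L) les$dvu, excl),
        endplate = c(if (n_les > 0L) les$endplate,
                     rep(NA_character_, length(excl))),
        region = c(if (n_les > 0L) les$region,
                   rep(NA_character_, length(excl))),
        slice_domain = c(if (n_les > 0L) les$slice_domain,
                         rep(NA_character_, length(excl))),
        size_grade = c(if (n_les > 0L) les$size_grade,
                       rep(NA_character_, length(excl))),
        cortex_large = c(if (n_les > 0L) les$cortex_large,
                         rep(NA_integer_, length(excl))),
        midpoint_large = c(if (n_les > 0L) les$midpoint_large,
                           rep(NA_integer_, length(excl))),
        stringsAsFactors = FALSE
      )
      k <- k + 1L
      out[[k]] <- rows
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' End-to-end reliability recovery experiment
#'
#' For each replicate: simulate a truth cohort, observe it with two
#' readers, score all exams, and compute the baseline ICC, change-score
#' ICC, SDC and mean scores. This mirrors a two-reader longitudinal
#' reading exercise on fully synthetic data.
#'
#' @param cohort A [cohort_params()]; its `seed` is advanced per replicate.
#' @param reader1,reader2 [reader_error_params()] for the two readers.
#' @param replicates Number of replicates (>= 1).
#' @return Data frame with one row per replicate: `replicate`,
#'   `icc_baseline`, `icc_change`, `sdc`, `mean_baseline_r1`,
#'   `mean_baseline_r2`, `mean_change_r1`, `mean_change_r2`.
#' @export
recovery_experiment <- function(cohort = cohort_params(),
                                reader1 = reader_error_params(seed_offset = 1L),
                                reader2 = reader_error_params(seed_offset = 2L),
                                replicates = 1L) {
  stopifnot(replicates >= 1L)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    p <- cohort
    p$seed <- cohort$seed + (r - 1L) * 1000L
    truth <- simulate_truth(p)
    ann <- rbind(simulate_reader(truth, reader1, "r1"),
                 simulate_reader(truth, reader2, "r2"))
    sheets <- fasss_score(ann, exam_grid = truth_exam_grid(truth))
    pairs <- reader_pairs(sheets)
    icc_b <- icc_a1(cbind(pairs$baseline_r1, pairs$baseline_r2))
    icc_c <- icc_a1(cbind(pairs$delta_r1, pairs$delta_r2))
    s <- sdc(pairs$delta_r1, pairs$delta_r2)
    rows[[r]] <- data.frame(
      replicate = r,
      icc_baseline = icc_b$estimate,
      icc_change = icc_c$estimate,
      sdc = s$sdc,
      mean_baseline_r1 = mean(pairs$baseline_r1),
      mean_baseline_r2 = mean(pairs$baseline_r2),
      mean_change_r1 = mean(pairs$delta_r1),
      mean_change_r2 = mean(pairs$delta_r2)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exam roster of a simulated cohort
#'
#' Every (patient, timepoint, reader) combination a two-reader reading of
#' the cohort comprises; used as the `exam_grid` of [fasss_score()] so
#' lesion-free exams are scored 0 rather than dropped.
#'
#' @param truth A [simulate_truth()] result.
#' @param reader_ids Reader identifiers (default `"r1"`, `"r2"`).
#' @return Data frame: `patient_id`, `exam_time_years`, `reader_id`.
#' @export
truth_exam_grid <- function(truth, reader_ids = c("r1", "r2")) {
  pat <- truth$patients
  grid <- expand.grid(
    i = seq_len(nrow(pat)), tp = c("baseline", "followup"),
    reader_id = reader_ids,
    stringsAsFactors = FALSE
  )
  data.frame(
    patient_id = pat$patient_id[grid$i],
    exam_time_years = ifelse(grid$tp == "baseline", 0,
                             pat$interval_years[grid$i]),
    reader_id = grid$reader_id,
    stringsAsFactors = FALSE
  )
}

#' Two-reader paired table from a score-sheet table
#'
#' Joins the two readers' baseline and change scores per patient into the
#' paired layout used by [icc_a1()], [sdc()] and
#' [stratified_reliability()].
#'
#' @param sheets Score-sheet data frame covering exactly two readers and
#'   two timepoints per patient.
#' @return Data frame: `patient_id`, `interval_years`, `baseline_r1`,
#'   `baseline_r2`, `followup_r1`, `followup_r2`, `delta_r1`, `delta_r2`,
#'   plus per-segment baseline and delta columns.
#' @export
reader_pairs <- function(sheets) {
  readers <- sort(unique(sheets$reader_id))
  if (length(readers) != 2L) {
    stop("expected exactly 2 readers, found ", length(readers),
         call. = FALSE)
  }
  ch <- fasss_change_table(sheets)
  c1 <- ch[ch$reader_id == readers[1], , drop = FALSE]
  c2 <- ch[ch$reader_id == readers[2], , drop = FALSE]
  m <- match(c1$patient_id, c2$patient_id)
  if (anyNA(m)) {
    stop("patients missing one reader: ",
         paste(c1$patient_id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  c2 <- c2[m, , drop = FALSE]
  data.frame(
    patient_id = c1$patient_id,
    interval_years = c1$interval_years,
    baseline_r1 = c1$baseline_total, baseline_r2 = c2$baseline_total,
    followup_r1 = c1$followup_total, followup_r2 = c2$followup_total,
    delta_r1 = c1$delta_total, delta_r2 = c2$delta_total,
    delta_cervical_r1 = c1$delta_cervical,
    delta_cervical_r2 = c2$delta_cervical,
    delta_thoracic_r1 = c1$delta_thoracic,
    delta_thoracic_r2 = c2$delta_thoracic,
    delta_lumbar_r1 = c1$delta_lumbar,
    delta_lumbar_r2 = c2$delta_lumbar,
    stringsAsFactors = FALSE
  )
}
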