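# Spine anatomy for FASSS: 24 vertebral levels C2..S1, 23 disco-vertebral
# units (DVUs) C2/C3..L5/S1, and the scoreable lesion sites of each DVU.

.levels_codes <- c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5), "S1")

#' Vertebral levels scored by FASSS
#'
#' Returns the 24 vertebral levels whose endplates bound the scoreable
#' disco-vertebral units, ordered cranio-caudally from C2 to S1.
#'
#' @return Character vector of 24 level codes (`"C2"` ... `"S1"`).
#' @export
#' @examples
#' vertebral_levels()
vertebral_levels <- function() .levels_codes

#' Disco-vertebral units of the FASSS
#'
#' Enumerates the 23 disco-vertebral units (DVUs) from C2/C3 to L5/S1 in
#' cranio-caudal order. A DVU is the region between horizontal lines through
#' the midpoints of two adjacent vertebrae on sagittal MRI; it is the scoring
#' unit of FASSS. Segment membership follows the partition that yields the
#' published score maxima: cervical C2/C3..C7/T1 (6 DVUs, max 8 each),
#' thoracic T1/T2..T12/L1 (12 DVUs, max 24 each), lumbar L1/L2..L5/S1
#' (5 DVUs, max 24 each); 6*8 + 17*24 = 456.
#'
#' @return A data frame with one row per DVU and columns `dvu` (code such as
#'   `"T12/L1"`), `upper`, `lower` (vertebral level codes) and `segment`
#'   (`"cervical"`, `"thoracic"` or `"lumbar"`).
#' @export
#' @examples
#' head(fasss_dvus())
fasss_dvus <- function() {
  upper <- .levels_codes[-24L]
  lower <- .levels_codes[-1L]
  segment <- c(rep("cervical", 6L), rep("thoracic", 12L), rep("lumbar", 5L))
  data.frame(
    dvu = paste0(upper, "/", lower),
    upper = upper,
    lower = lower,
    segment = segment,
    stringsAsFactors = FALSE
  )
}

.dvu_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- fasss_dvus()
    tab
  }
})

#' Parse and validate DVU codes
#'
#' DVU codes are written `"upper/lower"`, e.g. `"T12/L1"`. Parsing and
#' formatting round-trip exactly.
#'
#' @param dvu Character vector of DVU codes.
#' @return For `dvu_segment()`, the segment of each DVU.
#' @keywords internal
check_dvu <- function(dvu) {
  tab <- .dvu_table()
  bad <- setdiff(unique(dvu), tab$dvu)
  if (length(bad) > 0L) {
    stop("unknown DVU code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(dvu)
}

#' @rdname check_dvu
#' @export
#' @examples
#' dvu_segment(c("C2/C3", "T12/L1", "L5/S1"))
dvu_segment <- function(dvu) {
  check_dvu(dvu)
  tab <- .dvu_table()
  tab$segment[match(dvu, tab$dvu)]
}

#' Scoreable lesion sites of a disco-vertebral unit
#'
#' Each DVU has two endplates: `cranial` (the lower endplate of the DVU's
#' upper vertebra) and `caudal` (the upper endplate of the DVU's lower
#' vertebra). On the central sagittal slices every endplate carries an
#' anterior corner, a posterior corner and a noncorner site. Thoracic and
#' lumbar DVUs additionally carry lateral corner sites (left and right;
#' anterior and posterior per endplate); there are no lateral slices in the
#' cervical spine. Noncorner lesions are scored only in central slices.
#'
#' @param dvu A single DVU code, e.g. `"L2/L3"`.
#' @return A data frame with columns `dvu`, `segment`, `endplate`, `region`,
#'   `slice_domain` and `site_id`; 14 rows for a thoracic/lumbar DVU
#'   (4 central corner + 2 central noncorner + 8 lateral corner), 6 rows for
#'   a cervical DVU.
#' @export
#' @examples
#' nrow(fasss_sites("T12/L1"))  # 14
#' nrow(fasss_sites("C2/C3"))   # 6
fasss_sites <- function(dvu) {
  stopifnot(length(dvu) == 1L)
  check_dvu(dvu)
  seg <- dvu_segment(dvu)
  endplates <- c("cranial", "caudal")
  central <- expand.grid(
    endplate = endplates,
    region = c("anterior_corner", "posterior_corner", "noncorner"),
    slice_domain = "central",
    stringsAsFactors = FALSE
  )
  sites <- central
  if (seg != "cervical") {
    lateral <- expand.grid(
      endplate = endplates,
      region = c("anterior_corner", "posterior_corner"),
      slice_domain = c("lateral_left", "lateral_right"),
      stringsAsFactors = FALSE
    )
    sites <- rbind(central, lateral)
  }
  sites <- data.frame(
    dvu = dvu, segment = seg, sites,
    stringsAsFactors = FALSE
  )
  sites$site_id <- site_id(sites$dvu, sites$endplate, sites$region,
                           sites$slice_domain)
  sites[order(sites$slice_domain, sites$endplate, sites$region), ,
        drop = FALSE]
}

#' @keywords internal
site_id <- function(dvu, endplate, region, slice_domain) {
  paste(dvu, endplate, region, slice_domain, sep = "|")
}

# All 274 scoreable sites of the spine (6*6 cervical + 17*14 thoracolumbar),
# built once per session.
.site_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      parts <- lapply(fasss_dvus()$dvu, fasss_sites)
      out <- do.call(rbind, parts)
      rownames(out) <- NULL
      tab <<- out
    }
    tab
  }
})

#' All scoreable sites of the spine
#'
#' @return Data frame of all 274 lesion sites across the 23 DVUs, in
#'   cranio-caudal DVU order.
#' @export
fasss_all_sites <- function() .site_table()

#' Maximum FASSS of a disco-vertebral unit
#'
#' The scoring range of each thoracic and lumbar DVU is 0 to 24 (central
#' slices contribute at most 16, lateral slices at most 8); each cervical
#' DVU ranges 0 to 8. The total over all 23 DVUs therefore ranges 0 to 456.
#'
#' @param dvu Character vector of DVU codes.
#' @return Integer vector of per-DVU maxima.
#' @export
#' @examples
#' max_dvu_score("L2/L3")          # 24
#' max_dvu_score("C4/C5")          # 8
#' sum(max_dvu_score(fasss_dvus()$dvu))  # 456
max_dvu_score <- function(dvu) {
  seg <- dvu_segment(dvu)
  ifelse(seg == "cervical", 8L, 24L)
}
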