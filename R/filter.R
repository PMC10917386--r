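# Phenotype-based subject filtering.
#
# Mirrors the row-level exclusion criteria that can be expressed on a
# phenotype table (handedness, FIQ, scan length, peak motion, mean FD,
# missing behavioural score, user-supplied image-QC flags), followed by a
# site-size criterion applied to the survivors.  Image-based criteria
# (signal loss, bad normalization, poor coverage) cannot be computed here;
# they enter as pre-computed boolean QC columns.

#' Subject filter configuration
#'
#' Thresholds follow common practice for multi-site resting-state cohorts:
#' exclude mixed/unknown handedness, FIQ < 70, scans shorter than 100
#' timepoints, peak head motion over 2 mm or 2 degrees, mean framewise
#' displacement over 0.2 mm, missing target behavioural score, any
#' user-supplied QC failure flag, and finally sites contributing fewer than
#' 20 surviving subjects.  Set a threshold to `NULL` to deactivate that
#' criterion.
#'
#' @param fiq_min Minimum full-scale IQ (subjects with missing FIQ are also
#'   excluded while active).
#' @param min_timepoints Minimum number of retained timepoints.
#' @param max_motion_mm,max_motion_deg Peak translation (mm) / rotation
#'   (degrees) limits.
#' @param mfd_max Maximum mean framewise displacement (mm).
#' @param require_handedness Exclude subjects whose `handedness` is missing
#'   or `"mixed"`.
#' @param score_column Behavioural score column that must be non-missing
#'   (`NULL` to skip).
#' @param qc_fail_columns Character vector of boolean phenotype columns
#'   where `TRUE` marks an image-QC failure.
#' @param min_site_size Minimum subjects per site, applied after all
#'   row-level criteria.
#' @return A list of class `cpm_filter_config`.
#' @export
filter_config <- function(fiq_min = 70,
                          min_timepoints = 100,
                          max_motion_mm = 2,
                          max_motion_deg = 2,
                          mfd_max = 0.2,
                          require_handedness = TRUE,
                          score_column = "score_total",
                          qc_fail_columns = character(),
                          min_site_size = 20) {
  structure(list(fiq_min = fiq_min, min_timepoints = min_timepoints,
                 max_motion_mm = max_motion_mm,
                 max_motion_deg = max_motion_deg, mfd_max = mfd_max,
                 require_handedness = require_handedness,
                 score_column = score_column,
                 qc_fail_columns = qc_fail_columns,
                 min_site_size = min_site_size),
            class = "cpm_filter_config")
}

#' Filter subjects on phenotype criteria
#'
#' Applies the active criteria of a [filter_config()] in a fixed,
#' documented order; a subject's exclusion reason is the first criterion it
#' violates.  Order: handedness, FIQ, timepoints, peak motion, mean FD,
#' missing score, QC flags (in the order given), then site size.  The
#' site-size criterion counts subjects surviving all row-level criteria and
#' is re-evaluated on whatever table it is given, so filtering an
#' already-filtered table excludes nothing further.
#'
#' @param pheno Phenotype data frame with `subject_id` and the columns the
#'   active criteria reference (missing columns raise an error naming
#'   them).
#' @param config A [filter_config()].
#' @return List with `included` (character subject ids, input order),
#'   `excluded` (data frame `subject_id`, `reason`), and `config`.
#' @export
filter_subjects <- function(pheno, config = filter_config()) {
  stopifnot(inherits(config, "cpm_filter_config"))
  if (!"subject_id" %in% names(pheno)) stop("phenotype table must have subject_id")
  n <- nrow(pheno)
  need_col <- function(col, crit) {
    if (!col %in% names(pheno)) {
      stop("filter criterion '", crit, "' needs missing phenotype column '",
           col, "'")
    }
    pheno[[col]]
  }
  reason <- rep(NA_character_, n)
  mark <- function(reason, bad, label) {
    hit <- is.na(reason) & bad
    reason[hit] <- label
    reason
  }
  if (isTRUE(config$require_handedness)) {
    h <- need_col("handedness", "handedness")
    reason <- mark(reason, is.na(h) | h == "mixed", "handedness")
  }
  if (!is.null(config$fiq_min)) {
    f <- need_col("fiq", "fiq")
    reason <- mark(reason, is.na(f) | f < config$fiq_min,
                   paste0("fiq<", config$fiq_min))
  }
  if (!is.null(config$min_timepoints)) {
    tp <- need_col("n_timepoints", "timepoints")
    reason <- mark(reason, is.na(tp) | tp < config$min_timepoints,
                   paste0("timepoints<", config$min_timepoints))
  }
  if (!is.null(config$max_motion_mm)) {
    mm <- need_col("max_motion_mm", "motion_mm")
    reason <- mark(reason, is.na(mm) | mm > config$max_motion_mm,
                   paste0("motion>", config$max_motion_mm, "mm"))
  }
  if (!is.null(config$max_motion_deg)) {
    md <- need_col("max_motion_deg", "motion_deg")
    reason <- mark(reason, is.na(md) | md > config$max_motion_deg,
                   paste0("motion>", config$max_motion_deg, "deg"))
  }
  if (!is.null(config$mfd_max)) {
    mfd <- need_col("mfd", "mfd")
    reason <- mark(reason, is.na(mfd) | mfd > config$mfd_max,
                   paste0("mfd>", config$mfd_max))
  }
  if (!is.null(config$score_column)) {
    sc <- need_col(config$score_column, "score")
    reason <- mark(reason, is.na(sc), paste0("missing_", config$score_column))
  }
  for (qc in config$qc_fail_columns) {
    flag <- need_col(qc, qc)
    reason <- mark(reason, !is.na(flag) & as.logical(flag), paste0("qc_", qc))
  }
  if (!is.null(config$min_site_size)) {
    site <- need_col("site", "site_size")
    ok <- is.na(reason)
    counts <- table(site[ok])
    small <- names(counts)[counts < config$min_site_size]
    reason <- mark(reason, ok & site %in% small,
                   paste0("site<", config$min_site_size))
  }
  keep <- is.na(reason)
  list(included = as.character(pheno$subject_id[keep]),
       excluded = data.frame(subject_id = as.character(pheno$subject_id[!keep]),
                             reason = reason[!keep],
                             stringsAsFactors = FALSE),
       config = config)
}
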