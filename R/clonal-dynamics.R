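# The mTBI clonality statistic and treatment-dynamics metrics.
#
# mTBI (molecular tumor burden index): within one sample, calls whose VAF
# strictly exceeds 70% of the sample's maximal VAF (MVAF) are regarded as
# clonal; mTBI is the arithmetic mean of those clonal VAFs. The MVAF call
# itself always qualifies (mvaf > 0.7 * mvaf whenever mvaf > 0), so a
# non-empty sample always has at least one clonal mutation.

#' Compute the mTBI of one sample
#'
#' @param sample A non-empty filtered [compartment_sample()] or call table.
#' @param clonal_fraction Clonality cut as a fraction of MVAF, strict
#'   (default 0.70).
#' @param reference_sample Optional sample whose MVAF is used as the
#'   clonality reference instead of `sample`'s own (e.g. the matched tissue
#'   sample); the default uses the same sample.
#' @return A one-row data.frame (`mtbi_result`): patient, compartment,
#'   `mvaf`, `clonal_threshold`, `n_clonal`, `mtbi`.
#' @export
compute_mtbi <- function(sample, clonal_fraction = 0.70,
                         reference_sample = NULL) {
  calls <- as_calls(sample)
  if (!nrow(calls)) stop("mTBI undefined for an empty sample")
  m <- mvaf(if (is.null(reference_sample)) sample else reference_sample)
  thr <- clonal_fraction * m
  clonal <- calls$vaf[calls$vaf > thr]
  if (!length(clonal))
    stop("no clonal mutations above threshold ", thr)
  data.frame(
    patient_id = if (inherits(sample, "compartment_sample"))
      sample$patient_id else NA_character_,
    compartment = if (inherits(sample, "compartment_sample"))
      sample$compartment else NA_character_,
    mvaf = m, clonal_threshold = thr, n_clonal = length(clonal),
    mtbi = mean(clonal), stringsAsFactors = FALSE)
}

#' mTBI decrease rate between two timepoints
#'
#' `(mtbi_pre - mtbi_post) / mtbi_pre`; 1 means complete molecular
#' clearance, negative values mean the post-treatment burden exceeded the
#' pre-treatment burden (progression direction). A post-treatment sample
#' with no surviving somatic calls is treated as mTBI 0 for dynamics only
#' (pass `post = NULL` or an empty sample).
#'
#' @param pre A `mtbi_result` row, [compartment_sample()] or single mTBI
#'   value for the pre-treatment sample; must be positive.
#' @param post Same for the post-treatment sample; `NULL`/empty means
#'   complete clearance (mTBI 0).
#' @param clonal_fraction Passed to [compute_mtbi()] when samples are given.
#' @return A one-row data.frame: `patient_id`, `mtbi_pre`, `mtbi_post`,
#'   `decrease_rate`.
#' @export
mtbi_decrease_rate <- function(pre, post = NULL, clonal_fraction = 0.70) {
  as_mtbi <- function(x, allow_empty = FALSE) {
    if (is.null(x)) {
      if (allow_empty) return(list(id = NA_character_, mtbi = 0))
      stop("pre-treatment sample required")
    }
    if (is.numeric(x) && length(x) == 1L)
      return(list(id = NA_character_, mtbi = x))
    if (is.data.frame(x) && "mtbi" %in% names(x))
      return(list(id = x$patient_id[1L], mtbi = x$mtbi[1L]))
    calls <- as_calls(x)
    id <- if (inherits(x, "compartment_sample")) x$patient_id else NA_character_
    if (!nrow(calls)) {
      if (allow_empty) return(list(id = id, mtbi = 0))
      stop("mTBI undefined for an empty pre-treatment sample")
    }
    list(id = id, mtbi = compute_mtbi(x, clonal_fraction)$mtbi)
  }
  a <- as_mtbi(pre)
  b <- as_mtbi(post, allow_empty = TRUE)
  if (!is.na(a$id) && !is.na(b$id) && a$id != b$id)
    stop("pre and post samples belong to different patients")
  if (a$mtbi <= 0) stop("undefined decrease rate: pre-treatment mTBI is 0")
  data.frame(patient_id = if (!is.na(a$id)) a$id else b$id,
             mtbi_pre = a$mtbi, mtbi_post = b$mtbi,
             decrease_rate = (a$mtbi - b$mtbi) / a$mtbi,
             stringsAsFactors = FALSE)
}

#' Cohort mTBI dynamics table
#'
#' One row per patient with a pre-treatment plasma sample (and mTBI > 0):
#' pre/post plasma mTBI and the decrease rate, with the response label when
#' available. Patients whose post-treatment sample is absent are skipped;
#' patients whose post-treatment sample is empty get decrease rate 1.
#'
#' @param cohort Named list of filtered [patient_record()]s.
#' @param clonal_fraction Clonality cut (default 0.70).
#' @return Data.frame: patient, mtbi_pre, mtbi_post, decrease_rate, response.
#' @export
mtbi_dynamics <- function(cohort, clonal_fraction = 0.70) {
  rows <- list()
  for (rec in cohort) {
    pre <- rec$samples[["plasma_pre"]]
    post <- rec$samples[["plasma_post"]]
    if (is.null(pre) || !nrow(pre$calls) || is.null(post)) next
    d <- mtbi_decrease_rate(pre, post, clonal_fraction)
    d$response <- if (!is.null(rec$clinical) &&
                      "response" %in% names(rec$clinical))
      rec$clinical$response else NA_character_
    rows[[length(rows) + 1L]] <- d
  }
  if (!length(rows)) stop("no patients with both plasma timepoints")
  do.call(rbind, rows)
}

#' Paired per-patient burden metrics for two compartments
#'
#' Builds the paired table feeding the cohort-level signed-rank tests. For
#' per-sample metrics (`n_mutations`, `mvaf`, `mtbi`) the table has one row
#' per patient carrying both compartments. For `vaf_all_calls` the pairing
#' is per variant: VAFs are matched by variant identity key, one row per
#' variant detected in both compartments (variants private to one
#' timepoint enter the count metric but not the paired-VAF metric).
#'
#' @param cohort Named list of filtered [patient_record()]s.
#' @param compartment_a,compartment_b Compartment labels.
#' @param metric One of `"n_mutations"`, `"vaf_all_calls"`, `"mvaf"`,
#'   `"mtbi"`.
#' @param clonal_fraction Clonality cut for the `mtbi` metric.
#' @return Data.frame with columns `patient_id`, `value_a`, `value_b` (and
#'   `key` for `vaf_all_calls`).
#' @export
paired_burden_table <- function(cohort, compartment_a, compartment_b,
                                metric = c("n_mutations", "vaf_all_calls",
                                           "mvaf", "mtbi"),
                                clonal_fraction = 0.70) {
  metric <- match.arg(metric)
  rows <- list()
  for (rec in cohort) {
    a <- rec$samples[[compartment_a]]
    b <- rec$samples[[compartment_b]]
    if (is.null(a) || is.null(b)) next
    if (metric == "n_mutations") {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$patient_id, value_a = nrow(a$calls),
        value_b = nrow(b$calls), stringsAsFactors = FALSE)
    } else if (metric == "vaf_all_calls") {
      shared <- intersect(a$calls$key, b$calls$key)
      if (!length(shared)) next
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$patient_id, key = shared,
        value_a = a$calls$vaf[match(shared, a$calls$key)],
        value_b = b$calls$vaf[match(shared, b$calls$key)],
        stringsAsFactors = FALSE)
    } else {
      if (!nrow(a$calls) || !nrow(b$calls)) next
      va <- if (metric == "mvaf") mvaf(a)
            else compute_mtbi(a, clonal_fraction)$mtbi
      vb <- if (metric == "mvaf") mvaf(b)
            else compute_mtbi(b, clonal_fraction)$mtbi
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$patient_id, value_a = va, value_b = vb,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no eligible patients with both compartments: ",
         compartment_a, ", ", compartment_b)
  do.call(rbind, rows)
}
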