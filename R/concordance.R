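# Cross-compartment mutation-set concordance: detection rates,
# intersection/union (Jaccard-style) concordance, multi-way overlaps and
# driver-gene concordance.
#
# Aggregation is count-weighted across patients: the cohort rate is the sum
# of per-patient shared counts over the sum of per-patient reference (or
# union) counts -- the same variant in two patients counts twice. Patients
# missing either compartment are dropped from that comparison.

#' Per-patient variant identity sets for one compartment
#'
#' @param cohort Named list of [patient_record()]s.
#' @param compartment Compartment label.
#' @param drivers_only Restrict to calls with `is_driver = TRUE`.
#' @return Named list (patient -> character vector of identity keys);
#'   patients lacking the compartment are omitted.
#' @export
compartment_keys <- function(cohort, compartment, drivers_only = FALSE) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  out <- list()
  for (rec in cohort) {
    s <- rec$samples[[compartment]]
    if (is.null(s)) next
    keys <- s$calls$key
    if (drivers_only) keys <- keys[s$calls$is_driver]
    out[[rec$patient_id]] <- keys
  }
  out
}

new_concordance_result <- function(per_patient) {
  n_reference <- sum(per_patient$n_reference)
  n_query <- sum(per_patient$n_query)
  n_shared <- sum(per_patient$n_shared)
  n_union <- n_reference + n_query - n_shared
  stopifnot(n_shared <= min(n_reference, n_query))
  structure(list(
    n_reference = n_reference, n_query = n_query, n_union = n_union,
    n_shared = n_shared,
    detection_rate = if (n_reference > 0)
      round_half_up(100 * n_shared / n_reference, 1) else NA_real_,
    jaccard_concordance = if (n_union > 0)
      round_half_up(100 * n_shared / n_union, 1) else NA_real_,
    per_patient = per_patient
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(paste0("<concordance_result> %d patients: ref %d, query %d, ",
                     "shared %d, union %d | detection %.1f%%, concordance %.1f%%\n"),
              nrow(x$per_patient), x$n_reference, x$n_query, x$n_shared,
              x$n_union, x$detection_rate, x$jaccard_concordance))
  invisible(x)
}

#' @export
as.data.frame.concordance_result <- function(x, ...) {
  data.frame(n_reference = x$n_reference, n_query = x$n_query,
             n_shared = x$n_shared, n_union = x$n_union,
             detection_rate = x$detection_rate,
             jaccard_concordance = x$jaccard_concordance)
}

# Core set arithmetic on two named lists of identity-key vectors.
concordance_from_sets <- function(ref_sets, query_sets) {
  patients <- intersect(names(ref_sets), names(query_sets))
  if (!length(patients)) stop("no patients with both compartments")
  per_patient <- do.call(rbind, lapply(patients, function(p) {
    r <- unique(ref_sets[[p]])
    q <- unique(query_sets[[p]])
    data.frame(patient_id = p, n_reference = length(r), n_query = length(q),
               n_shared = length(intersect(r, q)), stringsAsFactors = FALSE)
  }))
  new_concordance_result(per_patient)
}

#' Detection rate of a query compartment against a reference compartment
#'
#' The fraction (as a percent, one decimal) of reference-compartment
#' alterations also detected in the matched query compartment, aggregated
#' count-weighted across patients:
#' `100 * sum_i |ref_i intersect query_i| / sum_i |ref_i|`.
#'
#' @param cohort Named list of [patient_record()]s, or a named list of
#'   per-patient key vectors (reference) when `query` is also such a list.
#' @param reference,query Compartment labels (or key-set lists).
#' @param drivers_only Restrict to driver-gene calls.
#' @return A `concordance_result`.
#' @export
detection_rate <- function(cohort, reference = "tissue", query = "bwfs",
                           drivers_only = FALSE) {
  sets <- .resolve_sets(cohort, reference, query, drivers_only)
  res <- concordance_from_sets(sets$ref, sets$query)
  if (res$n_reference == 0)
    stop("undefined detection rate: empty reference cohort")
  res
}

#' Pairwise (intersection-over-union) concordance of two compartments
#'
#' `100 * sum_i |A_i intersect B_i| / sum_i |A_i union B_i|`, the
#' proportion of all alterations detected in either compartment that were
#' detected in both. Symmetric in its two arguments.
#'
#' @inheritParams detection_rate
#' @param a,b Compartment labels (or key-set lists).
#' @return A `concordance_result`.
#' @export
pairwise_concordance <- function(cohort, a = "tissue", b = "bwfp",
                                 drivers_only = FALSE) {
  sets <- .resolve_sets(cohort, a, b, drivers_only)
  res <- concordance_from_sets(sets$ref, sets$query)
  if (res$n_union == 0)
    stop("undefined concordance: empty union")
  res
}

#' Driver-gene detection concordance
#'
#' [detection_rate()] restricted to calls in the panel's driver-gene
#' subset.
#'
#' @inheritParams detection_rate
#' @return A `concordance_result`.
#' @export
driver_concordance <- function(cohort, reference = "tissue", query = "bwfs") {
  sets <- .resolve_sets(cohort, reference, query, drivers_only = TRUE)
  res <- concordance_from_sets(sets$ref, sets$query)
  if (res$n_reference == 0)
    stop("undefined driver concordance: no driver mutations in reference")
  res
}

.resolve_sets <- function(cohort, reference, query, drivers_only) {
  if (is.list(reference) && is.list(query)) {
    list(ref = reference, query = query)
  } else {
    list(ref = compartment_keys(cohort, reference, drivers_only),
         query = compartment_keys(cohort, query, drivers_only))
  }
}

#' Multi-way overlap table across compartments
#'
#' Counts cohort alterations (per-patient identity keys) by membership
#' pattern over `k >= 2` compartments: all `2^k - 1` non-empty patterns,
#' encoded as a bitmask string in compartment order (e.g. `"1010"`).
#' Pattern counts sum to the union count. Only patients carrying every
#' requested compartment are included (matched-sample analysis).
#'
#' @param cohort Named list of [patient_record()]s.
#' @param compartments Two or more compartment labels.
#' @param drivers_only Restrict to driver-gene calls.
#' @return A data.frame with columns `pattern` (bitmask), one logical
#'   column per compartment, and `count`.
#' @export
multiway_overlap <- function(cohort, compartments, drivers_only = FALSE) {
  if (length(compartments) < 2L) stop("need at least 2 compartments")
  bad <- setdiff(compartments, COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
  sets <- lapply(compartments, compartment_keys, cohort = cohort,
                 drivers_only = drivers_only)
  names(sets) <- compartments
  patients <- Reduce(intersect, lapply(sets, names))
  k <- length(compartments)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  names(patterns) <- compartments
  patterns <- patterns[do.call(order, lapply(patterns, function(c) !c)), ,
                       drop = FALSE]
  counts <- integer(nrow(patterns))
  for (p in patients) {
    keys <- unique(unlist(lapply(sets, function(s) s[[p]])))
    if (!length(keys)) next
    member <- vapply(compartments, function(cp) keys %in% sets[[cp]][[p]],
                     logical(length(keys)))
    member <- matrix(member, nrow = length(keys))
    for (i in seq_len(nrow(patterns))) {
      target <- unlist(patterns[i, ])
      counts[i] <- counts[i] +
        sum(apply(member, 1L, function(m) all(m == target)))
    }
  }
  out <- data.frame(
    pattern = apply(patterns, 1L, function(r) paste(as.integer(r), collapse = "")),
    patterns, count = counts, row.names = NULL, check.names = FALSE)
  out
}

#' Full concordance report for a cohort
#'
#' One row per comparison: detection rates of each biofluid compartment
#' against tissue, pairwise concordances, and driver-gene detection rates.
#'
#' @param cohort Named list of filtered [patient_record()]s.
#' @param queries Biofluid compartments compared against tissue.
#' @return A data.frame, one row per comparison.
#' @export
concordance_report <- function(cohort,
                               queries = c("bwfs", "bwfp", "plasma_pre")) {
  rows <- list()
  add <- function(label, type, res) {
    df <- as.data.frame(res)
    df <- cbind(data.frame(comparison = label, type = type,
                           stringsAsFactors = FALSE), df)
    rows[[length(rows) + 1L]] <<- df
  }
  for (q in queries) {
    add(paste0("tissue_vs_", q), "detection",
        detection_rate(cohort, "tissue", q))
    add(paste0("tissue_vs_", q), "pairwise",
        pairwise_concordance(cohort, "tissue", q))
    dc <- tryCatch(driver_concordance(cohort, "tissue", q),
                   error = function(e) NULL)
    if (!is.null(dc)) add(paste0("tissue_vs_", q), "driver", dc)
  }
  do.call(rbind, rows)
}
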