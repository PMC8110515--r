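# Post-calling somatic filters: read support / quality, germline subtraction
# against the matched PBL sample, and population-SNP exclusion.

#' Somatic filter configuration
#'
#' Defaults follow the study design this pipeline implements: a call must be
#' supported by at least 5 high-quality reads with mean mapping quality
#' strictly above 30 and mean base quality strictly above 30 (quality
#' thresholds are exclusive, the support threshold inclusive). Germline
#' subtraction removes any candidate whose identity key is seen in the
#' matched PBL sample with at least `germline_min_alt_reads` supporting
#' reads (2 by default; the minimal non-noise evidence level).
#'
#' @param min_alt_reads Minimum supporting reads, inclusive (default 5).
#' @param min_mapq Mapping-quality threshold, exclusive (default 30).
#' @param min_baseq Base-quality threshold, exclusive (default 30).
#' @param germline_min_alt_reads PBL evidence needed to call a candidate
#'   germline (default 2).
#' @param snp_exclusion Character vector of variant identity keys to exclude
#'   (population SNPs); see [read_snp_list()].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_alt_reads = 5L, min_mapq = 30, min_baseq = 30,
                          germline_min_alt_reads = 2L,
                          snp_exclusion = character()) {
  if (min_alt_reads < 1L) stop("min_alt_reads must be >= 1")
  if (!is.finite(min_mapq) || !is.finite(min_baseq))
    stop("quality thresholds must be finite")
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_mapq = min_mapq, min_baseq = min_baseq,
                 germline_min_alt_reads = as.integer(germline_min_alt_reads),
                 snp_exclusion = unique(as.character(snp_exclusion))),
            class = "filter_config")
}

#' Read a population-SNP exclusion list
#'
#' Accepts a 4-column TSV (`chrom`, `pos`, `ref`, `alt`) or a VCF; returns
#' canonicalized identity keys.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Character vector of identity keys.
#' @export
read_snp_list <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("chrom", "pos", "ref", "alt")
    if (!all(req %in% names(df)))
      stop("SNP list must have columns chrom, pos, ref, alt")
    if (!nrow(df)) return(character())
    variant_key(df$chrom, df$pos, df$ref, df$alt)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    if (!nrow(fix)) return(character())
    keys <- character()
    for (i in seq_len(nrow(fix)))
      for (a in strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
        keys <- c(keys, variant_key(fix$CHROM[i], fix$POS[i], fix$REF[i], a))
    unique(keys)
  }
}

#' Filter calls by read support and quality
#'
#' Retains a call iff `alt_reads >= min_alt_reads` and `mean_mapq >
#' min_mapq` and `mean_baseq > min_baseq`. Calls with missing quality
#' summaries are retained (quality unknown is not evidence against).
#'
#' @param x A [compartment_sample()] or call table.
#' @param config A [filter_config()].
#' @return Same type as `x`, with failing calls removed.
#' @export
filter_by_support <- function(x, config = filter_config()) {
  calls <- as_calls(x)
  if (!nrow(calls)) return(x)
  keep <- calls$alt_reads >= config$min_alt_reads &
    (is.na(calls$mean_mapq) | calls$mean_mapq > config$min_mapq) &
    (is.na(calls$mean_baseq) | calls$mean_baseq > config$min_baseq)
  rewrap_calls(x, calls[keep, , drop = FALSE])
}

#' Subtract germline variants seen in the matched PBL sample
#'
#' A candidate is removed iff its identity key appears in the PBL call set
#' with at least `germline_min_alt_reads` supporting reads.
#'
#' @param x A [compartment_sample()] or call table.
#' @param pbl The patient's PBL [compartment_sample()] (or `NULL` to skip).
#' @param config A [filter_config()].
#' @return Same type as `x`.
#' @export
filter_germline <- function(x, pbl, config = filter_config()) {
  if (is.null(pbl)) return(x)
  if (inherits(x, "compartment_sample") && inherits(pbl, "compartment_sample")) {
    if (pbl$compartment != "pbl")
      stop("germline reference must have compartment 'pbl'")
    if (pbl$patient_id != x$patient_id)
      stop(sprintf("patient_id mismatch: sample %s vs PBL %s",
                   x$patient_id, pbl$patient_id))
  }
  calls <- as_calls(x)
  if (!nrow(calls)) return(x)
  pcalls <- as_calls(pbl)
  germ <- pcalls$key[pcalls$alt_reads >= config$germline_min_alt_reads]
  rewrap_calls(x, calls[!calls$key %in% germ, , drop = FALSE])
}

#' Remove calls present in a population-SNP exclusion list
#'
#' Matching is allele-exact on the canonical identity key; a call at the
#' same position with a different alternate allele is retained.
#'
#' @param x A [compartment_sample()] or call table.
#' @param config A [filter_config()] carrying `snp_exclusion` keys.
#' @return Same type as `x`.
#' @export
filter_population_snps <- function(x, config = filter_config()) {
  calls <- as_calls(x)
  if (!nrow(calls) || !length(config$snp_exclusion)) return(x)
  rewrap_calls(x, calls[!calls$key %in% config$snp_exclusion, , drop = FALSE])
}

#' Run the full somatic filter chain
#'
#' Composition of [filter_by_support()], [filter_germline()] and
#' [filter_population_snps()]; the three filters commute and the
#' composition is idempotent (each filter only removes rows on
#' row-intrinsic criteria).
#'
#' @param raw A raw candidate [compartment_sample()] or call table.
#' @param pbl The matched PBL sample (or `NULL`).
#' @param config A [filter_config()].
#' @return Same type as `raw`, containing the somatic calls.
#' @export
run_somatic_filter <- function(raw, pbl = NULL, config = filter_config()) {
  filter_population_snps(
    filter_germline(filter_by_support(raw, config), pbl, config),
    config)
}

#' Apply the somatic filter chain to every non-PBL sample of a cohort
#'
#' @param cohort Named list of [patient_record()]s (raw call sets including
#'   PBL samples).
#' @param config A [filter_config()].
#' @param drop_pbl Drop the PBL samples from the output (default `TRUE`).
#' @return Cohort with filtered samples.
#' @export
filter_cohort <- function(cohort, config = filter_config(), drop_pbl = TRUE) {
  lapply(cohort, function(rec) {
    pbl <- rec$samples[["pbl"]]
    samples <- lapply(rec$samples, function(s) {
      if (s$compartment == "pbl") s
      else run_somatic_filter(s, pbl, config)
    })
    if (drop_pbl) samples <- samples[names(samples) != "pbl"]
    patient_record(rec$patient_id, samples, rec$clinical)
  })
}
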