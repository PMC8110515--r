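# Synthetic matched multi-compartment cohorts.
#
# Generative model (deliberately minimal): each patient carries a Poisson
# number of somatic mutations with Beta-distributed cancer-cell (clone)
# fractions. A compartment dilutes the tumor signal through a tumor-content
# factor tau in [0, 1]; the expected VAF of a mutation with clone fraction f
# is f * tissue_purity * tau / 2 (heterozygous). Supporting reads are drawn
# Binomial(depth, expected VAF) and a call is emitted when the simulated
# caller sees at least `caller_min_alt_reads` reads. Heterozygous germline
# SNPs (expected VAF 0.5) appear in every compartment including the PBL
# germline reference, so the somatic filter chain is exercised end to end.
# Post-treatment plasma rescales clone fractions by a response-dependent
# factor before resampling.

#' Default 1,021-gene capture panel
#'
#' A synthetic stand-in for a pan-cancer capture panel: recurrent SCLC
#' genes (TP53, RB1, ...) flagged as drivers, padded with generic symbols
#' to 1,021 genes covering 1.6 Mb.
#'
#' @return A [panel_definition()].
#' @export
default_panel <- function() {
  drivers <- c("TP53", "RB1", "PTEN", "PIK3CA", "MYC", "MYCL", "MYCN",
               "FGFR1", "KIT", "EGFR", "KRAS", "BRAF", "NOTCH1", "PTPRD",
               "CREBBP")
  named <- c(drivers, "EP300", "KMT2D", "FAT1", "APC", "ARID1A", "ATM",
             "ATRX", "BRCA2", "CCNE1", "CDKN2A", "SMARCA4", "STK11",
             "NFE2L2", "TERT", "SOX2")
  filler <- sprintf("PANEL%04d", seq_len(1021L - length(named)))
  panel_definition(c(named, filler), capture_size_mb = 1.6,
                   driver_genes = drivers)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: 21 patients,
#' a mean of 11 somatic mutations per patient, tissue purity 0.6,
#' Beta(2, 3) clone fractions, per-compartment median depths of 897x
#' (tissue), 4276x (BWFs), 4189x (BWFp) and 893x (plasma, both
#' timepoints), a caller support floor of 5 reads, a driver spectrum
#' dominated by TP53 and RB1, and a partial-response fraction of 17/21
#' with post-treatment plasma available for 13/17 of responders. The
#' tumor-content factors are ordered tissue (1) > BWFs (0.45) >
#' plasma (0.25) > BWFp (0.12), reproducing the observed VAF ordering
#' (tissue highest, BWFp lowest) and, through BWFp's high depth, its
#' intermediate detection rate.
#'
#' @param n_patients Number of patients.
#' @param mutations_per_patient Poisson mean of the somatic mutation count.
#' @param clone_fraction_shape Beta shape parameters of clone fractions.
#' @param tissue_purity Tumor purity of the tissue sample, in [0, 1].
#' @param compartment_params Named list per compartment with `tau`
#'   (tumor-content factor in [0, 1]) and `depth` (reads).
#' @param caller_min_alt_reads Minimum supporting reads the simulated
#'   caller requires to emit a call (default 5).
#' @param driver_gene_weights Named probability masses for dominant driver
#'   genes; the remaining mass is spread uniformly over the rest of the
#'   panel.
#' @param germline_snps_per_patient Heterozygous germline SNPs per patient.
#' @param response_factor Multipliers on clone fractions after treatment,
#'   named by response (default PR 0.3, PD 1.5).
#' @param pr_fraction Probability a patient is a partial responder.
#' @param post_plasma_fraction Probability a responder has a post-treatment
#'   plasma sample.
#' @param panel A [panel_definition()] (default [default_panel()]).
#' @param seed Mandatory integer seed; all randomness flows through it,
#'   with the patient index partitioning the stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 21L,
                              mutations_per_patient = 11,
                              clone_fraction_shape = c(2, 3),
                              tissue_purity = 0.6,
                              compartment_params = list(
                                tissue = list(tau = 1, depth = 897L),
                                bwfs = list(tau = 0.45, depth = 4276L),
                                bwfp = list(tau = 0.12, depth = 4189L),
                                plasma_pre = list(tau = 0.25, depth = 893L),
                                plasma_post = list(tau = 0.25, depth = 893L),
                                pbl = list(tau = 0, depth = 897L)),
                              caller_min_alt_reads = 5L,
                              driver_gene_weights = c(TP53 = 0.30, RB1 = 0.22),
                              germline_snps_per_patient = 30L,
                              response_factor = c(PR = 0.3, PD = 1.5),
                              pr_fraction = 17 / 21,
                              post_plasma_fraction = 13 / 17,
                              panel = default_panel(),
                              seed) {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory for any stochastic run")
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (tissue_purity < 0 || tissue_purity > 1)
    stop("tissue_purity must be in [0, 1]")
  for (cp in names(compartment_params)) {
    p <- compartment_params[[cp]]
    if (p$tau < 0 || p$tau > 1)
      stop("tau must be in [0, 1] for compartment ", cp)
    if (p$depth < 1L) stop("depth must be >= 1 for compartment ", cp)
  }
  if (sum(driver_gene_weights) >= 1)
    stop("driver_gene_weights must sum to less than 1")
  if (!all(names(driver_gene_weights) %in% panel$genes))
    stop("driver_gene_weights must name panel genes")
  structure(list(
    n_patients = as.integer(n_patients),
    mutations_per_patient = mutations_per_patient,
    clone_fraction_shape = clone_fraction_shape,
    tissue_purity = tissue_purity,
    compartment_params = compartment_params,
    caller_min_alt_reads = as.integer(caller_min_alt_reads),
    driver_gene_weights = driver_gene_weights,
    germline_snps_per_patient = as.integer(germline_snps_per_patient),
    response_factor = response_factor,
    pr_fraction = pr_fraction,
    post_plasma_fraction = post_plasma_fraction,
    panel = panel,
    seed = as.integer(seed)), class = "simulation_config")
}

# Per-patient seed: partitions the stream so cohorts are reproducible
# under out-of-order or parallel generation. Kept below 2^31.
.patient_seed <- function(config, patient_index) {
  as.integer((as.numeric(config$seed) * 7919 + patient_index * 104729) %%
               2147483647)
}

.sample_genes <- function(config, n) {
  w <- config$driver_gene_weights
  rest <- setdiff(config$panel$genes, names(w))
  probs <- c(w, stats::setNames(rep((1 - sum(w)) / length(rest),
                                    length(rest)), rest))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate one patient
#'
#' Deterministic given `(seed, patient_index)`. Returns the raw (unfiltered)
#' record -- germline SNPs are present in every compartment and in the PBL
#' sample -- plus a truth record with the underlying clone fractions and
#' per-compartment expected VAFs.
#'
#' @param config A [simulation_config()].
#' @param patient_index 1-based patient index.
#' @return List with `record` (a [patient_record()]) and `truth`
#'   (list of `mutations` and `germline` data.frames).
#' @export
simulate_patient <- function(config, patient_index) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(.patient_seed(config, patient_index))
  pid <- sprintf("P%03d", patient_index)

  n_mut <- stats::rpois(1L, config$mutations_per_patient)
  n_germ <- config$germline_snps_per_patient
  pos <- sample.int(99000000L, n_mut + n_germ) + 1000000L
  chrom <- as.character(sample.int(22L, n_mut + n_germ, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_mut + n_germ, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  eff <- sample(c("nonsynonymous_snv", "synonymous_snv", "indel"),
                n_mut + n_germ, replace = TRUE,
                prob = c(0.75, 0.10, 0.15))
  # indels: extend the reference allele so ref/alt lengths differ
  idl <- which(eff == "indel")
  ref[idl] <- paste0(ref[idl],
                     sample(bases, length(idl), replace = TRUE))
  gene <- .sample_genes(config, n_mut + n_germ)

  som <- seq_len(n_mut)
  germ <- if (n_germ) n_mut + seq_len(n_germ) else integer()
  f <- stats::rbeta(n_mut, config$clone_fraction_shape[1L],
                    config$clone_fraction_shape[2L])

  response <- if (stats::runif(1) < config$pr_fraction) "PR" else "PD"
  has_post <- response == "PR" &&
    stats::runif(1) < config$post_plasma_fraction

  expected_vaf <- function(fr, tau) pmin(0.5, fr * config$tissue_purity * tau / 2)

  make_sample <- function(compartment) {
    p <- config$compartment_params[[compartment]]
    post_scale <- if (compartment == "plasma_post")
      unname(config$response_factor[response]) else 1
    evaf_som <- expected_vaf(pmin(1, f * post_scale), p$tau)
    idx_all <- c(som, germ)
    evaf <- c(evaf_som, rep(0.5, length(germ)))
    if (compartment == "pbl") evaf[seq_along(som)] <- 0
    alt_reads <- stats::rbinom(length(evaf), p$depth, evaf)
    keep <- alt_reads >= config$caller_min_alt_reads
    if (!any(keep))
      return(compartment_sample(pid, compartment, effective_depth = p$depth))
    sel <- idx_all[keep]
    calls <- call_table(
      chrom[sel], pos[sel], ref[sel], alt[sel], gene = gene[sel],
      effect = eff[sel], alt_reads = alt_reads[keep], depth = p$depth,
      mean_mapq = stats::runif(sum(keep), 40, 60),
      mean_baseq = stats::runif(sum(keep), 31, 40),
      is_driver = gene[sel] %in% config$panel$driver_genes)
    compartment_sample(pid, compartment, calls, effective_depth = p$depth)
  }

  compartments <- c("tissue", "bwfs", "bwfp", "plasma_pre",
                    if (has_post) "plasma_post", "pbl")
  samples <- lapply(compartments, make_sample)

  clinical <- data.frame(
    patient_id = pid,
    age = round(stats::runif(1, 46, 77)),
    sex = sample(c("M", "F"), 1L, prob = c(15, 6) / 21),
    stage = sample(c("III", "IV"), 1L, prob = c(13, 8) / 21),
    hyponatremia = stats::runif(1) < 4 / 21,
    tumor_size_class = sample(c("<=3", "3-5", "5-7", ">7"), 1L,
                              prob = c(1, 5, 9, 6) / 21),
    progrp_positive = stats::runif(1) < 18 / 21,
    nse_positive = stats::runif(1) < 11 / 21,
    cea_positive = stats::runif(1) < 12 / 21,
    response = response,
    stringsAsFactors = FALSE)
  burden <- if (n_mut) mean(f) else 0
  clinical$os_months <- stats::rexp(1, rate = log(2) / 14 *
                                      exp(1.2 * (burden - 0.4)))
  clinical$os_event <- stats::runif(1) < 0.8
  clinical$pfs_months <- clinical$os_months * stats::runif(1, 0.3, 0.8)
  clinical$pfs_event <- stats::runif(1) < 0.9

  key_all <- variant_key(chrom, pos, ref, alt)
  truth_mut <- if (n_mut) data.frame(
    patient_id = pid, key = key_all[som], gene = gene[som],
    effect = eff[som], clone_fraction = f,
    evaf_tissue = expected_vaf(f, config$compartment_params$tissue$tau),
    evaf_bwfs = expected_vaf(f, config$compartment_params$bwfs$tau),
    evaf_bwfp = expected_vaf(f, config$compartment_params$bwfp$tau),
    evaf_plasma = expected_vaf(f, config$compartment_params$plasma_pre$tau),
    stringsAsFactors = FALSE) else NULL
  truth_germ <- if (length(germ)) data.frame(
    patient_id = pid, key = key_all[germ], gene = gene[germ],
    stringsAsFactors = FALSE) else NULL

  list(record = patient_record(pid, samples, clinical),
       truth = list(mutations = truth_mut, germline = truth_germ))
}

#' Simulate a matched cohort
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (named list of raw [patient_record()]s,
#'   germline SNPs included -- run [filter_cohort()] before analysis) and
#'   `truth` (mutation and germline truth tables).
#' @export
simulate_cohort <- function(config) {
  sims <- lapply(seq_len(config$n_patients), simulate_patient,
                 config = config)
  cohort <- lapply(sims, function(s) s$record)
  names(cohort) <- vapply(cohort, `[[`, "", "patient_id")
  mutations <- do.call(rbind, lapply(sims, function(s) s$truth$mutations))
  germline <- do.call(rbind, lapply(sims, function(s) s$truth$germline))
  list(cohort = cohort, truth = list(mutations = mutations,
                                     germline = germline))
}

#' Model-implied detection rate of a compartment against tissue
#'
#' The analytic counterpart of the simulator: the probability, under the
#' binomial shedding model and the Beta clone-fraction distribution, that a
#' mutation detected in tissue is also detected in the query compartment.
#' Used as the recovery target in parameter-recovery checks.
#'
#' @param config A [simulation_config()].
#' @param query Query compartment.
#' @param reference Reference compartment (default `"tissue"`).
#' @param grid_n Integration grid size.
#' @return Expected detection rate (fraction).
#' @export
expected_detection_rate <- function(config, query, reference = "tissue",
                                    grid_n = 4000L) {
  fgrid <- seq(1e-5, 1 - 1e-5, length.out = grid_n)
  w <- stats::dbeta(fgrid, config$clone_fraction_shape[1L],
                    config$clone_fraction_shape[2L])
  w <- w / sum(w)
  pdet <- function(compartment) {
    p <- config$compartment_params[[compartment]]
    evaf <- pmin(0.5, fgrid * config$tissue_purity * p$tau / 2)
    1 - stats::pbinom(config$caller_min_alt_reads - 1L, p$depth, evaf)
  }
  pr <- pdet(reference)
  pq <- pdet(query)
  sum(w * pr * pq) / sum(w * pr)
}

## ---- deterministic count-constrained fixtures ------------------------------

#' Deterministic cohort fixture from printed count totals
#'
#' Builds a two-compartment matched cohort whose aggregate counts are met
#' exactly: `n_reference` alterations in the reference compartment spread
#' round-robin over `n_patients`, of which `n_shared` also appear in the
#' query compartment, plus `n_query_only` alterations private to the query
#' compartment; optionally `n_driver_reference` of the reference
#' alterations are driver-gene mutations with `n_driver_shared` of them
#' shared. No randomness: the construction is a fixed layout.
#'
#' @param n_patients Number of matched patients.
#' @param n_reference Total reference-compartment alterations.
#' @param n_shared Alterations present in both compartments.
#' @param n_query_only Alterations private to the query compartment.
#' @param n_driver_reference Driver alterations among the reference total.
#' @param n_driver_shared Driver alterations among the shared subset.
#' @param reference,query Compartment labels.
#' @param depth Constant per-call depth (default 1000).
#' @return Named list of [patient_record()]s.
#' @export
fixture_from_counts <- function(n_patients, n_reference, n_shared,
                                n_query_only = 0L,
                                n_driver_reference = 0L,
                                n_driver_shared = 0L,
                                reference = "tissue", query = "bwfs",
                                depth = 1000L) {
  if (n_shared > n_reference)
    stop("inconsistent counts: n_shared <= n_reference violated")
  if (n_driver_reference > n_reference)
    stop("inconsistent counts: n_driver_reference <= n_reference violated")
  if (n_driver_shared > n_driver_reference)
    stop("inconsistent counts: n_driver_shared <= n_driver_reference violated")
  if (n_driver_shared > n_shared)
    stop("inconsistent counts: n_driver_shared <= n_shared violated")
  if (n_driver_reference - n_driver_shared > n_reference - n_shared)
    stop(paste("inconsistent counts: n_driver_reference - n_driver_shared <=",
               "n_reference - n_shared violated"))
  if (n_patients < 1L) stop("inconsistent counts: n_patients >= 1 violated")

  n_union <- n_reference + n_query_only
  j <- seq_len(n_union)
  patient <- (j - 1L) %% n_patients + 1L
  in_ref <- j <= n_reference
  in_query <- (j <= n_shared) | (j > n_reference)
  # driver layout: first slots of the shared block, then first slots of the
  # reference-only block
  is_driver <- (j <= n_driver_shared) |
    (j > n_shared & j <= n_shared + (n_driver_reference - n_driver_shared))
  gene <- ifelse(is_driver, c("TP53", "RB1")[(j %% 2L) + 1L],
                 sprintf("GENE%03d", (j %% 199L) + 1L))
  vaf <- 0.05 + 0.40 * ((j %% 8L) / 8L)
  alt_reads <- as.integer(round(vaf * depth))
  calls_all <- data.frame(
    chrom = as.character((j - 1L) %% 22L + 1L), pos = 10000L + 10L * j,
    ref = "A", alt = "G", gene = gene, is_driver = is_driver,
    alt_reads = alt_reads, stringsAsFactors = FALSE)

  cohort <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    mk <- function(sel, compartment) {
      rows <- calls_all[sel & patient == p, , drop = FALSE]
      calls <- if (nrow(rows))
        call_table(rows$chrom, rows$pos, rows$ref, rows$alt,
                   gene = rows$gene, effect = "nonsynonymous_snv",
                   alt_reads = rows$alt_reads, depth = depth,
                   mean_mapq = 60, mean_baseq = 40,
                   is_driver = rows$is_driver)
      else empty_call_table()
      compartment_sample(pid, compartment, calls)
    }
    cohort[[pid]] <- patient_record(pid, list(mk(in_ref, reference),
                                              mk(in_query, query)))
  }
  cohort
}

#' Deterministic clinical table from count totals
#'
#' Builds an n-patient clinical table meeting the requested positives
#' exactly (the first k patients of each column are positive). Useful for
#' reproducing printed marker-sensitivity percentages.
#'
#' @param n Number of patients.
#' @param progrp_positive,nse_positive,cea_positive Marker-positive counts.
#' @param stage_iv,hyponatremia,male,pr Counts for the other covariates.
#' @return A clinical data.frame keyed by `patient_id`.
#' @export
clinical_from_counts <- function(n = 21L, progrp_positive = 18L,
                                 nse_positive = 11L, cea_positive = 12L,
                                 stage_iv = 8L, hyponatremia = 4L,
                                 male = 15L, pr = 17L) {
  for (k in c(progrp_positive, nse_positive, cea_positive, stage_iv,
              hyponatremia, male, pr))
    if (k > n) stop("inconsistent counts: count exceeds n")
  first <- function(k) seq_len(n) <= k
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = ifelse(first(male), "M", "F"),
    stage = ifelse(first(stage_iv), "IV", "III"),
    hyponatremia = first(hyponatremia),
    progrp_positive = first(progrp_positive),
    nse_positive = first(nse_positive),
    cea_positive = first(cea_positive),
    response = ifelse(first(pr), "PR", "PD"),
    stringsAsFactors = FALSE)
}
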