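# Core data types and readers/writers for variant call sets, sample sheets,
# panels and clinical tables.

#' Compartment labels recognized by the pipeline
#'
#' The five analyzed sample types of a matched liquid-biopsy cohort --
#' tumor tissue, bronchial washing fluid supernatant (bwfs) and precipitate
#' (bwfp), pre- and post-treatment plasma -- plus the peripheral-blood
#' lymphocyte (pbl) germline reference. PBL samples are only ever used for
#' germline subtraction, never as inputs to concordance, TMB or mTBI.
#'
#' @format Character vector of the six valid compartment labels.
#' @export
COMPARTMENTS <- c("tissue", "bwfs", "bwfp", "plasma_pre", "plasma_post", "pbl")

#' Effect-class vocabulary
#'
#' Fixed four-member enumeration of variant effect classes. Unknown
#' annotations map to `"other"` with a warning at read time.
#'
#' @format Character vector of the four effect classes.
#' @export
EFFECT_CLASSES <- c("nonsynonymous_snv", "synonymous_snv", "indel", "other")

## ---- identity keys and normalization -------------------------------------

#' Canonical variant identity key
#'
#' Variant identity throughout the pipeline is `(chrom, pos, ref, alt)`,
#' rendered as `"chrom:pos:ref:alt"`. Alleles are normalized (minimal
#' left-aligned representation) before keying, so the keying is idempotent.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Reference / alternate alleles (uppercase DNA strings).
#' @return Character vector of identity keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  nv <- normalize_variant(chrom, pos, ref, alt)
  paste(nv$chrom, nv$pos, nv$ref, nv$alt, sep = ":")
}

#' Normalize variant representation
#'
#' Trims shared trailing bases, then shared leading bases (advancing `pos`),
#' yielding the minimal left-aligned representation; e.g. `pos=100,
#' ref="CAT", alt="CGT"` becomes `pos=101, ref="A", alt="G"`. Idempotent.
#'
#' @inheritParams variant_key
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(chrom, n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  pos <- rep_len(as.integer(pos), n)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("ref and alt alleles must be non-empty")
  if (any(pos < 1L)) stop("pos must be >= 1")
  for (i in seq_along(ref)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # shared suffix first, keeping at least one base on each side
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # then shared prefix, advancing pos
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

## ---- call tables and samples ----------------------------------------------

.CALL_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "effect", "is_driver",
                   "alt_reads", "depth", "vaf", "mean_mapq", "mean_baseq", "key")

#' Build a validated call table
#'
#' One row per variant call. Enforces the call-level invariants:
#' `0 <= alt_reads <= depth`, `depth >= 1`, `vaf == alt_reads/depth`
#' (computed when absent), a valid effect class, and unique identity keys.
#'
#' @param chrom,pos,ref,alt Variant identity fields.
#' @param gene Gene symbols.
#' @param effect Effect classes (see [EFFECT_CLASSES]); unknown labels are
#'   mapped to `"other"` with a warning.
#' @param alt_reads,depth Supporting read count and total depth.
#' @param vaf Variant allele fraction; computed as `alt_reads/depth` when `NULL`.
#' @param mean_mapq,mean_baseq Mapping/base quality summaries.
#' @param is_driver Logical; membership in the panel's driver subset.
#' @return A data.frame of validated calls with a `key` column.
#' @export
call_table <- function(chrom, pos, ref, alt, gene = NA_character_,
                       effect = "nonsynonymous_snv", alt_reads, depth,
                       vaf = NULL, mean_mapq = NA_real_, mean_baseq = NA_real_,
                       is_driver = FALSE) {
  nv <- normalize_variant(chrom, pos, ref, alt)
  n <- nrow(nv)
  effect <- as.character(rep_len(effect, n))
  bad <- !effect %in% EFFECT_CLASSES
  if (any(bad)) {
    warning(sprintf("%d call(s) with unknown effect class mapped to 'other'",
                    sum(bad)))
    effect[bad] <- "other"
  }
  alt_reads <- as.integer(rep_len(alt_reads, n))
  depth <- as.integer(rep_len(depth, n))
  if (any(depth < 1L)) stop("depth must be >= 1 for every call")
  if (any(alt_reads < 0L) || any(alt_reads > depth))
    stop("alt_reads must satisfy 0 <= alt_reads <= depth")
  if (is.null(vaf)) {
    vaf <- alt_reads / depth
  } else {
    vaf <- rep_len(as.numeric(vaf), n)
    if (any(abs(vaf - alt_reads / depth) > 1e-9))
      stop("vaf inconsistent with alt_reads/depth")
  }
  calls <- data.frame(
    chrom = nv$chrom, pos = nv$pos, ref = nv$ref, alt = nv$alt,
    gene = as.character(rep_len(gene, n)), effect = effect,
    is_driver = as.logical(rep_len(is_driver, n)),
    alt_reads = alt_reads, depth = depth, vaf = vaf,
    mean_mapq = as.numeric(rep_len(mean_mapq, n)),
    mean_baseq = as.numeric(rep_len(mean_baseq, n)),
    stringsAsFactors = FALSE
  )
  calls$key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  if (anyDuplicated(calls$key))
    stop("duplicate variant identity key(s): ",
         paste(unique(calls$key[duplicated(calls$key)]), collapse = ", "))
  calls
}

empty_call_table <- function() {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), gene = character(), effect = character(),
                    is_driver = logical(), alt_reads = integer(),
                    depth = integer(), vaf = numeric(), mean_mapq = numeric(),
                    mean_baseq = numeric(), key = character(),
                    stringsAsFactors = FALSE)
  out
}

#' One sample's call set, labeled by patient and compartment
#'
#' @param patient_id Patient identifier.
#' @param compartment One of [COMPARTMENTS].
#' @param calls A call table as built by [call_table()] (may be empty).
#' @param effective_depth Median sequencing depth of the sample (coverage x).
#' @return An object of class `compartment_sample`.
#' @export
compartment_sample <- function(patient_id, compartment, calls = empty_call_table(),
                               effective_depth = NA_real_) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (nrow(calls) && anyDuplicated(calls$key))
    stop("duplicate variant identity key(s) in sample")
  structure(
    list(patient_id = as.character(patient_id), compartment = compartment,
         calls = calls, effective_depth = as.numeric(effective_depth)),
    class = "compartment_sample"
  )
}

#' @export
print.compartment_sample <- function(x, ...) {
  cat(sprintf("<compartment_sample> patient %s, %s: %d call(s)\n",
              x$patient_id, x$compartment, nrow(x$calls)))
  invisible(x)
}

# Accept either a compartment_sample or a bare call table.
as_calls <- function(x) {
  if (inherits(x, "compartment_sample")) x$calls
  else if (is.data.frame(x)) x
  else stop("expected a compartment_sample or a call table")
}

# Return an object of the same shape as `template` carrying `calls`.
rewrap_calls <- function(template, calls) {
  if (inherits(template, "compartment_sample")) {
    template$calls <- calls
    template
  } else calls
}

#' Matched compartment samples plus clinical covariates for one patient
#'
#' @param patient_id Patient identifier.
#' @param samples Named list of [compartment_sample()] objects, at most one
#'   per compartment, each carrying the same `patient_id`.
#' @param clinical One-row data.frame of clinical covariates (may be `NULL`).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, samples = list(), clinical = NULL) {
  patient_id <- as.character(patient_id)
  if (length(samples)) {
    comps <- vapply(samples, `[[`, "", "compartment")
    if (anyDuplicated(comps))
      stop("at most one sample per compartment (patient ", patient_id, ")")
    pids <- vapply(samples, `[[`, "", "patient_id")
    if (any(pids != patient_id))
      stop("sample patient_id mismatch for patient ", patient_id)
    names(samples) <- comps
  }
  if (!is.null(clinical)) {
    for (col in c("os_months", "pfs_months")) {
      if (col %in% names(clinical) && !is.na(clinical[[col]]) &&
          clinical[[col]] < 0)
        stop(col, " must be >= 0")
    }
  }
  structure(list(patient_id = patient_id, samples = samples,
                 clinical = clinical),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: compartments {%s}\n", x$patient_id,
              paste(names(x$samples), collapse = ", ")))
  invisible(x)
}

#' Flatten a cohort to one call table
#'
#' @param cohort Named list of [patient_record()] objects.
#' @param compartments Optional subset of compartments to keep.
#' @return A data.frame of calls with `patient_id` and `compartment` columns.
#' @export
cohort_calls <- function(cohort, compartments = NULL) {
  rows <- list()
  for (rec in cohort) {
    for (s in rec$samples) {
      if (!is.null(compartments) && !s$compartment %in% compartments) next
      if (!nrow(s$calls)) next
      df <- s$calls
      df$patient_id <- rec$patient_id
      df$compartment <- s$compartment
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (!length(rows)) {
    out <- empty_call_table()
    out$patient_id <- character()
    out$compartment <- character()
    return(out)
  }
  do.call(rbind, rows)
}

## ---- readers ---------------------------------------------------------------

.MAF_REQUIRED <- c("chrom", "pos", "ref", "alt", "gene", "effect",
                   "alt_reads", "depth")

#' Read a per-sample somatic call set
#'
#' Supports two formats: a MAF-like tab-separated table (columns `chrom`,
#' `pos`, `ref`, `alt`, `gene`, `effect`, `alt_reads`, `depth`, optionally
#' `vaf`, `mean_mapq`, `mean_baseq`) and VCF v4.2 (parsed with
#' \pkg{vcfR}; per-sample `AD` or `AO`/`DP` fields supply read counts, and
#' optional `GENE=`/`EFFECT=` INFO fields supply annotation). Multi-allelic
#' VCF records are split into biallelic records. VAF is computed from
#' `alt_reads/depth` when absent. Duplicate identity keys within a file are
#' rejected.
#'
#' @param path File path.
#' @param format `"maf_tsv"` or `"vcf"`.
#' @param patient_id,compartment Sample metadata attached to the result.
#' @param panel Optional [panel_definition()]; used to flag driver genes.
#' @param effective_depth Optional median depth annotation.
#' @return A [compartment_sample()].
#' @export
read_callset <- function(path, format = c("maf_tsv", "vcf"), patient_id,
                         compartment, panel = NULL,
                         effective_depth = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(format,
               maf_tsv = .read_maf_tsv(path),
               vcf = .read_vcf_calls(path))
  calls <- if (nrow(df)) {
    call_table(df$chrom, df$pos, df$ref, df$alt, gene = df$gene,
               effect = df$effect, alt_reads = df$alt_reads, depth = df$depth,
               vaf = df$vaf, mean_mapq = df$mean_mapq,
               mean_baseq = df$mean_baseq)
  } else empty_call_table()
  if (!is.null(panel) && nrow(calls))
    calls$is_driver <- calls$gene %in% panel$driver_genes
  compartment_sample(patient_id, compartment, calls, effective_depth)
}

.read_maf_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(.MAF_REQUIRED, names(df))
  if (length(missing))
    stop("malformed call table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) return(df)
  for (col in c("pos", "alt_reads", "depth")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("malformed record at line %d of %s: non-integer %s",
                   bad[1L] + 1L, path, col))
    df[[col]] <- v
  }
  if (is.null(df$vaf)) df$vaf <- NULL
  for (col in c("mean_mapq", "mean_baseq"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (is.null(df$vaf)) df$vaf <- df$alt_reads / df$depth
  df
}

.read_vcf_calls <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_call_table())
  info_field <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_field("GENE")
  effect <- info_field("EFFECT")
  effect[is.na(effect)] <- "other"
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP"),
                 error = function(e) NULL)
  ao <- tryCatch(vcfR::extract.gt(vcf, element = "AO"),
                 error = function(e) NULL)
  mq <- info_field("MMQ")
  bq <- info_field("MBQ")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_i <- if (!is.null(ad) && !is.na(ad[i, 1L]))
      as.integer(strsplit(ad[i, 1L], ",", fixed = TRUE)[[1]]) else NULL
    for (k in seq_along(alts)) {
      if (!is.null(ad_i)) {
        alt_reads <- ad_i[k + 1L]
        depth <- sum(ad_i)
      } else if (!is.null(ao) && !is.null(dp)) {
        ao_i <- as.integer(strsplit(ao[i, 1L], ",", fixed = TRUE)[[1]])
        alt_reads <- ao_i[k]
        depth <- as.integer(dp[i, 1L])
      } else {
        stop(sprintf("malformed record at VCF row %d of %s: no AD or AO/DP",
                     i, path))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
        alt = alts[k], gene = gene[i], effect = effect[i],
        alt_reads = alt_reads, depth = depth, vaf = alt_reads / depth,
        mean_mapq = suppressWarnings(as.numeric(mq[i])),
        mean_baseq = suppressWarnings(as.numeric(bq[i])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a sample sheet mapping patient and compartment to call-set files
#'
#' Expects a TSV with columns `patient_id`, `compartment`, `path` (and
#' optionally `format`). Returns one [patient_record()] skeleton per patient
#' with samples loaded via [read_callset()] when `load = TRUE`, or with
#' empty call sets otherwise.
#'
#' @param path Sample sheet TSV.
#' @param load Load the referenced call sets (default `TRUE`).
#' @param panel Optional [panel_definition()] passed through to the reader.
#' @return Named list of [patient_record()] objects.
#' @export
read_sample_sheet <- function(path, load = TRUE, panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(sheet)) return(structure(list(), names = character()))
  req <- c("patient_id", "compartment", "path")
  missing <- setdiff(req, names(sheet))
  if (length(missing))
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  bad <- !sheet$compartment %in% COMPARTMENTS
  if (any(bad))
    stop("unknown compartment label(s): ",
         paste(unique(sheet$compartment[bad]), collapse = ", "))
  dup <- duplicated(sheet[c("patient_id", "compartment")])
  if (any(dup))
    stop("patient+compartment listed twice: ",
         paste(sheet$patient_id[dup], sheet$compartment[dup], collapse = "; "))
  if (is.null(sheet$format)) sheet$format <- "maf_tsv"
  cohort <- list()
  for (pid in unique(sheet$patient_id)) {
    rows <- sheet[sheet$patient_id == pid, , drop = FALSE]
    samples <- lapply(seq_len(nrow(rows)), function(i) {
      if (load)
        read_callset(rows$path[i], rows$format[i], pid, rows$compartment[i],
                     panel = panel)
      else compartment_sample(pid, rows$compartment[i])
    })
    cohort[[pid]] <- patient_record(pid, samples)
  }
  cohort
}

#' Capture-panel definition
#'
#' @param genes Character vector of panel gene symbols.
#' @param capture_size_mb Captured genome size in megabases (default 1.6).
#' @param driver_genes Subset of `genes` regarded as oncogenic drivers.
#' @return An object of class `panel_definition`.
#' @export
panel_definition <- function(genes, capture_size_mb = 1.6,
                             driver_genes = character()) {
  genes <- unique(as.character(genes))
  driver_genes <- unique(as.character(driver_genes))
  if (!all(driver_genes %in% genes))
    stop("driver_genes must be a subset of panel genes")
  if (!is.numeric(capture_size_mb) || capture_size_mb <= 0)
    stop("capture_size_mb must be > 0")
  structure(list(genes = genes, capture_size_mb = capture_size_mb,
                 driver_genes = driver_genes),
            class = "panel_definition")
}

#' Read a panel file
#'
#' Format: a header line `#capture_size_mb=<x>`, then one gene per line,
#' driver genes flagged with a second tab-separated column `driver`.
#'
#' @param path Panel file path.
#' @return A [panel_definition()].
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*capture_size_mb\\s*=", lines, value = TRUE)
  size <- if (length(hdr))
    as.numeric(sub("^#\\s*capture_size_mb\\s*=\\s*", "", hdr[1L])) else 1.6
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(parts, `[`, "", 1L)
  flags <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
  panel_definition(genes, size, genes[flags == "driver"])
}

#' Write a panel file readable by [read_panel()]
#' @param panel A [panel_definition()].
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  flags <- ifelse(panel$genes %in% panel$driver_genes, "\tdriver", "")
  writeLines(c(sprintf("#capture_size_mb=%g", panel$capture_size_mb),
               paste0(panel$genes, flags)), path)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' TSV with one row per patient; expects at least `patient_id`, and passes
#' through stage, hyponatremia, tumor-marker positivity (`progrp_positive`,
#' `nse_positive`, `cea_positive`), response, and OS/PFS columns as present.
#'
#' @param path Clinical table TSV.
#' @return A data.frame keyed by `patient_id`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("clinical table must contain a patient_id column")
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in clinical table")
  df
}

## ---- report writers --------------------------------------------------------

#' Write an analysis report table
#'
#' Writes a data.frame as TSV or JSON such that it round-trips losslessly
#' through [read_report()]. Non-finite numeric values are rejected.
#'
#' @param table A data.frame (or named list of data.frames for JSON).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  check_finite <- function(df) {
    for (col in names(df))
      if (is.numeric(df[[col]]) && any(!is.finite(df[[col]]) & !is.na(df[[col]])))
        stop("non-finite value in column ", col)
  }
  if (format == "tsv") {
    if (!is.data.frame(table)) stop("TSV reports require a data.frame")
    check_finite(table)
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.data.frame(table)) check_finite(table)
    else if (is.list(table)) lapply(Filter(is.data.frame, table), check_finite)
    jsonlite::write_json(table, path, dataframe = "columns", digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path Report path.
#' @param format `"tsv"` or `"json"`.
#' @return The table (data.frame) or list structure.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::read.delim(path, stringsAsFactors = FALSE)
  else
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
}

#' Write a call set in MAF-like TSV or VCF format
#'
#' The emitted files are readable by [read_callset()]; VCF output carries
#' `GENE`/`EFFECT`/`MMQ`/`MBQ` INFO fields and a single sample column with
#' `GT:AD:DP`.
#'
#' @param sample A [compartment_sample()].
#' @param path Output path.
#' @param format `"maf_tsv"` or `"vcf"`.
#' @export
write_callset <- function(sample, path, format = c("maf_tsv", "vcf")) {
  format <- match.arg(format)
  calls <- as_calls(sample)
  if (format == "maf_tsv") {
    cols <- setdiff(.CALL_COLUMNS, "key")
    utils::write.table(calls[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
             "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect class\">",
             "##INFO=<ID=MMQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
             "##INFO=<ID=MBQ,Number=1,Type=Float,Description=\"Mean base quality\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   if (inherits(sample, "compartment_sample"))
                     sample$patient_id else "SAMPLE", sep = "\t"))
    body <- if (nrow(calls)) {
      ord <- order(calls$chrom, calls$pos)
      calls <- calls[ord, , drop = FALSE]
      info <- sprintf("GENE=%s;EFFECT=%s;MMQ=%g;MBQ=%g", calls$gene,
                      calls$effect,
                      ifelse(is.na(calls$mean_mapq), 0, calls$mean_mapq),
                      ifelse(is.na(calls$mean_baseq), 0, calls$mean_baseq))
      fmt <- sprintf("0/1:%d,%d:%d", calls$depth - calls$alt_reads,
                     calls$alt_reads, calls$depth)
      paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
            info, "GT:AD:DP", fmt, sep = "\t")
    } else character()
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

## ---- rounding --------------------------------------------------------------

#' Round half away from zero
#'
#' Percentages throughout the reports are rounded half-up at a fixed number
#' of decimals (e.g. 92.65 -> 92.7), matching how clinical tables are
#' conventionally printed, rather than R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
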