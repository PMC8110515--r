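test_that("MAF-like TSV call sets parse with identity and invariants enforced", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(chrom = c("1", "2", "X"), pos = c(100L, 200L, 300L),
                   ref = "A", alt = "G", gene = c("TP53", "RB1", "PTEN"),
                   effect = "nonsynonymous_snv", alt_reads = c(10L, 20L, 5L),
                   depth = 100L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- read_callset(path, "maf_tsv", "P1", "tissue")
  expect_s3_class(s, "compartment_sample")
  expect_equal(nrow(s$calls), 3L)
  expect_equal(s$calls$vaf, c(0.10, 0.20, 0.05))
  expect_equal(s$calls$key[1], "1:100:A:G")

  # duplicate identity key rejected
  dup <- rbind(df, df[1, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_callset(path, "maf_tsv", "P1", "tissue"), "duplicate")
})

test_that("call-table invariants: depth, alt_reads bounds, vaf consistency", {
  expect_error(call_table("1", 1, "A", "G", alt_reads = 1, depth = 0),
               "depth")
  expect_error(call_table("1", 1, "A", "G", alt_reads = 11, depth = 10),
               "alt_reads")
  expect_error(call_table("1", 1, "A", "G", alt_reads = 5, depth = 10,
                          vaf = 0.9), "inconsistent")
  expect_warning(ct <- call_table("1", 1, "A", "G", effect = "missense",
                                  alt_reads = 5, depth = 10), "other")
  expect_equal(ct$effect, "other")
})

test_that("VCF records parse through the standard AD/DP fields and
           multi-allelic sites are split", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    paste("1", "100", ".", "A", "G", ".", "PASS",
          "GENE=TP53;EFFECT=nonsynonymous_snv", "GT:AD:DP", "0/1:45,5:50",
          sep = "\t"),
    paste("2", "500", ".", "C", "A,T", ".", "PASS",
          "GENE=RB1;EFFECT=nonsynonymous_snv", "GT:AD:DP",
          "1/2:60,30,10:100", sep = "\t")), path)
  s <- read_callset(path, "vcf", "P1", "bwfs")
  expect_equal(nrow(s$calls), 3L)
  # AD is ref,alt: 45 ref + 5 alt reads
  first <- s$calls[s$calls$key == "1:100:A:G", ]
  expect_equal(first$alt_reads, 5L)
  expect_equal(first$depth, 50L)
  expect_equal(first$vaf, 0.10)
  expect_equal(first$gene, "TP53")
  # multi-allelic site split into biallelic records sharing the depth
  multi <- s$calls[s$calls$chrom == "2", ]
  expect_setequal(multi$alt, c("A", "T"))
  expect_equal(sort(multi$alt_reads), c(10L, 30L))
  expect_equal(unique(multi$depth), 100L)
})

test_that("variant normalization is minimal, left-aligned and idempotent", {
  nv <- normalize_variant("1", 100, "CAT", "CGT")
  expect_equal(nv$pos, 101L)
  expect_equal(nv$ref, "A")
  expect_equal(nv$alt, "G")
  # idempotent
  nv2 <- normalize_variant(nv$chrom, nv$pos, nv$ref, nv$alt)
  expect_equal(nv, nv2)
  # deletion keeps an anchor base
  nv3 <- normalize_variant("1", 100, "ACCA", "AA")
  expect_equal(nv3$ref, "ACC")
  expect_equal(nv3$alt, "A")
  expect_error(normalize_variant("1", 100, "A", "A"), "differ")
  set.seed(11)
  for (i in 1:20) {
    b <- c("A", "C", "G", "T")
    r <- paste(sample(b, sample(1:4, 1), replace = TRUE), collapse = "")
    a <- paste(sample(b, sample(1:4, 1), replace = TRUE), collapse = "")
    if (r == a) next
    n1 <- normalize_variant("7", 5000, r, a)
    n2 <- normalize_variant(n1$chrom, n1$pos, n1$ref, n1$alt)
    expect_equal(n1, n2)
  }
})

test_that("sample sheets validate compartments and duplicates", {
  dir <- withr::local_tempdir()
  files <- character()
  for (p in c("P1", "P2")) for (cp in c("tissue", "bwfs", "bwfp", "pbl")) {
    f <- file.path(dir, paste0(p, "_", cp, ".tsv"))
    s <- compartment_sample(p, cp, make_calls(c(0.1, 0.2)))
    write_callset(s, f, "maf_tsv")
    files <- rbind(files, c(p, cp, f))
  }
  sheet <- file.path(dir, "sheet.tsv")
  write.table(data.frame(patient_id = files[, 1], compartment = files[, 2],
                         path = files[, 3]),
              sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort <- read_sample_sheet(sheet)
  expect_length(cohort, 2L)
  expect_setequal(names(cohort$P1$samples), c("tissue", "bwfs", "bwfp", "pbl"))
  expect_equal(nrow(cohort$P2$samples$bwfs$calls), 2L)

  bad <- data.frame(patient_id = "P1", compartment = "serum", path = "x")
  write.table(bad, sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(sheet), "unknown compartment")

  dup <- data.frame(patient_id = "P1", compartment = "tissue",
                    path = files[1, 3])[c(1, 1), ]
  write.table(dup, sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(sheet), "twice")

  writeLines("patient_id\tcompartment\tpath", sheet)
  expect_length(read_sample_sheet(sheet), 0L)
})

test_that("call sets round-trip through both on-disk formats", {
  set.seed(21)
  for (fmt in c("maf_tsv", "vcf")) {
    vafs <- round(runif(6, 0.05, 0.6), 2)
    s <- compartment_sample("P9", "plasma_pre",
                            make_calls(vafs, depth = 200L))
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_callset(s, path, if (fmt == "vcf") "vcf" else "maf_tsv")
    back <- read_callset(path, if (fmt == "vcf") "vcf" else "maf_tsv",
                         "P9", "plasma_pre")
    cols <- c("key", "gene", "effect", "alt_reads", "depth", "vaf")
    a <- s$calls[order(s$calls$key), cols]
    b <- back$calls[order(back$calls$key), cols]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("report tables round-trip and reject non-finite values", {
  tab <- data.frame(comparison = c("a", "b"), rate = c(92.6, 85.4),
                    n = c(204L, 267L))
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile()
    write_report(tab, path, fmt)
    back <- read_report(path, fmt)
    expect_equal(back$rate, tab$rate)
    expect_equal(back$n, tab$n)
  }
  # empty table -> header-only file
  path <- withr::local_tempfile()
  write_report(tab[0, ], path, "tsv")
  expect_equal(readLines(path), "comparison\trate\tn")
  expect_error(write_report(data.frame(x = Inf), path, "tsv"), "non-finite")
})

test_that("panel files round-trip with driver flags and capture size", {
  p <- panel_definition(c("TP53", "RB1", "GENE1"), 1.6, c("TP53", "RB1"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_panel(p, path)
  back <- read_panel(path)
  expect_equal(back$genes, p$genes)
  expect_equal(back$driver_genes, p$driver_genes)
  expect_equal(back$capture_size_mb, 1.6)
  expect_error(panel_definition("TP53", driver_genes = "RB1"), "subset")
  expect_error(panel_definition("TP53", capture_size_mb = 0), "> 0")
})
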