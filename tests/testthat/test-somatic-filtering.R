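test_that("support filter applies >=5 reads and strict quality thresholds", {
  one <- function(alt, mapq, baseq)
    call_table("1", 100, "A", "G", alt_reads = alt, depth = 100,
               mean_mapq = mapq, mean_baseq = baseq)
  cfg <- filter_config()
  expect_equal(nrow(filter_by_support(one(4, 40, 35), cfg)), 0L)
  expect_equal(nrow(filter_by_support(one(5, 31, 31), cfg)), 1L)
  # quality thresholds are exclusive: mapq exactly 30 fails
  expect_equal(nrow(filter_by_support(one(10, 30, 40), cfg)), 0L)
  expect_equal(nrow(filter_by_support(one(10, 40, 30), cfg)), 0L)
})

test_that("germline subtraction removes PBL-supported keys only, with
           patient identity checked", {
  cand <- compartment_sample("P1", "tissue",
                             make_calls(c(0.2, 0.3, 0.4)))
  pbl_calls <- cand$calls[1:2, c("chrom", "pos", "ref", "alt")]
  pbl <- compartment_sample("P1", "pbl",
    call_table(pbl_calls$chrom, pbl_calls$pos, pbl_calls$ref, pbl_calls$alt,
               alt_reads = c(10L, 1L), depth = 100L))
  out <- filter_germline(cand, pbl)
  # key seen with 10 alt reads removed; key with 1 alt read (< 2) kept
  expect_equal(nrow(out$calls), 2L)
  expect_false(pbl$calls$key[1] %in% out$calls$key)
  expect_true(pbl$calls$key[2] %in% out$calls$key)

  empty_pbl <- compartment_sample("P1", "pbl")
  expect_equal(filter_germline(cand, empty_pbl)$calls, cand$calls)

  other <- compartment_sample("P2", "pbl")
  expect_error(filter_germline(cand, other), "mismatch")
  expect_error(filter_germline(cand, compartment_sample("P1", "tissue")),
               "pbl")
})

test_that("population-SNP exclusion is allele-exact", {
  calls <- call_table("1", c(100, 100, 200), "A", c("G", "T", "G"),
                      alt_reads = 10, depth = 100)
  cfg <- filter_config(snp_exclusion = "1:100:A:G")
  out <- filter_population_snps(calls, cfg)
  expect_equal(sort(out$key), c("1:100:A:T", "1:200:A:G"))
  # empty exclusion set is the identity
  expect_equal(filter_population_snps(calls, filter_config()), calls)
})

test_that("SNP exclusion lists load from TSV and VCF", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "1", pos = 100, ref = "A", alt = "G"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_snp_list(tsv), "1:100:A:G")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  s <- compartment_sample("X", "pbl", make_calls(c(0.5, 0.5)))
  write_callset(s, vcf, "vcf")
  expect_setequal(read_snp_list(vcf, "vcf"), s$calls$key)
})

test_that("the composed filter removes exactly the flagged calls", {
  # 6 candidates: 1 low-support, 1 low-mapq, 1 germline, 1 SNP-listed, 2 clean
  calls <- call_table("1", (1:6) * 100, "A", "G",
                      alt_reads = c(3L, 50L, 50L, 50L, 50L, 40L),
                      depth = 100L,
                      mean_mapq = c(50, 20, 50, 50, 50, 50),
                      mean_baseq = 35)
  raw <- compartment_sample("P1", "bwfs", calls)
  pbl <- compartment_sample("P1", "pbl",
    call_table("1", 300, "A", "G", alt_reads = 30L, depth = 100L))
  cfg <- filter_config(snp_exclusion = "1:400:A:G")
  out <- run_somatic_filter(raw, pbl, cfg)
  expect_setequal(out$calls$key, c("1:500:A:G", "1:600:A:G"))
  # idempotent
  again <- run_somatic_filter(out, pbl, cfg)
  expect_equal(again$calls, out$calls)
  # all-germline set -> empty
  germ_only <- compartment_sample("P1", "tissue", calls[5:6, ])
  all_pbl <- compartment_sample("P1", "pbl", calls[5:6, ])
  expect_equal(nrow(run_somatic_filter(germ_only, all_pbl)$calls), 0L)
})

test_that("filters commute, are idempotent, and only remove rows", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(3:12, 1)
    calls <- call_table("1", sample.int(10000, n) * 10, "A", "G",
                        alt_reads = sample(1:40, n, replace = TRUE),
                        depth = 100L,
                        mean_mapq = runif(n, 20, 60),
                        mean_baseq = runif(n, 20, 45))
    pbl <- call_table("2", 1:3 * 7L, "C", "T",
                      alt_reads = sample(0:10, 3), depth = 100L)
    pbl <- rbind(pbl, calls[sample(n, min(2, n)), ])
    pbl <- pbl[!duplicated(pbl$key), ]
    cfg <- filter_config(snp_exclusion = sample(calls$key, 2))
    f1 <- function(x) filter_by_support(x, cfg)
    f2 <- function(x) filter_germline(x, pbl, cfg)
    f3 <- function(x) filter_population_snps(x, cfg)
    ref <- f3(f2(f1(calls)))
    for (perm in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))) {
      fs <- list(f1, f2, f3)[perm]
      out <- fs[[3]](fs[[2]](fs[[1]](calls)))
      expect_equal(out, ref)
    }
    expect_equal(f3(f2(f1(ref))), ref)        # idempotence
    expect_true(all(ref$key %in% calls$key))  # output subset of input
  }
})
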