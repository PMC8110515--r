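test_that("simulation is deterministic given seed and patient index", {
  cfg <- simulation_config(n_patients = 3, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_equal(a$cohort$P001$samples$tissue$calls,
               b$cohort$P001$samples$tissue$calls)
  expect_equal(a$truth, b$truth)
  # patient streams are partitioned: simulating patient 2 alone matches
  solo <- simulate_patient(cfg, 2)
  expect_equal(solo$record$samples$bwfs$calls,
               a$cohort$P002$samples$bwfs$calls)
  # different seeds diverge
  c_ <- simulate_cohort(simulation_config(n_patients = 3, seed = 100))
  expect_false(identical(a$truth$mutations, c_$truth$mutations))
})

test_that("zero shedding and zero response factor empty the right
           compartments", {
  cfg <- simulation_config(n_patients = 4, seed = 7)
  cfg$compartment_params$plasma_pre$tau <- 0
  sim <- simulate_cohort(cfg)
  germ <- sim$truth$germline$key
  for (rec in sim$cohort) {
    pp <- rec$samples$plasma_pre
    # raw plasma calls are all germline SNPs; no somatic calls shed
    expect_true(all(pp$calls$key %in% germ))
  }
  filtered <- filter_cohort(sim$cohort)
  for (rec in filtered)
    expect_equal(nrow(rec$samples$plasma_pre$calls), 0L)

  cfg2 <- simulation_config(n_patients = 6, seed = 8,
                            response_factor = c(PR = 0, PD = 0),
                            pr_fraction = 1, post_plasma_fraction = 1)
  sim2 <- simulate_cohort(cfg2)
  for (rec in filter_cohort(sim2$cohort))
    expect_equal(nrow(rec$samples$plasma_post$calls), 0L)
})

test_that("germline SNPs appear in the PBL reference and are removed by
           filtering", {
  cfg <- simulation_config(n_patients = 3, seed = 13)
  sim <- simulate_cohort(cfg)
  germ <- sim$truth$germline
  for (rec in sim$cohort) {
    pbl_keys <- rec$samples$pbl$calls$key
    my_germ <- germ$key[germ$patient_id == rec$patient_id]
    # nearly all het SNPs are seen at depth >= 897 (binomial dropout only)
    expect_gt(mean(my_germ %in% pbl_keys), 0.95)
  }
  filtered <- filter_cohort(sim$cohort)
  for (rec in filtered)
    for (s in rec$samples)
      expect_false(any(s$calls$key %in% germ$key))
})

test_that("compartment VAF approaches the expected diluted fraction", {
  # undiluted, pure, fully clonal tumor at depth 10000: VAF ~ 0.5
  cfg <- simulation_config(n_patients = 2, seed = 17, tissue_purity = 1,
                           clone_fraction_shape = c(1e6, 1e-2),
                           germline_snps_per_patient = 0L)
  cfg$compartment_params$tissue <- list(tau = 1, depth = 10000L)
  sim <- simulate_cohort(cfg)
  vafs <- unlist(lapply(sim$cohort, function(r) r$samples$tissue$calls$vaf))
  expect_gt(length(vafs), 5)
  expect_lt(abs(mean(vafs) - 0.5), 0.01)
})

test_that("expected VAF ordering follows the tumor-content ordering", {
  cfg <- simulation_config(n_patients = 10, seed = 23)
  sim <- simulate_cohort(cfg)
  filtered <- filter_cohort(sim$cohort)
  mean_vaf <- function(cp)
    mean(unlist(lapply(filtered, function(r) r$samples[[cp]]$calls$vaf)))
  # tau ordering tissue (1) > bwfs (0.45) > plasma (0.25) > bwfp (0.12)
  expect_gt(mean_vaf("tissue"), mean_vaf("bwfs"))
  expect_gt(mean_vaf("bwfs"), mean_vaf("plasma_pre"))
  expect_gt(mean_vaf("plasma_pre"), mean_vaf("bwfp"))
})

test_that("tissue-BWFs TMB correlation rises with the BWFs tumor content", {
  rs <- vapply(c(0.12, 0.25, 0.45), function(tau) {
    cfg <- simulation_config(n_patients = 40, seed = 29)
    cfg$compartment_params$bwfs$tau <- tau
    filtered <- filter_cohort(simulate_cohort(cfg)$cohort)
    b <- burden_table(filtered, compartments = c("tissue", "bwfs"))
    wide <- merge(b[b$compartment == "tissue", c("patient_id", "tmb")],
                  b[b$compartment == "bwfs", c("patient_id", "tmb")],
                  by = "patient_id")
    correlation(wide$tmb.x, wide$tmb.y)$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("count-constrained fixtures meet their totals exactly and reject
           inconsistent count totals", {
  fx <- fixture_from_counts(19, 204, 189, 24, n_driver_reference = 54,
                            n_driver_shared = 51)
  keys <- compartment_keys(fx, "tissue")
  expect_equal(sum(lengths(keys)), 204L)
  expect_equal(sum(lengths(compartment_keys(fx, "bwfs"))), 189L + 24L)
  expect_equal(sum(lengths(compartment_keys(fx, "tissue",
                                            drivers_only = TRUE))), 54L)
  res <- detection_rate(fx, "tissue", "bwfs")
  expect_equal(res$n_shared, 189L)
  expect_error(fixture_from_counts(5, 10, 12), "n_shared <= n_reference")
  expect_error(fixture_from_counts(5, 10, 5, n_driver_reference = 11),
               "n_driver_reference <= n_reference")
  expect_error(fixture_from_counts(5, 10, 9, n_driver_reference = 5,
                                   n_driver_shared = 3),
               "n_reference - n_shared")
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(n_patients = 5), "seed")
  expect_error(simulation_config(n_patients = 0, seed = 1), "n_patients")
  expect_error(simulation_config(seed = 1, tissue_purity = 1.2), "purity")
  cfg <- simulation_config(seed = 1)
  cfg$compartment_params$bwfs$tau <- 2
  expect_error(do.call(simulation_config,
                       c(list(seed = 1),
                         list(compartment_params = cfg$compartment_params))),
               "tau")
})
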