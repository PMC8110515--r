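test_that("count-constrained fixtures reproduce the cohort detection rates", {
  fx <- fixture_from_counts(19, 204, 189, 24)
  res <- detection_rate(fx, "tissue", "bwfs")
  expect_equal(res$n_reference, 204L)
  expect_equal(res$n_shared, 189L)
  expect_equal(res$detection_rate, 92.6)

  # query sets all empty -> 0
  fx0 <- fixture_from_counts(5, 20, 0, 0)
  expect_equal(detection_rate(fx0, "tissue", "bwfs")$detection_rate, 0)

  # identity -> 100
  fxi <- fixture_from_counts(5, 20, 20, 0)
  expect_equal(detection_rate(fxi, "tissue", "bwfs")$detection_rate, 100)

  empty <- fixture_from_counts(3, 0, 0, 5)
  expect_error(detection_rate(empty, "tissue", "bwfs"), "empty reference")
})

test_that("pairwise concordance follows inclusion-exclusion and is symmetric", {
  fx <- fixture_from_counts(21, 258, 228, 9, reference = "tissue",
                            query = "bwfp")
  res <- pairwise_concordance(fx, "tissue", "bwfp")
  expect_equal(res$n_union, 267L)
  expect_equal(res$n_shared, 228L)
  expect_equal(res$jaccard_concordance, 85.4)
  rev <- pairwise_concordance(fx, "bwfp", "tissue")
  expect_equal(rev$jaccard_concordance, res$jaccard_concordance)
  expect_equal(rev$n_shared, res$n_shared)

  fx2 <- fixture_from_counts(21, 205, 172, 41, reference = "plasma_pre",
                             query = "bwfs")
  res2 <- pairwise_concordance(fx2, "plasma_pre", "bwfs")
  expect_equal(res2$n_shared, 205L + 213L - 246L)
  expect_equal(res2$jaccard_concordance, 69.9)

  disjoint <- fixture_from_counts(4, 10, 0, 10)
  expect_equal(pairwise_concordance(disjoint, "tissue",
                                    "bwfs")$jaccard_concordance, 0)
})

test_that("driver concordance restricts to the driver subset", {
  full <- fixture_from_counts(19, 54, 54, 0, n_driver_reference = 54,
                              n_driver_shared = 54)
  expect_equal(driver_concordance(full, "tissue", "bwfs")$detection_rate, 100)
  part <- fixture_from_counts(19, 54, 51, 0, n_driver_reference = 54,
                              n_driver_shared = 51)
  expect_equal(driver_concordance(part, "tissue", "bwfs")$detection_rate, 94.4)
  # drivers in reference, none shared
  none <- fixture_from_counts(19, 54, 0, 0, n_driver_reference = 54)
  expect_equal(driver_concordance(none, "tissue", "bwfs")$detection_rate, 0)
  # no drivers at all -> undefined
  plain <- fixture_from_counts(19, 54, 50, 0)
  expect_error(driver_concordance(plain, "tissue", "bwfs"), "driver")
})

test_that("every emitted result satisfies the set identities", {
  set.seed(41)
  for (i in 1:10) {
    cohort <- random_cohort(sample(2:6, 1))
    res <- pairwise_concordance(cohort, "tissue", "bwfs")
    expect_equal(res$n_union, res$n_reference + res$n_query - res$n_shared)
    expect_lte(res$n_shared, min(res$n_reference, res$n_query))
    expect_gte(res$detection_rate, 0)
    expect_lte(res$detection_rate, 100)
    # count-weighted aggregation equals per-patient sums
    expect_equal(res$n_shared, sum(res$per_patient$n_shared))
    # identity: each compartment against itself
    self <- detection_rate(cohort, "tissue", "tissue")
    expect_equal(self$detection_rate, 100)
  }
})

test_that("multiway overlap enumerates membership patterns", {
  mk <- function(pid, cp, keys)
    compartment_sample(pid, cp,
      call_table("1", keys * 100L, "A", "G", alt_reads = 10L, depth = 100L))
  cohort <- list(P1 = patient_record("P1", list(mk("P1", "tissue", c(1L, 2L)),
                                                mk("P1", "bwfs", c(2L, 3L)))))
  tab <- multiway_overlap(cohort, c("tissue", "bwfs"))
  expect_equal(sum(tab$count), 3L)
  expect_equal(tab$count[tab$pattern == "11"], 1L)
  expect_equal(tab$count[tab$pattern == "10"], 1L)
  expect_equal(tab$count[tab$pattern == "01"], 1L)

  # identical sets across four compartments: everything in the all-four cell
  four <- c("tissue", "bwfs", "bwfp", "plasma_pre")
  cohort4 <- list(P1 = patient_record("P1", lapply(four, mk, pid = "P1",
                                                   keys = 1:3)))
  tab4 <- multiway_overlap(cohort4, four)
  expect_equal(tab4$count[tab4$pattern == "1111"], 3L)
  expect_equal(sum(tab4$count), 3L)

  expect_error(multiway_overlap(cohort, "tissue"), "at least 2")
  expect_error(multiway_overlap(cohort, c("tissue", "serum")), "unknown")
})

test_that("multiway overlap matches a brute-force enumeration oracle", {
  set.seed(43)
  for (i in 1:8) {
    comps <- c("tissue", "bwfs", "bwfp")
    cohort <- random_cohort(sample(2:4, 1), pool_size = 8L,
                            compartments = comps)
    tab <- multiway_overlap(cohort, comps)
    oracle <- brute_overlap(cohort, comps)
    for (j in seq_len(nrow(tab))) {
      exp_count <- oracle[[tab$pattern[j]]]
      expect_equal(tab$count[j], if (is.null(exp_count)) 0L else exp_count)
    }
    expect_equal(sum(tab$count), sum(unlist(oracle)))
  }
})

test_that("patients missing a compartment are dropped per comparison", {
  mk <- function(pid, cp, keys)
    compartment_sample(pid, cp,
      call_table("1", keys * 100L, "A", "G", alt_reads = 10L, depth = 100L))
  cohort <- list(
    P1 = patient_record("P1", list(mk("P1", "tissue", 1:4),
                                   mk("P1", "bwfs", 1:2))),
    P2 = patient_record("P2", list(mk("P2", "tissue", 1:6))))
  res <- detection_rate(cohort, "tissue", "bwfs")
  expect_equal(nrow(res$per_patient), 1L)  # P2 has no bwfs sample
  expect_equal(res$n_reference, 4L)
  expect_equal(res$detection_rate, 50)
})
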