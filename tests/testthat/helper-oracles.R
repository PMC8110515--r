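# Independent brute-force oracles and small fixture builders used across
# the test files.

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled (mid)ranked values to group A; works with ties.
enum_unpaired_p <- function(a, b) {
  n <- length(a)
  N <- n + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  w_all <- apply(utils::combn(N, n), 2L, function(i) sum(r[i]))
  lo <- mean(w_all <= w_obs + 1e-9)
  hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided signed-rank p by enumerating every sign assignment of
# the non-zero paired differences; works with ties among |d|.
enum_paired_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  v_all <- numeric(2^n)
  for (s in seq_len(2^n) - 1L) {
    pos <- as.logical(bitwAnd(s, 2^(seq_len(n) - 1L)))
    v_all[s + 1L] <- sum(r[pos])
  }
  lo <- mean(v_all <= v_obs + 1e-9)
  hi <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Brute-force membership-pattern counts for multiway overlap: walk every
# variant of every patient and tabulate its membership vector.
brute_overlap <- function(cohort, compartments) {
  sets <- lapply(compartments, function(cp)
    bwfbiopsy::compartment_keys(cohort, cp))
  names(sets) <- compartments
  patients <- Reduce(intersect, lapply(sets, names))
  tab <- new.env()
  for (p in patients) {
    keys <- unique(unlist(lapply(sets, function(s) s[[p]])))
    for (k in keys) {
      pat <- paste(vapply(compartments, function(cp)
        as.integer(k %in% sets[[cp]][[p]]), integer(1)), collapse = "")
      tab[[pat]] <- (if (is.null(tab[[pat]])) 0L else tab[[pat]]) + 1L
    }
  }
  as.list(tab)
}

# A small valid call table with distinct loci.
make_calls <- function(vafs, depth = 100L, effect = "nonsynonymous_snv",
                       gene = "TP53", mapq = 50, baseq = 35,
                       is_driver = FALSE, chrom = "1") {
  n <- length(vafs)
  alt <- as.integer(round(vafs * depth))
  bwfbiopsy::call_table(chrom, seq_len(n) * 1000L, "A", "G", gene = gene,
                        effect = effect, alt_reads = alt, depth = depth,
                        mean_mapq = mapq, mean_baseq = baseq,
                        is_driver = is_driver)
}

# A random two-compartment cohort over a small shared key pool (keys are
# distinct loci; each patient/compartment draws a subset).
random_cohort <- function(n_patients, pool_size = 12L,
                          compartments = c("tissue", "bwfs")) {
  cohort <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("R%02d", p)
    samples <- lapply(compartments, function(cp) {
      k <- sort(sample.int(pool_size, sample.int(pool_size, 1L)))
      calls <- bwfbiopsy::call_table("1", k * 100L, "A", "G", gene = "TP53",
                                     effect = "nonsynonymous_snv",
                                     alt_reads = 10L, depth = 100L,
                                     mean_mapq = 50, mean_baseq = 35)
      bwfbiopsy::compartment_sample(pid, cp, calls)
    })
    cohort[[pid]] <- bwfbiopsy::patient_record(pid, samples)
  }
  cohort
}
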