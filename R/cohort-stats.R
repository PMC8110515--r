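# Cohort-level statistics: paired/unpaired rank tests, Pearson correlation,
# Kaplan-Meier survival stratification with a log-rank test, and
# tumor-marker sensitivity versus sequencing detection.
#
# All tests are two-sided; no multiple-testing correction is applied. Rank
# tests use the exact null distribution for small samples (n <= 25 without
# ties, full enumeration for small tied samples) and the normal
# approximation with continuity and tie correction above, so p-values are
# reproducible across platforms.

new_test_result <- function(test, statistic, p_value, n, method) {
  data.frame(test = test, statistic = as.numeric(statistic),
             p_value = as.numeric(p_value), n = sum(n),
             n_a = n[1L], n_b = if (length(n) > 1L) n[2L] else NA_integer_,
             alternative = "two_sided", method = method,
             stringsAsFactors = FALSE)
}

# Two-sided p from a discrete exact null: 2 * min tail, capped at 1
# (the convention of the exact Wilcoxon distributions in stats).
.two_sided_p <- function(null_values, observed, tol = 1e-9) {
  lo <- mean(null_values <= observed + tol)
  hi <- mean(null_values >= observed - tol)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon matched-pair signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (errors when all differences are zero). Without ties among the
#' absolute differences and n <= 25, the exact signed-rank null is used;
#' with ties and n <= 20 the exact null is obtained by enumerating all 2^n
#' sign assignments over midranks; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param x Pre values, or a [paired_burden_table()] data.frame with
#'   `value_a`/`value_b` columns.
#' @param y Post values (omit when `x` is a paired table).
#' @param exact_n Largest n for the exact no-ties null (default 25).
#' @param enum_n Largest n for the tied-data enumeration (default 20).
#' @return A one-row `test_result` data.frame.
#' @export
paired_test <- function(x, y = NULL, exact_n = 25L, enum_n = 20L) {
  if (is.data.frame(x)) {
    y <- x$value_b
    x <- x$value_a
  }
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d))
    stop("degenerate paired data: all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_n) {
    res <- stats::wilcox.test(d, exact = TRUE)
    new_test_result("wilcoxon_signed_rank", res$statistic, res$p.value, n,
                    "exact")
  } else if (ties && n <= enum_n) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null_v <- as.numeric(signs %*% r)
    new_test_result("wilcoxon_signed_rank", v, .two_sided_p(null_v, v), n,
                    "exact_enumeration")
  } else {
    res <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                               correct = TRUE))
    new_test_result("wilcoxon_signed_rank", res$statistic, res$p.value, n,
                    "normal_approx")
  }
}

#' Mann-Whitney U test
#'
#' Two-sided unpaired rank-sum test. Without ties and both groups of size
#' <= 25, the exact Mann-Whitney null is used; with ties, the exact null is
#' enumerated over all assignments of the pooled values to groups when
#' `choose(n + m, n)` is small enough; otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param a,b Group value vectors (both non-empty).
#' @param exact_n Largest per-group n for the exact no-ties null.
#' @param enum_max Largest number of arrangements to enumerate (default 1e5).
#' @return A one-row `test_result` data.frame.
#' @export
unpaired_test <- function(a, b, exact_n = 25L, enum_max = 1e5) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && max(n, m) <= exact_n) {
    res <- stats::wilcox.test(a, b, exact = TRUE)
    new_test_result("mann_whitney", res$statistic, res$p.value, c(n, m),
                    "exact")
  } else if (ties && choose(n + m, n) <= enum_max) {
    idx <- utils::combn(n + m, n)
    null_u <- apply(idx, 2L, function(i) sum(r[i])) - n * (n + 1) / 2
    new_test_result("mann_whitney", u, .two_sided_p(null_u, u), c(n, m),
                    "exact_enumeration")
  } else {
    res <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    new_test_result("mann_whitney", res$statistic, res$p.value, c(n, m),
                    "normal_approx")
  }
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation requires at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p_value = res$p.value, n = length(x))
}

#' Survival stratification by a per-patient score
#'
#' Splits the cohort at the median of `score` (low: score <= median; high:
#' score > median), fits Kaplan-Meier curves per group and runs a
#' two-group log-rank test. The median cut-point is a configurable choice
#' (`cut`), not a modeling claim.
#'
#' @param time Survival/censoring times (>= 0).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param score Per-patient stratification score (e.g. mTBI).
#' @param cut Cut-point; default the cohort median of `score`.
#' @return An object of class `survival_split`: `groups` (factor), `km`
#'   (data.frame: time, group, survival, n_risk), `chisq`, `p_value`.
#' @export
survival_split <- function(time, event, score, cut = stats::median(score)) {
  if (length(unique(stats::na.omit(c(length(time), length(event),
                                     length(score))))) != 1L)
    stop("time, event and score must have equal length")
  if (any(time < 0)) stop("survival times must be >= 0")
  if (all(time == 0)) stop("all patients censored at time 0")
  group <- factor(ifelse(score > cut, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) < 2L))
    stop("median split leaves a group with fewer than 2 patients")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_group <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  km <- data.frame(time = fit$time, group = strata_group,
                   survival = fit$surv, n_risk = fit$n.risk,
                   stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(groups = group, cut = cut, km = km, chisq = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
            class = "survival_split")
}

#' @export
print.survival_split <- function(x, ...) {
  cat(sprintf("<survival_split> cut %.4g: n(low)=%d n(high)=%d, log-rank chisq %.3f, p = %.4g\n",
              x$cut, sum(x$groups == "low"), sum(x$groups == "high"),
              x$chisq, x$p_value))
  invisible(x)
}

#' Tumor-marker sensitivity versus sequencing detection
#'
#' Percent of patients positive for each biochemical tumor marker (ProGRP,
#' NSE, CEA), alongside the percent of patients with at least one somatic
#' call per compartment.
#'
#' @param clinical Clinical data.frame with logical/0-1 marker columns
#'   (`progrp_positive`, `nse_positive`, `cea_positive` by default).
#' @param cohort Optional named list of filtered [patient_record()]s for
#'   the sequencing-detection rows.
#' @param markers Named character vector mapping display name to column.
#' @param compartments Compartments for the detection rows.
#' @param digits Decimals for percentages (default 1).
#' @return Data.frame: `type` (marker/sequencing), `name`, `n_positive`,
#'   `n`, `percent`.
#' @export
marker_sensitivity <- function(clinical, cohort = NULL,
                               markers = c(ProGRP = "progrp_positive",
                                           NSE = "nse_positive",
                                           CEA = "cea_positive"),
                               compartments = c("tissue", "bwfs", "bwfp",
                                                "plasma_pre"),
                               digits = 1) {
  rows <- list()
  for (nm in names(markers)) {
    col <- markers[[nm]]
    if (!col %in% names(clinical)) next
    flags <- as.logical(clinical[[col]])
    n <- sum(!is.na(flags))
    pos <- sum(flags, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "marker", name = nm, n_positive = pos, n = n,
      percent = round_half_up(100 * pos / n, digits),
      stringsAsFactors = FALSE)
  }
  if (!is.null(cohort)) {
    for (cp in compartments) {
      sets <- compartment_keys(cohort, cp)
      if (!length(sets)) next
      det <- sum(vapply(sets, length, integer(1)) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "sequencing", name = cp, n_positive = det, n = length(sets),
        percent = round_half_up(100 * det / length(sets), digits),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
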