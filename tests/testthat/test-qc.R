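# profile stub for QC tests (counts chosen per scenario)
qc_profile <- function(n_kept, n_host, n_nonhost, mirna, smallrna_other,
                       sample_id = "s") {
  bc <- stats::setNames(numeric(length(ev_biotypes())), ev_biotypes())
  bc["miRNA"] <- mirna
  bc["YRNA"] <- smallrna_other
  bc["host_other"] <- n_host - mirna - smallrna_other
  structure(list(sample_id = sample_id, n_trimmed_kept = n_kept,
                 n_host = n_host, n_nonhost = n_nonhost,
                 n_unmapped = n_kept - n_host - n_nonhost,
                 biotype_counts = bc, feature_counts = numeric(0),
                 feature_cpm = numeric(0), zero_input = n_kept == 0),
            class = "sample_profile")
}

test_that("QC metrics follow the stated ratio definitions", {
  p <- qc_profile(200000, 120000, 10000, mirna = 60000,
                  smallrna_other = 50000)
  r <- compute_qc(p)
  expect_equal(r$overall_map_rate, 0.65)
  expect_equal(r$host_frac, 0.6)
  expect_equal(r$smallrna_frac_of_host, 110000 / 120000)
  expect_equal(r$mirna_frac_of_host, 0.5)
})

test_that("zero-read samples get zero fractions and every flag", {
  r <- compute_qc(qc_profile(0, 0, 0, 0, 0))
  expect_equal(r$overall_map_rate, 0)
  expect_equal(r$host_frac, 0)
  expect_true(all(unlist(r[c("low_reads", "low_overall_map",
                             "low_host_reads", "low_host_frac",
                             "low_smallrna", "low_mirna")])))
})

test_that("gate boundaries follow the documented strictness conventions", {
  # more than 100,000 reads and at least 20% overall mapping pass
  r <- compute_qc(qc_profile(100001, 95000, 0, 80000, 10000))
  r$overall_map_rate <- 0.205
  r <- flag_sample(r)
  expect_false(r$low_reads)
  expect_false(r$low_overall_map)
  # exactly 100,000 trimmed reads fails the "more than" rule
  expect_true(flag_sample(compute_qc(
    qc_profile(100000, 60000, 0, 50000, 5000)))$low_reads)
  # host-read minimum of 100,000 passes; 99,999 fails
  expect_false(flag_sample(compute_qc(
    qc_profile(150000, 100000, 0, 80000, 15000)))$low_host_reads)
  expect_true(flag_sample(compute_qc(
    qc_profile(150000, 99999, 0, 80000, 15000)))$low_host_reads)
  # miRNA fraction exactly 0.10 passes, 0.099 fails
  r10 <- compute_qc(qc_profile(300000, 200000, 0, 20000, 160000))
  expect_false(r10$low_mirna)
  r099 <- compute_qc(qc_profile(300000, 200000, 0, 19800, 160200))
  expect_true(r099$low_mirna)
})

test_that("planted failure modes receive exactly the expected flags", {
  # low depth but clean content
  low_depth <- compute_qc(qc_profile(50000, 45000, 1000, 30000, 12000))
  expect_true(low_depth$low_reads)
  expect_true(low_depth$low_host_reads)
  expect_false(low_depth$low_overall_map)
  expect_false(low_depth$low_smallrna)
  expect_false(low_depth$low_mirna)
  # junk-heavy: deep but barely mapping
  junky <- compute_qc(qc_profile(500000, 50000, 10000, 30000, 15000))
  expect_true(junky$low_overall_map)
  expect_true(junky$low_host_frac)
  expect_false(junky$low_reads)
  expect_false(junky$low_smallrna)
  # miRNA-poor: host-rich but miRNA below 10%
  poor <- compute_qc(qc_profile(500000, 400000, 0, 20000, 370000))
  expect_true(poor$low_mirna)
  expect_false(poor$low_smallrna)
  expect_false(poor$low_host_frac)
})

test_that("raising thresholds can only add flags", {
  set.seed(9)
  for (i in 1:20) {
    p <- qc_profile(round(runif(1, 1e4, 5e5)), 0, 0, 0, 0)
    p$n_host <- round(p$n_trimmed_kept * runif(1, 0.1, 0.9))
    p$biotype_counts["miRNA"] <- round(p$n_host * runif(1, 0, 0.6))
    p$biotype_counts["YRNA"] <- round((p$n_host -
                                         p$biotype_counts["miRNA"]) *
                                        runif(1))
    p$biotype_counts["host_other"] <- p$n_host -
      p$biotype_counts["miRNA"] - p$biotype_counts["YRNA"]
    p$n_unmapped <- p$n_trimmed_kept - p$n_host
    base <- compute_qc(p)
    th <- qc_thresholds()
    th2 <- lapply(th, function(x) x * 1.5)
    harder <- flag_sample(base, th2)
    flags <- c("low_reads", "low_overall_map", "low_host_reads",
               "low_host_frac", "low_smallrna", "low_mirna")
    expect_true(all(unlist(base[flags]) <= unlist(harder[flags])))
  }
})

test_that("study exclusion fires iff strictly more than half fail", {
  mk <- function(n_bad, n_total) {
    r <- do.call(rbind, lapply(seq_len(n_total), function(i)
      compute_qc(qc_profile(300000, 250000, 0,
                            if (i <= n_bad) 10000 else 100000,
                            140000, sample_id = paste0("s", i)))))
    flag_study(r, rep("ST", n_total))
  }
  expect_true(mk(3, 5)$excluded)
  expect_false(mk(2, 4)$excluded)
  expect_true(mk(1, 1)$excluded)
  expect_false(mk(2, 5)$excluded)
})

test_that("study variability uses interpolated quantiles and labels", {
  sv <- study_variability(c(0.92, 0.93, 0.94), rep("A", 3))
  expect_equal(sv$median_smallrna_prop, 0.93)
  expect_equal(sv$iqr_smallrna_prop, 0.01)
  expect_equal(sv$label, "high_quality")

  sv2 <- study_variability(c(0.5, 0.95), rep("B", 2))
  # type-7 linear interpolation oracle for n = 2: quartiles at
  # x1 + p*(x2-x1)
  q1 <- 0.5 + 0.25 * 0.45; q3 <- 0.5 + 0.75 * 0.45
  expect_equal(sv2$iqr_smallrna_prop, q3 - q1)
  expect_equal(sv2$label, "variable")

  expect_warning(sv1 <- study_variability(0.9, "C"), "single-sample")
  expect_equal(sv1$iqr_smallrna_prop, 0)
  sv3 <- study_variability(rep(0.8, 4), rep("D", 4))
  expect_equal(sv3$iqr_smallrna_prop, 0)
})

test_that("group comparisons use Welch t-tests and skip tiny groups", {
  same <- compare_study_groups(c(0.9, 0.91, 0.92, 0.9, 0.91, 0.92),
                               rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  diffg <- compare_study_groups(c(0.9, 0.91, 0.92, 0.5, 0.52, 0.51),
                                rep(c("a", "b"), each = 3))
  expect_lt(diffg$p, 0.01)
  # closed-form Welch oracle
  x <- c(0.9, 0.91, 0.92); y <- c(0.5, 0.52, 0.51)
  tstat <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(abs(diffg$t), abs(tstat), tolerance = 1e-8)

  expect_warning(skip <- compare_study_groups(c(1, 2, 3),
                                              c("a", "a", "b")),
                 "skipped")
  expect_null(skip)
})
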