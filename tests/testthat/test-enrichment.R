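test_that("the compartment ANOVA reports exact nulls and planted shifts", {
  set.seed(101)
  # exact null: identical EV and cell values within each pair
  df <- null_proportions(3L, 6L)
  y <- df$y
  y[df$compartment == "EV"] <- y[df$compartment == "cell"]
  res <- anova_biotype(data.frame(rRNA = y), df[, 1:7])
  expect_equal(res$effect, 0, tolerance = 1e-12)
  expect_gt(res$p_compartment, 0.99)
  expect_equal(res$direction, "none")

  # planted enrichment
  set.seed(102)
  df2 <- null_proportions(3L, 10L, shift = 0.15)
  res2 <- anova_biotype(data.frame(rRNA = df2$y), df2[, 1:7])
  expect_lt(res2$p_compartment, 0.01)
  expect_equal(res2$direction, "enriched_in_EV")
})

test_that("rank-deficient designs drop the confounded term with a note", {
  set.seed(103)
  df <- null_proportions(1L, 8L)
  res <- anova_biotype(data.frame(miRNA = df$y), df[, 1:7])
  expect_true(grepl("study_id", res$dropped_terms))
  expect_true(grepl("isolation_method", res$dropped_terms))
  expect_true(is.finite(res$p_compartment))

  ev_only <- df[df$compartment == "EV", 1:7]
  expect_error(anova_biotype(data.frame(m = seq_len(nrow(ev_only))),
                             ev_only),
               "both EV and cell")
})

test_that("median normalization scales features by their medians", {
  m <- rbind(a = c(2, 4, 8), b = c(3, 3, 3), c = c(0, 0, 0))
  res <- median_normalize(m)
  expect_equal(unname(res$normalized["a", ]), c(0.5, 1, 2))
  expect_equal(unname(res$normalized["b", ]), c(1, 1, 1))
  expect_equal(unname(res$normalized["c", ]), c(0, 0, 0))
  expect_equal(unname(res$zero_median), c(FALSE, FALSE, TRUE))
  expect_error(median_normalize(m[, 1:2]), ">= 3 samples")
})

test_that("differential testing enforces its preconditions", {
  sim <- nb_counts(seed = 1, n_features = 20, n_ev = 3, n_cell = 3)
  frac <- sim$counts; frac[1, 1] <- 0.5
  expect_error(differential_mirnas(frac, sim$manifest), "integers")
  ev_only <- sim$manifest[sim$manifest$compartment == "EV", ]
  expect_error(
    differential_mirnas(sim$counts[, ev_only$sample_id], ev_only),
    ">= 2 EV and >= 2 cell")
})

test_that("significance combines the FDR and fold-change thresholds", {
  sim <- nb_counts(seed = 2, n_features = 150, n_ev = 8, n_cell = 8,
                   planted = 1:15, log2fc = 2)
  res <- differential_mirnas(sim$counts, sim$manifest)
  expect_identical(res$significant,
                   !is.na(res$fdr) & res$fdr < 0.05 &
                     abs(res$log2fc) > log2(1.5))
  # BH monotonicity: adjusted values ordered like the raw p-values
  ok <- !is.na(res$p)
  ord <- order(res$p[ok])
  expect_true(all(diff(res$fdr[ok][ord]) >= -1e-12))
})

test_that("planted fold changes are recovered with calibrated sign and size", {
  # recovery is assessed on moderately-to-well-expressed features
  # (baseline around 100 counts); at very low counts Poisson noise, not
  # the estimator, bounds the attainable accuracy
  sim <- nb_counts(seed = 3, n_features = 120, n_ev = 10, n_cell = 10,
                   planted = 1:30, log2fc = rep(c(2, -2), 15),
                   dispersion = 0.1, meanlog = log(100), sdlog = 1)
  res <- differential_mirnas(sim$counts, sim$manifest)
  planted <- res[1:30, ]
  truth <- rep(c(2, -2), 15)
  expect_lt(mean(abs(planted$log2fc - truth)), 0.3)
  # sign coherence with the CPM means at low dispersion
  cpm <- t(t(sim$counts) / colSums(sim$counts)) * 1e6
  ev <- sim$manifest$compartment == "EV"
  dir_cpm <- sign(rowMeans(cpm[1:30, ev]) - rowMeans(cpm[1:30, !ev]))
  expect_equal(sign(planted$log2fc), unname(dir_cpm))
})

test_that("export classes follow their cross-study definitions", {
  mk <- function(feature, l2fc, sig, p = 1e-4) {
    data.frame(feature_id = feature, base_mean = 100, log2fc = l2fc,
               se = 0.1, p = p, fdr = if (sig) 0.001 else 0.5,
               significant = sig, stringsAsFactors = FALSE)
  }
  per_study <- list(
    A = rbind(mk("m1", 2, TRUE), mk("m2", 2, TRUE), mk("m3", 0.1, FALSE)),
    B = rbind(mk("m1", 1.5, TRUE), mk("m2", -2, TRUE), mk("m3", 2, TRUE)),
    C = rbind(mk("m1", 2.2, TRUE), mk("m3", 0.2, FALSE)))
  cls <- classify_export(per_study, min_testable = 2L)
  got <- stats::setNames(cls$class, cls$feature_id)
  expect_equal(unname(got["m1"]), "context_independent_EV")  # 3/3 EV
  expect_equal(unname(got["m2"]), "study_specific")          # EV + cell mix
  expect_equal(unname(got["m3"]), "study_specific")          # 1 of 3 sig
  calls <- attr(cls, "per_study_calls")
  expect_equal(calls["m3", "A"], "ns")
  expect_equal(calls["m2", "C"], "untestable")

  # all-cell feature and the mostly_EV tolerance
  per_study2 <- list(
    A = rbind(mk("c1", -2, TRUE), mk("e1", 2, TRUE)),
    B = rbind(mk("c1", -1.8, TRUE), mk("e1", 1.7, TRUE)),
    C = rbind(mk("c1", -2.4, TRUE), mk("e1", 0.3, FALSE)))
  cls2 <- classify_export(per_study2)
  got2 <- stats::setNames(cls2$class, cls2$feature_id)
  expect_equal(unname(got2["c1"]), "context_independent_cell")
  expect_equal(unname(got2["e1"]), "mostly_EV")   # 2/3 EV, 1 ns, no cell
  expect_error(classify_export(per_study[1]), ">= 2 studies")
})

test_that("simulated universal exporters are classified context-independent", {
  per_study <- list()
  for (s in 1:4) {
    sim <- nb_counts(seed = 200 + s, n_features = 60, n_ev = 8, n_cell = 8,
                     planted = 1:8, log2fc = 3, dispersion = 0.05)
    per_study[[paste0("S", s)]] <- differential_mirnas(sim$counts,
                                                       sim$manifest)
  }
  cls <- classify_export(per_study)
  universal <- cls$feature_id[cls$class == "context_independent_EV"]
  expect_setequal(universal, sprintf("mir%03d", 1:8))
})
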