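test_that("host matching honours the 1-substitution, best-stratum contract", {
  cat <- test_catalog()
  mir <- cat[cat$biotype == "miRNA", ][1, ]
  hits <- align_host(mir$sequence, cat)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$feature_id, mir$feature_id)
  expect_equal(hits$n_mismatches, 0L)

  trna <- cat[cat$biotype == "tRNA", ][1, ]
  window <- substr(trna$sequence, 11L, 34L)
  set.seed(3)
  mutated <- mutate_seq(window, 1L)
  hits1 <- align_host(mutated, cat)
  expect_equal(hits1$feature_id, trna$feature_id)
  expect_equal(hits1$n_mismatches, 1L)
})

test_that("non-host matching is exact-only and skips short inserts", {
  cat <- test_catalog()
  nh <- cat[cat$origin == "nonhost", ][1, ]
  w19 <- substr(nh$sequence, 1L, 19L)
  expect_equal(nrow(align_nonhost(w19, cat)), 0L)
  w20 <- substr(nh$sequence, 1L, 20L)
  expect_equal(align_nonhost(w20, cat)$feature_id, nh$feature_id)
  set.seed(4)
  expect_equal(nrow(align_nonhost(mutate_seq(w20, 1L), cat)), 0L)
})

test_that("matcher agrees with the exhaustive Hamming-distance oracle", {
  cat <- test_catalog()
  host <- cat[cat$origin == "host", ]
  set.seed(11)
  inserts <- character(200)
  for (i in 1:200) {
    kind <- i %% 4L
    if (kind == 0L) {
      inserts[i] <- paste(sample(c("A", "C", "G", "T"), sample(16:30, 1),
                                 TRUE), collapse = "")
    } else {
      e <- host[sample.int(nrow(host), 1L), ]
      L <- min(nchar(e$sequence), sample(16:30, 1L))
      s <- sample.int(nchar(e$sequence) - L + 1L, 1L)
      w <- substr(e$sequence, s, s + L - 1L)
      inserts[i] <- mutate_seq(w, kind - 1L)   # 0, 1, or 2 substitutions
    }
  }
  for (ins in inserts) {
    got <- align_host(ins, cat)
    exp <- oracle_hits(ins, host, max_mm = 1L)
    expect_setequal(got$feature_id, exp$feature_id)
    if (nrow(got)) expect_equal(unique(got$n_mismatches),
                                unique(exp$n_mismatches))
  }
})

test_that("the batched sample path equals the per-insert path", {
  cat <- test_catalog()
  tr <- simulation_truth(seed = 61, n_reads = 1500L, error_rate = 0.01)
  sim <- simulate_sample(tr, cat)
  pat <- adapter_pattern(tr$adapter3, tr$rand5_len, tr$rand3_len)
  kept <- trim_sample(sim$reads, pat, discard_untrimmed = TRUE)$kept
  prof <- quantify_sample(unname(kept), cat, cat)
  # recompute read fates one insert at a time through the public matchers
  host_n <- 0L; nonhost_n <- 0L; un_n <- 0L
  for (ins in kept) {
    h <- align_host(ins, cat)
    if (nrow(h)) host_n <- host_n + 1L
    else if (nrow(align_nonhost(ins, cat))) nonhost_n <- nonhost_n + 1L
    else un_n <- un_n + 1L
  }
  expect_equal(prof$n_host, host_n)
  expect_equal(prof$n_nonhost, nonhost_n)
  expect_equal(prof$n_unmapped, un_n)
})

test_that("biotype priority and fractional feature splits are stable", {
  hits <- data.frame(feature_id = c("mirA", "rrnB"),
                     biotype = c("miRNA", "rRNA"),
                     origin = "host", n_mismatches = 0L,
                     stringsAsFactors = FALSE)
  expect_equal(assign_biotype(hits)$biotype, "miRNA")

  tie <- data.frame(feature_id = c("mirA", "mirB"),
                    biotype = "miRNA", origin = "host", n_mismatches = 0L,
                    stringsAsFactors = FALSE)
  asg <- assign_biotype(tie)
  expect_equal(asg$biotype, "miRNA")
  expect_setequal(asg$features, c("mirA", "mirB"))
  # permuting hit order changes nothing
  asg_rev <- assign_biotype(tie[2:1, ])
  expect_identical(asg, asg_rev)
})

test_that("quantification reproduces ground truth on error-free samples", {
  cat <- test_catalog()
  tr <- simulation_truth(seed = 71, n_reads = 4000L, error_rate = 0)
  sim <- simulate_sample(tr, cat)
  pat <- adapter_pattern(tr$adapter3, tr$rand5_len, tr$rand3_len)
  res <- trim_sample(sim$reads, pat)
  prof <- quantify_sample(unname(res$kept), cat, cat, sample_id = "gt")
  validate_profile(prof, cat)
  truth_counts <- table(sim$truth_table$biotype)
  for (bt in ev_biotypes()) {
    expected <- if (bt %in% names(truth_counts)) truth_counts[[bt]] else 0L
    expect_equal(unname(prof$biotype_counts[[bt]]), expected,
                 info = bt)
  }
  expect_equal(prof$n_host + prof$n_nonhost + prof$n_unmapped,
               prof$n_trimmed_kept)
  # feature-level recount against the truth table
  ft <- table(sim$truth_table$feature_id[sim$truth_table$biotype == "miRNA"])
  for (f in names(ft))
    expect_equal(unname(prof$feature_counts[[f]]), unname(ft[[f]]), info = f)
})

test_that("CPM arithmetic and degenerate profiles follow the conventions", {
  cat <- test_catalog()
  mirs <- cat[cat$biotype == "miRNA", ]
  inserts <- c(mirs$sequence[1], mirs$sequence[2], mirs$sequence[3],
               mirs$sequence[3])
  prof <- quantify_sample(inserts, cat, cat)
  expect_equal(unname(prof$feature_cpm[mirs$feature_id[1]]), 250000)
  expect_equal(unname(prof$feature_cpm[mirs$feature_id[3]]), 500000)

  set.seed(5)
  junk <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
    character(1))
  pj <- quantify_sample(junk, cat, cat)
  expect_equal(pj$n_host, 0)
  expect_true(all(pj$biotype_counts == 0))

  p0 <- quantify_sample(character(0), cat, cat)
  expect_true(p0$zero_input)
  expect_equal(p0$n_trimmed_kept, 0L)
})
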