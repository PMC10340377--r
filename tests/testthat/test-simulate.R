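test_that("degenerate compositions and offsets match the construction", {
  cat <- test_catalog()
  tr <- simulation_truth(seed = 1, n_reads = 100L,
                         composition = c(miRNA = 1.0), error_rate = 0)
  sim <- simulate_sample(tr, cat)
  expect_equal(nrow(sim$truth_table), 100L)
  expect_true(all(sim$truth_table$biotype == "miRNA"))
  # rand5 = 4: every insert starts at offset 4
  expect_true(all(sim$truth_table$insert_start == 4L))
  # reads carry the insert at the recorded offset
  with(sim$truth_table, expect_identical(
    unname(substr(sim$reads, insert_start + 1L, insert_start + insert_len)),
    unname(insert_seq)))
})

test_that("observed biotype fractions follow the requested composition", {
  cat <- test_catalog()
  tr <- simulation_truth(seed = 5, n_reads = 10000L,
                         composition = c(miRNA = 0.5, rRNA = 0.5),
                         error_rate = 0)
  sim <- simulate_sample(tr, cat)
  n_mirna <- sum(sim$truth_table$biotype == "miRNA")
  sd3 <- 3 * sqrt(10000 * 0.5 * 0.5)
  expect_lt(abs(n_mirna - 5000), sd3)
  expect_equal(sum(sim$truth_table$biotype %in% c("miRNA", "rRNA")), 10000L)
})

test_that("simulation is byte-deterministic and validates composition", {
  cat <- test_catalog()
  tr <- simulation_truth(seed = 9, n_reads = 500L)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_sample(tr, cat, fastq_path = f1)
  simulate_sample(tr, cat, fastq_path = f2)
  expect_identical(readLines(f1), readLines(f2))

  tiny <- cat[cat$biotype == "miRNA", ]
  expect_error(
    simulate_sample(simulation_truth(seed = 1, composition = c(rRNA = 1)),
                    tiny),
    "absent")
})

test_that("fragment biotypes yield 18-35 nt windows of their source", {
  cat <- test_catalog()
  tr <- simulation_truth(seed = 4, n_reads = 300L,
                         composition = c(rRNA = 1.0), error_rate = 0)
  sim <- simulate_sample(tr, cat)
  lens <- sim$truth_table$insert_len
  expect_true(all(lens >= 18L & lens <= 35L))
  # each insert is a substring of its source entry
  src <- cat$sequence[match(sim$truth_table$feature_id, cat$feature_id)]
  found <- mapply(grepl, sim$truth_table$insert_seq, src, fixed = TRUE)
  expect_true(all(found))
})

test_that("planted fold changes shift simulated counts as specified", {
  cat <- test_catalog()
  mirX <- cat$feature_id[cat$biotype == "miRNA"][1]
  ev_counts <- numeric(20)
  cell_counts <- numeric(20)
  for (r in seq_len(20)) {
    base_w <- local({set.seed(1000 + r); stats::setNames(
      rep(1, sum(cat$origin == "host")),
      cat$feature_id[cat$origin == "host"])})
    tr_ev <- simulation_truth(seed = 2000 + r, n_reads = 2000L,
                              composition = c(miRNA = 1.0), error_rate = 0,
                              per_feature_abundance = base_w,
                              planted_log2fc = stats::setNames(2, mirX))
    tr_cell <- simulation_truth(seed = 3000 + r, n_reads = 2000L,
                                composition = c(miRNA = 1.0), error_rate = 0,
                                per_feature_abundance = base_w)
    ev_counts[r] <- sum(simulate_sample(tr_ev, cat)$truth_table$feature_id ==
                          mirX)
    cell_counts[r] <- sum(
      simulate_sample(tr_cell, cat)$truth_table$feature_id == mirX)
  }
  # with 20 equal-weight miRNAs, planting +2 log2fc makes mirX's draw
  # probability 4/23 vs 1/20; the EV/cell count ratio should be ~3.48
  ratio <- mean(ev_counts) / mean(cell_counts)
  expected <- (4 / 23) / (1 / 20)
  se <- expected * sqrt(1 / sum(ev_counts) + 1 / sum(cell_counts))
  expect_lt(abs(ratio - expected), 3 * se + 0.3)
})

test_that("study sets write one FASTQ per sample plus manifest and truth", {
  cat <- test_catalog()
  design <- build_paired_design(seed = 11, n_studies = 2L,
                                pairs_per_study = 1L, n_reads = 50L,
                                catalog = cat)
  out <- withr::local_tempdir()
  ss <- simulate_study_set(design, cat, out)
  expect_equal(nrow(ss$manifest), 4L)
  expect_true(all(file.exists(ss$fastq_paths)))
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  expect_equal(length(list.files(file.path(out, "truth"))), 4L)
  # paired design: equal EV and cell rows
  expect_equal(sum(ss$manifest$compartment == "EV"),
               sum(ss$manifest$compartment == "cell"))

  dup <- design
  dup$manifest$sample_id <- rep(dup$manifest$sample_id[1], 4L)
  expect_error(simulate_study_set(dup, cat, withr::local_tempdir()))
})
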