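# Shared fixtures and independent oracles, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# A modest catalog shared across tests (built once per run).
test_catalog <- function() {
  if (is.null(.fixture_env$catalog)) {
    .fixture_env$catalog <- generate_catalog(
      seed = 42,
      n_per_biotype = c(miRNA = 20L, tRNA = 4L, rRNA = 4L, snRNA = 2L,
                        snoRNA = 2L, YRNA = 3L, mt_tRNA = 1L, lincRNA = 1L,
                        misc = 2L, host_other = 2L),
      n_nonhost = 3L)
  }
  .fixture_env$catalog
}

# Independent brute-force oracle: all catalog entries containing `insert`
# as a substring with <= max_mm substitutions, best stratum only.
# Character-level loops; shares no code with the implementation.
oracle_hits <- function(insert, entries, max_mm) {
  ichars <- strsplit(insert, "")[[1]]
  L <- length(ichars)
  best <- vector("list", 0L)
  best_mm <- Inf
  for (e in seq_len(nrow(entries))) {
    schars <- strsplit(entries$sequence[e], "")[[1]]
    S <- length(schars)
    if (S < L) next
    emm <- Inf
    for (p in seq_len(S - L + 1L)) {
      mm <- sum(schars[p:(p + L - 1L)] != ichars)
      emm <- min(emm, mm)
    }
    if (emm <= max_mm) {
      if (emm < best_mm) {
        best <- list()
        best_mm <- emm
      }
      if (emm == best_mm)
        best[[length(best) + 1L]] <- data.frame(
          feature_id = entries$feature_id[e], biotype = entries$biotype[e],
          origin = entries$origin[e], n_mismatches = emm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(best))
    return(data.frame(feature_id = character(0), biotype = character(0),
                      origin = character(0), n_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, best)
}

# Substitute `k` positions of a sequence (deterministic under the caller's
# RNG state).
mutate_seq <- function(seq, k) {
  pos <- sample.int(nchar(seq), k)
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  seq
}

# Minimal single-study manifest for the differential tests.
de_manifest <- function(n_ev, n_cell, study = "S1",
                        method = "ExoQuick") {
  data.frame(
    sample_id = c(sprintf("ev%02d", seq_len(n_ev)),
                  sprintf("cell%02d", seq_len(n_cell))),
    study_id = study,
    compartment = rep(c("EV", "cell"), c(n_ev, n_cell)),
    source = "cell_line",
    isolation_method = method,
    rna_kit = "kit",
    stringsAsFactors = FALSE)
}

# Negative binomial count matrix with planted EV-vs-cell fold changes.
nb_counts <- function(seed, n_features, n_ev, n_cell, planted = integer(0),
                      log2fc = 2, dispersion = 0.1,
                      meanlog = log(50), sdlog = 1.2) {
  set.seed(seed)
  mu0 <- rlnorm(n_features, meanlog, sdlog)
  comp <- rep(c("cell", "EV"), c(n_cell, n_ev))
  fc <- matrix(1, n_features, n_ev + n_cell)
  fc[planted, comp == "EV"] <- 2^log2fc
  counts <- matrix(
    rnbinom(n_features * (n_ev + n_cell),
            mu = mu0 * fc, size = 1 / dispersion),
    nrow = n_features)
  rownames(counts) <- sprintf("mir%03d", seq_len(n_features))
  colnames(counts) <- c(sprintf("cell%02d", seq_len(n_cell)),
                        sprintf("ev%02d", seq_len(n_ev)))
  list(counts = counts,
       manifest = data.frame(
         sample_id = colnames(counts), study_id = "S1",
         compartment = comp, source = "cell_line",
         isolation_method = "ExoQuick", rna_kit = "kit",
         stringsAsFactors = FALSE))
}

# Null per-sample biotype proportions for the ANOVA calibration checks:
# a study-level random effect plus sample noise, no compartment effect
# unless `shift` is given (added to EV samples).
null_proportions <- function(n_studies, pairs_per_study, shift = 0,
                             base = 0.4, study_sd = 0.05, noise_sd = 0.08) {
  rows <- list()
  for (s in seq_len(n_studies)) {
    se <- rnorm(1, 0, study_sd)
    method <- isolation_methods()[(s - 1L) %% 6L + 1L]
    for (p in seq_len(pairs_per_study)) {
      for (comp in c("EV", "cell")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("s%d_p%d_%s", s, p, comp),
          study_id = sprintf("S%d", s), compartment = comp,
          source = "cell_line", isolation_method = method, rna_kit = "kit",
          y = min(max(base + se + rnorm(1, 0, noise_sd) +
                        if (comp == "EV") shift else 0, 0), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
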