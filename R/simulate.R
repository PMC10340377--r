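# Seeded small RNA-seq read simulator.
#
# Each simulated read is
#   [rand5 bases] + insert + [rand3 bases] + 3' adapter ...
# truncated at the read length.  Inserts are drawn from a reference catalog
# according to a per-sample biotype composition; entries stored full-length
# (rRNA, tRNA, Y RNA, ...) contribute random 18-35 nt windows, emulating the
# fragment nature of those biotypes.  The remainder of the composition mass
# (1 - sum) becomes uniform random "junk" reads expected to stay unmapped.
# Base qualities are constant Phred 40: the assessment pipeline inspects but
# never filters on qualities.

#' Construct simulation ground truth for one sample
#'
#' Bundles every parameter that determines a simulated library, so the same
#' truth object always regenerates a byte-identical FASTQ.
#'
#' @param seed Integer seed for this sample.
#' @param n_reads Number of reads (>= 1).
#' @param composition Named vector of expected biotype proportions summing
#'   to at most 1; the remainder becomes random unmappable reads.
#' @param adapter3 3' adapter sequence, length >= 8.
#' @param rand5_len,rand3_len Number of degenerate bases flanking the insert
#'   (0-8 each), as placed by some library kits.
#' @param error_rate Per-base substitution probability in [0, 0.05].
#' @param read_length Instrument read length (default 51 nt).
#' @param abundance_sigma Log-normal sigma for per-feature abundance skew
#'   within a biotype.
#' @param per_feature_abundance Optional named vector of relative feature
#'   weights; if NULL, drawn log-normally from the sample seed.
#' @param planted_log2fc Named vector of per-feature log2 fold changes
#'   applied to the abundance weights (used by [simulate_study_set()] to
#'   plant EV-vs-cell effects).
#' @return An object of class \code{simulation_truth}.
#' @export
simulation_truth <- function(seed,
                             n_reads = 20000L,
                             composition = default_composition(),
                             adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             rand5_len = 4L,
                             rand3_len = 4L,
                             error_rate = 0.001,
                             read_length = 51L,
                             abundance_sigma = 1,
                             per_feature_abundance = NULL,
                             planted_log2fc = numeric(0)) {
  if (nchar(adapter3) < 8L) stop("adapter3 must be >= 8 nt")
  if (n_reads < 1L) stop("n_reads must be >= 1")
  if (rand5_len > 8L || rand3_len > 8L || rand5_len < 0L || rand3_len < 0L)
    stop("random-base lengths must be in 0..8")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (any(composition < 0) || sum(composition) > 1 + 1e-12)
    stop("composition must be nonnegative and sum to <= 1")
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 composition = composition, adapter3 = adapter3,
                 rand5_len = as.integer(rand5_len),
                 rand3_len = as.integer(rand3_len),
                 error_rate = error_rate,
                 read_length = as.integer(read_length),
                 abundance_sigma = abundance_sigma,
                 per_feature_abundance = per_feature_abundance,
                 planted_log2fc = planted_log2fc),
            class = "simulation_truth")
}

#' Default biotype composition for simulated EV libraries
#'
#' A miRNA-dominated mixture with substantial Y RNA, rRNA, and tRNA fragment
#' mass, small minor classes, some host_other (genomic) signal, and 4
#' percent unmappable mass.
#'
#' @return Named numeric vector summing to 0.96.
#' @export
default_composition <- function() {
  c(miRNA = 0.50, YRNA = 0.15, rRNA = 0.12, tRNA = 0.06,
    snRNA = 0.015, snoRNA = 0.015, mt_tRNA = 0.005, lincRNA = 0.005,
    misc = 0.01, host_other = 0.05)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", x$n_reads, "reads, adapter",
      substr(x$adapter3, 1, 12), "..., rand5/rand3 =",
      x$rand5_len, "/", x$rand3_len, ", error_rate =", x$error_rate, "\n")
  invisible(x)
}

# Draw log-normal per-feature weights for the host features of a catalog.
feature_abundances <- function(catalog, sigma) {
  host <- catalog[catalog$origin == "host", ]
  w <- stats::rlnorm(nrow(host), meanlog = 0, sdlog = sigma)
  names(w) <- host$feature_id
  w
}

#' Simulate one small RNA-seq sample
#'
#' Generates reads per the truth object and returns them together with a
#' per-read ground-truth table (source feature, biotype, insert boundaries,
#' and the sequenced insert after substitution errors).  Identical truth
#' objects always produce byte-identical output.
#'
#' @param truth A [simulation_truth()] object.
#' @param catalog Reference catalog containing at least one host entry for
#'   every biotype named in the composition.
#' @param fastq_path Optional path; when given, reads are written as FASTQ
#'   (gzip if the path ends in .gz) with constant 'I' qualities.
#' @param read_prefix Prefix for read ids.
#' @return List with elements \code{reads} (named character vector of read
#'   sequences) and \code{truth_table} (data.frame: read_id, feature_id,
#'   biotype, insert_start 0-based offset, insert_len, insert_seq).
#' @export
simulate_sample <- function(truth, catalog, fastq_path = NULL,
                            read_prefix = "read") {
  stopifnot(inherits(truth, "simulation_truth"))
  validate_catalog(catalog)
  comp <- truth$composition
  host <- catalog[catalog$origin == "host", ]
  missing_bt <- setdiff(names(comp)[comp > 0], unique(host$biotype))
  if (length(missing_bt))
    stop("composition references biotype(s) absent from catalog: ",
         paste(missing_bt, collapse = ", "))

  with_seed(truth$seed, {
    n <- truth$n_reads
    weights <- truth$per_feature_abundance %||%
      feature_abundances(catalog, truth$abundance_sigma)
    if (length(truth$planted_log2fc)) {
      idx <- intersect(names(truth$planted_log2fc), names(weights))
      weights[idx] <- weights[idx] * 2^truth$planted_log2fc[idx]
    }

    junk_p <- max(0, 1 - sum(comp))
    classes <- sample(c(names(comp), "junk"), n, replace = TRUE,
                      prob = c(comp, junk_p))

    feature_id <- rep(NA_character_, n)
    insert <- character(n)
    for (bt in unique(classes)) {
      sel <- which(classes == bt)
      if (bt == "junk") {
        insert[sel] <- random_dna(length(sel), truth$read_length)
        next
      }
      feats <- host[host$biotype == bt, ]
      w <- weights[feats$feature_id]
      w[is.na(w)] <- 1
      pick <- sample.int(nrow(feats), length(sel), replace = TRUE,
                         prob = w / sum(w))
      feature_id[sel] <- feats$feature_id[pick]
      seqs <- feats$sequence[pick]
      lens <- nchar(seqs)
      frag <- lens > 35L
      ins <- seqs
      if (any(frag)) {
        fl <- pmin(sample(18:35, sum(frag), replace = TRUE), lens[frag])
        fs <- vapply(lens[frag] - fl + 1L, function(m) sample.int(m, 1L),
                     integer(1))
        ins[frag] <- substr(seqs[frag], fs, fs + fl - 1L)
      }
      insert[sel] <- ins
    }

    r5 <- random_dna(n, truth$rand5_len)
    r3 <- random_dna(n, truth$rand3_len)
    reads <- substr(paste0(r5, insert, r3, truth$adapter3),
                    1L, truth$read_length)
    reads[classes == "junk"] <- insert[classes == "junk"]

    reads <- apply_substitutions(reads, truth$error_rate)
    read_id <- sprintf("%s%06d", read_prefix, seq_len(n))
    names(reads) <- read_id

    ins_start <- ifelse(classes == "junk", 0L, truth$rand5_len)
    ins_len <- pmin(nchar(insert), pmax(nchar(reads) - ins_start, 0L))
    truth_table <- data.frame(
      read_id = read_id,
      feature_id = feature_id,
      biotype = classes,
      insert_start = ins_start,
      insert_len = ins_len,
      insert_seq = substr(reads, ins_start + 1L, ins_start + ins_len),
      stringsAsFactors = FALSE)
    truth_table$insert_seq[classes == "junk"] <- reads[classes == "junk"]

    if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
    list(reads = reads, truth_table = truth_table)
  })
}

# Apply iid per-base substitutions: the number of substituted positions is
# Binomial(total bases, rate) and positions are uniform without replacement,
# equivalent to per-base Bernoulli noise.
apply_substitutions <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  k <- stats::rbinom(1L, total, rate)
  if (k == 0L) return(reads)
  pos <- sort(sample.int(total, k))
  ends <- cumsum(lens)
  ridx <- findInterval(pos - 1L, ends) + 1L
  within <- pos - c(0L, ends)[ridx]
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    i <- ridx[j]; p <- within[j]
    old <- substr(reads[i], p, p)
    new <- sample(setdiff(bases, old), 1L)
    substr(reads[i], p, p) <- new
  }
  reads
}

#' Write reads as FASTQ
#'
#' Four-line records with constant 'I' (Phred 40) quality strings; gzip
#' compression when the path ends in .gz.
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(reads)) {
    rec <- paste0("@", names(reads), "\n", reads, "\n+\n",
                  strrep("I", nchar(reads)))
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (gzip allowed).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in ", path)
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  names(seqs) <- sub("\\s.*$", "", sub("^@", "", ids))
  seqs
}

#' Simulate a full multi-study data set
#'
#' Writes one FASTQ per manifest row plus the manifest and a per-sample
#' ground-truth bundle, sufficient to score every downstream stage.
#'
#' @param design List with elements \code{manifest} (see
#'   [validate_manifest()]) and \code{truths}, a list of
#'   [simulation_truth()] objects named by sample_id (one per manifest row).
#' @param catalog Reference catalog.
#' @param out_dir Output directory (created if needed).
#' @return List with \code{manifest}, \code{fastq_paths} (named by sample),
#'   and \code{truths}; truth tables are written under
#'   \code{out_dir/truth/}.
#' @export
simulate_study_set <- function(design, catalog, out_dir) {
  manifest <- validate_manifest(design$manifest)
  truths <- design$truths
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in design")
  if (!all(manifest$sample_id %in% names(truths)))
    stop("every manifest sample needs a simulation_truth")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  fastq_paths <- character(0)
  for (sid in manifest$sample_id) {
    fq <- file.path(out_dir, paste0(sid, ".fastq"))
    sim <- simulate_sample(truths[[sid]], catalog, fastq_path = fq,
                           read_prefix = paste0(sid, "_r"))
    write_tsv(sim$truth_table, file.path(out_dir, "truth",
                                         paste0(sid, "_truth.tsv")))
    fastq_paths[sid] <- fq
  }
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  write_catalog_fasta(catalog, file.path(out_dir, "catalog.fa"))
  list(manifest = manifest, fastq_paths = fastq_paths, truths = truths)
}

#' Build a paired EV/cell study design with planted effects
#'
#' Convenience constructor for [simulate_study_set()]: a number of studies,
#' each with matched EV/cell pairs sharing a per-study feature abundance
#' baseline; EV samples receive planted per-feature log2 fold changes and an
#' optional biotype composition shift.
#'
#' @param seed Integer seed.
#' @param n_studies Number of paired studies.
#' @param pairs_per_study EV/cell pairs per study.
#' @param n_reads Reads per sample.
#' @param catalog Reference catalog (drives the abundance baselines).
#' @param planted_log2fc Named per-feature log2 fold changes (EV vs cell).
#' @param ev_composition,cell_composition Biotype compositions for the two
#'   compartments (defaults: both [default_composition()]).
#' @param error_rate Per-base substitution rate.
#' @return A design list usable as input to [simulate_study_set()].
#' @export
build_paired_design <- function(seed, n_studies = 2L, pairs_per_study = 3L,
                                n_reads = 20000L, catalog,
                                planted_log2fc = numeric(0),
                                ev_composition = default_composition(),
                                cell_composition = default_composition(),
                                error_rate = 0.001) {
  rows <- list(); truths <- list()
  for (s in seq_len(n_studies)) {
    study <- sprintf("SIM%03d", s)
    method <- isolation_methods()[(s - 1L) %% 6L + 1L]
    base_w <- with_seed(derive_seed(seed, paste0("abund", s)),
                        feature_abundances(catalog, 1))
    for (p in seq_len(pairs_per_study)) {
      for (comp in c("EV", "cell")) {
        sid <- sprintf("%s_%s%02d", study, comp, p)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, study_id = study, compartment = comp,
          source = "cell_line", biofluid_name = NA_character_,
          isolation_method = method, rna_kit = "TruSeq_smallRNA",
          pair_id = sprintf("%s_P%02d", study, p),
          stringsAsFactors = FALSE)
        truths[[sid]] <- simulation_truth(
          seed = derive_seed(seed, sid), n_reads = n_reads,
          composition = if (comp == "EV") ev_composition else cell_composition,
          error_rate = error_rate,
          per_feature_abundance = base_w,
          planted_log2fc = if (comp == "EV") planted_log2fc else numeric(0))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(manifest = manifest, truths = truths)
}
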