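# Reference catalogs of small RNA sequences labeled by biotype and origin.
#
# Catalogs are plain data frames with columns feature_id, sequence, biotype,
# origin.  Host entries carry one of the small RNA biotypes plus host_other
# (genome-mapped sequence outside small RNA annotation); non-host entries
# model exogenous sequence and are always matched exactly.

#' Small RNA biotype labels
#'
#' The host biotype vocabulary used throughout the package, in assignment
#' priority order: when an insert matches references of several biotypes
#' equally well, the earliest label in this vector wins.
#'
#' @return Character vector of biotype labels.
#' @export
ev_biotypes <- function() {
  c("miRNA", "tRNA", "rRNA", "snRNA", "snoRNA", "YRNA",
    "mt_tRNA", "lincRNA", "misc", "host_other")
}

#' Eight-class composition biotypes
#'
#' The biotype classes over which small RNA composition is reported.
#' lincRNA (and any other small RNA label outside the eight) is folded into
#' misc so that composition is a true partition of small RNA reads.
#'
#' @return Character vector of eight biotype labels.
#' @export
composition_biotypes <- function() {
  c("miRNA", "tRNA", "rRNA", "YRNA", "snRNA", "snoRNA", "mt_tRNA", "misc")
}

# Biotypes stored full-length whose reads are sampled as short fragments.
long_biotypes <- function() {
  c("tRNA", "rRNA", "snRNA", "snoRNA", "YRNA", "mt_tRNA", "lincRNA",
    "host_other")
}

default_catalog_sizes <- function() {
  c(miRNA = 30L, tRNA = 6L, rRNA = 6L, snRNA = 3L, snoRNA = 3L, YRNA = 4L,
    mt_tRNA = 2L, lincRNA = 2L, misc = 3L, host_other = 4L)
}

#' Generate a synthetic reference catalog
#'
#' Draws random sequences for each requested biotype.  Sequences are mutually
#' separated so that every 16-nt window of one entry differs from every
#' 16-nt window of every other entry by at least 3 substitutions; this makes
#' 1-mismatch assignment of inserts (length >= 16) unambiguous by
#' construction.  Fragment-source biotypes (tRNA, rRNA, Y RNA, snRNA,
#' snoRNA, mt-tRNA, lincRNA, host_other) are stored full-length and later
#' sampled as short windows; miRNA and misc entries are stored at insert
#' length.
#'
#' @param seed Integer seed; the same seed yields an identical catalog.
#' @param n_per_biotype Named integer vector, entries per biotype.  Defaults
#'   cover every biotype the composition analysis reports.
#' @param length_range Length range (min, max) for insert-length biotypes;
#'   the minimum must be at least 16 nt, the downstream keep-length.
#' @param long_length_range Length range for full-length fragment-source
#'   entries.
#' @param n_nonhost Number of non-host decoy entries (exogenous sequence,
#'   matched exactly and never counted toward host biotypes).
#' @return A data.frame with columns feature_id, sequence, biotype, origin.
#' @export
generate_catalog <- function(seed,
                             n_per_biotype = default_catalog_sizes(),
                             length_range = c(20L, 24L),
                             long_length_range = c(80L, 150L),
                             n_nonhost = 0L) {
  if (length_range[1] < 16L)
    stop("length_range minimum must be >= 16 nt (the keep-length floor)")
  bad <- setdiff(names(n_per_biotype), ev_biotypes())
  if (length(bad))
    stop("unknown biotype(s): ", paste(bad, collapse = ", "))
  if (any(n_per_biotype < 0L)) stop("n_per_biotype counts must be >= 0")

  with_seed(seed, {
    accepted <- character(0)
    rows <- vector("list", 0L)
    add_entries <- function(n, biotype, origin, lo, hi) {
      for (i in seq_len(n)) {
        seq <- propose_separated_sequence(accepted, lo, hi)
        accepted[[length(accepted) + 1L]] <<- seq
        rows[[length(rows) + 1L]] <<- data.frame(
          feature_id = sprintf("%s_%03d", sub("_", "", biotype), i),
          sequence = seq, biotype = biotype, origin = origin,
          stringsAsFactors = FALSE)
      }
    }
    for (bt in intersect(ev_biotypes(), names(n_per_biotype))) {
      n <- n_per_biotype[[bt]]
      if (n == 0L) next
      if (bt %in% long_biotypes()) {
        add_entries(n, bt, "host", long_length_range[1], long_length_range[2])
      } else {
        add_entries(n, bt, "host", length_range[1], length_range[2])
      }
    }
    if (n_nonhost > 0L) {
      for (i in seq_len(n_nonhost)) {
        seq <- propose_separated_sequence(accepted, long_length_range[1],
                                          long_length_range[2])
        accepted[[length(accepted) + 1L]] <- seq
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = sprintf("nonhost_%03d", i),
          sequence = seq, biotype = "misc", origin = "nonhost",
          stringsAsFactors = FALSE)
      }
    }
    cat <- if (length(rows)) do.call(rbind, rows) else
      data.frame(feature_id = character(0), sequence = character(0),
                 biotype = character(0), origin = character(0),
                 stringsAsFactors = FALSE)
    rownames(cat) <- NULL
    validate_catalog(cat)
    cat
  })
}

# Rejection-sample a random sequence whose every 16-nt window is Hamming
# >= 3 from every 16-nt window of the already accepted sequences.  Any two
# longer windows then also differ by >= 3 (each aligned pair contains an
# aligned 16-mer pair), so 1-substitution matching cannot cross features.
propose_separated_sequence <- function(accepted, lo, hi, max_tries = 100L) {
  ref <- if (length(accepted))
    Biostrings::DNAStringSet(accepted) else NULL
  for (try in seq_len(max_tries)) {
    len <- if (lo == hi) lo else sample(lo:hi, 1L)
    cand <- random_dna(1L, len)
    if (is.null(ref) || sequence_is_separated(cand, ref)) return(cand)
  }
  stop("could not generate a sufficiently separated sequence; ",
       "reduce catalog size or increase sequence length")
}

sequence_is_separated <- function(cand, ref) {
  n_win <- nchar(cand) - 15L
  for (p in seq_len(n_win)) {
    w <- substr(cand, p, p + 15L)
    hits <- Biostrings::vcountPattern(w, ref, max.mismatch = 2)
    if (any(hits > 0L)) return(FALSE)
  }
  TRUE
}

#' Validate a reference catalog
#'
#' Checks feature id uniqueness, the strict ACGT alphabet, the 16-nt minimum
#' length, and the biotype/origin vocabularies.  Called by every function
#' that consumes a catalog.
#'
#' @param catalog Catalog data.frame.
#' @return The catalog, invisibly, if valid; otherwise an error.
#' @export
validate_catalog <- function(catalog) {
  need <- c("feature_id", "sequence", "biotype", "origin")
  if (!all(need %in% names(catalog)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(catalog$feature_id))
    stop("duplicate feature_id in catalog")
  if (nrow(catalog)) {
    if (any(nchar(catalog$sequence) < 16L))
      stop("catalog sequences must be >= 16 nt")
    if (any(grepl("[^ACGT]", catalog$sequence)))
      stop("catalog sequences must be over {A,C,G,T}")
    if (!all(catalog$biotype %in% ev_biotypes()))
      stop("unknown biotype in catalog")
    if (!all(catalog$origin %in% c("host", "nonhost")))
      stop("catalog origin must be host or nonhost")
  }
  invisible(catalog)
}

#' Write a catalog to FASTA
#'
#' Biotype and origin are encoded on the description line as
#' \code{biotype=... origin=...}.
#'
#' @param catalog Catalog data.frame.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  validate_catalog(catalog)
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- sprintf("%s biotype=%s origin=%s", catalog$feature_id,
                         catalog$biotype, catalog$origin)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a catalog from FASTA
#'
#' @param path FASTA path with \code{biotype=}/\code{origin=} tags on the
#'   description lines (as written by [write_catalog_fasta()]); entries
#'   without tags default to biotype misc, origin host.
#' @return Catalog data.frame.
#' @export
read_catalog_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  grab <- function(key, default) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    out <- rep(default, length(hdr))
    hit <- grepl(paste0(key, "="), hdr)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  cat <- data.frame(
    feature_id = sub("\\s.*$", "", hdr),
    sequence = as.character(seqs),
    biotype = grab("biotype", "misc"),
    origin = grab("origin", "host"),
    stringsAsFactors = FALSE)
  rownames(cat) <- NULL
  validate_catalog(cat)
  cat
}
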