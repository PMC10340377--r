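# Reference-free 3' adapter pattern inference.
#
# Small RNA library kits differ in their 3' adapter and some place 0-8
# degenerate ("random") bases between insert and adapter at either end.
# Neither is always recorded in public metadata, so the pattern is inferred
# from the reads themselves: abundant miRNA sequences act as anchors that
# locate inserts inside raw reads; the offset of the anchor calls the number
# of 5' random bases, and a positional consensus over the sequence that
# follows the anchors calls the 3' random-base length and the adapter
# itself.  No kit metadata is ever consulted.

#' Construct an adapter pattern
#'
#' @param adapter3 3' adapter sequence (length >= 8).
#' @param rand5_len,rand3_len Random-base lengths at the 5' and 3' ends of
#'   the insert (0-8).
#' @param support_fraction Fraction of anchored reads consistent with the
#'   called pattern.
#' @param n_anchored Number of reads in which an anchor was located.
#' @return Object of class \code{adapter_pattern}.
#' @export
adapter_pattern <- function(adapter3, rand5_len = 0L, rand3_len = 0L,
                            support_fraction = NA_real_,
                            n_anchored = NA_integer_) {
  if (nchar(adapter3) < 8L) stop("adapter3 must be >= 8 nt")
  if (rand5_len < 0L || rand5_len > 8L || rand3_len < 0L || rand3_len > 8L)
    stop("random-base lengths must be in 0..8")
  structure(list(adapter3 = adapter3, rand5_len = as.integer(rand5_len),
                 rand3_len = as.integer(rand3_len),
                 support_fraction = support_fraction,
                 n_anchored = as.integer(n_anchored)),
            class = "adapter_pattern")
}

#' @export
print.adapter_pattern <- function(x, ...) {
  cat("adapter_pattern: 3' adapter", x$adapter3,
      sprintf("(rand5 %d, rand3 %d)", x$rand5_len, x$rand3_len), "\n")
  if (!is.na(x$support_fraction))
    cat(sprintf("  support %.3f over %d anchored reads\n",
                x$support_fraction, x$n_anchored))
  invisible(x)
}

#' Locate miRNA anchors in raw reads
#'
#' Scans up to \code{max_reads} reads for an exact occurrence of the first
#' 16 nt of any miRNA anchor sequence.  For each anchored read it records
#' the 0-based offset of the anchor (the candidate 5' random-base length)
#' and the read suffix following the full matched anchor extent (candidate
#' 3' random bases plus adapter).  The anchor is extended past its 16-nt
#' seed base by base while the read agrees exactly, so a sequencing error in
#' the anchor tail merely shortens the extension and contributes consensus
#' noise rather than bias.
#'
#' @param reads Character vector of read sequences.
#' @param anchors Reference catalog; only miRNA entries are used.
#' @param max_reads Scan at most this many reads from the start of the
#'   stream.
#' @return data.frame with columns prefix_offset (0-based) and suffix;
#'   empty when no anchor occurs.
#' @export
collect_anchor_hits <- function(reads, anchors, max_reads = 50000L) {
  if (max_reads < 1L) stop("max_reads must be >= 1")
  anchors <- anchors[anchors$biotype == "miRNA", , drop = FALSE]
  if (!nrow(anchors)) stop("anchor catalog contains no miRNA entries")
  reads <- utils::head(reads, max_reads)
  empty <- data.frame(prefix_offset = integer(0), suffix = character(0),
                      stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)

  offset <- rep(NA_integer_, length(reads))
  anchor_idx <- rep(NA_integer_, length(reads))
  for (a in seq_len(nrow(anchors))) {
    seed16 <- substr(anchors$sequence[a], 1L, 16L)
    todo <- is.na(offset)
    if (!any(todo)) break
    m <- regexpr(seed16, reads[todo], fixed = TRUE)
    hit <- m > 0L
    if (any(hit)) {
      idx <- which(todo)[hit]
      offset[idx] <- as.integer(m[hit]) - 1L
      anchor_idx[idx] <- a
    }
  }
  got <- which(!is.na(offset))
  if (!length(got)) return(empty)

  # extend each seed match along its full anchor while bases agree exactly
  ext <- rep(16L, length(got))
  alen <- nchar(anchors$sequence[anchor_idx[got]])
  active <- rep(TRUE, length(got))
  repeat {
    pos <- offset[got] + ext + 1L            # next 1-based read position
    live <- active & ext < alen & pos <= nchar(reads[got])
    if (!any(live)) break
    rb <- substr(reads[got][live], pos[live], pos[live])
    ab <- substr(anchors$sequence[anchor_idx[got]][live],
                 ext[live] + 1L, ext[live] + 1L)
    ok <- rb == ab
    grow <- which(live)[ok]
    ext[grow] <- ext[grow] + 1L
    active[which(live)[!ok]] <- FALSE
    if (!length(grow)) break
  }
  suffix <- substr(reads[got], offset[got] + ext + 1L, nchar(reads[got]))
  data.frame(prefix_offset = offset[got], suffix = suffix,
             stringsAsFactors = FALSE)
}

#' Infer the adapter pattern from anchor hits
#'
#' The 5' random-base length is the modal anchor offset (ties broken toward
#' the smaller offset).  The 3' random-base length is the smallest shift s
#' in 0..8 at which every one of the first 8 positions of the
#' shift-trimmed suffixes reaches a majority-base fraction of at least
#' \code{consensus_threshold}: random bases destroy the consensus until
#' the shift skips past them.  The adapter is
#' the per-position majority base of the shifted suffixes, truncated at the
#' first position covered by fewer than \code{min_anchored / 2} reads or at
#' 30 nt.  Base ties break toward the alphabetically smallest base.
#'
#' @param hits data.frame from [collect_anchor_hits()].
#' @param min_anchored Minimum anchored reads required to call a pattern.
#' @param consensus_threshold Required average majority fraction, in
#'   (0.5, 1].
#' @return An \code{adapter_pattern}, or NULL when too few reads anchor or
#'   no shift reaches the consensus threshold (no detectable adapter).
#' @export
infer_adapter_pattern <- function(hits, min_anchored = 100L,
                                  consensus_threshold = 0.8) {
  if (consensus_threshold <= 0.5 || consensus_threshold > 1)
    stop("consensus_threshold must be in (0.5, 1]")
  n_anchored <- nrow(hits)
  if (n_anchored < min_anchored) return(NULL)

  tab <- table(hits$prefix_offset)
  best <- max(tab)
  rand5 <- min(as.integer(names(tab)[tab == best]))

  cons <- suffix_consensus(hits$suffix)
  rand3 <- NA_integer_
  for (s in 0:8) {
    sc <- shifted_consensus_score(cons, s)
    if (!is.na(sc) && sc >= consensus_threshold) { rand3 <- s; break }
  }
  if (is.na(rand3)) return(NULL)

  prof <- position_profile(hits$suffix, rand3)
  keep <- prof$coverage >= max(1, min_anchored / 2)
  if (any(!keep)) {
    cut <- which(!keep)[1] - 1L
  } else cut <- length(prof$base)
  cut <- min(cut, 30L)
  if (cut < 8L) return(NULL)
  adapter3 <- paste(prof$base[seq_len(cut)], collapse = "")

  # support: suffixes whose first 10 adapter bases (after the called shift)
  # match the call within 1 mismatch
  L <- min(10L, cut)
  obs <- substr(hits$suffix, rand3 + 1L, rand3 + L)
  full <- nchar(obs) == L
  mm <- adapter_mismatches(obs[full], substr(adapter3, 1L, L))
  support <- if (any(full)) sum(mm <= 1L) / n_anchored else 0

  adapter_pattern(adapter3, rand5_len = rand5, rand3_len = rand3,
                  support_fraction = support, n_anchored = n_anchored)
}

# Per-position base counts over the first 40 positions of the suffixes.
suffix_consensus <- function(suffixes) {
  maxp <- min(40L, max(nchar(suffixes), 0L))
  counts <- matrix(0L, nrow = 4L, ncol = maxp,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (p in seq_len(maxp)) {
    b <- substr(suffixes, p, p)
    t <- table(factor(b[b != ""], levels = c("A", "C", "G", "T")))
    counts[, p] <- as.integer(t)
  }
  counts
}

# Minimum majority-base fraction over 8 positions starting at shift s.
# The minimum (not the mean) is the score: a single residual random-base
# position (~0.25-0.3 majority) then vetoes the shift outright, whereas
# averaging would let two random positions hide behind six perfect adapter
# positions and undercall the random-base length.
shifted_consensus_score <- function(counts, s) {
  idx <- (s + 1L):(s + 8L)
  if (max(idx) > ncol(counts)) return(NA_real_)
  cov <- colSums(counts[, idx, drop = FALSE])
  if (any(cov == 0L)) return(NA_real_)
  min(apply(counts[, idx, drop = FALSE], 2L, max) / cov)
}

# Majority base and coverage per position of the suffixes after dropping
# `shift` leading bases; ties break to the alphabetically smallest base.
position_profile <- function(suffixes, shift) {
  trimmed <- substr(suffixes, shift + 1L, nchar(suffixes))
  maxp <- max(nchar(trimmed), 0L)
  base <- character(maxp); coverage <- integer(maxp)
  for (p in seq_len(maxp)) {
    b <- substr(trimmed, p, p)
    t <- table(factor(b[b != ""], levels = c("A", "C", "G", "T")))
    coverage[p] <- sum(t)
    base[p] <- names(t)[which.max(t)]   # which.max takes the first = smallest
  }
  list(base = base, coverage = coverage)
}

# Hamming mismatches of each observed string against one pattern.
adapter_mismatches <- function(obs, pattern) {
  if (!length(obs)) return(integer(0))
  L <- nchar(pattern)
  mm <- integer(length(obs))
  for (j in seq_len(L)) {
    mm <- mm + (substr(obs, j, j) != substr(pattern, j, j))
  }
  mm
}

#' Known adapter dialects of common small RNA kits
#'
#' A reference table of widely used 3' adapters and their random-base
#' layouts.  Used only to annotate an inferred pattern with a familiar kit
#' name; inference itself never consults it, preserving the no-prior
#' contract.
#'
#' @return data.frame with kit, adapter3, rand5_len, rand3_len.
#' @export
known_adapters <- function() {
  data.frame(
    kit = c("Illumina TruSeq small RNA", "NEXTflex small RNA 4N",
            "QIAseq miRNA", "Legacy small RNA (v1.5)"),
    adapter3 = c("TGGAATTCTCGGGTGCCAAGG", "TGGAATTCTCGGGTGCCAAGG",
                 "AACTGTAGGCACCATCAAT", "TCGTATGCCGTCTTCTGCTTG"),
    rand5_len = c(0L, 4L, 0L, 0L),
    rand3_len = c(0L, 4L, 0L, 0L),
    stringsAsFactors = FALSE)
}

#' Annotate an inferred pattern with a known kit dialect
#'
#' @param pattern An \code{adapter_pattern}.
#' @param table Dialect table, see [known_adapters()].
#' @return The kit name whose adapter (first 12 nt) and random-base
#'   layout match the pattern, or NA when no dialect matches.
#' @export
annotate_adapter <- function(pattern, table = known_adapters()) {
  if (is.null(pattern)) return(NA_character_)
  hit <- substr(table$adapter3, 1, 12) == substr(pattern$adapter3, 1, 12) &
    table$rand5_len == pattern$rand5_len &
    table$rand3_len == pattern$rand3_len
  if (any(hit)) table$kit[which(hit)[1]] else NA_character_
}

#' Detect the adapter pattern of a library
#'
#' Convenience wrapper: [collect_anchor_hits()] then
#' [infer_adapter_pattern()].
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param anchors Reference catalog (miRNA entries are the anchors).
#' @param max_reads,min_anchored,consensus_threshold See the two stages.
#' @return An \code{adapter_pattern} or NULL (none detected).
#' @export
detect_adapter <- function(reads, anchors, max_reads = 50000L,
                           min_anchored = 100L, consensus_threshold = 0.8) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  hits <- collect_anchor_hits(reads, anchors, max_reads)
  infer_adapter_pattern(hits, min_anchored, consensus_threshold)
}
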