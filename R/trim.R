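# Adapter and random-base trimming with the 16-nt keep-length filter.
#
# The 3' adapter is located as the leftmost occurrence of an adapter prefix
# with minimum overlap 7: exact below overlap 10, at most one substitution
# at overlap >= 10 (a deterministic stand-in for a 10% error-rate policy).
# A partial adapter running off the 3' read end counts when at least 7
# bases overlap.  After adapter removal the called numbers of 5' and 3'
# random bases are stripped, and inserts shorter than 16 nt are classified
# "too short" and discarded.

#' Trim one read
#'
#' @param read Read sequence (character scalar).
#' @param pattern An \code{adapter_pattern}.
#' @return List: read_id-free record with \code{insert} and \code{status}
#'   (kept / too_short / no_adapter).  \code{no_adapter} reads pass through
#'   completely untrimmed: with no adapter located, neither random-base
#'   length can be anchored.
#' @export
trim_read <- function(read, pattern) {
  res <- trim_reads(stats::setNames(read, "r"), pattern)
  list(insert = res$insert[1], status = res$status[1])
}

#' Trim a vector of reads
#'
#' Vectorized core of the trimming stage; see [trim_read()] for the rules.
#'
#' @param reads Named character vector of read sequences.
#' @param pattern An \code{adapter_pattern}, or NULL (no detectable
#'   adapter): every read passes through untrimmed with status no_adapter.
#' @return data.frame with read_id, insert, status.
#' @export
trim_reads <- function(reads, pattern) {
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  n <- length(reads)
  if (!n) return(data.frame(read_id = character(0), insert = character(0),
                            status = character(0), stringsAsFactors = FALSE))
  if (is.null(pattern)) {
    return(data.frame(read_id = ids, insert = unname(reads),
                      status = "no_adapter", stringsAsFactors = FALSE))
  }
  stopifnot(inherits(pattern, "adapter_pattern"))
  adapter <- pattern$adapter3
  alen <- nchar(adapter)
  rlen <- nchar(reads)
  maxlen <- max(rlen)

  # leftmost adapter start position per read (1-based); Inf = not found
  adpos <- rep(Inf, n)
  for (p in seq_len(max(maxlen - 6L, 0L))) {
    open <- is.infinite(adpos)
    if (!any(open)) break
    ov <- pmin(alen, rlen - p + 1L)
    cand <- open & ov >= 7L
    if (!any(cand)) next
    ovc <- ov[cand]
    mm <- integer(sum(cand))
    maxov <- max(ovc)
    rs <- reads[cand]
    for (j in seq_len(maxov)) {
      inrange <- ovc >= j
      if (!any(inrange)) break
      mm[inrange] <- mm[inrange] +
        (substr(rs[inrange], p + j - 1L, p + j - 1L) !=
           substr(adapter, j, j))
    }
    allowed <- ifelse(ovc >= 10L, 1L, 0L)
    found <- mm <= allowed
    adpos[which(cand)[found]] <- p
  }

  insert <- unname(reads)
  has_ad <- is.finite(adpos)
  insert[has_ad] <- substr(insert[has_ad], 1L, adpos[has_ad] - 1L)
  # strip random bases only when the adapter was located; a read with no
  # adapter occurrence passes through untrimmed, which also makes trimming
  # idempotent on already-trimmed inserts
  r5 <- pattern$rand5_len; r3 <- pattern$rand3_len
  ilen <- nchar(insert)
  insert[has_ad] <- substr(insert[has_ad], r5 + 1L,
                           pmax(ilen[has_ad] - r3, 0L))

  status <- ifelse(has_ad,
                   ifelse(nchar(insert) >= 16L, "kept", "too_short"),
                   "no_adapter")
  data.frame(read_id = ids, insert = insert, status = status,
             stringsAsFactors = FALSE)
}

#' Trim a FASTQ sample
#'
#' Applies [trim_reads()] to a whole library, writes kept inserts (plus
#' untrimmed no-adapter reads unless discarded), and returns trimming
#' statistics that partition the input exactly.
#'
#' @param fastq_in FASTQ path or named character vector of reads.
#' @param pattern \code{adapter_pattern} or NULL.
#' @param fastq_out Optional output FASTQ path for surviving inserts.
#' @param discard_untrimmed Drop reads in which no adapter was found
#'   (default keeps them untrimmed).
#' @return List: \code{trimmed} data.frame (read_id, insert, status),
#'   \code{kept} named character vector of surviving inserts, and
#'   \code{stats} (n_input, n_kept, n_too_short, n_no_adapter).
#' @export
trim_sample <- function(fastq_in, pattern, fastq_out = NULL,
                        discard_untrimmed = FALSE) {
  reads <- if (is.character(fastq_in) && length(fastq_in) == 1L &&
               file.exists(fastq_in)) read_fastq(fastq_in) else fastq_in
  tr <- trim_reads(reads, pattern)
  stats <- list(n_input = nrow(tr),
                n_kept = sum(tr$status == "kept"),
                n_too_short = sum(tr$status == "too_short"),
                n_no_adapter = sum(tr$status == "no_adapter"))
  surv <- tr$status == "kept"
  if (!discard_untrimmed)
    surv <- surv | (tr$status == "no_adapter" & nchar(tr$insert) >= 16L)
  kept <- stats::setNames(tr$insert[surv], tr$read_id[surv])
  if (!is.null(fastq_out)) write_fastq(kept, fastq_out)
  list(trimmed = tr, kept = kept, stats = stats)
}
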