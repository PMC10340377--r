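# Two-tier assignment of trimmed inserts to small RNA biotypes.
#
# Inserts are matched as substrings of catalog sequences: host references
# tolerate at most one substitution (no indels), with exact hits
# suppressing 1-mismatch hits (best-stratum rule); inserts that fail host
# matching and are longer than 19 nt are then matched exactly against the
# non-host catalog.  Reads count once toward the highest-priority biotype
# among their best-stratum hits and fractionally (1/k) toward the k tied
# features of that biotype.

#' Align one insert against host references
#'
#' Finds every host catalog entry containing the insert as a substring with
#' at most one substitution; when any exact hit exists, 1-mismatch hits are
#' suppressed.
#'
#' @param insert Insert sequence (>= 16 nt).
#' @param catalog Reference catalog; only host entries are searched.
#' @return data.frame of hits (feature_id, biotype, origin, n_mismatches);
#'   zero rows when nothing matches.
#' @export
align_host <- function(insert, catalog) {
  if (nchar(insert) < 16L) stop("insert must be >= 16 nt")
  host <- catalog[catalog$origin == "host", , drop = FALSE]
  hit_stratum(insert, host, max_mismatch = 1L)
}

#' Align one insert against non-host references
#'
#' Exact substring matching only; inserts of 19 nt or shorter are not
#' searched at all and return no hits.
#'
#' @param insert Insert sequence.
#' @param catalog Reference catalog; only nonhost entries are searched.
#' @return data.frame of hits as in [align_host()] (n_mismatches all 0).
#' @export
align_nonhost <- function(insert, catalog) {
  empty <- empty_hits()
  if (nchar(insert) <= 19L) return(empty)
  nh <- catalog[catalog$origin == "nonhost", , drop = FALSE]
  hit_stratum(insert, nh, max_mismatch = 0L)
}

empty_hits <- function() {
  data.frame(feature_id = character(0), biotype = character(0),
             origin = character(0), n_mismatches = integer(0),
             stringsAsFactors = FALSE)
}

# Best-stratum substring hits of one insert against a catalog subset.
hit_stratum <- function(insert, entries, max_mismatch) {
  if (!nrow(entries)) return(empty_hits())
  subject <- Biostrings::DNAStringSet(entries$sequence)
  n0 <- Biostrings::vcountPattern(insert, subject, max.mismatch = 0)
  if (any(n0 > 0L)) {
    sel <- n0 > 0L
    mm <- 0L
  } else if (max_mismatch >= 1L) {
    n1 <- Biostrings::vcountPattern(insert, subject, max.mismatch = 1)
    if (!any(n1 > 0L)) return(empty_hits())
    sel <- n1 > 0L
    mm <- 1L
  } else {
    return(empty_hits())
  }
  data.frame(feature_id = entries$feature_id[sel],
             biotype = entries$biotype[sel],
             origin = entries$origin[sel],
             n_mismatches = mm,
             stringsAsFactors = FALSE)
}

# Batch best-stratum substring matching of many distinct inserts against a
# catalog subset.  Exact hits are found with one Aho-Corasick pass per
# catalog entry (trusted band = first 16 nt, the minimum insert length);
# only inserts without an exact hit fall back to per-insert 1-substitution
# matching.  Returns a list (one element per insert): NULL for no hit,
# otherwise a hits data.frame as produced by align_host / align_nonhost.
batch_substring_hits <- function(inserts, entries, max_mismatch) {
  out <- vector("list", length(inserts))
  if (!nrow(entries) || !length(inserts)) return(out)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(inserts),
                          tb.start = 1L, tb.end = 16L)
  subjects <- Biostrings::DNAStringSet(entries$sequence)
  ins_idx <- list(); ent_idx <- list()
  for (e in seq_len(nrow(entries))) {
    w <- Biostrings::whichPDict(pd, subjects[[e]], max.mismatch = 0)
    if (length(w)) {
      ins_idx[[length(ins_idx) + 1L]] <- w
      ent_idx[[length(ent_idx) + 1L]] <- rep.int(e, length(w))
    }
  }
  ii <- unlist(ins_idx); ee <- unlist(ent_idx)
  if (length(ii)) {
    sp <- split(ee, ii)
    for (k in seq_along(sp)) {
      i <- as.integer(names(sp)[k])
      sel <- sp[[k]]
      out[[i]] <- data.frame(feature_id = entries$feature_id[sel],
                             biotype = entries$biotype[sel],
                             origin = entries$origin[sel],
                             n_mismatches = 0L,
                             stringsAsFactors = FALSE)
    }
  }
  if (max_mismatch >= 1L) {
    # pigeonhole pre-filter: a substring match with one substitution
    # leaves one error-free insert half, which must occur exactly in the
    # concatenated catalog; inserts failing both half-checks (typically
    # unmappable junk) skip the expensive mismatch search
    big <- paste(entries$sequence, collapse = "NN")
    miss <- which(vapply(out, is.null, logical(1)))
    for (i in miss) {
      ins <- inserts[i]
      L <- nchar(ins)
      h1 <- substr(ins, 1L, L %/% 2L)
      h2 <- substr(ins, L %/% 2L + 1L, L)
      if (!grepl(h1, big, fixed = TRUE) && !grepl(h2, big, fixed = TRUE))
        next
      h <- hit_stratum(ins, entries, max_mismatch = 1L)
      if (nrow(h)) out[[i]] <- h
    }
  }
  out
}

#' Assign a biotype from a set of alignment hits
#'
#' @param hits Best-stratum hits for one insert.
#' @param priority Biotype priority order; the earliest biotype present
#'   wins.  Defaults to [ev_biotypes()] (miRNA first).
#' @return List with \code{biotype} (NA when no hits) and \code{features},
#'   the tied feature ids of the winning biotype, each to be credited 1/k.
#' @export
assign_biotype <- function(hits, priority = ev_biotypes()) {
  if (!nrow(hits)) return(list(biotype = NA_character_,
                               features = character(0)))
  present <- priority[priority %in% hits$biotype]
  bt <- present[1]
  feats <- sort(unique(hits$feature_id[hits$biotype == bt]))
  list(biotype = bt, features = feats)
}

#' Quantify a trimmed sample
#'
#' Runs the two-tier assignment over all kept inserts and accumulates a
#' per-sample profile: read-fate counts (host / non-host / unmapped),
#' biotype counts, per-feature fractional counts, and feature CPM
#' (counts per million trimmed kept reads).
#'
#' @param inserts Character vector of kept inserts (each >= 16 nt).
#' @param host_catalog,nonhost_catalog Reference catalogs (subset by origin
#'   internally, so the same full catalog may be passed twice).
#' @param sample_id Sample label carried into the profile.
#' @param priority Biotype priority order.
#' @return Object of class \code{sample_profile}: sample_id,
#'   n_trimmed_kept, n_host, n_nonhost, n_unmapped, biotype_counts (named
#'   over [ev_biotypes()]), feature_counts, feature_cpm, and
#'   \code{zero_input} flag when no reads were supplied.
#' @export
quantify_sample <- function(inserts, host_catalog, nonhost_catalog = NULL,
                            sample_id = "sample",
                            priority = ev_biotypes()) {
  validate_catalog(host_catalog)
  if (is.null(nonhost_catalog)) nonhost_catalog <- host_catalog
  validate_catalog(nonhost_catalog)

  biotype_counts <- stats::setNames(numeric(length(ev_biotypes())),
                                    ev_biotypes())
  feature_counts <- numeric(0)
  n <- length(inserts)
  n_host <- 0L; n_nonhost <- 0L; n_unmapped <- 0L

  if (n > 0L) {
    if (any(nchar(inserts) < 16L))
      stop("all kept inserts must be >= 16 nt")
    # inserts are drawn from small catalogs, so libraries repeat the same
    # strings heavily; align each distinct insert once, batching the exact
    # stage through an Aho-Corasick dictionary
    uniq <- unique(inserts)
    mult <- as.numeric(table(factor(inserts, levels = uniq)))
    host <- host_catalog[host_catalog$origin == "host", , drop = FALSE]
    host_hits <- batch_substring_hits(uniq, host, max_mismatch = 1L)
    unmatched <- which(vapply(host_hits, is.null, logical(1)))
    nonhost <- nonhost_catalog[nonhost_catalog$origin == "nonhost", ,
                               drop = FALSE]
    long <- unmatched[nchar(uniq[unmatched]) > 19L]
    nh_hits <- vector("list", length(uniq))
    if (length(long) && nrow(nonhost))
      nh_hits[long] <- batch_substring_hits(uniq[long], nonhost,
                                            max_mismatch = 0L)
    for (i in seq_along(uniq)) {
      w <- mult[i]
      if (!is.null(host_hits[[i]])) {
        n_host <- n_host + w
        hits <- host_hits[[i]]
        asg <- assign_biotype(hits, priority)
        biotype_counts[asg$biotype] <- biotype_counts[asg$biotype] + w
        share <- w / length(asg$features)
        for (f in asg$features) {
          cur <- if (f %in% names(feature_counts)) feature_counts[[f]] else 0
          feature_counts[f] <- cur + share
        }
      } else if (!is.null(nh_hits[[i]])) {
        n_nonhost <- n_nonhost + w
      } else {
        n_unmapped <- n_unmapped + w
      }
    }
  }
  cpm <- if (n > 0L) feature_counts * 1e6 / n else feature_counts * 0
  structure(list(sample_id = sample_id,
                 n_trimmed_kept = n,
                 n_host = n_host, n_nonhost = n_nonhost,
                 n_unmapped = n_unmapped,
                 biotype_counts = biotype_counts,
                 feature_counts = feature_counts,
                 feature_cpm = cpm,
                 zero_input = n == 0L),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("sample_profile", x$sample_id, ":", x$n_trimmed_kept, "kept reads;",
      x$n_host, "host /", x$n_nonhost, "nonhost /", x$n_unmapped,
      "unmapped\n")
  bt <- x$biotype_counts[x$biotype_counts > 0]
  if (length(bt))
    cat("  ", paste(names(bt), bt, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Validate a sample profile
#'
#' Checks the partition invariants: host + nonhost + unmapped = kept,
#' biotype counts sum to the host count, and miRNA feature counts sum to
#' the miRNA biotype count.
#'
#' @param profile A \code{sample_profile}.
#' @param catalog Catalog used for quantification (to identify miRNA
#'   features); optional.
#' @return The profile, invisibly, if valid.
#' @export
validate_profile <- function(profile, catalog = NULL) {
  stopifnot(inherits(profile, "sample_profile"))
  with(profile, {
    if (n_trimmed_kept != n_host + n_nonhost + n_unmapped)
      stop("read fates do not partition the kept reads")
    if (abs(sum(biotype_counts) - n_host) > 1e-6)
      stop("biotype counts do not sum to the host count")
  })
  if (!is.null(catalog)) {
    mir <- catalog$feature_id[catalog$biotype == "miRNA"]
    s <- sum(profile$feature_counts[names(profile$feature_counts) %in% mir])
    if (abs(s - profile$biotype_counts[["miRNA"]]) > 1e-6)
      stop("miRNA feature counts do not sum to the miRNA biotype count")
  }
  invisible(profile)
}

#' Write a sample profile as TSV tables
#'
#' @param profile A \code{sample_profile}.
#' @param dir Output directory; writes \code{<sample>_biotypes.tsv} and
#'   \code{<sample>_features.tsv}.
#' @return The directory, invisibly.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bt <- data.frame(sample_id = profile$sample_id,
                   biotype = names(profile$biotype_counts),
                   count = as.numeric(profile$biotype_counts),
                   stringsAsFactors = FALSE)
  write_tsv(bt, file.path(dir, paste0(profile$sample_id, "_biotypes.tsv")))
  fc <- data.frame(sample_id = profile$sample_id,
                   feature_id = names(profile$feature_counts),
                   count = as.numeric(profile$feature_counts),
                   cpm = as.numeric(profile$feature_cpm),
                   stringsAsFactors = FALSE)
  fc <- fc[order(fc$feature_id), , drop = FALSE]
  write_tsv(fc, file.path(dir, paste0(profile$sample_id, "_features.tsv")))
  invisible(dir)
}
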