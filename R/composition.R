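# Small RNA composition: eight-class biotype proportions and log2
# abundance ratios.
#
# Proportions divide each biotype count by the total number of small RNA
# reads (all biotype counts except host_other); lincRNA and any label
# outside the eight reported classes are folded into misc so the
# proportions always partition to 1.  The log2 miRNA/rRNA and
# Y RNA/tRNA ratios add a pseudocount of 1 to both counts, keeping them
# finite when a class is absent.

#' Biotype composition of one sample
#'
#' @param profile A \code{sample_profile}.
#' @return One-row data.frame: sample_id, one proportion column per
#'   biotype in [composition_biotypes()], log2_mirna_rrna, log2_yrna_trna,
#'   and \code{no_smallrna} (TRUE when the sample has no small RNA reads,
#'   in which case all proportions are 0).
#' @export
biotype_proportions <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  counts <- profile$biotype_counts
  eight <- stats::setNames(numeric(8L), composition_biotypes())
  for (bt in names(counts)) {
    if (bt == "host_other") next
    tgt <- if (bt %in% composition_biotypes()) bt else "misc"
    eight[tgt] <- eight[tgt] + counts[[bt]]
  }
  total <- sum(eight)
  props <- if (total > 0) eight / total else eight
  if (total == 0) warning("sample ", profile$sample_id,
                          " has no small RNA reads")
  out <- data.frame(sample_id = profile$sample_id, t(props),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$log2_mirna_rrna <- log2((eight[["miRNA"]] + 1) / (eight[["rRNA"]] + 1))
  out$log2_yrna_trna <- log2((eight[["YRNA"]] + 1) / (eight[["tRNA"]] + 1))
  out$no_smallrna <- total == 0
  out
}

#' Per-study medians of the log2 composition ratios
#'
#' @param comp data.frame of per-sample composition rows (as from
#'   [biotype_proportions()], row-bound across samples).
#' @param study_id Study label per row.
#' @return data.frame: study_id, n_samples, median log2 miRNA/rRNA and
#'   Y RNA/tRNA ratios, and indicator columns for a median above 1.
#' @export
ratio_summary <- function(comp, study_id) {
  stopifnot(nrow(comp) == length(study_id))
  out <- do.call(rbind, lapply(split(seq_len(nrow(comp)), study_id),
                               function(idx) {
    data.frame(
      study_id = study_id[idx[1]],
      n_samples = length(idx),
      median_log2_mirna_rrna = stats::median(comp$log2_mirna_rrna[idx]),
      median_log2_yrna_trna = stats::median(comp$log2_yrna_trna[idx]),
      stringsAsFactors = FALSE)
  }))
  out$mirna_rrna_above_1 <- out$median_log2_mirna_rrna > 1
  out$yrna_trna_above_1 <- out$median_log2_yrna_trna > 1
  rownames(out) <- NULL
  out
}

#' Compare composition summaries between groups of studies
#'
#' Welch two-sample t-test on per-study summary values (e.g. medians or
#' IQRs of a proportion or ratio) between two groups defined by a manifest
#' column such as the isolation method.
#'
#' @param values Per-study numeric summaries.
#' @param group Two-level grouping aligned with \code{values}.
#' @return As [compare_study_groups()].
#' @export
compare_composition_groups <- function(values, group) {
  compare_study_groups(values, group)
}
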