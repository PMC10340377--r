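# Per-sample QC metrics, gates, and study-level summaries.
#
# Metric definitions: the overall mapping rate and the host fraction divide
# by the total number of reads after trimming; the small RNA fraction is
# small RNA reads (all biotype counts except host_other) over host reads;
# the miRNA fraction is miRNA reads over host reads.  Zero denominators
# yield a fraction of 0 plus the corresponding flag.

#' Default QC gate thresholds
#'
#' Read-depth and mapping gates (more than 100,000 trimmed reads, overall
#' mapping rate at least 20 percent), host-genome gates (at least 100,000
#' host reads, host fraction above 50 percent), and content gates (at
#' least 75 percent small RNA and 10 percent miRNA of host reads).
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(min_reads = 1e5,         # low_reads when n_trimmed <= min_reads
       min_overall_map = 0.20,  # low_overall_map when rate <  min
       min_host_reads = 1e5,    # low_host_reads  when n_host  <  min
       min_host_frac = 0.50,    # low_host_frac   when frac    <= min
       min_smallrna = 0.75,     # low_smallrna    when frac    <  min
       min_mirna = 0.10)        # low_mirna       when frac    <  min
}

#' Compute QC metrics for one sample
#'
#' @param profile A \code{sample_profile}.
#' @param thresholds Gate thresholds, see [qc_thresholds()]; flags are
#'   attached via [flag_sample()].
#' @return One-row data.frame of class \code{qc_report}: sample_id,
#'   n_trimmed, overall_map_rate, n_host, host_frac, smallrna_frac_of_host,
#'   mirna_frac_of_host, plus one logical column per flag.
#' @export
compute_qc <- function(profile, thresholds = qc_thresholds()) {
  stopifnot(inherits(profile, "sample_profile"))
  n <- profile$n_trimmed_kept
  n_host <- profile$n_host
  smallrna <- sum(profile$biotype_counts) -
    profile$biotype_counts[["host_other"]]
  mirna <- profile$biotype_counts[["miRNA"]]
  rep <- data.frame(
    sample_id = profile$sample_id,
    n_trimmed = n,
    overall_map_rate = if (n > 0) (n_host + profile$n_nonhost) / n else 0,
    n_host = n_host,
    host_frac = if (n > 0) n_host / n else 0,
    smallrna_frac_of_host = if (n_host > 0) smallrna / n_host else 0,
    mirna_frac_of_host = if (n_host > 0) mirna / n_host else 0,
    stringsAsFactors = FALSE)
  flag_sample(rep, thresholds)
}

#' Apply the QC gates to a report
#'
#' Boundary semantics (defaults): low_reads when n_trimmed <= 100,000
#' (passing requires more than 100,000 reads); low_overall_map when the
#' rate is below 0.20; low_host_reads when host reads fall below 100,000
#' (a minimum of 100,000 passes); low_host_frac when the host fraction is
#' at or below 0.50 (passing requires greater than 50 percent);
#' low_smallrna below 0.75; low_mirna below 0.10.
#'
#' @param report \code{qc_report} row(s) from [compute_qc()].
#' @param thresholds Named list as from [qc_thresholds()].
#' @return The report with the six flag columns (re)computed.
#' @export
flag_sample <- function(report, thresholds = qc_thresholds()) {
  th <- utils::modifyList(qc_thresholds(), thresholds)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  report$low_reads <- report$n_trimmed <= th$min_reads
  report$low_overall_map <- report$overall_map_rate < th$min_overall_map
  report$low_host_reads <- report$n_host < th$min_host_reads
  report$low_host_frac <- report$host_frac <= th$min_host_frac
  report$low_smallrna <- report$smallrna_frac_of_host < th$min_smallrna
  report$low_mirna <- report$mirna_frac_of_host < th$min_mirna
  class(report) <- unique(c("qc_report", class(report)))
  report
}

#' Study-level content exclusion
#'
#' A study is excluded when strictly more than half of its samples fail the
#' small RNA (75 percent) or miRNA (10 percent) content gates.  The
#' decision depends only on the low_smallrna / low_mirna flags.
#'
#' @param reports \code{qc_report} rows for several samples.
#' @param study_id Study label per report row.
#' @return data.frame: study_id, n_samples, n_failing, excluded.
#' @export
flag_study <- function(reports, study_id) {
  stopifnot(nrow(reports) == length(study_id), nrow(reports) >= 1L)
  failing <- reports$low_smallrna | reports$low_mirna
  out <- do.call(rbind, lapply(split(seq_len(nrow(reports)), study_id),
                               function(idx) {
    data.frame(study_id = study_id[idx[1]],
               n_samples = length(idx),
               n_failing = sum(failing[idx]),
               stringsAsFactors = FALSE)
  }))
  out$excluded <- out$n_failing > out$n_samples / 2
  rownames(out) <- NULL
  out
}

#' Within-study variability of small RNA proportions
#'
#' Median and interquartile range (Q3 - Q1, linear-interpolation quantiles)
#' of the per-sample small RNA proportions of each study, with the quality
#' label: high_quality when the median exceeds \code{median_cut} and the
#' IQR stays below \code{iqr_cut}; excluded when the study failed the
#' content exclusion; variable otherwise.
#'
#' @param smallrna_props Numeric vector of per-sample small RNA proportions
#'   in [0, 1].
#' @param study_id Study label per sample.
#' @param excluded Optional named logical (by study) from [flag_study()].
#' @param median_cut,iqr_cut Label thresholds (defaults 0.9 and 0.06).
#' @return data.frame: study_id, n_samples, median_smallrna_prop,
#'   iqr_smallrna_prop, excluded, label, single_sample warning column.
#' @export
study_variability <- function(smallrna_props, study_id, excluded = NULL,
                              median_cut = 0.9, iqr_cut = 0.06) {
  if (any(smallrna_props < 0 | smallrna_props > 1))
    stop("proportions must be in [0, 1]")
  groups <- split(smallrna_props, study_id)
  out <- do.call(rbind, lapply(names(groups), function(s) {
    x <- groups[[s]]
    data.frame(study_id = s,
               n_samples = length(x),
               median_smallrna_prop = stats::median(x),
               iqr_smallrna_prop = unname(
                 stats::quantile(x, 0.75, type = 7) -
                   stats::quantile(x, 0.25, type = 7)),
               single_sample = length(x) == 1L,
               stringsAsFactors = FALSE)
  }))
  out$excluded <- if (is.null(excluded)) FALSE else
    as.logical(excluded[out$study_id])
  out$label <- ifelse(out$excluded, "excluded",
                      ifelse(out$median_smallrna_prop > median_cut &
                               out$iqr_smallrna_prop < iqr_cut,
                             "high_quality", "variable"))
  if (any(out$single_sample))
    warning("IQR of single-sample studies is 0 by convention: ",
            paste(out$study_id[out$single_sample], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Compare study-level QC summaries between groups
#'
#' Welch two-sample t-test on per-study summary values (medians or IQRs)
#' between two groups of studies, e.g. donor sources or isolation methods.
#'
#' @param values Per-study summary values.
#' @param group Two-level grouping factor aligned with \code{values}.
#' @return List with t, p, estimate (group mean difference), and the group
#'   labels; NULL with a warning when either group has fewer than 2
#'   studies.
#' @export
compare_study_groups <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("grouping must have exactly two levels")
  n <- table(group)
  if (any(n < 2L)) {
    warning("group with fewer than 2 studies; comparison skipped")
    return(NULL)
  }
  tt <- stats::t.test(values ~ group)
  list(t = unname(tt$statistic), p = tt$p.value,
       estimate = unname(diff(rev(tt$estimate))),
       groups = levels(group))
}
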