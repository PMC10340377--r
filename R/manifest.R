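# Sample manifests: the study design table linking samples to studies,
# compartments (EV vs donor cell), donor sources, and EV isolation methods.

#' EV isolation methods
#'
#' The six commonly used EV extraction methods modeled by the manifest
#' generator: precipitation and column kits plus differential
#' ultracentrifugation.
#'
#' @return Character vector of method labels.
#' @export
isolation_methods <- function() {
  c("ExoQuick", "ExoEasy", "ExoRNeasy", "qEV",
    "TotalExosomeIsolation", "Ultracentrifugation")
}

#' Validate a sample manifest
#'
#' Requires unique sample ids, compartment in {EV, cell}, isolation methods
#' from [isolation_methods()], and every non-empty pair_id occurring on
#' exactly one EV row and one cell row.
#'
#' @param manifest Manifest data.frame.
#' @return The manifest, invisibly, if valid.
#' @export
validate_manifest <- function(manifest) {
  need <- c("sample_id", "study_id", "compartment", "source",
            "isolation_method", "rna_kit")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest")
  if (!all(manifest$compartment %in% c("EV", "cell")))
    stop("compartment must be EV or cell")
  if (!all(manifest$isolation_method %in% isolation_methods()))
    stop("unknown isolation_method in manifest")
  if ("pair_id" %in% names(manifest)) {
    pid <- manifest$pair_id
    pid[is.na(pid)] <- ""
    for (p in unique(pid[pid != ""])) {
      comp <- manifest$compartment[pid == p]
      if (!(length(comp) == 2L && setequal(comp, c("EV", "cell"))))
        stop("pair_id ", p, " must occur on exactly one EV and one cell row")
    }
  }
  invisible(manifest)
}

#' Read a manifest from TSV
#'
#' @param path TSV path with a header row.
#' @return Validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- read_tsv(path)
  validate_manifest(m)
  m
}

#' Write a manifest to TSV
#'
#' @param manifest Manifest data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write_tsv(manifest, path)
  invisible(path)
}

#' Summarize a manifest
#'
#' Counts studies and samples overall and by compartment.  A study is
#' "paired" if it contains at least one donor-cell sample.
#'
#' @param manifest Manifest data.frame.
#' @return List with n_studies, n_samples, n_ev_samples, n_cell_samples,
#'   n_paired_studies, n_ev_only_studies.
#' @export
manifest_summary <- function(manifest) {
  validate_manifest(manifest)
  has_cell <- tapply(manifest$compartment == "cell", manifest$study_id, any)
  list(
    n_studies = length(unique(manifest$study_id)),
    n_samples = nrow(manifest),
    n_ev_samples = sum(manifest$compartment == "EV"),
    n_cell_samples = sum(manifest$compartment == "cell"),
    n_paired_studies = sum(has_cell),
    n_ev_only_studies = sum(!has_cell))
}

#' Simulate a sample manifest
#'
#' Builds a manifest with a fixed number of EV-only and paired (EV plus
#' matched donor cell) studies and exact overall sample totals.  Donor-cell
#' samples are spread as evenly as possible across the paired studies and
#' matched one-to-one with EV samples of the same study via pair_id;
#' remaining EV samples are spread across all studies.  Isolation method,
#' donor source, and RNA kit are drawn per study.
#'
#' @param seed Integer seed.
#' @param n_ev_only_studies Studies profiling EVs only.
#' @param n_paired_studies Studies profiling EVs and matched donor cells.
#' @param n_samples Total number of samples across all studies.
#' @param n_cell Number of donor-cell samples (the rest are EV).
#' @return Manifest data.frame with one row per sample.
#' @export
simulate_manifest <- function(seed = 1L,
                              n_ev_only_studies = 55L,
                              n_paired_studies = 28L,
                              n_samples = 2756L,
                              n_cell = 513L) {
  n_studies <- n_ev_only_studies + n_paired_studies
  n_ev <- n_samples - n_cell
  if (n_cell < n_paired_studies)
    stop("need at least one cell sample per paired study")
  if (n_ev < n_studies)
    stop("need at least one EV sample per study")
  with_seed(seed, {
    study_ids <- sprintf("STUDY%03d", seq_len(n_studies))
    paired <- rep(c(FALSE, TRUE), c(n_ev_only_studies, n_paired_studies))
    # even split with remainder on the first studies
    split_even <- function(total, k) {
      base <- total %/% k
      extra <- total %% k
      base + as.integer(seq_len(k) <= extra)
    }
    cell_per <- integer(n_studies)
    cell_per[paired] <- split_even(n_cell, n_paired_studies)
    ev_per <- split_even(n_ev, n_studies)
    # paired studies need at least as many EVs as cells for 1:1 matching
    short <- pmax(cell_per - ev_per, 0L)
    if (sum(short) > 0L) {
      donors <- which(ev_per - cell_per > 1L)
      for (i in which(short > 0L)) {
        take <- short[i]
        for (d in donors) {
          avail <- ev_per[d] - cell_per[d] - 1L
          mv <- min(avail, take)
          ev_per[d] <- ev_per[d] - mv
          ev_per[i] <- ev_per[i] + mv
          take <- take - mv
          if (take == 0L) break
        }
        if (take > 0L) stop("cannot balance paired studies")
      }
    }
    rows <- lapply(seq_len(n_studies), function(i) {
      method <- sample(isolation_methods(), 1L)
      src <- sample(c("biofluid", "cell_line", "primary_culture"), 1L,
                    prob = c(0.5, 0.35, 0.15))
      fluid <- if (src == "biofluid")
        sample(c("plasma", "serum", "urine", "saliva"), 1L,
               prob = c(0.5, 0.25, 0.15, 0.1)) else NA_character_
      kit <- sample(c("miRNeasy", "TruSeq_smallRNA", "NEXTflex", "CleanTag"),
                    1L)
      n_e <- ev_per[i]; n_c <- cell_per[i]
      n_pairs <- min(n_e, n_c)
      pair <- function(k) if (k <= n_pairs)
        sprintf("%s_P%02d", study_ids[i], k) else NA_character_
      data.frame(
        sample_id = c(sprintf("%s_EV%03d", study_ids[i], seq_len(n_e)),
                      if (n_c) sprintf("%s_C%03d", study_ids[i], seq_len(n_c))),
        study_id = study_ids[i],
        compartment = rep(c("EV", "cell"), c(n_e, n_c)),
        source = src,
        biofluid_name = fluid,
        isolation_method = method,
        rna_kit = kit,
        pair_id = c(vapply(seq_len(n_e), pair, character(1)),
                    if (n_c) vapply(seq_len(n_c), pair, character(1))),
        stringsAsFactors = FALSE)
    })
    m <- do.call(rbind, rows)
    rownames(m) <- NULL
    validate_manifest(m)
    m
  })
}
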