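# End-to-end orchestration: simulate (optional) -> infer adapter -> trim ->
# quantify -> QC -> composition -> enrichment, with every intermediate
# written to disk and all randomness derived from a single config seed.

#' Default pipeline configuration
#'
#' A small fully-synthetic run: a seeded catalog, two paired studies of
#' three EV/cell pairs, 20,000 reads per sample, and the default QC,
#' adapter-inference, and enrichment parameters.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return Named list usable as \code{config} in [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("evqc_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_studies = 2L, pairs_per_study = 3L, n_reads = 20000L,
                    error_rate = 0.001, n_nonhost = 3L,
                    planted_log2fc = c(miRNA_001 = 2)),
    adapter = list(max_reads = 50000L, min_anchored = 100L,
                   consensus_threshold = 0.8),
    trim = list(discard_untrimmed = FALSE),
    qc = qc_thresholds(),
    enrichment = list(fdr_cut = 0.05, fc_cut = 1.5, min_testable = 2L,
                      k_tolerance = 3L))
}

#' Read a pipeline configuration from YAML
#'
#' Missing sections fall back to [default_run_config()] values, so a config
#' file only needs the fields it changes.
#'
#' @param path YAML path.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(seed = cfg$seed %||% 1L),
                    cfg)
}

#' Run the full assessment pipeline
#'
#' Simulates a multi-study EV/cell data set (unless FASTQ inputs are
#' supplied), infers the adapter pattern of every library without prior
#' kit information, trims, quantifies biotypes, applies the QC gates and
#' study-level summaries, computes composition statistics, and runs the
#' enrichment analyses.  Every stage writes TSV artifacts under
#' \code{config$out_dir}; a JSON run summary records per-sample QC,
#' per-study summaries, enrichment results, package version, and a config
#' hash.  Rerunning with the same config reproduces byte-identical tables.
#'
#' @param config List as from [default_run_config()] or
#'   [read_run_config()].
#' @return Invisibly, a list with the manifest, profiles, QC report,
#'   composition table, enrichment results, and the summary path.
#' @export
run_pipeline <- function(config = default_run_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ---------------------------------------------------------
  sim_cfg <- config$simulate
  catalog <- stage("simulate", generate_catalog(
    seed = derive_seed(config$seed, "catalog"),
    n_nonhost = sim_cfg$n_nonhost %||% 3L))
  design <- stage("simulate", build_paired_design(
    seed = derive_seed(config$seed, "design"),
    n_studies = sim_cfg$n_studies, pairs_per_study = sim_cfg$pairs_per_study,
    n_reads = sim_cfg$n_reads, catalog = catalog,
    planted_log2fc = sim_cfg$planted_log2fc %||% numeric(0),
    ev_composition = sim_cfg$ev_composition %||% default_composition(),
    cell_composition = sim_cfg$cell_composition %||% default_composition(),
    error_rate = sim_cfg$error_rate))
  simdir <- file.path(out, "reads")
  ss <- stage("simulate", simulate_study_set(design, catalog, simdir))
  manifest <- ss$manifest

  # --- adapter + trim + quantify per sample -----------------------------
  profiles <- list()
  patterns <- list()
  trim_stats <- list()
  for (sid in manifest$sample_id) {
    reads <- stage(paste("read", sid), read_fastq(ss$fastq_paths[[sid]]))
    pat <- stage(paste("adapter", sid), detect_adapter(
      reads, catalog, max_reads = config$adapter$max_reads,
      min_anchored = config$adapter$min_anchored,
      consensus_threshold = config$adapter$consensus_threshold))
    patterns[[sid]] <- pat
    tr <- stage(paste("trim", sid), trim_sample(
      reads, pat, discard_untrimmed = config$trim$discard_untrimmed))
    trim_stats[[sid]] <- tr$stats
    profiles[[sid]] <- stage(paste("quantify", sid), quantify_sample(
      unname(tr$kept), catalog, catalog, sample_id = sid))
  }
  pat_df <- do.call(rbind, lapply(names(patterns), function(sid) {
    p <- patterns[[sid]]
    data.frame(sample_id = sid,
               adapter3 = if (is.null(p)) NA_character_ else p$adapter3,
               rand5_len = if (is.null(p)) NA_integer_ else p$rand5_len,
               rand3_len = if (is.null(p)) NA_integer_ else p$rand3_len,
               support_fraction = if (is.null(p)) NA_real_ else
                 p$support_fraction,
               n_anchored = if (is.null(p)) NA_integer_ else p$n_anchored,
               stringsAsFactors = FALSE)
  }))
  write_tsv(pat_df, file.path(out, "adapter_patterns.tsv"))
  ts_df <- do.call(rbind, lapply(names(trim_stats), function(sid)
    cbind(data.frame(sample_id = sid), as.data.frame(trim_stats[[sid]]))))
  write_tsv(ts_df, file.path(out, "trim_stats.tsv"))
  for (p in profiles) write_profile(p, file.path(out, "profiles"))

  # --- QC ---------------------------------------------------------------
  qc <- do.call(rbind, lapply(profiles, compute_qc, thresholds = config$qc))
  rownames(qc) <- NULL
  study_of <- manifest$study_id[match(qc$sample_id, manifest$sample_id)]
  study_flags <- flag_study(qc, study_of)
  smallrna_prop <- qc$smallrna_frac_of_host
  variability <- suppressWarnings(study_variability(
    smallrna_prop, study_of,
    excluded = stats::setNames(study_flags$excluded, study_flags$study_id)))
  write_tsv(qc, file.path(out, "qc_report.tsv"))
  write_tsv(study_flags, file.path(out, "study_exclusion.tsv"))
  write_tsv(variability, file.path(out, "study_variability.tsv"))

  # --- composition ------------------------------------------------------
  comp <- do.call(rbind, lapply(profiles, function(p)
    suppressWarnings(biotype_proportions(p))))
  rownames(comp) <- NULL
  ratios <- ratio_summary(comp, study_of)
  write_tsv(comp, file.path(out, "composition.tsv"))
  write_tsv(ratios, file.path(out, "ratio_summary.tsv"))

  # --- enrichment -------------------------------------------------------
  prop_mat <- comp[, composition_biotypes(), drop = FALSE]
  anova_res <- stage("enrichment",
                     anova_biotype(prop_mat, manifest))
  write_tsv(anova_res, file.path(out, "biotype_anova.tsv"))

  mir_ids <- sort(catalog$feature_id[catalog$biotype == "miRNA"])
  count_mat <- vapply(profiles, function(p) {
    v <- p$feature_counts[mir_ids]
    v[is.na(v)] <- 0
    round(v)
  }, numeric(length(mir_ids)))
  rownames(count_mat) <- mir_ids
  write_tsv(cbind(data.frame(feature_id = mir_ids), as.data.frame(count_mat)),
            file.path(out, "mirna_counts.tsv"))

  per_study <- list()
  for (st in unique(manifest$study_id)) {
    m <- manifest[manifest$study_id == st, , drop = FALSE]
    de <- stage(paste("differential", st), differential_mirnas(
      count_mat[, m$sample_id, drop = FALSE], m,
      fdr_cut = config$enrichment$fdr_cut,
      fc_cut = config$enrichment$fc_cut))
    per_study[[st]] <- de
    write_tsv(de, file.path(out, paste0("de_", st, ".tsv")))
  }
  export_cls <- if (length(per_study) >= 2L)
    classify_export(per_study,
                    min_testable = config$enrichment$min_testable,
                    k_tolerance = config$enrichment$k_tolerance) else NULL
  if (!is.null(export_cls))
    write_tsv(export_cls, file.path(out, "export_classification.tsv"))

  # --- summary ----------------------------------------------------------
  summary <- list(
    package_version = as.character(utils::packageVersion("evqc")),
    config_hash = config_hash(config),
    n_samples = nrow(manifest),
    n_studies = length(unique(manifest$study_id)),
    qc = qc, study_exclusion = study_flags,
    study_variability = variability,
    biotype_anova = anova_res,
    export_classification = export_cls)
  summary_path <- file.path(out, "run_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(manifest = manifest, patterns = patterns,
                 profiles = profiles, qc = qc,
                 study_flags = study_flags, variability = variability,
                 composition = comp, ratios = ratios,
                 anova = anova_res, per_study_de = per_study,
                 export_classification = export_cls,
                 summary_path = summary_path, out_dir = out))
}

# Stable hash of the configuration (stringified, md5).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(config)),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}
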