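# EV-versus-donor-cell enrichment analysis.
#
# Two complementary layers: (i) a three-factor ANOVA on per-sample biotype
# proportions (compartment + isolation method + study, type-II sums of
# squares) that tests enrichment or depletion of whole biotypes in EVs
# while adjusting for the isolation method as a confounder; (ii) per-miRNA
# negative binomial log-linear models within each paired study
# (count ~ compartment + isolation method with a log library-size offset,
# Wald test, Benjamini-Hochberg correction), followed by a cross-study
# classification of each miRNA's export behaviour.

#' Confounder-adjusted ANOVA on biotype proportions
#'
#' Fits proportion ~ compartment + isolation_method + study by least
#' squares for one biotype at a time and reports the compartment term's
#' type-II F-test p-value together with the raw mean EV-minus-cell
#' difference.  Factors with fewer than two levels (e.g. a single
#' isolation method) are dropped with a note; a rank-deficient design drops
#' the offending confounder rather than failing.
#'
#' @param proportions Numeric matrix or data.frame, samples in rows,
#'   one column per biotype (e.g. stacked [biotype_proportions()] rows).
#' @param manifest Manifest rows aligned with the proportion rows; must
#'   contain both compartments.
#' @param alpha Significance level used to call a direction.
#' @return data.frame with one row per biotype: biotype, p_compartment,
#'   effect (mean EV proportion - mean cell proportion), direction
#'   (enriched_in_EV / depleted_in_EV / none), dropped_terms.
#' @export
anova_biotype <- function(proportions, manifest, alpha = 0.05) {
  validate_manifest(manifest)
  if (length(unique(manifest$compartment)) < 2L)
    stop("manifest must contain both EV and cell samples")
  proportions <- as.data.frame(proportions)
  stopifnot(nrow(proportions) == nrow(manifest))

  terms <- c("isolation_method", "study_id")
  keep <- vapply(terms, function(tm)
    length(unique(manifest[[tm]])) >= 2L, logical(1))
  # compartment nested in a single study is fine; compartment fully
  # confounded with study would make the design rank-deficient, so drop
  # study if every study is single-compartment
  if (keep[["study_id"]]) {
    tabs <- table(manifest$study_id, manifest$compartment)
    if (all(rowSums(tabs > 0) < 2L)) keep[["study_id"]] <- FALSE
  }
  dropped <- terms[!keep]
  rhs <- paste(c("compartment", terms[keep]), collapse = " + ")

  df <- manifest
  df$compartment <- factor(df$compartment, levels = c("cell", "EV"))
  df$isolation_method <- factor(df$isolation_method)
  df$study_id <- factor(df$study_id)

  rows <- lapply(names(proportions), function(bt) {
    df$y <- proportions[[bt]]
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
    p <- tryCatch({
      # aliased confounders (e.g. isolation method constant within study)
      # are handled by model comparison; the note it prints is silenced
      a2 <- suppressMessages(car::Anova(fit, type = 2))
      a2["compartment", "Pr(>F)"]
    }, error = function(e) NA_real_)
    eff <- mean(df$y[df$compartment == "EV"]) -
      mean(df$y[df$compartment == "cell"])
    dir <- if (!is.na(p) && p < alpha) {
      if (eff > 0) "enriched_in_EV" else "depleted_in_EV"
    } else "none"
    data.frame(biotype = bt, p_compartment = p, effect = eff,
               direction = dir,
               dropped_terms = paste(dropped, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median normalization of an expression table
#'
#' Divides each feature's values by that feature's median across samples,
#' the scaling used to rank highly expressed miRNAs.  Features whose
#' median is 0 are set to 0 and flagged.
#'
#' @param expression Numeric matrix, features x samples (>= 3 samples).
#' @return List: \code{normalized} matrix and \code{zero_median} logical
#'   vector per feature.
#' @export
median_normalize <- function(expression) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 3L) stop("median normalization needs >= 3 samples")
  med <- apply(expression, 1L, stats::median)
  zero <- med == 0
  norm <- expression / ifelse(zero, 1, med)
  norm[zero, ] <- 0
  list(normalized = norm, zero_median = zero)
}

# Median-of-ratios size factors (geometric-mean reference, computed over
# features with no zero count), normalized to geometric mean 1.  Robust to
# a minority of strongly differential features, which bias raw library
# totals and with them every fold-change estimate.  Falls back to scaled
# totals when no feature is zero-free.
size_factors <- function(counts) {
  totals <- colSums(counts)
  fallback <- totals / exp(mean(log(pmax(totals, 1))))
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  gm <- exp(rowMeans(lg))
  use <- is.finite(gm) & gm > 0
  if (!any(use)) return(fallback)
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(col) stats::median(col / gm[use]))
  if (any(!is.finite(sf) | sf <= 0)) return(fallback)
  sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion for one feature: pooled within
# compartments on offset-normalized counts, floored at `floor`.
mom_dispersion <- function(y, size, group, floor = 0.01) {
  q <- y * mean(size) / size
  est <- vapply(split(seq_along(y), group), function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    m <- mean(q[idx]); v <- stats::var(q[idx])
    if (m <= 0) return(NA_real_)
    (v - m) / m^2
  }, numeric(1))
  est <- est[is.finite(est)]
  if (!length(est)) return(floor)
  max(floor, mean(est))
}

#' Per-miRNA differential abundance between EV and cell samples
#'
#' For one paired study: per-feature negative binomial log-linear model
#' count ~ compartment + isolation_method with a log size-factor offset
#' (median-of-ratios size factors, robust to a minority of strongly
#' differential features that would bias raw library totals), dispersion
#' estimated by method of moments per feature and
#' floored at 0.01, Wald test on the compartment coefficient (referred to
#' a t distribution with the model's residual degrees of freedom, a
#' small-sample correction for the plug-in dispersion), and
#' Benjamini-Hochberg correction across the tested features.  A feature is
#' significant when FDR < 0.05 and the fold change exceeds 1.5 in either
#' direction.
#'
#' @param counts Integer matrix, features x samples (raw counts).
#' @param manifest Manifest rows for the columns of \code{counts}; must be
#'   a single study with at least 2 EV and 2 cell samples.
#' @param fdr_cut,fc_cut Significance thresholds (defaults 0.05 and 1.5).
#' @param dispersion_floor Lower bound for the per-feature dispersion.
#' @return data.frame: feature_id, base_mean, log2fc (EV vs cell), se, p,
#'   fdr, significant.  All-zero features are excluded before testing.
#' @export
differential_mirnas <- function(counts, manifest, fdr_cut = 0.05,
                                fc_cut = 1.5, dispersion_floor = 0.01) {
  counts <- as.matrix(counts)
  if (any(counts != round(counts)) || any(counts < 0))
    stop("counts must be nonnegative integers")
  validate_manifest(manifest)
  if (length(unique(manifest$study_id)) != 1L)
    stop("differential_mirnas runs one study at a time")
  ncomp <- table(factor(manifest$compartment, levels = c("cell", "EV")))
  if (any(ncomp < 2L))
    stop("study ", manifest$study_id[1],
         " needs >= 2 EV and >= 2 cell samples")
  stopifnot(ncol(counts) == nrow(manifest))

  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  size <- size_factors(counts)
  comp <- factor(manifest$compartment, levels = c("cell", "EV"))
  iso <- factor(manifest$isolation_method)
  use_iso <- nlevels(iso) >= 2L
  off <- log(size)

  res <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    disp <- mom_dispersion(y, size, comp, dispersion_floor)
    dat <- data.frame(y = y, comp = comp, iso = iso)
    form <- if (use_iso) y ~ comp + iso + offset(off) else
      y ~ comp + offset(off)
    fit <- tryCatch(suppressWarnings(
      stats::glm(form, data = dat,
                 family = MASS::negative.binomial(theta = 1 / disp))),
      error = function(e) NULL)
    if (is.null(fit) || !("compEV" %in% rownames(summary(fit)$coefficients)))
      return(data.frame(base_mean = mean(y * mean(size) / size),
                        log2fc = NA_real_, se = NA_real_, p = NA_real_))
    co <- summary(fit)$coefficients["compEV", ]
    z <- co[["Estimate"]] / co[["Std. Error"]]
    # t reference with residual df: the plug-in dispersion makes the
    # normal-referenced Wald statistic anti-conservative at small n
    data.frame(base_mean = mean(y * mean(size) / size),
               log2fc = co[["Estimate"]] / log(2),
               se = co[["Std. Error"]] / log(2),
               p = 2 * stats::pt(-abs(z), df = fit$df.residual))
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(feature_id = rownames(counts),
                          stringsAsFactors = FALSE), out)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cut &
    abs(out$log2fc) > log2(fc_cut)
  rownames(out) <- NULL
  out
}

#' Classify miRNA export behaviour across studies
#'
#' For each feature, the per-study call is EV-enriched (significant with
#' positive log2 fold change), cell-enriched (significant, negative),
#' ns (tested, not significant), or untestable (not tested in that study).
#' Classes, in precedence order: context_independent_EV (EV-enriched in
#' every testable study, at least \code{min_testable} of them);
#' context_independent_cell (symmetric); mostly_EV (EV-enriched in a
#' majority of testable studies and in all but at most \code{k_tolerance}
#' of them, never cell-enriched);
#' study_specific (significant somewhere but not consistently);
#' unclassified otherwise.
#'
#' @param per_study Named list (by study_id) of [differential_mirnas()]
#'   result tables.
#' @param min_testable Minimum testable studies for a context-independent
#'   call (default 2).
#' @param k_tolerance Maximum non-enriched testable studies for mostly_EV
#'   (default 3).
#' @return data.frame: feature_id, n_testable, n_ev, n_cell, n_ns, class;
#'   attribute \code{per_study_calls} holds the feature x study call
#'   matrix.
#' @export
classify_export <- function(per_study, min_testable = 2L, k_tolerance = 3L) {
  if (length(per_study) < 2L) stop("classification needs >= 2 studies")
  studies <- names(per_study)
  feats <- sort(unique(unlist(lapply(per_study, `[[`, "feature_id"))))
  calls <- matrix("untestable", nrow = length(feats),
                  ncol = length(studies),
                  dimnames = list(feats, studies))
  for (s in studies) {
    r <- per_study[[s]]
    tested <- r[!is.na(r$p), , drop = FALSE]
    call <- ifelse(!tested$significant, "ns",
                   ifelse(tested$log2fc > 0, "EV-enriched", "cell-enriched"))
    calls[tested$feature_id, s] <- call
  }
  n_test <- rowSums(calls != "untestable")
  n_ev <- rowSums(calls == "EV-enriched")
  n_cell <- rowSums(calls == "cell-enriched")
  n_ns <- rowSums(calls == "ns")
  cls <- rep("unclassified", length(feats))
  testable_ok <- n_test >= min_testable
  cls[testable_ok & n_ev == n_test] <- "context_independent_EV"
  cls[testable_ok & n_cell == n_test & cls == "unclassified"] <-
    "context_independent_cell"
  cls[testable_ok & n_cell == 0 & n_ev > n_test / 2 &
        (n_test - n_ev) <= k_tolerance & cls == "unclassified"] <-
    "mostly_EV"
  cls[(n_ev + n_cell) > 0 & cls == "unclassified"] <- "study_specific"
  out <- data.frame(feature_id = feats, n_testable = n_test, n_ev = n_ev,
                    n_cell = n_cell, n_ns = n_ns, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "per_study_calls") <- calls
  out
}
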