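#' Discovery thresholds for differentially methylated CpGs
#'
#' Defaults follow the discovery criteria used throughout the package:
#' FDR-adjusted p below `1e-10`, methylation difference above 0.3, mean
#' background beta below 0.1, and at least 2 differentially methylated
#' probes within a 5 kb region (pairwise distance at most
#' `window_bp / 2` = 2.5 kb, boundary inclusive).
#'
#' @param fdr_max Strict upper bound on the BH-adjusted p-value.
#' @param delta_min Strict lower bound on the target-minus-other mean
#'   beta difference.
#' @param other_mean_max Strict upper bound on mean beta in non-target
#'   tissues.
#' @param window_bp Regional window size in bp (a probe's neighbourhood is
#'   `+/- window_bp / 2`).
#' @param min_probes_in_window Minimum passing probes (self included)
#'   required within the window.
#' @return Named list of thresholds.
#' @export
dmc_thresholds <- function(fdr_max = 1e-10, delta_min = 0.3,
                           other_mean_max = 0.1, window_bp = 5000,
                           min_probes_in_window = 2L) {
  stopifnot(fdr_max > 0, delta_min > 0, delta_min <= 1, other_mean_max > 0,
            window_bp > 0, min_probes_in_window >= 1)
  list(fdr_max = fdr_max, delta_min = delta_min,
       other_mean_max = other_mean_max, window_bp = window_bp,
       min_probes_in_window = as.integer(min_probes_in_window))
}

#' Per-probe differential methylation against all other tissues
#'
#' For every probe, compares beta-values of the target tissue's discovery
#' samples to all other discovery samples with a two-sided rank-sum test
#' and reports group means, their difference, and BH-adjusted p-values
#' (adjusted jointly across every probe tested in the run). Missing values
#' are excluded pairwise; probes without at least one non-missing value in
#' each group are dropped with a warning.
#'
#' @param beta A [beta_matrix()].
#' @param sheet Sample sheet (`data.frame` with `sample_id`, `tissue`,
#'   `role`); only `role == "discovery"` samples are used.
#' @param target_tissue Tissue label to test (e.g. `"Kidney"`).
#' @return `data.frame` with columns `probe_id`, `mean_target`,
#'   `mean_other`, `delta`, `p_value`, `fdr`.
#' @export
differential_methylation <- function(beta, sheet, target_tissue) {
  sheet <- sheet[sheet$role == "discovery", , drop = FALSE]
  if (!target_tissue %in% sheet$tissue) {
    stop("unknown target tissue: ", target_tissue, call. = FALSE)
  }
  tgt_ids <- sheet$sample_id[sheet$tissue == target_tissue]
  oth_ids <- sheet$sample_id[sheet$tissue != target_tissue]
  if (length(tgt_ids) < 2) stop("need >= 2 discovery samples in target tissue",
                                call. = FALSE)
  if (length(oth_ids) < 1) stop("need >= 1 other-tissue discovery sample",
                                call. = FALSE)
  missing_cols <- setdiff(c(tgt_ids, oth_ids), colnames(beta))
  if (length(missing_cols) > 0) {
    stop("samples absent from beta matrix: ",
         paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  tgt <- beta[, tgt_ids, drop = FALSE]
  oth <- beta[, oth_ids, drop = FALSE]
  n_tgt <- rowSums(!is.na(tgt))
  n_oth <- rowSums(!is.na(oth))
  keep <- n_tgt >= 1 & n_oth >= 1
  if (!all(keep)) {
    warning(sum(!keep), " probe(s) dropped: no non-missing value in a group")
  }
  tgt <- tgt[keep, , drop = FALSE]
  oth <- oth[keep, , drop = FALSE]
  mean_target <- rowMeans(tgt, na.rm = TRUE)
  mean_other <- rowMeans(oth, na.rm = TRUE)
  p <- vapply(seq_len(nrow(tgt)), function(i) {
    rank_sum_test(tgt[i, ], oth[i, ])$p_value
  }, numeric(1))
  data.frame(probe_id = rownames(tgt),
             mean_target = unname(mean_target),
             mean_other = unname(mean_other),
             delta = unname(mean_target - mean_other),
             p_value = p,
             fdr = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter per-probe results on the discovery thresholds
#'
#' Retains probes with `fdr < fdr_max`, `delta > delta_min` and
#' `mean_other < other_mean_max` — all inequalities strict.
#'
#' @param results Output of [differential_methylation()].
#' @param thresholds A [dmc_thresholds()] list.
#' @return The passing subset of `results`.
#' @export
dmc_filter <- function(results, thresholds = dmc_thresholds()) {
  keep <- results$fdr < thresholds$fdr_max &
    results$delta > thresholds$delta_min &
    results$mean_other < thresholds$other_mean_max
  results[keep, , drop = FALSE]
}

.annotated_positions <- function(probe_ids, annotation) {
  idx <- match(probe_ids, annotation$probe_id)
  if (anyNA(idx)) {
    stop("probes missing genomic annotation: ",
         paste(probe_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  data.frame(probe_id = probe_ids, chrom = annotation$chrom[idx],
             position = annotation$position[idx], stringsAsFactors = FALSE)
}

#' Regional density filter over 5 kb windows
#'
#' A probe is retained iff at least `min_probes_in_window` passing probes
#' (itself included) lie on the same chromosome within
#' `+/- window_bp / 2` of its position; a distance of exactly
#' `window_bp / 2` counts as inside. This removes isolated single-probe
#' hits that cannot support a region-level PCR assay.
#'
#' @param probe_ids Probes that passed [dmc_filter()].
#' @param annotation Probe annotation (`probe_id`, `chrom`, `position`).
#' @param thresholds A [dmc_thresholds()] list.
#' @return Character vector of retained probe ids.
#' @export
region_density_filter <- function(probe_ids, annotation,
                                  thresholds = dmc_thresholds()) {
  if (length(probe_ids) == 0) return(character(0))
  ann <- .annotated_positions(probe_ids, annotation)
  half <- thresholds$window_bp / 2
  keep <- vapply(seq_len(nrow(ann)), function(i) {
    same <- ann$chrom == ann$chrom[i]
    sum(same & abs(ann$position - ann$position[i]) <= half) >=
      thresholds$min_probes_in_window
  }, logical(1))
  ann$probe_id[keep]
}

#' Assemble differentially methylated regions
#'
#' Single-linkage clustering per chromosome: probes whose positions differ
#' by at most `window_bp / 2` are joined transitively; each cluster becomes
#' one DMR spanning the minimum to maximum member position (1-based
#' inclusive, no padding).
#'
#' @param probe_ids Retained probes (normally from
#'   [region_density_filter()]).
#' @param annotation Probe annotation.
#' @param thresholds A [dmc_thresholds()] list.
#' @return `data.frame` with `chrom`, `start`, `end`, `n_probes`,
#'   `probe_ids` (comma-separated, ordered by position) and `name`.
#' @export
assemble_dmrs <- function(probe_ids, annotation,
                          thresholds = dmc_thresholds()) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer(),
                      probe_ids = character(), name = character(),
                      stringsAsFactors = FALSE)
  if (length(probe_ids) == 0) return(empty)
  ann <- .annotated_positions(probe_ids, annotation)
  half <- thresholds$window_bp / 2
  out <- list()
  for (chrom in unique(ann$chrom)) {
    sub <- ann[ann$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    gap_new <- c(TRUE, diff(sub$position) > half)
    cl <- cumsum(gap_new)
    for (k in unique(cl)) {
      members <- sub[cl == k, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = min(members$position),
        end = max(members$position),
        n_probes = nrow(members),
        probe_ids = paste(members$probe_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  dmrs <- do.call(rbind, out)
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  dmrs$name <- sprintf("dmr_%d", seq_len(nrow(dmrs)))
  rownames(dmrs) <- NULL
  dmrs
}

#' Blood background metrics per probe
#'
#' Median beta across blood reference samples and the fraction of
#' non-missing blood samples exceeding the positivity cutoff. Probes absent
#' from the blood matrix are carried forward with `NA` metrics and a
#' warning rather than scored.
#'
#' @param blood A [beta_matrix()] of blood reference samples.
#' @param probe_ids Probes to score.
#' @param positivity_cutoff Beta above which a blood sample counts as
#'   positive (default 0.2).
#' @return `data.frame` with `probe_id`, `median_beta`, `positivity`,
#'   `available`.
#' @export
blood_metrics <- function(blood, probe_ids, positivity_cutoff = 0.2) {
  if (ncol(blood) < 1) stop("blood matrix needs >= 1 sample", call. = FALSE)
  present <- probe_ids %in% rownames(blood)
  if (any(!present)) {
    warning("probe(s) absent from blood matrix, carried forward unscored: ",
            paste(probe_ids[!present], collapse = ", "))
  }
  med <- pos <- rep(NA_real_, length(probe_ids))
  for (i in which(present)) {
    v <- blood[probe_ids[i], ]
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    med[i] <- stats::median(v)
    pos[i] <- mean(v > positivity_cutoff)
  }
  data.frame(probe_id = probe_ids, median_beta = med, positivity = pos,
             available = present & !is.na(med), stringsAsFactors = FALSE)
}

#' Exclude probes with blood background signal
#'
#' Excludes probes whose blood median beta exceeds `median_max` or whose
#' blood positivity exceeds `positivity_max` (strict inequalities: values
#' exactly at a boundary are retained). Probes with unavailable metrics are
#' retained (they were already flagged by [blood_metrics()]).
#'
#' @param metrics Output of [blood_metrics()].
#' @param median_max Maximum tolerated blood median beta (default 0.1).
#' @param positivity_max Maximum tolerated blood positivity (default 0.02).
#' @return Character vector of retained probe ids.
#' @export
blood_exclude <- function(metrics, median_max = 0.1, positivity_max = 0.02) {
  excl <- metrics$available &
    (metrics$median_beta > median_max | metrics$positivity > positivity_max)
  metrics$probe_id[!excl]
}

#' Restrict assembled DMRs to a retained probe set
#'
#' Drops excluded probes from each DMR, recomputes the span over the
#' remaining member positions, and removes DMRs that fall below
#' `min_probes_in_window` members.
#'
#' @param dmrs Output of [assemble_dmrs()].
#' @param retained Character vector of retained probe ids.
#' @param annotation Probe annotation.
#' @param thresholds A [dmc_thresholds()] list.
#' @return Filtered DMR `data.frame`.
#' @export
restrict_dmrs <- function(dmrs, retained, annotation,
                          thresholds = dmc_thresholds()) {
  if (nrow(dmrs) == 0) return(dmrs)
  rows <- list()
  for (i in seq_len(nrow(dmrs))) {
    members <- strsplit(dmrs$probe_ids[i], ",")[[1]]
    members <- members[members %in% retained]
    if (length(members) < thresholds$min_probes_in_window) next
    ann <- .annotated_positions(members, annotation)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = dmrs$chrom[i], start = min(ann$position),
      end = max(ann$position), n_probes = length(members),
      probe_ids = paste(members[order(ann$position)], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(dmrs[0, setdiff(names(dmrs), "name"), drop = FALSE])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("dmr_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Run the full DMR discovery chain
#'
#' Differential methylation, threshold filtering, regional density
#' filtering, DMR assembly and (optionally) blood-background exclusion, with
#' a stage log of probe counts mirroring the decision flowchart of the
#' discovery phase.
#'
#' @param beta Discovery [beta_matrix()].
#' @param sheet Sample sheet.
#' @param annotation Probe annotation.
#' @param target_tissue Tissue to find hypermethylated markers for.
#' @param blood Optional blood-reference [beta_matrix()]; when `NULL` the
#'   blood filter is skipped.
#' @param thresholds A [dmc_thresholds()] list.
#' @param positivity_cutoff Blood positivity beta cutoff (default 0.2).
#' @param median_max,positivity_max Blood exclusion bounds (defaults 0.1
#'   and 0.02).
#' @return List with `dmc` (per-probe table), `dmc_pass`, `region_pass`,
#'   `blood` (metrics or `NULL`), `retained`, `dmrs`, and `counts` (named
#'   stage log).
#' @export
discover_dmrs <- function(beta, sheet, annotation, target_tissue,
                          blood = NULL, thresholds = dmc_thresholds(),
                          positivity_cutoff = 0.2, median_max = 0.1,
                          positivity_max = 0.02) {
  dmc <- differential_methylation(beta, sheet, target_tissue)
  pass <- dmc_filter(dmc, thresholds)
  dense <- region_density_filter(pass$probe_id, annotation, thresholds)
  dmrs <- assemble_dmrs(dense, annotation, thresholds)
  bm <- NULL
  retained <- dense
  if (!is.null(blood) && length(dense) > 0) {
    bm <- blood_metrics(blood, dense, positivity_cutoff)
    retained <- blood_exclude(bm, median_max, positivity_max)
    dmrs <- restrict_dmrs(dmrs, retained, annotation, thresholds)
  }
  counts <- c(probes_tested = nrow(dmc), dmc_pass = nrow(pass),
              region_pass = length(dense), blood_pass = length(retained),
              dmrs = nrow(dmrs))
  list(dmc = dmc, dmc_pass = pass, region_pass = dense, blood = bm,
       retained = retained, dmrs = dmrs, counts = counts,
       thresholds = thresholds)
}
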