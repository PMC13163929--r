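#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' tunable at its default. Fields under `inputs` may point at files on
#' disk; when the `simulate` stage is enabled the generators produce the
#' corresponding objects instead and the paths are ignored.
#'
#' @param output_dir Where stage outputs and the run report are written.
#' @param seed Integer seed driving every stochastic step.
#' @return Named list.
#' @export
default_run_config <- function(output_dir = "methylmsp_run", seed = 1L) {
  list(
    output_dir = output_dir,
    seed = seed,
    stages = c("simulate", "discover", "design", "evaluate"),
    target_tissue = "Kidney",
    thresholds = dmc_thresholds(),
    blood = list(positivity_cutoff = 0.2, median_max = 0.1,
                 positivity_max = 0.02),
    design = list(strand = "top", min_len = 58L, max_len = 72L,
                  min_cpg = 6L, max_windows = 5L),
    simulate = list(n_target = 45L, n_other = 489L, delta = 0.5,
                    n_background_probes = 600L, n_blood_samples = 200L,
                    region_length = 300L, region_cpg_density = 0.06),
    inputs = list(beta = NULL, sample_sheet = NULL, annotation = NULL,
                  blood = NULL, fasta = NULL, variant_mask = NULL,
                  screens = NULL, partitions = NULL, clinical_sheet = NULL),
    missing_token = "NA"
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the biomarker development pipeline
#'
#' Orchestrates the enabled stages in order — `simulate` (generate all
#' inputs with known truth), `discover` (differential methylation through
#' DMR assembly and blood filtering), `design` (bisulphite MSP design on
#' the candidate region) and `evaluate` (replicate-screen and clinical
#' statistics) — writing each stage's outputs as plain files with stable
#' names plus a JSON report of counts and settings. A stage failure aborts
#' downstream stages; the report records partial completion.
#'
#' @param config A configuration list (see [default_run_config()]), or a
#'   path to a YAML file with overrides of the defaults.
#' @return The run report, invisibly (also written to
#'   `output_dir/report.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .merge_config(default_run_config(), config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(config$output_dir, "config.yaml"))
  report <- list(seed = config$seed, stages_run = character(0),
                 thresholds = config$thresholds, counts = list(),
                 status = "ok")
  state <- list()
  stage_defs <- list(
    simulate = .stage_simulate, discover = .stage_discover,
    design = .stage_design, evaluate = .stage_evaluate)
  for (stage in intersect(c("simulate", "discover", "design", "evaluate"),
                          config$stages)) {
    res <- tryCatch(stage_defs[[stage]](config, state, report),
                    error = function(e) e)
    if (inherits(res, "error")) {
      report$status <- paste0("failed at stage '", stage, "': ",
                              conditionMessage(res))
      break
    }
    state <- res$state
    report <- res$report
    report$stages_run <- c(report$stages_run, stage)
  }
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

.stage_simulate <- function(config, state, report) {
  sim <- config$simulate
  atlas <- simulate_beta_matrix(
    n_target = sim$n_target, n_other = sim$n_other,
    target_tissue = config$target_tissue,
    n_background_probes = sim$n_background_probes,
    planted = default_planted_dmrs(sim$delta), seed = config$seed)
  contaminated <- stats::setNames(0.05, atlas$truth$planted$probe_id[1])
  blood <- simulate_blood_reference(
    rownames(atlas$beta), n_samples = sim$n_blood_samples,
    contaminated = contaminated, seed = config$seed)
  region <- simulate_genomic_region(sim$region_length,
                                    sim$region_cpg_density,
                                    clustered = TRUE, seed = config$seed)
  cohort <- simulate_clinical_cohort(seed = config$seed)
  state$beta <- atlas$beta
  state$sheet <- atlas$sheet
  state$annotation <- atlas$annotation
  state$truth <- atlas$truth
  state$blood <- blood
  state$region <- region
  state$cohort <- cohort
  write_beta_matrix(atlas$beta,
                    file.path(config$output_dir, "beta_matrix.tsv"))
  .write_tsv(atlas$sheet, file.path(config$output_dir, "sample_sheet.tsv"))
  .write_tsv(atlas$annotation,
             file.path(config$output_dir, "probe_annotation.tsv"))
  report$counts$simulate <- list(
    probes = nrow(atlas$beta), samples = ncol(atlas$beta),
    planted_probes = nrow(atlas$truth$planted),
    blood_samples = ncol(blood), region_bp = nchar(region$seq),
    clinical_samples = nrow(cohort$sheet))
  list(state = state, report = report)
}

.stage_discover <- function(config, state, report) {
  if (is.null(state$beta)) {
    inp <- config$inputs
    if (is.null(inp$beta) || is.null(inp$sample_sheet) ||
        is.null(inp$annotation)) {
      stop("discover stage needs beta, sample_sheet and annotation inputs")
    }
    state$beta <- read_beta_matrix(inp$beta, na = config$missing_token)
    state$sheet <- read_sample_sheet(inp$sample_sheet)
    state$annotation <- read_probe_annotation(inp$annotation)
    if (!is.null(inp$blood)) {
      state$blood <- read_beta_matrix(inp$blood, na = config$missing_token)
    }
  }
  th <- do.call(dmc_thresholds, config$thresholds)
  disc <- discover_dmrs(state$beta, state$sheet, state$annotation,
                        config$target_tissue, blood = state$blood,
                        thresholds = th,
                        positivity_cutoff = config$blood$positivity_cutoff,
                        median_max = config$blood$median_max,
                        positivity_max = config$blood$positivity_max)
  state$discovery <- disc
  .write_tsv(disc$dmc, file.path(config$output_dir, "dmc_statistics.tsv"))
  .write_tsv(data.frame(probe_id = disc$retained),
             file.path(config$output_dir, "retained_probes.tsv"))
  write_regions_bed(disc$dmrs, file.path(config$output_dir, "dmrs.bed"))
  report$counts$discover <- as.list(disc$counts)
  list(state = state, report = report)
}

.stage_design <- function(config, state, report) {
  region <- state$region
  if (is.null(region)) {
    if (is.null(config$inputs$fasta)) {
      stop("design stage needs a region FASTA (or the simulate stage)")
    }
    regions <- read_region_fasta(config$inputs$fasta)
    if (!is.null(config$inputs$variant_mask)) {
      regions <- apply_variant_mask_bed(regions, config$inputs$variant_mask)
    }
    region <- regions[[1]]
  }
  d <- config$design
  res <- design_assays(region, strand = d$strand, min_len = d$min_len,
                       max_len = d$max_len, min_cpg = d$min_cpg,
                       max_windows = d$max_windows)
  state$designs <- res
  .write_tsv(res$table, file.path(config$output_dir, "designs.tsv"))
  tmpl <- Biostrings::DNAStringSet(res$template$seq)
  names(tmpl) <- sprintf("%s:%d converted_%s_%s", region$chrom, region$start,
                         res$template$strand,
                         res$template$methylation_state)
  Biostrings::writeXStringSet(tmpl, file.path(config$output_dir,
                                              "converted_template.fasta"))
  by_rating <- table(factor(vapply(res$designs, `[[`, "", "overall"),
                            levels = .rating_levels))
  report$counts$design <- list(candidate_windows = nrow(res$windows),
                               designs = length(res$designs),
                               green = unname(by_rating[["green"]]),
                               yellow = unname(by_rating[["yellow"]]),
                               red = unname(by_rating[["red"]]))
  list(state = state, report = report)
}

.stage_evaluate <- function(config, state, report) {
  screens <- NULL
  if (!is.null(config$inputs$screens)) {
    screens <- utils::read.delim(config$inputs$screens)
  } else if (!is.null(state$truth)) {
    # paired single-copy screens for the two best-performing assays
    screens <- rbind(
      as.data.frame(simulate_replicate_screen(0.17, 1.0, 343L,
                                              seed = config$seed,
                                              assay_id = "assay_4")),
      as.data.frame(simulate_replicate_screen(0.17, 0.65, 341L,
                                              seed = config$seed,
                                              assay_id = "assay_1")))
  }
  perf <- NULL
  if (!is.null(screens)) {
    perf <- do.call(rbind, lapply(seq_len(nrow(screens)), function(i)
      screen_summary(screens[i, ])))
    .write_tsv(perf, file.path(config$output_dir, "screen_performance.tsv"))
    if (nrow(screens) >= 2) {
      pairs <- utils::combn(nrow(screens), 2)
      fish <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        i1 <- pairs[1, j]; i2 <- pairs[2, j]
        data.frame(assay_a = screens$assay_id[i1],
                   assay_b = screens$assay_id[i2],
                   p_value = fisher_exact(screens$k_positive[i1],
                                          screens$n_replicates[i1],
                                          screens$k_positive[i2],
                                          screens$n_replicates[i2]),
                   stringsAsFactors = FALSE)
      }))
      .write_tsv(fish, file.path(config$output_dir, "fisher_pairwise.tsv"))
    }
  }
  cohort <- state$cohort
  if (is.null(cohort) && !is.null(config$inputs$partitions)) {
    cohort <- list(partitions = utils::read.delim(config$inputs$partitions),
                   sheet = utils::read.delim(config$inputs$clinical_sheet))
  }
  clin <- NULL
  if (!is.null(cohort)) {
    clin <- clinical_summary(cohort$partitions, cohort$sheet)
    .write_tsv(clin$per_sample,
               file.path(config$output_dir, "clinical_per_sample.tsv"))
    .write_tsv(clin$group_summary,
               file.path(config$output_dir, "clinical_groups.tsv"))
  }
  state$evaluation <- list(performance = perf, clinical = clin)
  report$counts$evaluate <- list(
    assays = if (is.null(perf)) 0L else nrow(perf),
    clinical_samples = if (is.null(clin)) 0L else nrow(clin$per_sample),
    kw_absolute_p = if (is.null(clin)) NULL else clin$kw_absolute$p_value,
    kw_relative_p = if (is.null(clin)) NULL else clin$kw_relative$p_value)
  list(state = state, report = report)
}
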