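#' Derive a reproducible sub-seed from a base seed and a purpose label
#'
#' A single integer seed drives a hierarchy of named streams so that adding
#' one generator call does not perturb the draws of the others. The mapping
#' is a simple deterministic hash kept below 2^31.
#'
#' @param seed Base integer seed.
#' @param purpose Stream label (e.g. `"beta_matrix"`).
#' @return Integer sub-seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, purpose) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(purpose)) h <- (h * 31 + ch) %% m
  as.integer(((seed %% m) * 69069 + h) %% m)
}

.with_stream <- function(seed, purpose, code) {
  withr::with_seed(derive_seed(seed, purpose), code)
}

.beta_shapes <- function(mean, concentration) {
  c(shape1 = mean * concentration, shape2 = (1 - mean) * concentration)
}

.default_other_tissues <- c("Bile duct", "Bladder", "Breast", "Cervix",
                            "Colon", "Oesophagus", "Head and Neck", "Liver",
                            "Lung", "Pancreas", "Prostate", "Rectum",
                            "Stomach", "Thymus", "Thyroid gland", "Uterus")

#' Default planted DMR layout
#'
#' Three two-probe hypermethylated regions on separate chromosomes, probes
#' spaced well within the 2.5 kb linkage distance.
#'
#' @param delta Planted beta-value increase in the target tissue.
#' @return `data.frame` with `probe_id`, `chrom`, `position`, `delta`.
#' @export
default_planted_dmrs <- function(delta = 0.5) {
  data.frame(
    probe_id = sprintf("cg_planted_%02d", 1:6),
    chrom = rep(c("chr10", "chr3", "chr7"), each = 2),
    position = c(1000000L, 1001200L, 5000000L, 5002100L, 800000L, 800400L),
    delta = delta, stringsAsFactors = FALSE)
}

#' Simulate a tissue methylation atlas with planted effects
#'
#' Emulates the statistical structure of a normal-tissue beta-value atlas:
#' background probes draw from a low-mean Beta distribution (unimodal near
#' 0, respecting the `[0, 1]` support) in every tissue; planted probes draw
#' from a Beta centred `delta` higher, but only in the target tissue.
#' Default cohort sizes mirror a realistic discovery setting: 45 target
#' samples versus 489 spread over 16 other tissues. Sporadic missingness is
#' injected uniformly at random.
#'
#' @param n_target Target-tissue discovery samples (default 45).
#' @param n_other Total other-tissue discovery samples (default 489, split
#'   near-evenly across `other_tissues`).
#' @param target_tissue Label of the target tissue (default `"Kidney"`).
#' @param other_tissues Labels for the background tissues.
#' @param n_background_probes Unplanted probes (default 600), laid out
#'   10 kb apart across chromosomes so they never cluster with planted
#'   regions.
#' @param planted Planted probe layout as from [default_planted_dmrs()];
#'   use `NULL` or a 0-row frame for a null (no-effect) matrix.
#' @param background_mean Mean background beta (default 0.03).
#' @param concentration Beta-distribution concentration (shape1 + shape2)
#'   for both components (default 20).
#' @param missing_rate Fraction of cells set missing (default 0.01).
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return List with `beta` ([beta_matrix()]), `sheet`, `annotation`, and
#'   `truth` (planted layout, per-probe deltas, seed, parameters).
#' @export
simulate_beta_matrix <- function(n_target = 45L, n_other = 489L,
                                 target_tissue = "Kidney",
                                 other_tissues = .default_other_tissues,
                                 n_background_probes = 600L,
                                 planted = default_planted_dmrs(),
                                 background_mean = 0.03,
                                 concentration = 20,
                                 missing_rate = 0.01, seed = 1L) {
  if (is.null(planted)) {
    planted <- default_planted_dmrs()[0, , drop = FALSE]
  }
  if (nrow(planted) > 0 &&
      any(background_mean + planted$delta > 1 | planted$delta < 0)) {
    stop("planted effect pushes mean beta outside [0, 1]", call. = FALSE)
  }
  n_bt <- length(other_tissues)
  base_n <- n_other %/% n_bt
  extra <- n_other %% n_bt
  other_sizes <- rep(base_n, n_bt) + rep(c(1L, 0L), c(extra, n_bt - extra))
  tissue <- c(rep(target_tissue, n_target), rep(other_tissues, other_sizes))
  sheet <- data.frame(sample_id = sprintf("S%04d", seq_along(tissue)),
                      tissue = tissue, role = "discovery",
                      group = NA_character_, stringsAsFactors = FALSE)
  bg_chroms <- sprintf("chr%d", 12:22)
  annotation <- data.frame(
    probe_id = sprintf("cg_bg_%05d", seq_len(n_background_probes)),
    chrom = rep(bg_chroms, length.out = n_background_probes),
    position = 100000L + 10000L *
      (seq_len(n_background_probes) %/% length(bg_chroms)),
    strand = "+", stringsAsFactors = FALSE)
  if (nrow(planted) > 0) {
    annotation <- rbind(annotation,
                        data.frame(probe_id = planted$probe_id,
                                   chrom = planted$chrom,
                                   position = planted$position,
                                   strand = "+", stringsAsFactors = FALSE))
  }
  n_probes <- nrow(annotation)
  n_samples <- nrow(sheet)
  bg <- .beta_shapes(background_mean, concentration)
  values <- .with_stream(seed, "beta_matrix", {
    m <- matrix(stats::rbeta(n_probes * n_samples, bg[1], bg[2]),
                nrow = n_probes)
    if (nrow(planted) > 0) {
      tgt_cols <- which(sheet$tissue == target_tissue)
      for (i in seq_len(nrow(planted))) {
        hi <- .beta_shapes(background_mean + planted$delta[i], concentration)
        row <- n_background_probes + i
        m[row, tgt_cols] <- stats::rbeta(length(tgt_cols), hi[1], hi[2])
      }
    }
    if (missing_rate > 0) {
      m[stats::runif(length(m)) < missing_rate] <- NA_real_
    }
    m
  })
  rownames(values) <- annotation$probe_id
  colnames(values) <- sheet$sample_id
  truth <- list(planted = planted, target_tissue = target_tissue,
                background_mean = background_mean,
                concentration = concentration, seed = seed)
  list(beta = beta_matrix(values), sheet = sheet, annotation = annotation,
       truth = truth)
}

#' Simulate a blood reference beta matrix
#'
#' Background probes draw from the low-mean Beta noise; contaminated
#' probes are positive (beta drawn uniformly in `[0.25, 0.8]`, always
#' above the 0.2 positivity cutoff) in the configured fraction of samples,
#' emulating sporadic blood methylation that the blood filter must catch.
#'
#' @param probe_ids Probes to simulate.
#' @param n_samples Blood samples (default 662, a whole-blood reference
#'   cohort scale).
#' @param contaminated Named numeric vector: positivity rate per
#'   contaminated probe id (others get rate 0).
#' @param background_mean,concentration Background Beta parameters.
#' @param seed Integer seed.
#' @return A [beta_matrix()].
#' @export
simulate_blood_reference <- function(probe_ids, n_samples = 662L,
                                     contaminated = numeric(0),
                                     background_mean = 0.03,
                                     concentration = 20, seed = 1L) {
  if (length(contaminated) > 0 &&
      (any(contaminated < 0) || any(contaminated > 1))) {
    stop("contamination rates must lie in [0, 1]", call. = FALSE)
  }
  bg <- .beta_shapes(background_mean, concentration)
  values <- .with_stream(seed, "blood_reference", {
    m <- matrix(stats::rbeta(length(probe_ids) * n_samples, bg[1], bg[2]),
                nrow = length(probe_ids))
    for (nm in names(contaminated)) {
      i <- match(nm, probe_ids)
      if (is.na(i)) next
      hit <- stats::runif(n_samples) < contaminated[[nm]]
      m[i, hit] <- stats::runif(sum(hit), 0.25, 0.8)
    }
    m
  })
  rownames(values) <- probe_ids
  colnames(values) <- sprintf("WB%04d", seq_len(n_samples))
  beta_matrix(values)
}

#' Simulate a genomic region with controlled CpG density
#'
#' Builds a sequence base by base: at each step a CpG dinucleotide is
#' placed with probability `cpg_density` (optionally concentrated around
#' the region centre), otherwise a single background base is drawn with GC
#' content `gc_background`, avoiding accidental CG formation so that
#' density 0 yields a CpG-free sequence.
#'
#' @param length Region length in bp.
#' @param cpg_density Per-position CpG placement probability, in
#'   `[0, 0.2]`.
#' @param gc_background Background GC fraction (default 0.4).
#' @param clustered Concentrate CpGs around the centre with a Gaussian
#'   profile (mean density preserved), emulating a CpG-island core.
#' @param seed Integer seed.
#' @param chrom,start Coordinates for the returned region.
#' @return A [genomic_region()].
#' @export
simulate_genomic_region <- function(length = 300L, cpg_density = 0.05,
                                    gc_background = 0.4, clustered = FALSE,
                                    seed = 1L, chrom = "chrSim",
                                    start = 1L) {
  if (cpg_density < 0 || cpg_density > 0.2) {
    stop("cpg_density must lie in [0, 0.2]", call. = FALSE)
  }
  dens <- rep(cpg_density, length)
  if (clustered && cpg_density > 0) {
    prof <- exp(-((seq_len(length) - length / 2)^2) / (2 * (length / 6)^2))
    dens <- cpg_density * prof / mean(prof)
    dens <- pmin(dens, 0.5)
  }
  p_gc <- gc_background / 2
  p_at <- (1 - gc_background) / 2
  seq <- .with_stream(seed, "genomic_region", {
    out <- character(length)
    i <- 1L
    prev <- ""
    while (i <= length) {
      if (i < length && stats::runif(1) < dens[i]) {
        out[i] <- "C"
        out[i + 1L] <- "G"
        prev <- "G"
        i <- i + 2L
      } else {
        b <- sample(c("A", "C", "G", "T"), 1,
                    prob = c(p_at, p_gc, p_gc, p_at))
        # avoid completing an unplanned CpG after a background C
        if (prev == "C" && b == "G") b <- "A"
        out[i] <- b
        prev <- b
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  })
  genomic_region(seq, chrom = chrom, start = start)
}

#' Simulate a single-copy replicate screen
#'
#' Replicates at mean input `lambda` copies/reaction are positive with
#' probability `1 - exp(-efficiency * lambda)` (Poisson occupancy thinned
#' by the assay's detection efficiency); the positive count is one
#' binomial draw.
#'
#' @param lambda Mean copies per reaction (>= 0).
#' @param detection_efficiency Per-molecule detection probability in
#'   `[0, 1]` (default 1).
#' @param n_replicates Number of replicate reactions (default 343).
#' @param seed Integer seed.
#' @param assay_id Label for the simulated assay.
#' @return List with `assay_id`, `n_replicates`, `k_positive`,
#'   `nominal_copies`.
#' @export
simulate_replicate_screen <- function(lambda = 0.17,
                                      detection_efficiency = 1,
                                      n_replicates = 343L, seed = 1L,
                                      assay_id = "assay") {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (detection_efficiency < 0 || detection_efficiency > 1) {
    stop("detection efficiency must lie in [0, 1]", call. = FALSE)
  }
  p <- poisson_positivity(detection_efficiency * lambda)
  k <- .with_stream(seed, paste0("replicate_screen/", assay_id),
                    stats::rbinom(1, n_replicates, p))
  list(assay_id = assay_id, n_replicates = n_replicates, k_positive = k,
       nominal_copies = lambda)
}

#' Simulate digital PCR partition counts
#'
#' @param lambda Mean copies per partition (>= 0).
#' @param n_partitions Partitions analysed (default 26000).
#' @param seed Integer seed.
#' @param sample_id,target Labels carried into the result.
#' @return One-row `data.frame` with `sample_id`, `target`,
#'   `n_partitions`, `k_positive`.
#' @export
simulate_partitions <- function(lambda, n_partitions = 26000L, seed = 1L,
                                sample_id = "sample", target = "marker") {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  k <- .with_stream(seed, paste0("partitions/", sample_id, "/", target),
                    stats::rbinom(1, n_partitions,
                                  poisson_positivity(lambda)))
  data.frame(sample_id = sample_id, target = target,
             n_partitions = n_partitions, k_positive = k,
             stringsAsFactors = FALSE)
}

#' Simulate a clinical cfDNA cohort
#'
#' Per-sample marker and total-reference partition results for a cohort of
#' clinical groups. Defaults emulate a small kidney-transplant study:
#' healthy controls (HC, n = 9), pre-transplant (Pre-Tx, n = 5), day 1
#' post-transplant (D1, n = 7) and day 7 (D7, n = 2); the kidney marker is
#' absent (`lambda = 0`) in HC and Pre-Tx, elevated at D1 and partially
#' resolved by D7, while total cfDNA is present in every group.
#'
#' @param group_sizes Named integer vector of samples per group.
#' @param marker_lambda Named per-group marker mean copies/partition.
#' @param reference_lambda Named per-group total-cfDNA mean
#'   copies/partition.
#' @param n_partitions Partitions per reaction.
#' @param reaction_to_plasma_factor Scale to copies/mL plasma.
#' @param seed Integer seed.
#' @return List with `partitions` (two rows per sample) and `sheet`
#'   (`sample_id`, `group`).
#' @export
simulate_clinical_cohort <- function(
    group_sizes = c(HC = 9L, `Pre-Tx` = 5L, D1 = 7L, D7 = 2L),
    marker_lambda = c(HC = 0, `Pre-Tx` = 0, D1 = 0.005, D7 = 0.001),
    reference_lambda = c(HC = 0.05, `Pre-Tx` = 0.03, D1 = 0.05, D7 = 0.05),
    n_partitions = 26000L, reaction_to_plasma_factor = 1, seed = 1L) {
  if (any(marker_lambda < 0) || any(reference_lambda < 0)) {
    stop("lambdas must be >= 0", call. = FALSE)
  }
  miss <- setdiff(names(group_sizes),
                  intersect(names(marker_lambda), names(reference_lambda)))
  if (length(miss) > 0) {
    stop("missing lambda for group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  sheet <- list()
  idx <- 0L
  for (g in names(group_sizes)) {
    for (j in seq_len(group_sizes[[g]])) {
      idx <- idx + 1L
      id <- sprintf("P%03d", idx)
      sheet[[idx]] <- data.frame(sample_id = id, group = g,
                                 stringsAsFactors = FALSE)
      mk <- simulate_partitions(marker_lambda[[g]], n_partitions,
                                seed = seed, sample_id = id,
                                target = "marker")
      rf <- simulate_partitions(reference_lambda[[g]], n_partitions,
                                seed = seed, sample_id = id,
                                target = "total_reference")
      rows[[length(rows) + 1L]] <- mk
      rows[[length(rows) + 1L]] <- rf
    }
  }
  partitions <- do.call(rbind, rows)
  partitions$reaction_to_plasma_factor <- reaction_to_plasma_factor
  list(partitions = partitions, sheet = do.call(rbind, sheet))
}
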