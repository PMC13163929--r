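.guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Values must parse as numbers in `[0, 1]`; the missing-value token
#' (default `"NA"`) becomes `NA`. Parse failures are reported with their
#' probe/sample location.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param na Missing-value token.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, sep = NULL, na = "NA") {
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 2) stop("beta matrix needs a probe column and at least one sample",
                         call. = FALSE)
  probes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at probe '%s', sample '%s': '%s'",
                 probes[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  out <- which(!is.na(num) & (num < 0 | num > 1), arr.ind = TRUE)
  if (nrow(out) > 0) {
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s': %s",
                 probes[out[1, 1]], colnames(vals)[out[1, 2]],
                 vals[out[1, , drop = FALSE]]), call. = FALSE)
  }
  rownames(num) <- probes
  colnames(num) <- colnames(vals)
  beta_matrix(num)
}

#' Write a beta-value matrix as tab-separated text
#'
#' Full float precision is kept; rounding happens only in reports.
#'
#' @param x A [beta_matrix()] (or numeric matrix with dimnames).
#' @param path Output path.
#' @param na Token used for missing values.
#' @export
write_beta_matrix <- function(x, path, na = "NA") {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na)
  invisible(path)
}

.sample_roles <- c("discovery", "blood_reference", "validation")

#' Read a sample sheet
#'
#' A sample sheet maps sample ids to tissue labels, a cohort role
#' (`discovery`, `blood_reference` or `validation`), and an optional
#' clinical group label (e.g. HC, Pre-Tx, D1, D7).
#'
#' @param path Delimited text with columns `sample_id`, `tissue`, `role`
#'   and optionally `group`.
#' @param sep Field separator; `NULL` auto-detects.
#' @return A `data.frame` with validated columns.
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df A data.frame to validate as a sample sheet.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "tissue", "role")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("sample sheet missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  if (any(is.na(df$tissue) | !nzchar(df$tissue))) {
    stop("empty tissue label in sample sheet", call. = FALSE)
  }
  bad <- setdiff(unique(df$role), .sample_roles)
  if (length(bad) > 0) {
    stop("unknown sample role(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.sample_roles, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$group)) df$group <- NA_character_
  df[, c("sample_id", "tissue", "role", "group")]
}

#' Read probe genomic annotation (manifest style)
#'
#' Probe coordinates follow the Illumina manifest convention: 1-based
#' position of the interrogated CpG cytosine on the given assembly.
#'
#' @param path Delimited text with columns `probe_id`, `chrom`, `position`
#'   and optionally `strand`.
#' @param sep Field separator; `NULL` auto-detects.
#' @return A `data.frame` with one row per probe.
#' @export
read_probe_annotation <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param df A data.frame to validate as probe annotation.
#' @export
probe_annotation <- function(df) {
  need <- c("probe_id", "chrom", "position")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("probe annotation missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in annotation",
                                       call. = FALSE)
  if (any(is.na(df$chrom) | !nzchar(df$chrom))) {
    stop("empty chromosome in probe annotation", call. = FALSE)
  }
  if (any(is.na(df$position) | df$position < 1)) {
    stop("probe positions must be >= 1", call. = FALSE)
  }
  if (is.null(df$strand)) df$strand <- "+"
  df[, c("probe_id", "chrom", "position", "strand")]
}

#' Write differentially methylated regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, with columns chrom, start, end, name, score (member probe
#' count) and strand. Rows are sorted by chromosome then start. An empty
#' region set produces a file holding only the header comment.
#'
#' @param dmrs `data.frame` with columns `chrom`, `start`, `end`,
#'   `n_probes`, and optionally `name` and `probe_ids`.
#' @param path Output path.
#' @export
write_regions_bed <- function(dmrs, path) {
  header <- "# chrom\tstart\tend\tname\tscore\tstrand"
  if (is.null(dmrs) || nrow(dmrs) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (any(dmrs$start < 1) || any(dmrs$end < dmrs$start)) {
    stop("DMR coordinates must satisfy 1 <= start <= end", call. = FALSE)
  }
  ord <- order(dmrs$chrom, dmrs$start, dmrs$end)
  dmrs <- dmrs[ord, , drop = FALSE]
  name <- if (!is.null(dmrs$name)) dmrs$name else
    sprintf("dmr_%d", seq_len(nrow(dmrs)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", dmrs$chrom,
                   as.integer(dmrs$start) - 1L, as.integer(dmrs$end),
                   name, as.integer(dmrs$n_probes))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED region file written by [write_regions_bed()]
#'
#' Converts back to 1-based inclusive internal coordinates.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `n_probes`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      n_probes = integer(), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(chrom = parts[, 1],
             start = as.integer(parts[, 2]) + 1L,
             end = as.integer(parts[, 3]),
             name = parts[, 4],
             n_probes = as.integer(parts[, 5]),
             stringsAsFactors = FALSE)
}

#' Read candidate regions from FASTA
#'
#' Headers of the form `chrom:start-end` (e.g. `chr10:102505468-102505700`)
#' carry absolute 1-based genomic coordinates; other headers are kept as
#' region names with `start = 1`.
#'
#' @param path FASTA file path.
#' @return List of `genomic_region` objects (see [genomic_region()]).
#' @export
read_region_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    seq <- toupper(as.character(set[[i]]))
    m <- regmatches(nm, regexec("^(\\S+):(\\d+)-(\\d+)", nm))[[1]]
    if (length(m) == 4) {
      genomic_region(seq, chrom = m[2], start = as.integer(m[3]))
    } else {
      genomic_region(seq, chrom = nm, start = 1L)
    }
  })
}

#' Construct a genomic region for assay design
#'
#' Holds an unconverted reference sequence with its coordinates and an
#' optional mask of positions overlapping known variants (SNVs/indels),
#' which assay design must avoid.
#'
#' @param seq Uppercase A/C/G/T/N string.
#' @param chrom Chromosome or region name.
#' @param start 1-based start coordinate of the first base of `seq`.
#' @param variant_mask Integer vector of masked positions, 1-based relative
#'   to `seq`.
#' @return Object of class `genomic_region`.
#' @export
genomic_region <- function(seq, chrom = "region", start = 1L,
                           variant_mask = integer(0)) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence may contain only A/C/G/T/N",
                                   call. = FALSE)
  if (length(variant_mask) > 0 &&
      (min(variant_mask) < 1 || max(variant_mask) > nchar(seq))) {
    stop("variant mask positions outside the region", call. = FALSE)
  }
  structure(list(chrom = chrom, start = as.integer(start), seq = seq,
                 variant_mask = as.integer(sort(unique(variant_mask)))),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%d-%d (%d bp, %d masked)\n", x$chrom,
              x$start, x$start + nchar(x$seq) - 1L, nchar(x$seq),
              length(x$variant_mask)))
  invisible(x)
}

#' Apply a BED variant mask to genomic regions
#'
#' Reads BED intervals (0-based half-open) and marks every overlapped base
#' of each region as masked.
#'
#' @param regions List of [genomic_region()] objects.
#' @param path BED file with at least chrom/start/end columns.
#' @return The regions with updated `variant_mask` slots.
#' @export
apply_variant_mask_bed <- function(regions, path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#|^track|^browser", lines) & nzchar(lines)]
  if (length(lines) == 0) return(regions)
  parts <- do.call(rbind, strsplit(lines, "\t"))
  bed <- data.frame(chrom = parts[, 1], start = as.integer(parts[, 2]) + 1L,
                    end = as.integer(parts[, 3]), stringsAsFactors = FALSE)
  lapply(regions, function(r) {
    hits <- bed[bed$chrom == r$chrom, , drop = FALSE]
    if (nrow(hits) == 0) return(r)
    span_end <- r$start + nchar(r$seq) - 1L
    masked <- r$variant_mask
    for (i in seq_len(nrow(hits))) {
      lo <- max(hits$start[i], r$start)
      hi <- min(hits$end[i], span_end)
      if (lo <= hi) masked <- c(masked, (lo:hi) - r$start + 1L)
    }
    r$variant_mask <- sort(unique(as.integer(masked)))
    r
  })
}

#' Read a run configuration file
#'
#' YAML key/value configuration holding input paths, thresholds, seed and
#' output directory for [run_pipeline()]. Unknown keys are kept verbatim.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg
}
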