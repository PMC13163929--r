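#' Compute a beta-value from methylated/unmethylated probe intensities
#'
#' The Illumina beta-value is the ratio of methylated probe intensity to the
#' sum of methylated and unmethylated intensities plus a stabilising offset
#' of 100: `M / (M + U + 100)`. It ranges from 0 (fully unmethylated)
#' towards, but never reaching, 1 (fully methylated).
#'
#' @param M Methylated probe intensity, finite and non-negative. Vectorised.
#' @param U Unmethylated probe intensity, finite and non-negative.
#' @return Numeric vector of beta fractions in `[0, 1)`.
#' @examples
#' beta_from_intensities(900, 0)   # 0.9
#' beta_from_intensities(450, 450) # 0.45
#' @export
beta_from_intensities <- function(M, U) {
  if (!is.numeric(M) || !is.numeric(U)) {
    stop("intensities must be numeric", call. = FALSE)
  }
  if (any(!is.finite(M)) || any(!is.finite(U))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(M < 0) || any(U < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  M / (M + U + 100)
}

#' Convert beta fractions to percent methylation
#'
#' Display-only scaling of beta-values to percentages. Statistical analyses
#' should always use the original beta fractions; this helper exists for
#' reporting and plotting.
#'
#' @param beta Numeric vector of beta fractions in `[0, 1]` (`NA` allowed).
#' @return `beta * 100`.
#' @export
beta_to_percent <- function(beta) {
  if (!is.numeric(beta)) stop("beta must be numeric", call. = FALSE)
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop("beta values outside [0, 1]: ",
         paste(utils::head(beta[bad], 5), collapse = ", "), call. = FALSE)
  }
  beta * 100
}

#' Construct a validated beta-value matrix
#'
#' A `beta_matrix` is a plain numeric matrix (probes in rows, samples in
#' columns) whose entries are methylation fractions in `[0, 1]`, with `NA`
#' marking missing probes. The constructor enforces unique probe and sample
#' identifiers and the value range.
#'
#' @param values Numeric matrix with rownames (probe ids) and colnames
#'   (sample ids).
#' @return The matrix with class `beta_matrix` prepended.
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix needs probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s': %g",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @rdname beta_matrix
#' @param x Object to test.
#' @export
is_beta_matrix <- function(x) inherits(x, "beta_matrix")
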