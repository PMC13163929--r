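#' Concentrations of a geometric dilution series
#'
#' @param start Starting concentration (copies/reaction), > 0.
#' @param fold Dilution factor between points, > 1.
#' @param n_points Number of points, >= 1.
#' @return Numeric vector `start / fold^(0:(n_points-1))`.
#' @examples
#' dilution_series_points(500, 2.5, 7)  # 500 ... 2.048
#' @export
dilution_series_points <- function(start, fold, n_points) {
  if (!is.numeric(start) || start <= 0) stop("start must be > 0",
                                             call. = FALSE)
  if (!is.numeric(fold) || fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  start / fold^(seq_len(n_points) - 1)
}

#' Expected positive fraction under a Poisson single-molecule model
#'
#' With template molecules distributed Poisson across reactions at mean
#' `lambda` copies/reaction, a reaction is positive when it receives at
#' least one molecule: `1 - exp(-lambda)`.
#'
#' @param lambda Mean copies per reaction, >= 0. Vectorised.
#' @return Expected positive fraction in `[0, 1)`.
#' @export
poisson_positivity <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("lambda must be finite and >= 0", call. = FALSE)
  }
  1 - exp(-lambda)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Interval from beta distribution quantiles; the lower bound is 0 when
#' `k = 0` and the upper bound is 1 when `k = n`.
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials, >= 1.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `level`, `method`, `estimate`.
#' @examples
#' clopper_pearson(69, 343)  # approx (0.160, 0.248)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integer counts with 0 <= k <= n, n >= 1", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  list(lower = lower, upper = upper, level = level,
       method = "clopper-pearson", estimate = k / n)
}

#' Two-sided Fisher's exact test on two positivity counts
#'
#' Exact test on the 2x2 table `(k1, n1-k1; k2, n2-k2)`, two-sided by the
#' usual probability-mass convention (summing hypergeometric probabilities
#' no larger than the observed table's).
#'
#' @param k1,n1 Positives and total for the first assay/group.
#' @param k2,n2 Positives and total for the second.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(k1, n1, k2, n2) {
  counts <- c(k1, n1, k2, n2)
  if (any(counts < 0) || any(counts != round(counts)) ||
      k1 > n1 || k2 > n2 || n1 < 1 || n2 < 1) {
    stop("need integer counts with 0 <= k <= n", call. = FALSE)
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Digital PCR concentration from partition counts
#'
#' With molecules Poisson-distributed over `n` partitions, the mean
#' occupancy is `lambda = -ln(1 - k/n)` where `k` partitions are positive.
#' Copies/reaction is `lambda * n`, and copies per mL plasma scales by the
#' reaction-to-plasma factor. A Clopper-Pearson interval on `k/n`
#' propagates to `lambda` and the derived quantities.
#'
#' @param k Positive partitions (0 <= k < n; `k = n` means saturation and
#'   is an error).
#' @param n_partitions Total partitions analysed.
#' @param reaction_to_plasma_factor Scale from copies/reaction to
#'   copies/mL plasma (1 when the reaction held the cfDNA of exactly 1 mL).
#' @param level Confidence level for the propagated interval.
#' @return List with `lambda`, `copies_per_reaction`, `copies_per_ml`,
#'   each with a `*_ci` two-vector, plus `k`, `n_partitions`.
#' @export
dpcr_concentration <- function(k, n_partitions, reaction_to_plasma_factor = 1,
                               level = 0.95) {
  if (is.na(k)) stop("k must be defined", call. = FALSE)
  if (k < 0 || k != round(k) || n_partitions < 1) {
    stop("need integer 0 <= k and n_partitions >= 1", call. = FALSE)
  }
  if (k >= n_partitions) {
    stop("all partitions positive: saturated, concentration undefined",
         call. = FALSE)
  }
  ci <- clopper_pearson(k, n_partitions, level)
  lambda <- -log(1 - k / n_partitions)
  lambda_ci <- c(-log(1 - ci$lower), -log(1 - ci$upper))
  cpr <- lambda * n_partitions
  cpr_ci <- lambda_ci * n_partitions
  list(lambda = lambda, lambda_ci = lambda_ci,
       copies_per_reaction = cpr, copies_per_reaction_ci = cpr_ci,
       copies_per_ml = cpr * reaction_to_plasma_factor,
       copies_per_ml_ci = cpr_ci * reaction_to_plasma_factor,
       k = k, n_partitions = n_partitions, level = level)
}

#' Marker signal as a percentage of total cfDNA
#'
#' @param target_copies Marker copies (>= 0). Vectorised.
#' @param reference_copies Total-cfDNA reference copies (> 0; zero yields
#'   `NA` with a warning — percent methylation is undefined without
#'   reference signal).
#' @return `100 * target / reference`.
#' @export
percent_methylation <- function(target_copies, reference_copies) {
  if (any(target_copies < 0, na.rm = TRUE)) {
    stop("target copies must be >= 0", call. = FALSE)
  }
  zero <- !is.na(reference_copies) & reference_copies <= 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero reference copies: percent ",
            "methylation undefined, reported as NA")
    reference_copies[zero] <- NA_real_
  }
  100 * target_copies / reference_copies
}

.kw_statistic <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  sums <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
  tab <- table(values)
  tie <- 1 - sum(tab^3 - tab) / (N^3 - N)
  if (tie > 0) H <- H / tie
  H
}

# enumerate all distinct assignments of indices into groups of given sizes
.kw_exact_p <- function(values, groups) {
  sizes <- table(groups)
  obs <- .kw_statistic(values, groups)
  n <- length(values)
  total <- 0
  extreme <- 0
  recurse <- function(remaining, assigned_groups, assigned_idx) {
    if (length(assigned_groups) == length(sizes)) {
      lab <- integer(n)
      for (g in seq_along(assigned_idx)) lab[assigned_idx[[g]]] <- g
      total <<- total + 1
      if (.kw_statistic(values, lab) >= obs - 1e-10) extreme <<- extreme + 1
      return(invisible())
    }
    g <- length(assigned_groups) + 1L
    k <- sizes[[g]]
    if (g == length(sizes)) {
      recurse(integer(0), c(assigned_groups, g),
              c(assigned_idx, list(remaining)))
    } else {
      picks <- utils::combn(remaining, k, simplify = FALSE)
      for (p in picks) {
        recurse(setdiff(remaining, p), c(assigned_groups, g),
                c(assigned_idx, list(p)))
      }
    }
  }
  recurse(seq_len(n), integer(0), list())
  extreme / total
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `groups - 1`
#' degrees of freedom. For small studies (`exact = TRUE`, practical for
#' total n up to about 10) the p-value is instead computed by full
#' enumeration of the distinct assignments of observations to groups.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 1 value.
#' @param exact Use the enumeration p-value (default `FALSE`).
#' @return List with `statistic` (H), `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  values <- unlist(groups)
  lab <- rep(seq_along(groups), lengths(groups))
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                method = "degenerate"))
  }
  if (exact) {
    H <- .kw_statistic(values, lab)
    return(list(statistic = H, df = length(groups) - 1L,
                p_value = .kw_exact_p(values, lab), method = "exact"))
  }
  kt <- stats::kruskal.test(values, factor(lab))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "chi-square")
}

#' Reconstruct screen counts from printed positivity rate and interval
#'
#' Finds the positive/total counts behind a reported positivity percentage
#' when only the rate (at one decimal place), an approximate replicate
#' range, and the reported confidence interval are available. Candidates
#' must reproduce the printed rate exactly at its precision and have an
#' exact binomial interval within `ci_tol` percentage points of the printed
#' one at both ends; among those the count pair whose exact rate is closest
#' to the printed value is returned.
#'
#' @param rate_percent Printed positivity rate, in percent, one decimal.
#' @param ci_percent Printed `c(lower, upper)` interval, in percent.
#' @param n_range Candidate replicate totals (e.g. `338:343`).
#' @param level Confidence level of the printed interval.
#' @param ci_tol Tolerated absolute CI deviation in percentage points
#'   (default 0.1; the publication's interval method is typically
#'   unstated, so the interval is a consistency check, not an exact
#'   constraint).
#' @return List with `k`, `n`, `rate_percent` (exact), `ci` (exact
#'   binomial, percent).
#' @export
reconstruct_screen_counts <- function(rate_percent, ci_percent,
                                      n_range = 338:343, level = 0.95,
                                      ci_tol = 0.1) {
  best <- NULL
  for (n in n_range) {
    ks <- which(round(100 * (0:n) / n, 1) == rate_percent) - 1L
    for (k in ks) {
      ci <- clopper_pearson(k, n, level)
      dev <- max(abs(100 * c(ci$lower, ci$upper) - ci_percent))
      if (dev > ci_tol) next
      gap <- abs(100 * k / n - rate_percent)
      if (is.null(best) || gap < best$gap) {
        best <- list(k = k, n = n, gap = gap,
                     rate_percent = 100 * k / n,
                     ci = 100 * c(ci$lower, ci$upper))
      }
    }
  }
  if (is.null(best)) {
    stop("no count pair consistent with the printed rate and interval",
         call. = FALSE)
  }
  best$gap <- NULL
  best
}

#' Summarise a replicate screen
#'
#' Positivity with its exact binomial interval, alongside the positivity
#' expected from the Poisson single-molecule model at the nominal input.
#'
#' @param screen List or one-row data.frame with `assay_id`,
#'   `n_replicates`, `k_positive`, `nominal_copies`.
#' @param level Confidence level.
#' @return One-row `data.frame`.
#' @export
screen_summary <- function(screen, level = 0.95) {
  ci <- clopper_pearson(screen$k_positive, screen$n_replicates, level)
  data.frame(assay_id = screen$assay_id,
             n_replicates = screen$n_replicates,
             k_positive = screen$k_positive,
             positivity = ci$estimate,
             ci_lower = ci$lower, ci_upper = ci$upper,
             nominal_copies = screen$nominal_copies,
             expected_positivity = poisson_positivity(screen$nominal_copies),
             stringsAsFactors = FALSE)
}

#' Per-sample quantification and clinical group comparison
#'
#' For each sample with both a marker and a total-reference partition
#' result, computes absolute marker concentration (copies/mL plasma) and
#' the marker as a percentage of total cfDNA, then summarises per clinical
#' group (median, IQR) and tests both measures across groups with
#' Kruskal-Wallis. Samples missing either target are excluded with a
#' warning; undetected markers count as 0 copies, not missing.
#'
#' @param partitions `data.frame` with columns `sample_id`, `target`
#'   (`"marker"` or `"total_reference"`), `n_partitions`, `k_positive`,
#'   and optionally `reaction_to_plasma_factor` (default 1).
#' @param sheet `data.frame` with `sample_id` and `group`.
#' @return List with `per_sample`, `group_summary`, `kw_absolute`,
#'   `kw_relative`.
#' @export
clinical_summary <- function(partitions, sheet) {
  if (is.null(partitions$reaction_to_plasma_factor)) {
    partitions$reaction_to_plasma_factor <- 1
  }
  ids <- unique(partitions$sample_id)
  rows <- list()
  skipped <- character(0)
  for (id in ids) {
    sub <- partitions[partitions$sample_id == id, , drop = FALSE]
    mk <- sub[sub$target == "marker", , drop = FALSE]
    rf <- sub[sub$target == "total_reference", , drop = FALSE]
    if (nrow(mk) != 1 || nrow(rf) != 1) {
      skipped <- c(skipped, id)
      next
    }
    mq <- dpcr_concentration(mk$k_positive, mk$n_partitions,
                             mk$reaction_to_plasma_factor)
    rq <- dpcr_concentration(rf$k_positive, rf$n_partitions,
                             rf$reaction_to_plasma_factor)
    pct <- if (rq$copies_per_ml > 0) {
      100 * mq$copies_per_ml / rq$copies_per_ml
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = id,
      group = sheet$group[match(id, sheet$sample_id)],
      marker_copies_per_ml = mq$copies_per_ml,
      total_copies_per_ml = rq$copies_per_ml,
      percent_of_total = pct, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("sample(s) missing marker or reference result, excluded: ",
            paste(skipped, collapse = ", "))
  }
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample) || length(unique(per_sample$group)) < 2) {
    stop("group comparison needs >= 2 groups with quantified samples",
         call. = FALSE)
  }
  summ <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               marker_median = stats::median(g$marker_copies_per_ml),
               marker_iqr = stats::IQR(g$marker_copies_per_ml),
               total_median = stats::median(g$total_copies_per_ml),
               percent_median = stats::median(g$percent_of_total, na.rm = TRUE),
               percent_iqr = stats::IQR(g$percent_of_total, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  groups_abs <- split(per_sample$marker_copies_per_ml, per_sample$group)
  groups_rel <- split(per_sample$percent_of_total, per_sample$group)
  list(per_sample = per_sample, group_summary = summ,
       kw_absolute = kruskal_wallis(groups_abs),
       kw_relative = kruskal_wallis(groups_rel))
}
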