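#' Enumerate candidate MSP amplicon windows
#'
#' All windows of the converted template whose length lies in
#' `[min_len, max_len]` (default 58-72 bp, short enough for fragmented
#' cfDNA) and which contain at least `min_cpg` retained CpG cytosines —
#' enough to place two CpGs on each of the three oligonucleotides. Windows
#' are sorted by CpG count (descending) then start.
#'
#' @param template A `converted_template` from [bisulfite_convert()]
#'   (methylated state; an unmethylated template retains no CpG and yields
#'   no windows).
#' @param min_len,max_len Amplicon length bounds in bp.
#' @param min_cpg Minimum CpG cytosines fully inside the window.
#' @return `data.frame` with `start`, `end`, `length`, `n_cpg` (template
#'   coordinates, 1-based inclusive).
#' @export
enumerate_amplicons <- function(template, min_len = 58L, max_len = 72L,
                                min_cpg = 6L) {
  stopifnot(inherits(template, "converted_template"))
  n <- nchar(template$seq)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      n_cpg = integer())
  if (n < min_len) {
    warning("template shorter than min_len; no candidate windows")
    return(empty)
  }
  cpg <- template$cpg_positions
  ind <- integer(n)
  ind[cpg] <- 1L
  cum <- c(0L, cumsum(ind))
  rows <- list()
  for (len in seq.int(min_len, min(max_len, n))) {
    starts <- seq_len(n - len + 1L)
    ends <- starts + len - 1L
    # a CpG is inside the window when both its C and G are: C at p <= end-1
    counts <- cum[ends] - cum[starts]
    keep <- counts >= min_cpg
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(start = starts[keep],
                                              end = ends[keep],
                                              length = len,
                                              n_cpg = counts[keep])
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_cpg, out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.max_run <- function(seq, base = "G") {
  r <- rle(strsplit(seq, "")[[1]])
  runs <- r$lengths[r$values == base]
  if (length(runs) == 0) 0L else max(runs)
}

.oligo_record <- function(template, role, start, end, ch_pos) {
  span <- start:end
  raw <- substr(template$seq, start, end)
  seq <- if (role == "reverse") .revcomp(raw) else raw
  n_cpg <- sum(template$cpg_positions >= start & template$cpg_positions <= end)
  list(role = role, seq = seq, start = start, end = end,
       n_cpg = n_cpg,
       n_ch = sum(ch_pos >= start & ch_pos <= end),
       gc_fraction = mean(strsplit(seq, "")[[1]] %in% c("G", "C")),
       three_prime_on_cpg = role %in% c("forward", "reverse"),
       max_g_run = .max_run(seq, "G"),
       tm_wallace = {
         b <- strsplit(seq, "")[[1]]
         2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
       })
}

#' Design MSP primer/probe sets for a candidate amplicon window
#'
#' Enumerates forward primers anchored at the window start, reverse primers
#' (reverse-complement of the converted sense strand) anchored at the
#' window end, and an internal hydrolysis probe, then combines them into
#' scored candidates. Hard constraints, enforced on every emitted design:
#'
#' * each oligo spans at least `min_cpg_per_oligo` (default 2) CpGs;
#' * the forward primer's 3' terminal base is the C of a CpG and the
#'   reverse primer's 3' terminal base pairs with the C of a CpG
#'   (methylation specificity);
#' * no oligo overlaps a masked variant position or an ambiguous base (N);
#' * the probe does not cover either primer's 3' terminal position, and the
#'   primer binding sites do not overlap each other.
#'
#' When no design satisfies the constraints an empty list is returned whose
#' `"failure_counts"` attribute names how many candidate oligos each
#' constraint rejected.
#'
#' @param template A methylated `converted_template`.
#' @param window One row of [enumerate_amplicons()] output (or a list with
#'   `start` and `end` in template coordinates).
#' @param primer_len,probe_len Length ranges (nt), defaults 18-30.
#' @param min_cpg_per_oligo Minimum CpGs per oligo (default 2).
#' @param mask Integer template positions overlapping known variants.
#' @param max_per_role Candidate oligos kept per role before combination
#'   (most CpG-dense first); keeps the search bounded.
#' @param max_candidates Maximum scored designs returned.
#' @return List of `amplicon_design` objects (scored, unranked).
#' @export
design_oligos <- function(template, window, primer_len = c(18L, 30L),
                          probe_len = c(18L, 30L), min_cpg_per_oligo = 2L,
                          mask = integer(0), max_per_role = 8L,
                          max_candidates = 50L) {
  stopifnot(inherits(template, "converted_template"))
  if (template$methylation_state != "methylated") {
    stop("design requires the methylated converted template", call. = FALSE)
  }
  a0 <- as.integer(window$start)
  a1 <- as.integer(window$end)
  amp_len <- a1 - a0 + 1L
  cpg <- template$cpg_positions
  src <- strsplit(template$source_seq, "")[[1]]
  ch_pos <- setdiff(which(src == "C"), cpg)
  bad_pos <- sort(unique(c(as.integer(mask), which(src == "N"))))
  fails <- c(forward_three_prime_not_cpg = 0L, forward_too_few_cpg = 0L,
             forward_excluded_position = 0L, reverse_three_prime_not_cpg = 0L,
             reverse_too_few_cpg = 0L, reverse_excluded_position = 0L,
             probe_too_few_cpg = 0L, probe_excluded_position = 0L,
             probe_overlaps_primer_three_prime = 0L, primer_overlap = 0L,
             probe_not_flanked = 0L)
  count_in <- function(pos, lo, hi) sum(pos >= lo & pos <= hi)

  fwd <- list()
  for (l in seq.int(primer_len[1], primer_len[2])) {
    fe <- a0 + l - 1L
    if (fe >= a1) break
    if (!(fe %in% cpg)) { fails["forward_three_prime_not_cpg"] <-
      fails["forward_three_prime_not_cpg"] + 1L; next }
    if (count_in(cpg, a0, fe) < min_cpg_per_oligo) {
      fails["forward_too_few_cpg"] <- fails["forward_too_few_cpg"] + 1L; next }
    if (count_in(bad_pos, a0, fe) > 0) {
      fails["forward_excluded_position"] <-
        fails["forward_excluded_position"] + 1L; next }
    fwd[[length(fwd) + 1L]] <- .oligo_record(template, "forward", a0, fe,
                                             ch_pos)
  }
  rev <- list()
  for (l in seq.int(primer_len[1], primer_len[2])) {
    rs <- a1 - l + 1L
    if (rs <= a0) break
    if (!(rs %in% cpg)) { fails["reverse_three_prime_not_cpg"] <-
      fails["reverse_three_prime_not_cpg"] + 1L; next }
    if (count_in(cpg, rs, a1) < min_cpg_per_oligo) {
      fails["reverse_too_few_cpg"] <- fails["reverse_too_few_cpg"] + 1L; next }
    if (count_in(bad_pos, rs, a1) > 0) {
      fails["reverse_excluded_position"] <-
        fails["reverse_excluded_position"] + 1L; next }
    rev[[length(rev) + 1L]] <- .oligo_record(template, "reverse", rs, a1,
                                             ch_pos)
  }
  prb <- list()
  for (l in seq.int(probe_len[1], probe_len[2])) {
    if (l > amp_len - 2L) break
    for (s in seq.int(a0 + 1L, a1 - l)) {
      e <- s + l - 1L
      if (count_in(cpg, s, e) < min_cpg_per_oligo) {
        fails["probe_too_few_cpg"] <- fails["probe_too_few_cpg"] + 1L; next }
      if (count_in(bad_pos, s, e) > 0) {
        fails["probe_excluded_position"] <-
          fails["probe_excluded_position"] + 1L; next }
      prb[[length(prb) + 1L]] <- .oligo_record(template, "probe", s, e,
                                               ch_pos)
    }
  }
  keep_top <- function(x, k) {
    if (length(x) <= k) return(x)
    ord <- order(-vapply(x, `[[`, 0, "n_cpg"),
                 vapply(x, function(o) o$end - o$start, 0))
    x[ord[seq_len(k)]]
  }
  fwd <- keep_top(fwd, max_per_role)
  rev <- keep_top(rev, max_per_role)
  prb <- keep_top(prb, 4L * max_per_role)

  designs <- list()
  for (f in fwd) for (r in rev) {
    if (f$end >= r$start) { fails["primer_overlap"] <-
      fails["primer_overlap"] + 1L; next }
    for (p in prb) {
      if (p$start <= f$end && f$end <= p$end ||
          p$start <= r$start && r$start <= p$end) {
        fails["probe_overlaps_primer_three_prime"] <-
          fails["probe_overlaps_primer_three_prime"] + 1L
        next
      }
      if (p$start <= a0 || p$end >= a1) {
        fails["probe_not_flanked"] <- fails["probe_not_flanked"] + 1L
        next
      }
      d <- structure(list(start = a0, end = a1, length = amp_len,
                          oligos = list(forward = f, reverse = r, probe = p),
                          n_cpg_total = f$n_cpg + r$n_cpg + p$n_cpg,
                          ratings = NULL, overall = NULL),
                     class = "amplicon_design")
      designs[[length(designs) + 1L]] <- score_design(d)
      if (length(designs) >= max_candidates) {
        attr(designs, "failure_counts") <- fails
        return(designs)
      }
    }
  }
  attr(designs, "failure_counts") <- fails
  designs
}

.rating_levels <- c("green", "yellow", "red")

.rate_length <- function(len) {
  if (len >= 58 && len <= 72) "green"
  else if (len > 72 && len <= 120) "yellow"
  else if (len > 120) "red"
  else "yellow"  # shorter than the cfDNA-optimised range: suboptimal
}

.rate_gc <- function(gc) {
  if (gc >= 0.40 && gc <= 0.60) "green"
  else if (gc >= 0.35 && gc <= 0.65) "yellow"
  else "red"
}

.rate_ch <- function(n_ch) {
  if (n_ch >= 3) "green" else if (n_ch >= 1) "yellow" else "red"
}

.rate_polyg <- function(run) {
  if (run <= 3) "green" else if (run == 4) "yellow" else "red"
}

#' Traffic-light scoring of an amplicon design
#'
#' Rates each criterion green (optimal), yellow (suboptimal but
#' acceptable) or red (increased risk of technical problems): amplicon
#' length (green 58-72 bp, yellow up to the conventional 120 bp, red
#' beyond), per-oligo GC fraction (green 40%-60%, yellow within 5
#' percentage points outside, else red), per-oligo non-CpG cytosine (CH)
#' count which enforces conversion specificity (green >= 3, yellow 1-2,
#' red 0), and per-oligo longest poly-G run (green <= 3, yellow 4, red
#' >= 5). The overall rating is the worst across criteria and oligos.
#'
#' @param design An `amplicon_design` satisfying the hard constraints.
#' @return The design with `ratings` (named character vector) and
#'   `overall` filled in.
#' @export
score_design <- function(design) {
  r <- c(amplicon_length = .rate_length(design$length))
  for (role in c("forward", "reverse", "probe")) {
    o <- design$oligos[[role]]
    r[paste0("gc_", role)] <- .rate_gc(o$gc_fraction)
    r[paste0("ch_", role)] <- .rate_ch(o$n_ch)
    r[paste0("polyg_", role)] <- .rate_polyg(o$max_g_run)
  }
  design$ratings <- r
  design$overall <- .rating_levels[max(match(r, .rating_levels))]
  design
}

#' Deterministically rank scored designs
#'
#' Order: overall rating (green before yellow before red), then more CpGs
#' covered in total, then shorter amplicon, then leftmost start, with
#' remaining ties broken lexicographically by the concatenated oligo
#' sequences (stable).
#'
#' @param designs List of scored `amplicon_design` objects.
#' @return The same designs, reordered.
#' @export
rank_designs <- function(designs) {
  if (length(designs) == 0) return(designs)
  key_rating <- vapply(designs, function(d) match(d$overall, .rating_levels),
                       0)
  key_cpg <- vapply(designs, `[[`, 0, "n_cpg_total")
  key_len <- vapply(designs, `[[`, 0, "length")
  key_start <- vapply(designs, `[[`, 0, "start")
  key_seq <- vapply(designs, function(d)
    paste(d$oligos$forward$seq, d$oligos$reverse$seq, d$oligos$probe$seq),
    "")
  designs[order(key_rating, -key_cpg, key_len, key_start, key_seq)]
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat(sprintf("<amplicon_design> %d-%d (%d bp), %d CpG total, overall %s\n",
              x$start, x$end, x$length, x$n_cpg_total, x$overall))
  invisible(x)
}

#' Summarise designs as a data frame
#'
#' One row per design with amplicon coordinates, oligo sequences and
#' statistics, per-criterion ratings and the overall traffic light.
#' Melting temperatures (Wallace rule, degrees C) are informational only.
#'
#' @param designs List of scored `amplicon_design` objects.
#' @param region_start Absolute 1-based coordinate of template position 1
#'   (adds `abs_start`/`abs_end` columns when not `NULL`).
#' @return `data.frame`, one row per design.
#' @export
design_table <- function(designs, region_start = NULL) {
  if (length(designs) == 0) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      n_cpg_total = integer(), overall = character()))
  }
  rows <- lapply(designs, function(d) {
    row <- data.frame(start = d$start, end = d$end, length = d$length,
                      n_cpg_total = d$n_cpg_total, overall = d$overall,
                      stringsAsFactors = FALSE)
    for (role in c("forward", "reverse", "probe")) {
      o <- d$oligos[[role]]
      row[[paste0(role, "_seq")]] <- o$seq
      row[[paste0(role, "_n_cpg")]] <- o$n_cpg
      row[[paste0(role, "_n_ch")]] <- o$n_ch
      row[[paste0(role, "_gc")]] <- round(o$gc_fraction, 3)
      row[[paste0(role, "_tm")]] <- o$tm_wallace
    }
    for (nm in names(d$ratings)) row[[paste0("rating_", nm)]] <- d$ratings[[nm]]
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(region_start)) {
    out$abs_start <- out$start + region_start - 1L
    out$abs_end <- out$end + region_start - 1L
  }
  rownames(out) <- NULL
  out
}

#' End-to-end MSP assay design for a genomic region
#'
#' Converts the region in silico (methylated state, chosen strand),
#' enumerates candidate amplicon windows, designs and scores primer/probe
#' sets for the most CpG-dense windows, and returns the ranked candidates.
#'
#' @param region A [genomic_region()] (carrying any variant mask) or a
#'   plain sequence string.
#' @param strand Strand to design on (default `"top"`).
#' @param min_len,max_len Amplicon length bounds (default 58-72 bp).
#' @param min_cpg Minimum CpGs per window (default 6).
#' @param max_windows Number of top windows to attempt designs in.
#' @param ... Passed to [design_oligos()].
#' @return List with `template`, `windows`, `designs` (ranked), `table`
#'   (via [design_table()]) and `failure_counts` (aggregate).
#' @export
design_assays <- function(region, strand = "top", min_len = 58L,
                          max_len = 72L, min_cpg = 6L, max_windows = 10L,
                          ...) {
  if (is.character(region)) region <- genomic_region(region)
  template <- bisulfite_convert(region$seq, "methylated", strand)
  n <- nchar(region$seq)
  mask <- region$variant_mask
  if (strand == "bottom" && length(mask) > 0) mask <- n - mask + 1L
  windows <- enumerate_amplicons(template, min_len, max_len, min_cpg)
  designs <- list()
  fail_total <- NULL
  for (i in seq_len(min(nrow(windows), max_windows))) {
    cand <- design_oligos(template, windows[i, ], mask = mask, ...)
    fc <- attr(cand, "failure_counts")
    fail_total <- if (is.null(fail_total)) fc else fail_total + fc
    designs <- c(designs, cand)
  }
  designs <- rank_designs(designs)
  list(template = template, windows = windows, designs = designs,
       table = design_table(designs, region_start = region$start),
       failure_counts = fail_total)
}
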