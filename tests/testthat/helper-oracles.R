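# Independent brute-force oracles used to validate the fast implementations.

# Exact two-sided rank-sum p by full enumeration of rank assignments:
# distance of the Mann-Whitney U from the centre of its support.
oracle_rank_sum_exact <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  centre_dist <- function(u) min(u, na * nb - u)
  sets <- utils::combn(na + nb, na, simplify = FALSE)
  us <- vapply(sets, function(s) sum(r[s]) - na * (na + 1) / 2, numeric(1))
  mean(vapply(us, centre_dist, numeric(1)) <= centre_dist(u_obs))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins.
oracle_fisher <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  lo <- max(0, m - n2)
  hi <- min(m, n1)
  xs <- lo:hi
  d <- stats::dhyper(xs, n1, n2, m)
  sum(d[d <= d[xs == k1] * (1 + 1e-7)])
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  running <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(running, 1)
  adj
}

# Kruskal-Wallis H (tie corrected), independent of the package internals.
oracle_kw_H <- function(values, lab) {
  unname(stats::kruskal.test(values, factor(lab))$statistic)
}

# Permutation p for Kruskal-Wallis by enumerating ALL permutations of the
# pooled values (feasible for total n <= 7).
oracle_kw_perm <- function(groups) {
  values <- unlist(groups)
  lab <- rep(seq_along(groups), lengths(groups))
  n <- length(values)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- oracle_kw_H(values, lab)
  hs <- vapply(perms(seq_len(n)),
               function(p) oracle_kw_H(values[p], lab), numeric(1))
  mean(hs >= obs - 1e-10)
}

# Transitive closure clustering of probes: all-pairs adjacency (same chrom,
# distance <= half) closed under composition; returns cluster labels.
oracle_cluster_closure <- function(chrom, position, half) {
  n <- length(position)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(position[i] - position[j]) <= half)
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  match(apply(adj, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(adj, 1, function(r) paste(which(r), collapse = ","))))
}

# Regex-based bisulphite conversion oracle (top strand).
oracle_convert <- function(seq, state) {
  if (state == "methylated") gsub("C(?!G)", "T", seq, perl = TRUE)
  else gsub("C", "T", seq, fixed = TRUE)
}

revcomp_chr <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Audit that a design satisfies every hard constraint on its template.
expect_hard_constraints <- function(design, template, mask = integer(0),
                                    min_cpg = 2L) {
  cpg <- template$cpg_positions
  f <- design$oligos$forward
  r <- design$oligos$reverse
  p <- design$oligos$probe
  expect_gte(design$length, 58)
  expect_lte(design$length, 72)
  expect_true(f$end %in% cpg)                    # forward 3' on CpG C
  expect_true(r$start %in% cpg)                  # reverse 3' pairs a CpG C
  for (o in list(f, r, p)) {
    expect_gte(o$n_cpg, min_cpg)
    expect_length(intersect(o$start:o$end, mask), 0)
    expect_false(grepl("N", o$seq))
  }
  expect_lt(f$end, r$start)                      # primers do not overlap
  expect_false(p$start <= f$end && f$end <= p$end)
  expect_false(p$start <= r$start && r$start <= p$end)
}
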