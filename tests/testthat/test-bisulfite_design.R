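test_that("bisulphite conversion applies the CpG rule", {
  expect_equal(bisulfite_convert("ACGGACCGA", "methylated")$seq,
               "ACGGATCGA")
  expect_equal(bisulfite_convert("ACGGACCGA", "unmethylated")$seq,
               "ATGGATTGA")
  expect_equal(bisulfite_convert("ATTGA", "methylated")$seq, "ATTGA")
  expect_error(bisulfite_convert("ACGU", "methylated"), "invalid character")
  # terminal C cannot be called CpG: converted and flagged
  ct <- bisulfite_convert("ATC", "methylated")
  expect_equal(ct$seq, "ATT")
  expect_true(ct$ambiguous_terminal_c)
})

test_that("conversion preserves exactly the CpG cytosines (all octamers)", {
  bases <- c("A", "C", "G", "T")
  octs <- do.call(paste0, expand.grid(rep(list(bases), 8),
                                      stringsAsFactors = FALSE))
  meth <- vapply(octs, function(s)
    bisulfite_convert(s, "methylated")$seq, "", USE.NAMES = FALSE)
  unmeth <- vapply(octs, function(s)
    bisulfite_convert(s, "unmethylated")$seq, "", USE.NAMES = FALSE)
  expect_identical(meth, vapply(octs, oracle_convert, "",
                                state = "methylated", USE.NAMES = FALSE))
  expect_identical(unmeth, vapply(octs, oracle_convert, "",
                                  state = "unmethylated", USE.NAMES = FALSE))
  expect_false(any(grepl("C", unmeth)))
})

test_that("conversion is idempotent on unmethylated templates", {
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    once <- bisulfite_convert(s, "unmethylated")$seq
    expect_identical(bisulfite_convert(once, "unmethylated")$seq, once)
  }
})

test_that("bottom-strand conversion equals top-strand of the reverse complement", {
  set.seed(14)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    for (state in c("methylated", "unmethylated")) {
      expect_identical(bisulfite_convert(s, state, strand = "bottom")$seq,
                       bisulfite_convert(revcomp_chr(s), state)$seq)
    }
  }
})

test_that("amplicon enumeration respects length and CpG bounds", {
  seq60 <- paste0(strrep("CGTAT", 8), strrep("AT", 10))  # 8 CpGs in 60 bp
  tmpl <- bisulfite_convert(seq60, "methylated")
  w <- enumerate_amplicons(tmpl)
  expect_gt(nrow(w), 0)
  no_cpg <- bisulfite_convert(strrep("AT", 40), "methylated")
  expect_equal(nrow(enumerate_amplicons(no_cpg)), 0)
  expect_warning(enumerate_amplicons(bisulfite_convert("ACGT", "methylated")),
                 "shorter")
  reg <- simulate_genomic_region(200, 0.08, clustered = TRUE, seed = 99)
  w <- enumerate_amplicons(bisulfite_convert(reg$seq, "methylated"))
  expect_true(all(w$length >= 58 & w$length <= 72))
  expect_true(all(w$n_cpg >= 6))
  expect_equal(order(-w$n_cpg, w$start, w$length), seq_len(nrow(w)))
})

test_that("oligo design emits only candidates satisfying hard constraints", {
  reg <- simulate_genomic_region(220, 0.08, clustered = TRUE, seed = 4)
  tmpl <- bisulfite_convert(reg$seq, "methylated")
  w <- enumerate_amplicons(tmpl)
  expect_gt(nrow(w), 0)
  designs <- design_oligos(tmpl, w[1, ])
  expect_gt(length(designs), 0)
  for (d in designs) expect_hard_constraints(d, tmpl)
})

test_that("masked positions under every forward primer suppress design", {
  reg <- simulate_genomic_region(220, 0.08, clustered = TRUE, seed = 4)
  tmpl <- bisulfite_convert(reg$seq, "methylated")
  w <- enumerate_amplicons(tmpl)[1, ]
  mask <- w$start + 2L  # inside every possible forward primer
  designs <- design_oligos(tmpl, w, mask = mask)
  expect_length(designs, 0)
  fails <- attr(designs, "failure_counts")
  expect_gt(fails[["forward_excluded_position"]], 0)
})

test_that("windows without primer-accessible CpGs yield no designs", {
  # CpGs confined to the middle: no primer 3' end can sit on one
  seq <- paste0(strrep("AT", 12), "TACGTACGTACGTA", strrep("AT", 12))
  tmpl <- bisulfite_convert(seq, "methylated")
  designs <- design_oligos(tmpl, list(start = 1L, end = nchar(seq)))
  expect_length(designs, 0)
})

test_that("traffic-light boundaries follow the design-rule table", {
  reg <- simulate_genomic_region(220, 0.08, clustered = TRUE, seed = 4)
  tmpl <- bisulfite_convert(reg$seq, "methylated")
  w <- enumerate_amplicons(tmpl)
  base <- design_oligos(tmpl, w[1, ])[[1]]

  tweak <- function(d, role = NULL, field = NULL, value = NULL,
                    length = NULL) {
    if (!is.null(length)) d$length <- length
    if (!is.null(role)) d$oligos[[role]][[field]] <- value
    score_design(d)
  }
  ideal <- base
  for (role in c("forward", "reverse", "probe")) {
    ideal$oligos[[role]]$gc_fraction <- 0.5
    ideal$oligos[[role]]$n_ch <- 3L
    ideal$oligos[[role]]$max_g_run <- 2L
  }
  ideal <- score_design(ideal)
  expect_identical(ideal$overall, "green")
  expect_identical(tweak(ideal, "forward", "n_ch", 2L)$overall, "yellow")
  expect_identical(tweak(ideal, "forward", "n_ch", 0L)$overall, "red")
  expect_identical(tweak(ideal, "probe", "max_g_run", 4L)$overall, "yellow")
  expect_identical(tweak(ideal, "probe", "max_g_run", 5L)$overall, "red")
  expect_identical(tweak(ideal, "reverse", "gc_fraction", 0.62)$overall,
                   "yellow")
  expect_identical(tweak(ideal, "reverse", "gc_fraction", 0.30)$overall,
                   "red")
  expect_identical(tweak(ideal, length = 80L)$overall, "yellow")
  expect_identical(tweak(ideal, length = 121L)$overall, "red")
  expect_identical(tweak(ideal, length = 72L)$overall, "green")
})

test_that("design ranking is deterministic with documented tie-breaks", {
  d <- function(overall, cpg, len, start, seqs = "A") {
    structure(list(start = start, end = start + len - 1L, length = len,
                   n_cpg_total = cpg, overall = overall,
                   oligos = list(forward = list(seq = seqs),
                                 reverse = list(seq = seqs),
                                 probe = list(seq = seqs))),
              class = "amplicon_design")
  }
  ranked <- rank_designs(list(d("yellow", 9, 60, 1), d("green", 6, 60, 5),
                              d("green", 7, 60, 9)))
  expect_equal(vapply(ranked, `[[`, "", "overall"),
               c("green", "green", "yellow"))
  expect_equal(ranked[[1]]$n_cpg_total, 7)  # more CpGs first
  dup1 <- d("green", 5, 60, 1, "AAA")
  dup2 <- d("green", 5, 60, 1, "CCC")
  expect_equal(rank_designs(list(dup2, dup1))[[1]]$oligos$forward$seq, "AAA")
})

test_that("end-to-end design avoids masked variants", {
  reg <- simulate_genomic_region(250, 0.07, clustered = TRUE, seed = 23)
  reg$variant_mask <- c(120L, 121L)
  res <- design_assays(reg)
  expect_gt(length(res$designs), 0)
  for (d in res$designs) {
    expect_hard_constraints(d, res$template, mask = reg$variant_mask)
  }
})
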