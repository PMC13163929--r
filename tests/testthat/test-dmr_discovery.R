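test_that("rank-sum test handles degenerate and textbook cases", {
  expect_equal(rank_sum_test(c(0.5, 0.5), c(0.5, 0.5))$p_value, 1)
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact")
  expect_error(rank_sum_test(numeric(0), 1), "non-missing")
  expect_equal(rank_sum_test(c(NA, 1), c(1, NA))$p_value, 1)
})

test_that("exact rank-sum branch equals full enumeration", {
  set.seed(42)
  for (i in 1:30) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    a <- runif(na)
    b <- runif(nb) + runif(1, -0.5, 0.5)
    expect_equal(rank_sum_test(a, b)$p_value, oracle_rank_sum_exact(a, b),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation stays close to the exact p at small n", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(6)
    b <- runif(6) + runif(1, -0.3, 0.3)
    exact <- rank_sum_test(a, b)$p_value
    approx <- rank_sum_test(a, b, exact_max = 0L)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("BH adjustment matches hand step-up and is permutation invariant", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(c(0.001, 0.01, 0.05, 0.5)),
               c(0.004, 0.02, 0.05 * 4 / 3, 0.5))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  set.seed(3)
  for (n in c(5, 100, 1000)) {
    p <- runif(n)^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("differential methylation separates planted probes", {
  sim <- simulate_beta_matrix(seed = 101, missing_rate = 0.02,
                              n_background_probes = 120L)
  dmc <- differential_methylation(sim$beta, sim$sheet, "Kidney")
  expect_equal(nrow(dmc), nrow(sim$beta))
  planted <- dmc[dmc$probe_id %in% sim$truth$planted$probe_id, ]
  expect_true(all(abs(planted$delta - 0.5) < 0.05))
  expect_true(all(planted$fdr < 1e-10))
  background <- dmc[!dmc$probe_id %in% sim$truth$planted$probe_id, ]
  expect_true(all(abs(background$delta) < 0.05))
  expect_error(differential_methylation(sim$beta, sim$sheet, "Spleen"),
               "unknown target tissue")
})

test_that("complete separation yields the expected delta and tiny FDR", {
  vals <- rbind(c(rep(0.8, 10), rep(0.05, 50)))
  rownames(vals) <- "cgX"
  colnames(vals) <- sprintf("s%02d", 1:60)
  sheet <- data.frame(sample_id = colnames(vals),
                      tissue = rep(c("Kidney", "Lung"), c(10, 50)),
                      role = "discovery")
  dmc <- differential_methylation(beta_matrix(vals), sheet, "Kidney")
  expect_equal(dmc$delta, 0.75)
  expect_lt(dmc$fdr, 1e-10)
})

test_that("DMC filter applies strict inequalities exactly as stated", {
  res <- data.frame(probe_id = c("a", "b", "c"),
                    mean_target = 0.5, mean_other = c(0.05, 0.05, 0.10),
                    delta = c(0.35, 0.29, 0.35),
                    p_value = 1e-13, fdr = 1e-12)
  kept <- dmc_filter(res, dmc_thresholds())
  expect_identical(kept$probe_id, "a")  # b fails delta, c fails background
})

test_that("regional density filter uses an inclusive 2.5 kb distance", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    chrom = c("chr1", "chr1", "chr1", "chr2"),
                    position = c(1000L, 3200L, 9000L, 500L))
  expect_setequal(region_density_filter(c("p1", "p2", "p3", "p4"), ann),
                  c("p1", "p2"))  # 2200 apart; p3 and p4 isolated
  ann$position[2] <- 3500L        # exactly 2500: boundary counts as inside
  expect_setequal(region_density_filter(c("p1", "p2"), ann), c("p1", "p2"))
  ann$position[2] <- 3501L
  expect_length(region_density_filter(c("p1", "p2"), ann), 0)
  expect_error(region_density_filter("nope", ann), "missing genomic")
})

test_that("DMR assembly is single linkage and matches transitive closure", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    chrom = c("chr1", "chr1", "chr2", "chr2"),
                    position = c(1000L, 3200L, 500L, 700L))
  dmrs <- assemble_dmrs(ann$probe_id, ann)
  expect_equal(nrow(dmrs), 2)  # chromosomes never merge
  expect_equal(dmrs$start, c(1000L, 500L))
  expect_equal(dmrs$end, c(3200L, 700L))
  expect_equal(nrow(assemble_dmrs(character(0), ann)), 0)

  set.seed(5)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    ann <- data.frame(probe_id = sprintf("p%03d", 1:n),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      position = sample.int(20000, n))
    dmrs <- assemble_dmrs(ann$probe_id, ann)
    lab <- oracle_cluster_closure(ann$chrom, ann$position, 2500)
    member_sets <- lapply(strsplit(dmrs$probe_ids, ","), sort)
    oracle_sets <- lapply(split(ann$probe_id, lab), sort)
    expect_setequal(vapply(member_sets, paste, "", collapse = ","),
                    vapply(unname(oracle_sets), paste, "", collapse = ","))
  }
})

test_that("blood metrics count positivity over non-missing samples", {
  m <- matrix(rep(0.05, 100), 1,
              dimnames = list("cg1", sprintf("w%03d", 1:100)))
  bm <- blood_metrics(beta_matrix(m), "cg1")
  expect_equal(bm$median_beta, 0.05)
  expect_equal(bm$positivity, 0)
  m[1, 1:3] <- 0.3
  bm <- blood_metrics(beta_matrix(m), "cg1")
  expect_equal(bm$positivity, 0.03)
  m10 <- matrix(rep(0.25, 10), 1,
                dimnames = list("cg2", sprintf("w%03d", 1:10)))
  bm <- blood_metrics(beta_matrix(m10), "cg2")
  expect_equal(bm$median_beta, 0.25)
  expect_equal(bm$positivity, 1)
  expect_warning(blood_metrics(beta_matrix(m10), c("cg2", "absent")),
                 "absent")
})

test_that("blood exclusion is strict on both rules", {
  metrics <- data.frame(probe_id = c("a", "b", "c"),
                        median_beta = c(0.15, 0.05, 0.10),
                        positivity = c(0.01, 0.03, 0.02),
                        available = TRUE)
  expect_identical(blood_exclude(metrics), "c")  # boundaries not exceeded
})

test_that("filters are monotone in their thresholds", {
  set.seed(9)
  res <- data.frame(probe_id = sprintf("p%02d", 1:40),
                    mean_target = runif(40), mean_other = runif(40, 0, 0.2),
                    delta = runif(40, 0, 0.6), p_value = runif(40)^4,
                    fdr = runif(40)^2)
  tight <- dmc_filter(res, dmc_thresholds(fdr_max = 1e-2, delta_min = 0.4,
                                          other_mean_max = 0.05))
  loose <- dmc_filter(res, dmc_thresholds(fdr_max = 1e-1, delta_min = 0.3,
                                          other_mean_max = 0.10))
  expect_true(all(tight$probe_id %in% loose$probe_id))

  ann <- data.frame(probe_id = sprintf("p%02d", 1:40),
                    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                    position = sample.int(30000, 40))
  tight <- region_density_filter(ann$probe_id, ann,
                                 dmc_thresholds(window_bp = 3000))
  loose <- region_density_filter(ann$probe_id, ann,
                                 dmc_thresholds(window_bp = 5000))
  expect_true(all(tight %in% loose))

  metrics <- data.frame(probe_id = sprintf("p%02d", 1:40),
                        median_beta = runif(40, 0, 0.2),
                        positivity = runif(40, 0, 0.05), available = TRUE)
  tight <- blood_exclude(metrics, median_max = 0.05, positivity_max = 0.01)
  loose <- blood_exclude(metrics, median_max = 0.10, positivity_max = 0.02)
  expect_true(all(tight %in% loose))
})

test_that("restricting DMRs to retained probes drops thin regions", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                    chrom = "chr1",
                    position = c(1000L, 2000L, 3000L, 10000L, 11000L))
  dmrs <- assemble_dmrs(ann$probe_id, ann)
  expect_equal(nrow(dmrs), 2)
  out <- restrict_dmrs(dmrs, c("p1", "p2", "p4"), ann)
  expect_equal(nrow(out), 1)       # p4's region falls below 2 members
  expect_equal(out$end, 2000L)     # span recomputed without p3
})
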