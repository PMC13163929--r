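test_that("dilution series is the stated geometric sequence", {
  expect_equal(dilution_series_points(500, 2.5, 7),
               c(500, 200, 80, 32, 12.8, 5.12, 2.048))
  expect_equal(dilution_series_points(500, 2.5, 1), 500)
  pts <- dilution_series_points(37, 3.1, 5)
  expect_equal(pts[5] * 3.1^4, 37)  # inverse identity
  expect_error(dilution_series_points(0, 2, 3), "> 0")
  expect_error(dilution_series_points(10, 1, 3), "> 1")
})

test_that("Poisson positivity is 1 - exp(-lambda) and monotone", {
  expect_equal(poisson_positivity(0), 0)
  expect_equal(poisson_positivity(0.17), 1 - exp(-0.17))
  lam <- seq(0, 5, by = 0.25)
  expect_true(all(diff(poisson_positivity(lam)) > 0))
  expect_error(poisson_positivity(-0.1), ">= 0")
})

test_that("Clopper-Pearson interval hits boundaries and known values", {
  expect_equal(clopper_pearson(0, 50)$lower, 0)
  expect_equal(clopper_pearson(50, 50)$upper, 1)
  ci <- clopper_pearson(69, 343)
  expect_equal(ci$lower, 0.160, tolerance = 5e-3)
  expect_equal(ci$upper, 0.248, tolerance = 5e-3)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:400, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    bt <- stats::binom.test(k, n)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-10)
  }
  expect_error(clopper_pearson(5, 4), "0 <= k <= n")
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact(5, 10, 5, 10), 1)
  expect_equal(fisher_exact(3, 3, 0, 3), 0.1)
  set.seed(8)
  for (i in 1:30) {
    n1 <- sample(2:12, 1)
    n2 <- sample(2:(20 - n1), 1)
    k1 <- sample(0:n1, 1)
    k2 <- sample(0:n2, 1)
    expect_equal(fisher_exact(k1, n1, k2, n2),
                 oracle_fisher(k1, n1, k2, n2), tolerance = 1e-9)
    expect_equal(fisher_exact(k1, n1, k2, n2),
                 fisher_exact(k2, n2, k1, n1), tolerance = 1e-12)
  }
})

test_that("dPCR quantification inverts Poisson occupancy", {
  expect_equal(dpcr_concentration(0, 10000)$copies_per_reaction, 0)
  expect_equal(dpcr_concentration(6321, 10000)$lambda, 1, tolerance = 1e-3)
  ks <- c(10, 100, 1000, 5000)
  lam <- vapply(ks, function(k) dpcr_concentration(k, 10000)$lambda, 0)
  expect_true(all(diff(lam) > 0))
  expect_error(dpcr_concentration(100, 100), "saturated")
  # mutual inverse with the positivity model, to machine precision
  for (l in c(0.01, 0.17, 1, 3)) {
    expect_equal(-log(1 - poisson_positivity(l)), l, tolerance = 1e-12)
  }
})

test_that("percent methylation handles zero reference explicitly", {
  expect_equal(percent_methylation(c(0, 5, 100), c(100, 100, 100)),
               c(0, 5, 100))
  expect_warning(out <- percent_methylation(5, 0), "undefined")
  expect_true(is.na(out))
})

test_that("Kruskal-Wallis matches its oracles", {
  expect_equal(kruskal_wallis(list(1:3 * 0 + 2, 1:3 * 0 + 2,
                                   1:3 * 0 + 2))$p_value, 1)
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 4.571, tolerance = 1e-3)
  set.seed(12)
  for (i in 1:5) {
    g <- list(runif(2), runif(3), runif(2))
    ex <- kruskal_wallis(g, exact = TRUE)
    expect_equal(ex$p_value, oracle_kw_perm(g), tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("screen counts are reconstructed from printed summaries", {
  r4 <- reconstruct_screen_counts(20.1, c(16.0, 24.8))
  expect_equal(c(r4$k, r4$n), c(69L, 343L))
  r1 <- reconstruct_screen_counts(13.2, c(9.8, 17.2))
  expect_equal(c(r1$k, r1$n), c(45L, 341L))
  expect_error(reconstruct_screen_counts(50, c(1, 2)), "consistent")
})

test_that("clinical summary separates constructed groups", {
  cohort <- simulate_clinical_cohort(seed = 2)
  cs <- clinical_summary(cohort$partitions, cohort$sheet)
  med <- setNames(cs$group_summary$marker_median, cs$group_summary$group)
  expect_equal(unname(med["HC"]), 0)
  expect_equal(unname(med["Pre-Tx"]), 0)
  expect_gt(unname(med["D1"]), 0)
  expect_lt(cs$kw_absolute$p_value, 0.05)

  single <- cohort$partitions[cohort$partitions$sample_id %in%
                                cohort$sheet$sample_id[cohort$sheet$group ==
                                                         "HC"], ]
  expect_error(clinical_summary(single, cohort$sheet), ">= 2 groups")

  broken <- cohort$partitions[-1, ]  # first sample loses its marker row
  expect_warning(clinical_summary(broken, cohort$sheet), "excluded")
})

test_that("screen summary couples observed and model-expected positivity", {
  sc <- simulate_replicate_screen(0.17, 1, 343L, seed = 6, assay_id = "a4")
  out <- screen_summary(sc)
  expect_equal(out$expected_positivity, 1 - exp(-0.17))
  expect_true(out$ci_lower <= out$positivity &
                out$positivity <= out$ci_upper)
})
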