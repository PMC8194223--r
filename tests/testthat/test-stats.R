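test_that("paired positions collapse to single rates; loops keep their own", {
  rt <- data.frame(column = 1:8, coverage = 1,
                   class = "variable",
                   rate = c(0.4, 0.6, NA, 0.9, 0.3, 0.8, 0.2, 0.1))
  # pairs (1,2) and (3,4); 5..8 unpaired
  sm <- structure_map("ACGTACGT",
                      pair = c(2L, 1L, 4L, 3L, 0L, 0L, 0L, 0L))
  cp <- collapse_paired(rt, sm)
  expect_equal(nrow(cp$pairs), 1L)          # (3,4) dropped: rate 3 is NA
  expect_equal(cp$pairs$collapsed, 0.5)
  expect_equal(sort(cp$loops), c(0.1, 0.2, 0.3, 0.8))

  # map with no pairs: everything scored is a loop
  sm0 <- structure_map("ACGTACGT")
  cp0 <- collapse_paired(rt, sm0)
  expect_equal(nrow(cp0$pairs), 0L)
  expect_equal(length(cp0$loops), 7L)
})

test_that("signed-rank statistics match direct computation and flag degenerate input", {
  x <- c(1.2, 0.8, 0.5, 2.0, 1.1, 0.9, 1.4, 0.7)
  y <- c(1.0, 0.9, 0.5, 1.5, 1.2, 0.4, 1.0, 0.9)
  res <- wilcoxon_signed_rank(x, y)
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  expect_equal(res$statistic, max(sum(r[d > 0]), sum(r[d < 0])))
  expect_equal(res$n, c(7L, 8L))
  # degenerate: all differences zero
  same <- wilcoxon_signed_rank(x, x)
  expect_equal(same$n[1], 0L)
  expect_true(is.na(same$p))
})

test_that("signed-rank normal approximation tracks the exact permutation null", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(8:10, 1)
    x <- round(runif(n, 0, 2), 2)
    y <- round(x + rnorm(n, 0.15, 0.4), 2)
    res <- wilcoxon_signed_rank(x, y)
    if (res$n[1] < 5) next
    exact <- oracle_wilcoxon_exact_p(x, y)
    expect_lt(abs(res$p - exact), 0.08)
  }
})

test_that("rank-sum U matches brute-force pairwise counting", {
  a <- c(3.1, 2.2, 5.5, 4.0, 2.2)
  b <- c(1.0, 2.2, 3.5, 6.0)
  res <- mann_whitney_u(a, b)
  u1 <- oracle_u_statistic(a, b)
  expect_equal(res$statistic, max(u1, length(a) * length(b) - u1))
  # identical multisets: U at its null expectation, Z = 0
  res0 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$statistic, 4.5)
  expect_equal(res0$Z, 0)
  expect_equal(res0$p, 1)
})

test_that("rank-sum approximation tracks the exact permutation null", {
  set.seed(29)
  for (rep in 1:10) {
    n1 <- sample(4:5, 1); n2 <- sample(4:5, 1)
    a <- round(runif(n1, 0, 3), 1)
    b <- round(runif(n2, 0.5, 3.5), 1)
    res <- mann_whitney_u(a, b)
    exact <- oracle_mw_exact_p(a, b)
    expect_lt(abs(res$p - exact), 0.12)
  }
})

test_that("Kruskal-Wallis agrees with the base implementation and the two-group identity", {
  g <- list(c(2.1, 3.3, 1.2), c(4.5, 3.3, 5.1), c(0.3, 0.9, 2.8))
  res <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, unname(ref$p.value))
  expect_equal(res$df, 2L)

  # two groups: H equals the squared tie-corrected normal deviate
  a <- c(1.1, 2.3, 2.3, 4.1, 0.7); b <- c(2.3, 3.9, 5.2, 1.8)
  kw <- kruskal_wallis(list(a, b))
  mw <- mann_whitney_u(a, b)
  expect_equal(kw$statistic, mw$Z^2, tolerance = 1e-10)

  # all values identical
  flat <- kruskal_wallis(list(c(1, 1), c(1, 1, 1)))
  expect_equal(flat$statistic, 0)
})

test_that("2x2 chi-square is Pearson without continuity correction", {
  expect_equal(chi2_2x2(matrix(c(10, 1, 20, 2), 2))$statistic, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
  res <- chi2_2x2(matrix(c(940, 488, 90, 185), 2))
  expect_equal(res$df, 1)
  expect_lt(res$p, 1e-20)
})

test_that("the battery detects a hypervariable rate effect and not a null one", {
  regions <- default_sim_regions(1800L)
  # effect present: hypervariable multiplier 3 (the default)
  sim <- simulate_alignment(simulation_config(seed = 101))
  rt <- tiger_rates(sim$aln)
  bat <- run_test_battery(rt, structureMap = NULL, regions)
  expect_lt(bat$hyper_vs_non_rates$p, 0.05)
  expect_lt(bat$among_regions$p, 0.05)
  expect_equal(bat$paired$test, "not run")

  # no region effect: multiplier 1
  sim0 <- simulate_alignment(simulation_config(
    seed = 102, n_taxa = c(a = 12L, b = 12L, c = 12L), n_sites = 900L,
    regions = region_set(c("V1", "V2", "V3"), c(101L, 301L, 501L),
                         c(60L, 80L, 92L)),
    hyper_multiplier = 1, indel_rate_hyper = 0.15,
    deletion_carrier_fraction = 0))
  rt0 <- tiger_rates(sim0$aln)
  bat0 <- run_test_battery(rt0, NULL, sim0$truth$config$regions)
  expect_gt(bat0$hyper_vs_non_rates$p, 0.05)
  expect_gt(bat0$among_regions$p, 0.05)
})

test_that("statistics are invariant to within-group ordering", {
  set.seed(7)
  a <- runif(12); b <- runif(15)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(sample(a), sample(b))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
  cc <- runif(6)
  k1 <- kruskal_wallis(list(a, b, cc))
  k2 <- kruskal_wallis(list(sample(a), rev(b), sample(cc)))
  expect_equal(k1$statistic, k2$statistic)
})
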