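test_that("site partitions apply exclusion and ambiguity rules", {
  aln <- as_alignment(c("AAGG", "AAGG", "GAGG", "GAGG"), paste0("t", 1:4))
  p <- site_partition(aln, 1L)
  expect_setequal(p$taxa, paste0("t", 1:4))
  expect_equal(sort(names(p$sets)), c("A", "G"))
  expect_setequal(p$sets$A, c("t1", "t2"))
  expect_setequal(p$sets$G, c("t3", "t4"))

  # ambiguity code places its taxon in each component set
  aln2 <- as_alignment(c("AC", "RC", "GC"), paste0("t", 1:3))
  p2 <- site_partition(aln2, 1L)
  expect_setequal(p2$sets$A, c("t1", "t2"))
  expect_setequal(p2$sets$G, c("t2", "t3"))

  # terminal gap and N drop taxa from the site
  aln3 <- as_alignment(c("AGT", "-GT", "ANT", "NGT"), paste0("t", 1:4))
  p3 <- site_partition(aln3, 1L)   # t2's '-' is terminal, t4 has N
  expect_setequal(p3$taxa, c("t1", "t3"))
  expect_equal(length(p3$sets), 1L)
  p3b <- site_partition(aln3, 2L)  # t3's N at column 2
  expect_setequal(p3b$taxa, c("t1", "t2", "t4"))
})

test_that("partition agreement follows the nested-subset definition", {
  aln <- as_alignment(c("AA", "AA", "GA", "GA"), paste0("t", 1:4))
  P_var <- site_partition(aln, 1L)
  P_const <- site_partition(aln, 2L)
  # constant focal site: every restricted set nests
  expect_equal(partition_agreement(P_const, P_var), 1)
  # self-agreement
  expect_equal(partition_agreement(P_var, P_var), 1)
  # fully conflicting splits of the same taxa
  alnx <- as_alignment(c("AA", "AG", "GA", "GG"), paste0("t", 1:4))
  Pi <- site_partition(alnx, 1L)   # {a,b} vs {c,d}
  Pj <- site_partition(alnx, 2L)   # {a,c} vs {b,d}
  expect_equal(partition_agreement(Pi, Pj), 0)
})

test_that("rates are exact on hand-computed toys and constant alignments", {
  # identical rows: every column constant, all rates 1
  aln <- as_alignment(rep("ACGTACGT", 5), paste0("t", 1:5))
  rt <- tiger_rates(aln)
  expect_true(all(rt$rate == 1))
  expect_true(all(rt$class == "constant"))

  # 4-taxon, 3-column toy AAAA / AAGG / AGAG: constant column scores 1,
  # the two conflicting splits score 0 against each other and 0 against
  # the constant column's partition (the full taxon set nests in neither)
  toy <- as_alignment(c("AAA", "AAG", "AGA", "AGG"), paste0("t", 1:4))
  rt <- tiger_rates(toy)
  expect_equal(rt$rate, c(1, 0, 0))

  expect_error(tiger_rates(aln[, 1, drop = FALSE]), "at least 2")
})

test_that("rates are invariant to taxon order", {
  set.seed(31)
  aln <- random_alignment(12, 25)
  rt1 <- tiger_rates(aln)
  perm <- sample(nrow(aln))
  rt2 <- tiger_rates(aln[perm, , drop = FALSE])
  expect_equal(rt1$rate, rt2$rate)
})

test_that("rates match the brute-force oracle on random alignments", {
  set.seed(17)
  for (rep in 1:8) {
    aln <- random_alignment(sample(5:12, 1), sample(10:25, 1))
    rt <- tiger_rates(aln)
    expect_equal(rt$rate, oracle_tiger(aln), tolerance = 1e-12)
  }
})

test_that("a refined split never outscores the coarser column it refines", {
  # col 1 splits {1,2,3} vs {4,5,6}; col 2 refines it into three sets
  aln <- as_alignment(c("AAC", "AAC", "ACC", "GGC", "GGC", "GTC"),
                      paste0("t", 1:6))
  rt <- tiger_rates(aln, threshold = 0.01)
  expect_lte(rt$rate[2], rt$rate[1])
})

test_that("rate summaries split constant and variable sites", {
  aln <- as_alignment(c("AAA", "AAG", "AAG", "AAA"), paste0("t", 1:4))
  rt <- tiger_rates(aln)
  all_s <- summarize_rates(rt, "all")
  var_s <- summarize_rates(rt, "variable_only")
  expect_equal(all_s$n, 3L)
  expect_equal(var_s$n, 1L)
  expect_true(var_s$mean <= all_s$mean)

  const <- tiger_rates(as_alignment(rep("AAAA", 4), paste0("t", 1:4)))
  expect_equal(summarize_rates(const, "all")$mean, 1)
  expect_equal(summarize_rates(const, "variable_only")$n, 0L)
})

test_that("rolling averages truncate at ends and skip undefined positions", {
  expect_equal(rolling_average(rep(0.4, 100), 35), rep(0.4, 100))
  # impulse: single 0 among 1s
  x <- rep(1, 101); x[51] <- 0
  ra <- rolling_average(x, 35)
  expect_equal(ra[51], 34 / 35)
  expect_equal(ra[1], 1)              # truncated window of 18 constant values
  # NA positions are excluded from each window mean
  y <- rep(0.5, 50); y[25] <- NA
  expect_equal(rolling_average(y, 7), rep(0.5, 50))
  expect_error(rolling_average(1:5, 4), "window")
})

test_that("rate histograms partition all columns with a left-closed rule", {
  tab <- data.frame(column = 1:4, coverage = 1,
                    class = c("variable", "variable", "constant",
                              "insufficient_coverage"),
                    rate = c(0.2, 0.45, 1.0, NA))
  h <- rate_histogram(tab, 0.5)
  expect_equal(h$count, c(2L, 0L, 1L, 1L))   # [0,.5) [.5,1) [1,1.5) n/a
  expect_equal(sum(h$count), nrow(tab))
})
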