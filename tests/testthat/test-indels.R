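one_region <- function(n) region_set("R1", 1L, n)

test_that("maximal gap runs are found and split at region boundaries", {
  aln <- as_alignment(c("AC--G-T", "ACCCGGT"), c("x", "ref"))
  runs <- indel_runs(aln, "x", one_region(7L))
  expect_equal(runs$start, c(3L, 6L))
  expect_equal(runs$length, c(2L, 1L))

  expect_equal(nrow(indel_runs(aln, "ref", one_region(7L))), 0L)

  # a run crossing the region boundary is split and counted in each region
  regions <- region_set(c("A", "B"), c(1L, 5L), c(4L, 4L))
  aln2 <- as_alignment(c("AC---CGT", "ACGTACGT"), c("x", "ref"))
  runs2 <- indel_runs(aln2, "x", regions)
  expect_equal(runs2$region, c("A", "B"))
  expect_equal(runs2$start, c(3L, 5L))
  expect_equal(runs2$length, c(2L, 1L))
})

test_that("terminal-gap runs are excluded from the pooled non-hypervariable region", {
  regions <- region_set("V1", 4L, 3L)
  aln <- as_alignment(c("--ACGTA-C--", "ACGTACGTACG"), c("x", "ref"))
  runs <- indel_runs(aln, "x", regions)
  # leading 2 and trailing 2 are terminal (non-hypervariable): excluded;
  # the internal single gap at column 8 remains
  expect_equal(runs$start, 8L)
  runs_all <- indel_runs(aln, "x", regions, terminal_policy = "include")
  expect_equal(sort(runs_all$start), c(1L, 8L, 10L))
})

test_that("per-region summaries satisfy the nucleotide + gap conservation identity", {
  set.seed(41)
  for (rep in 1:4) {
    aln <- random_alignment(6, 40)
    regions <- region_set(c("V1", "V2"), c(6L, 21L), c(10L, 8L))
    for (tx in rownames(aln)) {
      s <- region_indel_summary(aln, tx, regions, terminal_policy = "include")
      runs <- indel_runs(aln, tx, regions, terminal_policy = "include")
      for (k in seq_len(nrow(s))) {
        gap_cols <- sum(runs$length[runs$region == s$region[k]])
        expect_equal(s$nucleotides[k] + gap_cols, s$region_length[k])
        # mean length x count = total gapped columns
        if (s$n_indels[k] > 0)
          expect_equal(s$mean_indel_length[k] * s$n_indels[k], gap_cols)
      }
    }
  }
})

test_that("summary rows reproduce a known exemplar pattern", {
  # a 10-column region holding 7 nucleotides and one 3-gap run
  aln <- as_alignment(c("ACG---TACG", "ACGTTTTACG"), c("x", "ref"))
  s <- region_indel_summary(aln, "x", one_region(10L))
  r1 <- s[s$region == "R1", ]
  expect_equal(r1$nucleotides, 7L)
  expect_equal(r1$n_indels, 1L)
  expect_equal(r1$mean_indel_length, 3)
  # region with no indels reports an undefined mean
  s_ref <- region_indel_summary(aln, "ref", one_region(10L))
  expect_true(is.na(s_ref$mean_indel_length[1]))
})

test_that("the deletion window derives from the 3' end of the named region", {
  w <- deletion_window(rotifer_regions(), "V3", tail = 14L, extension = 78L)
  expect_equal(w[["start"]], 593)   # V3 spans 524..606
  expect_equal(w[["length"]], 92)
  expect_error(deletion_window(rotifer_regions(), "V99"), "not found")
})

test_that("deletion motifs are classified by exact span coordinates", {
  rows <- c(full = "ACGTACGTACGTACGTACGT",
            d1 = "ACGT----ACGTACGTACGT",
            d1b = "ACGT----ACGTACGTACGT",
            d2 = "ACGTACGT----ACGTACGT",    # same length, different position
            d3 = "ACGT--G-ACGTACGTACGT")
  aln <- as_alignment(rows, names(rows))
  win <- c(start = 3L, length = 14L)
  dr <- detect_deletion(aln, win)
  expect_equal(dr$class[dr$taxon == "full"], "absent")
  expect_equal(dr$expressed_length[dr$taxon == "full"], 0L)
  expect_equal(dr$class[dr$taxon == "d1"], dr$class[dr$taxon == "d1b"])
  expect_false(dr$class[dr$taxon == "d1"] == dr$class[dr$taxon == "d2"])
  expect_equal(dr$expressed_length[dr$taxon == "d1"], 4L)
  expect_equal(dr$spans[dr$taxon == "d3"], "5-6;8-8")
  expect_equal(length(unique(dr$class)), 4L)

  # idempotent and invariant to taxa outside the queried group
  groups <- setNames(c("g2", "g1", "g1", "g1", "g1"), names(rows))
  dr_g1 <- detect_deletion(aln, win, groups, "g1")
  dr_g1_again <- detect_deletion(aln[names(rows) != "full", , drop = FALSE],
                                 win, groups, "g1")
  expect_identical(dr_g1, dr_g1_again)

  expect_error(detect_deletion(aln, c(start = 15L, length = 10L)),
               "outside")
})

test_that("runs intersecting the window boundary are clipped to it", {
  aln <- as_alignment(c("A----CGTACGT", "ACGTACGTACGT"), c("x", "ref"))
  dr <- detect_deletion(aln, c(start = 4L, length = 6L))
  expect_equal(dr$spans[dr$taxon == "x"], "4-5")
  expect_equal(dr$expressed_length[dr$taxon == "x"], 2L)
})
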