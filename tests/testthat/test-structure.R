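test_that("dot-bracket parsing handles layers and reports errors with positions", {
  pk <- parse_dotbracket("((..))")
  expect_equal(pk$pair, c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_equal(pk$knot, rep(0L, 6))

  # crossing pseudoknot layer: ( ( . . [ [ . . ) ) . . ] ]
  pk2 <- parse_dotbracket("((..[[..))..]]")
  expect_equal(pk2$pair[1], 10L)
  expect_equal(pk2$pair[2], 9L)
  expect_equal(pk2$knot[5], 14L)
  expect_equal(pk2$knot[6], 13L)

  expect_error(parse_dotbracket("(()"), "unbalanced '\\('.*position 1")
  expect_error(parse_dotbracket("())"), "unbalanced '\\)'.*position 3")
  expect_error(parse_dotbracket("(a)"), "illegal structure character")
})

test_that("structure maps enforce involution and layer crossing rules", {
  expect_error(structure_map("ACGT", c(3L, 0L, 0L, 0L)), "involution")
  # crossing pairs are rejected in the primary layer ...
  expect_error(structure_map("ACGTACGTAC",
                             pair = c(6L, 8L, 0L, 0L, 0L, 1L, 0L, 2L, 0L, 0L)),
               "crossing")
  # ... but allowed in the knot layer
  m <- structure_map("ACGTACGTAC",
                     pair = c(6L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
                     knot = c(0L, 0L, 8L, 0L, 0L, 0L, 0L, 3L, 0L, 0L))
  expect_s3_class(m, "structure_map")
})

test_that("vienna files round-trip including the pseudoknot layer", {
  seq <- "GGGAAACCCAAGGGAAACCC"
  db <- "(((...)))..(((...)))"
  m1 <- structure_map(seq, parse_dotbracket(db)$pair)
  m2 <- structure_map("ACGTACGTACGTAC",
                      pair = parse_dotbracket("((..[[..))..]]")$pair,
                      knot = parse_dotbracket("((..[[..))..]]")$knot)
  f <- tempfile(fileext = ".vienna")
  write_vienna(list(hairpins = m1, knotted = m2), f)
  back <- read_vienna(f)
  expect_equal(names(back), c("hairpins", "knotted"))
  expect_equal(back$hairpins$pair, m1$pair)
  expect_equal(back$knotted$knot, m2$knot)
  expect_equal(format_dotbracket(back$knotted), "((..[[..))..]]")
})

test_that("the reference folder maximizes pairs and honours constraints", {
  expect_equal(reference_fold("AAAA")$score, 0L)
  f <- reference_fold("GGGAAACCC")
  expect_equal(f$score, 3L)
  expect_equal(format_dotbracket(f$map), "(((...)))")
  # constraint supremacy: x positions never pair
  fx <- reference_fold("GGGAAACCC", "xxxxxxxxx")
  expect_equal(fx$score, 0L)
  fpart <- reference_fold("GGGAAACCC", "x........")
  expect_equal(fpart$map$pair[1], 0L)
  # enforced pairs are honoured even when the free fold would differ
  fe <- reference_fold("GGGAAACCC", "(.......)", enforce = TRUE)
  expect_equal(fe$map$pair[1], 9L)
})

test_that("the reference folder equals exhaustive enumeration on short sequences", {
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    cons <- paste(sample(c(".", "x"), n, replace = TRUE, prob = c(0.8, 0.2)),
                  collapse = "")
    f <- reference_fold(seq, cons)
    expect_equal(f$score, oracle_max_pairs(seq, cons))
    expect_true(oracle_structure_valid(f$map, cons))
  }
})

test_that("consensus constraints encode agreement, disagreement and forced loops", {
  # 30-nt backbone: hairpin at 3..12 shared by all refs, hypervariable
  # window at 16..21, tail unpaired
  db <- "..(((....))).................."
  mk <- function(d) structure_map(strrep("A", 30), parse_dotbracket(d)$pair)
  refs <- list(mk(db), mk(db), mk(db))
  hyper <- region_set("V", 16L, 6L)
  cons <- build_consensus_constraint(refs, hyper)
  expect_equal(cons, "xx(((xxxx)))xxxxxxxxxxxxxxxxxx")

  # one reference disagrees at the hairpin: those positions become '.'
  refs2 <- list(mk(db), mk(db), mk("..((......)).................."))
  cons2 <- build_consensus_constraint(refs2, hyper)
  expect_equal(substr(cons2, 5, 5), ".")   # paired in 2/3 refs only
  expect_equal(substr(cons2, 3, 3), "(")   # still consensus-paired
  # pseudoknot positions are forced unpaired
  cons3 <- build_consensus_constraint(refs, hyper,
                                      knots = cbind(3L, 25L))
  expect_equal(substr(cons3, 3, 3), "x")
  expect_equal(substr(cons3, 12, 12), ".")  # partner degrades to unconstrained
})

test_that("constraints project through gapped target rows", {
  #            123456789
  cons <-     "((..x.))."
  target <-   "AC-GTACGT"          # position 3 deleted in the target
  # wait: rows must match constraint length
  proj <- project_constraint(cons, target)
  expect_equal(nchar(proj), 8L)
  expect_equal(proj, "((.x.)).")
  # a pair whose partner is deleted degrades to '.'
  proj2 <- project_constraint("(.....).", "AC-GTACG")
  expect_equal(substr(proj2, 1, 1), "(")
  proj3 <- project_constraint("(....)..", "ACGTA-CG")
  expect_equal(substr(proj3, 1, 1), ".")
})

test_that("region folds keep bracket pairings only when they are real positions", {
  # all-A region: nothing can pair inside it
  seq <- paste0("GGGG", strrep("A", 12), "CCCC")
  f <- fold_hypervariable_region(seq, c(start = 5L, length = 12L),
                                 "artificial", bracket_len = 2L)
  expect_true(all(f$pair == 0L))
  expect_equal(length(f$pair), 12L)

  # adjacent mode: returned pairs lie entirely within the region
  seq2 <- "GGCGGGAAACCCAGG"
  f2 <- fold_hypervariable_region(seq2, c(start = 4L, length = 10L),
                                  "adjacent", bracket_len = 2L)
  expect_equal(length(f2$pair), 10L)
  idx <- which(f2$pair > 0L)
  expect_true(all(f2$pair[idx] >= 1L & f2$pair[idx] <= 10L))

  # internal mode: the bracketing stem is part of the region and kept
  seq3 <- "GGAAAACC"
  f3 <- fold_hypervariable_region(seq3, c(start = 1L, length = 8L),
                                  "internal", bracket_len = 2L)
  expect_equal(f3$pair[1], 8L)
  expect_equal(f3$pair[2], 7L)

  expect_error(fold_hypervariable_region("ACGT", c(start = 1L, length = 4L),
                                         "internal", bracket_len = 2L),
               "shorter")
})

test_that("splicing unions pairings and rejects collisions", {
  core <- structure_map("GGGAAAAAAACCC",
                        parse_dotbracket("(((.......)))")$pair)
  sub <- list(pair = c(0L, 6L, 0L, 0L, 0L, 2L, 0L), start = 4L)
  spliced <- splice(core, sub, c(start = 4L, length = 7L))
  expect_equal(spliced$pair[5], 9L)
  expect_equal(spliced$pair[9], 5L)
  expect_equal(spliced$pair[1], 13L)        # core pairing untouched
  # empty sub: identity
  empty <- list(pair = integer(7), start = 4L)
  expect_equal(splice(core, empty, c(start = 4L, length = 7L))$pair,
               core$pair)
  # collision with an already-paired core position
  bad_core <- structure_map("GGGAAAAAAACCC",
                            parse_dotbracket("(((.(...).)))")$pair)
  expect_error(splice(bad_core, sub, c(start = 4L, length = 7L)),
               "collision")
})

test_that("pseudoknot transfer maps homologous coordinates and reports failures", {
  ref_seq <- "GGAACCTTGG"
  refmap <- structure_map(ref_seq, knot = c(0L, 9L, 0L, 0L, 0L, 0L, 0L, 0L,
                                            2L, 0L))
  target <- structure_map("GGAACCTTGG")
  # identity alignment
  tr <- transfer_pseudoknots(refmap, ref_seq, ref_seq, target)
  expect_equal(tr$map$knot, refmap$knot)
  expect_equal(nrow(tr$unmapped), 0L)

  # 2-column insertion in the target before the knot shifts coordinates
  ref_row <- "--GGAACCTTGG"
  tgt_row <- "TTGGAACCTTGG"
  target2 <- structure_map("TTGGAACCTTGG")
  tr2 <- transfer_pseudoknots(refmap, ref_row, tgt_row, target2)
  expect_equal(tr2$map$knot[4], 11L)
  expect_equal(tr2$map$knot[11], 4L)

  # partner deleted in the target: reported unmapped, target unchanged
  tgt_del <- "GGAACCTT-G"
  target3 <- structure_map("GGAACCTTG")
  tr3 <- transfer_pseudoknots(refmap, ref_seq, tgt_del, target3)
  expect_equal(nrow(tr3$unmapped), 1L)
  expect_true(all(tr3$map$knot == 0L))
})

test_that("the external MFE adapter honours unpairable constraints", {
  f <- rnafold_engine("GGGGAAAACCCC", "xxxxxxxxxxxx")
  expect_true(all(f$map$pair == 0L))
  g <- rnafold_engine("GGGGAAAACCCC")
  expect_gt(sum(g$map$pair > 0L), 0L)
})

test_that("fold + splice + knot transfer assemble the expected toy map end to end", {
  # toy molecule: core hairpin . hypervariable window . core hairpin,
  # with one knot pairing added afterwards
  seq <- paste0("GGG", "AAA", "CCC",            # core hairpin 1..9
                "TT",
                "GGCAAAGCC",                     # hypervariable 12..20
                "TT",
                "GGG", "AAA", "CCC")             # core hairpin 23..31
  core <- structure_map(seq, parse_dotbracket(
    paste0("(((...)))", "..", ".........", "..", "(((...)))"))$pair)
  sub <- fold_hypervariable_region(seq, c(start = 12L, length = 9L),
                                   "internal", bracket_len = 2L)
  full <- splice(core, sub, c(start = 12L, length = 9L))
  # the window folds into its own hairpin: GGC...GCC pairs 12-20, 13-19
  expect_equal(full$pair[12], 20L)
  expect_equal(full$pair[13], 19L)
  refmap <- structure_map(gsub("-", "", seq),
                          knot = replace(integer(31), c(10, 22), c(22L, 10L)))
  final <- transfer_pseudoknots(refmap, seq, seq, full)$map
  expect_equal(final$knot[10], 22L)
  # constraint supremacy held throughout: primary layer non-crossing etc.
  expect_s3_class(final, "structure_map")
})
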