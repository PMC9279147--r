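bp_loop <- function(b1, b2, bin = 10000) {
  data.frame(chrom = "chrT", start1 = b1 * bin, end1 = (b1 + 1) * bin,
             start2 = b2 * bin, end2 = (b2 + 1) * bin)
}
bp_cbs <- function(bins, orientations, bin = 10000) {
  data.frame(chrom = "chrT", start = bins * bin + 100, end = bins * bin + 119,
             orientation = orientations)
}

test_that("anchor categories follow the directional-CBS rule", {
  # A(fwd) -> B(rev); B -> C(rev): B anchors a rightward loop without a
  # forward CBS -> nonconvergent and bidirectional
  loops <- rbind(bp_loop(10, 50), bp_loop(50, 90))
  cbs <- bp_cbs(c(10, 50, 90), c("forward", "reverse", "reverse"))
  aset <- classify_anchors(loops, cbs)
  a <- aset$anchors[order(aset$anchors$start), ]
  expect_equal(a$category, c("convergent_only", "nonconvergent", "convergent_only"))
  expect_equal(a$bidirectional, c(FALSE, TRUE, FALSE))
})

test_that("anchors with no CBS are no_ctcf", {
  loops <- bp_loop(10, 50)
  aset <- classify_anchors(loops, bp_cbs(10, "forward"))
  a <- aset$anchors[order(aset$anchors$start), ]
  expect_equal(a$category, c("convergent_only", "no_ctcf"))
})

test_that("loop categories implement the five-way scheme with precedence", {
  # isolated convergent loop -> single_sided_convergent
  aset1 <- classify_anchors(bp_loop(10, 50), bp_cbs(c(10, 50), c("forward", "reverse")))
  expect_equal(classify_loops(aset1)$category, "single_sided_convergent")
  # paired convergent/nonconvergent sharing an anchor
  loops <- rbind(bp_loop(10, 50), bp_loop(50, 90))
  aset2 <- classify_anchors(loops, bp_cbs(c(10, 50, 90),
                                          c("forward", "reverse", "reverse")))
  lc <- classify_loops(aset2)
  expect_equal(lc$convergent, c(TRUE, FALSE))
  expect_equal(lc$category, c("convergent_associated", "nonconvergent_associated"))
  # two convergent loops sharing a divergent middle anchor in both directions
  loops3 <- rbind(bp_loop(10, 50), bp_loop(50, 90))
  cbs3 <- rbind(bp_cbs(10, "forward"), bp_cbs(90, "reverse"),
                data.frame(chrom = "chrT", start = 50 * 10000 + 200,
                           end = 50 * 10000 + 219, orientation = "reverse"),
                data.frame(chrom = "chrT", start = 50 * 10000 + 400,
                           end = 50 * 10000 + 419, orientation = "forward"))
  lc3 <- classify_loops(classify_anchors(loops3, cbs3))
  expect_equal(lc3$category, rep("double_sided_convergent", 2))
})

test_that("classification matches the brute-force evaluator on random toy sets", {
  set.seed(99)
  for (rep_ in 1:200) {
    toy <- random_toy_set()
    aset <- classify_anchors(toy$loops_bp, toy$cbs, anchor_merge_bp = toy$bin)
    oracle <- brute_classify(toy$loops_abstract, toy$anchors)
    used <- sort(unique(c(toy$loops_abstract$a1, toy$loops_abstract$a2)))
    a <- aset$anchors[order(aset$anchors$start), ]
    expect_equal(a$category, oracle$anchor_category[used])
    expect_equal(a$bidirectional, oracle$bidirectional[used])
    lc <- classify_loops(aset)
    expect_equal(lc$convergent, oracle$loop_convergent)
    expect_equal(lc$category, oracle$loop_category)
  }
})

test_that("categories partition the loop set", {
  set.seed(7)
  toy <- random_toy_set()
  lc <- classify_loops(classify_anchors(toy$loops_bp, toy$cbs))
  expect_true(all(lc$category %in% c(
    "single_sided_convergent", "double_sided_convergent",
    "convergent_associated", "nonconvergent", "nonconvergent_associated")))
  expect_equal(length(lc$category), nrow(toy$loops_bp))
})

test_that("mirror reflection with flipped orientations preserves category counts", {
  set.seed(17)
  for (rep_ in 1:20) {
    toy <- random_toy_set()
    lc1 <- classify_loops(classify_anchors(toy$loops_bp, toy$cbs))
    span <- 1e9
    mirrored <- data.frame(
      chrom = "chrT",
      start1 = span - toy$loops_bp$end2, end1 = span - toy$loops_bp$start2,
      start2 = span - toy$loops_bp$end1, end2 = span - toy$loops_bp$start1)
    mcbs <- data.frame(chrom = "chrT",
                       start = span - toy$cbs$end, end = span - toy$cbs$start,
                       orientation = ifelse(toy$cbs$orientation == "forward",
                                            "reverse", "forward"))
    lc2 <- classify_loops(classify_anchors(mirrored, mcbs))
    expect_equal(sort(table(lc1$category)), sort(table(lc2$category)))
  }
})

test_that("bidirectional statistics handle degenerate and textbook tables", {
  anchors <- data.frame(
    category = rep(c("convergent_only", "nonconvergent", "no_ctcf"), c(5, 3, 2)),
    bidirectional = FALSE)
  st <- bidirectional_stats(anchors)
  expect_equal(st$fractions$fraction, rep(0, 3))
  expect_equal(st$omnibus$statistic, 0)
  # textbook 2x2: [[45,55],[5,95]]
  tab <- matrix(c(55, 95, 45, 5), 2, 2) # columns FALSE, TRUE
  anchors2 <- data.frame(
    category = rep(rep(c("convergent_only", "nonconvergent"), 2),
                   c(55, 95, 45, 5)),
    bidirectional = rep(c(FALSE, TRUE), c(150, 50)))
  st2 <- suppressWarnings(bidirectional_stats(anchors2))
  oracle <- chisq_oracle(matrix(c(45, 55, 5, 95), 2, 2, byrow = TRUE))
  ph <- st2$posthoc
  expect_equal(ph$statistic[1], oracle$statistic, tolerance = 1e-12)
  expect_equal(oracle$statistic, 42 + 2 / 3, tolerance = 1e-12)
  expect_equal(ph$p_value[1], oracle$p_value, tolerance = 1e-12)
})

test_that("omnibus requires at least two populated categories", {
  anchors <- data.frame(category = rep("convergent_only", 4), bidirectional = TRUE)
  expect_error(suppressWarnings(bidirectional_stats(anchors)), "fewer than 2")
})

test_that("loop strength is the log2 center-over-corner enrichment", {
  oe <- matrix(1, 60, 60)
  expect_equal(loop_strength(oe, 25, 40), 0)
  oe2 <- matrix(1, 60, 60)
  oe2[25:27, 41:43] <- 4  # center square around pixel (25, 41) 1-based (26, 42)
  expect_equal(loop_strength(oe2, 25, 41), 2)
  expect_error(loop_strength(oe, 5, 40), "bounds")
})

test_that("aggregate loop signal averages the windows", {
  set.seed(23)
  oe <- matrix(stats::runif(3600), 60, 60)
  l1 <- bp_loop(20, 40); l2 <- bp_loop(25, 45)
  agg1 <- aggregate_loops(l1, oe, 10000, window_bins = 5)
  expect_equal(agg1$apa, oe[16:26, 36:46])
  agg2 <- aggregate_loops(rbind(l1, l2), oe, 10000, window_bins = 5)
  expect_equal(agg2$apa, (oe[16:26, 36:46] + oe[21:31, 41:51]) / 2)
  expect_equal(agg2$n_loops, 2)
})

test_that("corner association flags loops between planted boundaries", {
  loops <- rbind(bp_loop(10, 50), bp_loop(10, 70), bp_loop(20, 60), bp_loop(20, 80))
  cats <- data.frame(loop_id = letters[1:4], convergent = TRUE,
                     category = rep(c("single_sided_convergent",
                                      "double_sided_convergent"), each = 2))
  ca <- corner_association(loops, cats,
                           boundary_bins = c(10L, 20L, 50L, 60L, 70L, 80L),
                           bin_size = 10000, zone_bins = 2L)
  expect_true(all(ca$loops$at_tad_corner))
  expect_equal(ca$corner_fractions$at_tad_corner, c(1, 1))
  # identical distance distributions across categories: no post-hoc tests
  expect_gt(ca$kruskal$p_value, 0.5)
  expect_null(ca$pairwise)
})

test_that("the simple caller finds planted peaks and suppresses neighbors", {
  oe <- matrix(1, 200, 200)
  expect_equal(nrow(call_loops_simple(oe, 3)), 0)
  oe[51, 151] <- oe[151, 51] <- 5
  l <- call_loops_simple(oe, 3, radius_bins = 2L, bin_size = 10000)
  expect_equal(nrow(l), 1)
  expect_equal(l$start1 / 10000, 50) # 0-based bin
  expect_equal(l$start2 / 10000, 150)
  # two peaks one bin apart: only the larger survives
  oe[51, 152] <- oe[152, 51] <- 4
  l2 <- call_loops_simple(oe, 3, radius_bins = 2L, bin_size = 10000)
  expect_equal(nrow(l2), 1)
  expect_equal(l2$oe, 5)
})
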