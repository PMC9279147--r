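jaspar_lines <- c(
  ">MA0000.1 TESTMOTIF",
  "A [ 10  0  0  2 ]",
  "C [  0 10  0  2 ]",
  "G [  0  0 10  2 ]",
  "T [  0  0  0  4 ]")

test_that("JASPAR raw counts parse into column-normalized probabilities", {
  pwm <- read_jaspar_pwm(jaspar_lines)
  expect_equal(pwm$length, 4L)
  expect_equal(colSums(pwm$prob), rep(1, 4), tolerance = 1e-12)
  # +0.25 pseudocount per cell: column 1 = (10.25, .25, .25, .25) / 11
  expect_equal(pwm$prob[, 1], c(A = 10.25, C = 0.25, G = 0.25, T = 0.25) / 11)
})

test_that("the consensus embedded in a peak is found on the + strand", {
  pwm <- read_jaspar_pwm(jaspar_lines)
  consensus <- "ACGT"
  seq <- paste0("TTTTTTT", consensus, "TTTTT")
  hit <- scan_peak(seq, pwm)
  expect_equal(hit$start, 7)
  expect_equal(hit$strand, "+")
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$score, sum(log2(apply(pwm$prob, 2, max) / 0.25)))
})

test_that("best hit equals exhaustive enumeration over offsets and strands", {
  set.seed(12)
  pwm <- pwm_from_counts(matrix(stats::rpois(12, 5), 4, 3))
  lods <- log2(pwm$prob / pwm$background)
  score_one <- function(s) {
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(idx)) -Inf else sum(lods[cbind(idx, seq_along(idx))])
  }
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (rep_ in 1:50) {
    n <- sample(3:30, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    cand <- NULL
    for (o in 0:(n - 3)) {
      win <- substr(seq, o + 1, o + 3)
      cand <- rbind(cand,
                    data.frame(offset = o, strand = "+", score = score_one(win)),
                    data.frame(offset = o, strand = "-", score = score_one(rc(win))))
    }
    cand <- cand[order(-cand$score, cand$offset, cand$strand), ]
    best <- cand[1, ]
    hit <- scan_peak(seq, pwm, threshold = -Inf)
    expect_equal(hit$score, best$score)
    expect_equal(hit$start, best$offset)
    expect_equal(hit$strand, best$strand)
  }
})

test_that("ties resolve leftmost then + strand", {
  # uniform PWM scores every window 0 on both strands
  pwm <- pwm_from_counts(matrix(1, 4, 2))
  hit <- scan_peak("ACGTAC", pwm, threshold = -Inf)
  expect_equal(hit$start, 0)
  expect_equal(hit$strand, "+")
})

test_that("N positions and sub-threshold scores yield no hit", {
  pwm <- read_jaspar_pwm(jaspar_lines)
  expect_null(scan_peak("NNNNNNNN", pwm))
  expect_null(scan_peak("TTTTTTTT", pwm, threshold = 100))
  expect_error(scan_peak("AC", pwm), "shorter")
})

test_that("reverse complementing a peak flips orientation and keeps the score", {
  # non-palindromic consensus AACG
  counts <- rbind(A = c(10, 10, 0, 0), C = c(0, 0, 10, 0),
                  G = c(0, 0, 0, 10), T = c(0, 0, 0, 0))
  pwm <- pwm_from_counts(counts)
  seq <- "TTTAACGATTTT" # contains the consensus but not its reverse complement
  rcseq <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  h1 <- scan_peak(seq, pwm, threshold = -Inf)
  h2 <- scan_peak(rcseq, pwm, threshold = -Inf)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$orientation, "forward")
  expect_equal(h2$orientation, "reverse")
})

boundary_df <- function(start, end) {
  data.frame(chrom = "chrT", start = start, end = end, boundary_score = 1)
}
cbs_df <- function(starts, orientations) {
  data.frame(chrom = "chrT", start = starts, end = starts + 19L,
             orientation = orientations)
}

test_that("the six-CBS divergent cluster composes as expected", {
  comp <- compose_boundaries(
    boundary_df(1990000, 2010000),
    cbs_df(seq(1900000, 2100000, by = 40000),
           c("reverse", "reverse", "forward", "reverse", "forward", "reverse")),
    flank_bp = 100000)
  expect_equal(comp$n_cbs, 6)
  expect_equal(comp$n_reverse, 4)
  expect_equal(comp$n_forward, 2)
  expect_true(comp$divergent)
})

test_that("divergent pair counting enumerates reverse-upstream-of-forward pairs", {
  comp_fff <- compose_boundaries(boundary_df(0, 1000),
                                 cbs_df(c(100, 300, 500), rep("forward", 3)), 1000)
  expect_equal(comp_fff$n_divergent_pairs, 0)
  expect_false(comp_fff$divergent)
  comp_rfrf <- compose_boundaries(boundary_df(0, 1000),
                                  cbs_df(c(100, 300, 500, 700),
                                         c("reverse", "forward", "reverse", "forward")),
                                  1000)
  expect_equal(comp_rfrf$n_divergent_pairs, 3) # pairs 1-2, 1-4, 3-4
})

test_that("divergence is invariant to translating the locus", {
  cbs <- cbs_df(c(100, 500), c("reverse", "forward"))
  c1 <- compose_boundaries(boundary_df(0, 1000), cbs, 500)
  cbs2 <- cbs; cbs2$start <- cbs2$start + 1e6; cbs2$end <- cbs2$end + 1e6
  c2 <- compose_boundaries(boundary_df(1e6, 1e6 + 1000), cbs2, 500)
  expect_equal(c1$divergent, c2$divergent)
  expect_equal(c1$n_divergent_pairs, c2$n_divergent_pairs)
})

test_that("negative flank is rejected and out-of-flank CBSs are excluded", {
  expect_error(compose_boundaries(boundary_df(0, 1000), cbs_df(100, "forward"), -1),
               "flank")
  comp <- compose_boundaries(boundary_df(0, 1000), cbs_df(5000, "forward"), 100)
  expect_equal(comp$n_cbs, 0)
})

test_that("composition summaries use boxplot statistics", {
  comp <- data.frame(id = letters[1:5], n_cbs = rep(3, 5),
                     n_divergent_pairs = 1, divergent = TRUE,
                     boundary_score = 1:5)
  s <- composition_summary(comp)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  single <- composition_summary(comp[1, ])
  expect_equal(single$median, 1)
  expect_equal(single$q1, single$q3)
})
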