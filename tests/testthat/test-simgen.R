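cfg20 <- function(...) {
  sim_config(n_bins = 20, bin_size_bp = 10000, burn_in_steps = 0,
             steps_per_snapshot = 1, unload_prob = 0,
             capture_prob_default = 1, ...)
}

test_that("no extruders means no dynamics", {
  cfg <- cfg20(n_extruders = 0, n_snapshots = 5, seed = 1)
  s <- simulate_extrusion(cfg)
  expect_equal(ncol(s$left), 0)
  expect_equal(nrow(s$left), 5)
})

test_that("single extruder stalls permanently at a convergent CBS pair", {
  cfg <- cfg20(n_extruders = 1, n_snapshots = 8, seed = 1)
  cbs <- planted_cbs(c(5L, 15L), c("forward", "reverse"), 1)
  init <- data.frame(left = 10L, right = 10L, left_state = 0L, right_state = 0L)
  s <- simulate_extrusion(cfg, cbs, init)
  # hand-stepped trajectory: one bin outward per step, captured on entry
  expect_equal(s$left[, 1], c(9:5, 5, 5, 5))
  expect_equal(s$right[, 1], c(11:15, 15, 15, 15))
  expect_equal(s$left_state[5:8, 1], rep(1L, 4))
  expect_equal(s$right_state[5:8, 1], rep(1L, 4))
})

test_that("steric interference blocks a leg adjacent to a stalled one", {
  cbs <- planted_cbs(c(5L, 15L), c("forward", "reverse"), 1)
  init <- data.frame(left = c(5L, 3L), right = c(15L, 3L),
                     left_state = c(1L, 0L), right_state = c(1L, 0L))
  cfg_on <- cfg20(n_extruders = 2, n_snapshots = 6, seed = 1)
  s_on <- simulate_extrusion(cfg_on, cbs, init)
  expect_equal(s_on$right[6, 2], 4L)     # blocked entering bin 5
  expect_equal(s_on$right_state[6, 2], 2L)
  expect_equal(s_on$left[6, 2], 0L)
  cfg_off <- cfg20(n_extruders = 2, n_snapshots = 14, seed = 1,
                   interference_enabled = FALSE)
  s_off <- simulate_extrusion(cfg_off, cbs, init)
  expect_equal(s_off$right[14, 2], 15L)  # passes bin 5 freely, stalls at 15
  expect_equal(s_off$right_state[14, 2], 1L)
})

test_that("left leg never exceeds right leg across random trajectories", {
  for (s in 1:5) {
    cfg <- sim_config(n_bins = 60, n_extruders = 10, n_snapshots = 50,
                      burn_in_steps = 10, steps_per_snapshot = 2,
                      unload_prob = 0.05, seed = s)
    cbs <- planted_cbs(c(10L, 30L, 50L), c("forward", "reverse", "reverse"), 0.7)
    snaps <- simulate_extrusion(cfg, cbs)
    expect_true(all(snaps$left <= snaps$right))
    expect_true(all(snaps$left >= 0 & snaps$right < 60))
  }
})

test_that("CBS validation rejects bad input", {
  cfg <- cfg20(n_extruders = 1, n_snapshots = 1, seed = 1)
  expect_error(simulate_extrusion(cfg, planted_cbs(25L, "forward")), "out of range")
  expect_error(simulate_extrusion(cfg, planted_cbs(c(5L, 5L), "forward")), "unique")
})

test_that("background-only map is a pure power-law decay", {
  cfg <- sim_config(n_bins = 20, n_extruders = 0, n_snapshots = 1,
                    burn_in_steps = 0, steps_per_snapshot = 1,
                    background_weight = 1, background_exponent = 1, seed = 1)
  s <- simulate_extrusion(cfg)
  r <- render_contact_map(s, cfg)
  d <- abs(outer(1:20, 1:20, "-"))
  expect_equal(r$matrix$counts, 1 / (d + 1))
})

test_that("a stalled loop dominates its own diagonal", {
  cfg <- cfg20(n_extruders = 1, n_snapshots = 50, seed = 4,
               intra_loop_samples = 2)
  cbs <- planted_cbs(c(5L, 15L), c("forward", "reverse"), 1)
  init <- data.frame(left = 10L, right = 10L, left_state = 0L, right_state = 0L)
  s <- simulate_extrusion(cfg, cbs, init)
  r <- render_contact_map(s, cfg)
  M <- r$matrix$counts
  # brute-force maximum over the |i-j| = 10 diagonal
  diag10 <- M[cbind(1:10, 11:20)]
  expect_equal(which.max(diag10), 6) # 0-based pixel (5, 15)
  expect_true(all(M[6, 16] > diag10[-6]))
})

test_that("masked bins have empty rows and columns", {
  cfg <- sim_config(n_bins = 30, n_extruders = 5, n_snapshots = 20,
                    burn_in_steps = 5, steps_per_snapshot = 1, seed = 9)
  s <- simulate_extrusion(cfg)
  r <- render_contact_map(s, cfg, masked_bins = c(7L, 8L))
  expect_true(all(r$matrix$counts[8, ] == 0))
  expect_true(all(r$matrix$counts[, 9] == 0))
  expect_equal(r$truth$masked_bins, c(7L, 8L))
})

test_that("contact maps are symmetric, nonnegative and seed-reproducible", {
  sim1 <- simulate_scenario("two_tads", seed = 5,
                            config_overrides = list(n_snapshots = 200L))
  sim2 <- simulate_scenario("two_tads", seed = 5,
                            config_overrides = list(n_snapshots = 200L))
  M <- sim1$matrix$counts
  expect_equal(M, t(M))
  expect_true(all(M >= 0))
  expect_identical(M, sim2$matrix$counts)
})

test_that("dataset generation is byte-identical across reruns", {
  d1 <- file.path(tempdir(), "lf_ds1"); d2 <- file.path(tempdir(), "lf_ds2")
  p1 <- generate_dataset("two_tads", seed = 1, out_dir = d1,
                         config_overrides = list(n_snapshots = 200L))
  p2 <- generate_dataset("two_tads", seed = 1, out_dir = d2,
                         config_overrides = list(n_snapshots = 200L))
  for (k in names(p1))
    expect_identical(unname(tools::md5sum(p1[[k]])), unname(tools::md5sum(p2[[k]])))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("interference flag controls expected nonconvergent ground truth", {
  on <- simulate_scenario("forward_only_boundary", seed = 1,
                          config_overrides = list(n_snapshots = 100L))
  off <- simulate_scenario("forward_only_boundary", seed = 1,
                           config_overrides = list(n_snapshots = 100L),
                           interference = FALSE)
  expect_gt(nrow(on$truth$expected_nonconvergent_pairs), 0)
  expect_equal(nrow(off$truth$expected_nonconvergent_pairs), 0)
  # blocked legs park adjacent to the rightmost forward-cluster site
  expect_equal(on$truth$expected_nonconvergent_pairs[1, ], c(40L, 201L))
})

test_that("the six-CBS boundary dataset writes the R,R,F,R,F,R pattern", {
  d <- file.path(tempdir(), "lf_ep")
  p <- generate_dataset("ep_boundary_like", seed = 2, out_dir = d,
                        config_overrides = list(n_snapshots = 100L))
  bed <- read.table(p$cbs, sep = "\t")
  expect_equal(nrow(bed), 6)
  expect_equal(bed$V6, c("-", "-", "+", "-", "+", "-"))
  truth <- jsonlite::read_json(p$truth, simplifyVector = TRUE)
  expect_equal(sort(truth$cbs$bin), c(190, 194, 198, 202, 206, 210))
  unlink(d, recursive = TRUE)
})

test_that("a deterministic convergent pair is the stationary loop base", {
  cfg <- cfg20(n_extruders = 1, n_snapshots = 30, seed = 2)
  cbs <- planted_cbs(c(3L, 17L), c("forward", "reverse"), 1)
  init <- data.frame(left = 9L, right = 9L, left_state = 0L, right_state = 0L)
  s <- simulate_extrusion(cfg, cbs, init)
  expect_equal(s$left[30, 1], 3L)
  expect_equal(s$right[30, 1], 17L)
})
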