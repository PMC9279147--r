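# End-to-end synthetic experiments. All randomness flows from one root seed;
# per-run seeds are derived as root * 1000 + offset (kept well below 2^31).

derive_seed <- function(root, offset) {
  (as.integer(root) %% 1000000L) * 1000L + as.integer(offset)
}

#' Insulation pipeline for one contact matrix
#'
#' Balance, fit the mappability mask, compute insulation and call
#' boundaries — the shared first half of the synthetic experiments.
#'
#' @param m a raw `contact_matrix`.
#' @param window_bp insulation window (default 250 kb).
#' @param exclusion_radius_bp mappability exclusion radius (default 125 kb).
#' @param smooth_bins moving-average half-width for boundary calling
#'   (default 2 bins; see [call_boundaries()]).
#' @return list with `matrix` (balanced), `mask`, `track`, `boundaries`.
#' @export
boundary_pipeline <- function(m, window_bp = 250000, exclusion_radius_bp = 125000,
                              smooth_bins = 2L) {
  mask <- fit_mappability_mask(m, exclusion_radius_bp)
  bal <- kr_balance(m)
  track <- insulation_score(bal, window_bp)
  calls <- call_boundaries(track, mask, smooth_bins = smooth_bins)
  list(matrix = bal, mask = mask, track = track, boundaries = calls)
}

# junction CBS cluster for the composition panels: divergent places reverse
# sites upstream and forward sites downstream of the junction (motifs
# pointing apart); nondivergent uses reverse-only sites
panel_cluster <- function(junction, n_cbs, arrangement = c("divergent", "nondivergent"),
                          capture_prob = 0.4, spacing = 1L) {
  arrangement <- match.arg(arrangement)
  if (n_cbs == 0) return(NULL)
  if (arrangement == "divergent") {
    n_rev <- ceiling(n_cbs / 2); n_fwd <- n_cbs - n_rev
    bins <- c(junction - spacing * seq_len(n_rev),
              junction + spacing * seq_len(n_fwd))
    orient <- c(rep("reverse", n_rev), rep("forward", n_fwd))
  } else {
    bins <- junction + spacing * (seq_len(n_cbs) - ceiling(n_cbs / 2))
    orient <- rep("reverse", n_cbs)
  }
  planted_cbs(sort(bins), orient[order(bins)], capture_prob)
}

simulate_panel_map <- function(n_cbs, arrangement, seed, config_overrides = list(),
                               capture_prob = 0.4) {
  # composition panels isolate the insulation response of the CBS cluster
  # from steric queueing; steric blocking is studied by the interference
  # experiment instead
  args <- utils::modifyList(list(interference_enabled = FALSE), config_overrides)
  args$seed <- seed
  cfg <- do.call(sim_config, args)
  junction <- as.integer(cfg$n_bins / 2)
  cbs <- panel_cluster(junction, n_cbs, arrangement, capture_prob)
  snaps <- simulate_extrusion(cfg, cbs)
  rend <- render_contact_map(snaps, cfg)
  list(matrix = rend$matrix, truth = rend$truth, junction = junction, cbs = cbs)
}

#' Boundary-composition panel
#'
#' Simulates maps whose central junction carries 0 to `max(n_cbs)` CBSs of
#' moderate occupancy, runs the boundary pipeline and records the boundary
#' score recovered at the junction (the strongest unfiltered call within
#' `match_bins`; 0 when no boundary is called). Reports per-level medians
#' and the Spearman correlation between CBS count and boundary score.
#'
#' @param n_cbs integer vector of planted CBS counts (default 0:10).
#' @param n_seeds replicate simulations per level.
#' @param seed root seed.
#' @param arrangement `"divergent"` or `"nondivergent"` junction layout.
#' @param window_bp insulation window.
#' @param match_bins junction matching radius in bins.
#' @param config_overrides [sim_config()] overrides (e.g. smaller lattices).
#' @return list with `scores` (per level x seed), `medians`, `spearman_rho`.
#' @export
run_boundary_panel <- function(n_cbs = 0:10, n_seeds = 10, seed = 1,
                               arrangement = "divergent", window_bp = 250000,
                               match_bins = 10L, config_overrides = list()) {
  rows <- NULL
  for (k in n_cbs) {
    for (s in seq_len(n_seeds)) {
      sim <- simulate_panel_map(k, arrangement, derive_seed(seed, k * 37L + s),
                                config_overrides)
      bp <- suppressWarnings(boundary_pipeline(sim$matrix, window_bp))
      calls <- bp$boundaries
      calls <- calls[!calls$filtered & abs(calls$bin - sim$junction) <= match_bins, ,
                     drop = FALSE]
      bs <- if (nrow(calls)) max(calls$boundary_score) else 0
      rows <- rbind(rows, data.frame(n_cbs = k, seed_index = s,
                                     boundary_score = bs))
    }
  }
  medians <- stats::aggregate(boundary_score ~ n_cbs, data = rows, FUN = stats::median)
  rho <- stats::cor(medians$n_cbs, medians$boundary_score, method = "spearman")
  list(scores = rows, medians = medians, spearman_rho = rho)
}

# run one interference-arm simulation end to end: loops called on obs/exp,
# anchors classified against the planted CBSs, loop categories and strengths
interference_run <- function(seed, interference, loop_threshold = 50,
                             min_count = 30, config_overrides = list()) {
  sim <- simulate_scenario("forward_only_boundary", seed, config_overrides,
                           interference = interference)
  bal <- kr_balance(sim$matrix)
  oe <- oe_transform(bal)
  bs <- bal$bin_size
  # long-range distance window: the scenario's planted and interference
  # loops sit > 150 bins out; short-range parking pixels at lattice edges
  # are not loops of interest
  loops <- call_loops_simple(oe, loop_threshold, radius_bins = 2L,
                             bin_size = bs, chrom = bal$chrom,
                             counts = sim$matrix$counts, min_count = min_count,
                             min_separation_bins = 50L)
  if (!nrow(loops)) return(NULL)
  cbs_bp <- data.frame(chrom = bal$chrom, start = sim$truth$cbs$bin * bs,
                       end = (sim$truth$cbs$bin + 1L) * bs,
                       orientation = sim$truth$cbs$orientation)
  aset <- classify_anchors(loops, cbs_bp, anchor_merge_bp = bs)
  lclass <- classify_loops(aset)
  strengths <- loop_strengths(loops, oe, bs)
  list(anchors = aset$anchors,
       loops = cbind(lclass, strength = strengths,
                     distance = loops$start2 - loops$start1))
}

#' Loop-interference experiment
#'
#' Runs the forward-only-boundary scenario with steric interference enabled
#' and disabled over matched seeds, pools loop anchors and loop categories
#' per arm, and contrasts (i) the bidirectional fraction of nonconvergent
#' anchors against convergent-only anchors within each arm (post-hoc
#' chi-squared, BH-corrected) and (ii) the strengths of convergent loops
#' paired with nonconvergent loops against their nonconvergent partners
#' (one-sided Mann-Whitney).
#'
#' @param n_seeds seeds per arm (>= 2).
#' @param seed root seed.
#' @param loop_threshold obs/exp threshold of the simple loop caller.
#' @param config_overrides [sim_config()] overrides.
#' @return list with per-arm summaries (`on`, `off`: fractions, stats,
#'   pooled loop table) and `contrast` (`fraction_ratio`,
#'   `strength_p_one_sided`, per-arm nonconvergent-vs-convergent-only
#'   p-values).
#' @export
run_interference_experiment <- function(n_seeds = 20, seed = 1,
                                        loop_threshold = 50, min_count = 30,
                                        config_overrides = list()) {
  if (n_seeds < 2) stop("need at least 2 seeds per arm")
  arm <- function(interference, offset) {
    anchors <- NULL; loops <- NULL
    for (s in seq_len(n_seeds)) {
      run <- interference_run(derive_seed(seed, offset + s), interference,
                              loop_threshold, min_count, config_overrides)
      if (is.null(run)) next
      anchors <- rbind(anchors, run$anchors)
      loops <- rbind(loops, run$loops)
    }
    stats_ <- tryCatch(suppressWarnings(bidirectional_stats(anchors)),
                       error = function(e) NULL)
    frac <- function(cat) {
      sub <- anchors[anchors$category == cat, , drop = FALSE]
      if (!nrow(sub)) 0 else mean(sub$bidirectional)
    }
    list(anchors = anchors, loops = loops, stats = stats_,
         fraction_nonconvergent = frac("nonconvergent"),
         fraction_convergent_only = frac("convergent_only"))
  }
  on <- arm(TRUE, 0L)
  off <- arm(FALSE, 500L)
  posthoc_p <- function(a) {
    if (is.null(a$stats)) return(NA_real_)
    ph <- a$stats$posthoc
    row <- ph$category_a == "convergent_only" & ph$category_b == "nonconvergent" |
      ph$category_a == "nonconvergent" & ph$category_b == "convergent_only"
    if (!any(row)) NA_real_ else ph$p_adjusted[row][1]
  }
  conv_assoc <- on$loops$strength[on$loops$category == "convergent_associated"]
  nonconv_assoc <- on$loops$strength[on$loops$category == "nonconvergent_associated"]
  strength_p <- if (length(conv_assoc) && length(nonconv_assoc)) {
    suppressWarnings(stats::wilcox.test(conv_assoc, nonconv_assoc,
                                        alternative = "greater")$p.value)
  } else NA_real_
  ratio <- if (off$fraction_nonconvergent == 0) Inf else
    on$fraction_nonconvergent / off$fraction_nonconvergent
  list(on = on, off = off,
       contrast = list(fraction_ratio = ratio,
                       on_posthoc_p = posthoc_p(on),
                       off_posthoc_p = posthoc_p(off),
                       strength_p_one_sided = strength_p,
                       n_conv_associated = length(conv_assoc),
                       n_nonconv_associated = length(nonconv_assoc)))
}

#' Boundary-weakening virtual-4C series
#'
#' Builds the six-CBS divergent boundary of the `ep_boundary_like` layout
#' and removes its CBSs one at a time (left to right), re-simulating each
#' level from the same seed within a series. Quantifies the share of the
#' virtual-4C profile (multi-bin viewpoint on the telomeric side, like a
#' promoter-region viewpoint) that falls in a fixed window on the
#' centromeric side of the boundary.
#'
#' @param n_seeds number of series.
#' @param seed root seed.
#' @param viewpoint 0-based viewpoint bins (telomeric side); a region-sized
#'   viewpoint averages out single-row sampling noise.
#' @param window 0-based inclusive bin range quantified (centromeric side).
#' @param config_overrides [sim_config()] overrides.
#' @return list with `quantifications` (matrix: series x removal level,
#'   column `k` = `k` CBSs removed) and `monotone_fraction` (share of series
#'   with a non-decreasing trend).
#' @export
run_boundary_weakening <- function(n_seeds = 20, seed = 1, viewpoint = 250:270,
                                   window = c(80L, 160L),
                                   config_overrides = list()) {
  lay <- scenario_layout("ep_boundary_like")
  full <- lay$cbs
  n_levels <- nrow(full) + 1L
  quant <- matrix(NA_real_, n_seeds, n_levels,
                  dimnames = list(NULL, paste0("removed_", 0:(n_levels - 1))))
  for (s in seq_len(n_seeds)) {
    series_seed <- derive_seed(seed, s)
    for (k in 0:(n_levels - 1)) {
      cbs <- if (k == 0) full else full[-seq_len(k), , drop = FALSE]
      # insulation-response series: steric blocking off so each removed CBS
      # lifts one factor of the crossing probability (graded weakening)
      args <- utils::modifyList(list(interference_enabled = FALSE),
                                config_overrides)
      args$seed <- series_seed
      cfg <- do.call(sim_config, args)
      vb <- unique(as.integer(round(viewpoint * cfg$n_bins / 400)))
      win <- as.integer(round(window * cfg$n_bins / 400))
      snaps <- simulate_extrusion(cfg, if (is.null(cbs) || !nrow(cbs)) NULL else cbs)
      rend <- render_contact_map(snaps, cfg)
      bal <- kr_balance(rend$matrix)
      v4c <- virtual_4c(bal, vb, exclusion_bins = 2L, quant_window = win)
      quant[s, k + 1L] <- v4c$quantification
    }
  }
  monotone <- apply(quant, 1, function(q) all(diff(q) >= 0))
  list(quantifications = quant, monotone_fraction = mean(monotone))
}
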