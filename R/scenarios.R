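#' Built-in synthetic scenarios
#'
#' Named presets of planted CBS layouts on the default 400-bin / 10-kb
#' lattice:
#' \describe{
#'   \item{two_tads}{two edge-to-edge domains separated by a divergent
#'     reverse/forward CBS pair at bins 199/201 (junction at bin 200); bins
#'     97-98 are masked as a low-mappability patch.}
#'   \item{ep_boundary_like}{a six-CBS boundary cluster ordered
#'     R,R,F,R,F,R with heterogeneous occupancy between two TADs — the
#'     divergent clustered-CBS layout of a prototypical developmental
#'     boundary.}
#'   \item{forward_only_boundary}{a boundary carrying only forward CBSs; with
#'     interference enabled, extruders blocked behind the stalled cluster
#'     form leftward (nonconvergent) loops paired with the convergent ones.}
#'   \item{divergent_vs_nondivergent_panel}{two boundaries with four CBSs
#'     each — one divergent (R,R,F,F), one reverse-only — for
#'     composition-vs-insulation comparisons.}
#' }
#'
#' @param scenario scenario name.
#' @return list with elements `cbs`, `masked_bins`, `junctions` (0-based
#'   boundary-junction bins) and `config_overrides`.
#' @export
scenario_layout <- function(scenario) {
  scenario <- match.arg(scenario, c("two_tads", "ep_boundary_like",
                                    "forward_only_boundary",
                                    "divergent_vs_nondivergent_panel"))
  switch(scenario,
    two_tads = list(
      cbs = planted_cbs(c(199L, 201L), c("reverse", "forward")),
      masked_bins = c(97L, 98L),
      junctions = 200L,
      # clean-boundary scenario: steric blocking off so the insulation dip
      # is centred on the planted junction rather than on interference loops
      config_overrides = list(interference_enabled = FALSE)),
    ep_boundary_like = list(
      # R1,R2,F1,R3,F2,R4 with heterogeneous occupancy (R1/F1/F2 strong)
      cbs = planted_cbs(c(190L, 194L, 198L, 202L, 206L, 210L),
                        c("reverse", "reverse", "forward",
                          "reverse", "forward", "reverse"),
                        c(0.9, 0.5, 0.9, 0.7, 0.9, 0.5)),
      masked_bins = integer(0),
      junctions = 200L,
      config_overrides = list()),
    forward_only_boundary = list(
      cbs = planted_cbs(c(40L, 198L, 200L, 202L, 360L),
                        c("forward", "forward", "forward", "forward", "reverse")),
      masked_bins = integer(0),
      junctions = 200L,
      config_overrides = list()),
    divergent_vs_nondivergent_panel = list(
      cbs = rbind(
        planted_cbs(c(20L, 380L), c("forward", "reverse")),
        planted_cbs(c(129L, 131L, 135L, 137L),
                    c("reverse", "reverse", "forward", "forward")),
        planted_cbs(c(262L, 264L, 266L, 268L), "reverse")),
      masked_bins = integer(0),
      junctions = c(133L, 265L),
      config_overrides = list())
  )
}

#' Simulate a scenario in memory
#'
#' Runs [simulate_extrusion()] and [render_contact_map()] for a named
#' scenario and returns the rendered matrix with its ground truth.
#'
#' @param scenario scenario name (see [scenario_layout()]).
#' @param seed integer seed controlling all randomness of the run.
#' @param config_overrides named list of [sim_config()] fields to override.
#' @param interference optional logical overriding `interference_enabled`.
#' @return list with `matrix`, `truth`, `config`, `cbs`, `junctions`.
#' @export
simulate_scenario <- function(scenario, seed = 1L, config_overrides = list(),
                              interference = NULL) {
  lay <- scenario_layout(scenario)
  args <- utils::modifyList(lay$config_overrides, config_overrides)
  if (!is.null(interference)) args$interference_enabled <- interference
  args$seed <- as.integer(seed)
  cfg <- do.call(sim_config, args)
  snaps <- simulate_extrusion(cfg, lay$cbs)
  rend <- render_contact_map(snaps, cfg, masked_bins = lay$masked_bins)
  list(matrix = rend$matrix, truth = rend$truth, config = cfg,
       cbs = lay$cbs, junctions = lay$junctions)
}

#' Write a full synthetic dataset to disk
#'
#' Writes the rendered matrix (triplet TSV), the planted CBSs (BED6, strand
#' `+` = forward, score = `round(1000 * capture_prob)`), the expected loops
#' (BEDPE, anchor1 the lower-coordinate anchor) and the ground truth (JSON).
#' Rerunning with the same seed is byte-identical.
#'
#' @inheritParams simulate_scenario
#' @param out_dir output directory (created if missing).
#' @return invisibly, the named list of file paths.
#' @export
generate_dataset <- function(scenario, seed = 1L, out_dir,
                             config_overrides = list(), interference = NULL) {
  sim <- simulate_scenario(scenario, seed, config_overrides, interference)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  bs <- sim$config$bin_size_bp
  chrom <- sim$matrix$chrom
  paths <- list(matrix = file.path(out_dir, "matrix.tsv"),
                cbs = file.path(out_dir, "cbs.bed"),
                loops = file.path(out_dir, "loops.bedpe"),
                truth = file.path(out_dir, "truth.json"))
  write_contact_matrix(sim$matrix, paths$matrix)
  tr <- sim$truth
  bed <- sprintf("%s\t%d\t%d\tCBS_%d\t%d\t%s", chrom,
                 tr$cbs$bin * bs, (tr$cbs$bin + 1L) * bs,
                 seq_len(nrow(tr$cbs)), round(1000 * tr$cbs$capture_prob),
                 ifelse(tr$cbs$orientation == "forward", "+", "-"))
  writeLines(bed, paths$cbs)
  pairs <- rbind(tr$expected_convergent_pairs, tr$expected_nonconvergent_pairs)
  kind <- c(rep("convergent", nrow(tr$expected_convergent_pairs)),
            rep("nonconvergent", nrow(tr$expected_nonconvergent_pairs)))
  bedpe <- if (nrow(pairs)) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\tloop_%d\t%s", chrom,
            pairs[, 1] * bs, (pairs[, 1] + 1L) * bs, chrom,
            pairs[, 2] * bs, (pairs[, 2] + 1L) * bs,
            seq_len(nrow(pairs)), kind)
  } else character(0)
  writeLines(bedpe, paths$loops)
  jsonlite::write_json(
    list(cbs = tr$cbs,
         expected_convergent_pairs = tr$expected_convergent_pairs,
         expected_nonconvergent_pairs = tr$expected_nonconvergent_pairs,
         boundaries = tr$boundaries, masked_bins = tr$masked_bins),
    paths$truth, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(paths)
}
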