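#' Configuration for the 1D loop-extrusion simulator
#'
#' The simulator places cohesin-like extruders on a lattice of `n_bins` bins.
#' Each non-stalled leg moves one bin outward per step; a left-moving leg
#' stalls with the site's capture probability on entering a bin holding a
#' forward-oriented CBS, a right-moving leg likewise at a reverse-oriented
#' CBS (the convergent-loop rule). With `interference_enabled`, a leg may
#' never enter a bin occupied by another extruder's stalled leg: it parks in
#' the adjacent bin and stays blocked while the blocker persists — the steric
#' mechanism that produces paired nonconvergent loops.
#'
#' @param n_bins lattice size (>= 20).
#' @param bin_size_bp bin width in bp.
#' @param n_extruders number of extruders.
#' @param steps_per_snapshot steps between recorded snapshots.
#' @param n_snapshots number of snapshots after burn-in.
#' @param burn_in_steps steps discarded before the first snapshot.
#' @param unload_prob per-step, per-extruder unloading probability; unloaded
#'   extruders reload with both legs co-located at a uniform random bin.
#' @param capture_prob_default stalling probability at a cognate CBS, used
#'   when a planted CBS does not override it.
#' @param interference_enabled logical; steric blocking on/off.
#' @param intra_loop_samples random intra-loop contact pairs added per
#'   extruder per snapshot when rendering.
#' @param background_exponent distance-decay exponent of the background.
#' @param background_weight scalar weight of the background.
#' @param seed integer seed; if non-NULL, [simulate_extrusion()] and
#'   [render_contact_map()] are deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_bins = 400L, bin_size_bp = 10000L, n_extruders = 40L,
                       steps_per_snapshot = 5L, n_snapshots = 2000L,
                       burn_in_steps = 500L, unload_prob = 0.002,
                       capture_prob_default = 0.9, interference_enabled = TRUE,
                       intra_loop_samples = 3L, background_exponent = 1,
                       background_weight = 0.5, seed = NULL) {
  cfg <- list(n_bins = as.integer(n_bins), bin_size_bp = as.integer(bin_size_bp),
              n_extruders = as.integer(n_extruders),
              steps_per_snapshot = as.integer(steps_per_snapshot),
              n_snapshots = as.integer(n_snapshots),
              burn_in_steps = as.integer(burn_in_steps),
              unload_prob = unload_prob,
              capture_prob_default = capture_prob_default,
              interference_enabled = isTRUE(interference_enabled),
              intra_loop_samples = as.integer(intra_loop_samples),
              background_exponent = background_exponent,
              background_weight = background_weight, seed = seed)
  probs <- c(cfg$unload_prob, cfg$capture_prob_default)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_bins < 20) stop("n_bins must be >= 20")
  counts <- c(cfg$n_extruders, cfg$steps_per_snapshot, cfg$n_snapshots,
              cfg$burn_in_steps, cfg$intra_loop_samples)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$background_exponent <= 0) stop("background_exponent must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Planted CTCF binding sites for the simulator
#'
#' @param bin 0-based lattice bin indices.
#' @param orientation `"forward"` or `"reverse"` per site. A forward CBS
#'   stalls left-moving legs (it is the left anchor of rightward loops); a
#'   reverse CBS stalls right-moving legs.
#' @param capture_prob per-site stalling probability (occupancy proxy); NA
#'   entries take the config default.
#' @return data.frame with columns `bin`, `orientation`, `capture_prob`.
#' @export
planted_cbs <- function(bin, orientation, capture_prob = NA_real_) {
  if (!length(bin))
    return(data.frame(bin = integer(0), orientation = character(0),
                      capture_prob = numeric(0)))
  orientation <- match.arg(orientation, c("forward", "reverse"), several.ok = TRUE)
  if (length(orientation) == 1) orientation <- rep(orientation, length(bin))
  data.frame(bin = as.integer(bin), orientation = orientation,
             capture_prob = rep_len(as.numeric(capture_prob), length(bin)))
}

validate_cbs <- function(cbs, config) {
  if (is.null(cbs) || !nrow(cbs)) return(invisible(TRUE))
  if (any(cbs$bin < 0 | cbs$bin >= config$n_bins))
    stop("CBS bin out of range [0, n_bins)")
  if (anyDuplicated(cbs$bin)) stop("CBS bins must be unique")
  ok <- cbs$orientation %in% c("forward", "reverse")
  if (!all(ok)) stop("orientation must be 'forward' or 'reverse'")
  cp <- cbs$capture_prob
  if (any(!is.na(cp) & (cp < 0 | cp > 1))) stop("capture_prob must lie in [0, 1]")
  invisible(TRUE)
}

#' Run the loop-extrusion simulation
#'
#' Steps the extruder ensemble and records leg positions and stall states at
#' regular snapshots. Deterministic given `config$seed` (or the R RNG state
#' when `seed` is NULL).
#'
#' @param config a [sim_config()].
#' @param cbs planted sites from [planted_cbs()] (may be NULL/empty).
#' @param init optional data.frame with columns `left`, `right`,
#'   `left_state`, `right_state` (states 0 = moving, 1 = CBS-stalled,
#'   2 = blocked) giving the initial ensemble; defaults to co-located legs at
#'   uniform random bins.
#' @return object of class `extrusion_snapshots`: integer matrices `left`,
#'   `right`, `left_state`, `right_state` (`n_snapshots x n_extruders`), plus
#'   the config and CBS table.
#' @export
simulate_extrusion <- function(config, cbs = NULL, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_cbs(cbs, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_bins
  fwd <- rev_ <- numeric(n)
  if (!is.null(cbs) && nrow(cbs)) {
    cp <- ifelse(is.na(cbs$capture_prob), config$capture_prob_default, cbs$capture_prob)
    f <- cbs$orientation == "forward"
    fwd[cbs$bin[f] + 1L] <- cp[f]
    rev_[cbs$bin[!f] + 1L] <- cp[!f]
  }
  ne <- config$n_extruders
  if (is.null(init)) {
    u <- if (ne > 0) as.integer(floor(stats::runif(ne) * n)) else integer(0)
    u[u >= n] <- n - 1L
    init <- data.frame(left = u, right = u,
                       left_state = integer(ne), right_state = integer(ne))
  }
  if (nrow(init) != ne) stop("init must have one row per extruder")
  if (any(init$left > init$right)) stop("init: left leg must be <= right leg")
  snaps <- cpp_simulate_extrusion(
    n, ne, config$burn_in_steps, config$steps_per_snapshot, config$n_snapshots,
    config$unload_prob, config$interference_enabled, fwd, rev_,
    as.integer(init$left), as.integer(init$right),
    as.integer(init$left_state), as.integer(init$right_state))
  structure(c(snaps, list(config = config, cbs = cbs)),
            class = "extrusion_snapshots")
}

#' @export
print.extrusion_snapshots <- function(x, ...) {
  cat(sprintf("<extrusion_snapshots> %d snapshots x %d extruders on %d bins\n",
              nrow(x$left), ncol(x$left), x$config$n_bins))
  invisible(x)
}

#' Render a Hi-C-like contact map from extrusion snapshots
#'
#' Adds a deterministic distance-decay background
#' `background_weight * (|i-j|+1)^-background_exponent`, one count per
#' extruder per snapshot at its (left, right) pixel, and
#' `intra_loop_samples` uniformly sampled bin pairs inside each extruded
#' interval. Masked bins have all contacts zeroed.
#'
#' @param snapshots an `extrusion_snapshots` object.
#' @param config the [sim_config()] used (defaults to the one stored in
#'   `snapshots`).
#' @param masked_bins 0-based bins to zero out (low-mappability emulation).
#' @param chrom region name for the output matrix.
#' @return list with `matrix` (a `contact_matrix`) and `truth` (planted CBSs,
#'   boundary bins, expected convergent and nonconvergent pairs, masked
#'   bins).
#' @export
render_contact_map <- function(snapshots, config = snapshots$config,
                               masked_bins = integer(0), chrom = "chrS") {
  if (is.null(snapshots$left)) stop("need extrusion snapshots")
  if (nrow(snapshots$left) < 1) stop("need at least one snapshot")
  n <- config$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  counts <- config$background_weight * (d + 1)^(-config$background_exponent)
  L <- as.vector(snapshots$left); R <- as.vector(snapshots$right)
  if (length(L)) {
    add_pairs <- function(cnt, i, j) {
      lo <- pmin(i, j); hi <- pmax(i, j)
      idx <- lo + n * hi + 1L # 0-based bins -> upper-triangle linear index
      tab <- tabulate(idx, nbins = n * n)
      inc <- matrix(tab, n, n)
      inc <- inc + t(inc)
      diag(inc) <- diag(inc) / 2
      cnt + inc
    }
    counts <- add_pairs(counts, L, R)
    s <- config$intra_loop_samples
    if (s > 0) {
      len <- R - L + 1L
      Lrep <- rep(L, each = s); lenrep <- rep(len, each = s)
      u1 <- Lrep + as.integer(floor(stats::runif(length(Lrep)) * lenrep))
      u2 <- Lrep + as.integer(floor(stats::runif(length(Lrep)) * lenrep))
      counts <- add_pairs(counts, pmin(u1, lenrep + Lrep - 1L), pmin(u2, lenrep + Lrep - 1L))
    }
  }
  mask <- rep(FALSE, n)
  mask[masked_bins + 1L] <- TRUE
  m <- contact_matrix(counts, config$bin_size_bp, chrom, mask = mask)
  truth <- ground_truth(snapshots$cbs, config, masked_bins)
  list(matrix = m, truth = truth)
}

# Ground-truth annotations recovered by downstream tests: boundaries are CBS
# bins with capture >= 0.5; convergent pairs pair each forward CBS with the
# nearest reverse CBS to its right; expected nonconvergent pairs mark, when
# interference is on, the bin adjacent to the rightmost member of a forward
# cluster reachable (no intervening reverse CBS, gap > 10 bins) from another
# forward CBS to its left -- where blocked legs park.
ground_truth <- function(cbs, config, masked_bins = integer(0)) {
  if (is.null(cbs)) cbs <- planted_cbs(integer(0), character(0))
  cp <- ifelse(is.na(cbs$capture_prob), config$capture_prob_default, cbs$capture_prob)
  ord <- order(cbs$bin)
  cbs <- cbs[ord, , drop = FALSE]; cp <- cp[ord]
  fwd <- cbs$bin[cbs$orientation == "forward"]
  rev_ <- cbs$bin[cbs$orientation == "reverse"]
  conv <- NULL
  for (f in fwd) {
    r <- rev_[rev_ > f]
    if (length(r)) conv <- rbind(conv, c(f, min(r)))
  }
  nonconv <- NULL
  if (config$interference_enabled && length(fwd) >= 2) {
    # group forward CBSs into clusters of members within 5 bins
    cl <- cumsum(c(1L, diff(fwd) > 5))
    for (k in unique(cl)) {
      members <- fwd[cl == k]
      f_max <- max(members)
      left_fwd <- fwd[cl != k & fwd < min(members)]
      if (!length(left_fwd)) next
      partner <- max(left_fwd)
      if (min(members) - partner <= 10) next
      if (any(rev_ > partner & rev_ < min(members))) next
      nonconv <- rbind(nonconv, c(partner, f_max - 1L))
    }
  }
  as_pairs <- function(x) if (is.null(x)) matrix(integer(0), 0, 2) else x
  list(cbs = data.frame(bin = cbs$bin, orientation = cbs$orientation,
                        capture_prob = cp),
       boundaries = cbs$bin[cp >= 0.5],
       expected_convergent_pairs = as_pairs(conv),
       expected_nonconvergent_pairs = as_pairs(nonconv),
       masked_bins = as.integer(masked_bins))
}
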