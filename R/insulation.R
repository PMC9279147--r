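#' Per-bin insulation score
#'
#' For each bin `i`, the raw score is the mean balanced signal in the square
#' window `[i-w, i-1] x [i+1, i+w]` straddling the diagonal (restricted to
#' unmasked pixels); the track is `IS(i) = log2(raw(i) / mean(raw))`, the
#' log2 ratio to the arithmetic mean over valid bins. Bins within `w` of the
#' matrix edge, with more than 50% of their window masked, or with zero raw
#' signal, are invalid.
#'
#' @param m a balanced `contact_matrix`.
#' @param window_bp window size in bp; must be a multiple of `bin_size`
#'   (e.g. 250 kb on 25-kb bins gives w = 10 bins).
#' @return object of class `insulation_track`: fields `values`, `valid`,
#'   `window_bins`, `bin_size`, `chrom`.
#' @export
insulation_score <- function(m, window_bp = 250000) {
  if (window_bp %% m$bin_size != 0)
    stop("window_bp must be a multiple of bin_size")
  w <- as.integer(window_bp / m$bin_size)
  if (w < 1) stop("window must span at least one bin")
  n <- m$n_bins
  if (w >= n / 2) stop("window too large: w must be < n_bins / 2")
  b <- balanced_counts(m)
  raw <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    win <- b[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    n_na <- sum(is.na(win))
    if (n_na > 0.5 * length(win)) next
    r <- mean(win, na.rm = TRUE)
    if (!is.finite(r) || r <= 0) next
    raw[i] <- r
    valid[i] <- TRUE
  }
  if (!any(valid)) stop("no valid bins for insulation track")
  values <- rep(NA_real_, n)
  values[valid] <- log2(raw[valid] / mean(raw[valid]))
  structure(list(values = values, valid = valid, window_bins = w,
                 bin_size = m$bin_size, chrom = m$chrom),
            class = "insulation_track")
}

#' Construct an insulation track from precomputed values
#'
#' Useful for feeding externally computed or hand-built tracks into
#' [call_boundaries()].
#'
#' @param values per-bin insulation values (`NA` = invalid).
#' @param valid logical; defaults to `!is.na(values)`.
#' @param window_bins,bin_size,chrom track metadata.
#' @return an `insulation_track`.
#' @export
insulation_track <- function(values, valid = !is.na(values), window_bins = 1L,
                             bin_size = 1L, chrom = "chrS") {
  structure(list(values = values, valid = valid,
                 window_bins = as.integer(window_bins),
                 bin_size = as.integer(bin_size), chrom = chrom),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat(sprintf("<insulation_track> %s: %d bins (w = %d), %d valid\n",
              x$chrom, length(x$values), x$window_bins, sum(x$valid)))
  invisible(x)
}

#' Call boundaries at local insulation minima
#'
#' A boundary is placed at every strict local minimum of the valid track
#' (plateaus resolve to their leftmost bin). The boundary score is the depth
#' to the lower of the two nearest flanking maxima,
#' `BS = min(IS_leftmax, IS_rightmax) - IS(min)`; the edges of a contiguous
#' valid segment act as flanking maxima. Boundaries within the mappability
#' exclusion radius of a low-mappability bin are flagged `filtered` (kept in
#' the output, excluded from summaries downstream).
#'
#' @param track an `insulation_track`.
#' @param mask optional [fit_mappability_mask()] result, or a logical per-bin
#'   low-mappability vector.
#' @param exclusion_radius_bp exclusion radius around low-mappability bins
#'   (default 125 kb), used when `mask` is a plain logical vector.
#' @param smooth_bins half-width of a moving-average smoother applied to the
#'   track (within valid segments) before minima detection; 0 (default)
#'   calls on the raw track. Smoothing suppresses single-bin noise bumps
#'   that would otherwise truncate the depth measure.
#' @return data.frame with columns `bin` (0-based), `insulation`,
#'   `boundary_score`, `filtered`.
#' @export
call_boundaries <- function(track, mask = NULL, exclusion_radius_bp = 125000,
                            smooth_bins = 0L) {
  v <- track$values
  ok <- track$valid & !is.na(v)
  if (smooth_bins > 0) {
    sm <- v
    for (i in which(ok)) {
      lo <- max(1, i - smooth_bins); hi <- min(length(v), i + smooth_bins)
      w <- v[lo:hi][ok[lo:hi]]
      sm[i] <- mean(w)
    }
    v <- sm
  }
  if (!any(ok)) stop("track has no valid bins")
  low <- rep(FALSE, length(v))
  if (inherits(mask, "mappability_mask")) {
    low <- mask$low
    exclusion_radius_bp <- mask$exclusion_radius_bp
  } else if (!is.null(mask)) {
    low <- as.logical(mask)
  }
  res <- NULL
  seg_id <- cumsum(c(ok[1], diff(ok) == 1))
  for (s in unique(seg_id[ok])) {
    bins <- which(ok & seg_id == s)
    if (length(bins) < 3) next
    r <- rle(v[bins])
    k <- length(r$values)
    if (k < 3) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    is_min <- c(FALSE, r$values[2:(k - 1)] < r$values[1:(k - 2)] &
                         r$values[2:(k - 1)] < r$values[3:k], FALSE)
    # flank maxima: interior runs higher than both neighbours, plus segment ends
    is_max <- c(TRUE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                        r$values[2:(k - 1)] > r$values[3:k], TRUE)
    for (j in which(is_min)) {
      left <- max(which(is_max[seq_len(j - 1)]))
      right <- j + min(which(is_max[(j + 1):k]))
      bs <- min(r$values[left], r$values[right]) - r$values[j]
      res <- rbind(res, data.frame(bin = bins[starts[j]] - 1L,
                                   insulation = r$values[j],
                                   boundary_score = bs))
    }
  }
  if (is.null(res))
    return(data.frame(bin = integer(0), insulation = numeric(0),
                      boundary_score = numeric(0), filtered = logical(0)))
  if (any(low)) {
    low_bins <- which(low) - 1L
    dist_bp <- vapply(res$bin, function(b)
      min(abs(b - low_bins)) * track$bin_size, numeric(1))
    res$filtered <- dist_bp <= exclusion_radius_bp
  } else {
    res$filtered <- FALSE
  }
  rownames(res) <- NULL
  res
}

#' Fit a low-mappability mask from raw marginal counts
#'
#' Fits a two-component Gaussian mixture to `log1p` of the per-bin marginal
#' counts of the raw matrix; bins with posterior probability > 0.5 for the
#' lower-mean component are flagged as low-mappability. If the fitted means
#' differ by less than one pooled standard deviation, or the lower-mean
#' component is the majority component, or it holds fewer than 1% of bins
#' (a mappability dropout class is a minority class with real support, not a
#' lone depleted bin), there is no separable low-mappability class and
#' nothing is flagged. Bins with zero marginals are always flagged.
#'
#' @param m a raw (unbalanced) `contact_matrix`.
#' @param exclusion_radius_bp radius used downstream to filter boundaries
#'   near flagged bins (default 125 kb, i.e. 5 bins at 25-kb resolution).
#' @return object of class `mappability_mask`: `low` (logical per bin),
#'   `gmm` (means, variances, weights or NULL), `exclusion_radius_bp`,
#'   `bin_size`.
#' @export
fit_mappability_mask <- function(m, exclusion_radius_bp = 125000) {
  n <- m$n_bins
  if (n < 10) stop("need at least 10 bins to fit a mappability mask")
  marg <- rowSums(m$counts)
  low <- marg == 0
  gmm <- NULL
  pos <- which(!low)
  x <- log1p(marg[pos])
  if (length(pos) >= 10 && length(unique(round(x, 10))) >= 3 && stats::sd(x) > 1e-12) {
    mclustBIC <- mclust::mclustBIC # Mclust resolves it in the caller frame
    fit <- tryCatch(
      mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) {
      mu <- fit$parameters$mean
      sig2 <- fit$parameters$variance$sigmasq
      if (length(sig2) == 1) sig2 <- rep(sig2, 2)
      pro <- fit$parameters$pro
      gmm <- list(means = mu, variances = sig2, weights = pro)
      pooled_sd <- sqrt(sum(pro * sig2))
      lowcomp <- which.min(mu)
      flag <- fit$z[, lowcomp] > 0.5
      # a separable mappability class is a minority class with real support:
      # at least 2 bins and 1% of the lattice, clearly below the main mode
      if (abs(diff(mu)) >= pooled_sd && pro[lowcomp] <= 0.5 &&
          sum(flag) >= max(2L, ceiling(0.01 * n))) {
        low[pos[flag]] <- TRUE
      }
    }
  }
  structure(list(low = low, gmm = gmm,
                 exclusion_radius_bp = exclusion_radius_bp,
                 bin_size = m$bin_size),
            class = "mappability_mask")
}

#' @export
print.mappability_mask <- function(x, ...) {
  cat(sprintf("<mappability_mask> %d/%d bins flagged (exclusion %g bp)\n",
              sum(x$low), length(x$low), x$exclusion_radius_bp))
  invisible(x)
}

#' Write an insulation track as bedGraph
#'
#' Valid bins only; 0-based half-open intervals.
#'
#' @param track an `insulation_track`.
#' @param path output file.
#' @param chrom chromosome name (defaults to the track's).
#' @export
write_insulation_bedgraph <- function(track, path, chrom = track$chrom) {
  bins <- which(track$valid) - 1L
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, bins * track$bin_size,
                     (bins + 1L) * track$bin_size,
                     formatC(track$values[bins + 1L], format = "g", digits = 8)),
             path)
  invisible(path)
}

#' Write boundary calls as BED
#'
#' Score column holds `round(1000 * boundary_score)`; filtered calls are
#' skipped.
#'
#' @param calls data.frame from [call_boundaries()].
#' @param path output file.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @export
write_boundaries_bed <- function(calls, path, bin_size, chrom = "chrS") {
  keep <- calls[!calls$filtered, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\tboundary_%d\t%d\t.", chrom,
                     keep$bin * bin_size, (keep$bin + 1L) * bin_size,
                     seq_len(nrow(keep)), round(1000 * keep$boundary_score)),
             path)
  invisible(path)
}

#' Convert boundary calls to genomic intervals
#'
#' @param calls data.frame from [call_boundaries()].
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @return data.frame with `id`, `chrom`, `start`, `end` (0-based half-open,
#'   one bin wide) and `boundary_score`.
#' @export
boundaries_to_bp <- function(calls, bin_size, chrom = "chrS") {
  data.frame(id = sprintf("boundary_%d", seq_len(nrow(calls))),
             chrom = chrom, start = calls$bin * bin_size,
             end = (calls$bin + 1L) * bin_size,
             boundary_score = calls$boundary_score,
             filtered = calls$filtered)
}
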