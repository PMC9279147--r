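#' Classify loop anchors by CBS orientation and loop directions
#'
#' Anchor intervals from all loops are merged when they overlap after
#' padding each side by `anchor_merge_bp` (multi-resolution loop calls share
#' overlapping anchors). Each merged anchor records its rightward loops
#' (where it is the lower-coordinate anchor), leftward loops, and the CBSs it
#' overlaps. An anchor "has a directional CBS" for rightward loops iff it
#' contains a forward CBS, for leftward loops iff a reverse CBS. Categories:
#' `no_ctcf` (zero CBSs), `nonconvergent` (anchors at least one loop in a
#' direction lacking a directional CBS), else `convergent_only`. An anchor is
#' `bidirectional` when it anchors loops in both directions.
#'
#' @param loops data.frame with `chrom`, `start1`, `end1`, `start2`, `end2`
#'   (bp, 0-based half-open, anchor1 the lower-coordinate anchor) and
#'   optionally `id`.
#' @param cbs data.frame with `chrom`, `start`, `end`, `orientation`.
#' @param anchor_merge_bp padding added to each anchor side before merging
#'   (default one 10-kb bin).
#' @return object of class `anchor_set`: `anchors` (one row per merged
#'   anchor: `anchor_id`, `chrom`, `start`, `end`, `n_cbs`, `has_forward`,
#'   `has_reverse`, `n_rightward`, `n_leftward`, `category`,
#'   `bidirectional`), `loop_map` (`loop_id`, `anchor1_id`, `anchor2_id`) and
#'   the input `loops`.
#' @export
classify_anchors <- function(loops, cbs, anchor_merge_bp = 10000) {
  if (anchor_merge_bp < 0) stop("anchor_merge_bp must be >= 0")
  loops <- validate_loops(loops)
  nl <- nrow(loops)
  iv <- data.frame(
    chrom = rep(loops$chrom, 2),
    start = c(loops$start1, loops$start2),
    end = c(loops$end1, loops$end2),
    loop = rep(seq_len(nl), 2),
    side = rep(1:2, each = nl))
  anchors <- NULL
  map1 <- map2 <- integer(nl)
  next_id <- 0L
  for (chrom in unique(iv$chrom)) {
    sub <- iv[iv$chrom == chrom, , drop = FALSE]
    padded <- IRanges::IRanges(start = sub$start + 1L - anchor_merge_bp,
                               end = sub$end + anchor_merge_bp)
    merged <- IRanges::reduce(padded)
    grp <- IRanges::findOverlaps(padded, merged, select = "first")
    for (g in sort(unique(grp))) {
      next_id <- next_id + 1L
      rows <- sub[grp == g, , drop = FALSE]
      a_start <- min(rows$start); a_end <- max(rows$end)
      on_chrom <- cbs[cbs$chrom == chrom, , drop = FALSE]
      hit <- on_chrom[on_chrom$end > a_start & on_chrom$start < a_end, , drop = FALSE]
      right_loops <- rows$loop[rows$side == 1]
      left_loops <- rows$loop[rows$side == 2]
      map1[right_loops] <- next_id
      map2[left_loops] <- next_id
      has_f <- any(hit$orientation == "forward")
      has_r <- any(hit$orientation == "reverse")
      category <- if (nrow(hit) == 0) "no_ctcf"
      else if ((length(right_loops) > 0 && !has_f) ||
               (length(left_loops) > 0 && !has_r)) "nonconvergent"
      else "convergent_only"
      anchors <- rbind(anchors, data.frame(
        anchor_id = next_id, chrom = chrom, start = a_start, end = a_end,
        n_cbs = nrow(hit), has_forward = has_f, has_reverse = has_r,
        n_rightward = length(right_loops), n_leftward = length(left_loops),
        category = category,
        bidirectional = length(right_loops) > 0 && length(left_loops) > 0))
    }
  }
  rownames(anchors) <- NULL
  structure(list(anchors = anchors,
                 loop_map = data.frame(loop_id = loops$id,
                                       anchor1_id = map1, anchor2_id = map2),
                 loops = loops),
            class = "anchor_set")
}

validate_loops <- function(loops) {
  if (!nrow(loops)) stop("no loops")
  need <- c("chrom", "start1", "end1", "start2", "end2")
  if (!all(need %in% names(loops))) stop("loops need columns ", paste(need, collapse = ", "))
  if (any(loops$start1 >= loops$start2))
    stop("anchor1 must be the lower-coordinate anchor")
  if (any(loops$end1 > loops$start2))
    stop("loop anchors must not overlap")
  if (is.null(loops$id)) loops$id <- sprintf("loop_%d", seq_len(nrow(loops)))
  loops
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> %d anchors / %d loops: %s\n",
              nrow(x$anchors), nrow(x$loop_map),
              paste(sprintf("%s=%d", names(table(x$anchors$category)),
                            table(x$anchors$category)), collapse = ", ")))
  invisible(x)
}

#' Classify loops into convergence categories
#'
#' A loop is convergent iff its lower anchor contains at least one forward
#' CBS and its upper anchor at least one reverse CBS. Convergent loops
#' subdivide by what their anchors do in the opposite direction:
#' `convergent_associated` (some anchor engages a nonconvergent loop in the
#' opposite direction), else `double_sided_convergent` (some anchor engages a
#' convergent loop in the opposite direction), else
#' `single_sided_convergent`. Nonconvergent loops are
#' `nonconvergent_associated` when an anchor engages a convergent loop in the
#' opposite direction, else `nonconvergent`.
#'
#' @param anchor_set result of [classify_anchors()].
#' @return data.frame with `loop_id`, `convergent`, `category`.
#' @export
classify_loops <- function(anchor_set) {
  a <- anchor_set$anchors
  m <- anchor_set$loop_map
  nl <- nrow(m)
  conv <- a$has_forward[m$anchor1_id] & a$has_reverse[m$anchor2_id]
  category <- character(nl)
  for (k in seq_len(nl)) {
    a1 <- m$anchor1_id[k]; a2 <- m$anchor2_id[k]
    # opposite-direction partners: leftward loops at the lower anchor,
    # rightward loops at the upper anchor (excluding this loop itself)
    opp <- c(which(m$anchor2_id == a1), which(m$anchor1_id == a2))
    opp <- setdiff(opp, k)
    if (conv[k]) {
      category[k] <- if (any(!conv[opp])) "convergent_associated"
      else if (any(conv[opp])) "double_sided_convergent"
      else "single_sided_convergent"
    } else {
      category[k] <- if (any(conv[opp])) "nonconvergent_associated"
      else "nonconvergent"
    }
  }
  data.frame(loop_id = m$loop_id, convergent = conv, category = category)
}

#' Bidirectional-anchor fractions and contingency tests
#'
#' Computes the fraction of bidirectional anchors per category, an omnibus
#' chi-squared test on the category-by-bidirectional table (2 df for the
#' three categories) and pairwise post-hoc chi-squared tests with
#' Benjamini-Hochberg correction. No continuity correction is applied.
#' Categories with zero anchors are dropped with a warning.
#'
#' @param anchors an `anchor_set` or its `anchors` data.frame (needs
#'   `category` and `bidirectional` columns).
#' @return list with `fractions` (per-category `n`, `n_bidirectional`,
#'   `fraction`), `omnibus` (`statistic`, `df`, `p_value`) and `posthoc`
#'   (pairwise `statistic`, `p_value`, `p_adjusted`).
#' @export
bidirectional_stats <- function(anchors) {
  if (inherits(anchors, "anchor_set")) anchors <- anchors$anchors
  cats <- c("convergent_only", "nonconvergent", "no_ctcf")
  present <- cats[cats %in% anchors$category]
  if (length(setdiff(cats, present)))
    warning("categories with zero anchors dropped: ",
            paste(setdiff(cats, present), collapse = ", "))
  if (length(present) < 2)
    stop("omnibus test undefined with fewer than 2 categories")
  tab <- table(factor(anchors$category, levels = present),
               factor(anchors$bidirectional, levels = c(FALSE, TRUE)))
  fractions <- data.frame(
    category = present, n = as.integer(rowSums(tab)),
    n_bidirectional = as.integer(tab[, 2]),
    fraction = as.numeric(tab[, 2] / rowSums(tab)))
  omnibus <- chisq_raw(tab)
  pairs <- utils::combn(present, 2, simplify = FALSE)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    sub <- tab[pr, , drop = FALSE]
    ct <- chisq_raw(sub)
    data.frame(category_a = pr[1], category_b = pr[2],
               statistic = ct$statistic, p_value = ct$p_value)
  }))
  posthoc$p_adjusted <- stats::p.adjust(posthoc$p_value, method = "BH")
  list(fractions = fractions, omnibus = omnibus, posthoc = posthoc)
}

# chi-squared without continuity correction; degenerate tables (a zero
# margin) have statistic 0 and p 1
chisq_raw <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, df = (nrow(tab) - 1) * (ncol(tab) - 1), p_value = 1))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Loop strength from an obs/exp matrix
#'
#' `log2` enrichment of the loop pixel's center square over the two corner
#' squares of the surrounding window that lie along the diagonal direction
#' (same genomic distance as the pixel): corners at offsets `-window_bins`
#' and `+window_bins` on both axes, each of side `center_bins`, pooled.
#'
#' @param oe obs/exp matrix (from [oe_transform()]).
#' @param i,j 0-based bin coordinates of the loop pixel (`i < j`).
#' @param window_bins half-width of the evaluation window (default 10).
#' @param center_bins side of the center and corner squares (odd, default 3).
#' @return the strength, or `NA` when a region is fully undefined.
#' @export
loop_strength <- function(oe, i, j, window_bins = 10L, center_bins = 3L) {
  n <- nrow(oe)
  hw <- window_bins; hc <- (center_bins - 1L) %/% 2L
  i <- i + 1L; j <- j + 1L # to 1-based
  if (i - hw < 1 || j - hw < 1 || i + hw > n || j + hw > n)
    stop("window exceeds matrix bounds")
  center <- oe[(i - hc):(i + hc), (j - hc):(j + hc)]
  c1 <- oe[(i - hw):(i - hw + center_bins - 1L),
           (j - hw):(j - hw + center_bins - 1L)]
  c2 <- oe[(i + hw - center_bins + 1L):(i + hw),
           (j + hw - center_bins + 1L):(j + hw)]
  corners <- c(c1, c2)
  if (all(is.na(center)) || all(is.na(corners))) return(NA_real_)
  log2(mean(center, na.rm = TRUE) / mean(corners, na.rm = TRUE))
}

#' Strengths for a set of loops
#'
#' Maps each loop to its pixel (anchor-midpoint bins) and evaluates
#' [loop_strength()]; loops whose window leaves the matrix are `NA`.
#'
#' @param loops loops data.frame (see [classify_anchors()]).
#' @param oe obs/exp matrix.
#' @param bin_size bin width in bp.
#' @inheritParams loop_strength
#' @return numeric vector of strengths, one per loop.
#' @export
loop_strengths <- function(loops, oe, bin_size, window_bins = 10L,
                           center_bins = 3L) {
  i <- pmin(loop_bin(loops$start1, loops$end1, bin_size),
            loop_bin(loops$start2, loops$end2, bin_size))
  j <- pmax(loop_bin(loops$start1, loops$end1, bin_size),
            loop_bin(loops$start2, loops$end2, bin_size))
  vapply(seq_along(i), function(k) {
    tryCatch(loop_strength(oe, i[k], j[k], window_bins, center_bins),
             error = function(e) NA_real_)
  }, numeric(1))
}

loop_bin <- function(start, end, bin_size) {
  as.integer(floor(((start + end) / 2) / bin_size))
}

#' Aggregate loop signal (APA-style)
#'
#' Elementwise mean of the `(2 * window_bins + 1)^2` obs/exp windows centered
#' on each usable loop pixel (undefined cells ignored per position).
#'
#' @inheritParams loop_strengths
#' @param window_bins window half-width.
#' @return list with `apa` (the mean window) and `n_loops` (contributing
#'   loops).
#' @export
aggregate_loops <- function(loops, oe, bin_size, window_bins = 10L) {
  n <- nrow(oe); w <- window_bins
  i <- loop_bin(loops$start1, loops$end1, bin_size) + 1L
  j <- loop_bin(loops$start2, loops$end2, bin_size) + 1L
  usable <- i - w >= 1 & j - w >= 1 & i + w <= n & j + w <= n
  if (!any(usable)) stop("zero usable loops for aggregation")
  acc <- matrix(0, 2 * w + 1, 2 * w + 1)
  cnt <- matrix(0, 2 * w + 1, 2 * w + 1)
  for (k in which(usable)) {
    win <- oe[(i[k] - w):(i[k] + w), (j[k] - w):(j[k] + w)]
    ok <- !is.na(win)
    acc[ok] <- acc[ok] + win[ok]
    cnt <- cnt + ok
  }
  apa <- acc / cnt
  apa[cnt == 0] <- NA_real_
  list(apa = apa, n_loops = sum(usable))
}

#' TAD-corner association and anchor distances per loop category
#'
#' Flags each loop as corner-associated when both anchors lie within
#' `zone_bins` of a boundary bin; reports per-category fractions and
#' anchor-distance comparisons (Kruskal-Wallis over categories, then, when
#' significant at 0.05, pairwise Mann-Whitney tests with BH correction).
#'
#' @param loops loops data.frame.
#' @param categories data.frame from [classify_loops()] (matched by row
#'   order).
#' @param boundary_bins 0-based boundary bins, or NULL (corner fractions
#'   undefined; distances still computed).
#' @param bin_size bin width in bp.
#' @param zone_bins corner zone radius in bins (default 2).
#' @return list with `loops` (input plus `at_tad_corner`, `distance`,
#'   `category`), `corner_fractions`, `kruskal` and `pairwise`.
#' @export
corner_association <- function(loops, categories, boundary_bins, bin_size,
                               zone_bins = 2L) {
  loops$category <- categories$category
  loops$distance <- loops$start2 - loops$start1
  if (is.null(boundary_bins) || !length(boundary_bins)) {
    loops$at_tad_corner <- NA
    corner_fractions <- NULL
  } else {
    near <- function(b) vapply(b, function(x) min(abs(x - boundary_bins)) <= zone_bins,
                               logical(1))
    b1 <- loop_bin(loops$start1, loops$end1, bin_size)
    b2 <- loop_bin(loops$start2, loops$end2, bin_size)
    loops$at_tad_corner <- near(b1) & near(b2)
    corner_fractions <- stats::aggregate(
      at_tad_corner ~ category, data = loops, FUN = mean)
  }
  kr <- if (length(unique(loops$category)) >= 2) {
    kt <- stats::kruskal.test(distance ~ factor(category), data = loops)
    list(statistic = unname(kt$statistic), p_value = kt$p.value)
  } else list(statistic = NA_real_, p_value = NA_real_)
  pairwise <- NULL
  if (!is.na(kr$p_value) && kr$p_value < 0.05) {
    cats <- sort(unique(loops$category))
    prs <- utils::combn(cats, 2, simplify = FALSE)
    pairwise <- do.call(rbind, lapply(prs, function(pr) {
      wt <- suppressWarnings(stats::wilcox.test(
        loops$distance[loops$category == pr[1]],
        loops$distance[loops$category == pr[2]]))
      data.frame(category_a = pr[1], category_b = pr[2],
                 statistic = unname(wt$statistic), p_value = wt$p.value)
    }))
    pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = "BH")
  }
  list(loops = loops, corner_fractions = corner_fractions,
       kruskal = kr, pairwise = pairwise)
}

#' Simple local-enrichment loop caller
#'
#' Stand-in caller that closes the synthetic pipeline end to end: pixels that
#' exceed `threshold`, lie more than 2 bins off-diagonal and are the maximum
#' of their Chebyshev `radius_bins` neighborhood (ties resolve to the
#' lexicographically smallest pixel) become loops whose anchors are the pixel
#' bins expanded to bin intervals. Deterministic.
#'
#' @param oe obs/exp matrix.
#' @param threshold minimum obs/exp value (> 1).
#' @param radius_bins non-maximum suppression radius.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name for the output.
#' @param counts optional raw count matrix for an absolute-support filter.
#' @param min_count with `counts`, pixels below this raw support are never
#'   called (suppresses obs/exp spikes at sparsely sampled distances, the
#'   analogue of an enrichment caller's observed-count requirement).
#' @param min_separation_bins minimum anchor separation; the default 3
#'   excludes pixels within 2 bins of the diagonal, larger values restrict
#'   calling to a long-range distance window.
#' @return loops data.frame (`chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `id`, `oe`), possibly empty.
#' @export
call_loops_simple <- function(oe, threshold, radius_bins = 2L,
                              bin_size = 10000L, chrom = "chrS",
                              counts = NULL, min_count = 0,
                              min_separation_bins = 3L) {
  if (threshold <= 1) stop("threshold must be > 1")
  n <- nrow(oe)
  sel <- !is.na(oe) & oe > threshold &
    col(oe) - row(oe) >= max(3L, min_separation_bins)
  if (!is.null(counts) && min_count > 0) sel <- sel & counts >= min_count
  cand <- which(sel, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  r <- radius_bins
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- oe[max(1, i - r):min(n, i + r), max(1, j - r):min(n, j + r)]
    v <- oe[i, j]
    mx <- max(nb, na.rm = TRUE)
    if (v < mx) next
    # tie-break: survive only if no equal-valued pixel precedes lexicographically
    ties <- which(!is.na(nb) & nb == v, arr.ind = TRUE)
    ti <- ties[, 1] + max(1, i - r) - 1L
    tj <- ties[, 2] + max(1, j - r) - 1L
    first <- order(ti, tj)[1]
    keep[k] <- ti[first] == i && tj[first] == j
  }
  cand <- cand[keep, , drop = FALSE]
  i0 <- cand[, 1] - 1L; j0 <- cand[, 2] - 1L
  data.frame(chrom = rep(chrom, length(i0)),
             start1 = i0 * bin_size, end1 = (i0 + 1L) * bin_size,
             start2 = j0 * bin_size, end2 = (j0 + 1L) * bin_size,
             id = if (length(i0)) sprintf("sloop_%d", seq_along(i0)) else character(0),
             oe = oe[cand])
}
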