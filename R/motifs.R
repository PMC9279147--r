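#' Read a PWM from JASPAR raw-count format
#'
#' Accepts the JASPAR PFM dialects: an optional `>ID name` header followed by
#' four rows of counts, either bare (`A`, `C`, `G`, `T` order) or prefixed
#' with the letter and wrapped in brackets
#' (`A [ 87 167 ... ]`). Counts are converted to per-position probabilities
#' with a pseudocount of 0.25 per cell.
#'
#' @param path file path, or a character vector of the lines themselves.
#' @param background length-4 background letter probabilities (A,C,G,T);
#'   default uniform.
#' @return object of class `pwm`: probability matrix (4 x L, rows A,C,G,T),
#'   `background`, `length`.
#' @export
read_jaspar_pwm <- function(path, background = rep(0.25, 4)) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines[nzchar(trimws(lines))])
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) != 4) stop("expected 4 count rows (A, C, G, T)")
  rows <- lapply(lines, function(l) {
    l <- sub("^[ACGTacgt]", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  })
  L <- unique(lengths(rows))
  if (length(L) != 1) stop("count rows have unequal lengths")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  pwm_from_counts(counts, background)
}

#' Build a PWM from a count (or probability) matrix
#'
#' @param counts 4 x L matrix with rows A,C,G,T.
#' @param background length-4 background probabilities.
#' @param pseudocount added to every cell before normalization.
#' @return a `pwm` object.
#' @export
pwm_from_counts <- function(counts, background = rep(0.25, 4), pseudocount = 0.25) {
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  p <- counts + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  rownames(p) <- c("A", "C", "G", "T")
  structure(list(prob = p, background = background, length = ncol(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> length %d, consensus %s\n", x$length,
              paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = "")))
  invisible(x)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(base::rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# log2-odds scores of every window of `seq` against the PWM (+ strand only);
# windows containing N score -Inf
score_windows <- function(seq, pwm) {
  L <- pwm$length
  n <- nchar(seq)
  letters <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  lods <- log2(pwm$prob / pwm$background)
  n_off <- n - L + 1L
  scores <- numeric(n_off)
  for (o in seq_len(n_off)) {
    idx <- letters[o:(o + L - 1L)]
    if (anyNA(idx)) { scores[o] <- -Inf; next }
    scores[o] <- sum(lods[cbind(idx, seq_len(L))])
  }
  scores
}

#' Best motif hit in a peak sequence
#'
#' Scores every offset on both strands with the log2-odds
#' `sum(log2(p_pos(letter) / bg(letter)))` (the reverse strand is scored on
#' the reverse complement) and returns the single maximum-scoring hit. Ties
#' resolve to the leftmost offset, then to the `+` strand. The hit is
#' discarded when its score falls below `threshold`.
#'
#' @param sequence uppercase ACGTN string of length >= motif length.
#' @param pwm a `pwm` object.
#' @param threshold minimum log2-odds score to report (default 0).
#' @return one-row data.frame with `start` (0-based offset), `end`, `strand`,
#'   `orientation` (`forward` for `+`), `score`; or `NULL` when no hit
#'   reaches the threshold.
#' @export
scan_peak <- function(sequence, pwm, threshold = 0) {
  sequence <- toupper(sequence)
  L <- pwm$length
  if (nchar(sequence) < L) stop("sequence shorter than motif length")
  fwd <- score_windows(sequence, pwm)
  rc <- score_windows(revcomp(sequence), pwm)
  # window at rc offset o (1-based) covers original offset n - L - o + 2
  n_off <- length(fwd)
  rev_scores <- rc[n_off:1]
  cand <- data.frame(
    offset = c(seq_len(n_off), seq_len(n_off)) - 1L,
    strand = rep(c("+", "-"), each = n_off),
    score = c(fwd, rev_scores))
  cand <- cand[order(-cand$score, cand$offset, cand$strand), ]
  best <- cand[1, ]
  if (!is.finite(best$score) || best$score < threshold) return(NULL)
  data.frame(start = best$offset, end = best$offset + L,
             strand = best$strand,
             orientation = if (best$strand == "+") "forward" else "reverse",
             score = best$score)
}

#' CBS calls from peaks and a genome
#'
#' Extracts each peak's sequence from the genome, keeps the highest-scoring
#' motif per peak and returns oriented CBS annotations in genome coordinates.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genome a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param pwm a `pwm` object.
#' @param threshold minimum log2-odds score.
#' @return data.frame with `chrom`, `start`, `end` (the motif interval),
#'   `orientation`, `score`, `source_peak`; peaks with no hit are dropped.
#' @export
cbs_from_peaks <- function(peaks, genome, pwm, threshold = 0) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- NULL
  for (k in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[k]
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    seq <- as.character(Biostrings::subseq(genome[[chrom]],
                                           peaks$start[k] + 1L, peaks$end[k]))
    hit <- scan_peak(seq, pwm, threshold)
    if (is.null(hit)) next
    out <- rbind(out, data.frame(
      chrom = chrom, start = peaks$start[k] + hit$start,
      end = peaks$start[k] + hit$end, orientation = hit$orientation,
      score = hit$score, source_peak = k))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      orientation = character(0), score = numeric(0),
                      source_peak = integer(0))
  out
}

#' CBS composition of boundaries
#'
#' Collects, for each boundary, the CBSs overlapping the boundary extended by
#' `flank_bp` on both sides (any overlap counts), in coordinate order, and
#' counts divergent pairs: ordered pairs `(i < j)` with a reverse-oriented
#' CBS upstream of a forward-oriented one (motifs pointing apart). Adjacency
#' is not required.
#'
#' @param boundaries data.frame with `chrom`, `start`, `end`,
#'   `boundary_score` (see [boundaries_to_bp()]); an optional `id` column is
#'   carried through.
#' @param cbs data.frame with `chrom`, `start`, `end`, `orientation`.
#' @param flank_bp flanking region added to each side (default 100 kb).
#' @return data.frame with `id`, `n_cbs`, `n_forward`, `n_reverse`,
#'   `n_divergent_pairs`, `divergent`, `boundary_score`.
#' @export
compose_boundaries <- function(boundaries, cbs, flank_bp = 100000) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  if (is.null(boundaries$id))
    boundaries$id <- sprintf("boundary_%d", seq_len(nrow(boundaries)))
  cbs <- cbs[order(cbs$chrom, cbs$start), , drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(boundaries))) {
    on_chrom <- cbs[cbs$chrom == boundaries$chrom[k], , drop = FALSE]
    win <- IRanges::IRanges(start = boundaries$start[k] - flank_bp + 1L,
                            end = boundaries$end[k] + flank_bp)
    keep <- IRanges::overlapsAny(
      IRanges::IRanges(start = on_chrom$start + 1L, end = on_chrom$end), win)
    sel <- on_chrom[keep, , drop = FALSE]
    sel <- sel[order(sel$start), , drop = FALSE]
    is_fwd <- sel$orientation == "forward"
    n_div <- sum(cumsum(!is_fwd)[is_fwd]) # reverse strictly upstream of forward
    out <- rbind(out, data.frame(
      id = boundaries$id[k], n_cbs = nrow(sel), n_forward = sum(is_fwd),
      n_reverse = sum(!is_fwd), n_divergent_pairs = n_div,
      divergent = n_div >= 1,
      boundary_score = boundaries$boundary_score[k]))
  }
  rownames(out) <- NULL
  out
}

#' Boundary-score distribution by CBS composition
#'
#' Summarizes boundary scores stratified by CBS count (capped at
#' `bucket_max`, pooled as `"<max>+"`) and, optionally, by divergence class,
#' using boxplot statistics: median, linear-interpolation quartiles and
#' whiskers at the last observation within 1.5 IQR of the quartiles.
#'
#' @param compositions output of [compose_boundaries()].
#' @param by_divergence also stratify by the divergent flag.
#' @param bucket_max CBS counts at or above this value share one bucket.
#' @return data.frame with one row per stratum: `n_cbs_bucket`,
#'   (`divergent`), `count`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`.
#' @export
composition_summary <- function(compositions, by_divergence = FALSE,
                                bucket_max = 10L) {
  if (!nrow(compositions)) stop("need at least one composition")
  bucket <- ifelse(compositions$n_cbs >= bucket_max,
                   paste0(bucket_max, "+"), as.character(compositions$n_cbs))
  groups <- if (by_divergence) {
    split(compositions$boundary_score,
          interaction(bucket, compositions$divergent, drop = TRUE))
  } else {
    split(compositions$boundary_score, bucket)
  }
  stats_one <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    inside <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
    c(count = length(x), median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(inside), whisker_high = max(inside))
  }
  tab <- t(vapply(groups, stats_one, numeric(6)))
  out <- data.frame(stratum = rownames(tab), tab, row.names = NULL)
  if (by_divergence) {
    parts <- strsplit(out$stratum, ".", fixed = TRUE)
    out$n_cbs_bucket <- vapply(parts, `[`, character(1), 1)
    out$divergent <- vapply(parts, `[`, character(1), 2) == "TRUE"
  } else {
    out$n_cbs_bucket <- out$stratum
  }
  out$stratum <- NULL
  out
}
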