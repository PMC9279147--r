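#' Binned contact matrix for one chromosome or captured region
#'
#' Container for symmetric, nonnegative binned contact counts, the per-bin
#' exclusion mask and (after balancing) per-bin balancing weights. Counts are
#' held dense; on disk the matrix uses the sparse upper-triangle triplet
#' dialect written by [write_contact_matrix()].
#'
#' @param counts numeric `n x n` matrix, symmetric and nonnegative.
#' @param bin_size bin width in bp.
#' @param chrom chromosome / region name.
#' @param mask optional logical vector of length `n`; `TRUE` marks excluded
#'   (e.g. low-mappability) bins. Masked bins have their rows and columns
#'   zeroed.
#' @return an object of class `contact_matrix` with fields `counts`,
#'   `bin_size`, `chrom`, `n_bins`, `mask` and `weights` (NA until
#'   [kr_balance()] is run).
#' @export
contact_matrix <- function(counts, bin_size, chrom = "chrS", mask = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("counts must be symmetric")
  counts <- (counts + t(counts)) / 2
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("mask length must equal n_bins")
  if (any(mask)) counts[mask, ] <- counts[, mask] <- 0
  structure(
    list(counts = counts, bin_size = as.integer(bin_size), chrom = chrom,
         n_bins = n, mask = mask, weights = rep(NA_real_, n)),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins x %d bp (%.3g total counts, %d masked%s)\n",
              x$chrom, x$n_bins, x$bin_size, sum(x$counts), sum(x$mask),
              if (is_balanced(x)) ", balanced" else ""))
  invisible(x)
}

is_balanced <- function(m) any(!is.na(m$weights))

#' Balanced view of a contact matrix
#'
#' Returns `w_i * counts(i,j) * w_j` using the weights stored by
#' [kr_balance()]. Entries involving masked bins are `NA`.
#'
#' @param m a balanced `contact_matrix`.
#' @return numeric matrix with `NA` on masked rows/columns.
#' @export
balanced_counts <- function(m) {
  if (!is_balanced(m)) stop("matrix has no balancing weights; run kr_balance() first")
  w <- m$weights
  b <- m$counts * outer(w, w)
  b[m$mask, ] <- b[, m$mask] <- NA_real_
  b
}

#' Write a contact matrix in the triplet TSV dialect
#'
#' One header line `#bin_size=<bp> #n_bins=<n> #chrom=<name>`, then 0-based
#' `bin_i <TAB> bin_j <TAB> count` rows for the nonzero upper triangle
#' (i <= j). Reruns are byte-identical for identical matrices.
#'
#' @param m a `contact_matrix`.
#' @param path output file.
#' @param kind optional extra header tag (e.g. `"zscore"` for z-maps).
#' @export
write_contact_matrix <- function(m, path, kind = NULL) {
  header <- sprintf("#bin_size=%d #n_bins=%d #chrom=%s", m$bin_size, m$n_bins, m$chrom)
  if (!is.null(kind)) header <- paste0(header, " #kind=", kind)
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  lines <- c(header,
             sprintf("%d\t%d\t%s", ut[, 1] - 1L, ut[, 2] - 1L,
                     formatC(m$counts[ut], format = "g", digits = 12)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a contact matrix from the triplet TSV dialect
#'
#' The stored upper triangle is mirrored so the returned counts are exactly
#' symmetric; all-zero bins are not masked automatically (see
#' [kr_balance()]).
#'
#' @param path file written by [write_contact_matrix()] or compatible.
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("line 1: missing '#bin_size=... #n_bins=... #chrom=...' header")
  hdr <- lines[1]
  grab <- function(tag) {
    mm <- regmatches(hdr, regexpr(paste0("#", tag, "=[^ ]+"), hdr))
    if (!length(mm)) stop(sprintf("line 1: malformed header, missing #%s=", tag))
    sub(paste0("#", tag, "="), "", mm)
  }
  bin_size <- as.integer(grab("bin_size"))
  n <- as.integer(grab("n_bins"))
  chrom <- grab("chrom")
  if (is.na(bin_size) || is.na(n)) stop("line 1: non-numeric header fields")
  counts <- matrix(0, n, n)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) stop(sprintf("line %d: expected 3 tab-separated fields", bad[1] + 1L))
    dat <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
    if (anyNA(dat)) stop(sprintf("line %d: non-numeric field",
                                 which(apply(is.na(dat), 1, any))[1] + 1L))
    i <- dat[, 1]; j <- dat[, 2]; v <- dat[, 3]
    oob <- which(i < 0 | j < 0 | i >= n | j >= n)
    if (length(oob)) stop(sprintf("line %d: bin index out of range [0, %d)", oob[1] + 1L, n))
    neg <- which(v < 0)
    if (length(neg)) stop(sprintf("line %d: negative count", neg[1] + 1L))
    lo <- pmin(i, j) + 1L; hi <- pmax(i, j) + 1L
    for (k in seq_along(lo)) counts[lo[k], hi[k]] <- counts[lo[k], hi[k]] + v[k]
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  }
  contact_matrix(counts, bin_size, chrom)
}

#' Balance a contact matrix to uniform row sums (KR-type)
#'
#' Computes per-bin weights by symmetric Sinkhorn-Knopp iteration, the same
#' doubly-stochastic-up-to-scale fixed point targeted by the Knight-Ruiz
#' algorithm. Bins with zero marginal counts are masked before balancing; the
#' target row sum is the mean unmasked marginal, so weights are O(1).
#'
#' @param m a `contact_matrix`.
#' @param tol relative row-sum convergence tolerance.
#' @param max_iter iteration limit; non-convergence is an error, never a
#'   silent partial result.
#' @return `m` with `weights` filled and `mask` extended to zero-marginal
#'   bins; attribute `"iterations"` records the iteration count.
#' @export
kr_balance <- function(m, tol = 1e-8, max_iter = 1000L) {
  mask <- m$mask | rowSums(m$counts) == 0
  keep <- which(!mask)
  if (length(keep) < 2) stop("fewer than 2 unmasked bins; cannot balance")
  A <- m$counts[keep, keep, drop = FALSE]
  x <- rep(1, length(keep))
  it <- 0L
  repeat {
    r <- x * as.vector(A %*% x)
    tgt <- mean(r)
    dev <- max(abs(r / tgt - 1))
    if (dev < tol) break
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf("balancing did not converge in %d iterations (rel. dev %.3g)",
                   max_iter, dev))
    x <- x / sqrt(r / tgt)
  }
  w <- rep(NA_real_, m$n_bins)
  w[keep] <- x
  m$weights <- w
  m$mask <- mask
  m$counts[mask, ] <- m$counts[, mask] <- 0
  attr(m, "iterations") <- it
  m
}

#' Mean balanced signal per genomic distance
#'
#' `e(d)` is the mean balanced value over all unmasked bin pairs at
#' separation `d` bins, for `d = 0 .. n_bins - 1` (NA where no unmasked pair
#' exists). This is the denominator of the observed/expected transform.
#'
#' @param m a balanced `contact_matrix`.
#' @return numeric vector of length `n_bins` (index 1 is distance 0).
#' @export
expected_by_distance <- function(m) {
  b <- balanced_counts(m)
  n <- m$n_bins
  idx <- which(upper.tri(b, diag = TRUE) & !is.na(b), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  e <- rep(NA_real_, n)
  if (length(d)) {
    agg <- tapply(b[idx], d, mean)
    e[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }
  e
}

#' Observed/expected transform
#'
#' Divides each balanced pixel by the expected value at its distance.
#' Undefined (`NA`) where either bin is masked or `e(d)` is zero/NA.
#'
#' @param m a balanced `contact_matrix`.
#' @param profile expected profile from [expected_by_distance()]; computed
#'   from `m` when omitted.
#' @return numeric `n x n` matrix of obs/exp values.
#' @export
oe_transform <- function(m, profile = NULL) {
  if (is.null(profile)) profile <- expected_by_distance(m)
  b <- balanced_counts(m)
  n <- m$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- profile[d + 1L]
  e[e == 0] <- NA_real_
  b / matrix(e, n, n)
}

#' Equalize the coverage of two matrices
#'
#' Divides each matrix by its own total count sum so both totals equal 1 —
#' the normalization applied before subtraction maps.
#'
#' @param a,b `contact_matrix` objects on the same binning.
#' @return list with elements `a` and `b`, each summing to 1.
#' @export
equalize_coverage <- function(a, b) {
  check_same_shape(a, b)
  ta <- sum(a$counts); tb <- sum(b$counts)
  if (ta <= 0 || tb <= 0) stop("cannot equalize a zero-total matrix")
  a$counts <- a$counts / ta
  b$counts <- b$counts / tb
  a$weights <- rep(NA_real_, a$n_bins)
  b$weights <- rep(NA_real_, b$n_bins)
  list(a = a, b = b)
}

check_same_shape <- function(a, b) {
  if (a$n_bins != b$n_bins || a$bin_size != b$bin_size || !identical(a$chrom, b$chrom))
    stop("matrices differ in n_bins, bin_size or chrom")
  invisible(TRUE)
}
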