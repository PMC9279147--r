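# Independent oracles used across the suite. These deliberately re-derive
# results by the most direct route available (alternating scaling, exhaustive
# enumeration, textbook formulas) and never call the code paths they check.

# Sinkhorn oracle: alternate row/column scaling of a nonnegative matrix until
# the row sums agree to `tol`; returns the balanced matrix.
sinkhorn_oracle <- function(M, tol = 1e-12, max_iter = 100000) {
  A <- M
  for (i in seq_len(max_iter)) {
    r <- rowSums(A)
    A <- A / r
    cs <- colSums(A)
    A <- sweep(A, 2, cs, "/")
    r <- rowSums(A)
    if (max(r) - min(r) < tol) break
  }
  A / mean(rowSums(A))
}

# Straight-line re-derivation of the anchor and loop classification rules on
# an abstract loop set: `loops` is a data.frame with columns a1, a2 (anchor
# ids, a1 < a2 positionally); `anchors` has has_f, has_r, n_cbs per id.
brute_classify <- function(loops, anchors) {
  n_anchor <- nrow(anchors)
  anchor_cat <- character(n_anchor)
  bidir <- logical(n_anchor)
  for (a in seq_len(n_anchor)) {
    right <- which(loops$a1 == a) # loops toward higher coordinates
    left <- which(loops$a2 == a)
    bidir[a] <- length(right) > 0 && length(left) > 0
    if (anchors$n_cbs[a] == 0) {
      anchor_cat[a] <- "no_ctcf"
    } else if ((length(right) > 0 && !anchors$has_f[a]) ||
               (length(left) > 0 && !anchors$has_r[a])) {
      anchor_cat[a] <- "nonconvergent"
    } else {
      anchor_cat[a] <- "convergent_only"
    }
  }
  conv <- anchors$has_f[loops$a1] & anchors$has_r[loops$a2]
  loop_cat <- character(nrow(loops))
  for (k in seq_len(nrow(loops))) {
    opp <- setdiff(c(which(loops$a2 == loops$a1[k]),
                     which(loops$a1 == loops$a2[k])), k)
    if (conv[k]) {
      loop_cat[k] <- if (any(!conv[opp])) "convergent_associated"
      else if (any(conv[opp])) "double_sided_convergent"
      else "single_sided_convergent"
    } else {
      loop_cat[k] <- if (any(conv[opp])) "nonconvergent_associated"
      else "nonconvergent"
    }
  }
  list(anchor_category = anchor_cat, bidirectional = bidir,
       loop_convergent = conv, loop_category = loop_cat)
}

# Random abstract toy loop set on well-separated anchors, plus its concrete
# bp-coordinate realization for the package path.
random_toy_set <- function(max_anchors = 20, max_loops = 50, bin = 10000) {
  n_anchor <- sample(3:max_anchors, 1)
  # anchors spaced >= 5 bins apart so interval merging is a no-op
  pos <- sort(sample.int(500, n_anchor)) * 5L
  has_f <- runif(n_anchor) < 0.5
  has_r <- runif(n_anchor) < 0.5
  n_loops <- sample(1:max_loops, 1)
  a1 <- sample.int(n_anchor, n_loops, replace = TRUE)
  a2 <- sample.int(n_anchor, n_loops, replace = TRUE)
  keep <- a1 != a2
  a1k <- pmin(a1[keep], a2[keep]); a2k <- pmax(a1[keep], a2[keep])
  if (!length(a1k)) { a1k <- 1L; a2k <- 2L }
  dup <- duplicated(paste(a1k, a2k))
  a1k <- a1k[!dup]; a2k <- a2k[!dup]
  anchors <- data.frame(pos = pos, has_f = has_f, has_r = has_r,
                        n_cbs = as.integer(has_f) + as.integer(has_r))
  loops_abstract <- data.frame(a1 = a1k, a2 = a2k)
  loops_bp <- data.frame(chrom = "chrT",
                         start1 = pos[a1k] * bin, end1 = (pos[a1k] + 1L) * bin,
                         start2 = pos[a2k] * bin, end2 = (pos[a2k] + 1L) * bin)
  cbs <- NULL
  for (a in seq_len(n_anchor)) {
    if (has_f[a]) cbs <- rbind(cbs, data.frame(
      chrom = "chrT", start = pos[a] * bin + 100, end = pos[a] * bin + 119,
      orientation = "forward"))
    if (has_r[a]) cbs <- rbind(cbs, data.frame(
      chrom = "chrT", start = pos[a] * bin + 300, end = pos[a] * bin + 319,
      orientation = "reverse"))
  }
  if (is.null(cbs)) cbs <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), orientation = character(0))
  list(anchors = anchors, loops_abstract = loops_abstract,
       loops_bp = loops_bp, cbs = cbs, bin = bin)
}

# Exact Mann-Whitney via enumeration of all group assignments; replicates
# the two-sided exact rule used by wilcox.test (no ties expected).
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  combs <- utils::combn(nx + ny, nx)
  ustat <- function(xs, ys) sum(outer(xs, ys, ">")) # U of first sample
  u_obs <- ustat(x, y)
  us <- apply(combs, 2, function(idx) ustat(pooled[idx], pooled[-idx]))
  if (u_obs > nx * ny / 2) {
    p <- 2 * mean(us >= u_obs)
  } else {
    p <- 2 * mean(us <= u_obs)
  }
  list(statistic = u_obs, p_value = min(1, p))
}

# Textbook chi-squared on a 2x2 (or r x c) table without continuity correction
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Benjamini-Hochberg by the textbook step-up formula
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# 1D two-component EM for Gaussian mixtures, random restarts; oracle for the
# mappability mask
em_gmm_oracle <- function(x, restarts = 10, iter = 200) {
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- sort(sample(x, 2))
    if (mu[1] == mu[2]) mu <- mu + c(-0.1, 0.1)
    s2 <- rep(stats::var(x) / 2 + 1e-6, 2)
    pi_ <- c(0.5, 0.5)
    for (i in seq_len(iter)) {
      d1 <- pi_[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
      d2 <- pi_[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
      z <- d1 / (d1 + d2)
      z[is.na(z)] <- 0.5
      pi_ <- c(mean(z), 1 - mean(z))
      mu <- c(sum(z * x) / sum(z), sum((1 - z) * x) / sum(1 - z))
      s2 <- c(sum(z * (x - mu[1])^2) / sum(z) + 1e-9,
              sum((1 - z) * (x - mu[2])^2) / sum(1 - z) + 1e-9)
    }
    ll <- sum(log(pi_[1] * stats::dnorm(x, mu[1], sqrt(s2[1])) +
                    pi_[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))))
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, mu = mu, s2 = s2, pi = pi_,
                   z_low = if (mu[1] < mu[2]) z else 1 - z)
  }
  best
}

# small random symmetric nonnegative contact matrix with full support
random_contact_matrix <- function(n = 50, bin_size = 10000) {
  M <- matrix(stats::runif(n * n, 0.2, 2), n, n)
  M <- M + t(M)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  M <- M * (d + 1)^-0.5
  contact_matrix(M, bin_size)
}
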