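#' Per-diagonal z-score subtraction map
#'
#' Equalizes the coverage of the two matrices (each divided by its total),
#' subtracts them elementwise and converts every value to a z-score against
#' the other values of the same sub-diagonal (interactions at the same
#' genomic distance): `Z = (D - mu_d) / sigma_d` with population standard
#' deviation. Diagonals with `sigma_d = 0` or fewer than 3 defined pixels
#' get `Z = 0` and are flagged. Pixels with either bin masked are undefined.
#'
#' @param a,b `contact_matrix` objects on the same binning (`a - b`).
#' @return object of class `subtraction_map`: `z` (symmetric matrix),
#'   `mu`, `sigma` (per-diagonal), `flagged_diagonals`, `chrom`, `bin_size`.
#' @export
subtraction_map <- function(a, b) {
  check_same_shape(a, b)
  eq <- equalize_coverage(a, b)
  n <- a$n_bins
  mask <- eq$a$mask | eq$b$mask
  D <- eq$a$counts - eq$b$counts
  D[mask, ] <- D[, mask] <- NA_real_
  z <- matrix(NA_real_, n, n)
  mu <- sigma <- rep(NA_real_, n)
  flagged <- logical(n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d); j <- i + d
    vals <- D[cbind(i, j)]
    def <- !is.na(vals)
    if (!any(def)) next
    m_ <- mean(vals[def])
    s_ <- sqrt(mean((vals[def] - m_)^2))
    mu[d + 1] <- m_; sigma[d + 1] <- s_
    if (sum(def) < 3 || s_ == 0) {
      flagged[d + 1] <- TRUE
      zd <- ifelse(def, 0, NA_real_)
    } else {
      zd <- (vals - m_) / s_
    }
    z[cbind(i, j)] <- zd
    z[cbind(j, i)] <- zd
  }
  structure(list(z = z, mu = mu, sigma = sigma,
                 flagged_diagonals = which(flagged) - 1L,
                 chrom = a$chrom, bin_size = a$bin_size),
            class = "subtraction_map")
}

#' @export
print.subtraction_map <- function(x, ...) {
  cat(sprintf("<subtraction_map> %s: %d bins, |Z| max %.2f, %d flagged diagonals\n",
              x$chrom, nrow(x$z), max(abs(x$z), na.rm = TRUE),
              length(x$flagged_diagonals)))
  invisible(x)
}

#' Write a z-score map in the triplet dialect
#'
#' Adds the `#kind=zscore` header tag; zero and undefined pixels are not
#' stored.
#'
#' @param sm a `subtraction_map`.
#' @param path output file.
#' @export
write_zscore_map <- function(sm, path) {
  z <- sm$z
  z[is.na(z)] <- 0
  m <- list(counts = z, bin_size = sm$bin_size, chrom = sm$chrom, n_bins = nrow(z))
  write_contact_matrix(m, path, kind = "zscore")
}

#' Virtual 4C profile from a contact matrix
#'
#' `v(i)` is the mean balanced signal between the viewpoint bins and bin
#' `i`. The viewpoint itself and bins within `exclusion_bins` of it are
#' undefined; the profile is normalized to sum to 1 over defined bins.
#' If a quantification window is given, the profile's share of signal inside
#' it is reported.
#'
#' @param m a balanced `contact_matrix`.
#' @param viewpoint 0-based bin indices of the viewpoint.
#' @param exclusion_bins half-width of the exclusion zone around the
#'   viewpoint (default 2).
#' @param quant_window optional 0-based `c(from, to)` bin range (inclusive)
#'   to quantify.
#' @return object of class `virtual4c`: `values` (normalized, `NA` where
#'   undefined), `viewpoint`, `exclusion_bins`, `quant_window`,
#'   `quantification`.
#' @export
virtual_4c <- function(m, viewpoint, exclusion_bins = 2L, quant_window = NULL) {
  n <- m$n_bins
  vp <- as.integer(viewpoint) + 1L
  if (any(vp < 1 | vp > n)) stop("viewpoint outside the region")
  if (all(m$mask[vp])) stop("viewpoint fully masked")
  b <- balanced_counts(m)
  v <- colMeans(b[vp, , drop = FALSE], na.rm = TRUE)
  v[m$mask] <- NA_real_
  excl <- unique(unlist(lapply(vp, function(p)
    max(1, p - exclusion_bins):min(n, p + exclusion_bins))))
  v[excl] <- NA_real_
  def <- !is.na(v)
  total <- sum(v[def])
  if (!any(def) || total <= 0) stop("profile has zero total signal over defined bins")
  v[def] <- v[def] / total
  quant <- NULL
  if (!is.null(quant_window)) {
    win <- (quant_window[1]:quant_window[2]) + 1L
    quant <- sum(v[win][!is.na(v[win])])
  }
  structure(list(values = v, viewpoint = viewpoint,
                 exclusion_bins = exclusion_bins, quant_window = quant_window,
                 quantification = quant),
            class = "virtual4c")
}

#' Write a virtual-4C profile as bedGraph
#'
#' Defined bins only.
#'
#' @param v4c a `virtual4c` object.
#' @param path output file.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @export
write_virtual4c_bedgraph <- function(v4c, path, bin_size, chrom = "chrS") {
  bins <- which(!is.na(v4c$values)) - 1L
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, bins * bin_size,
                     (bins + 1L) * bin_size,
                     formatC(v4c$values[bins + 1L], format = "g", digits = 8)),
             path)
  invisible(path)
}

#' @export
print.virtual4c <- function(x, ...) {
  cat(sprintf("<virtual4c> viewpoint bin(s) %s, %d defined bins%s\n",
              paste(x$viewpoint, collapse = ","), sum(!is.na(x$values)),
              if (!is.null(x$quantification))
                sprintf(", window share %.3f", x$quantification) else ""))
  invisible(x)
}
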