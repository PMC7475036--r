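#' Relative allele frequency from two-channel pool intensities
#'
#' RAF = X / (X + Y), the pooled-array estimate of the X-channel allele's
#' frequency in the DNA pool. Sites with X + Y = 0 are flagged missing
#' (NA), not an error, and are excluded downstream.
#'
#' @param X,Y non-negative intensity vectors for the two alleles.
#' @return Numeric vector in \[0, 1\], NA where X + Y = 0.
#' @examples
#' compute_raf(300, 100) # 0.75
#' @export
compute_raf <- function(X, Y) {
  if (any(X < 0, na.rm = TRUE) || any(Y < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tot <- X + Y
  ifelse(tot > 0, X / tot, NA_real_)
}

#' Absolute RAF difference between two pools
#'
#' @param raf_a,raf_b RAF vectors in \[0, 1\] (NA passed through).
#' @return `abs(raf_a - raf_b)`.
#' @export
abs_raf_dif <- function(raf_a, raf_b) {
  if (any(raf_a < 0 | raf_a > 1, na.rm = TRUE) ||
      any(raf_b < 0 | raf_b > 1, na.rm = TRUE))
    stop("RAF values must lie in [0, 1]")
  abs(raf_a - raf_b)
}

#' Per-SNP RAF scan contrasting two pools
#'
#' Computes each pool's RAF and their absolute pairwise difference from a
#' long pool-intensity table (as produced by [simulate_pool_array()] or
#' read from a TSV with the same columns).
#'
#' @param tab data frame with columns `snp_id`, `chrom`, `pos`, `pool`,
#'   `X`, `Y`.
#' @param pool_a,pool_b names of the two pools to contrast (default: the
#'   first two pools in the table).
#' @return Data frame `snp_id`, `chrom`, `pos`, `raf_a`, `raf_b`,
#'   `absrafdif`, sorted by (chrom, pos).
#' @export
raf_scan <- function(tab, pool_a = NULL, pool_b = NULL) {
  pools <- unique(tab$pool)
  if (is.null(pool_a)) pool_a <- pools[1]
  if (is.null(pool_b)) pool_b <- pools[2]
  if (!all(c(pool_a, pool_b) %in% pools)) stop("pool not found in table")
  a <- tab[tab$pool == pool_a, ]
  b <- tab[tab$pool == pool_b, ]
  m <- merge(a, b, by = c("snp_id", "chrom", "pos"),
             suffixes = c("_a", "_b"))
  out <- data.frame(snp_id = m$snp_id, chrom = m$chrom, pos = m$pos,
                    raf_a = compute_raf(m$X_a, m$Y_a),
                    raf_b = compute_raf(m$X_b, m$Y_b),
                    stringsAsFactors = FALSE)
  out$absrafdif <- abs_raf_dif(out$raf_a, out$raf_b)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Call the peak region of a chromosome scan
#'
#' The peak interval spans the minimum to the maximum position of the
#' SNPs whose scan value strictly exceeds the threshold on the requested
#' chromosome (the rule that delimits a pooled-array signal region, e.g.
#' all SNPs with absRAFdif > 0.35).
#'
#' @param scan data frame with `chrom`, `pos` and the value column.
#' @param chrom chromosome to scan.
#' @param threshold calling threshold (default 0.35).
#' @param value_col name of the value column (default "absrafdif").
#' @return A `scan_peak` list: `interval` (1-row [genomic_interval()], or
#'   0-row when no SNP exceeds the threshold), `threshold`, `n_snps`.
#' @export
call_peak_region <- function(scan, chrom, threshold = 0.35,
                             value_col = "absrafdif") {
  v <- scan[[value_col]]
  hit <- scan$chrom == chrom & !is.na(v) & v > threshold
  if (!any(hit)) {
    iv <- genomic_interval(character(0), numeric(0), numeric(0))
  } else {
    iv <- genomic_interval(chrom, min(scan$pos[hit]), max(scan$pos[hit]),
                           name = "peak")
  }
  structure(list(interval = iv, threshold = threshold, n_snps = sum(hit)),
            class = "scan_peak")
}

#' @export
print.scan_peak <- function(x, ...) {
  if (nrow(x$interval) == 0) {
    cat("scan_peak: no SNP above threshold", x$threshold, "\n")
  } else {
    cat(sprintf("scan_peak: %s:%s-%s (%d SNPs > %g)\n",
                x$interval$chrom,
                format(x$interval$start, big.mark = ",", scientific = FALSE),
                format(x$interval$end, big.mark = ",", scientific = FALSE),
                x$n_snps, x$threshold))
  }
  invisible(x)
}

#' Per-site FST between two pools
#'
#' Plain heterozygosity-based fixation index on pool allele frequencies:
#' with mean frequency p̄, `FST = (H_T - H_S) / H_T` where
#' `H_T = 2 p̄ (1 - p̄)` and `H_S` is the mean of the two within-pool
#' heterozygosities `2 p_i (1 - p_i)`. No pool-size or coverage bias
#' correction is applied (window ranks are insensitive to a monotone
#' estimator change); sites with `H_T = 0` return NA.
#'
#' @param p1,p2 alt-allele frequency vectors in \[0, 1\].
#' @return FST vector, NA where the site is monomorphic overall.
#' @examples
#' fst_site(0.8, 0.2) # 0.36
#' @export
fst_site <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  ifelse(ht > 0, (ht - hs) / ht, NA_real_)
}

#' Filtered per-site FST scan from pool-seq counts
#'
#' Merges the two pools' allele counts by site, applies depth and allele
#' count filters, and computes [fst_site()] on the read-frequency
#' estimates. Filters (all configurable): per-pool depth within
#' `[min_depth, max_depth]` (default max = 3x the pool's mean depth),
#' minor allele count over both pools >= `min_count`, and `H_T > 0`.
#'
#' @param tab long count table: `chrom`, `pos`, `pool`, `ref_count`,
#'   `alt_count` (as from [simulate_pool_reads()]).
#' @param pool_a,pool_b pool names (default: first two).
#' @param min_depth minimum per-pool depth (default 10).
#' @param min_count minimum minor-allele read count summed over pools
#'   (default 2).
#' @param max_depth maximum per-pool depth; default 3x mean depth.
#' @return Data frame `chrom`, `pos`, `p1`, `p2`, `fst` for the sites
#'   passing all filters, sorted by (chrom, pos).
#' @export
fst_scan <- function(tab, pool_a = NULL, pool_b = NULL, min_depth = 10,
                     min_count = 2, max_depth = NULL) {
  pools <- unique(tab$pool)
  if (is.null(pool_a)) pool_a <- pools[1]
  if (is.null(pool_b)) pool_b <- pools[2]
  a <- tab[tab$pool == pool_a, ]
  b <- tab[tab$pool == pool_b, ]
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  d1 <- m$ref_count_a + m$alt_count_a
  d2 <- m$ref_count_b + m$alt_count_b
  if (is.null(max_depth)) max_depth <- 3 * mean(c(d1, d2))
  alt_tot <- m$alt_count_a + m$alt_count_b
  ref_tot <- m$ref_count_a + m$ref_count_b
  keep <- d1 >= min_depth & d2 >= min_depth &
    d1 <= max_depth & d2 <= max_depth &
    pmin(alt_tot, ref_tot) >= min_count
  m <- m[keep, , drop = FALSE]
  p1 <- m$alt_count_a / (m$ref_count_a + m$alt_count_a)
  p2 <- m$alt_count_b / (m$ref_count_b + m$alt_count_b)
  fst <- fst_site(p1, p2)
  out <- data.frame(chrom = m$chrom, pos = m$pos, p1 = p1, p2 = p2,
                    fst = fst, stringsAsFactors = FALSE)
  out <- out[!is.na(out$fst), , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Sliding-window mean of a per-site statistic
#'
#' Windows are anchored at position 1 on every chromosome and advance by
#' `step`; only full-size windows are emitted (window `i` covers
#' `[1 + (i-1) step, (i-1) step + window]`). The window value is the mean
#' of the contained sites' values; windows containing no site are emitted
#' with an NA value so the genome tiling stays complete.
#'
#' @param sites data frame with `chrom`, `pos` and the value column,
#'   sorted or not (sorted internally; the result is invariant to input
#'   order).
#' @param window window size in bp (default 50000).
#' @param step step size in bp (default 10000); must not exceed `window`.
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   default: the maximum site position per chromosome.
#' @param value_col value column name (default "fst").
#' @return Data frame `chrom`, `start`, `end`, `value`, `n_snps`.
#' @export
sliding_windows <- function(sites, window = 50000, step = 10000,
                            chrom_lengths = NULL, value_col = "fst") {
  if (window < step) stop("window must be >= step")
  if (window < 1 || step < 1) stop("window and step must be >= 1")
  chroms <- if (is.null(chrom_lengths)) unique(sites$chrom)
            else names(chrom_lengths)
  out <- lapply(chroms, function(ch) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    L <- if (is.null(chrom_lengths)) max(s$pos) else chrom_lengths[[ch]]
    if (L < window) return(NULL)
    starts <- seq(1, L - window + 1, by = step)
    lo <- findInterval(starts - 1, s$pos)
    hi <- findInterval(starts + window - 1, s$pos)
    cs <- c(0, cumsum(s[[value_col]]))
    n <- hi - lo
    val <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
    data.frame(chrom = ch, start = starts, end = starts + window - 1,
               value = val, n_snps = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Z-normalize window statistics genome-wide
#'
#' Adds a `z` column: `(value - mean) / sd` with the mean and sample
#' (n - 1) SD taken over all non-missing windows genome-wide; missing
#' windows stay missing.
#'
#' @param windows output of [sliding_windows()].
#' @return The input with a `z` column appended.
#' @export
z_normalize <- function(windows) {
  v <- windows$value
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need >= 2 non-missing windows")
  s <- stats::sd(v[ok])
  if (s == 0) stop("degenerate scan: zero dispersion across windows")
  windows$z <- (v - mean(v[ok])) / s
  windows
}

#' Plot a window scan along the genome
#'
#' Simple base-graphics Manhattan-style plot of a window statistic
#' (e.g. ZFST) against window midpoints, one panel colour per chromosome.
#'
#' @param windows output of [sliding_windows()] / [z_normalize()].
#' @param value_col column to plot ("z" if present, else "value").
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot_scan <- function(windows, value_col = NULL, ...) {
  if (is.null(value_col))
    value_col <- if ("z" %in% names(windows)) "z" else "value"
  mid <- (windows$start + windows$end) / 2
  col <- as.integer(factor(windows$chrom))
  graphics::plot(mid, windows[[value_col]], col = col, pch = 16,
                 cex = 0.5, xlab = "position (bp)", ylab = value_col, ...)
  invisible(windows)
}
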