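#' Count informative meioses and recombinants at a backcross marker
#'
#' In a backcross segregating a dominant trait, every scored offspring is
#' an informative meiosis: the offspring is heterozygous at a marker
#' fixed for different alleles in the founders iff it received the
#' trait-line allele. The recombinant count is the number of offspring
#' whose marker state disagrees with their trait carrier status, under
#' the phase that minimizes recombinants (two-point convention;
#' linkage phase is generally unknown). Offspring with a missing marker
#' genotype or `NA` carrier status (e.g. excluded intermediates) are not
#' scored.
#'
#' @param marker_geno alt dosage {0, 1, 2, NA} at the marker for each
#'   offspring.
#' @param carrier logical: does the offspring carry the dominant trait
#'   allele (read directly from the phenotype for a dominant backcross
#'   trait; `NA` = excluded).
#' @return List with `n` (scored individuals) and `r` (recombinants).
#' @export
score_recombinants <- function(marker_geno, carrier) {
  if (length(marker_geno) != length(carrier))
    stop("marker_geno and carrier must have equal length")
  keep <- !is.na(marker_geno) & !is.na(carrier)
  g <- marker_geno[keep]
  cr <- carrier[keep]
  ishet <- g == 1L
  if (length(unique(ishet)) < 2 && length(unique(cr)) >= 2)
    stop("uninformative marker: monomorphic in the informative parent")
  r1 <- sum(ishet != cr)
  list(n = length(g), r = min(r1, length(g) - r1))
}

#' Two-point LOD score for a backcross
#'
#' Maximum-likelihood two-point linkage between a marker and the trait
#' locus from `n` informative meioses and `r` recombinants. The
#' recombination fraction estimate is `theta = min(r/n, 0.5)` and
#' `LOD = (n - r) log10(2 (1 - theta)) + r log10(2 theta)`, i.e. the
#' log10 likelihood ratio against free recombination (theta = 0.5); the
#' r = 0 limit is `n log10(2)` and the theta = 0.5 value is 0.
#'
#' @param n informative meioses (>= 1).
#' @param r recombinant count, `0 <= r <= n`.
#' @param marker_id optional marker label carried through.
#' @return List of class `two_point`: `marker_id`, `n`, `r`, `theta`,
#'   `lod`.
#' @examples
#' two_point_lod(178, 0)$lod # 53.58: complete cosegregation in 178 birds
#' @export
two_point_lod <- function(n, r, marker_id = NA_character_) {
  if (n < 1) stop("n must be >= 1")
  if (r < 0 || r > n) stop("r must lie in [0, n]")
  theta <- min(r / n, 0.5)
  lod <- if (r == 0) {
    n * log10(2)
  } else if (theta >= 0.5) {
    0
  } else {
    (n - r) * log10(2 * (1 - theta)) + r * log10(2 * theta)
  }
  structure(list(marker_id = marker_id, n = n, r = r, theta = theta,
                 lod = lod),
            class = "two_point")
}

#' @export
print.two_point <- function(x, ...) {
  cat(sprintf("two-point linkage%s: n = %d, r = %d, theta = %.4f, LOD = %.2f\n",
              if (is.na(x$marker_id)) "" else paste0(" (", x$marker_id, ")"),
              x$n, x$r, x$theta, x$lod))
  invisible(x)
}

#' Two-point scan of every marker against the trait locus
#'
#' Applies [score_recombinants()] and [two_point_lod()] to each marker
#' of a genotype matrix; markers that are uninformative are reported
#' with NA.
#'
#' @param geno individuals x markers dosage matrix.
#' @param carrier per-individual carrier status (NA = excluded).
#' @param map optional marker map (`id`, `chrom`, `pos`) matching the
#'   columns.
#' @return Data frame `marker_id`, `chrom`, `pos`, `n`, `r`, `theta`,
#'   `lod`.
#' @export
linkage_scan <- function(geno, carrier, map = NULL) {
  ids <- colnames(geno)
  res <- lapply(seq_len(ncol(geno)), function(j) {
    sr <- tryCatch(score_recombinants(geno[, j], carrier),
                   error = function(e) NULL)
    if (is.null(sr)) return(data.frame(marker_id = ids[j], n = NA, r = NA,
                                       theta = NA, lod = NA))
    tp <- two_point_lod(sr$n, sr$r, ids[j])
    data.frame(marker_id = ids[j], n = tp$n, r = tp$r, theta = tp$theta,
               lod = tp$lod, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(map)) {
    i <- match(out$marker_id, map$id)
    out$chrom <- map$chrom[i]
    out$pos <- map$pos[i]
    out <- out[, c("marker_id", "chrom", "pos", "n", "r", "theta", "lod")]
  }
  out
}

#' Narrow a candidate interval using recombinant individuals
#'
#' Second-round linkage narrowing: for each recombinant offspring, each
#' marker is concordant if its genotype matches the trait-linked
#' expectation (heterozygous iff carrier, for founder-fixed markers in a
#' backcross), and the crossover is localized between the last
#' concordant and first discordant marker. The candidate interval is the
#' maximal run of markers concordant with every recombinant's trait
#' status: its bounds are the outermost concordant markers, extended to
#' the prior interval's edge on a side with no discordant marker. A
#' recombinant whose concordance pattern implies a double crossover
#' (more than one switch across the ordered markers) is flagged with a
#' warning and excluded.
#'
#' @param rec_geno recombinants x markers dosage matrix (markers ordered
#'   by position).
#' @param carrier per-recombinant carrier status (logical).
#' @param markers data frame `id`, `pos` for the (ordered) markers.
#' @param prior 1-row [genomic_interval()]: the interval being narrowed
#'   (returned unchanged when no recombinant is supplied).
#' @return List of class `candidate_interval`: `interval`,
#'   `flanking_markers` (ids bounding the run, NA at a prior edge),
#'   `excluded` (ids/indices of flagged double-crossover individuals).
#' @export
narrow_interval <- function(rec_geno, carrier, markers, prior) {
  if (nrow(prior) != 1) stop("prior must be a single interval")
  if (is.null(rec_geno) || nrow(rec_geno) == 0) {
    return(structure(list(interval = prior,
                          flanking_markers = c(NA, NA),
                          excluded = character(0)),
                     class = "candidate_interval"))
  }
  if (any(diff(markers$pos) < 0)) stop("markers must be ordered by position")
  ids <- rownames(rec_geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rec_geno)))
  conc <- matrix(NA, nrow(rec_geno), ncol(rec_geno))
  for (i in seq_len(nrow(rec_geno))) {
    conc[i, ] <- (rec_geno[i, ] == 1L) == carrier[i]
  }
  # a single crossover allows at most one switch in the concordance
  # pattern; more switches means an (unlikely) double crossover or a
  # genotyping error
  switches <- apply(conc, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else sum(diff(x) != 0)
  })
  excluded <- ids[switches > 1]
  if (length(excluded))
    warning("excluding recombinant(s) with double-crossover pattern: ",
            paste(excluded, collapse = ", "))
  keep <- switches <= 1
  if (!any(keep)) {
    return(structure(list(interval = prior, flanking_markers = c(NA, NA),
                          excluded = excluded),
                     class = "candidate_interval"))
  }
  allconc <- apply(conc[keep, , drop = FALSE], 2, function(x) all(x, na.rm = TRUE))
  if (!any(allconc)) {
    iv <- genomic_interval(character(0), numeric(0), numeric(0))
    return(structure(list(interval = iv, flanking_markers = c(NA, NA),
                          excluded = excluded),
                     class = "candidate_interval"))
  }
  # maximal run of all-concordant markers (longest; distal on ties)
  rl <- rle(allconc)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  runs <- which(rl$values)
  best <- runs[which.max(rl$lengths[runs] + seq_along(rl$lengths)[runs] * 1e-9)]
  i0 <- starts[best]
  i1 <- ends[best]
  lower <- if (i0 == 1) prior$start else markers$pos[i0]
  upper <- if (i1 == ncol(rec_geno)) prior$end else markers$pos[i1]
  structure(list(interval = genomic_interval(prior$chrom, lower, upper,
                                             name = "candidate"),
                 flanking_markers = c(if (i0 == 1) NA else markers$id[i0],
                                      if (i1 == ncol(rec_geno)) NA else markers$id[i1]),
                 excluded = excluded),
            class = "candidate_interval")
}

#' @export
print.candidate_interval <- function(x, ...) {
  if (nrow(x$interval) == 0) {
    cat("candidate_interval: no marker run consistent with all recombinants\n")
  } else {
    cat(sprintf("candidate_interval: %s:%s-%s (%.2f Mb)\n",
                x$interval$chrom,
                format(x$interval$start, big.mark = ",", scientific = FALSE),
                format(x$interval$end, big.mark = ",", scientific = FALSE),
                interval_length(x$interval) / 1e6))
  }
  invisible(x)
}
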