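#' Annotate candidate variants against conserved elements
#'
#' For each candidate variant (an SNV is a point; a deletion spans
#' `pos..end`), lists every conserved element (CE) overlapping it by at
#' least 1 bp, the total overlapping bp, and any named region fully
#' containing the variant's span (e.g. the interval homologous to a
#' deletion mapped in another species).
#'
#' @param candidates data frame with `id`, `chrom`, `pos`, `end` (e.g. a
#'   [filter_candidates()] result).
#' @param ces [genomic_interval()] of conserved elements (named).
#' @param named_regions optional [genomic_interval()] of named regions
#'   tested for containment.
#' @return Data frame of class `annotation`: `id`, `chrom`, `pos`,
#'   `end`, `svtype` (if present), `n_ce`, `total_ce_bp`, `ce_ids`,
#'   `contained_in` (comma-separated names), in input order.
#' @export
annotate_variants <- function(candidates, ces, named_regions = NULL) {
  span <- genomic_interval(candidates$chrom, candidates$pos,
                           candidates$end)
  n <- nrow(candidates)
  n_ce <- integer(n); tot <- numeric(n)
  ce_ids <- character(n); contained <- character(n)
  for (i in seq_len(n)) {
    ov <- interval_overlap(span[i, ], ces)
    hit <- ov >= 1
    n_ce[i] <- sum(hit)
    tot[i] <- sum(ov[hit])
    ce_ids[i] <- paste(ces$name[hit], collapse = ",")
    if (!is.null(named_regions) && nrow(named_regions)) {
      inr <- named_regions$chrom == span$chrom[i] &
        named_regions$start <= span$start[i] &
        named_regions$end >= span$end[i]
      contained[i] <- paste(named_regions$name[inr], collapse = ",")
    }
  }
  out <- data.frame(id = candidates$id, chrom = candidates$chrom,
                    pos = candidates$pos, end = candidates$end,
                    stringsAsFactors = FALSE)
  if (!is.null(candidates$svtype)) out$svtype <- candidates$svtype
  out$n_ce <- n_ce
  out$total_ce_bp <- tot
  out$ce_ids <- ce_ids
  out$contained_in <- contained
  class(out) <- c("annotation", "data.frame")
  out
}

#' Rank annotated candidates by conserved-element disruption
#'
#' Candidates overlapping at least one CE rank above those overlapping
#' none; ties are broken by total overlapping bp (descending), then by
#' position; the sort is stable, so candidates tied on all keys keep
#' their input order.
#'
#' @param annotated an [annotate_variants()] result.
#' @return The same data frame reordered, with a `rank` column.
#' @export
rank_candidates <- function(annotated) {
  ord <- order(-(annotated$n_ce > 0), -annotated$total_ce_bp,
               annotated$chrom, annotated$pos)
  out <- annotated[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Percent identity of two nucleotide sequences by global alignment
#'
#' Needleman-Wunsch global (end-to-end) alignment with a linear gap
#' penalty, scored via Biostrings: match +1, mismatch -1, gap -2 per
#' gapped column by default. Percent identity is
#' `100 * matches / alignment length`, with the alignment length
#' counting every column including gap columns (the declared convention
#' for CE-scale homology checks).
#'
#' @param seq_a,seq_b non-empty nucleotide strings over A, C, G, T, N
#'   (identical letters match; N matches only N).
#' @param match,mismatch,gap alignment scores (gap per column, linear).
#' @return List of class `identity_result`: `percent_identity`,
#'   `alignment_length`, `matches`, `score`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")$percent_identity # 75
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap = -2) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  up_a <- toupper(seq_a); up_b <- toupper(seq_b)
  if (grepl("[^ACGTN]", up_a) || grepl("[^ACGTN]", up_b))
    stop("sequences must be over {A, C, G, T, N}")
  letters5 <- c("A", "C", "G", "T", "N")
  sub <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(sub) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(up_a), Biostrings::DNAString(up_b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = -gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == sa & pa != "-")
  len <- length(pa)
  structure(list(percent_identity = 100 * matches / len,
                 alignment_length = len, matches = matches,
                 score = Biostrings::score(aln)),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("global alignment: %.1f%% identity (%d/%d columns, score %g)\n",
              x$percent_identity, x$matches, x$alignment_length, x$score))
  invisible(x)
}
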