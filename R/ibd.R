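# Site classification for the consensus IBD scan. A site is "defining"
# when a consensus allele exists: every genotyped core sample is
# homozygous for the same allele, and every genotyped carrier sample
# carries at least one copy of it. Any other configuration (a
# heterozygous core, cores homozygous for different alleles, or a
# carrier without the consensus allele) is a "break". Missing genotypes
# are compatible with any consensus (the sample is skipped site-wise).
.classify_sites <- function(geno, core_idx, carrier_idx) {
  nv <- nrow(geno)
  defining <- logical(nv)
  consensus <- rep(NA_integer_, nv)  # 0 = ref allele, 1 = alt allele
  for (i in seq_len(nv)) {
    gc <- geno[i, core_idx]
    gc <- gc[!is.na(gc)]
    if (length(gc) == 0) next
    if (any(gc == 1L)) next
    u <- unique(gc)
    if (length(u) != 1) next
    cons <- if (u == 2L) 1L else 0L
    if (length(carrier_idx)) {
      gk <- geno[i, carrier_idx]
      gk <- gk[!is.na(gk)]
      ok <- if (cons == 1L) all(gk >= 1L) else all(gk <= 1L)
      if (!ok) next
    }
    defining[i] <- TRUE
    consensus[i] <- cons
  }
  list(defining = defining, consensus = consensus)
}

#' Detect identical-by-descent regions shared by case samples
#'
#' Scans a candidate region for runs of sites at which all core case
#' samples are homozygous for a common consensus allele and all carrier
#' cases hold at least one copy of it — the unphased-genotype signature
#' of a haplotype shared identical by descent. Sites violating the
#' consensus are breaks; maximal runs of defining sites (allowing up to
#' `max_mismatch` break sites to be skipped per region, e.g. to tolerate
#' genotyping errors) with at least `min_sites` defining sites are
#' reported, each spanning its first to last defining site.
#'
#' @param vs a [variant_set()].
#' @param panel a [sample_panel()]; samples with carrier_class "core"
#'   anchor the consensus, "carrier" samples must be compatible,
#'   "non_carrier" cases and controls are ignored by the scan.
#' @param region optional 1-row [genomic_interval()] restricting the
#'   scan (default: all records).
#' @param min_sites minimum defining sites per reported region
#'   (default 1).
#' @param max_mismatch break sites tolerated inside one region
#'   (default 0).
#' @return Data frame of class `ibd_regions`: `chrom`, `start`, `end`,
#'   `n_defining_sites`, with attributes `core_samples` and
#'   `carrier_samples`.
#' @export
find_ibd_regions <- function(vs, panel, region = NULL, min_sites = 1,
                             max_mismatch = 0) {
  cores <- panel$sample_id[!is.na(panel$carrier_class) &
                             panel$carrier_class == "core"]
  carriers <- panel$sample_id[!is.na(panel$carrier_class) &
                                panel$carrier_class == "carrier"]
  if (length(cores) == 0) stop("panel has no core case samples")
  va <- vs$variants
  geno <- vs$geno
  if (!is.null(region)) {
    keep <- va$chrom == region$chrom & va$pos >= region$start &
      va$pos <= region$end
    va <- va[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_defining_sites = integer(0))
  if (nrow(va) == 0) {
    out <- empty
  } else {
    cl <- .classify_sites(geno, match(cores, vs$samples),
                          match(carriers, vs$samples))
    rows <- list()
    for (ch in unique(va$chrom)) {
      idx <- which(va$chrom == ch)
      def <- cl$defining[idx]
      # greedy left-to-right segmentation: a region absorbs break sites
      # while its mismatch budget lasts, then closes at its last
      # defining site
      i <- 1
      while (i <= length(idx)) {
        if (!def[i]) { i <- i + 1; next }
        first <- i
        last <- i
        budget <- max_mismatch
        j <- i + 1
        while (j <= length(idx)) {
          if (def[j]) {
            last <- j
          } else {
            if (budget == 0) break
            budget <- budget - 1
          }
          j <- j + 1
        }
        ndef <- sum(def[first:last])
        if (ndef >= min_sites) {
          rows[[length(rows) + 1]] <-
            data.frame(chrom = ch, start = va$pos[idx[first]],
                       end = va$pos[idx[last]], n_defining_sites = ndef)
        }
        i <- last + 1
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else empty
  }
  attr(out, "core_samples") <- cores
  attr(out, "carrier_samples") <- carriers
  class(out) <- c("ibd_regions", "data.frame")
  out
}

#' Exclusion-filter candidate causal variants inside an IBD region
#'
#' Keeps the variants whose span intersects the IBD interval and whose
#' genotypes show the causal pattern: every genotyped core case
#' homozygous alt, every genotyped carrier case het or homozygous alt,
#' and the alt allele absent from all genotyped controls — provided at
#' least `1 - max_missing` of the controls are genotyped at the site
#' (default: >= 90% genotyped and all alt-free).
#'
#' @param vs a [variant_set()].
#' @param panel a [sample_panel()].
#' @param ibd 1-row interval (one row of a [find_ibd_regions()] result,
#'   or any `genomic_interval`-like data frame with `chrom`, `start`,
#'   `end`).
#' @param max_missing maximum fraction of controls allowed to be
#'   ungenotyped at a surviving candidate site (default 0.1).
#' @return Data frame of class `candidate_variants`: the surviving
#'   variant records plus `control_alt_count` (always 0),
#'   `n_controls_genotyped`.
#' @export
filter_candidates <- function(vs, panel, ibd, max_missing = 0.1) {
  if (nrow(ibd) != 1) stop("ibd must be a single region")
  cores <- panel$sample_id[!is.na(panel$carrier_class) &
                             panel$carrier_class == "core"]
  carriers <- panel$sample_id[!is.na(panel$carrier_class) &
                                panel$carrier_class == "carrier"]
  controls <- panel$sample_id[panel$phenotype == "control"]
  va <- vs$variants
  span_hit <- va$chrom == ibd$chrom &
    pmax(va$pos, ibd$start) <= pmin(va$end, ibd$end)
  keep <- logical(nrow(va))
  nco_geno <- integer(nrow(va))
  ci <- match(cores, vs$samples)
  ki <- match(carriers, vs$samples)
  oi <- match(controls, vs$samples)
  for (i in which(span_hit)) {
    gc <- vs$geno[i, ci]
    if (!all(gc[!is.na(gc)] == 2L)) next
    if (length(ki)) {
      gk <- vs$geno[i, ki]
      if (!all(gk[!is.na(gk)] >= 1L)) next
    }
    go <- vs$geno[i, oi]
    ngeno <- sum(!is.na(go))
    nco_geno[i] <- ngeno
    if (length(oi)) {
      if (ngeno < (1 - max_missing) * length(oi)) next
      if (any(go[!is.na(go)] > 0L)) next
    }
    keep[i] <- TRUE
  }
  out <- va[keep, , drop = FALSE]
  out$control_alt_count <- integer(nrow(out))
  out$n_controls_genotyped <- nco_geno[keep]
  rownames(out) <- NULL
  class(out) <- c("candidate_variants", "data.frame")
  out
}

#' Genotype counts by phenotype class for one variant
#'
#' Diagnostic cross-tabulation of a variant's genotypes over a panel,
#' e.g. to verify that all cases carry the candidate mutation and no
#' control does.
#'
#' @param vs a [variant_set()].
#' @param variant variant id (or integer row index).
#' @param panel a [sample_panel()].
#' @return Integer matrix: rows "case"/"control", columns "hom_ref",
#'   "het", "hom_alt", "missing".
#' @export
zygosity_profile <- function(vs, variant, panel) {
  i <- if (is.numeric(variant)) variant else match(variant, vs$variants$id)
  if (is.na(i)) stop("variant not found: ", variant)
  out <- matrix(0L, nrow = 2, ncol = 4,
                dimnames = list(c("case", "control"),
                                c("hom_ref", "het", "hom_alt", "missing")))
  if (nrow(panel) == 0) return(out)
  g <- vs$geno[i, match(panel$sample_id, vs$samples)]
  lab <- factor(gt_label(g),
                levels = c("hom_ref", "het", "hom_alt", "missing"))
  tab <- table(factor(panel$phenotype, levels = c("case", "control")), lab)
  out[, ] <- as.integer(tab)
  out
}
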