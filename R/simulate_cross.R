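#' Build an evenly spaced marker map
#'
#' Convenience grid of markers on one chromosome with a linear genetic
#' map (constant recombination rate).
#'
#' @param chrom chromosome name.
#' @param n_markers number of markers.
#' @param len_bp chromosome length in bp; markers are evenly spaced from
#'   1 to `len_bp`.
#' @param cM_per_Mb recombination rate (default 5, a microchromosome-like
#'   rate).
#' @return Data frame with columns `id`, `chrom`, `pos`, `cM`.
#' @export
marker_map <- function(chrom, n_markers, len_bp, cM_per_Mb = 5) {
  pos <- round(seq(1, len_bp, length.out = n_markers))
  data.frame(id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
             cM = pos / 1e6 * cM_per_Mb, stringsAsFactors = FALSE)
}

#' Specify an experimental cross
#'
#' Describes a backcross or F2 intercross between two founder lines fixed
#' for different alleles at every marker (allele 0 = founder A, the
#' wild-type/tester line; allele 1 = founder B, the trait line). The
#' phenotype is an ordinal category obtained by thresholding an
#' additive + dominance liability: for each causal locus with alt dosage
#' `g`, the liability gains `a * g + d * [g == 1]`, plus Normal(0, sigma)
#' residual noise; `cuts` are the strictly increasing category cut-points
#' (category = number of cut-points below the liability).
#'
#' @param design "backcross" (F1 females crossed back to founder A) or
#'   "F2" (F1 x F1).
#' @param n_offspring number of offspring to simulate.
#' @param map marker map as from [marker_map()] (columns `id`, `chrom`,
#'   `pos`, `cM`, cM non-decreasing within chromosome).
#' @param causal data frame with columns `chrom`, `pos` (must match map
#'   positions), `a` (additive effect per alt allele) and `d` (dominance
#'   deviation added for heterozygotes); may have zero rows.
#' @param sigma residual liability standard deviation (>= 0).
#' @param cuts strictly increasing liability cut-points.
#' @param class_labels optional labels for the `length(cuts) + 1`
#'   categories (e.g. `c("clean", "intermediate", "feathered")`).
#' @return A `cross_design` list.
#' @export
cross_design <- function(design = c("backcross", "F2"), n_offspring, map,
                         causal = NULL, sigma = 0, cuts = numeric(0),
                         class_labels = NULL) {
  design <- match.arg(design)
  if (is.null(map) || nrow(map) == 0) stop("empty genetic map")
  if (!all(c("chrom", "pos", "cM") %in% names(map)))
    stop("map needs chrom, pos, cM columns")
  if (is.null(map$id)) map$id <- paste0(map$chrom, "_", map$pos)
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  if (any(unlist(tapply(map$cM, map$chrom, function(x) diff(x) < 0))))
    stop("cM must be non-decreasing with position")
  if (sigma < 0) stop("sigma must be >= 0")
  if (length(cuts) > 1 && any(diff(cuts) <= 0))
    stop("cuts must be strictly increasing")
  cidx <- integer(0)
  if (!is.null(causal) && nrow(causal) > 0) {
    cidx <- match(paste(causal$chrom, causal$pos),
                  paste(map$chrom, map$pos))
    if (any(is.na(cidx)))
      stop("causal loci must coincide with map markers")
  }
  if (!is.null(class_labels) && length(class_labels) != length(cuts) + 1)
    stop("need length(cuts) + 1 class labels")
  structure(list(design = design, n_offspring = n_offspring, map = map,
                 causal = causal, causal_idx = cidx, sigma = sigma,
                 cuts = cuts, class_labels = class_labels),
            class = "cross_design")
}

# One F1 gamete across all chromosomes under Haldane's model (no
# interference): crossover count ~ Poisson(map length in Morgans),
# positions uniform on the cM scale. Returns founder labels (0 = A,
# 1 = B) at every marker.
.sim_gamete <- function(map) {
  lab <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    cm <- map$cM[i]
    len <- max(cm) - min(cm)
    nxo <- stats::rpois(1, len / 100)
    xo <- sort(stats::runif(nxo, min(cm), max(cm)))
    phase <- stats::rbinom(1, 1, 0.5)
    lab[i] <- (phase + findInterval(cm, xo)) %% 2L
  }
  lab
}

#' Simulate offspring of a two-line cross
#'
#' Meioses follow Haldane's model; founders are fixed for different
#' alleles at every marker, so each F1 gamete is a mosaic of founder A
#' and founder B segments. Backcross offspring receive one F1 gamete and
#' one pure founder-A haplotype; F2 offspring receive two independent F1
#' gametes. Phenotypes come from the design's thresholded liability.
#'
#' @param design a [cross_design()].
#' @param seed integer seed; the simulation is fully reproducible given
#'   the seed.
#' @return An object of class `cross_sim`: list with `map`, founder-origin
#'   haplotype matrices `hap1`/`hap2` (individuals x markers, 0 = founder
#'   A allele, 1 = founder B), genotype dosage matrix `geno`
#'   (`hap1 + hap2`), `liability`, integer `score` (0-based category),
#'   optional `pheno_class`, and `causal_dosage` (individuals x causal
#'   loci).
#' @examples
#' mp <- marker_map("chr15", 20, 13e6)
#' cd <- cross_design("backcross", 50, mp,
#'                    causal = data.frame(chrom = "chr15", pos = mp$pos[15],
#'                                        a = 0.5, d = 0.5),
#'                    sigma = 0.25, cuts = c(0.161, 0.724),
#'                    class_labels = c("clean", "intermediate", "feathered"))
#' cs <- simulate_cross(cd, seed = 1)
#' table(cs$pheno_class)
#' @export
simulate_cross <- function(design, seed) {
  if (!inherits(design, "cross_design")) stop("need a cross_design")
  set.seed(seed)
  map <- design$map
  n <- design$n_offspring
  nm <- nrow(map)
  hap1 <- matrix(0L, n, nm)  # maternal (F1) gamete
  hap2 <- matrix(0L, n, nm)  # paternal gamete (founder A in backcross)
  for (i in seq_len(n)) {
    hap1[i, ] <- .sim_gamete(map)
    if (design$design == "F2") hap2[i, ] <- .sim_gamete(map)
  }
  geno <- hap1 + hap2
  colnames(geno) <- colnames(hap1) <- colnames(hap2) <- map$id
  liability <- stats::rnorm(n, 0, design$sigma)
  causal_dosage <- NULL
  if (length(design$causal_idx)) {
    causal_dosage <- geno[, design$causal_idx, drop = FALSE]
    for (k in seq_along(design$causal_idx)) {
      g <- causal_dosage[, k]
      liability <- liability + design$causal$a[k] * g +
        design$causal$d[k] * (g == 1L)
    }
  }
  score <- findInterval(liability, design$cuts)
  pheno_class <- NULL
  if (!is.null(design$class_labels))
    pheno_class <- factor(design$class_labels[score + 1L],
                          levels = design$class_labels)
  structure(list(design = design, map = map, hap1 = hap1, hap2 = hap2,
                 geno = geno, liability = liability, score = score,
                 pheno_class = pheno_class, causal_dosage = causal_dosage),
            class = "cross_sim")
}

#' @export
print.cross_sim <- function(x, ...) {
  cat("cross_sim:", x$design$design, "with", nrow(x$geno), "offspring,",
      ncol(x$geno), "markers\n")
  if (!is.null(x$pheno_class)) print(table(x$pheno_class))
  invisible(x)
}

#' Simulate pooled SNP-array intensities
#'
#' Models equal DNA contribution per pooled individual: at each marker
#' the two channel intensities are proportional to the pool's allele
#' counts, `X = gain * n_A + noise`, `Y = gain * n_B + noise`, with
#' independent Normal(0, `noise_sd`) errors clamped at zero. Channel X
#' tracks the founder-A (wild-type) allele, Y the founder-B allele, so
#' the downstream relative allele frequency X/(X+Y) estimates the pool's
#' A-allele frequency.
#'
#' @param cross a `cross_sim`.
#' @param pools named list of individual index vectors, one per pool
#'   (each non-empty).
#' @param gain intensity units per allele copy (> 0).
#' @param noise_sd intensity noise SD (>= 0).
#' @param seed integer seed.
#' @return Long data frame: `snp_id`, `chrom`, `pos`, `pool`, `X`, `Y`.
#' @export
simulate_pool_array <- function(cross, pools, gain = 1000, noise_sd = 0,
                                seed = 1) {
  if (gain < 0) stop("gain must be non-negative")
  if (any(lengths(pools) == 0)) stop("each pool must be non-empty")
  set.seed(seed)
  out <- lapply(names(pools), function(p) {
    g <- cross$geno[pools[[p]], , drop = FALSE]
    nB <- colSums(g)
    nA <- 2 * nrow(g) - nB
    X <- pmax(0, gain * nA + stats::rnorm(length(nA), 0, noise_sd))
    Y <- pmax(0, gain * nB + stats::rnorm(length(nB), 0, noise_sd))
    data.frame(snp_id = cross$map$id, chrom = cross$map$chrom,
               pos = cross$map$pos, pool = p, X = X, Y = Y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate pool-seq allele counts
#'
#' Per marker and pool, sequencing depth is Poisson(`mean_depth`) and the
#' alt (founder-B) read count is Binomial(depth, pool alt-allele
#' frequency).
#'
#' @inheritParams simulate_pool_array
#' @param mean_depth mean coverage per pool (> 0), e.g. 30 for a 30x
#'   pool.
#' @return Long data frame: `snp_id`, `chrom`, `pos`, `pool`,
#'   `ref_count`, `alt_count`.
#' @export
simulate_pool_reads <- function(cross, pools, mean_depth = 30, seed = 1) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (any(lengths(pools) == 0)) stop("each pool must be non-empty")
  set.seed(seed)
  out <- lapply(names(pools), function(p) {
    g <- cross$geno[pools[[p]], , drop = FALSE]
    f <- colSums(g) / (2 * nrow(g))
    depth <- stats::rpois(length(f), mean_depth)
    alt <- stats::rbinom(length(f), depth, f)
    data.frame(snp_id = cross$map$id, chrom = cross$map$chrom,
               pos = cross$map$pos, pool = p,
               ref_count = depth - alt, alt_count = alt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
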