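#' Specify a case/control sequence panel with a planted IBD haplotype
#'
#' Describes the panel the IBD mapping stage consumes: a set of case
#' samples descending from a common founder haplotype carrying one or
#' more causal variants, plus unrelated controls. Each case's shared
#' segment shrinks with the number of generations since the founder
#' mutation (`G`): the two arms around the causal site are independent
#' Exponential(rate = `G` per Morgan) lengths, converted to bp through a
#' linear genetic map of `cM_per_Mb`.
#'
#' @param region a 1-row [genomic_interval()]: the candidate region the
#'   panel spans.
#' @param n_case_core cases expected homozygous for the shared haplotype
#'   (>= 1).
#' @param n_case_carrier cases carrying exactly one copy (e.g. a
#'   segregating breed).
#' @param n_controls control samples; the causal alt allele never
#'   appears in controls.
#' @param G generations since the founder mutation (>= 1; default 200,
#'   i.e. an old mutation spread across breeds).
#' @param causal list of causal variant specs, each a list with `svtype`
#'   ("SNV" or "DEL"), `pos`, and for DEL a `length` in bp. All planted
#'   causal variants are carried by every case.
#' @param background_per_kb expected background variant density per kb
#'   (default 0.5).
#' @param cM_per_Mb linear recombination rate used to convert Morgans to
#'   bp (default 5).
#' @param maf_range range of background population alt-allele
#'   frequencies (default c(0.05, 0.95)).
#' @return A `panel_design` list.
#' @export
panel_design <- function(region,
                         n_case_core = 8, n_case_carrier = 0,
                         n_controls = 159, G = 200,
                         causal = list(list(svtype = "SNV",
                                            pos = NULL, length = 1)),
                         background_per_kb = 0.5, cM_per_Mb = 5,
                         maf_range = c(0.05, 0.95)) {
  if (G < 1) stop("G must be >= 1")
  if (n_case_core < 1) stop("need at least one core case")
  if (n_case_carrier < 0 || n_controls < 0) stop("counts must be >= 0")
  if (nrow(region) != 1) stop("region must be a single interval")
  mid <- round((region$start + region$end) / 2)
  causal <- lapply(causal, function(cv) {
    if (is.null(cv$pos)) cv$pos <- mid
    if (is.null(cv$length)) cv$length <- 1
    if (!cv$svtype %in% c("SNV", "DEL")) stop("causal svtype must be SNV or DEL")
    if (cv$svtype == "DEL" && cv$length < 2) stop("DEL length must be >= 2")
    cv
  })
  structure(list(region = region, n_case_core = n_case_core,
                 n_case_carrier = n_case_carrier, n_controls = n_controls,
                 G = G, causal = causal,
                 background_per_kb = background_per_kb,
                 cM_per_Mb = cM_per_Mb, maf_range = maf_range),
            class = "panel_design")
}

#' Simulate a case/control panel sharing an IBD causal haplotype
#'
#' Core cases are homozygous for the founder haplotype inside their
#' shared segment (autozygous, as in breed samples fixed for the swept
#' haplotype); carrier cases hold one founder copy; the causal alt
#' alleles are absent from every control. Background variants get
#' population frequencies drawn uniformly from `maf_range`; outside its
#' segment a case's genotype is an ordinary Hardy-Weinberg draw. Each
#' case's segment is anchored at the causal site with independent
#' exponential arms (see [panel_design()]); when several causal variants
#' are planted, each arm is extended to cover the farthest causal edge so
#' every case carries all of them. The realized IBD interval (the
#' intersection of all case segments, clipped to the region) is returned
#' for recovery testing.
#'
#' @param pd a [panel_design()].
#' @param seed integer seed.
#' @return List of class `panel_sim`: `vs` (a [variant_set()]), `panel`
#'   (a [sample_panel()]), `true_ibd` (1-row [genomic_interval()]),
#'   `segments` (per-case data frame with unclipped arm lengths in bp),
#'   and `causal_ids` (variant ids of the planted causal records).
#' @export
simulate_panel <- function(pd, seed) {
  if (!inherits(pd, "panel_design")) stop("need a panel_design")
  set.seed(seed)
  reg <- pd$region
  chrom <- reg$chrom
  bp_per_morgan <- 100 * 1e6 / pd$cM_per_Mb
  n_cases <- pd$n_case_core + pd$n_case_carrier
  ids <- c(if (pd$n_case_core) paste0("core_", seq_len(pd$n_case_core)),
           if (pd$n_case_carrier) paste0("carrier_", seq_len(pd$n_case_carrier)),
           if (pd$n_controls) paste0("control_", seq_len(pd$n_controls)))
  pheno <- rep(c("case", "control"), c(n_cases, pd$n_controls))
  cclass <- c(rep("core", pd$n_case_core),
              rep("carrier", pd$n_case_carrier),
              rep(NA, pd$n_controls))
  panel <- sample_panel(ids, pheno, cclass)

  cpos <- vapply(pd$causal, function(cv) cv$pos, numeric(1))
  cend <- vapply(pd$causal, function(cv) cv$pos + cv$length - 1, numeric(1))
  anchor <- cpos[1]
  # per-case shared segment: exponential arms (in Morgans) around the
  # anchor, stretched to cover every planted causal variant
  arm_l <- stats::rexp(n_cases, pd$G) * bp_per_morgan + (anchor - min(cpos))
  arm_r <- stats::rexp(n_cases, pd$G) * bp_per_morgan + (max(cend) - anchor)
  seg_start <- pmax(reg$start, anchor - arm_l)
  seg_end <- pmin(reg$end, anchor + arm_r)
  true_ibd <- genomic_interval(chrom, max(seg_start), min(seg_end),
                               name = "true_ibd")

  n_bg <- stats::rpois(1, pd$background_per_kb *
                          (reg$end - reg$start + 1) / 1000)
  bg_pos <- numeric(0)
  if (n_bg > 0) {
    bg_pos <- reg$start + sample.int(reg$end - reg$start + 1, n_bg) - 1
    bg_pos <- sort(bg_pos[!bg_pos %in% round(cpos)])
  }
  n_bg <- length(bg_pos)
  freq <- stats::runif(n_bg, pd$maf_range[1], pd$maf_range[2])
  founder_allele <- stats::rbinom(n_bg, 1, freq)  # allele on shared haplotype

  n_samp <- length(ids)
  geno <- matrix(NA_integer_, nrow = n_bg, ncol = n_samp,
                 dimnames = list(NULL, ids))
  for (j in seq_len(n_samp)) {
    hwe <- stats::rbinom(n_bg, 2, freq)
    if (pheno[j] == "control") {
      geno[, j] <- hwe
    } else {
      inseg <- bg_pos >= seg_start[j] & bg_pos <= seg_end[j]
      if (!is.na(cclass[j]) && cclass[j] == "core") {
        g <- hwe
        g[inseg] <- 2L * founder_allele[inseg]
      } else {
        other <- stats::rbinom(n_bg, 1, freq)
        g <- hwe
        g[inseg] <- founder_allele[inseg] + other[inseg]
      }
      geno[, j] <- g
    }
  }
  bases <- c("A", "C", "G", "T")
  bg_ref <- sample(bases, n_bg, replace = TRUE)
  bg_alt <- vapply(bg_ref, function(b) sample(setdiff(bases, b), 1), "")
  variants <- data.frame(chrom = rep(chrom, n_bg), pos = bg_pos,
                         id = sprintf("bg_%d", seq_len(n_bg)),
                         ref = bg_ref, alt = bg_alt,
                         svtype = rep("SNV", n_bg), end = bg_pos,
                         stringsAsFactors = FALSE)

  causal_ids <- character(0)
  for (k in seq_along(pd$causal)) {
    cv <- pd$causal[[k]]
    cid <- paste0("causal_", k)
    causal_ids <- c(causal_ids, cid)
    isdel <- cv$svtype == "DEL"
    variants <- rbind(variants,
                      data.frame(chrom = chrom, pos = cv$pos, id = cid,
                                 ref = if (isdel) "N" else "T",
                                 alt = if (isdel) "<DEL>" else "C",
                                 svtype = cv$svtype,
                                 end = cv$pos + cv$length - 1,
                                 stringsAsFactors = FALSE))
    g <- c(rep(2L, pd$n_case_core), rep(1L, pd$n_case_carrier),
           rep(0L, pd$n_controls))
    geno <- rbind(geno, g)
  }
  structure(list(vs = variant_set(variants, geno), panel = panel,
                 true_ibd = true_ibd,
                 segments = data.frame(sample_id = ids[seq_len(n_cases)],
                                       arm_left_bp = arm_l,
                                       arm_right_bp = arm_r,
                                       start = seg_start, end = seg_end),
                 causal_ids = causal_ids),
            class = "panel_sim")
}
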