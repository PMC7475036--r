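#' Cross-tabulate genotypes by phenotype class or breed
#'
#' Diagnostic genotype-distribution table: counts of each genotype at
#' one locus, per phenotype class (or per population/breed), with
#' missing genotypes in their own column.
#'
#' @param records data frame of individuals with a genotype column for
#'   the locus (values "hom_mut", "het", "hom_wt", "missing"/NA) and the
#'   grouping column.
#' @param locus name of the genotype column (e.g. "locus1" for the
#'   chromosome-15 TBX5-type locus, "locus2" for the chromosome-13
#'   PITX1-type locus).
#' @param by grouping column name (default "pheno_class").
#' @return Integer matrix (groups x genotype classes) of class
#'   `cross_tab`; row sums equal group sizes.
#' @export
cross_tabulate <- function(records, locus, by = "pheno_class") {
  glev <- c("hom_mut", "het", "hom_wt", "missing")
  g <- as.character(records[[locus]])
  g[is.na(g)] <- "missing"
  if (!all(g %in% glev)) stop("genotypes must be hom_mut/het/hom_wt/missing")
  grp <- records[[by]]
  tab <- table(factor(grp, levels = unique(grp)), factor(g, levels = glev))
  out <- matrix(as.integer(tab), nrow = nrow(tab), ncol = length(glev),
                dimnames = list(rownames(tab), glev))
  class(out) <- c("cross_tab", class(out))
  out
}

#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit test of observed class counts against a
#' stated segregation ratio (e.g. 15:1 for an F2 trait controlled by two
#' independent dominant loci), via [stats::chisq.test()] without
#' continuity correction.
#'
#' @param observed integer class counts (length >= 2).
#' @param expected_ratio positive ratio of the same length (e.g.
#'   `c(15, 1)` or `c(1, 1)`).
#' @return List: `chi2`, `df` (= classes - 1), `p`.
#' @examples
#' segregation_test(c(82, 96), c(1, 1)) # chi2 = 1.101, df = 1
#' @export
segregation_test <- function(observed, expected_ratio) {
  if (length(observed) < 2) stop("need >= 2 classes")
  if (length(observed) != length(expected_ratio))
    stop("observed and ratio lengths differ")
  if (any(expected_ratio <= 0)) stop("expected ratio must be positive")
  ct <- suppressWarnings(
    stats::chisq.test(observed, p = expected_ratio / sum(expected_ratio)))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Expected clean-leg fraction in an F2 intercross
#'
#' With `n` independent, fully dominant feathering loci, an F2 bird is
#' clean-legged only when it carries no dominant allele at any locus:
#' probability `(1/4)^n` (so two loci give the classical 15:1
#' feathered:clean ratio).
#'
#' @param n_dominant_loci integer >= 1.
#' @return `(1/4)^n_dominant_loci`.
#' @export
expected_f2_clean_fraction <- function(n_dominant_loci) {
  if (n_dominant_loci < 1) stop("need >= 1 locus")
  (1 / 4)^n_dominant_loci
}

#' Adjusted digit length
#'
#' Fourth-digit length divided by the shank length of the same
#' individual — a size-adjusted brachydactyly proxy.
#'
#' @param digit4,shank lengths in mm (> 0).
#' @return `digit4 / shank`.
#' @export
adjusted_digit_length <- function(digit4, shank) {
  if (any(digit4 <= 0 | shank <= 0, na.rm = TRUE))
    stop("lengths must be positive")
  digit4 / shank
}

#' Per-genotype-combination summary statistics and pairwise t-tests
#'
#' Summarizes an ordinal feathering score (treated as numeric) or the
#' adjusted digit length over the two-locus genotype combinations of an
#' F2 (3 x 3 = 9 combinations, or the 3 marginal classes of one locus),
#' and runs two-sided pairwise Student's t-tests (pooled variance by
#' default; Welch by flag) between requested pairs.
#'
#' @param records data frame with genotype columns `locus1`, `locus2`
#'   (values "hom_mut", "het", "hom_wt") and the trait column(s):
#'   `hatch_score` (0-4), `adult_score` (0-9), or `digit4` + `shank`
#'   (mm) for `trait = "adjusted_digit"`.
#' @param trait "hatch_score", "adult_score" or "adjusted_digit".
#' @param by "both" (9 combinations), "locus1" or "locus2" (marginal).
#' @param pairs list of length-2 character vectors naming group pairs to
#'   test, or "all" (default) for every pair with data.
#' @param welch use Welch's unequal-variance t-test (default FALSE:
#'   pooled-variance Student's t).
#' @param bonferroni multiply p-values by the number of tests, capped at
#'   1 (default FALSE; no correction).
#' @return List of class `combo_stats`: `stats` (group, n, mean, sd) and
#'   `tests` (group_a, group_b, t, df, p; a pair with any group n < 2 is
#'   reported with NA and a note, other pairs are unaffected).
#' @export
genotype_combo_stats <- function(records,
                                 trait = c("hatch_score", "adult_score",
                                           "adjusted_digit"),
                                 by = c("both", "locus1", "locus2"),
                                 pairs = "all", welch = FALSE,
                                 bonferroni = FALSE) {
  trait <- match.arg(trait)
  by <- match.arg(by)
  y <- if (trait == "adjusted_digit") {
    adjusted_digit_length(records$digit4, records$shank)
  } else {
    as.numeric(records[[trait]])
  }
  glev <- c("hom_wt", "het", "hom_mut")
  l1 <- factor(records$locus1, levels = glev)
  l2 <- factor(records$locus2, levels = glev)
  grp <- switch(by,
                both = interaction(l1, l2, sep = "/", lex.order = TRUE),
                locus1 = l1,
                locus2 = l2)
  ok <- !is.na(grp) & !is.na(y)
  y <- y[ok]; grp <- droplevels(grp[ok])
  stats_tab <- do.call(rbind, lapply(levels(grp), function(g) {
    v <- y[grp == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  if (identical(pairs, "all")) {
    pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
  }
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    va <- y[grp == pr[1]]; vb <- y[grp == pr[2]]
    if (length(va) < 2 || length(vb) < 2) {
      return(data.frame(group_a = pr[1], group_b = pr[2], t = NA_real_,
                        df = NA_real_, p = NA_real_,
                        note = "group with n < 2",
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(va, vb, var.equal = !welch)
    data.frame(group_a = pr[1], group_b = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = unname(tt$p.value), note = "",
               stringsAsFactors = FALSE)
  }))
  if (bonferroni && !is.null(tests)) {
    ntest <- sum(!is.na(tests$p))
    tests$p <- pmin(1, tests$p * ntest)
  }
  structure(list(trait = trait, by = by, stats = stats_tab, tests = tests,
                 welch = welch),
            class = "combo_stats")
}

#' @export
print.combo_stats <- function(x, ...) {
  cat("genotype combination statistics for", x$trait, "(by", x$by, ")\n")
  print(x$stats, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat(if (x$welch) "Welch" else "pooled-variance Student's",
        "t-tests:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
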