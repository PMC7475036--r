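test_that("cross_tabulate reproduces a diagnostic genotype table", {
  # clean-leg panel: every bird wild-type at both loci
  records <- data.frame(
    pheno_class = rep(c("feathered", "clean"), c(20, 379)),
    locus1 = c(rep("hom_mut", 15), rep("het", 5), rep("hom_wt", 379)),
    locus2 = c(rep("hom_mut", 8), rep("het", 4), rep("hom_wt", 8),
               rep("hom_wt", 379)),
    stringsAsFactors = FALSE)
  t1 <- cross_tabulate(records, "locus1")
  expect_equal(unname(t1["clean", ]), c(0L, 0L, 379L, 0L))
  expect_equal(unname(t1["feathered", ]), c(15L, 5L, 0L, 0L))
  t2 <- cross_tabulate(records, "locus2")
  expect_equal(unname(t2["clean", ]), c(0L, 0L, 379L, 0L))
  expect_equal(sum(t2), nrow(records))
})

test_that("cross_tabulate handles empty input and missing genotypes", {
  empty <- data.frame(pheno_class = character(0), locus1 = character(0))
  t0 <- cross_tabulate(empty, "locus1")
  expect_equal(sum(t0), 0L)
  expect_equal(ncol(t0), 4L)

  rec <- data.frame(pheno_class = c("a", "a", "b"),
                    locus1 = c("het", NA, "missing"))
  tt <- cross_tabulate(rec, "locus1")
  expect_equal(unname(tt[, "missing"]), c(1L, 1L))
})

test_that("cross-tab marginals reconcile with input counts", {
  set.seed(91)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    rec <- data.frame(
      pheno_class = sample(c("feathered", "intermediate", "clean"), n, TRUE),
      locus1 = sample(c("hom_mut", "het", "hom_wt", "missing"), n, TRUE),
      stringsAsFactors = FALSE)
    tt <- cross_tabulate(rec, "locus1")
    expect_equal(sum(tt), n)
    expect_equal(unname(rowSums(tt)),
                 unname(as.integer(table(factor(rec$pheno_class,
                                                levels = rownames(tt))))))
  }
})

test_that("segregation_test matches the textbook chi-square", {
  perfect <- segregation_test(c(150, 10), c(15, 1))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)

  bc <- segregation_test(c(82, 96), c(1, 1))
  expect_equal(round(bc$chi2, 3), 1.101)
  expect_equal(bc$df, 1)
  expect_equal(bc$p, stats::pchisq(bc$chi2, 1, lower.tail = FALSE))

  expect_error(segregation_test(c(10, 10), c(1, 0)), "positive")
  expect_error(segregation_test(c(10), c(1)), "classes")
})

test_that("chi-square against a stated ratio equals direct arithmetic", {
  set.seed(101)
  for (k in 1:20) {
    ncl <- sample(2:5, 1)
    obs <- sample(5:100, ncl, replace = TRUE)
    ratio <- sample(1:5, ncl, replace = TRUE)
    got <- segregation_test(obs, ratio)
    exp_counts <- sum(obs) * ratio / sum(ratio)
    chi2 <- sum((obs - exp_counts)^2 / exp_counts)
    expect_equal(got$chi2, chi2)
    expect_equal(got$df, ncl - 1)
    expect_true(got$p >= 0 && got$p <= 1)
  }
})

test_that("expected F2 clean fraction is (1/4)^n", {
  expect_equal(expected_f2_clean_fraction(2), 1 / 16)
  expect_equal(expected_f2_clean_fraction(1), 1 / 4)
  expect_equal(expected_f2_clean_fraction(3), 1 / 64)
  expect_error(expected_f2_clean_fraction(0), ">= 1")
})

test_that("adjusted digit length is digit4/shank", {
  expect_equal(adjusted_digit_length(60, 100), 0.6)
  expect_error(adjusted_digit_length(-1, 100), "positive")
})

f2_records <- function(n, seed, digit_effect_locus1 = -3, sigma = 0.5) {
  mp <- rbind(marker_map("chr13", 3, 5e6), marker_map("chr15", 3, 5e6))
  cd <- cross_design("F2", n, mp,
                     causal = data.frame(chrom = c("chr15", "chr13"),
                                         pos = c(mp$pos[5], mp$pos[2]),
                                         a = c(1.5, 1.0), d = c(0.75, 0.5)),
                     sigma = sigma)
  cs <- simulate_cross(cd, seed = seed)
  lev <- c("hom_wt", "het", "hom_mut")
  g1 <- cs$causal_dosage[, 1]  # locus1 = chr15 (TBX5-like)
  g2 <- cs$causal_dosage[, 2]  # locus2 = chr13 (PITX1-like)
  shank <- rnorm(n, 100, 2)
  digit4 <- 60 + digit_effect_locus1 * g1 + rnorm(n, 0, 1.5)
  data.frame(adult_score = cs$liability,
             hatch_score = cs$liability,
             locus1 = lev[g1 + 1], locus2 = lev[g2 + 1],
             digit4 = digit4, shank = shank,
             g1 = g1, g2 = g2, stringsAsFactors = FALSE)
}

test_that("combination means rise with mutant dosage at each locus", {
  rec <- f2_records(900, seed = 5, sigma = 0.2)
  st <- genotype_combo_stats(rec, trait = "adult_score", by = "both")$stats
  key <- do.call(rbind, strsplit(st$group, "/"))
  lev <- c("hom_wt", "het", "hom_mut")
  for (l2 in lev) {
    m <- st$mean[key[, 2] == l2][order(match(key[key[, 2] == l2, 1], lev))]
    expect_true(all(diff(m) > 0), info = paste("locus1 dosage at", l2))
  }
  for (l1 in lev) {
    m <- st$mean[key[, 1] == l1][order(match(key[key[, 1] == l1, 2], lev))]
    expect_true(all(diff(m) > 0), info = paste("locus2 dosage at", l1))
  }
})

test_that("two identical groups give t = 0, p = 1", {
  rec <- data.frame(hatch_score = rep(c(1, 2, 3), 2),
                    locus1 = rep(c("hom_wt", "hom_mut"), each = 3),
                    locus2 = "hom_wt")
  out <- genotype_combo_stats(rec, trait = "hatch_score", by = "locus1",
                              pairs = list(c("hom_wt", "hom_mut")))
  expect_equal(out$tests$t, 0)
  expect_equal(out$tests$p, 1)
})

test_that("a group with n < 2 fails only its own pair", {
  rec <- data.frame(hatch_score = c(1, 2, 3, 4, 9),
                    locus1 = c("hom_wt", "hom_wt", "het", "het", "hom_mut"),
                    locus2 = "hom_wt")
  out <- genotype_combo_stats(rec, trait = "hatch_score", by = "locus1")
  bad <- out$tests$group_a == "hom_mut" | out$tests$group_b == "hom_mut"
  expect_true(all(is.na(out$tests$p[bad])))
  expect_true(all(!is.na(out$tests$p[!bad])))
})

test_that("a TBX5-only digit effect leaves the PITX1 contrast null", {
  # locus2 has no digit effect: its hom_wt vs hom_mut contrast on
  # adjusted digit length should be non-significant in >= 90/100 seeds
  nonsig <- 0L
  sig1 <- 0L
  for (s in 1:100) {
    rec <- f2_records(200, seed = 4000 + s)
    t2 <- genotype_combo_stats(rec, trait = "adjusted_digit", by = "locus2",
                               pairs = list(c("hom_wt", "hom_mut")))$tests
    nonsig <- nonsig + (t2$p > 0.05)
    t1 <- genotype_combo_stats(rec, trait = "adjusted_digit", by = "locus1",
                               pairs = list(c("hom_wt", "hom_mut")))$tests
    sig1 <- sig1 + (t1$p < 0.05)
  }
  expect_gte(nonsig, 90L)
  expect_gte(sig1, 95L)  # the true locus1 effect is detected
})

test_that("Welch flag and Bonferroni correction are honoured", {
  rec <- f2_records(120, seed = 9)
  student <- genotype_combo_stats(rec, trait = "adult_score", by = "locus1")
  welch <- genotype_combo_stats(rec, trait = "adult_score", by = "locus1",
                                welch = TRUE)
  expect_false(isTRUE(all.equal(student$tests$df, welch$tests$df)))
  bonf <- genotype_combo_stats(rec, trait = "adult_score", by = "locus1",
                               bonferroni = TRUE)
  expect_true(all(bonf$tests$p >= student$tests$p - 1e-15))
})
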