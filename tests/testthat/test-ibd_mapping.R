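make_vs <- function(geno, pos = seq_len(nrow(geno)), chrom = "chr1") {
  samples <- colnames(geno)
  variant_set(data.frame(chrom = chrom, pos = pos,
                         id = paste0("v", seq_along(pos)), ref = "A",
                         alt = "G", svtype = "SNV", end = pos,
                         stringsAsFactors = FALSE),
              geno)
}

test_that("a discordant core splits the consensus run", {
  # 3 cores identical hom at sites 1-5 except core3 opposite hom at site 4
  geno <- matrix(2L, nrow = 5, ncol = 3,
                 dimnames = list(NULL, c("c1", "c2", "c3")))
  geno[4, "c3"] <- 0L
  vs <- make_vs(geno)
  panel <- sample_panel(c("c1", "c2", "c3"), rep("case", 3))
  ib <- find_ibd_regions(vs, panel, min_sites = 1)
  expect_equal(ib$start, c(1, 5))
  expect_equal(ib$end, c(3, 5))
  expect_equal(ib$n_defining_sites, c(3L, 1L))
})

test_that("identical homozygous samples yield one region spanning everything", {
  geno <- matrix(rep(c(0L, 2L), each = 4), nrow = 8, ncol = 5)
  colnames(geno) <- paste0("s", 1:5)
  vs <- make_vs(geno, pos = c(3, 9, 20, 21, 40, 44, 60, 90))
  panel <- sample_panel(paste0("s", 1:5),
                        rep(c("case", "control"), c(3, 2)))
  ib <- find_ibd_regions(vs, panel)
  expect_equal(nrow(ib), 1)
  expect_equal(c(ib$start, ib$end), c(3, 90))
  expect_equal(ib$n_defining_sites, 8L)
})

test_that("carrier incompatibility breaks a region; het carriers are fine", {
  geno <- cbind(c1 = rep(2L, 4), c2 = rep(2L, 4), k1 = c(1L, 1L, 0L, 2L))
  vs <- make_vs(geno)
  panel <- sample_panel(c("c1", "c2", "k1"), rep("case", 3),
                        c("core", "core", "carrier"))
  ib <- find_ibd_regions(vs, panel)
  # site 3: carrier has no alt copy -> break
  expect_equal(ib$start, c(1, 4))
  expect_equal(ib$end, c(2, 4))
})

test_that("max_mismatch skips break sites up to the budget", {
  geno <- matrix(2L, nrow = 5, ncol = 2, dimnames = list(NULL, c("a", "b")))
  geno[3, "b"] <- 1L  # het core -> break
  vs <- make_vs(geno)
  panel <- sample_panel(c("a", "b"), c("case", "case"))
  strict <- find_ibd_regions(vs, panel, max_mismatch = 0)
  expect_equal(nrow(strict), 2)
  lax <- find_ibd_regions(vs, panel, max_mismatch = 1)
  expect_equal(nrow(lax), 1)
  expect_equal(c(lax$start, lax$end), c(1, 5))
  expect_equal(lax$n_defining_sites, 4L)
})

test_that("find_ibd_regions equals exhaustive search on small random panels", {
  set.seed(31)
  for (k in 1:30) {
    ns <- sample(2:8, 1)
    nv <- sample(3:20, 1)
    n_core <- sample(1:ns, 1)
    geno <- matrix(sample(c(0L, 1L, 2L, NA), ns * nv, replace = TRUE,
                          prob = c(0.4, 0.25, 0.3, 0.05)),
                   nrow = nv, dimnames = list(NULL, paste0("s", 1:ns)))
    pos <- sort(sample.int(500, nv))
    vs <- make_vs(geno, pos = pos)
    cc <- rep("carrier", ns)
    cc[seq_len(n_core)] <- "core"
    panel <- sample_panel(paste0("s", 1:ns), rep("case", ns), cc)
    min_sites <- sample(1:3, 1)
    got <- find_ibd_regions(vs, panel, min_sites = min_sites)
    want <- oracle_ibd(geno, seq_len(n_core),
                       setdiff(seq_len(ns), seq_len(n_core)), pos,
                       min_sites = min_sites)
    expect_equal(nrow(got), nrow(want), info = paste("case", k))
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = paste("case", k))
      expect_equal(got$end, want$end, info = paste("case", k))
      expect_equal(got$n_defining_sites, as.integer(want$n),
                   info = paste("case", k))
    }
  }
})

test_that("exclusion filtering keeps exactly the planted causal variants", {
  reg <- genomic_interval("chr13", 15.815e6, 16.815e6)
  pd <- panel_design(reg, n_case_core = 6, n_case_carrier = 2,
                     n_controls = 159, G = 150,
                     causal = list(list(svtype = "SNV", pos = 16.09e6),
                                   list(svtype = "DEL", pos = 16.0925e6,
                                        length = 17668)),
                     background_per_kb = 0.05)
  ps <- simulate_panel(pd, seed = 17)
  expect_gte(nrow(ps$vs$variants), 30)
  ib <- find_ibd_regions(ps$vs, ps$panel, region = reg)
  hit <- ib[ib$start <= 16.09e6 & ib$end >= 16.0925e6, , drop = FALSE]
  expect_equal(nrow(hit), 1)
  cand <- filter_candidates(ps$vs, ps$panel, hit[1, ])
  expect_equal(sort(cand$id), c("causal_1", "causal_2"))
  expect_setequal(cand$svtype, c("SNV", "DEL"))
  expect_true(all(cand$control_alt_count == 0))
})

test_that("one alt allele in a control excludes a variant", {
  geno <- cbind(core1 = c(2L, 2L), core2 = c(2L, 2L),
                ctrl1 = c(0L, 0L), ctrl2 = c(0L, 1L))
  vs <- make_vs(geno)
  panel <- sample_panel(colnames(geno),
                        rep(c("case", "control"), each = 2))
  ibd <- data.frame(chrom = "chr1", start = 1, end = 2)
  cand <- filter_candidates(vs, panel, ibd)
  expect_equal(cand$id, "v1")
})

test_that("the max-missing policy governs poorly genotyped control sites", {
  ng <- 20
  geno <- cbind(core = rep(2L, 2),
                matrix(0L, 2, ng, dimnames = list(NULL, paste0("ct", 1:ng))))
  geno[2, 1 + seq_len(4)] <- NA  # 4/20 controls missing at site 2
  vs <- make_vs(geno)
  panel <- sample_panel(colnames(geno), rep(c("case", "control"), c(1, ng)))
  ibd <- data.frame(chrom = "chr1", start = 1, end = 2)
  expect_equal(filter_candidates(vs, panel, ibd, max_missing = 0.1)$id, "v1")
  expect_equal(filter_candidates(vs, panel, ibd, max_missing = 0.25)$id,
               c("v1", "v2"))
})

test_that("adding a control can only shrink the candidate list", {
  set.seed(41)
  for (k in 1:20) {
    vsall <- random_variant_set(15, paste0("s", 1:8), seed = 500 + k)
    vsall$geno[, 1:2] <- 2L  # two cores hom_alt everywhere
    panel6 <- sample_panel(paste0("s", 1:7),
                           rep(c("case", "control"), c(2, 5)))
    panel7 <- sample_panel(paste0("s", 1:8),
                           rep(c("case", "control"), c(2, 6)))
    ibd <- data.frame(chrom = "chr1", start = min(vsall$variants$pos),
                      end = max(vsall$variants$pos))
    c6 <- filter_candidates(vsall, panel6, ibd, max_missing = 0.5)
    c7 <- filter_candidates(vsall, panel7, ibd, max_missing = 0.5)
    expect_true(all(c7$id %in% c6$id))
  }
})

test_that("returned candidates satisfy their own invariants (self-audit)", {
  reg <- genomic_interval("chr15", 12.06e6, 13.06e6)
  pd <- panel_design(reg, n_case_core = 5, n_case_carrier = 1,
                     n_controls = 30, G = 150, background_per_kb = 0.2)
  ps <- simulate_panel(pd, seed = 23)
  ib <- find_ibd_regions(ps$vs, ps$panel, region = reg)
  hit <- ib[which.max(ib$n_defining_sites), ]
  cand <- filter_candidates(ps$vs, ps$panel, hit)
  panel <- ps$panel
  for (i in seq_len(nrow(cand))) {
    j <- match(cand$id[i], ps$vs$variants$id)
    g <- ps$vs$geno[j, ]
    cores <- panel$sample_id[panel$carrier_class %in% "core"]
    carriers <- panel$sample_id[panel$carrier_class %in% "carrier"]
    controls <- panel$sample_id[panel$phenotype == "control"]
    expect_true(all(g[cores] == 2L, na.rm = TRUE))
    expect_true(all(g[carriers] >= 1L, na.rm = TRUE))
    expect_equal(sum(g[controls], na.rm = TRUE), 0L)
    expect_true(cand$pos[i] <= hit$end && cand$end[i] >= hit$start)
  }
})

test_that("IBD recovery on simulated panels is accurate to marker spacing", {
  errs <- c()
  hits <- 0L
  spacing <- 1000 / 0.6  # mean background marker spacing (bp)
  for (s in 1:25) {
    reg <- genomic_interval("chr15", 12.06e6, 12.46e6)
    pd <- panel_design(reg, n_case_core = 8, n_controls = 40, G = 200,
                       causal = list(list(svtype = "SNV", pos = 12.26e6)),
                       background_per_kb = 0.6)
    ps <- simulate_panel(pd, seed = 3000 + s)
    ib <- find_ibd_regions(ps$vs, ps$panel, region = reg)
    hit <- ib[ib$start <= 12.26e6 & ib$end >= 12.26e6, , drop = FALSE]
    if (nrow(hit) == 1 && interval_overlap(
          genomic_interval(hit$chrom, hit$start, hit$end),
          ps$true_ibd) > 0) {
      hits <- hits + 1L
      errs <- c(errs, abs(hit$start - ps$true_ibd$start),
                abs(hit$end - ps$true_ibd$end))
    }
  }
  expect_equal(hits, 25L)
  expect_lt(mean(errs), 2 * spacing)
})

test_that("zygosity_profile counts genotypes by phenotype class", {
  geno <- cbind(a = 2L, b = 2L, c = 2L, d = 2L, e = 2L,
                f = 0L, g = 0L, h = 0L)
  vs <- make_vs(geno)
  panel <- sample_panel(colnames(geno), rep(c("case", "control"), c(5, 3)))
  zp <- zygosity_profile(vs, "v1", panel)
  expect_equal(unname(zp["case", ]), c(0L, 0L, 5L, 0L))
  expect_equal(unname(zp["control", ]), c(3L, 0L, 0L, 0L))

  empty <- sample_panel(character(0), character(0))
  expect_equal(sum(zygosity_profile(vs, "v1", empty)), 0L)

  set.seed(51)
  for (k in 1:100) {
    n <- sample(2:10, 1)
    vsr <- random_variant_set(3, paste0("s", 1:n), seed = 700 + k)
    ph <- sample(c("case", "control"), n, replace = TRUE)
    pan <- sample_panel(paste0("s", 1:n), ph)
    zp <- zygosity_profile(vsr, "v2", pan)
    expect_equal(unname(rowSums(zp)),
                 c(sum(ph == "case"), sum(ph == "control")))
  }
})
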