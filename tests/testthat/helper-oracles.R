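# Independent oracles used by the tests. These deliberately recompute
# quantities by brute force (per-base sets, exhaustive enumeration,
# direct likelihood arithmetic) so the implementation is checked against
# a second, slower route.

# log10 likelihood ratio of linkage from the binomial likelihood,
# evaluated directly: L(theta) = theta^r (1-theta)^(n-r), theta_hat =
# min(r/n, 1/2), ratio against theta = 1/2 (0^0 = 1).
oracle_lod <- function(n, r) {
  theta <- min(r / n, 0.5)
  loglik <- function(th) {
    (if (r == 0) 0 else r * log10(th)) +
      (if (r == n) 0 else (n - r) * log10(1 - th))
  }
  loglik(theta) - loglik(0.5)
}

# per-base set intersection of two 1-based inclusive intervals
oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
}

# exhaustive global alignment score by recursion over the three moves
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# brute-force IBD: classify every site by direct per-sample inspection,
# then enumerate all contiguous runs of defining sites and keep the
# maximal ones with >= min_sites sites (max_mismatch = 0 semantics).
oracle_ibd <- function(geno, core_idx, carrier_idx, pos, min_sites = 1) {
  nv <- nrow(geno)
  defining <- logical(nv)
  for (i in seq_len(nv)) {
    cons <- NULL
    ok <- TRUE
    for (s in core_idx) {
      g <- geno[i, s]
      if (is.na(g)) next
      if (g == 1L) { ok <- FALSE; break }
      al <- if (g == 2L) 1L else 0L
      if (is.null(cons)) cons <- al
      else if (cons != al) { ok <- FALSE; break }
    }
    if (!ok || is.null(cons)) next
    for (s in carrier_idx) {
      g <- geno[i, s]
      if (is.na(g)) next
      has <- if (cons == 1L) g >= 1L else g <= 1L
      if (!has) { ok <- FALSE; break }
    }
    defining[i] <- ok
  }
  runs <- list()
  i <- 1
  while (i <= nv) {
    if (defining[i]) {
      j <- i
      while (j < nv && defining[j + 1]) j <- j + 1
      if (sum(defining[i:j]) >= min_sites)
        runs[[length(runs) + 1]] <- c(start = pos[i], end = pos[j],
                                      n = sum(defining[i:j]))
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) {
    return(data.frame(start = numeric(0), end = numeric(0), n = integer(0)))
  }
  as.data.frame(do.call(rbind, runs))
}

# random variant_set for round-trip and counting tests
random_variant_set <- function(n_var, samples, seed, chrom = "chr1",
                               p_del = 0.1, p_missing = 0.05) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n_var))
  isdel <- stats::runif(n_var) < p_del
  bases <- c("A", "C", "G", "T")
  ref <- ifelse(isdel, "N", sample(bases, n_var, replace = TRUE))
  alt <- ifelse(isdel, "<DEL>",
                vapply(ref, function(b)
                  sample(setdiff(bases, b), 1), ""))
  end <- ifelse(isdel, pos + sample(100:5000, n_var, replace = TRUE), pos)
  geno <- matrix(sample(c(0L, 1L, 2L), n_var * length(samples),
                        replace = TRUE),
                 nrow = n_var, dimnames = list(NULL, samples))
  geno[stats::runif(length(geno)) < p_missing] <- NA_integer_
  variant_set(data.frame(chrom = chrom, pos = pos,
                         id = paste0("v", seq_len(n_var)), ref = ref,
                         alt = alt, svtype = ifelse(isdel, "DEL", "SNV"),
                         end = end, stringsAsFactors = FALSE),
              geno)
}

# small backcross design used across tests: one causal locus with
# incomplete dominance; class cut-points chosen so carriers are mostly
# feathered, non-carriers mostly clean, both with some intermediates
bc_design <- function(n = 222, n_markers = 50, len_bp = 13e6,
                      causal_marker = NULL) {
  mp <- marker_map("chr15", n_markers, len_bp)
  if (is.null(causal_marker)) causal_marker <- round(n_markers * 0.9)
  cross_design("backcross", n, mp,
               causal = data.frame(chrom = "chr15",
                                   pos = mp$pos[causal_marker],
                                   a = 0.5, d = 0.5),
               sigma = 0.25, cuts = c(0.161, 0.724),
               class_labels = c("clean", "intermediate", "feathered"))
}
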