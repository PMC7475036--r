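Package: ptilomap
Title: Fine-Mapping of Mendelian Feathered-Leg Loci from Pooled Scans,
    Linkage and Identity-by-Descent Haplotype Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping Mendelian loci in domestic birds using the
    combined evidence chain of pooled-DNA genome scans, experimental-cross
    linkage and identity-by-descent (IBD) haplotype sharing. Implements
    pooled SNP-array relative allele frequency (RAF) scans with pairwise
    absRAFdif peak calling, pooled-sequencing per-site FST with sliding
    window Z-normalisation (ZFST), two-point LOD linkage for a dominant
    locus in a backcross with recombinant-driven interval narrowing,
    consensus-based IBD region detection across case/control whole-genome
    panels with candidate causal variant exclusion filtering, conserved
    element annotation and ranking of candidates, and two-locus
    genotype-phenotype statistics (segregation ratio tests, genotype
    cross-tabulations, ordinal score and adjusted digit length contrasts).
    Includes seed-deterministic simulators for backcross and F2 pedigrees,
    pooled array intensities, pool-seq read counts, and case/control
    sequence panels carrying a planted IBD causal haplotype, so the whole
    pipeline can be exercised end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
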