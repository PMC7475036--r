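# Genotypes are stored as integer alt-allele dosage: 0 = hom_ref,
# 1 = het, 2 = hom_alt, NA = missing. gt_label()/gt_code() convert to and
# from the four named codes.

.gt_labels <- c("hom_ref", "het", "hom_alt")

#' Convert genotype dosage codes to labels and back
#'
#' @param x integer dosages in {0,1,2,NA} (`gt_label`) or character labels
#'   in {"hom_ref","het","hom_alt","missing"} (`gt_code`).
#' @return Character labels, or integer dosages with NA for "missing".
#' @export
gt_label <- function(x) {
  out <- .gt_labels[x + 1L]
  out[is.na(x)] <- "missing"
  names(out) <- names(x)
  out
}

#' @rdname gt_label
#' @export
gt_code <- function(x) {
  out <- match(x, .gt_labels) - 1L
  bad <- is.na(out) & x != "missing"
  if (any(bad)) stop("unknown genotype label: ", x[bad][1])
  out
}

#' Construct a multi-sample variant set
#'
#' The container used by the IBD mapping and filtering stages: a table of
#' variant records (SNVs, short indels, and symbolic deletions with an END
#' coordinate) together with a variants x samples genotype dosage matrix.
#' Records are kept sorted by (chrom, pos, id).
#'
#' @param variants data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `svtype` (one of "SNV", "INDEL", "DEL") and `end` (= `pos`
#'   except for DEL records, whose `end` is the right edge of the deleted
#'   segment, 1-based inclusive).
#' @param geno integer matrix (variants x samples) of alt dosages
#'   {0, 1, 2, NA}; column names are the sample ids.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, geno) {
  need <- c("chrom", "pos", "id", "ref", "alt", "svtype", "end")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants table lacks columns: ", paste(miss, collapse = ", "))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants))
    stop("genotype matrix rows must match variant count")
  if (is.null(colnames(geno))) stop("genotype matrix must have sample ids as colnames")
  if (any(variants$pos < 1)) stop("pos must be >= 1")
  if (any(variants$end < variants$pos)) stop("end must be >= pos")
  isdel <- variants$svtype == "DEL"
  if (any(isdel & variants$end <= variants$pos))
    stop("DEL records require end > pos")
  if (!all(variants$svtype %in% c("SNV", "INDEL", "DEL")))
    stop("svtype must be SNV, INDEL or DEL")
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA")
  ord <- order(variants$chrom, variants$pos, variants$id)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno,
                 samples = colnames(geno)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "records x", length(x$samples),
      "samples\n")
  tab <- table(x$variants$svtype)
  cat("  svtypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.parse_info_field <- function(info, key) {
  m <- regexpr(paste0("(^|;)", key, "=[^;]+"), info)
  out <- rep(NA_character_, length(info))
  out[m > 0] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
  out
}

#' Read a minimal GT-only VCF
#'
#' Supports the VCF v4.2 subset used throughout the package: biallelic
#' records, `FORMAT` containing `GT`, symbolic deletions as `ALT=<DEL>`
#' with `INFO` keys `SVTYPE=DEL` and `END`. Phased separators ("|") are
#' treated as unphased; `./.` (or a missing GT) is a missing genotype.
#' Multi-allelic records and GT fields other than 0/0, 0/1, 1/0, 1/1 and
#' ./. are rejected with an error naming the offending record.
#'
#' @param path path to a VCF (plain text or bgzip/gzip).
#' @return A [variant_set()] with records sorted by (chrom, pos, id).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)
    samples <- samples[samples != "FORMAT"]
    if (is.null(samples)) samples <- character(0)
    geno <- matrix(integer(0), nrow = 0, ncol = length(samples),
                   dimnames = list(NULL, samples))
    empty <- data.frame(chrom = character(0), pos = numeric(0),
                        id = character(0), ref = character(0),
                        alt = character(0), svtype = character(0),
                        end = numeric(0), stringsAsFactors = FALSE)
    return(variant_set(empty, geno))
  }
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stop("multi-allelic records are not supported (line with ALT=",
         alt[grepl(",", alt)][1], ")")
  info <- fix[, "INFO"]
  info[is.na(info)] <- "."
  svtype_info <- .parse_info_field(info, "SVTYPE")
  end_info <- suppressWarnings(as.numeric(.parse_info_field(info, "END")))
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  svtype <- ifelse(alt == "<DEL>" | (!is.na(svtype_info) & svtype_info == "DEL"),
                   "DEL",
                   ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "INDEL"))
  end <- ifelse(svtype == "DEL", end_info, pos)
  if (any(svtype == "DEL" & is.na(end_info)))
    stop("DEL record without INFO END at ",
         fix[svtype == "DEL" & is.na(end_info), "CHROM"][1], ":",
         pos[svtype == "DEL" & is.na(end_info)][1])
  if (any(!is.na(end) & end < pos))
    stop("INFO END < POS at ", fix[which(end < pos)[1], "CHROM"], ":",
         pos[which(end < pos)[1]])
  gtmat <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gtmat)) stop("VCF has no GT FORMAT field")
  gt <- gsub("|", "/", gtmat, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  dosage[gt == "0/0"] <- 0L
  dosage[gt == "0/1" | gt == "1/0"] <- 1L
  dosage[gt == "1/1"] <- 2L
  bad <- !is.na(gt) & gt != "./." & is.na(dosage)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt[bad][1], "' at record ", fix[i[1], "CHROM"],
         ":", pos[i[1]], " sample ", colnames(gt)[i[2]])
  }
  rownames(dosage) <- NULL
  id <- fix[, "ID"]
  id[is.na(id)] <- "."
  variants <- data.frame(chrom = fix[, "CHROM"], pos = pos, id = id,
                         ref = ref, alt = alt, svtype = svtype, end = end,
                         stringsAsFactors = FALSE)
  variant_set(variants, dosage)
}

#' Write a variant set as a minimal GT-only VCF
#'
#' Inverse of [read_vcf()] on the supported subset; a write/read round
#' trip reproduces the records and genotypes exactly.
#'
#' @param vs a [variant_set()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end (1-based inclusive)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  va <- vs$variants
  info <- ifelse(va$svtype == "DEL",
                 paste0("SVTYPE=DEL;END=",
                        format(va$end, scientific = FALSE, trim = TRUE)),
                 ".")
  gtchr <- c("0/0", "0/1", "1/1")[vs$geno + 1L]
  gtchr[is.na(gtchr)] <- "./."
  gtm <- matrix(gtchr, nrow = nrow(va))
  body <- paste(va$chrom, format(va$pos, scientific = FALSE, trim = TRUE),
                va$id, va$ref, va$alt, ".", ".", info, "GT",
                sep = "\t")
  if (ncol(gtm) > 0)
    body <- paste(body, apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a case/control sample panel
#'
#' Describes the samples of a sequence panel for IBD mapping: each sample
#' is a case (shows the trait) or a control, and each case is assigned a
#' carrier class saying what the IBD scan may assume about it: `"core"`
#' (expected homozygous carrier of the shared haplotype), `"carrier"`
#' (at least one copy, e.g. a heterozygous breed sample), or
#' `"non_carrier"` (a case explained by the other locus, excluded from
#' the consensus).
#'
#' @param sample_ids unique character ids, matching the variant set's
#'   sample columns.
#' @param phenotype per-sample, "case" or "control".
#' @param carrier_class per-case class (controls must be `NA`); default
#'   makes every case "core" (the all-case scan mode).
#' @return Data frame of class `sample_panel`.
#' @export
sample_panel <- function(sample_ids,
                         phenotype,
                         carrier_class = ifelse(phenotype == "case", "core", NA)) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (!all(phenotype %in% c("case", "control")))
    stop("phenotype must be 'case' or 'control'")
  cc <- as.character(carrier_class)
  iscase <- phenotype == "case"
  if (any(iscase & (is.na(cc) | !cc %in% c("core", "carrier", "non_carrier"))))
    stop("every case needs carrier_class in {core, carrier, non_carrier}")
  if (any(!iscase & !is.na(cc)))
    stop("controls must not have a carrier_class")
  out <- data.frame(sample_id = sample_ids, phenotype = phenotype,
                    carrier_class = cc, stringsAsFactors = FALSE)
  class(out) <- c("sample_panel", "data.frame")
  out
}

#' Read/write a sample panel as TSV
#'
#' Columns `sample_id`, `phenotype`, `carrier_class` (empty for controls).
#'
#' @param path TSV path.
#' @return [sample_panel()] for `read_panel`; `path` invisibly for
#'   `write_panel`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sample_panel(tab$sample_id, tab$phenotype, tab$carrier_class)
}

#' @rdname read_panel
#' @param panel a [sample_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
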