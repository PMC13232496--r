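# Genotype container and VCF v4.2 import/export.
#
# Dosages are diploid alternate-allele counts {0, 1, 2}, NA = missing,
# individuals in rows and SNPs in columns. Coordinates are 1-based
# inclusive, matching VCF. Reading goes through vcfR; multiallelic records
# are excluded on import (only biallelic SNPs are retained). Writing emits
# plain-text VCF v4.2 with diploid GT fields, one contig line per
# chromosome.

#' Construct a genotype matrix
#'
#' @param dosages individuals x SNPs matrix with values in `{0, 1, 2, NA}`.
#' @param chrom per-SNP chromosome labels.
#' @param pos per-SNP 1-based positions, strictly increasing within each
#'   chromosome.
#' @param ids individual labels (defaults to `rownames(dosages)`).
#' @param snp_ids per-SNP identifiers.
#' @param ref,alt per-SNP reference/alternate alleles.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, ids = rownames(dosages),
                            snp_ids = NULL, ref = NULL, alt = NULL) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% c(0, 1, 2) | is.na(dosages))) {
    stop("dosages must be in {0, 1, 2} or NA", call. = FALSE)
  }
  n_snps <- ncol(dosages)
  stopifnot(length(chrom) == n_snps, length(pos) == n_snps)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  if (is.null(ids)) ids <- sprintf("IND%04d", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) {
    snp_ids <- sprintf("%s_%d", chrom, pos)
  }
  if (is.null(ref)) ref <- rep("A", n_snps)
  if (is.null(alt)) alt <- rep("T", n_snps)
  rownames(dosages) <- ids
  colnames(dosages) <- snp_ids
  structure(
    list(dosages = dosages, chrom = as.character(chrom), pos = as.integer(pos),
         ids = as.character(ids), snp_ids = as.character(snp_ids),
         ref = as.character(ref), alt = as.character(alt)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file (plain or gzipped) with vcfR and converts GT
#' fields to diploid alternate-allele dosages. Only biallelic SNP records
#' are retained; multiallelic records are excluded with a logged count.
#' `./.` (or `.|.`) becomes missing.
#'
#' @param path path to the VCF file.
#' @return A [genotype_matrix].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_dropped <- sum(!biallelic)
  if (n_dropped > 0) {
    message("excluded ", n_dropped, " multiallelic record(s); ",
            "only biallelic SNPs are retained")
  }
  if (!any(biallelic)) stop("no biallelic records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # GT like 0/1, 0|1, ./.; dosage = count of "1" alleles
  alleles <- gsub("\\|", "/", gt)
  dos <- matrix(NA_real_, nrow(alleles), ncol(alleles))
  dos[alleles == "0/0"] <- 0
  dos[alleles %in% c("0/1", "1/0")] <- 1
  dos[alleles == "1/1"] <- 2
  bad <- !is.na(alleles) & !(alleles %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(bad)) {
    stop("malformed GT fields at record(s): ",
         paste(utils::head(which(rowSums(bad) > 0), 5), collapse = ", "),
         call. = FALSE)
  }
  genotype_matrix(
    t(dos),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ids = colnames(gt),
    snp_ids = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                     sprintf("%s_%s", fix[, "CHROM"], fix[, "POS"]),
                     fix[, "ID"]),
    ref = fix[, "REF"], alt = fix[, "ALT"]
  )
}

#' Write a genotype matrix to a plain-text VCF v4.2
#'
#' Emits unphased diploid GT fields (`0/0`, `0/1`, `1/1`, `./.`) and one
#' `##contig` line per chromosome. Round-trips losslessly through
#' [read_vcf], including missing genotypes.
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(g$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$ids), collapse = "\t")
  )
  body <- vapply(seq_along(g$pos), function(j) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(g$chrom[j], g$pos[j], g$snp_ids[j], g$ref[j], g$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
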