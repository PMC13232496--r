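# Single-marker association scan, significance filtering with
# Benjamini-Hochberg validation, and LD-informed QTL window construction.

#' Single-marker association scan
#'
#' Per-SNP linear model `y ~ covariates + dosage` with a two-sided t-test
#' on the dosage coefficient. This is deliberately plain plumbing for
#' testing and simulation work, not a multi-locus GWAS model. Missing
#' dosages are mean-imputed per SNP; a zero-variance SNP gets `p = 1`
#' (reported in a warning count).
#'
#' @param g a [genotype_matrix].
#' @param y per-individual trait values: a named numeric vector or a data
#'   frame with columns `genotype` and a value column.
#' @param covariates optional per-individual covariate matrix (e.g. PC
#'   scores from [pc_covariates]), rows aligned or named by individual.
#' @return Data frame with `snp_id`, `chrom`, `pos`, `effect`, `se`,
#'   `p_value`, `maf`, `pve` (partial R-squared of the SNP term).
#' @export
scan_association <- function(g, y, covariates = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.data.frame(y)) {
    val_col <- setdiff(names(y), "genotype")[1]
    y <- setNames(y[[val_col]], y$genotype)
  }
  if (is.null(names(y))) {
    if (length(y) != length(g$ids)) {
      stop("unnamed `y` must match the number of individuals", call. = FALSE)
    }
    names(y) <- g$ids
  }
  if (!all(g$ids %in% names(y))) {
    stop("trait values and genotype matrix have misaligned ids",
         call. = FALSE)
  }
  yv <- y[g$ids]
  keep <- !is.na(yv)
  yv <- yv[keep]
  n <- length(yv)
  X0 <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) {
      if (!all(g$ids %in% rownames(covariates))) {
        stop("covariates and genotype matrix have misaligned ids",
             call. = FALSE)
      }
      covariates <- covariates[g$ids, , drop = FALSE]
    } else if (nrow(covariates) != length(g$ids)) {
      stop("covariates and genotype matrix have misaligned ids",
           call. = FALSE)
    }
    X0 <- cbind(X0, covariates[keep, , drop = FALSE])
  }
  D <- impute_dosages(g)[keep, , drop = FALSE]
  qr0 <- qr(X0)
  ry <- qr.resid(qr0, yv)
  RD <- qr.resid(qr0, D)
  df <- n - ncol(X0) - 1L
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  s_dd <- colSums(RD^2)
  s_dy <- colSums(RD * ry)
  s_yy <- sum(ry^2)
  mono <- s_dd <= 1e-12 * max(s_dd, 1)
  s_dd[mono] <- NA_real_
  beta <- s_dy / s_dd
  rss <- pmax(s_yy - s_dy^2 / s_dd, 0)
  se <- sqrt(rss / df / s_dd)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  pve <- (s_dy^2 / s_dd) / s_yy
  beta[mono] <- 0; se[mono] <- NA_real_; p[mono] <- 1; pve[mono] <- 0
  if (any(mono)) {
    warning(sum(mono), " zero-variance SNP(s) assigned p = 1")
  }
  st <- snp_stats(g)
  data.frame(snp_id = g$snp_ids, chrom = g$chrom, pos = g$pos,
             effect = unname(beta), se = unname(se), p_value = unname(p),
             maf = st$maf, pve = unname(pve), stringsAsFactors = FALSE)
}

#' Significant marker-trait associations with BH validation
#'
#' Keeps SNPs with `-log10(p) > threshold_log10p` and attaches
#' Benjamini-Hochberg adjusted q-values computed over all tested SNPs. An
#' empty result is a valid outcome.
#'
#' @param results scan results (data frame with at least `snp_id`,
#'   `chrom`, `pos`, `p_value`; `effect` and `maf` carried through).
#' @param threshold_log10p genome-wide significance threshold on
#'   `-log10(p)` (default 6).
#' @param trait,model optional labels stamped onto the retained MTAs.
#' @return Data frame of MTAs (possibly 0 rows) with a `q_value` column.
#' @export
significant_mtas <- function(results, threshold_log10p = 6,
                             trait = NA_character_, model = NA_character_) {
  if (nrow(results) == 0L) stop("empty scan results", call. = FALSE)
  q <- p.adjust(results$p_value, method = "BH")
  keep <- -log10(results$p_value) > threshold_log10p
  out <- results[keep, , drop = FALSE]
  out$q_value <- q[keep]
  if (!"trait" %in% names(out)) out$trait <- rep_len(trait, nrow(out))
  if (!"model" %in% names(out)) out$model <- rep_len(model, nrow(out))
  rownames(out) <- NULL
  out
}

#' Assemble a marker-trait association table
#'
#' Constructor used when MTAs come from an external source (e.g. a
#' published result table) rather than [significant_mtas].
#'
#' @param snp_id,chrom,pos,trait per-MTA fields (recycled where scalar).
#' @param p_value,effect,maf optional per-MTA statistics.
#' @param model model label.
#' @return Data frame with validated MTA columns.
#' @export
mta_table <- function(snp_id, chrom, pos, trait, p_value = NA_real_,
                      effect = NA_real_, maf = NA_real_,
                      model = NA_character_) {
  if (any(!is.na(p_value) & (p_value <= 0 | p_value > 1))) {
    stop("p_value must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5))) {
    stop("maf must lie in [0, 0.5]", call. = FALSE)
  }
  data.frame(snp_id = snp_id, chrom = as.character(chrom),
             pos = as.integer(pos), p_value = p_value, effect = effect,
             maf = maf, trait = trait, model = model,
             stringsAsFactors = FALSE)
}

# Map an MTA trait label to a QTL name prefix; patterns are matched in
# order against the lower-cased label (total plant damage wins over
# necrotic tissue when a merged window carries both, as in the qTPD/qNT
# convention).
.default_trait_prefix <- c("total plant damage" = "qTPD",
                           "necrotic tissue" = "qNT")

#' Build LD-informed QTL windows around significant MTAs
#'
#' For each half-width w, every MTA yields the interval
#' `[max(1, pos - w), pos + w]` (1-based inclusive). Overlapping windows
#' on the same chromosome are merged (order-invariant, idempotent), member
#' traits are unioned, and merged windows are named
#' `<prefix><chromosome>` with a `-k` ordinal when several windows of the
#' same prefix share a chromosome.
#'
#' @param mtas MTA data frame ([significant_mtas] or [mta_table]).
#' @param half_widths window half-widths in bp (default 2, 5 and 10 kb;
#'   the 10 kb track is the canonical reported window).
#' @param trait_prefix named character vector mapping (lower-case) trait
#'   label patterns to name prefixes, in priority order.
#' @return Data frame with `name`, `chrom`, `start`, `end`, `half_width`,
#'   `traits` (";"-separated), `n_mtas`, `lead_snps`.
#' @export
build_qtl_windows <- function(mtas, half_widths = c(2000, 5000, 10000),
                              trait_prefix = .default_trait_prefix) {
  if (nrow(mtas) == 0L) {
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      half_width = integer(0), traits = character(0),
                      n_mtas = integer(0), lead_snps = character(0)))
  }
  pick_prefix <- function(traits) {
    lt <- tolower(traits)
    for (pat in names(trait_prefix)) {
      if (any(grepl(pat, lt, fixed = TRUE))) return(trait_prefix[[pat]])
    }
    "qTL"
  }
  out <- list()
  for (w in half_widths) {
    gr <- GenomicRanges::GRanges(
      seqnames = mtas$chrom,
      ranges = IRanges::IRanges(start = pmax(1L, mtas$pos - as.integer(w)),
                                end = mtas$pos + as.integer(w)))
    red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
    rv <- S4Vectors::mcols(red)$revmap
    tab <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red),
      end = GenomicRanges::end(red),
      stringsAsFactors = FALSE)
    tab$half_width <- as.integer(w)
    tab$traits <- vapply(rv, function(i)
      paste(sort(unique(mtas$trait[i])), collapse = "; "), character(1))
    tab$n_mtas <- lengths(rv)
    tab$lead_snps <- vapply(rv, function(i)
      paste(mtas$snp_id[i], collapse = ";"), character(1))
    prefix <- vapply(rv, function(i) pick_prefix(mtas$trait[i]), character(1))
    chrom_num <- sub("^chr", "", tab$chrom, ignore.case = TRUE)
    base <- paste0(prefix, chrom_num)
    ord <- order(tab$chrom, tab$start)
    tab <- tab[ord, , drop = FALSE]
    base <- base[ord]
    name <- base
    for (b in unique(base)) {
      idx <- which(base == b)
      if (length(idx) > 1L) {
        name[idx] <- paste0(b, "-", seq_along(idx))
      }
    }
    tab$name <- name
    out[[as.character(w)]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("name", "chrom", "start", "end", "half_width", "traits",
          "n_mtas", "lead_snps")]
}

#' Intersect QTL windows with a gene-interval table
#'
#' Genes overlapping each window by at least 1 bp are listed (1-based
#' inclusive coordinates on both sides, so a gene starting exactly at the
#' window end is included).
#'
#' @param windows data frame from [build_qtl_windows] (`name`, `chrom`,
#'   `start`, `end`).
#' @param genes data frame with `chrom`, `start`, `end`, `id`.
#' @return Data frame with one row per window x overlapping gene
#'   (`window`, `gene`, `gene_start`, `gene_end`), plus per-window counts
#'   in `attr(, "n_genes")`.
#' @export
intersect_genes <- function(windows, genes) {
  gw <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start, windows$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gw, gg, minoverlap = 1L)
  out <- data.frame(
    window = windows$name[S4Vectors::queryHits(hits)],
    gene = genes$id[S4Vectors::subjectHits(hits)],
    gene_start = genes$start[S4Vectors::subjectHits(hits)],
    gene_end = genes$end[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  counts <- table(factor(out$window, levels = windows$name))
  attr(out, "n_genes") <- as.data.frame(counts, responseName = "n_genes",
                                        stringsAsFactors = FALSE)
  out
}
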