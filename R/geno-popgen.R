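# Genotype QC, VanRaden kinship, PC covariates, pairwise dosage LD and
# binned LD decay with the r2 = 0.2 crossing distance.

#' Per-SNP minor allele frequency and call rate
#'
#' MAF is computed on non-missing dosages; call rate is the fraction of
#' non-missing genotypes at the SNP.
#'
#' @param g a [genotype_matrix].
#' @return Data frame with `snp_id`, `chrom`, `pos`, `maf`, `call_rate`.
#' @export
snp_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  data.frame(
    snp_id = g$snp_ids, chrom = g$chrom, pos = g$pos,
    maf = pmin(p, 1 - p),
    call_rate = colMeans(!is.na(g$dosages)),
    stringsAsFactors = FALSE
  )
}

subset_snps <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  chrom = g$chrom[keep], pos = g$pos[keep], ids = g$ids,
                  snp_ids = g$snp_ids[keep], ref = g$ref[keep],
                  alt = g$alt[keep])
}

#' Filter SNPs on minor allele frequency and call rate
#'
#' Keeps SNPs with MAF >= `maf_min` (computed on non-missing dosages) and
#' call rate >= `call_rate_min`. Idempotent: filtering twice equals
#' filtering once.
#'
#' @param g a [genotype_matrix].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_rate_min minimum fraction of non-missing genotypes
#'   (default 0.40).
#' @return The filtered [genotype_matrix]; the removal counts per criterion
#'   are in `attr(, "filter_report")`.
#' @export
filter_snps <- function(g, maf_min = 0.01, call_rate_min = 0.40) {
  st <- snp_stats(g)
  fail_cr <- st$call_rate < call_rate_min
  fail_maf <- !fail_cr & (is.na(st$maf) | st$maf < maf_min)
  keep <- !fail_cr & !fail_maf
  if (!any(keep)) {
    stop("all SNPs removed by MAF/call-rate filtering", call. = FALSE)
  }
  out <- subset_snps(g, keep)
  attr(out, "filter_report") <- data.frame(
    n_input = ncol(g$dosages),
    n_fail_call_rate = sum(fail_cr),
    n_fail_maf = sum(fail_maf),
    n_kept = sum(keep)
  )
  out
}

# Mean-impute missing dosages per SNP (drops SNPs with no data).
impute_dosages <- function(g) {
  M <- g$dosages
  mu <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx) > 0) M[idx] <- mu[idx[, 2]]
  M
}

#' VanRaden genomic relationship matrix
#'
#' `G = W W' / (2 * sum_k p_k (1 - p_k))` with `W = dosage - 2p`, where
#' `p_k` is the alternate-allele frequency at SNP k. Missing dosages are
#' mean-imputed per SNP.
#'
#' @param g a [genotype_matrix] with >= 2 individuals and >= 1 polymorphic
#'   SNP.
#' @return A symmetric individuals x individuals kinship matrix.
#' @export
vanraden_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosages) < 2L) stop("need >= 2 individuals", call. = FALSE)
  M <- impute_dosages(g)
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs", call. = FALSE)
  W <- sweep(M[, poly, drop = FALSE], 2L, 2 * p[poly])
  G <- tcrossprod(W) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(G) <- list(g$ids, g$ids)
  (G + t(G)) / 2
}

#' Principal-component covariates from genotype dosages
#'
#' Eigen-decomposition of the covariance of centered (mean-imputed)
#' dosages; returns per-individual scores and the fraction of variance
#' captured by each component.
#'
#' @param g a [genotype_matrix] with more individuals than `n_pcs`.
#' @param n_pcs number of components to return (default 3, the standard
#'   structure-covariate choice).
#' @return A list with `scores` (individuals x `n_pcs`) and
#'   `var_explained` (fractions).
#' @export
pc_covariates <- function(g, n_pcs = 3L) {
  stopifnot(inherits(g, "genotype_matrix"))
  M <- impute_dosages(g)
  if (nrow(M) < n_pcs + 1L) stop("need >= n_pcs + 1 individuals",
                                 call. = FALSE)
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev^2 > 1e-12 * pc$sdev[1]^2)
  if (n_pcs > rank) {
    warning("requested ", n_pcs, " PCs but genotype rank is ", rank,
            "; truncating")
    n_pcs <- rank
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       var_explained = varfrac[seq_len(n_pcs)])
}

#' Pairwise dosage LD (r^2) within chromosomes
#'
#' `r^2` is the squared Pearson correlation of allele-dosage vectors
#' (composite LD), computed over pairwise-complete observations. Only
#' intra-chromosome pairs separated by at most `max_dist` bp are returned.
#'
#' @param g a (filtered) [genotype_matrix].
#' @param max_dist maximum pair distance in bp (default 100 kb).
#' @param maf_min SNPs below this MAF are excluded first (default 0.01).
#' @return Data frame with `chrom`, `dist`, `r2` (one row per SNP pair).
#' @export
pairwise_r2 <- function(g, max_dist = 1e5, maf_min = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  st <- snp_stats(g)
  keep <- !is.na(st$maf) & st$maf >= maf_min
  g <- subset_snps(g, keep)
  out <- list()
  for (ch in unique(g$chrom)) {
    j <- which(g$chrom == ch)
    if (length(j) < 2L) next
    D <- g$dosages[, j, drop = FALSE]
    keep_var <- apply(D, 2L, function(v) stats::sd(v, na.rm = TRUE) > 0)
    j <- j[keep_var]; D <- D[, keep_var, drop = FALSE]
    if (ncol(D) < 2L) next
    r2 <- cor(D, use = "pairwise.complete.obs")^2
    pos <- g$pos[j]
    dist <- abs(outer(pos, pos, "-"))
    sel <- upper.tri(dist) & dist <= max_dist
    if (!any(sel)) next
    out[[ch]] <- data.frame(chrom = rep(ch, sum(sel)), dist = dist[sel],
                            r2 = r2[sel], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(0), dist = numeric(0),
                                      r2 = numeric(0))
  rownames(res) <- NULL
  res
}

#' Binned LD decay and the r^2 = 0.2 crossing distance
#'
#' Pairwise `r^2` values are averaged in fixed distance bins (1 kb by
#' default). The decay curve is the monotone non-increasing (isotonic)
#' regression of the bin means over bin midpoints; the decay distance is
#' the linear interpolation of the first crossing of the fitted curve
#' below `r2_threshold`. `Inf` is returned when the curve never crosses
#' the threshold within the observed range ("beyond max_dist").
#'
#' @param pairs data frame from [pairwise_r2] (`dist`, `r2`).
#' @param bin_width bin width in bp (default 1000).
#' @param r2_threshold crossing level (default 0.2).
#' @return A list with `bins` (data frame `distance_lo`, `distance_hi`,
#'   `midpoint`, `mean_r2`, `fitted_r2`, `n_pairs`; empty bins skipped)
#'   and `decay_distance` (bp, or `Inf`).
#' @export
ld_decay <- function(pairs, bin_width = 1000, r2_threshold = 0.2) {
  if (nrow(pairs) == 0L) stop("no SNP pairs supplied", call. = FALSE)
  bin <- floor(pairs$dist / bin_width)
  agg <- stats::aggregate(pairs$r2, by = list(bin = bin),
                          FUN = function(v) c(mean(v), length(v)))
  bins <- data.frame(
    distance_lo = agg$bin * bin_width,
    distance_hi = (agg$bin + 1) * bin_width,
    mean_r2 = agg$x[, 1],
    n_pairs = agg$x[, 2]
  )
  bins <- bins[order(bins$distance_lo), , drop = FALSE]
  bins$midpoint <- (bins$distance_lo + bins$distance_hi) / 2
  # isoreg fits non-decreasing curves; fit the negated means
  fit <- isoreg(bins$midpoint, -bins$mean_r2)
  bins$fitted_r2 <- -fit$yf
  below <- which(bins$fitted_r2 < r2_threshold)
  if (length(below) == 0L) {
    decay <- Inf
  } else {
    i <- below[1]
    if (i == 1L) {
      decay <- bins$midpoint[1]
    } else {
      x0 <- bins$midpoint[i - 1]; y0 <- bins$fitted_r2[i - 1]
      x1 <- bins$midpoint[i]; y1 <- bins$fitted_r2[i]
      decay <- x0 + (y0 - r2_threshold) / (y0 - y1) * (x1 - x0)
    }
  }
  list(bins = bins[, c("distance_lo", "distance_hi", "midpoint",
                       "mean_r2", "fitted_r2", "n_pairs")],
       decay_distance = decay)
}
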