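# End-to-end pipeline: images -> damage table -> mixed model -> genotype
# QC -> LD -> association scan -> QTL windows, with a JSON run manifest.

#' Assemble and validate a pipeline configuration
#'
#' Defaults follow the standard analysis settings: MAF >= 0.01, call rate
#' >= 0.40, -log10(p) > 6, per-trial H2 >= 0.2, window half-widths 2/5/10
#' kb.
#'
#' @param out_dir output directory (created if needed).
#' @param images,masks optional image and mask directories.
#' @param vcf optional VCF path.
#' @param phenotypes optional long-format phenotype CSV
#'   (`genotype,trial,block,value`).
#' @param pedigree optional pedigree CSV (`id,sire,dam`).
#' @param method damage method: `"dtr"`, `"dqu"` or `"both"`.
#' @param background_color,tol background rule for images without masks.
#' @param maf_min,call_rate_min,log10p_threshold,h2_threshold,half_widths
#'   analysis thresholds.
#' @param seed integer seed for any stochastic step.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, images = NULL, masks = NULL,
                            vcf = NULL, phenotypes = NULL, pedigree = NULL,
                            method = "both", background_color = NULL,
                            tol = 2 / 255, maf_min = 0.01,
                            call_rate_min = 0.40, log10p_threshold = 6,
                            h2_threshold = 0.2,
                            half_widths = c(2000, 5000, 10000), seed = 1L) {
  for (f in c(images, masks)) {
    if (!is.null(f) && !dir.exists(f)) {
      stop("config error: directory not found: ", f, call. = FALSE)
    }
  }
  for (nm in c("vcf", "phenotypes", "pedigree")) {
    f <- get(nm)
    if (!is.null(f) && !file.exists(f)) {
      stop("config error: `", nm, "` file not found: ", f, call. = FALSE)
    }
  }
  stopifnot(maf_min >= 0, maf_min <= 0.5, call_rate_min >= 0,
            call_rate_min <= 1, h2_threshold >= 0, h2_threshold <= 1,
            log10p_threshold > 0, all(half_widths > 0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  structure(
    list(out_dir = out_dir, images = images, masks = masks, vcf = vcf,
         phenotypes = phenotypes, pedigree = pedigree, method = method,
         background_color = background_color, tol = tol, maf_min = maf_min,
         call_rate_min = call_rate_min, log10p_threshold = log10p_threshold,
         h2_threshold = h2_threshold, half_widths = half_widths,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (damage quantification,
#' phenotypic mixed-model analysis, genotype QC + LD, association scan +
#' QTL windows), writing per-stage CSV/BED outputs and a JSON manifest
#' (seed, input digests, record counts). A stage failure halts the run
#' with the failing stage named; outputs of completed stages are
#' retained, and `stages` allows resuming from any point.
#'
#' @param config a [pipeline_config].
#' @param stages which stages to run, in order.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("damage", "pheno", "geno", "gwas")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "background_color")],
    inputs = list(), stages = list()
  )
  for (f in c(config$vcf, config$phenotypes, config$pedigree)) {
    if (!is.null(f)) manifest$inputs[[basename(f)]] <- unname(tools::md5sum(f))
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- res
  }

  if ("damage" %in% stages && !is.null(config$images)) {
    run_stage("damage", function() {
      tab <- batch_quantify(config$images, method = config$method,
                            mask_dir = config$masks,
                            background_color = config$background_color,
                            tol = config$tol,
                            out = file.path(out, "damage.csv"))
      list(n_images = length(unique(tab$image_id)), n_rows = nrow(tab),
           n_skipped = attr(tab, "n_skipped"))
    })
  }

  pheno_values <- NULL
  if ("pheno" %in% stages && !is.null(config$phenotypes)) {
    run_stage("pheno", function() {
      ph <- read.csv(config$phenotypes, stringsAsFactors = FALSE)
      A <- if (!is.null(config$pedigree)) {
        build_pedigree_A(read.csv(config$pedigree, stringsAsFactors = FALSE))
      }
      qc <- trial_qc(ph, threshold = config$h2_threshold, A = A)
      write.csv(qc$h2, file.path(out, "trial_qc.csv"), row.names = FALSE)
      kept <- ph[ph$trial %in% qc$retained, , drop = FALSE]
      multi <- length(qc$retained) > 1L
      fit_r <- fit_lmm(kept, A = A, genotype_as = "random",
                       include_gxt = multi)
      fit_f <- fit_lmm(kept, A = A, genotype_as = "fixed",
                       include_gxt = multi)
      write.csv(data.frame(component = names(fit_r$var_components),
                           estimate = unname(fit_r$var_components)),
                file.path(out, "variance_components.csv"), row.names = FALSE)
      write.csv(fit_r$blups, file.path(out, "blups.csv"), row.names = FALSE)
      write.csv(fit_f$blues, file.path(out, "blues.csv"), row.names = FALSE)
      h2 <- cullis_h2(fit_r)
      writeLines(jsonlite::toJSON(list(cullis_h2 = h2), auto_unbox = TRUE),
                 file.path(out, "heritability.json"))
      pheno_values <<- setNames(fit_f$blues$blue, fit_f$blues$genotype)
      list(n_records_in = nrow(ph), n_records_retained = nrow(kept),
           trials_retained = qc$retained, trials_excluded = qc$excluded,
           cullis_h2 = h2)
    })
  }

  geno <- NULL
  if ("geno" %in% stages && !is.null(config$vcf)) {
    run_stage("geno", function() {
      g <- read_vcf(config$vcf)
      gf <- filter_snps(g, maf_min = config$maf_min,
                        call_rate_min = config$call_rate_min)
      geno <<- gf
      rep_ <- attr(gf, "filter_report")
      K <- vanraden_kinship(gf)
      write.csv(data.frame(id = rownames(K), K, check.names = FALSE),
                file.path(out, "kinship.csv"), row.names = FALSE)
      pcs <- pc_covariates(gf, n_pcs = min(3L, length(gf$ids) - 1L))
      write.csv(data.frame(id = rownames(pcs$scores), pcs$scores,
                           check.names = FALSE),
                file.path(out, "pc_scores.csv"), row.names = FALSE)
      pr <- pairwise_r2(gf, maf_min = config$maf_min)
      ld <- if (nrow(pr) > 0) ld_decay(pr) else NULL
      if (!is.null(ld)) {
        write.csv(ld$bins, file.path(out, "ld_bins.csv"), row.names = FALSE)
      }
      c(as.list(rep_),
        list(ld_decay_distance = if (is.null(ld)) NA else ld$decay_distance))
    })
  }

  if ("gwas" %in% stages && !is.null(geno) && !is.null(pheno_values)) {
    run_stage("gwas", function() {
      common <- intersect(geno$ids, names(pheno_values))
      keep <- geno$ids %in% common
      g2 <- genotype_matrix(geno$dosages[keep, , drop = FALSE],
                            chrom = geno$chrom, pos = geno$pos,
                            ids = geno$ids[keep], snp_ids = geno$snp_ids,
                            ref = geno$ref, alt = geno$alt)
      pcs <- pc_covariates(g2, n_pcs = min(3L, length(g2$ids) - 2L))
      res <- scan_association(g2, pheno_values[common], pcs$scores)
      write.csv(res, file.path(out, "scan.csv"), row.names = FALSE)
      mt <- significant_mtas(res, config$log10p_threshold,
                             trait = "total plant damage")
      write.csv(mt, file.path(out, "mtas.csv"), row.names = FALSE)
      wins <- build_qtl_windows(mt, half_widths = config$half_widths)
      write.csv(wins, file.path(out, "qtl_windows.csv"), row.names = FALSE)
      bed <- convert_coordinates(
        wins[, c("chrom", "start", "end")], from = "one_based", to = "bed")
      bed$name <- wins$name
      utils::write.table(bed, file.path(out, "qtl_windows.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      list(n_snps_scanned = nrow(res), n_mtas = nrow(mt),
           n_windows = nrow(wins))
    })
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

#' Convert intervals between 1-based inclusive and BED coordinates
#'
#' BED intervals are 0-based half-open; 1-based inclusive `[s, e]`
#' corresponds to BED `(s - 1, e]`. The round trip is the identity.
#'
#' @param intervals data frame with `start` and `end`.
#' @param from,to `"one_based"` or `"bed"`.
#' @return The data frame with converted `start`/`end`.
#' @export
convert_coordinates <- function(intervals, from = c("one_based", "bed"),
                                to = c("bed", "one_based")) {
  from <- match.arg(from); to <- match.arg(to)
  s <- intervals$start; e <- intervals$end
  if (any(s < 0 | e < 0)) stop("negative coordinates", call. = FALSE)
  if (from == to) return(intervals)
  if (from == "one_based") {
    if (any(e < s)) stop("invalid 1-based interval (end < start)",
                         call. = FALSE)
    intervals$start <- s - 1L
  } else {
    if (any(e <= s)) stop("zero-length BED interval", call. = FALSE)
    intervals$start <- s + 1L
  }
  intervals
}
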