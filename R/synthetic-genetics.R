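# Synthetic F1 biparental families, multi-trial phenotypes and insect
# counts with known ground truth.
#
# The default design emulates four F1 families (70, 120, 120, 29 progeny)
# sharing a common tester parent, segregating biallelic SNPs coded as
# diploid dosages. Recombination between adjacent SNPs follows Haldane's
# map (probability 0.5 * (1 - exp(-2 * rate * distance))), so linkage
# disequilibrium decays with physical distance at a tunable rate.

#' Design of a set of F1 biparental families
#'
#' @param family_sizes progeny counts per cross (default the four-family
#'   design 70, 120, 120, 29).
#' @param n_snps number of SNPs (>= 2), split evenly across chromosomes.
#' @param n_chrom number of synthetic chromosomes.
#' @param snp_spacing distance in bp between adjacent SNPs.
#' @param recomb_rate per-bp recombination rate in \[0, 0.5\]; the
#'   recombination probability between adjacent SNPs is Haldane's
#'   `0.5 * (1 - exp(-2 * recomb_rate * snp_spacing))`, so 0.5 with unit
#'   spacing gives free recombination.
#' @param missing_rate fraction of genotype calls set to missing, in \[0, 1).
#' @param het_frac fraction of SNPs at which each parent is heterozygous
#'   (default 0.5, maximizing segregation as in an F1 mapping family).
#' @param seed integer seed.
#' @return An object of class `family_design`.
#' @export
family_design <- function(family_sizes = c(70L, 120L, 120L, 29L),
                          n_snps = 500L, n_chrom = 1L, snp_spacing = 100,
                          recomb_rate = 1e-3, missing_rate = 0,
                          het_frac = 0.5, seed = 1L) {
  if (any(family_sizes < 1L)) stop("family_sizes must all be >= 1",
                                   call. = FALSE)
  if (n_snps < 2L) stop("n_snps must be >= 2", call. = FALSE)
  if (recomb_rate < 0 || recomb_rate > 0.5) {
    stop("recomb_rate must lie in [0, 0.5]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(family_sizes = as.integer(family_sizes), n_snps = as.integer(n_snps),
         n_chrom = as.integer(n_chrom), snp_spacing = snp_spacing,
         recomb_rate = recomb_rate, missing_rate = missing_rate,
         het_frac = het_frac, seed = as.integer(seed)),
    class = "family_design"
  )
}

# One gamete per progeny from a parent's two haplotypes: start on a random
# haplotype, switch between adjacent SNPs with per-interval recombination
# probability r (vector of length n_snps - 1, zeroed across chromosome
# boundaries by passing r = 0.5 there is avoided: chromosomes are handled
# by forcing independence, r = 0.5, at boundaries).
.sample_gametes <- function(hap1, hap2, n_gametes, r_adj) {
  n_snps <- length(hap1)
  switches <- matrix(rbinom(n_gametes * (n_snps - 1L), 1L,
                            rep(r_adj, each = n_gametes)),
                     nrow = n_gametes)
  cum <- switches
  if (ncol(cum) > 1L) {
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + cum[, j]
  }
  start <- rbinom(n_gametes, 1L, 0.5)
  phase <- (start + cbind(0L, cum)) %% 2L
  # phase == 0 -> hap1 allele, phase == 1 -> hap2 allele
  matrix(ifelse(phase == 0L, rep(hap1, each = n_gametes),
                rep(hap2, each = n_gametes)),
         nrow = n_gametes)
}

#' Simulate F1 biparental families of diploid biallelic SNPs
#'
#' All crosses share one tester parent; each family adds its own second
#' parent. Parents are heterozygous at a `het_frac` fraction of SNPs;
#' progeny genotypes arise from gamete sampling with Haldane recombination
#' between adjacent SNPs. Missing genotypes are injected at
#' `missing_rate`. Deterministic given `design$seed`.
#'
#' @param design a [family_design].
#' @return A list with `geno` (a [genotype_matrix] of the progeny),
#'   `pedigree` (data frame `id`, `sire`, `dam`; founders have `NA`
#'   parents), `family` (family index per progeny) and `parent_geno`
#'   (founder dosage matrix).
#' @export
simulate_f1_families <- function(design) {
  stopifnot(inherits(design, "family_design"))
  n_fam <- length(design$family_sizes)
  n_snps <- design$n_snps
  per_chrom <- rep(n_snps %/% design$n_chrom, design$n_chrom)
  if (sum(per_chrom) < n_snps) {
    per_chrom[1] <- per_chrom[1] + (n_snps - sum(per_chrom))
  }
  chrom <- rep(paste0("chr", seq_len(design$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) design$snp_spacing * seq_len(k)))
  # per-interval recombination probability; independence across chromosomes
  r_adj <- 0.5 * (1 - exp(-2 * design$recomb_rate * design$snp_spacing))
  r_vec <- rep(r_adj, n_snps - 1L)
  r_vec[chrom[-1L] != chrom[-n_snps]] <- 0.5

  with_seed(design$seed, {
    parent_ids <- c("TESTER", paste0("PAR", seq_len(n_fam)))
    make_parent <- function() {
      het <- runif(n_snps) < design$het_frac
      a1 <- rbinom(n_snps, 1L, 0.5)
      h1 <- a1
      h2 <- ifelse(het, 1L - a1, a1)
      rbind(h1, h2)
    }
    parents <- lapply(parent_ids, function(i) make_parent())
    names(parents) <- parent_ids

    dos_list <- list(); ids <- character(0); fam_of <- integer(0)
    ped <- data.frame(id = parent_ids, sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    for (f in seq_len(n_fam)) {
      nf <- design$family_sizes[f]
      g_sire <- .sample_gametes(parents$TESTER[1, ], parents$TESTER[2, ],
                                nf, r_vec)
      dam_id <- paste0("PAR", f)
      g_dam <- .sample_gametes(parents[[dam_id]][1, ], parents[[dam_id]][2, ],
                               nf, r_vec)
      dos <- g_sire + g_dam
      prog_ids <- sprintf("F%d_%03d", f, seq_len(nf))
      dos_list[[f]] <- dos
      ids <- c(ids, prog_ids)
      fam_of <- c(fam_of, rep.int(f, nf))
      ped <- rbind(ped, data.frame(id = prog_ids, sire = "TESTER",
                                   dam = dam_id, stringsAsFactors = FALSE))
    }
    dosages <- do.call(rbind, dos_list)
    if (design$missing_rate > 0) {
      miss <- matrix(runif(length(dosages)) < design$missing_rate,
                     nrow = nrow(dosages))
      dosages[miss] <- NA_integer_
    }
    rownames(dosages) <- ids
    parent_dos <- t(vapply(parents, function(h) h[1, ] + h[2, ],
                           integer(n_snps)))
    geno <- genotype_matrix(dosages, chrom = chrom, pos = pos, ids = ids)
    list(geno = geno, pedigree = ped, family = fam_of,
         parent_geno = parent_dos)
  })
}

#' Specification for a multi-trial phenotype simulation
#'
#' Houses the variance components of the trial model: genotype (`var_g`),
#' genotype-by-trial (`var_gxt`), block (`var_block`) and residual
#' (`var_e`), plus optional additive QTL effects.
#'
#' @param n_trials number of trials (>= 1).
#' @param var_g,var_gxt,var_block,var_e variance components (trait units^2,
#'   all >= 0).
#' @param qtl_effects named numeric vector mapping SNP index to additive
#'   effect per alternate-allele dosage (empty for a purely polygenic trait).
#' @param trial_means per-trial intercepts (recycled to `n_trials`).
#' @param seed integer seed.
#' @return An object of class `pheno_sim_spec`.
#' @export
pheno_sim_spec <- function(n_trials = 2L, var_g = 1, var_gxt = 0,
                           var_block = 0, var_e = 1,
                           qtl_effects = numeric(0),
                           trial_means = 0, seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  if (any(c(var_g, var_gxt, var_block, var_e) < 0)) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  structure(
    list(n_trials = as.integer(n_trials), var_g = var_g, var_gxt = var_gxt,
         var_block = var_block, var_e = var_e, qtl_effects = qtl_effects,
         trial_means = rep_len(trial_means, n_trials),
         seed = as.integer(seed)),
    class = "pheno_sim_spec"
  )
}

#' Simulate multi-trial phenotypes with planted variance components
#'
#' Generates `y = trial mean + sum_k beta_k dosage_k + g + (g x t) + block
#' + e` over an augmented-block-style layout: in each trial every genotype
#' appears in `n_reps` replicates, allocated at random to `n_blocks`
#' incomplete blocks. Deterministic given `spec$seed`.
#'
#' @param geno a [genotype_matrix] (or `NULL` for a purely polygenic trait
#'   over `n_geno` genotypes).
#' @param spec a [pheno_sim_spec].
#' @param n_reps replicates per genotype per trial.
#' @param n_blocks incomplete blocks per trial.
#' @param n_geno number of genotypes when `geno` is `NULL`.
#' @return A long-format data frame (`genotype`, `trial`, `block`, `rep`,
#'   `value`) with the planted genotype effects in
#'   `attr(, "genetic_values")`.
#' @export
simulate_phenotypes <- function(geno, spec, n_reps = 1L, n_blocks = 4L,
                                n_geno = NULL) {
  stopifnot(inherits(spec, "pheno_sim_spec"))
  if (!is.null(geno)) {
    stopifnot(inherits(geno, "genotype_matrix"))
    ids <- geno$ids
    m <- length(ids)
    qtl <- numeric(m)
    if (length(spec$qtl_effects) > 0) {
      k_idx <- as.integer(names(spec$qtl_effects))
      if (any(is.na(k_idx)) || any(k_idx < 1L) || any(k_idx > ncol(geno$dosages))) {
        stop("qtl_effects names must be valid SNP indices", call. = FALSE)
      }
      for (j in seq_along(k_idx)) {
        d <- geno$dosages[, k_idx[j]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        qtl <- qtl + spec$qtl_effects[j] * d
      }
    }
  } else {
    if (is.null(n_geno)) stop("supply `geno` or `n_geno`", call. = FALSE)
    ids <- sprintf("G%04d", seq_len(n_geno))
    m <- n_geno
    qtl <- numeric(m)
  }
  with_seed(spec$seed, {
    g <- rnorm(m, 0, sqrt(spec$var_g))
    rows <- vector("list", spec$n_trials)
    for (t in seq_len(spec$n_trials)) {
      gxt <- rnorm(m, 0, sqrt(spec$var_gxt))
      blk_eff <- rnorm(n_blocks, 0, sqrt(spec$var_block))
      for (r in seq_len(n_reps)) {
        blk <- sample(rep_len(seq_len(n_blocks), m))
        e <- rnorm(m, 0, sqrt(spec$var_e))
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = ids,
          trial = sprintf("T%d", t),
          block = sprintf("T%d_B%d", t, blk),
          rep = r,
          value = spec$trial_means[t] + qtl + g + gxt + blk_eff[blk] + e,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "genetic_values") <- setNames(g + qtl, ids)
    out
  })
}

#' Simulate bounded insect survival counts
#'
#' Each plant is infested with `n_infested` eggs; the number surviving to
#' 35 days after infestation is Binomial(`n_infested`, `survival_prob`).
#'
#' @param n_plants number of plants.
#' @param survival_prob per-insect survival probability in \[0, 1\].
#' @param n_infested insects per plant (default 6, the standard no-choice
#'   infestation rate).
#' @param seed integer seed.
#' @return Data frame with `plant`, `living`, `total_infested`.
#' @export
simulate_insect_counts <- function(n_plants, survival_prob, n_infested = 6L,
                                   seed = 1L) {
  stop_if_not_scalar_prob(survival_prob, "survival_prob")
  with_seed(seed, {
    data.frame(
      plant = sprintf("P%05d", seq_len(n_plants)),
      living = rbinom(n_plants, n_infested, survival_prob),
      total_infested = as.integer(n_infested),
      stringsAsFactors = FALSE
    )
  })
}
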