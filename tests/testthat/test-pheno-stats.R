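test_that("insect survival percentages take the discrete values", {
  expect_identical(nts(0), 0)
  expect_identical(nts(1), 16.7)
  expect_identical(nts(2), 33.3)
  expect_identical(nts(6), 100)
  expect_equal(nts(c(0, 3, 6)), c(0, 50, 100))
  expect_equal(nts(5, total_infested = 10), 50)
  expect_error(nts(7), "total_infested")
  expect_error(nts(1, total_infested = 0), "> 0")
})

test_that("pedigree A matrix reproduces textbook relationships", {
  ped <- data.frame(id = c("A", "B", "C", "D", "E"),
                    sire = c(NA, NA, "A", "A", "C"),
                    dam = c(NA, NA, "B", "B", "D"))
  A <- build_pedigree_A(ped)$A
  expect_equal(A["A", "B"], 0)            # unrelated founders
  expect_equal(diag(A)[c("A", "B")], c(A = 1, B = 1))
  expect_equal(A["C", "D"], 0.5)          # full sibs
  expect_equal(A["A", "C"], 0.5)          # parent-offspring
  expect_equal(A["E", "E"], 1.25)         # full-sib mating: 1 + 0.5/2
  expect_equal(A["A", "E"], 0.5)          # grandparent via both paths
  expect_true(isSymmetric(A))
  expect_true(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
              > -1e-8)
})

test_that("pedigree A matches the gene-dropping expectation", {
  # independent oracle: drop founder alleles through the pedigree 1e5
  # times; a_ij = 2 * P(random allele of i IBD to random allele of j)
  ped <- data.frame(id = c("A", "B", "C", "D", "E"),
                    sire = c(NA, NA, "A", "A", "C"),
                    dam = c(NA, NA, "B", "B", "D"))
  A <- build_pedigree_A(ped)$A
  set.seed(99)
  n_rep <- 1e5
  pick <- function(h1, h2) ifelse(runif(n_rep) < 0.5, h1, h2)
  a1 <- rep(1L, n_rep); a2 <- rep(2L, n_rep)       # founder A alleles
  b1 <- rep(3L, n_rep); b2 <- rep(4L, n_rep)
  c1 <- pick(a1, a2); c2 <- pick(b1, b2)           # C = A x B
  d1 <- pick(a1, a2); d2 <- pick(b1, b2)           # D = A x B
  e1 <- pick(c1, c2); e2 <- pick(d1, d2)           # E = C x D
  haps <- list(A = cbind(a1, a2), B = cbind(b1, b2), C = cbind(c1, c2),
               D = cbind(d1, d2), E = cbind(e1, e2))
  kin <- function(x, y) mean(pick(x[, 1], x[, 2]) == pick(y[, 1], y[, 2]))
  for (i in names(haps)) {
    for (j in names(haps)) {
      if (i < j) {
        expect_lt(abs(2 * kin(haps[[i]], haps[[j]]) - A[i, j]), 0.01)
      }
    }
  }
})

test_that("pedigree errors are caught", {
  expect_error(build_pedigree_A(data.frame(id = "X", sire = "Y", dam = NA)),
               "not marked as founders")
  cyc <- data.frame(id = c("A", "B"), sire = c("B", "A"), dam = c(NA, NA))
  expect_error(build_pedigree_A(cyc), "cycle")
})

test_that("noiseless data give exact BLUEs and a vanishing residual", {
  g_true <- seq(-2, 2, length.out = 20)
  d <- expand.grid(genotype = sprintf("G%02d", 1:20), trial = c("T1", "T2"),
                   rep = 1:2, stringsAsFactors = FALSE)
  trial_eff <- c(T1 = 0, T2 = 3)
  d$value <- g_true[match(d$genotype, sprintf("G%02d", 1:20))] +
    trial_eff[d$trial]
  fit <- fit_lmm(d, genotype_as = "fixed")
  expect_lt(fit$var_components[["residual"]], 1e-12)
  blue <- fit$blues$blue[match(sprintf("G%02d", 1:20), fit$blues$genotype)]
  expect_equal(blue - mean(blue), g_true - mean(g_true), tolerance = 1e-8)
})

test_that("balanced one-trial REML matches the ANOVA moment estimator", {
  set.seed(7)
  m <- 30; r <- 4
  g <- rnorm(m, 0, sqrt(2))
  d <- expand.grid(genotype = sprintf("G%02d", 1:m), rep = 1:r,
                   stringsAsFactors = FALSE)
  d$trial <- "T1"
  d$value <- g[match(d$genotype, sprintf("G%02d", 1:m))] + rnorm(nrow(d))
  fit <- fit_lmm(d, genotype_as = "random")
  means <- tapply(d$value, d$genotype, mean)
  msg <- r * var(means)
  mse <- sum((d$value - means[d$genotype])^2) / (m * (r - 1))
  expect_equal(fit$var_components[["genotype"]], (msg - mse) / r,
               tolerance = 1e-6)
  expect_equal(fit$var_components[["residual"]], mse, tolerance = 1e-6)
})

test_that("REML agrees with lme4 on an identity-kinship model", {
  skip_if_not_installed("lme4")
  ph <- simulate_phenotypes(NULL,
    pheno_sim_spec(n_trials = 2, var_g = 1, var_e = 1, seed = 11),
    n_geno = 100)
  fit <- fit_lmm(ph, genotype_as = "random")
  lf <- lme4::lmer(value ~ trial + (1 | genotype), ph, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(unname(fit$var_components), vc, tolerance = 1e-5)
  blup_lme4 <- lme4::ranef(lf)$genotype[, 1]
  expect_equal(fit$blups$blup, blup_lme4, tolerance = 1e-5)
})

test_that("REML with several random components agrees with lme4", {
  skip_if_not_installed("lme4")
  ph <- simulate_phenotypes(NULL,
    pheno_sim_spec(n_trials = 3, var_g = 1, var_gxt = 0.5, var_e = 1,
                   seed = 13),
    n_reps = 2, n_geno = 60)
  fit <- fit_lmm(ph, genotype_as = "random", include_gxt = TRUE)
  lf <- lme4::lmer(value ~ trial + (1 | genotype) + (1 | genotype:trial),
                   ph, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$var_components[["genotype"]],
               vc$vcov[vc$grp == "genotype"], tolerance = 1e-3)
  expect_equal(fit$var_components[["genotype_trial"]],
               vc$vcov[vc$grp == "genotype:trial"], tolerance = 1e-3)
  expect_equal(fit$var_components[["residual"]],
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
})

test_that("BLUPs shrink relative to BLUE deviations under identity kinship", {
  ph <- simulate_phenotypes(NULL,
    pheno_sim_spec(n_trials = 2, var_g = 1, var_e = 2, seed = 17),
    n_geno = 50)
  fr <- fit_lmm(ph, genotype_as = "random")
  ff <- fit_lmm(ph, genotype_as = "fixed")
  blue_dev <- ff$blues$blue - mean(ff$blues$blue)
  ord <- match(fr$blups$genotype, ff$blues$genotype)
  expect_true(all(abs(fr$blups$blup) <= abs(blue_dev[ord]) + 1e-8))
})

test_that("pedigree kinship reranks only between families, not within", {
  fam <- simulate_f1_families(family_design(family_sizes = c(25L, 25L),
                                            n_snps = 10, seed = 3))
  A <- build_pedigree_A(fam$pedigree)
  ph <- simulate_phenotypes(fam$geno,
    pheno_sim_spec(n_trials = 2, var_g = 1, var_e = 1, seed = 23))
  fit_i <- fit_lmm(ph, genotype_as = "random")
  fit_a <- fit_lmm(ph, A = A, genotype_as = "random")
  for (f in 1:2) {
    ids <- fam$geno$ids[fam$family == f]
    bi <- fit_i$blups$blup[match(ids, fit_i$blups$genotype)]
    ba <- fit_a$blups$blup[match(ids, fit_a$blups$genotype)]
    expect_identical(order(bi), order(ba))
  }
})

test_that("degenerate designs are rejected", {
  d <- data.frame(genotype = "G1", trial = "T1", value = 1:3)
  expect_error(fit_lmm(d), ">= 2 genotypes")
  d2 <- data.frame(genotype = c("G1", "G2"), trial = "T1", value = c(1, 2))
  expect_error(fit_lmm(d2, genotype_as = "fixed"), "residual degrees")
  ped <- data.frame(id = c("X", "Y"), sire = NA, dam = NA)
  A <- build_pedigree_A(ped)
  d3 <- data.frame(genotype = rep(c("G1", "G2"), 3), trial = "T1",
                   value = rnorm(6))
  expect_error(fit_lmm(d3, A = A), "does not cover")
})

test_that("Cullis heritability follows the prediction-error formula", {
  mk_fit <- function(s2g, pec) {
    structure(list(genotype_as = "random", pec = pec,
                   var_components = c(genotype = s2g, residual = 1)),
              class = "lmm_fit")
  }
  m <- 20
  # PEV of every pairwise difference 0 => perfect prediction
  expect_equal(cullis_h2(mk_fit(1, matrix(0, m, m))), 1)
  # diag 0.34, zero covariances => mean pairwise PEV 0.68, H2 = 0.66
  expect_equal(cullis_h2(mk_fit(1, diag(0.34, m))), 0.66)
  # zero genotype variance defines H2 = 0
  expect_equal(cullis_h2(mk_fit(0, diag(0.1, m))), 0)
  # monotone decreasing in the mean PEV
  h <- vapply(c(0.1, 0.3, 0.5, 0.9),
              function(v) cullis_h2(mk_fit(1, diag(v, m))), numeric(1))
  expect_true(all(diff(h) < 0))
  expect_true(all(h >= 0 & h <= 1))
})

test_that("heritability is recovered near its simulation target", {
  # two trials of 500 genotypes with var_g = 1, var_e = 4/3 put the
  # expected genotype-mean heritability at 1 / (1 + (4/3)/2) = 0.6
  hits <- 0L
  for (s in 1:10) {
    ph <- simulate_phenotypes(NULL,
      pheno_sim_spec(n_trials = 2, var_g = 1, var_e = 4 / 3, seed = 400 + s),
      n_geno = 500)
    h2 <- cullis_h2(fit_lmm(ph, genotype_as = "random"))
    if (h2 >= 0.5 && h2 <= 0.7) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("trial QC excludes heritability-poor trials", {
  mk_trial <- function(trial, var_g, seed, n = 120) {
    ph <- simulate_phenotypes(NULL,
      pheno_sim_spec(n_trials = 1, var_g = var_g, var_e = 1, seed = seed),
      n_reps = 2, n_geno = n)
    ph$trial <- trial
    ph
  }
  d <- rbind(mk_trial("good", 1, 51), mk_trial("null", 0, 52))
  qc <- trial_qc(d, threshold = 0.2)
  expect_true("good" %in% qc$retained)
  expect_true("null" %in% qc$excluded)
  qc0 <- trial_qc(d, threshold = 0)
  expect_setequal(qc0$retained, c("good", "null"))
  d_bad <- mk_trial("null2", 0, 53)
  expect_error(trial_qc(d_bad, threshold = 0.2), "excluded every trial")
})

test_that("trait correlations match the direct Pearson formula", {
  x <- c(1, 2, 4, 5, 9)
  y <- c(2, 1, 5, 4, 10)
  tab <- data.frame(genotype = letters[1:5], t1 = x, t2 = y, t3 = -x,
                    t4 = rep(1, 5))
  res <- trait_correlations(tab)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r["t1", "t2"], r_direct, tolerance = 1e-12)
  expect_equal(res$r["t1", "t1"], 1)
  expect_equal(res$r["t1", "t3"], -1)
  expect_true(is.na(res$r["t1", "t4"]))   # constant trait: NA, not 0
  tt <- cor.test(x, y)
  expect_equal(res$p["t1", "t2"], tt$p.value)
})

test_that("genotype means average replicated measurements", {
  d <- data.frame(genotype = c("a", "a", "b"), trial = "T1",
                  value = c(1, 3, 5))
  gm <- genotype_means(d)
  expect_equal(gm$mean[gm$genotype == "a"], 2)
  expect_equal(gm$n[gm$genotype == "b"], 1)
})
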