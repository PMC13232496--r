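# Shared fixtures, built in code at test time.

# Small two-family genotype set reused across genotype/GWAS tests.
small_families <- function(n_snps = 200L, family_sizes = c(150L, 150L),
                           seed = 42L, ...) {
  simulate_f1_families(family_design(family_sizes = family_sizes,
                                     n_snps = n_snps, seed = seed, ...))
}

# Random damage proportions (green majority varies widely).
random_proportions <- function(seed) {
  set.seed(seed)
  g <- runif(1, 0.05, 0.95)
  rest <- 1 - g
  y <- rest * runif(1)
  c(g, y, rest - y)
}

# Hardy-Weinberg unrelated individuals, constructed directly (independent
# oracle for kinship/LD null expectations, not via the family simulator).
hw_genotypes <- function(n_ind, n_snps, seed, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(n_snps, maf_range[1], maf_range[2])
  dos <- vapply(p, function(pk) rbinom(n_ind, 2L, pk), integer(n_ind))
  genotype_matrix(dos, chrom = rep("chr1", n_snps),
                  pos = seq_len(n_snps) * 1000L,
                  ids = sprintf("HW%04d", seq_len(n_ind)))
}

# Write a small VCF text fixture with hand-chosen records.
write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}
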