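---
title: "Methods: image-based damage phenotyping and genetic mapping of spittlebug resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based damage phenotyping and genetic mapping of spittlebug resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spitres)
```

## Overview

`spitres` implements the computational core of an insect-resistance
phenotyping and mapping workflow for forage grasses attacked by
root-feeding spittlebug nymphs. Resistance is measured along two axes:

* **Antibiosis** — the plant reduces insect survival, scored as the
  survival percentage `NTS = living / total_infested * 100` at the end of
  the nymphal period, with 6 insects per plant as the standard no-choice
  infestation rate.
* **Tolerance** — the plant withstands feeding with less tissue damage,
  scored from lightbox photographs as the fraction of damaged plant
  pixels.

Damage phenotypes feed a multi-trial linear mixed model with a pedigree
relationship matrix; genotype predictions feed a marker association scan
whose significant hits are converted into LD-informed QTL windows. A
synthetic-data module generates images, F1 family genotypes, pedigrees,
phenotypes and insect counts with known ground truth, so that every stage
of the pipeline is testable without any external download.

## Damage quantification

### Supervised RGB thresholds (DTR)

Each plant pixel (channels normalized to [0, 1]) is assigned to the first
matching rule, in the order the rules are stated:

* **green**: `R < 0.9 G` and `B < 0.9 G` and `2 G > (20/255)(B + R)`;
* **yellow (chlorotic)**: `90/255 < R < 241/255`, `97/255 < G < 216/255`,
  `18/255 < B < 165/255`;
* **necrotic**: `27/255 < R < 225/255`, `56/255 < G < 213/255`,
  `0 < B < 53/255`.

All inequalities are strict. The yellow and necrotic boxes overlap; since
no precedence is defined by the rules themselves, the package applies
green → yellow → necrotic and the first match wins. Pixels matching no
rule are *unclassified* and excluded from the damage denominator, because
the damage statistic is defined over classified tissue only:

$$\mathrm{damage} = \frac{\mathrm{yellow} + \mathrm{necrotic}}
  {\mathrm{yellow} + \mathrm{necrotic} + \mathrm{green}}.$$

Classification requires a plant mask. Lightbox imaging gives a uniform
background, so the mask can either be supplied explicitly (a 0/255 PNG) or
derived by `mask_background()`, which removes pixels within a per-channel
tolerance of the background color (default tolerance 2/255).

### Unsupervised median-cut quantization (DQU)

`median_cut_quantize()` partitions the masked pixels into at most three
color subgroups: starting from one box containing all pixels, the box
whose widest channel range is largest is split at the median of that
channel, until three boxes exist or none is splittable. Determinism is
guaranteed by fixed tie-breaks: among equally wide boxes the larger pixel
count wins, then the lower box index; pixels whose value equals the
median go to the lower half (or, when that would empty the upper half, the
median value itself moves up). The centroid of a box is its mean color.

The mapping from color subgroups to tissue classes is not part of the
median-cut algorithm and had to be defined here: each centroid is
classified by the DTR rules; a centroid matching no rule falls back to
the nearest class prototype in RGB distance (prototypes default to the
centers of the synthetic color boxes and are configurable), with ties
broken by the fixed order green < yellow < necrotic. Cluster sizes are
then aggregated per class, so DQU never produces unclassified pixels.

### Synthetic images and what they do (not) show

`generate_plant_image()` colors plant pixels from fixed closed RGB boxes
lying strictly inside the DTR acceptance region of their class — and, for
yellow and necrotic, outside the regions of the classes that precede them
— with a margin of at least 5/255 on every face. All values sit on the
8-bit grid and fixtures are written as lossless PNG, so the planted
counts are exact, not approximate (JPEG is supported read-only, because
lossy compression perturbs threshold-adjacent pixels). Class proportions
are converted to integer pixel counts by largest remainder, which is why
`(0.85, 0.10, 0.05)` over 1000 plant pixels yields exactly
`(850, 100, 50)`.

The box geometry encodes one deliberate design choice: the green channel
carries the class signal (one constant level per class, ordered
necrotic < yellow < green), while within-class variation lives in the red
and blue channels. Under this geometry a median-cut box spanning several
classes always splits either between whole classes or within the two
damage classes, so three-subgroup quantization recovers the planted
damage exactly even on jittered fixtures. This makes the DTR/DQU
concordance checks sharp, but it also means the synthetic images are
easier than real photographs, where lighting gradients, specular
highlights and transitional tissue blur the class boundaries: passing
these tests validates the machinery, not field performance.

## Phenotypic analysis

### The mixed model

The multi-trial model is

$$y = X\beta + Z_g u_g + Z_{gt} u_{gt} + Z_b u_b + \varepsilon,$$

with trial as a fixed effect, genotype effects
$u_g \sim N(0, A\,\sigma^2_g)$ under an optional pedigree numerator
relationship matrix $A$, iid genotype-by-trial and block effects, and
homogeneous residuals. Two simplifications relative to a full
trial-network analysis are intentional: residuals are homogeneous rather
than per-trial heterogeneous, and row-by-column spatial effects are
omitted. Both choices keep the REML machinery self-contained and fully
testable from first principles; the genotype-by-trial and block terms
remain available as options (`include_gxt`, `include_block`).

`build_pedigree_A()` constructs $A$ by the recursive tabular method
($a_{ij} = (a_{is} + a_{id})/2$ for offspring $j$ of $(s, d)$;
$a_{jj} = 1 + a_{sd}/2$), with unknown parents treated as unrelated
non-inbred founders. The tests verify the matrix against an independent
gene-dropping simulation.

### REML implementation

Variance components are estimated by direct maximization of the
restricted log-likelihood. Components are parameterized as ratios
$\gamma_t = \sigma^2_t / \sigma^2_e$ on the log scale and the residual
variance is profiled out in closed form, which removes one dimension and
makes the optimization bounded and well-scaled. Models with a single
random term — the most common case — use a spectral shortcut: one SVD of
$Z L$ (where $K = L L^\top$) reduces every likelihood evaluation to
$O(m)$, and the one-dimensional profile likelihood is bracketed on a
40-point grid over $\log\gamma \in [-18, 12]$ before Brent refinement
(the grid guards against the mild multimodality a pure interval search
could miss). Models with several random terms use Nelder–Mead with a
dense Cholesky per evaluation (relative tolerance `1e-8`). Either way,
BLUPs, BLUEs and the *full* prediction-error covariance of the genotype
effects are computed once at the optimum from dense mixed-model algebra.
Non-convergence is flagged on the returned object, never silently
ignored. The identity-kinship case is cross-checked against `lme4` in the
test suite; the balanced one-trial case against the closed-form ANOVA
moment estimator.

Zero variance components are admissible: the profile likelihood simply
drives $\gamma \to 0$, and a data set with no residual noise yields BLUEs
equal to the planted genotype values with $\hat\sigma^2_e \to 0$.

### Cullis heritability and trial QC

Broad-sense heritability uses the prediction-error-variance form

$$H^2 = 1 - \frac{\overline{\mathrm{PEV}}}{2\hat\sigma^2_g},$$

where $\overline{\mathrm{PEV}}$ is the exact average over all genotype
pairs of $\mathrm{var}(\hat g_i - \hat g_j)$, computed from the
prediction-error covariance matrix as
$2\,(m\,\mathrm{tr}\,C - \mathbf{1}^\top C\,\mathbf{1})/(m(m-1))$ rather
than from the diagonal alone. The estimate is clamped to [0, 1] and
defined as 0 when $\hat\sigma^2_g = 0$. `trial_qc()` fits each trial
separately with genotype random and excludes trials that fail to converge
or fall below the heritability threshold (default 0.2). The same formula
serves per trial and across trials. Three genotype-value estimators are
exported side by side — arithmetic means, BLUEs (genotype fixed, used for
trait correlations because they carry no shrinkage) and BLUPs.

## Genotype analysis

* **Filtering**: SNPs are kept when MAF ≥ 0.01 (computed on non-missing
  dosages) and call rate ≥ 0.40, interpreted per SNP as the fraction of
  non-missing genotypes. Multiallelic records are excluded at VCF import.
* **Kinship**: the VanRaden genomic relationship
  $G = W W^\top / (2\sum_k p_k(1-p_k))$ with $W$ the centered dosage
  matrix; missing dosages are mean-imputed per SNP.
* **Structure**: the first three principal components of the centered
  dosage matrix, with variance-explained fractions.
* **LD**: $r^2$ is the squared Pearson correlation of allele dosages
  (composite LD) over pairwise-complete observations. Dosage $r^2$ was
  chosen over haplotype $r^2$ because the pipeline accepts unphased VCFs
  and the two agree under random mating; phasing is out of scope. Pairs
  within a chromosome are averaged in 1-kb bins, the decay curve is the
  monotone non-increasing (isotonic) regression of the bin means — a
  deliberately assumption-light fit that guarantees a unique first
  crossing, where a parametric expected-$r^2$ curve would impose a
  functional form the data may not follow — and the decay distance is the
  linear interpolation of the first crossing below $r^2 = 0.2$ between
  bin midpoints (bin means 0.5/0.3/0.1 at 0–1/1–2/2–3 kb interpolate to
  exactly 2.0 kb). `Inf` is the sentinel when the curve never crosses.
  The isotonic fit is unweighted across bins; with the near-uniform SNP
  spacing of the simulated panels bin occupancies are comparable, so
  weighting would change little.

## Association scan and QTL windows

The scan is single-marker linear regression
`y ~ covariates + dosage` with a two-sided t-test on the dosage term,
implemented by residualizing the trait and all dosages on the covariates
once. It is plumbing for testing the downstream window machinery — not a
replacement for multi-locus GWAS models, whose re-implementation is out
of scope. Reported `pve` is the partial $R^2$ of the SNP term. Zero
variance SNPs get `p = 1` with a warning count. Significance uses
`-log10(p) > 6` with Benjamini–Hochberg q-values computed over all tested
SNPs attached for validation; an empty hit list is a valid outcome.

Each significant association yields windows `[pos - w, pos + w]` (1-based
inclusive, clipped at 1) for half-widths 2, 5 and 10 kb — three tracks
because LD decay is heterogeneous across families and chromosomes; the
10-kb track is the canonical reported window. Overlapping windows on a
chromosome are merged before naming (merge-then-name), member traits are
unioned, and names follow the `qTPD`/`qNT` convention: a prefix chosen
from the member traits in priority order (total plant damage wins over
necrotic tissue when a merged window carries both), the chromosome
number, and a `-k` ordinal only when several windows of the same prefix
share a chromosome. Gene tables intersect windows with 1-bp-overlap
inclusive semantics; BED export converts 1-based inclusive to 0-based
half-open coordinates, a conversion that is itself round-trip tested.

## Synthetic genetics

`simulate_f1_families()` emulates a crossing design of four F1 families
(default sizes 70, 120, 120 and 29) sharing one tester parent. Parents
are heterozygous at a configurable fraction of SNPs (default 0.5, which
maximizes segregation in an F1 mapping family); progeny arise by gamete
sampling with Haldane recombination
$r = \tfrac12(1 - e^{-2 \cdot \mathrm{rate} \cdot d})$ between adjacent
SNPs, independence across chromosomes, and optional missing-call
injection. The per-bp rate, SNP spacing and family sizes tune the LD
landscape, which is how the decay-distance ordering checks (slow
recombination → longer LD) are driven. Phenotypes are simulated over an
augmented-block-style layout, $y$ = trial mean + QTL dosage effects +
genotype + genotype-by-trial + block + residual, each term with its
stated variance; insect counts are Binomial(6, survival). Every
generator takes an explicit integer seed and restores the caller's RNG
state; no global randomness is used.

Problem sizes in the shipped checks — 50 images of 800 plant pixels, 50
REML replicates of 500 genotypes by 2 trials, a 10,000-SNP null scan and
100 planted-QTL scans of 300 progeny — were chosen as the smallest
designs at which the targeted biases (10% on variance components, 0.1 on
$H^2$) and rates (90% top-ranking) are comfortably resolved.

## Known limitations

* Synthetic images contain no lighting gradients, shadows, soil debris or
  transitional tissue colors; DTR/DQU agreement on them is by
  construction sharper than on real photographs.
* The REML engine targets small numbers of variance components with dense
  algebra; it is not built for tens of thousands of observations or
  complex residual structures (heterogeneous per-trial residuals, spatial
  row-column models).
* The association scan ignores kinship beyond the PC covariates;
  family-induced inflation is controlled only as far as the PCs capture
  it.
* Diploid dosages only; tetraploid dosage models are out of scope.
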