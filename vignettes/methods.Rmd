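---
title: "Methods: pedigree-GLS association mapping, cis-eQTL scanning and QTL-eQTL colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pedgls)
```

# The statistical model

## Single-marker GLS

Each variant is tested one at a time in the linear model
$y = \beta_1 + \beta_2 x + \varepsilon$, where $x$ is the alternative-allele
dosage centred to mean zero and the error covariance is

$$W = \sigma^2_P \left( h^2 A + (1 - h^2) I \right),$$

the phenotypic variance $\sigma^2_P$ partitioned into an additive genetic
component whose correlation structure is the pedigree-expected (numerator)
relationship matrix $A$, and an i.i.d. environmental remainder, weighted by
the narrow-sense heritability $h^2$. The GLS estimate, its standard error
and the association statistic are

$$\hat\beta = (X'W^{-1}X)^{-1} X'W^{-1} y, \qquad
  \mathrm{s.e.}(\hat\beta) = \sqrt{\mathrm{diag}\,(X'W^{-1}X)^{-1}}, \qquad
  \hat\chi^2 = \left(\hat\beta_2 / \mathrm{s.e.}(\hat\beta_2)\right)^2,$$

with $\hat\chi^2 \sim \chi^2_{1}$ under the null. Three modelling
assumptions are worth making explicit:

* **$h^2$ and $\sigma^2_P$ are inputs, not estimates.** Variance components
  for production traits are routinely estimated once with dedicated REML
  software and then treated as known during the scan; this package follows
  that practice. $\sigma^2_P$ defaults to the sample variance of the
  phenotype when not supplied. Because $W$ is treated as known, the test is
  a Wald test with fixed weights, not a profiled mixed-model test.
* **The design always contains an intercept** alongside the centred dosage;
  $\hat\beta_2$ is the allele-substitution effect in trait units per
  alternative allele.
* **Missing dosages are mean-imputed per variant inside the engine only**
  (the common GWAS convention for nearly complete, imputed data); I/O never
  persists imputed values, and the limitation is flagged where it matters:
  heavily missing variants should be removed by the call-rate filter
  beforehand.

## Numerics

$W$ is never inverted. `variance_model()` performs one symmetric
eigendecomposition of $K = h^2 A + (1-h^2) I$ per trait and stores the
whitening rotation $Z = D^{-1/2} U'$; each per-variant regression is then an
ordinary least-squares fit on rotated data, so a genome scan costs one
$n \times n$ by $n \times m$ multiplication plus $O(m)$ closed-form 2×2
solves. The contract, enforced by test, is agreement with literal inversion
of the full equations to 1e-10. Eigenvalues are floored at 1e-10 to absorb
roundoff in near-singular pedigrees (e.g. clones); $K$ must otherwise be
PSD, which the tabular-method $A$ guarantees.

A subtle and easy-to-miss trap: the whitener of a *subset* of animals is
not a column subset of the full whitener (the inverse of a submatrix is not
the submatrix of the inverse). A `variance_model` therefore refuses scans
whose animal set differs from the one it was built for, and
`subset_variance_model()` refactorizes from the stored $A$. Permutations
are accepted, since permuting a whitener is exact.

Monomorphic variants receive missing statistics rather than zeros — a zero
$\chi^2$ would silently deflate the genome-wide median used by the
inflation factor. P-values are stored at full precision and serialised in
scientific notation; ties in tag-variant selection break deterministically
by (p, chromosome, position).

## Inflation, thresholds, loci

The genomic-control inflation factor is $\lambda = \mathrm{median}(\chi^2) /
0.45494$, using the conventional printed constant for the theoretical
$\chi^2_1$ median. Bonferroni thresholds are $\alpha/n$. The
inflation-adjusted threshold converts the Bonferroni p-value to its
$\chi^2_1$ quantile, multiplies by $\lambda$, and converts back; because
genome-wide $\lambda$ in a well-powered production-trait study is driven
substantially by real polygenic signal, the adjusted threshold is reported
for comparison but never applied to downstream filtering unless requested.
The locus-prioritisation threshold is $1.5\times$ the Bonferroni exponent on
the $-\log_{10}$ scale, i.e. `bonferroni_p^1.5`.

Loci are defined greedily: the most significant remaining variant below the
threshold becomes a tag, claims a 1 Mbp window centred on itself, and
removes everything inside. Windows are half-open `[start, end)` internally;
coordinates are 1-based as in VCF, and the reported inclusive window end is
`start + width - 1`.

## Variance explained

The fraction of phenotypic variance attributed to a tag variant is
$2p(1-p)\beta^2/\sigma^2_P$ under Hardy–Weinberg and additivity, summed over
tags for cumulative summaries. The additivity of this convention is itself
tested against a joint-model $R^2$ on simulated independent tags (within
10% relative).

# Expression traits

Genes are kept when their mean count per animal strictly exceeds 8 — the
conventional "more than 8 exonic reads per animal" floor. Whether that
phrase means a cohort mean or a per-animal minimum is genuinely ambiguous;
the mean reading is used (a per-animal minimum is far stricter in large
cohorts where a single zero kills a gene) and the floor is a parameter.

The variance-stabilising transformation is the closed form for
negative-binomial counts with common dispersion $\alpha$:

$$y = \frac{2}{\sqrt\alpha}\,\mathrm{asinh}\,\sqrt{\alpha\, x / s},$$

with $s$ the sample's median-of-ratios size factor (genes containing any
zero are skipped when forming the reference geometric means). For
$\mathrm{NB}(\mu, \alpha)$ data this makes the variance approximately
independent of $\mu$; the tests verify the per-gene variance of transformed
values stays within 3-fold across gene means spanning 10–10,000 while raw
variances span > 100-fold. A spline-based VST fitted per dataset (as the
established count-model packages provide) would adapt to non-constant
dispersion; the closed form was chosen because it is transparent,
parameter-light, exactly monotone, and every downstream consumer in this
package is calibrated on its own synthetic counts. When `dispersion =
"estimate"`, a method-of-moments common dispersion (median across genes of
$(\widehat{var} - \bar x)/\bar x^2$ on normalised counts) is used; note
both estimators are degenerate on a single-gene matrix, in which case the
known simulation parameters (or any externally estimated values) should be
passed explicitly.

Sample outliers are removed in a single PCA pass (samples as observations,
first 6 components, |score| > 3 SD); iteration is deliberately not
performed, so the excluded set is a deterministic function of the input.
The screen runs on VST values rather than FPKM — a documented divergence
from the reference procedure, avoiding a second normalisation pipeline that
nothing downstream would use.

cis-eQTL scans reuse the GLS engine unchanged with the gene's transformed
expression as the phenotype, over the variants of a 1 Mbp window, on the
intersection of genotyped, expressed and pedigreed animals. Expression
traits default to the supplied trait $h^2$; per-gene heritabilities are not
modelled.

# Colocalization and triage

If a trait QTL and a cis-eQTL respond to the same causal element, their
per-variant association statistics should rise and fall together across the
window. The co-segregation score is the Pearson ($r$) and Spearman ($\rho$,
average ranks on ties) correlation of paired $\chi^2$ vectors over variants
with finite statistics in both scans, dropped pairwise otherwise. LD is the
squared Pearson correlation of dosage vectors (composite LD — correct for
unphased data, and what genotype-based LD software computes).

A gene is triaged as a candidate when any rule fires, with all firing
reasons recorded: a protein-altering variant in LD $r^2 > 0.9$ with the QTL
tag; a significant eQTL with $r > 0.7$ or $\rho > 0.7$; or a significant
eQTL whose top variant has $r^2 > 0.9$ with the QTL tag. The eQTL
significance gate is configurable because the reference values for it are
internally inconsistent at the source (a genome-wide $2.53\times10^{-7}$ in
one place, $2.59\times10^{-8}$ in another); the former is the default,
neither is hard-coded as correct.

# The synthetic population

The generator produces the statistical structure every other module
assumes, not demographic realism:

* **Pedigree**: two labelled founder breeds, discrete non-overlapping
  generations, sexes alternating deterministically, sire/dam drawn from the
  previous generation. A lineage label (breed, or "X" once mixed) steers
  matings: with the configured crossbreeding probability a mating
  deliberately crosses lineages, otherwise it stays within one. Defaults
  (HF + J founders, crossbreeding 0.2) echo a mixed Holstein-Friesian /
  Jersey / crossbred herd structure.
* **Allele frequencies**: ancestral frequencies uniform on (0.05, 0.95);
  breed frequencies are Balding–Nichols Beta draws with divergence
  $F = 0.1$, of the order of the HF–Jersey differentiation and sufficient
  to reproduce the marked between-breed tag-variant frequency differences
  the method must tolerate.
* **LD**: haplotypes come from a latent Gaussian AR(1) copula
  ($\rho = 0.9$ between adjacent markers, reset at chromosome boundaries),
  giving the exponentially decaying local LD that multi-variant association
  "skylines" — and hence the colocalization statistic — require. This is
  orders of magnitude cheaper than coalescent simulation and is the main
  deliberate unrealism: no long-range LD, no allele-frequency/LD coupling,
  no mutation-age structure. A green colocalization test therefore
  establishes behaviour under smooth local LD, not under every real LD
  topology.
* **Gene drop**: founders take haplotype pairs from their breed pool;
  every gamete recombines with a Poisson(map length) crossover count at
  uniform positions. Mendelian consistency of trios is therefore exact by
  construction, which the concordance checker verifies as a property.
* **Phenotypes**: $y = \sum_j \beta_j (x_j - \bar x_j) + u + e$ with
  polygenic $u \sim N(0, (h^2\sigma^2_P - \sum_j 2p_jq_j\beta_j^2)\,A)$
  drawn through a Cholesky factor of $A$, and i.i.d.
  $e \sim N(0, (1-h^2)\sigma^2_P)$. Planted QTL count against the additive
  budget; configurations exceeding it error rather than silently rescale.
  Trait defaults ($h^2 = 0.557$, $\sigma^2_P = 0.0189$) are the
  lactose-concentration-like values of the target study's summary table;
  the yield-like alternative ($h^2 = 0.253$, $\sigma^2_P = 0.0147$) is one
  constructor call away.
* **Expression**: counts are $\mathrm{NB}(s_i\,e^{\mu + b g_{ij}}, \alpha)$
  with size factors uniform on (0.75, 1.33), dispersion $\alpha = 0.1$
  (typical of bulk RNA-seq after technical normalisation), baseline mean
  200 reads and allelic log-fold $b = 0.5$ for planted cis-eQTL; the
  expression cohort is a subset of the phenotyped animals, as in studies
  where only part of the genotyped population is RNA-sequenced.

Everything is reproducible bit-for-bit from `(config, seed)`: one RNG
stream seeded once, consumed in documented order (pedigree, founder
haplotypes, gene drop, phenotype, expression).

# What the acceptance world does and does not establish

The heavier acceptance criteria run on one cached population: n = 2,000
animals from 60 founders over four generations, 5,000 markers on a
10 Mbp / 1 Morgan chromosome, F = 0.1, LD $\rho$ = 0.9, trait $h^2 = 0.5$.
On this world the GLS scan is calibrated ($\lambda \in [0.9, 1.1]$; observed
≈ 1.05) while a naive OLS scan on identical data inflates to $\lambda
\approx 3$ — the covariance correction is doing real work, since the
60-founder base makes relatedness pervasive. Planted-effect recovery and
colocalization discrimination are measured over 50 replicates that redraw
phenotypes, expression and noise on the fixed genome; this isolates the
estimator properties being tested and keeps the suite fast, at the price of
not averaging over genome realisations. Replicate-level conclusions are
therefore conditional on one (representative) genome draw — the standard
trade-off in simulation studies of this size.

Two spec-level measurement choices deserve a note. The type-I
rejection-rate band is binomial, which presumes independent tests; it is
evaluated on LD-thinned markers (every 50th, ≈100 kb apart) rather than on
the full correlated panel. And the relationship-matrix invariant (rank
correlation > 0.9 between $A$ and empirical genotype covariance at 10k
markers) holds as stated only when realized relationships can concentrate
around their pedigree expectation — a 20-chromosome genome — and when
genotypes are standardized by the known founder frequencies; one
chromosome leaves too much Mendelian-sampling variance, and
sample-frequency standardization is confounded by founder drift. Both are
implemented that way, with the reasoning in the test files.

# Known limitations

* No REML/GREML variance-component estimation, no genomic relationship
  matrix, no multi-trait or repeated-measures models; phenotypes are
  assumed pre-adjusted.
* Mean imputation of missing dosages is a stand-in for the fully imputed
  data the method normally consumes.
* The Mendelian-concordance exclusion rule (opposite-homozygote rate,
  default threshold 0.02) is an assumption where the reference procedure
  left its statistic unstated; it is configurable and recorded in output.
* The closed-form VST assumes a common NB dispersion; strongly
  gene-specific dispersion will leave residual mean-variance trend.
* The simulator's LD and demography are deliberately stylised (above); it
  is a testbed, not a population-genetic forecast.
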