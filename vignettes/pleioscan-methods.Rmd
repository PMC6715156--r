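---
title: "Haplotype scans, pleiotropy and mediation for microbiome-metabolite genetics"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype scans, pleiotropy and mediation for microbiome-metabolite genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

# What the package does

`pleioscan` implements the statistical workflow used to connect host
genetics, gut microbial abundances and bile-acid levels in a Diversity
Outbred (DO) style multiparent mouse population: trait preparation, founder
haplotype genome scans with a linear mixed model, permutation thresholds,
detection of co-mapping microbe-metabolite QTL pairs, a pleiotropy-versus-
two-loci likelihood ratio test with parametric bootstrap, and bidirectional
mediation with causal model selection.  Because suitable genotype/trait data
of this kind are rarely public, the package ships a first-class synthetic
data module with known ground truth; every statistical claim made by the
test suite is a claim about recovery of that truth.

# The mapping model

At a marker $m$ the phenotype of individual $i$ is modeled as

$$ y_i = \mu + x_i^\top \beta + \sum_{f=1}^{8} d_{imf}\, a_f + u_i +
\varepsilon_i, \qquad u \sim N(0, \sigma_g^2 K^{(-c)}), \quad
\varepsilon \sim N(0, \sigma_e^2 I), $$

where $d_{imf}$ is the expected number of alleles inherited from founder
$f$ (0-2, the eight columns summing to 2), $x_i$ are additive covariates
(sex, wave, days on diet), and $K^{(-c)}$ is the kinship matrix computed
with the scanned chromosome left out (LOCO), so the polygenic term cannot
absorb the signal of the chromosome being scanned.  The variance ratio
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$ is estimated once per
(trait, chromosome) by REML under the null and held fixed across markers --
the standard speed/accuracy compromise in multiparent mapping -- and each
marker is then a generalized least squares fit.  The mapping statistic is
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$.

Identifiability: with an intercept the eight dosage columns are collinear
(they sum to 2), so fits drop one founder column; reported founder allele
effects are re-expressed in the sum-to-zero parameterization, which treats
the eight strains symmetrically.  When the REML profile is flat in $h^2$
(e.g. $K = I$) the boundary convention $h^2 = 0$ is used.

Significance comes from permutations that shuffle phenotype-with-covariate
rows against genotype rows (preserving the trait-covariate association) and
record the genome-wide maximum LOD.  Thresholds are pooled across
phenotypes, as in the study design this package follows; with
`pooled = TRUE` the `n_perm` argument is the *total* number of pooled
permutation maxima, spread as evenly as possible across the supplied traits.
Support intervals are 95% Bayes credible intervals: the posterior over the
chromosome grid is proportional to $10^{\mathrm{LOD}}$ and the interval
grows symmetrically outward from the peak until it holds the target mass.
This interval is known to be approximate; a dedicated simulation in the
test suite checks only that its coverage is within a broad, honest band.

# Trait preparation

Microbial counts pass through: prevalence filter (feature present in at
least 20% of individuals, inclusive -- the "core measurable microbiota"),
optional taxonomic agglomeration (summing Greengenes-style lineage
prefixes, with explicit `unclassified-<parent>` buckets), cumulative sum
scaling (CSS), then a rank-based inverse normal transform (RINT).  The CSS
scaling factor for sample $j$ is the sum of its counts at or below its
`quantile_l` quantile of *positive* counts; the default $l = 0.5$ and the
output scale constant 1000 are exposed in the configuration.  Since the
downstream RINT is rank-based, the scale constant cannot affect mapping,
only report readability.  RINT uses the Blom offset $c = 3/8$ with average
ranks for ties.

Metabolite peak areas are normalized to the internal standard (d4-CDCA):
$\mathrm{out}_{ij} = (\mathrm{area}_{ij} / \mathrm{IS}_j)\cdot
\overline{\mathrm{IS}}$, then $\log_2$ transformed (pseudo-count 0 by
default, as areas are strictly positive after the internal-standard step).
Clinical traits are RINT transformed.  The correlation screen between trait
classes is Spearman (average ranks, pairwise-complete) with Benjamini-
Hochberg adjustment over all tested pairs, retaining pairs with
FDR $< 0.01$ and $|\rho| > 0.35$ by default.

# Pleiotropy versus two linked loci

For two traits mapping to the same region, the null of one shared locus is
tested against the alternative of two distinct loci.  Over every ordered
position pair $(\lambda_1, \lambda_2)$ in the scanned interval, trait 1 is
regressed on the dosages at $\lambda_1$ and trait 2 on those at
$\lambda_2$, with shared covariates and an unstructured $2\times 2$
residual covariance (iterated feasible GLS from $\Sigma = I$; all
quantities are assembled from cross-products, so the per-cell cost is
independent of sample size and the grid loop is implemented in C++).  The
statistic is

$$ \mathrm{lrt} = \max_{(\lambda_1,\lambda_2)} \ell_{10}(\lambda_1,\lambda_2)
 - \max_{\lambda} \ell_{10}(\lambda,\lambda) \ \ge 0, $$

in $\log_{10}$ units, with $\ell_{10} = -(n/2)\log_{10}\det\hat\Sigma$.
Significance is by parametric bootstrap from the fitted pleiotropic null at
the diagonal argmax (where both equations share regressors, so the SUR fit
reduces to per-equation OLS), with the plus-one estimator
$p = (1 + \#\{\mathrm{lrt}_b \ge \mathrm{lrt}_{obs}\})/(B+1)$.
Non-convergent replicates are counted as exceedances and reported, never
dropped.  Kinship is omitted from the bivariate model by default; the
covariates absorb the main structure and the reference analysis does not
state that its pleiotropy run used kinship.  The full ordered grid is
scanned (no symmetry shortcut) so that the transposition property can be a
test rather than an assumption.

**A boundary statistic.**  The lrt is a maximum over a grid containing the
null's own diagonal, so under pleiotropy it equals exactly 0 whenever both
traits' profile maxima land on the same marker -- which is the *typical*
outcome on a coarse grid with tightly linked markers.  Its null
distribution therefore has an atom at zero and the bootstrap p has a
matching atom at one.  Consequently p cannot be two-sided uniform under the
null; what a valid bootstrap p must satisfy -- and what the tests check --
is one-sided calibration: $\hat P(p \le \alpha)$ does not exceed $\alpha$
beyond Monte-Carlo error.  Calibration simulations use a 0.5-cM grid
(echoing the fine pseudomarker grids used in practice) and moderate effect
sizes so the statistic is non-degenerate; on a 2-cM grid with strong
shared QTL the lrt is 0 almost surely and the test, while valid, is
extremely conservative.

# Mediation and causal model selection

A mediator-adjusted rescan adds the candidate mediator as an additive
covariate and reports the LOD at the QTL before and after; drops greater
than 2 pass the screening criterion, negative drops are flagged rather than
clipped, and a mediator collinear with the existing covariates is an error
rather than a silent double-fit.  Only individuals with both trait values
are used.

Causal model selection scores four directed models at the locus by BIC,
each a product of Gaussian regressions given the 8-founder dosage $Q$ and
covariates:

* M1 causal: $f(M\mid Q)\, f(T\mid M)$
* M2 reactive: $f(T\mid Q)\, f(M\mid T)$
* M3 independent: $f(M\mid Q)\, f(T\mid Q)$
* M4 full: $f(M\mid Q)\, f(T\mid Q, M)$

The verdict is the best model's label, with two deliberate conservatisms:
a tie band (gap of the top two BIC scores below 2 gives "undecided"), and
M4 itself mapping to "undecided" -- when the full model wins, the direction
is not identified.  This is a BIC-scored simplification of the published
causal model selection test (which uses penalized-likelihood pairwise
z-tests); the locus genotype enters as the 8-column allele dosage rather
than a biallelic SNP, matching the rest of the pipeline.  Note that the
"independent" generating model here means *both* traits driven by the same
locus with no trait-trait edge -- i.e. exactly the pleiotropic
architecture of the synthetic-data module.

# The synthetic-data module

Genomes: each individual carries two founder mosaics per chromosome;
founder switches follow a homogeneous Poisson process on the cM scale
(default 0.2 switches/cM per haplotype, chosen once to approximate the
block structure after ~20 outbreeding generations; the true DO
recombination density is not published, so this is a documented knob, not a
claim).  After a switch the new founder is drawn from the other seven,
avoiding phantom zero-length blocks.  HMM-style dosage uncertainty can be
emulated by mixing each slice with a symmetric Dirichlet draw (weight 0.05
when enabled; off by default so oracle tests see hard mosaics).  The X
chromosome is not simulated; autosomes are labeled "1".."19".

Traits: latent value = scaled QTL term + polygenic term (covariance
$\propto$ overall kinship) + noise on a unit variance budget
(`qtl_var + h2 + residual = 1`), plus optional covariate effects.
Microbial counts are negative binomial (log link, default size 2, base mean
100) with **one** log-normal sequencing depth per individual shared across
all microbial traits -- a per-sample property, and the reason CSS can remove
it; requested prevalence is hit exactly by zeroing the lowest-latent
individuals.  Metabolites are log-normal peak areas sharing a per-sample
injection factor with a simulated d4-CDCA internal-standard channel, so
the internal-standard normalization genuinely removes the nuisance.  Days on diet
are uniform on 147-175 (21-25 weeks); waves are up to five levels; one
global seed fans out deterministically to per-component child seeds.

Trait pairs are generated under five architectures: `pleiotropic` (one
shared locus), `linked` (two loci), `causal` ($Q \to a \to b$ with no
direct edge), `reactive` (the mirror), and `independent` (distinct loci on
possibly different chromosomes).

What the generator does *not* emulate: pedigree-accurate DO breeding,
sex-chromosome inheritance, compositional coupling between taxa (counts are
conditionally independent given depth), taxonomic correlation structure,
batch effects beyond the wave covariate, or heavy-tailed LC-MS noise.
Passing tests therefore demonstrate correct recovery under the stated
generative assumptions, not performance on real data.

# Numerical choices and degenerate inputs

* REML for $h^2$ via eigendecomposition and 1-D optimization on
  $[0, 0.999]$; flat profiles return the boundary 0.
* LOD values are clamped at 0 against floating-point negatives; a constant
  (or fully covariate-explained) phenotype scans to LOD 0 everywhere.
* The bivariate grid floors $\det\hat\Sigma$ at $10^{-12}$ of its scale so
  duplicated traits (singular residual covariance) yield a finite surface
  maximized on the diagonal, hence lrt 0, rather than overflow.
* Peak merging keeps the higher of two local maxima closer than 10 cM
  (default); Bayes intervals around secondary peaks grow from that peak.
* Trait-wise complete-case analysis; two-trait modules use pairwise
  complete observations.
* Closed-interval overlap for co-mapping (touching endpoints count):
  support intervals are approximate, so the rule is deliberately generous.

# Problem sizes used by the checks

The packaged checks run at sizes chosen to make the Monte-Carlo bands tight
enough to be meaningful on a single CPU: oracle equivalence on 50 datasets
(n = 100, 200 markers); threshold calibration with 100 null traits and 200
pooled permutations at n = 150; QTL recovery over 200 replicates at
n = 400; pleiotropy type-I over 100 pairs and power over 20 pairs with
B = 200 bootstrap replicates; mediation over 40 full-mediation and 100
null replicates; causal-model-selection accuracy over 100 replicates per
architecture.  The end-to-end demo plants one pleiotropic
microbe-metabolite pair in 200 individuals over five chromosomes with 20
background microbes and 4 background metabolites, strong planted effect
(half the latent variance), and verifies that the pair is reported as
co-mapped, that the bootstrap does not reject pleiotropy, and that a rerun
is byte-identical.

# Known limitations

* The causal model selection is a BIC variant, not the published penalized
  z-test procedure; verdict frequencies, not p-values, are its output.
* The pleiotropy test's conservatism on coarse grids is intrinsic to the
  boundary statistic (see above); use fine pseudomarker grids in the
  scanned interval.
* Permutation thresholds assume exchangeable individuals; strong family
  structure would call for stratified permutations, which are not
  implemented.
* No X-chromosome handling, no SNP-imputation association scans over
  founder variant catalogs, and no interactive-covariate scans.
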