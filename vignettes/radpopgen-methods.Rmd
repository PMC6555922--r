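---
title: "Models and methods behind RadPopGen"
author: "RadPopGen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind RadPopGen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

RadPopGen analyses diploid biallelic SNP panels from
reduced-representation sequencing of structured populations: a quality
filter cascade, diversity and differentiation statistics,
maximum-likelihood admixture, approximate Bayesian computation (ABC)
for choosing among introduction scenarios, three complementary
selection scans, and sliding-window scans for genomic islands of
differentiation. This vignette explains the models, the defaults and
the numerical choices; it states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

# The data container

`GenotypeData` extends `RangedSummarizedExperiment`: the `dosage` assay
holds alternate-allele counts (0/1/2, `NA` for a missing call) with
loci in rows and individuals in columns; `rowRanges` carries scaffold
coordinates and RAD-tag ids; `colData` carries the population map
(population, river-system group, native/introduced flag); the site
covariate table (latitude, longitude, annual mean temperature) lives in
`metadata()`. Every locus filter is a subset operation on this object,
so filters are pure projections and never alter surviving genotypes.
Coordinates are 1-based in all files (VCF convention); window
arithmetic converts to half-open `[start, end)` intervals at a single
boundary.

# The synthetic study design

All statistical guarantees are exercised on synthetic data whose
generator (`simulateMetapopulation()`) emulates a river-system survey:
six native populations in three clusters, one admixed northern
population combining all three clusters (proportions 48.8/43.6/7.5
before normalisation), and three introduced populations founded
through a bottleneck from a 50/50 admixture of the two southern
clusters. Sample sizes default to 22 diploids per population (21 in
one), 197 in total.

Allele-frequency drift along each branch is the Balding–Nichols
construction: the child frequency is Beta-distributed with mean equal
to the parent frequency $p$ and variance $c\,p(1-p)$, so the branch
parameter $c$ *is* the expected Weir–Cockerham $F_{ST}$ between parent
and child — an analytic oracle that the tests exploit. Defaults
$c_\text{among} = 0.03$ and $c_\text{within} = 0.012$ put native–native
$F_{ST}$ at the few-percent level; the founder effect of an
introduction of $N_m$ diploids lasting $d_b$ generations adds the
Wright–Fisher increment $c_f = 1 - (1 - 1/2N_m)^{d_b}$ (defaults
$N_m = 100$, $d_b = 30$, $c_f \approx 0.14$), which reproduces the
order-of-magnitude gap between native–native and native–introduced
differentiation that such surveys report. Annual mean temperature is
an affine function of latitude plus Gaussian noise (sd 0.3 °C), so the
strong temperature–latitude collinearity of a 30°-latitude design is
present. Planted selection classes: *clinal* loci follow
$\mathrm{logit}(p_j) = \mathrm{logit}(p_0) + s\,\tilde z_j$ with
$\tilde z_j$ the standardized latitude (default slope $s = 2$);
*divergent* loci multiply branch drift by an inflation factor;
*balanced* loci draw all population frequencies from a Beta centred at
0.5 with small variance. Truth labels are kept in `metadata()` and
survive any filter because locus ids are stable.

What the generator does **not** emulate: linkage disequilibrium between
tags, genotyping-error or allele-dropout structure, depth-dependent
missingness, and within-population relatedness. Passing tests
therefore demonstrate correctness of the estimators and calibration
under the stated sampling models, not robustness to those artefacts.

RAD-tag layout: tags are placed uniformly on 24 scaffolds (9.6–19.1
Mb); SNPs per tag are Poisson with configurable mean (0.61 by default,
the regime where most tags carry no SNP), truncated at the 100 bp tag
length; within-tag offsets are distinct positions inside the tag.

# Filter cascade

The cascade applies, in order: per-population call rate (strictly
greater than 0.7 in *every* population), paralogous-tag removal, one
SNP per tag, and per-population exact Hardy–Weinberg tests; the marker
subset for demographic inference additionally applies overall
missingness ≤ 0.05, pooled MAF strictly > 0.05, and greedy LD pruning.
Choices worth stating:

* **Paralog rule.** A whole tag is dropped when any of its SNPs has
  more than two alleles *or* observed heterozygosity above 0.5. The
  two conditions are independent symptoms of collapsed paralogues and
  a >2-allele site cannot be represented as a biallelic dosage anyway,
  so the disjunction is the default; the literal conjunction is
  available via `rule = "and"`.
* **HWE test.** With ~20 diploids per population, the chi-square
  approximation is unusable, so the exact conditional test is used:
  the Levene/Haldane distribution of the heterozygote count given the
  allele counts, two-sided by summing probabilities not exceeding the
  observed one. A locus deviating at $\alpha = 0.01$ in *at least one*
  population is removed (`scope = "any"`); this inclusive reading
  matches the purpose of purging null-allele tags, and the
  exactly-one reading remains available (`scope = "one"`).
* **LD pruning direction.** Markers are *removed* when genotype
  $r^2 \ge 0.05$ against an already-kept locus within a 500 kb window,
  i.e. a low-LD panel is retained — the behaviour consistent with
  keeping a few thousand quasi-independent markers for ABC.
* Thresholds are strict inequalities at the boundary: a call rate of
  exactly 0.70 or a MAF of exactly 0.05 removes the locus.

# Diversity, differentiation, distance

$H_O$ is the fraction of heterozygotes among genotyped individuals;
$H_E$ is the unbiased $2\hat p(1-\hat p)\,2n/(2n-1)$; per-variant-site
nucleotide diversity equals $H_E$ at a biallelic site (the average
proportion of differing pairs among the $2n$ sampled alleles) and is
averaged over variant sites only. $F_{ST}$ is fixed to Weir–Cockerham
$\theta$ throughout the package — one estimator keeps the filter,
scan, ABC and window stages coherent — with multi-locus values as the
ratio of summed variance components. Pairwise significance is an
individual-permutation test of $\theta$ with
$p = (1 + \#\{\theta^* \ge \theta\})/(B+1)$ and Bonferroni flags at
$\alpha$ divided by the number of pairs. Gene flow uses the
island-model inversion $N_m = (1/F_{ST} - 1)/4$. Isolation by distance
correlates $F_{ST}/(1-F_{ST})$ with great-circle distance (the sites
span ~30° of latitude, so planar distance is offered only as an
option) through a Mantel test with simultaneous row/column
permutations, one-sided for positive association, reporting $R^2 =
r^2$. Nei's standard distance sums gene identities over loci before
taking logs; trees are neighbour-joining (via `ape`) with support from
bootstrap over loci. PCA uses the allele-frequency normalisation
(centre by $2\hat p$, scale by $\sqrt{\hat p(1-\hat p)}$,
mean-imputation of missing entries).

# Admixture model

`fitAdmixture()` maximizes the standard binomial admixture likelihood
over row-stochastic ancestry fractions $Q$ and cluster frequencies
$F$. The maximizer is EM over allele-copy responsibilities with
SQUAREM extrapolation (two EM steps, a squared extrapolated iterate,
one stabilizing EM step; any cycle that fails to improve the
likelihood falls back to the plain double step), which preserves the
monotone likelihood trace while converging an order of magnitude
faster than plain EM near the boundary. Restarts (default 5) guard
against local optima. Cross-validation masks random folds of observed
genotype entries (not individuals) and scores masked entries by
squared deviance against $2\sum_k q_{ik}f_{kl}$; the K with the lowest
error is reported, and near-ties are left visible in the returned
table rather than auto-resolved.

A property of the *estimator itself* worth knowing: at weak
differentiation ($F_{ST}\approx 0.05$) with a few thousand loci and ~20
individuals per population, the global maximum-likelihood solution
assigns unadmixed individuals ancestries around 0.9 rather than 1 —
the likelihood is genuinely higher at that interior point than at the
truth vertex (the test suite verifies this by direct likelihood
comparison), so ancestry fractions carry a shrinkage bias of order
0.05–0.1 under these conditions regardless of optimizer. The
acceptance suite reports the resulting recovery error honestly rather
than tuning around it.

# ABC origin tracing

Three competing scenarios for an introduced population I with source
candidates A and B: founding from an admixed population (created at
$t_2$ with proportion $r$ from A), founding directly from A, or
directly from B; all share a deeper A/B split at $t_3$ and a founder
bottleneck of size $N_m$ for $d_b$ generations after founding. Priors
are uniform with the ordering constraints $t_3 > t_2 > t_1 > d_b$ and
$N > N_m$; sizes 10–10,000, recent times 1–150 generations, deep split
10–10,000. Times are interpreted as generations (the alternative —
years with a generation-time conversion — would only rescale the
priors).

The per-locus simulator is a coalescent with one segregating site per
locus placed on a branch chosen proportional to branch length —
matching the ascertainment of a SNP panel — implemented in C++ and
cross-checked in the tests against msprime genealogies under the same
one-site protocol (mean diversity and $F_{ST}$ within Monte-Carlo
error for three parameter sets). Summary statistics are computed from
per-population allele counts: genic diversity mean and variance,
pairwise $\theta$ (heterozygosity terms at their random-pairing
expectation so the statistic is a pure function of counts), pairwise
Nei distance, and pooled-MAF deciles — 21 statistics for three
populations, the same code path for observed and simulated data. The
statistic panel is configurable; the reference implementation of this
kind of analysis uses a fixed 52-statistic panel for this design, but
the panel composition is not fully enumerable from the outside, so
RadPopGen documents its own.

Model choice retains the 1% of simulations closest in standardized
Euclidean distance and fits a multinomial logistic regression of the
scenario on statistic differences; the posterior probability is the
fitted value at zero difference with a delta-method CI (a bootstrap
CI was considered and rejected on speed grounds; the regression CI is
reported with the retained-set size). Type I/II errors come from
re-classifying pseudo-observed datasets. Parameter posteriors use
local-linear adjustment on transformed scales (log for sizes and
times, logit for $r$); model checking projects the observed statistics
onto the principal components of the reference table.

Desk-scale defaults: the acceptance suite uses 12,000 reference
simulations of 1,000 loci with 10 diploids per population and 60
pseudo-observed datasets per scenario (the acceptance script 6,000
and 20); a full-scale run ($10^6$ simulations of ~3,000 retained
markers) is a configuration change, not a code change. Two
scale-dependent points deserve emphasis. First, the retention
*fraction* should be chosen so that a few hundred simulations are
retained: the canonical 1% presumes a very large reference table, and
local-linear posteriors built from only a few dozen retained draws
undercover. Second, parameter identifiability has a physical limit:
when the founder bottleneck is severe enough that the introduced
sample coalesces to a handful of lineages before reaching the
admixture event, the admixture proportion is genuinely unidentifiable
and the competing scenarios converge; recovery studies (and real
inferences) are only meaningful in the regime where the bottleneck
leaves the signal intact, which is how the coverage and assignment
checks are posed.

# Selection scans

**Environmental association.** Population allele frequencies are
standardized as $y_j = (\hat p_j - \bar p)/\sqrt{\bar p(1-\bar p)}$;
the neutral covariance $\Omega$ of these deviations is estimated by a
Gibbs sampler (conjugate normal latent deviations, inverse-Wishart
draws for $\Omega$) whose posterior mean and thinned draws are kept.
The Bayes factor per locus compares
$y \sim N(\beta z, \Omega + D)$ — $z$ the standardized covariate, $D$
the binomial sampling variance, $\beta$ integrated over a Gaussian
prior on a quadrature grid — against $\beta = 0$. This Gaussian
approximation with numerical $\beta$ integration preserves the
covariance-controlled contract of the full MCMC treatment at a small
fraction of its cost. The prior scale (default sd 0.2) is set from
the analytic null floor $\mathrm{BF}_{\min} =
(1 + c_0\sigma_\beta^2)^{-1/2}$ with $c_0 = z'\Sigma^{-1}z$: a locus
perfectly consistent with the null then stays inside Jeffreys'
inconclusive band $[1/3, 3]$ for typical panel precisions, while
power for clinal slopes of order 1 is essentially unaffected. The
scan runs five times with independent $\Omega$ draws; significance
(BF > 3) must hold in every run, and latitudinal candidates must be
significant for both temperature and latitude.

**Hierarchical island outliers.** The null is a finite hierarchical
island universe (10 groups × 100 demes) simulated by a structured
coalescent. Because demes within a group are exchangeable, the chain
is lumped over co-location clusters of lineages; migrations of a
singleton lineage to an empty deme of its own group leave the lumped
state unchanged and are skipped, which removes the overwhelming
majority of events at realistic migration rates and makes 10⁴–10⁵
null loci affordable. Within- and among-group migration rates are
calibrated to the observed global $\theta$ and among-group
differentiation by damped fixed-point iteration on the linearized
scale ($F/(1-F)$ is approximately inverse in the migration rate); the
calibration trace is attached to the result. Each observed locus is
placed at its conditional $\theta$ quantile given its
heterozygosity bin (20 quantile bins; mid-quantiles against ties);
flags require quantile > 0.995 *and* Benjamini–Hochberg FDR ≤ 0.01
(the FDR procedure is BH, the stated rate having no named procedure
attached in the source methodology), with the symmetric low tail
flagging balancing candidates.

**F-model.** `fmodelOutliers()` samples the Bayesian F-model —
$\mathrm{logit}(F_{ST}^{lj}) = \alpha_l + \beta_j$ with beta-binomial
allele-count likelihood — by reversible-jump MCMC over inclusion of
the locus effects, proposing $\alpha$ from its prior (so the jump
acceptance reduces to a likelihood ratio times the prior odds,
default 10:1 for neutrality). q-values are running means of the
posterior error down the ranked list; outliers at q ≤ 0.05 are
classified positive or balancing by the sign of $\alpha$. Mixing is
monitored through the effective sample size of the population effects
(warning below 50). Chain defaults (4,000 iterations, 1,000 burn-in)
are desk-scale; the error-control test in the acceptance suite runs
10⁴ neutral loci.

The whole-versus-reduced protocol (with and without flagged admixed
migrants) and leave-one-out reruns are first-class operations
returning common-locus counts and stability proportions.

# Genomic windows

Windows are tumbling by default (step = size; any step is accepted —
the source methodology states only window sizes, so non-overlapping
tiling is the least-assuming choice, with step sensitivity exposed as
configuration). A window's $\theta$ is the mean of per-locus
Weir–Cockerham $\theta$ between two pooled river-system groups over
SNPs in `[start, end)`, defined only when at least 3 SNPs are
informative. Islands are maximal runs of adjacent windows exceeding
the background mean by $z$ SDs (default $z = 3$; the elevation rule is
z-score-based because "higher than average" needs an operational
definition) that contain at least a minimum number of outlier SNPs; a
single background window breaks a run. SNP density per window and a
Spearman correlation diagnostic (with permutation p) check that
differentiation patterns are not density artefacts.

Window depth matters for both diagnostics. Per-locus $\theta$ is
right-skewed, so means over very few SNPs are noisy *and* skewed: with
shallow windows the maximum z-score across many windows exceeds 3
frequently even on neutral data (with 60 windows this happens in
roughly a third of genomes for perfectly normal window means), and the
skew induces a small positive rank correlation between window mean
$\theta$ and SNP count. Island calling and the density diagnostic are
therefore meaningful only at adequate depth; the shipped checks use
windows of ~20–100 SNPs, and `min_snps` exists precisely to keep
under-populated windows out of the background distribution.

# Numerical and reproducibility notes

* Every randomized stage takes an explicit seed; C++ samplers draw
  from R's RNG, so `set.seed()` makes simulation, MCMC and permutation
  results bit-reproducible.
* Degenerate inputs have defined behaviour: monomorphic loci give HWE
  p = 1 and are excluded from $\theta$ sums; zero-variance pairs have
  $r^2 = 0$ in pruning; constant covariates and constant distance
  matrices are errors; a constant-density window table reports a
  flagged zero correlation.
* Ties: the first SNP of a tag at equal positions is broken by locus
  id; conditional quantiles in the island test use mid-ranks; equal
  cluster-label votes in `labelClustersByGroup()` are a hard error
  rather than a silent choice.
* Problem sizes in the shipped tests (reference-table size, null-locus
  counts, chain lengths, numbers of seeds) are the package's
  desk-scale defaults chosen to keep the full suite runnable on a
  single CPU; all are arguments, and scaling them up changes no code
  path.

# Known limitations

* The admixture ancestry shrinkage at weak differentiation described
  above is a property of the maximum-likelihood estimator, not of the
  optimizer; a penalized or informative-prior variant would trade bias
  for calibration and is out of scope.
* Relatedly, when one ancestry cluster is anchored by only a handful of
  pure individuals (e.g. a single admixed population whose residents are
  the sole representatives of their river system), the under-constrained
  cluster's frequencies drift toward the migrants' composite profile and
  absorb part of their ancestry: population-mean composition estimates
  then carry a systematic bias of roughly 5-10 points for the
  under-anchored component. This is inherent to unsupervised
  maximum-likelihood admixture, affects the reference tools identically,
  and is why the synthetic design keeps a pure-resident component in the
  admixed population at all — without it the decomposition is not
  identifiable.
* The environmental-association model approximates allele-frequency
  likelihoods as Gaussian in standardized deviations; at extreme
  frequencies (pooled MAF near the 0.05 filter boundary) the
  approximation is coarser, which is one reason the scan is always run
  on MAF-filtered panels.
* The ABC simulator models unlinked loci; linked-marker designs would
  need a recombination-aware simulator.
* The hierarchical island null fixes the universe at 10 × 100 demes;
  misspecification of the group number is not corrected for, matching
  standard practice for this test.
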