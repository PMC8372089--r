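---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fragpop` implements a complete population-genomic workflow for asking
whether the genetic structure observed in river fish sampled above and below
a barrier (a dam) is consistent with divergence *since* the barrier was
built, or must predate it. This vignette documents the statistical models,
the estimators, the synthetic-data generator that stands in for real RADseq
genotypes, and the places where the design was genuinely open.

## The genotype model and quality control

Genotypes are biallelic SNP dosages (0, 1, 2 copies of the alternate
allele) for individuals at loci grouped on RAD tags, with optional
per-genotype read depths. Missing genotypes are a first-class sentinel
(`NA`), never a silent zero; a call with total read depth zero must be
missing, and the container enforces this.

The QC chain runs in a fixed order, each stage acting on its predecessor's
output: (1) loci genotyped in fewer than 70% of individuals are removed
(strict inequality: exactly 70% is retained), (2) then individuals
genotyped at fewer than 70% of the remaining loci, (3) loci with minor
allele count below 3, (4) HDPlot, (5) one SNP per tag (highest minor allele
frequency; ties to the smaller position, then the lexicographically smaller
locus id). Minor allele counts are recomputed on the current matrix at each
stage — each filter sees the data it actually operates on. Rerunning the
chain on its own output changes nothing.

HDPlot flags merged paralogs: for each locus, `H` is the heterozygote
proportion and `D = (sum_ref - sum_alt) / sqrt(sum_ref + sum_alt)` the
z-score of allelic read imbalance summed over heterozygous calls (the
binomial-0.5 standardization; loci with no heterozygotes get `D = 0`).
A true single-copy locus has balanced reads in heterozygotes; two collapsed
duplicates produce excess heterozygosity and a skewed read ratio. Loci with
`H > 0.60` or `|D| > 5` are removed. The summed-depth z-score (rather than
averaging per-individual z-scores) is the published HDPlot form and is what
we implement. HDPlot requires depths; depth-free matrices must skip the
stage explicitly (`filter_chain(hdplot = FALSE)`).

## Differentiation and diversity

FST is the Weir–Cockerham (1984) variance-components estimator: per locus
the components *a* (among populations), *b* (among individuals within) and
*c* (within individuals) are computed from per-group sample sizes, allele
frequencies and heterozygote proportions, with missing genotypes excluded
locus by locus; the multi-locus estimate is the ratio of sums
`theta = sum(a) / sum(a+b+c)` — the standard multi-locus form, rather than
an average of per-locus ratios, which would weight noisy loci equally.
Loci monomorphic across all groups are excluded. Fixed differences with no
heterozygotes give exactly 1; duplicating one group into two gives a
non-positive estimate.

Per-group diversity: observed heterozygosity `Ho` (mean over loci),
unbiased expected heterozygosity `He` with the small-sample `2n/(2n-1)`
correction, rarefied allelic richness
`AR = sum_alleles [1 - C(2N - count, g) / C(2N, g)]` averaged over loci,
and `FIS = 1 - mean(Ho_l) / mean(He_l)`. The ratio-of-means form of FIS is
used because per-locus ratios explode at low-diversity loci. The default
rarefaction depth is twice the smallest group size, capped at the smallest
per-locus genotyped allele count so that missing data cannot push a locus
below the rarefaction depth; an explicitly supplied larger depth is an
error rather than a silent NA.

The differentiation test is a permutation test on the multi-locus theta:
individuals are permuted across the two groups preserving sizes, and
`p = (1 + #{theta_perm >= theta_obs}) / (n_perm + 1)`. This replaces the
exact genic G-test used historically for this role: the inferential target
(H0: no differentiation) is the same, the null is exact by construction,
and the statistic tested is the one actually reported. The add-one rule
bounds the smallest attainable p at `1/(n_perm + 1)`. One caveat worked
out during design: with very small groups the permutation space contains
"degenerate" relabelings that exactly recreate the observed partition (or
its mirror), so the minimal p is only reachable when group sizes make those
relabelings vanishingly rare — with 12 + 12 individuals their probability
is about 7e-7 per draw; with 4 + 4 it is 1/35 and p near 0.001 cannot be
expected.

## Ancestry: PCA, the admixture model, K, and regrouping

PCA imputes missing dosages with the locus mean, centers, optionally scales
by `sqrt(p(1-p))`, and eigendecomposes via SVD. Variance explained is
non-increasing and sums to at most 1.

The admixture model is the standard binomial likelihood: individual `i`
carries ancestry fractions `q_i` (a point on the K-simplex) and population
`k` has allele frequencies `f_k`; a genotype is Binomial(2, pi_il) with
`pi_il = sum_k q_ik f_kl`, and missing entries drop their terms. We fit it
by EM with multiplicative updates — the same maximum-likelihood target as
the block-relaxation optimizer usually used for this model, chosen because
every EM step provably does not decrease the log-likelihood, which makes
the optimizer auditable by a property test. Plain multiplicative EM crawls
near the simplex boundary (thousands of iterations before Q-scores of pure
individuals reach their MLE corner), so each iteration applies a
SQUAREM-style extrapolation: two EM steps define a step direction, the
squared-residual ratio a step length, and the extrapolated point is kept
only if it does not lower the log-likelihood (falling back to the plain
double step otherwise). Monotonicity is therefore preserved exactly.
Convergence is declared on an absolute log-likelihood change below `tol`
(default 1e-6); fits run from `n_restarts` random starts (Dirichlet Q,
frequencies jittered around the pooled estimates) seeded from a master
seed, and the best likelihood wins. `K = 1` is returned in closed form
(Q = 1, F = observed frequencies).

K is chosen by cross-validation on masked genotype *entries* (not masked
individuals): the non-missing entries are split into folds, each fold is
hidden in turn, the model refit, and the hidden dosages predicted as
`2 * pi_hat`; the CV error is the mean squared prediction error and the
best K minimizes it. The fold refits use deliberately lighter EM settings
(single restart, loose tolerance) because the prediction error plateaus
long before the parameters polish; the K ranking is insensitive to this.
Components are identifiable only up to label switching, so all recovery
metrics are computed after aligning fitted to reference frequencies by the
permutation maximizing summed correlation.

Group reassignment follows the Q-score rules: an individual joins its
maximum-Q component (a tie at exactly 0.5/0.5 goes to the lower-index
component and is flagged), and is flagged putatively admixed when its
maximum Q-score is below 0.7. Raising the admixture cutoff never unflags
anyone. Per-location admixed proportions are reported alongside.

## Effective population size from linkage disequilibrium

Drift in a finite population generates association between unlinked loci;
its expected magnitude is `~1/(3Ne)` after removing the sampling
contribution. For every retained locus pair we compute Burrows' composite
disequilibrium from unphased dosages, `Delta = cov(X, Y) / 2` over
pairwise-complete individuals (sample covariance), and
`r2 = Delta^2 / (pA(1-pA) pB(1-pB))` with pair-specific frequencies.
Loci with within-group minor allele frequency below the screening threshold
(`pcrit`, default 0.05) are excluded first — rare alleles make `r2`
erratic. The weighted mean `r2` (weights = pair sample sizes) minus the
sampling expectation `E[r2|S] = 1/S + 3.19/S^2` (random mating, S >= 30;
S is the harmonic mean pair sample size, and S < 10 is refused) gives the
drift signal `r2'`, and
`Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`. Non-positive `r2'` means
sampling noise swallowed the drift signal: the point estimate is `+Inf`,
which is a real and informative outcome for large populations, and the
same convention applies to upper confidence limits.

Physical linkage inflates LD and biases Ne downward. With a chromosome map
the pair set is restricted to cross-chromosome pairs (the restriction can
only shrink the pair set); without one, the point estimate is divided by
`0.098 + 0.219 * ln(Chr)` using the species' haploid chromosome number —
an externally published correction whose coefficients are shipped as
config-overridable constants, with defaults 23 (smallmouth bass), 24 (rock
bass) and 50 (white sucker). Confidence intervals are parametric
chi-square on the number of pairs, mirroring common LD-Ne practice; a
jackknife-over-individuals interval is available behind a flag. The method
assumes a closed, random-mating population at drift equilibrium and a
single cohort; mixed-cohort samples bias it modestly downward, which is
reported as a caveat, not corrected.

## Relatedness

Pairwise relatedness uses a genotype-similarity moment estimator in the
Wang tradition, specialized to biallelic loci, where a pair's genotypes at
a locus fall into exactly three categories: identical, homozygote +
heterozygote sharing one allele, or opposite homozygotes (the
two-heterozygotes-sharing-one-allele category of multiallelic data cannot
occur). Writing `phi` and `Delta` for the probabilities of sharing exactly
one or two allele pairs identical by descent, the category probabilities
are linear in `(phi, Delta)` with coefficients that are exact functions of
the allele frequency (derived from the IBD-state decomposition under
Hardy-Weinberg). Summing indicators over loci and solving the ratio-of-sums
moment equations yields `phi_hat`, `Delta_hat` and
`r = phi/2 + Delta = 1 - u_hat - phi_hat/2`. The estimator is symmetric,
invariant to allele relabeling, unbiased given reference frequencies, and
deliberately not clipped to [0, 1] — small-sample excursions carry
information. Reference frequencies default to the whole sample (the
within-species analysis), overridable. Expected values: clones 1, full sibs
and parent-offspring 0.5, half sibs 0.25, unrelated 0; pairs above 0.4
(strictly) are flagged as likely first-degree relatives. Sib vs
parent-offspring cannot be distinguished by this estimator; body-length
differences are reported as annotation only, never as a classification.

## The barrier divergence simulator

The simulator asks: if two connected populations were split by a barrier 30
generations ago, how much FST should we see today? Two demes of `Ne`
diploids evolve at `L = 15,000` unlinked biallelic loci. Each generation
applies, in order: migration (deterministic frequency mixing), symmetric
two-allele mutation at `mu = 1e-4`, and binomial drift of `2Ne` gametes.
The order of events is stated because it is not identifiable from the
scenario description; at these parameter values the choice is numerically
negligible. Shared ancestral frequencies are drawn uniformly on
[0.05, 0.95]; a burn-in of `4Ne` generations at symmetric `m = 0.1` brings
the pair to migration-drift near-equilibrium (the approximation of a
coalescent-equilibrium start); the post-barrier phase runs 30 generations
with zero upstream migration and downstream migration `m` in
{0, 0.01, 0.05, 0.1}; then 50 diploids per deme are sampled
Hardy-Weinberg and multi-locus theta is computed over loci polymorphic in
the pooled sample. A forward frequency simulation was chosen over a
coalescent engine deliberately: the demography is tiny, vectorizing over
loci makes it fast, and every step is directly auditable.

The full factorial grid (2 Ne x 4 m, 10 replicates) shares each
replicate's burn-in across the four migration rates at a given Ne: the
scenarios are *defined* as identical histories up to the barrier, so the
migration contrast becomes a paired comparison and the grid runs in about
a quarter of the time. Expected behavior, which the tests assert: means
decrease strictly in `m`, decrease in `Ne`, and the isolated large-deme
scenario sits near the drift closed form `1 - (1 - 1/(2Ne))^30` plus the
small pre-barrier baseline. The `compare_empirical()` verdict maps an
observed FST onto the grid of the nearest Ne: below every scenario mean
reads as high gene flow, above every mean as divergence that predates the
barrier.

## The synthetic-data generator

Downstream stages are tested against data with known truth. Source
populations follow the Balding-Nichols model: a locus's ancestral
frequency `p` is uniform on the ancestral MAF range or its mirror, and
each population draws its frequency from
`Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `F` is interpretable as the expected
FST to the ancestor and the realized between-population FST of samples is
close to it (checked: F = 0.1 yields sample theta in [0.07, 0.13]).
Individuals have admixture vectors per sampling cohort; genotypes are
Binomial(2, q'f); missingness is MCAR (the study gives no missingness
mechanism, so none is invented); read depths are shifted Poisson with
heterozygote reads split Binomial(total, 0.5). A configurable fraction of
loci emulate merged paralogs — forced heterozygote rate 0.7 with
alternate-read probability 0.2 — which is precisely the signature HDPlot
is designed to catch (checked: >= 90% of paralog-class loci fail the
filter while <= 5% of normal loci do). Pedigree spikes append
parent-offspring and full-sib pairs built by explicit Mendelian gamete
transmission. Body lengths are truncated normals per group.

What the generator does *not* emulate: within-chromosome linkage (loci are
unlinked by construction, so LD-based Ne on Balding-Nichols data is
meaningless — the dedicated Wright-Fisher individual simulator provides
drift-generated LD instead), non-random missingness, allele-dropout,
batch effects, and sequencing error beyond the paralog class. Passing
tests therefore demonstrate estimator correctness under the stated models,
not robustness to every pathology of real RADseq data.

## Numerical choices and problem sizes

Scales were chosen so the whole workflow runs comfortably on a laptop
core: the simulation grid at full design scale (15,000 loci, 10
replicates) takes a few minutes; EM recovery checks use 100 individuals at
2,000 loci; the Wright-Fisher LD recovery uses 100 diploids at 5,000 loci
for 100 generations (LD among unlinked loci equilibrates within tens of
generations); relatedness calibration uses 50 pairs per relationship at
1,000 loci. Every stochastic step derives its seed from a single master
seed, so reruns are bit-identical. Frequencies are clamped away from 0 and
1 only where a likelihood would otherwise produce `log(0)` (EM clamps F to
[1e-6, 1-1e-6]); the simulators never clamp, and allele frequencies remain
in [0, 1] by construction. Ties are always broken deterministically
(lower index, smaller position, lexicographic id) so that outputs are
stable across platforms.

## Known limitations

Estimates inherit the assumptions above: LD-Ne assumes a single closed
random-mating cohort; the admixture model assumes Hardy-Weinberg within
sources and free recombination; the permutation test assumes
exchangeability of individuals under H0 (related individuals in the sample
mildly violate it); the barrier simulator holds Ne constant and models
exactly two demes with no selection. The chromosome-count Ne correction
uses literature karyotypes, not a genome assembly. These mirror the
limitations of the tools standard in this field.
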