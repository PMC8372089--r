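# fragpop

Population-genomic analysis of fish populations in a barrier-fragmented
river. Five native species were sampled above and below a 150-year-old dam
and genotyped at thousands of RADseq SNPs; the scientific question is
whether the genetic structure seen today is the *product* of the dam or
predates it. `fragpop` re-implements that entire analysis as a reusable,
tested R package, with a synthetic-data module standing in for the
sequenced fish so that every stage runs and is verifiable without any
download.

## What it does

* **QC filtering** — call-rate filters (loci genotyped in <70% of
  individuals, individuals genotyped at <70% of loci), minor allele count
  ≥ 3, HDPlot paralog detection (heterozygosity H > 0.60 or read-ratio
  deviation |D| > 5, with D = (ΣA − ΣB)/√(ΣA + ΣB) over heterozygote
  reads), and one SNP per RAD tag (highest minor allele frequency).
* **Differentiation & diversity** — Weir–Cockerham FST
  (θ = Σa / Σ(a+b+c), ratio of sums over loci), observed/unbiased expected
  heterozygosity, rarefied allelic richness, FIS, and a permutation test
  for differentiation (α = 0.01).
* **Ancestry** — PCA; the ADMIXTURE binomial likelihood
  π<sub>il</sub> = Σ<sub>k</sub> q<sub>ik</sub> f<sub>kl</sub> fit by
  accelerated EM with a provably non-decreasing log-likelihood; K chosen by
  cross-validation on masked genotype entries; group reassignment by
  Q-score (assigned at 0.5; max Q < 0.7 flagged putatively admixed).
* **Effective population size** — the bias-corrected LD method: Burrows
  composite r² with p-crit 0.05, E[r²|S] = 1/S + 3.19/S² subtracted, Ne =
  (1/3 + √(1/9 − 2.76 r²′)) / (2 r²′), cross-chromosome pair restriction
  when a genome is available and the chromosome-count correction
  Ne/(0.098 + 0.219 ln Chr) otherwise, parametric chi-square CIs (∞ upper
  limits are a real outcome).
* **Relatedness** — a Wang-type genotype-similarity moment estimator
  (r = φ/2 + Δ) with the strict > 0.4 rule for likely first-degree pairs.
* **Barrier simulations** — a forward-in-time two-deme Wright–Fisher
  model: symmetric migration m = 0.1 to equilibrium, then a barrier with
  zero upstream and downstream migration m ∈ {0, 0.01, 0.05, 0.1} for 30
  generations; Ne ∈ {100, 1000}; 15,000 unlinked loci, μ = 1e-4; 50
  diploids sampled per deme; multi-locus FST per replicate, 10 replicates
  per scenario; plus the comparison of an observed FST against the grid.
* **Ecology** — body-length comparisons between genetic groups
  (Student/Welch t, ANOVA + Tukey HSD, α = 0.05) and descriptive
  genetic-group proportions per sampling event.
* **Synthetic data** — Balding–Nichols source populations, mixed-stock
  sampling designs, MCAR missingness, read depths with a merged-paralog
  class, pedigree spikes, multi-SNP tags and group-specific body lengths.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
dataset (75 fish, 4,000 SNPs, two source populations at F = 0.1 sampled as
a mixed stock around a barrier). `Rscript analysis/01_simulate_data.R`
through `07_ecology.R`; each writes its tables under `results/`. What they
print, abridged:

```
02: filter chain: 4000 -> 2627 loci; 75 -> 75 individuals
03: Weir-Cockerham multi-locus theta = 0.02602 over 2627 loci
    permutation p = 0.001
04: CV error by K:   1      2      3      4      5
                  0.4286 0.4003 0.4098 0.4195 0.4326   -> best K = 2
    <group_assignment> 75 individuals; 5 putatively admixed (max Q < 0.7)
     group  n     Ho     He    AR      FIS     fst
    group1 21 0.3767 0.3771 1.976 0.001006 0.09324
    group2 54 0.3851 0.3889 1.980 0.009845 0.09324
```

The story these numbers tell mirrors the study design: grouping fish by
*capture side* of the barrier gives a small FST (0.026), but the admixture
model finds the two true source populations (K = 2), flags exactly the five
simulated admixed individuals, and regrouping by ancestry nearly
quadruples FST (0.093, close to the generating divergence of 0.1). LD-Ne
on this generator is effectively infinite — Balding–Nichols data carry no
drift-generated linkage disequilibrium, which is itself a documented
property (see the methods vignette); the dedicated Wright–Fisher simulator
provides the LD-calibrated test bed instead.

`06_barrier_sim.R` then runs the full simulation grid and compares the
regrouped FST with it. The synthetic populations have a very large LD-Ne,
so the comparison lands on the large-deme grid and prints

```
observed FST 0.0932 vs Ne=1000 grid -> nearest m = 0 (exceeds_all_scenarios)
```

— divergence this strong cannot have accumulated in 30 generations at that
population size, i.e. the group structure predates the barrier, which is
exactly how the generating model built it. `07_ecology.R` closes the loop
on the ecological side: the lake-origin group is significantly shorter
(192 vs 341 mm, t = −12.6, p ≈ 5e-20).

## Layout

```
R/                  package code (one file per analysis stage)
analysis/01..07     numbered drivers of the full workflow
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/methods.Rmd   models, estimators, design choices, limitations
```
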