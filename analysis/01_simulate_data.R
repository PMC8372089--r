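#!/usr/bin/env Rscript
# Generate the synthetic study dataset: two source populations (a river
# group found above and below the dam, a lake group below only) at
# divergence F = 0.1, mixed-stock sampling with a few admixed fish, 5%
# missing genotypes, read depths with a 3% merged-paralog class, and
# group-specific body lengths. Writes VCF + metadata TSV under results/.

suppressMessages(library(fragpop))

seed <- 20210629
dir.create("results", showWarnings = FALSE)

model <- pop_model(K = 2, L = 4000, F_div = 0.1, n_chromosomes = 24,
                   missing_rate = 0.05, depth_mean = 20,
                   paralog_fraction = 0.03)
design <- default_design(n_above = 30, n_below_river = 20,
                         n_below_lake = 20, n_admixed = 5)

freqs <- draw_source_frequencies(model, derive_seeds(seed, 2)[1])
sim <- simulate_individuals(freqs, design, model, derive_seeds(seed, 2)[2])

write_genotypes(sim$genotypes, "results/genotypes.vcf")
write_metadata(sim$metadata, "results/metadata.tsv")

print(sim$genotypes)
cat("cohorts:\n")
print(table(sim$metadata$location, sim$metadata$true_group))
cat("wrote results/genotypes.vcf and results/metadata.tsv\n")
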