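#!/usr/bin/env Rscript
# Differentiation and diversity between the sampled locations (above vs
# below the dam): Weir-Cockerham FST, Ho / He / rarefied AR / FIS, and a
# permutation test for differentiation at alpha = 0.01.

suppressMessages(library(fragpop))

gm <- read_genotypes("results/genotypes_filtered.vcf")
md <- read_metadata("results/metadata.tsv", gm = gm)
md <- md[match(gm$individual_ids, md$individual_id), ]

fst <- wc_fst(gm, md$location)
div <- diversity_summary(gm, md$location)
test <- differentiation_test(gm, md$location, n_perm = 999, alpha = 0.01,
                             seed = 11)

tab <- cbind(div, fst = fst$theta, diff_p = test$p_value,
             diff_significant = test$significant)
utils::write.table(tab, "results/stats_by_location.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

print(fst)
print(tab, row.names = FALSE, digits = 4)
cat("permutation p =", test$p_value, "\n")
cat("wrote results/stats_by_location.tsv\n")
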