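#!/usr/bin/env Rscript
# Effective population size (LD method, p-crit 0.05, chromosome-count bias
# correction) and Wang-type pairwise relatedness with the > 0.4 rule, per
# reassigned genetic group.

suppressMessages(library(fragpop))

gm <- read_genotypes("results/genotypes_filtered.vcf")
md <- read_metadata("results/metadata.tsv", gm = gm)
md <- md[match(gm$individual_ids, md$individual_id), ]
asg <- utils::read.delim("results/group_assignments.tsv")
grp <- asg$group[match(gm$individual_ids, asg$individual_id)]

ne_rows <- do.call(rbind, lapply(unique(grp), function(g) {
  sel <- grp == g
  if (sum(sel) < 10) return(NULL)
  ne <- tryCatch(ld_ne(gm, group = sel, pcrit = 0.05, n_chromosomes = 24),
                 error = function(e) NULL)
  if (is.null(ne)) return(NULL)
  data.frame(group = g, n = sum(sel), ne = round(ne$ne, 1),
             ci_low = round(ne$ci[1], 1), ci_high = round(ne$ci[2], 1),
             r2_prime = signif(ne$r2_prime, 4), correction = ne$correction)
}))
utils::write.table(ne_rows, "results/ne_by_group.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(ne_rows, row.names = FALSE)

rel <- wang_relatedness(gm)
pairs <- find_related_pairs(rel, threshold = 0.4, metadata = md,
                            groups = stats::setNames(grp, gm$individual_ids))
utils::write.table(pairs, "results/related_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(nrow(pairs), "highly related pair(s) (r > 0.4)\n")
if (nrow(pairs)) print(pairs, row.names = FALSE, digits = 3)
cat("wrote results/ne_by_group.tsv and results/related_pairs.tsv\n")
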