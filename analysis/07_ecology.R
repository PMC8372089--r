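#!/usr/bin/env Rscript
# Ecology: body-length comparison between the reassigned genetic groups
# (Student/Welch t or ANOVA + Tukey, alpha = 0.05) and the descriptive
# genetic-group composition of each sampling event.

suppressMessages(library(fragpop))

gm <- read_genotypes("results/genotypes_filtered.vcf")
md <- read_metadata("results/metadata.tsv", gm = gm)
md <- md[match(gm$individual_ids, md$individual_id), ]
asg <- utils::read.delim("results/group_assignments.tsv")
grp <- asg$group[match(gm$individual_ids, asg$individual_id)]

lt <- compare_lengths(md, grp, alpha = 0.05)
print(lt)
utils::write.table(lt$per_group, "results/length_by_group.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

props <- group_proportions_by_event(md, grp)
utils::write.table(props, "results/group_proportions_by_event.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(props[props$count > 0, ], row.names = FALSE, digits = 3)
cat("wrote results/length_by_group.tsv and group_proportions_by_event.tsv\n")
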