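#!/usr/bin/env Rscript
# Post-genotyping quality control: 70% locus and individual call rates,
# minor allele count >= 3, HDPlot (H <= 0.60, |D| <= 5), one SNP per RAD
# tag. Writes the filtered VCF and a stage-by-stage JSON report.

suppressMessages(library(fragpop))

gm <- read_genotypes("results/genotypes.vcf")
res <- filter_chain(gm)

write_genotypes(res$genotypes, "results/genotypes_filtered.vcf")
jsonlite::write_json(
  list(counts = res$report$counts,
       removed = res$report$removed,
       hdplot = res$report$extra),
  "results/filter_report.json", dataframe = "rows", auto_unbox = TRUE,
  digits = NA)

print(res$report)
cat("wrote results/genotypes_filtered.vcf and results/filter_report.json\n")
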