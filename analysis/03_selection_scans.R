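#!/usr/bin/env Rscript
# iHS in both populations (normalized within 20 derived-allele-frequency
# bins) and XP-EHH contrasting them (normalized genome-wide; negative =
# candidate selection in pop1). Writes the per-SNP score tracks.

library(hapdiff)

panel <- read_panel_file("results/data/study.panel.txt")
ds <- read_phased_vcf("results/data/study.vcf", panel)
v <- ds$variants
for (ch in unique(v$chrom)) {
  m <- read_genetic_map(sprintf("results/data/study.map.chr%s.txt", ch))
  v$gpos_cm[v$chrom == ch] <- interpolate_gpos(m, v$pos_bp[v$chrom == ch])
}

ihs1 <- normalize_ihs(ihs_scan(ds$haplotypes, v, "pop1"))
ihs2 <- normalize_ihs(ihs_scan(ds$haplotypes, v, "pop2"))
xp <- normalize_xpehh(xpehh_scan(ds$haplotypes, v, "pop1", "pop2"))

dir.create("results/selection", showWarnings = FALSE, recursive = TRUE)
write.table(ihs1, "results/selection/ihs_pop1.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ihs2, "results/selection/ihs_pop2.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(xp, "results/selection/xpehh.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

i <- which.min(xp$norm_xpehh)
cat(sprintf("iHS scored: pop1 %d, pop2 %d of %d SNPs\n",
            sum(ihs1$skip_reason == "ok"), sum(ihs2$skip_reason == "ok"), nrow(v)))
cat(sprintf("most negative XP-EHH %.2f at chr%s:%d (negative = selection in pop1)\n",
            xp$norm_xpehh[i], xp$chrom[i], xp$pos_bp[i]))
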