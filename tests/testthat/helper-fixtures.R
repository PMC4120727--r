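# Shared fixture builders: everything is generated in code at test time.

# A minimal haplotype_matrix from a plain 0/1 matrix, one panel.
toy_haps <- function(m, panel = "pop1") {
  n <- nrow(m)
  haplotype_matrix(m, panel = rep_len(panel, n),
                   sample_of = paste0("s", rep(seq_len(ceiling(n / 2)), each = 2))[seq_len(n)])
}

toy_variants <- function(n, chrom = "1", spacing = 1000, ancestral = "ref",
                         rate = 1) {
  pos <- seq(spacing, by = spacing, length.out = n)
  variant_table(chrom = rep(chrom, n), pos_bp = pos,
                ref = rep("A", n), alt = rep("G", n), ancestral = ancestral,
                gpos_cm = (pos - 1) * rate / 1e6)
}

# Brute-force EHH oracle: enumerate all carrier pairs and count the pairs
# identical over every SNP between core and target inclusive.
ehh_oracle <- function(alleles, carriers, core, target) {
  iv <- min(core, target):max(core, target)
  n <- length(carriers)
  hom <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (all(alleles[carriers[i], iv] == alleles[carriers[j], iv])) hom <- hom + 1
  }
  hom / tot
}

# Write a small phased VCF from raw strings (for parser contract tests).
write_test_vcf <- function(records, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

small_sim <- function(seed, ...) {
  simulate_neutral(sim_config(seed = seed, n_haplotypes = 40, n_snps = 400,
                              chrom_length_bp = 1e6, divergence_level = 0.05,
                              ...))
}
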