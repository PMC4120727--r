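#' Allele frequency of the alternate (coded-1) allele in one panel
#'
#' @param haps a [haplotype_matrix()].
#' @param panel population label.
#' @param snp SNP column index (vectorized; default all SNPs).
#' @return fraction(s) in [0,1].
#' @export
allele_frequency <- function(haps, panel, snp = NULL) {
  rows <- haps$panel == panel
  if (!any(rows)) stop("empty panel: ", panel)
  m <- haps$alleles[rows, , drop = FALSE]
  if (is.null(snp)) colMeans(m) else colMeans(m)[snp]
}

#' Two-population Wright's F_ST for a single SNP
#'
#' F_ST = (p1 - p2)^2 / [(p1 + p2)(2 - p1 - p2)], the two-population
#' form computed from the frequencies of one scored allele. Symmetric
#' under population swap and allele relabeling (p -> 1-p in both
#' populations). Monomorphic input (p1 = p2 = 0 or 1) is defined as 0.
#'
#' @param p1,p2 allele frequencies in [0,1] (vectorized).
#' @return F_ST value(s) in [0,1].
#' @export
fst_two_pop <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) stop("frequencies must be in [0,1]")
  den <- (p1 + p2) * (2 - p1 - p2)
  out <- ifelse(den == 0, 0, (p1 - p2)^2 / den)
  as.numeric(out)
}

#' Genome-wide empirical p-values for F_ST values
#'
#' emp_p(x) = (number of SNPs with F_ST >= x) / N, counted including
#' the SNP itself, so the minimum attainable value is 1/N and tied
#' values share one p-value.
#'
#' @param fst_values numeric vector over all scored SNPs.
#' @return empirical p-value per SNP, same order.
#' @export
empirical_pvalues <- function(fst_values) {
  n <- length(fst_values)
  if (n < 1) stop("need at least one value")
  rank(-fst_values, ties.method = "max") / n
}

#' Compute per-SNP F_ST records for two panels
#'
#' Scores the alternate allele of every SNP; monomorphic SNPs
#' (p1 = p2 = 0 or 1) get fst = 0 and are flagged.
#'
#' @param haps a [haplotype_matrix()] containing both panels.
#' @param variants the matching [variant_table()].
#' @param pop1,pop2 panel labels.
#' @return `data.frame` with chrom, pos_bp, id, p1, p2, fst, emp_p,
#'   monomorphic.
#' @export
fst_records <- function(haps, variants, pop1, pop2) {
  p1 <- allele_frequency(haps, pop1)
  p2 <- allele_frequency(haps, pop2)
  fst <- fst_two_pop(p1, p2)
  data.frame(chrom = variants$chrom, pos_bp = variants$pos_bp,
             id = variants$id, p1 = p1, p2 = p2, fst = fst,
             emp_p = empirical_pvalues(fst),
             monomorphic = (p1 == p2) & (p1 == 0 | p1 == 1),
             stringsAsFactors = FALSE)
}

#' Windowed exact-binomial enrichment scan over F_ST empirical p-values
#'
#' Each chromosome is divided into non-overlapping windows of
#' `window_size` bp on a 0-based half-open grid over `pos_bp - 1`.
#' Per window, the number of SNPs with empirical p-value below
#' `tier_threshold` is tested against Binomial(n_snps, tier_threshold)
#' with the one-sided exact tail P(X >= n_extreme). Windows holding no
#' SNPs are omitted. All emitted windows are pooled genome-wide and
#' ranked by binomial p (ties broken by chrom, start), giving
#' `genome_rank_pct` = 100 * rank / number of windows.
#'
#' @param records output of [fst_records()].
#' @param window_size window width in bp (100 kb and 500 kb are the
#'   conventional choices).
#' @param tier_threshold empirical-p cutoff defining an "extreme" SNP
#'   (0.01 for 100 kb windows, 0.001 for 500 kb windows).
#' @return `data.frame` with chrom, start_bp, end_bp (0-based
#'   half-open), window_size, n_snps, n_extreme, binom_p,
#'   genome_rank_pct.
#' @export
window_binomial_scan <- function(records, window_size, tier_threshold) {
  if (tier_threshold <= 0 || tier_threshold >= 1)
    stop("tier_threshold must be in (0,1)")
  if (window_size <= 0) stop("window_size must be positive")
  win <- floor((records$pos_bp - 1) / window_size)
  key <- paste0(records$chrom, "\r", win)
  n_snps <- as.vector(table(key)[unique(key)])
  extreme <- records$emp_p < tier_threshold
  n_extreme <- as.vector(tapply(extreme, key, sum)[unique(key)])
  first <- !duplicated(key)
  out <- data.frame(chrom = records$chrom[first],
                    start_bp = win[first] * window_size,
                    end_bp = (win[first] + 1) * window_size,
                    window_size = window_size,
                    n_snps = as.integer(n_snps),
                    n_extreme = as.integer(n_extreme),
                    stringsAsFactors = FALSE)
  out$binom_p <- pbinom(out$n_extreme - 1L, out$n_snps, tier_threshold,
                        lower.tail = FALSE)
  ord <- order(out$binom_p, out$chrom, out$start_bp)
  rank <- integer(nrow(out)); rank[ord] <- seq_len(nrow(out))
  out$genome_rank <- rank
  out$genome_rank_pct <- 100 * rank / nrow(out)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}
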