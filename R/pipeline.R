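#' Run the full two-population differentiation scan
#'
#' Glues the stages in scan order: per-SNP F_ST with empirical
#' p-values; windowed exact-binomial enrichment at 100 kb
#' (empirical p < 0.01) and 500 kb (empirical p < 0.001); iHS in both
#' populations; XP-EHH contrasting them; tiered discovery per metric;
#' cross-metric validation; and, when a third panel is present, the
#' windowed haplotype similarity classification. Monomorphic SNPs are
#' dropped after loading, and the SNP attrition ladder is reported in
#' the manifest.
#'
#' @param haps a [haplotype_matrix()] holding all panels.
#' @param variants the matching [variant_table()] (with `gpos_cm`
#'   filled, e.g. via [interpolate_gpos()]).
#' @param pop1,pop2 the two populations to contrast (XP-EHH sign:
#'   negative = selection candidate in `pop1`).
#' @param pop3 optional third population for the similarity track
#'   (pair1 = `pop1` vs `pop3`, pair2 = `pop1` vs `pop2`).
#' @param thr a [criterion_thresholds()].
#' @param region_pad half-width for SNP-seeded regions, bp.
#' @param ehh_cutoff,max_gap_bp,min_carriers passed to the EHH scans.
#' @param out_dir optional directory; when given, all tracks, window
#'   tables, the final region table and a plain-text manifest are
#'   written there as TSV.
#' @return list with `fst`, `windows_100kb`, `windows_500kb`,
#'   `ihs_pop1`, `ihs_pop2`, `xpehh`, `candidates`, `regions`,
#'   `similarity` (or `NULL`), `manifest`.
#' @export
run_scan <- function(haps, variants, pop1, pop2, pop3 = NULL,
                     thr = criterion_thresholds(), region_pad = 100000,
                     ehh_cutoff = 0.05, max_gap_bp = 200000,
                     min_carriers = 3, out_dir = NULL) {
  n_parsed <- nrow(variants)
  p1 <- allele_frequency(haps, pop1)
  p2 <- allele_frequency(haps, pop2)
  mono <- (p1 == p2) & (p1 == 0 | p1 == 1)
  if (any(mono)) {
    keepc <- which(!mono)
    variants <- variants[keepc, , drop = FALSE]
    class(variants) <- c("variant_table", "data.frame")
    haps <- haplotype_matrix(haps$alleles[, keepc, drop = FALSE],
                             haps$panel, haps$sample_of)
  }
  labels <- c(pop1, pop2)

  fst <- fst_records(haps, variants, pop1, pop2)
  w100 <- window_binomial_scan(fst, 100000, 0.01)
  w500 <- window_binomial_scan(fst, 500000, 0.001)

  ihs1 <- normalize_ihs(ihs_scan(haps, variants, pop1, cutoff = ehh_cutoff,
                                 max_gap_bp = max_gap_bp,
                                 min_carriers = min_carriers))
  ihs2 <- normalize_ihs(ihs_scan(haps, variants, pop2, cutoff = ehh_cutoff,
                                 max_gap_bp = max_gap_bp,
                                 min_carriers = min_carriers))
  xp <- normalize_xpehh(xpehh_scan(haps, variants, pop1, pop2,
                                   cutoff = ehh_cutoff,
                                   max_gap_bp = max_gap_bp,
                                   min_carriers = min_carriers))

  cand <- rbind(discover_fst_regions(w100, w500, thr),
                discover_ihs_regions(ihs1, ihs2, thr, region_pad, labels),
                discover_xpehh_regions(xp, thr, region_pad, labels))
  cand <- cand[order(cand$chrom, cand$start_bp), , drop = FALSE]
  regions <- cross_validate(cand, w100, w500, ihs1, ihs2, xp, thr, labels)

  # pair1 = pop1 vs pop3, pair2 = pop1 vs pop2 (the three-way design)
  sim_track <- if (!is.null(pop3))
    similarity_track(haps, variants, pop1, pop3, pop2) else NULL

  manifest <- c(
    sprintf("populations: %s vs %s%s", pop1, pop2,
            if (is.null(pop3)) "" else sprintf(" (similarity vs %s)", pop3)),
    sprintf("snps_parsed: %d", n_parsed),
    sprintf("snps_monomorphic_dropped: %d", sum(mono)),
    sprintf("snps_scanned: %d", nrow(variants)),
    sprintf("snps_ihs_scored_%s: %d", pop1, sum(ihs1$skip_reason == "ok")),
    sprintf("snps_ihs_scored_%s: %d", pop2, sum(ihs2$skip_reason == "ok")),
    sprintf("snps_xpehh_scored: %d", sum(xp$skip_reason == "ok")),
    sprintf("windows_100kb: %d", nrow(w100)),
    sprintf("windows_500kb: %d", nrow(w500)),
    sprintf("candidate_regions: %d", nrow(cand)),
    sprintf("final_regions: %d", nrow(regions)),
    sprintf("thresholds: %s",
            paste(sprintf("%s=%g", names(thr), unlist(thr)), collapse = " ")))

  out <- list(fst = fst, windows_100kb = w100, windows_500kb = w500,
              ihs_pop1 = ihs1, ihs_pop2 = ihs2, xpehh = xp,
              candidates = cand, regions = regions, similarity = sim_track,
              manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(fst, "fst.tsv"); wt(w100, "windows_100kb.tsv"); wt(w500, "windows_500kb.tsv")
    wt(ihs1, paste0("ihs_", pop1, ".tsv")); wt(ihs2, paste0("ihs_", pop2, ".tsv"))
    wt(xp, "xpehh.tsv"); wt(regions, "regions.tsv")
    if (!is.null(sim_track)) wt(sim_track, "similarity.tsv")
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  out
}
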