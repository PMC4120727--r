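SKIP_LABELS <- c("ok", "edge", "gap", "no_ancestral", "daf", "min_carriers",
                 "degenerate")

skip_label <- function(code) SKIP_LABELS[code + 1L]

#' Extended haplotype homozygosity between a core and a target SNP
#'
#' Over the inclusive interval of SNPs between `core` and `target`,
#' carriers are grouped by identical extended haplotype; EHH is the
#' probability that two distinct carriers drawn at random are
#' identical over the interval: sum_h C(n_h,2) / C(n,2).
#'
#' @param haps a [haplotype_matrix()].
#' @param carriers haplotype row indices (1-based) to compute over;
#'   at least 2.
#' @param core,target SNP column indices (1-based).
#' @return EHH fraction in [0,1].
#' @export
ehh_at <- function(haps, carriers, core, target) {
  if (length(carriers) < 2) stop("need at least 2 carriers")
  ehh_at_cpp(haps$alleles, as.integer(carriers) - 1L,
             as.integer(core) - 1L, as.integer(target) - 1L)
}

#' EHH decay curve from a core SNP over a carrier set
#'
#' Walks outward from the core on one side, computing EHH at every SNP
#' until the chromosome end. Offsets are genetic distances (cM) from
#' the core. The first point is the core itself (offset 0; EHH 1 for an
#' allele-class carrier set).
#'
#' @param haps a [haplotype_matrix()].
#' @param carriers haplotype row indices (1-based).
#' @param core core SNP column index (1-based).
#' @param gpos_cm genetic position per SNP column.
#' @param side `"up"` (towards smaller indices) or `"down"`.
#' @return `data.frame` with `snp`, `offset_cm`, `ehh`.
#' @export
ehh_curve <- function(haps, carriers, core, gpos_cm, side = c("down", "up")) {
  side <- match.arg(side)
  dir <- if (side == "down") 1L else -1L
  nsnp <- ncol(haps$alleles)
  targets <- if (dir > 0) seq(core, nsnp) else seq(core, 1L)
  ehh <- vapply(targets, function(t)
    if (t == core) 1.0 else ehh_at(haps, carriers, core, t), numeric(1))
  data.frame(snp = targets, offset_cm = abs(gpos_cm[targets] - gpos_cm[core]),
             ehh = ehh)
}

#' Integrate one side of an EHH curve into an iHH area
#'
#' Trapezoid rule over genetic distance, truncated at the first point
#' where EHH drops below `cutoff`; the trapezoid through that point is
#' included. A curve that never decays below the cutoff before the
#' chromosome end (including a single-point curve with no flanking
#' SNPs) is non-computable and returns `NA` with attribute
#' `status = "edge"`. Callers sum the upstream and downstream sides.
#'
#' @param points `data.frame` with columns `offset_cm` (non-negative,
#'   starting at 0) and `ehh`, ordered outward from the core.
#' @param cutoff EHH truncation cutoff, default 0.05.
#' @return one-sided iHH area in cM, or `NA` flagged non-computable.
#' @export
integrate_ihh <- function(points, cutoff = 0.05) {
  x <- points$offset_cm; y <- points$ehh
  if (length(x) < 2) return(structure(NA_real_, status = "edge"))
  area <- 0
  for (i in 2:length(x)) {
    area <- area + 0.5 * (y[i - 1] + y[i]) * (x[i] - x[i - 1])
    if (y[i] < cutoff) return(structure(area, status = "ok"))
  }
  structure(NA_real_, status = "edge")
}

#' Unstandardized iHS scan for one population panel
#'
#' Per SNP with known ancestral allele, integrates EHH separately over
#' the derived-carrier and ancestral-carrier haplotype classes (both
#' sides, truncated where the class EHH drops below `cutoff`) and
#' reports raw_ihs = ln(iHH_ancestral / iHH_derived). SNPs are skipped
#' with a reason code when the ancestral state is unknown, the derived
#' allele frequency is outside [`min_daf`, `max_daf`], either class has
#' fewer than `min_carriers` haplotypes, the EHH curve runs off the
#' chromosome end before decaying (edge), or an inter-SNP physical gap
#' exceeds `max_gap_bp`.
#'
#' @param haps a [haplotype_matrix()] (all panels; `panel` selects one).
#' @param variants the matching [variant_table()] with `gpos_cm` filled.
#' @param panel population label to scan.
#' @param cutoff EHH truncation cutoff (default 0.05).
#' @param max_gap_bp maximum tolerated physical gap between adjacent
#'   SNPs on the integration path (default 200 kb).
#' @param min_carriers minimum haplotypes per allele class (default 3).
#' @param min_daf,max_daf derived-allele-frequency bounds (0.05, 0.95).
#' @return `data.frame`: chrom, pos_bp, id, daf, ihh_a, ihh_d, raw_ihs,
#'   bin_id, skip_reason.
#' @export
ihs_scan <- function(haps, variants, panel, cutoff = 0.05,
                     max_gap_bp = 200000, min_carriers = 3,
                     min_daf = 0.05, max_daf = 0.95) {
  sub <- subset_panel(haps, panel)
  derived <- ifelse(variants$ancestral == "ref", 1L,
                    ifelse(variants$ancestral == "alt", 0L, NA_integer_))
  out <- vector("list", length(unique(variants$chrom)))
  for (k in seq_along(unique(variants$chrom))) {
    ch <- unique(variants$chrom)[k]
    cols <- which(variants$chrom == ch)
    res <- ihs_scan_cpp(sub$alleles[, cols, drop = FALSE],
                        variants$gpos_cm[cols], as.numeric(variants$pos_bp[cols]),
                        derived[cols], cutoff, max_gap_bp,
                        as.integer(min_carriers), min_daf, max_daf)
    out[[k]] <- data.frame(chrom = ch, pos_bp = variants$pos_bp[cols],
                           id = variants$id[cols], daf = res$daf,
                           ihh_a = res$ihh_a, ihh_d = res$ihh_d,
                           skip = res$skip, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rec$raw_ihs <- log(rec$ihh_a / rec$ihh_d)
  bad <- rec$skip == 0L & !is.finite(rec$raw_ihs)
  rec$skip[bad] <- 6L
  rec$raw_ihs[rec$skip != 0L] <- NA_real_
  rec$bin_id <- pmin(pmax(floor(rec$daf / 0.05) + 1L, 1L), 20L)
  rec$skip_reason <- skip_label(rec$skip)
  rec$skip <- NULL
  rec
}

#' Standardize iHS within 20 derived-allele-frequency bins
#'
#' Within each 5%-wide DAF bin, norm_ihs = (raw - bin mean) / bin SD
#' (sample SD). Bins holding fewer than two scored SNPs, or with zero
#' spread, cannot be standardized: their records are flagged
#' `unnormalized` and carry `NA`, which excludes them from downstream
#' thresholds.
#'
#' @param records output of [ihs_scan()].
#' @return records with `norm_ihs` and logical `unnormalized` added.
#' @export
normalize_ihs <- function(records) {
  records$norm_ihs <- NA_real_
  records$unnormalized <- FALSE
  ok <- records$skip_reason == "ok" & is.finite(records$raw_ihs)
  for (b in unique(records$bin_id[ok])) {
    i <- which(ok & records$bin_id == b)
    m <- mean(records$raw_ihs[i]); s <- sd(records$raw_ihs[i])
    if (length(i) < 2 || !is.finite(s) || s == 0) {
      records$unnormalized[i] <- TRUE
    } else {
      records$norm_ihs[i] <- (records$raw_ihs[i] - m) / s
    }
  }
  records
}

#' Unstandardized XP-EHH scan contrasting two population panels
#'
#' Per SNP, EHH is computed over all haplotypes of each panel (the core
#' SNP included in the haplotype string) and both integrals are
#' truncated at the same genetic boundary — the first SNP on each side
#' where the EHH of the pooled two-panel set drops below `cutoff` — so
#' the two areas cover the same interval. raw_xpehh =
#' ln(iHH_pop2 / iHH_pop1): negative values mean longer haplotypes
#' (candidate selection) in `pop1`.
#'
#' @inheritParams ihs_scan
#' @param pop1,pop2 panel labels to contrast.
#' @return `data.frame`: chrom, pos_bp, id, ihh_pop1, ihh_pop2,
#'   raw_xpehh, skip_reason.
#' @export
xpehh_scan <- function(haps, variants, pop1, pop2, cutoff = 0.05,
                       max_gap_bp = 200000, min_carriers = 3) {
  sub <- subset_panel(haps, c(pop1, pop2))
  is2 <- as.integer(sub$panel == pop2)
  chroms <- unique(variants$chrom)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    cols <- which(variants$chrom == chroms[k])
    res <- xpehh_scan_cpp(sub$alleles[, cols, drop = FALSE], is2,
                          variants$gpos_cm[cols],
                          as.numeric(variants$pos_bp[cols]),
                          cutoff, max_gap_bp, as.integer(min_carriers))
    out[[k]] <- data.frame(chrom = chroms[k], pos_bp = variants$pos_bp[cols],
                           id = variants$id[cols],
                           ihh_pop1 = res$ihh_pop1, ihh_pop2 = res$ihh_pop2,
                           skip = res$skip, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rec$raw_xpehh <- log(rec$ihh_pop2 / rec$ihh_pop1)
  bad <- rec$skip == 0L & !is.finite(rec$raw_xpehh)
  rec$skip[bad] <- 6L
  rec$raw_xpehh[rec$skip != 0L] <- NA_real_
  rec$skip_reason <- skip_label(rec$skip)
  rec$skip <- NULL
  rec
}

#' Standardize XP-EHH genome-wide to zero mean and unit variance
#'
#' A single standardization over all scored SNPs (no binning), using
#' the population (denominator n) standard deviation so the normalized
#' scores have exactly mean 0 and variance 1.
#'
#' @param records output of [xpehh_scan()].
#' @return records with `norm_xpehh` added.
#' @export
normalize_xpehh <- function(records) {
  ok <- records$skip_reason == "ok" & is.finite(records$raw_xpehh)
  if (sum(ok) < 2) stop("need at least 2 scored SNPs to normalize")
  x <- records$raw_xpehh[ok]
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("degenerate scan: zero variance in raw XP-EHH")
  records$norm_xpehh <- NA_real_
  records$norm_xpehh[ok] <- (x - mean(x)) / s
  records
}
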