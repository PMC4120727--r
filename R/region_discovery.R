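#' Discovery and validation thresholds for differentiated regions
#'
#' Percentile tiers (in percent of the respective genome-wide
#' distribution) governing region discovery and the less stringent
#' cross-metric validation. Every discovery tier must be at least as
#' stringent as its validation tier.
#'
#' @param fst_discovery_pct windows in the top x% of the pooled
#'   binomial-p ranking seed F_ST regions (default 0.1).
#' @param fst_validation_pct F_ST validation tier (default 1).
#' @param ihs_discovery_pct |iHS| discovery tail in one population
#'   (default 0.1; 0.19 is an alternative reading of the same rule).
#' @param ihs_other_pop_exclusion_pct the other population must have no
#'   SNP in this |iHS| tail inside the region (default 1).
#' @param ihs_validation_pct |iHS| validation tier (default 1).
#' @param xpehh_discovery_pct per-extreme XP-EHH discovery tail
#'   (default 0.01).
#' @param xpehh_validation_pct per-extreme XP-EHH validation tail
#'   (default 0.5).
#' @return named list of class `criterion_thresholds`.
#' @export
criterion_thresholds <- function(fst_discovery_pct = 0.1,
                                 fst_validation_pct = 1,
                                 ihs_discovery_pct = 0.1,
                                 ihs_other_pop_exclusion_pct = 1,
                                 ihs_validation_pct = 1,
                                 xpehh_discovery_pct = 0.01,
                                 xpehh_validation_pct = 0.5) {
  thr <- list(fst_discovery_pct = fst_discovery_pct,
              fst_validation_pct = fst_validation_pct,
              ihs_discovery_pct = ihs_discovery_pct,
              ihs_other_pop_exclusion_pct = ihs_other_pop_exclusion_pct,
              ihs_validation_pct = ihs_validation_pct,
              xpehh_discovery_pct = xpehh_discovery_pct,
              xpehh_validation_pct = xpehh_validation_pct)
  if (any(unlist(thr) <= 0) || any(unlist(thr) >= 100))
    stop("thresholds must be percentages in (0, 100)")
  if (fst_discovery_pct > fst_validation_pct ||
      ihs_discovery_pct > ihs_validation_pct ||
      xpehh_discovery_pct > xpehh_validation_pct)
    stop("each discovery tier must be <= its validation tier")
  class(thr) <- "criterion_thresholds"
  thr
}

# Flag the top q% of a score vector: rank (descending score, ties broken by
# chrom then pos) <= floor(N*q/100), N counting finite scores only. The floor
# form means a tier the genome is too small to resolve stays empty rather
# than always promoting the single most extreme item.
tail_flags <- function(score, chrom, pos, q_pct) {
  flag <- rep(FALSE, length(score))
  fin <- which(is.finite(score))
  k <- floor(length(fin) * q_pct / 100)
  if (k >= 1) {
    ord <- fin[order(-score[fin], chrom[fin], pos[fin])]
    flag[ord[seq_len(k)]] <- TRUE
  }
  flag
}

# Merge overlapping/adjacent [start,end) intervals within (chrom, direction),
# summing SNP support.
merge_candidates <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- lapply(split(df, paste(df$chrom, df$direction, sep = "\r")), function(d) {
    ir <- IRanges::IRanges(start = d$start_bp + 1L, end = d$end_bp)
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red)
    supp <- tapply(d$n_support_snps[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit), sum)
    data.frame(chrom = d$chrom[1], start_bp = IRanges::start(red) - 1L,
               end_bp = IRanges::end(red),
               discovery_metric = d$discovery_metric[1],
               discovery_detail = d$discovery_detail[1],
               direction = d$direction[1],
               n_support_snps = as.integer(supp),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start_bp), , drop = FALSE]
}

#' Discover candidate regions from the windowed F_ST enrichment scan
#'
#' Windows (of either size) whose pooled genome-wide binomial-p rank
#' falls in the top `fst_discovery_pct` become candidates tagged with
#' their window size.
#'
#' @param windows_100kb,windows_500kb outputs of
#'   [window_binomial_scan()]; either may be `NULL`.
#' @param thr a [criterion_thresholds()].
#' @return candidate-region `data.frame`.
#' @export
discover_fst_regions <- function(windows_100kb, windows_500kb,
                                 thr = criterion_thresholds()) {
  take <- function(w) {
    if (is.null(w) || nrow(w) == 0) return(NULL)
    hit <- w[w$genome_rank_pct <= thr$fst_discovery_pct, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    data.frame(chrom = hit$chrom, start_bp = hit$start_bp,
               end_bp = hit$end_bp, discovery_metric = "FST",
               discovery_detail = paste0(hit$window_size / 1000, "kb"),
               direction = "none", n_support_snps = hit$n_extreme,
               stringsAsFactors = FALSE)
  }
  out <- rbind(take(windows_100kb), take(windows_500kb))
  if (is.null(out))
    out <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), discovery_metric = character(),
                      discovery_detail = character(), direction = character(),
                      n_support_snps = integer(), stringsAsFactors = FALSE)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Discover candidate regions from differential iHS signals
#'
#' A SNP in one population's top `ihs_discovery_pct` |iHS| tail seeds a
#' region (SNP position +/- `region_pad`), kept only if the other
#' population has no SNP reaching its top
#' `ihs_other_pop_exclusion_pct` |iHS| tail inside that region.
#' Overlapping regions with the same direction are merged.
#'
#' @param ihs_pop1,ihs_pop2 normalized tracks from [normalize_ihs()].
#' @param thr a [criterion_thresholds()].
#' @param region_pad half-width of the seeded region, bp (default 100 kb).
#' @param pop_labels direction labels for the two tracks.
#' @return candidate-region `data.frame`.
#' @export
discover_ihs_regions <- function(ihs_pop1, ihs_pop2,
                                 thr = criterion_thresholds(),
                                 region_pad = 100000,
                                 pop_labels = c("pop1", "pop2")) {
  one_way <- function(a, b, label) {
    disc <- tail_flags(abs(a$norm_ihs), a$chrom, a$pos_bp, thr$ihs_discovery_pct)
    excl <- tail_flags(abs(b$norm_ihs), b$chrom, b$pos_bp,
                       thr$ihs_other_pop_exclusion_pct)
    seeds <- which(disc)
    if (length(seeds) == 0) return(NULL)
    keep <- vapply(seeds, function(i) {
      lo <- a$pos_bp[i] - 1 - region_pad; hi <- a$pos_bp[i] - 1 + region_pad + 1
      !any(excl & b$chrom == a$chrom[i] & (b$pos_bp - 1) >= lo & (b$pos_bp - 1) < hi)
    }, logical(1))
    seeds <- seeds[keep]
    if (length(seeds) == 0) return(NULL)
    data.frame(chrom = a$chrom[seeds],
               start_bp = pmax(a$pos_bp[seeds] - 1 - region_pad, 0),
               end_bp = a$pos_bp[seeds] - 1 + region_pad + 1,
               discovery_metric = "iHS", discovery_detail = label,
               direction = label, n_support_snps = 1L,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_way(ihs_pop1, ihs_pop2, pop_labels[1]),
               one_way(ihs_pop2, ihs_pop1, pop_labels[2]))
  if (is.null(out))
    return(discover_fst_regions(NULL, NULL, thr))  # empty frame, same schema
  merge_candidates(out)
}

#' Discover candidate regions from extreme XP-EHH scores
#'
#' SNPs in the top `xpehh_discovery_pct` of either extreme of the
#' genome-wide normalized XP-EHH distribution seed regions
#' (+/- `region_pad`, merged); direction follows the sign (negative =
#' pop1, positive = pop2).
#'
#' @param xpehh normalized track from [normalize_xpehh()].
#' @param thr a [criterion_thresholds()].
#' @param region_pad half-width in bp (default 100 kb).
#' @param pop_labels direction labels, `c(pop1, pop2)`.
#' @return candidate-region `data.frame`.
#' @export
discover_xpehh_regions <- function(xpehh, thr = criterion_thresholds(),
                                   region_pad = 100000,
                                   pop_labels = c("pop1", "pop2")) {
  neg <- tail_flags(-xpehh$norm_xpehh, xpehh$chrom, xpehh$pos_bp,
                    thr$xpehh_discovery_pct) & xpehh$norm_xpehh < 0
  pos <- tail_flags(xpehh$norm_xpehh, xpehh$chrom, xpehh$pos_bp,
                    thr$xpehh_discovery_pct) & xpehh$norm_xpehh > 0
  seeds <- which(neg | pos)
  if (length(seeds) == 0) return(discover_fst_regions(NULL, NULL, thr))
  out <- data.frame(chrom = xpehh$chrom[seeds],
                    start_bp = pmax(xpehh$pos_bp[seeds] - 1 - region_pad, 0),
                    end_bp = xpehh$pos_bp[seeds] - 1 + region_pad + 1,
                    discovery_metric = "XPEHH",
                    discovery_detail = ifelse(neg[seeds], pop_labels[1],
                                              pop_labels[2]),
                    direction = ifelse(neg[seeds], pop_labels[1], pop_labels[2]),
                    n_support_snps = 1L, stringsAsFactors = FALSE)
  merge_candidates(out)
}

#' Cross-validate candidate regions against the other two metrics
#'
#' A candidate is reported only if at least one metric other than its
#' discovery metric meets its (less stringent) validation tier inside
#' the candidate interval: an overlapping F_ST window in the top
#' `fst_validation_pct` of the pooled ranking; at least one SNP in one
#' population's top `ihs_validation_pct` |iHS| tail with none of the
#' other population's inside the interval; or at least one SNP in the
#' top `xpehh_validation_pct` of either XP-EHH extreme. Regions whose
#' discovery carried no direction inherit one from an unambiguous
#' directional validation.
#'
#' @param candidates row-bound output of the `discover_*_regions`
#'   functions.
#' @param windows_100kb,windows_500kb F_ST window scans (may be `NULL`).
#' @param ihs_pop1,ihs_pop2 normalized iHS tracks.
#' @param xpehh normalized XP-EHH track.
#' @param thr a [criterion_thresholds()].
#' @param pop_labels direction labels, `c(pop1, pop2)`.
#' @return the validated regions with a `validations` column.
#' @export
cross_validate <- function(candidates, windows_100kb, windows_500kb,
                           ihs_pop1, ihs_pop2, xpehh,
                           thr = criterion_thresholds(),
                           pop_labels = c("pop1", "pop2")) {
  if (nrow(candidates) == 0) {
    candidates$validations <- character(0)
    return(candidates)
  }
  flag_fst <- function(w) {
    if (is.null(w) || nrow(w) == 0) return(NULL)
    w$fst_valid <- w$genome_rank_pct <= thr$fst_validation_pct
    w
  }
  wins <- rbind(flag_fst(windows_100kb), flag_fst(windows_500kb))
  ihs1_v <- tail_flags(abs(ihs_pop1$norm_ihs), ihs_pop1$chrom, ihs_pop1$pos_bp,
                       thr$ihs_validation_pct)
  ihs2_v <- tail_flags(abs(ihs_pop2$norm_ihs), ihs_pop2$chrom, ihs_pop2$pos_bp,
                       thr$ihs_validation_pct)
  xp_neg <- tail_flags(-xpehh$norm_xpehh, xpehh$chrom, xpehh$pos_bp,
                       thr$xpehh_validation_pct) & xpehh$norm_xpehh < 0
  xp_pos <- tail_flags(xpehh$norm_xpehh, xpehh$chrom, xpehh$pos_bp,
                       thr$xpehh_validation_pct) & xpehh$norm_xpehh > 0

  in_iv <- function(chrom, pos_bp, c, lo, hi)
    chrom == c & (pos_bp - 1) >= lo & (pos_bp - 1) < hi

  vals <- character(nrow(candidates))
  dirs <- candidates$direction
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    c <- candidates$chrom[i]; lo <- candidates$start_bp[i]; hi <- candidates$end_bp[i]
    got <- character(0); vdir <- character(0)
    if (!is.null(wins) && nrow(wins) > 0) {
      ov <- wins$chrom == c & wins$start_bp < hi & wins$end_bp > lo & wins$fst_valid
      if (any(ov)) got <- c(got, "FST")
    }
    h1 <- any(ihs1_v & in_iv(ihs_pop1$chrom, ihs_pop1$pos_bp, c, lo, hi))
    h2 <- any(ihs2_v & in_iv(ihs_pop2$chrom, ihs_pop2$pos_bp, c, lo, hi))
    # differential iHS: one population extreme, the other quiet; for a
    # directional candidate the extreme population must match the direction
    ihs_ok <- if (dirs[i] == pop_labels[1]) h1 && !h2
              else if (dirs[i] == pop_labels[2]) h2 && !h1
              else xor(h1, h2)
    if (ihs_ok) {
      got <- c(got, "iHS")
      vdir <- c(vdir, if (h1) pop_labels[1] else pop_labels[2])
    }
    xn <- any(xp_neg & in_iv(xpehh$chrom, xpehh$pos_bp, c, lo, hi))
    xp <- any(xp_pos & in_iv(xpehh$chrom, xpehh$pos_bp, c, lo, hi))
    # XP-EHH extreme must agree in sign with a directional candidate
    xp_ok <- if (dirs[i] == pop_labels[1]) xn
             else if (dirs[i] == pop_labels[2]) xp
             else xn || xp
    if (xp_ok) {
      got <- c(got, "XPEHH")
      if (xor(xn, xp)) vdir <- c(vdir, if (xn) pop_labels[1] else pop_labels[2])
    }
    got <- setdiff(got, candidates$discovery_metric[i])
    keep[i] <- length(got) >= 1
    vals[i] <- paste(got, collapse = "+")
    if (keep[i] && dirs[i] == "none" && length(unique(vdir)) == 1)
      dirs[i] <- vdir[1]
  }
  out <- candidates[keep, , drop = FALSE]
  out$direction <- dirs[keep]
  out$validations <- vals[keep]
  rownames(out) <- NULL
  out
}
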