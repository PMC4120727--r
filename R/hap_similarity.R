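#' Haplotype similarity score between two populations over one window
#'
#' Finds the set S of distinct haplotype strings whose frequency is at
#' least `freq_threshold` in population A and (by default) also in
#' population B, then scores the proportion of all haplotype copies in
#' the pooled two-population sample that match a member of S. Bounded
#' in [0,1]; larger means greater haplotype sharing.
#'
#' @param hapsA,hapsB 0/1 matrices (haplotype rows x identical SNP
#'   columns) for the two populations over one window's SNPs.
#' @param freq_threshold minimum within-population frequency for a
#'   haplotype to count as shared (default 0.02).
#' @param require_both if `TRUE` (default) the haplotype must reach the
#'   threshold in both populations separately; if `FALSE`, in either.
#' @return fraction in [0,1].
#' @export
similarity_score <- function(hapsA, hapsB, freq_threshold = 0.02,
                             require_both = TRUE) {
  if (nrow(hapsA) == 0 || nrow(hapsB) == 0) stop("both populations need haplotypes")
  if (ncol(hapsA) != ncol(hapsB)) stop("populations must share SNP columns")
  if (ncol(hapsA) == 0) stop("window holds no SNPs")
  keyA <- apply(hapsA, 1, paste, collapse = "")
  keyB <- apply(hapsB, 1, paste, collapse = "")
  fA <- table(keyA) / length(keyA)
  fB <- table(keyB) / length(keyB)
  inA <- names(fA)[fA >= freq_threshold]
  inB <- names(fB)[fB >= freq_threshold]
  S <- if (require_both) intersect(inA, inB) else union(inA, inB)
  (sum(keyA %in% S) + sum(keyB %in% S)) / (length(keyA) + length(keyB))
}

#' Windowed haplotype similarity track for two population pairs
#'
#' Divides each chromosome into non-overlapping `window_size` windows
#' (the same 0-based half-open grid as the F_ST scan), computes the
#' similarity score of `popA` against `popB` and against `popC` per
#' window, and classifies each window. Windows with no SNPs are
#' omitted; the per-window SNP count is reported so users can filter.
#'
#' @param haps a [haplotype_matrix()] holding all three panels.
#' @param variants the matching [variant_table()].
#' @param popA focal population; `popB`, `popC` the two comparators.
#' @param window_size window width in bp (default 100 kb).
#' @param freq_threshold passed to [similarity_score()].
#' @return `data.frame`: chrom, start_bp, end_bp, n_snps, score_pair1
#'   (A vs B), score_pair2 (A vs C), klass.
#' @export
similarity_track <- function(haps, variants, popA, popB, popC,
                             window_size = 100000, freq_threshold = 0.02) {
  mA <- subset_panel(haps, popA)$alleles
  mB <- subset_panel(haps, popB)$alleles
  mC <- subset_panel(haps, popC)$alleles
  win <- floor((variants$pos_bp - 1) / window_size)
  key <- paste0(variants$chrom, "\r", win)
  idx <- split(seq_len(nrow(variants)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(cols) {
    s1 <- similarity_score(mA[, cols, drop = FALSE], mB[, cols, drop = FALSE],
                           freq_threshold)
    s2 <- similarity_score(mA[, cols, drop = FALSE], mC[, cols, drop = FALSE],
                           freq_threshold)
    data.frame(chrom = variants$chrom[cols[1]],
               start_bp = win[cols[1]] * window_size,
               end_bp = (win[cols[1]] + 1) * window_size,
               n_snps = length(cols), score_pair1 = s1, score_pair2 = s2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$klass <- classify_windows(out$score_pair1, out$score_pair2)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Classify windows by the 0.5 similarity rule
#'
#' `pair1_similar` iff score_pair1 > 0.5 and score_pair2 < 0.5;
#' `pair2_similar` iff the reverse; otherwise `unclassified`.
#'
#' @param score_pair1,score_pair2 similarity scores in [0,1].
#' @return character vector of classes.
#' @export
classify_windows <- function(score_pair1, score_pair2) {
  ifelse(score_pair1 > 0.5 & score_pair2 < 0.5, "pair1_similar",
         ifelse(score_pair2 > 0.5 & score_pair1 < 0.5, "pair2_similar",
                "unclassified"))
}

#' Tally windows per similarity class
#'
#' @param klass character vector of classes (e.g. the `klass` column of
#'   [similarity_track()] output).
#' @return named integer vector over pair1_similar, pair2_similar,
#'   unclassified.
#' @export
count_classes <- function(klass) {
  lv <- c("pair1_similar", "pair2_similar", "unclassified")
  out <- table(factor(klass, levels = lv))
  setNames(as.integer(out), lv)
}
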