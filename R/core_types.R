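#' @useDynLib hapdiff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom rbeta rbinom rexp runif rpois sd setNames
#' @importFrom utils read.table write.table
NULL

#' Construct a variant table
#'
#' A variant table holds per-SNP identity for one panel: chromosome,
#' physical position (1-based, as parsed from the source file), alleles,
#' ancestral-allele status and interpolated genetic position.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos_bp integer vector of 1-based physical positions, strictly
#'   increasing within each chromosome.
#' @param id SNP identifiers (defaults to `chrom:pos`).
#' @param ref,alt reference / alternate allele nucleotide strings.
#' @param ancestral one of `"ref"`, `"alt"`, `"unknown"` per SNP.
#' @param gpos_cm genetic position in centimorgans (may be `NA` until a
#'   map is interpolated); must be non-decreasing within a chromosome.
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos_bp, id = NULL, ref, alt,
                          ancestral = "unknown", gpos_cm = NA_real_) {
  n <- length(pos_bp)
  if (is.null(id)) id <- paste0(chrom, ":", pos_bp)
  ancestral <- rep_len(as.character(ancestral), n)
  bad <- !ancestral %in% c("ref", "alt", "unknown")
  if (any(bad)) stop("ancestral must be 'ref', 'alt' or 'unknown'")
  vt <- data.frame(
    chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
    id = as.character(id), ref = as.character(ref), alt = as.character(alt),
    ancestral = ancestral, gpos_cm = rep_len(as.numeric(gpos_cm), n),
    stringsAsFactors = FALSE
  )
  for (ch in unique(vt$chrom)) {
    p <- vt$pos_bp[vt$chrom == ch]
    if (any(diff(p) <= 0)) stop("pos_bp must be strictly increasing within chromosome ", ch)
    g <- vt$gpos_cm[vt$chrom == ch]
    if (!anyNA(g) && any(diff(g) < 0)) stop("gpos_cm must be non-decreasing within chromosome ", ch)
  }
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Construct a phased haplotype matrix
#'
#' @param alleles integer matrix in {0,1}, haplotypes in rows, SNPs in
#'   columns; 0 codes the reference allele, 1 the alternate.
#' @param panel population label per haplotype (row).
#' @param sample_of diploid sample id per haplotype; each sample must
#'   contribute an even number of haplotypes.
#' @return list of class `haplotype_matrix` with elements `alleles`,
#'   `panel`, `sample_of`.
#' @export
haplotype_matrix <- function(alleles, panel, sample_of) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L)))
    stop("alleles must be a complete 0/1 matrix (phased input contract)")
  if (length(panel) != nrow(alleles) || length(sample_of) != nrow(alleles))
    stop("panel and sample_of must have one entry per haplotype row")
  if (any(table(sample_of) %% 2L != 0L))
    stop("each sample must contribute an even number of haplotypes")
  structure(list(alleles = alleles, panel = as.character(panel),
                 sample_of = as.character(sample_of)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d haplotypes x %d SNPs\n",
              nrow(x$alleles), ncol(x$alleles)))
  tab <- table(x$panel)
  cat("panels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Subset a haplotype matrix to one or more population panels
#'
#' @param haps a [haplotype_matrix()].
#' @param panels character vector of panel labels to keep.
#' @return a `haplotype_matrix` restricted to those haplotypes.
#' @export
subset_panel <- function(haps, panels) {
  keep <- haps$panel %in% panels
  if (!any(keep)) stop("no haplotypes in panel(s): ", paste(panels, collapse = ", "))
  haplotype_matrix(haps$alleles[keep, , drop = FALSE],
                   haps$panel[keep], haps$sample_of[keep])
}

#' Construct a genetic map
#'
#' @param pos_bp physical positions (bp), strictly increasing.
#' @param rate_cm_per_mb local recombination rate, cM/Mb, non-negative.
#' @param map_cm cumulative genetic position (cM), non-decreasing.
#' @return `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(pos_bp, rate_cm_per_mb, map_cm) {
  if (length(pos_bp) == 0L) stop("empty genetic map")
  if (any(diff(pos_bp) <= 0)) stop("map pos_bp must be strictly increasing")
  if (any(rate_cm_per_mb < 0)) stop("recombination rate must be >= 0")
  if (any(diff(map_cm) < 0)) stop("map_cm must be non-decreasing")
  gm <- data.frame(pos_bp = as.numeric(pos_bp),
                   rate_cm_per_mb = as.numeric(rate_cm_per_mb),
                   map_cm = as.numeric(map_cm))
  class(gm) <- c("genetic_map", "data.frame")
  gm
}
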