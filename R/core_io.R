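#' Read a phased VCF into a variant table and haplotype matrix
#'
#' Only biallelic SNPs with fully phased ("|") diploid genotypes are
#' accepted; anything else is a hard error naming the offending record.
#' The ancestral allele is taken from the `AA` INFO key where present
#' (matched against REF/ALT by nucleotide identity), otherwise `unknown`.
#'
#' @param path path to a VCF file (plain text or gzip).
#' @param panel_assignments named character vector mapping sample id to
#'   population label; every sample in the VCF must be present.
#' @return list with `variants` (a [variant_table()]) and `haplotypes`
#'   (a [haplotype_matrix()]); two haplotypes are emitted per sample, in
#'   sample order, alleles coded 0=ref / 1=alt.
#' @export
read_phased_vcf <- function(path, panel_assignments) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(samples, names(panel_assignments))
  if (length(missing) > 0)
    stop("sample(s) absent from panel_assignments: ", paste(missing, collapse = ", "))

  rec_label <- paste0(fix$CHROM, ":", fix$POS)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi))
    stop("multiallelic or ALT-less record at ", rec_label[which(multi)[1]])
  not_snp <- nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(not_snp))
    stop("non-SNP record at ", rec_label[which(not_snp)[1]])

  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(fix),
                                   dimnames = list(NULL, samples))
  unphased <- grepl("/", gt) | !grepl("^[01]\\|[01]$", gt)
  if (any(unphased)) {
    w <- arrayInd(which(unphased)[1], dim(gt))
    stop("unphased genotype at ", rec_label[w[1]], " sample ", colnames(gt)[w[2]])
  }

  # columns: SNPs; rows: haplotypes, two per sample in sample order
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  nh <- 2L * length(samples)
  alleles <- matrix(0L, nrow = nh, ncol = nrow(gt))
  alleles[seq(1, nh, by = 2), ] <- t(a1)
  alleles[seq(2, nh, by = 2), ] <- t(a2)

  aa <- vcfR::extract.info(v, element = "AA")
  ancestral <- rep("unknown", nrow(fix))
  if (!is.null(aa)) {
    aa <- toupper(aa)
    ancestral[!is.na(aa) & aa == toupper(fix$REF)] <- "ref"
    ancestral[!is.na(aa) & aa == toupper(fix$ALT)] <- "alt"
  }

  id <- ifelse(is.na(fix$ID) | fix$ID == ".", rec_label, fix$ID)
  vt <- variant_table(chrom = fix$CHROM, pos_bp = as.integer(fix$POS), id = id,
                      ref = fix$REF, alt = fix$ALT, ancestral = ancestral)
  sample_of <- rep(samples, each = 2)
  haps <- haplotype_matrix(alleles, panel = unname(panel_assignments[sample_of]),
                           sample_of = sample_of)
  list(variants = vt, haplotypes = haps)
}

#' Write a variant table + haplotype matrix as a phased VCF
#'
#' Emits a minimal plain-text VCFv4.2 with an `AA` INFO tag for SNPs
#' whose ancestral allele is known. Round-trips losslessly through
#' [read_phased_vcf()].
#'
#' @param variants a [variant_table()].
#' @param haps a [haplotype_matrix()] over the same SNP columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(variants, haps, path) {
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path))
  if (ncol(haps$alleles) != nrow(variants))
    stop("haplotype columns (", ncol(haps$alleles),
         ") do not match variant rows (", nrow(variants), ")")
  samples <- unique(haps$sample_of)
  info <- ifelse(variants$ancestral == "unknown", ".",
                 paste0("AA=", ifelse(variants$ancestral == "ref",
                                      variants$ref, variants$alt)))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gtcols <- vapply(samples, function(s) {
    rows <- which(haps$sample_of == s)
    paste0(haps$alleles[rows[1], ], "|", haps$alleles[rows[2], ])
  }, character(nrow(variants)))
  if (nrow(variants) == 1L) gtcols <- matrix(gtcols, nrow = 1L)
  body <- cbind(variants$chrom, variants$pos_bp, variants$id, variants$ref,
                variants$alt, ".", "PASS", info, "GT", gtcols)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read IMPUTE-style hap/legend/sample files
#'
#' The legend needs columns `id`, `position`, `a0`, `a1` (or
#' `allele0`/`allele1`), optionally `aa` naming the ancestral
#' nucleotide. The hap file holds one row per SNP of space-separated
#' 0/1 alleles, two columns per sample in sample-file order.
#'
#' @param hap_path,legend_path,sample_path file paths.
#' @param panel_assignments named character vector, sample id -> panel.
#' @param chrom chromosome label to assign (legend files carry none).
#' @return same contract as [read_phased_vcf()].
#' @export
read_impute_haps <- function(hap_path, legend_path, sample_path,
                             panel_assignments, chrom = "1") {
  leg <- read.table(legend_path, header = TRUE, stringsAsFactors = FALSE)
  names(leg) <- sub("^allele0$", "a0", sub("^allele1$", "a1", names(leg)))
  need <- c("id", "position", "a0", "a1")
  if (!all(need %in% names(leg)))
    stop("legend must have columns id, position, a0, a1")

  sl <- readLines(sample_path)
  sl <- sl[nzchar(trimws(sl))]
  if (length(sl) >= 1 && grepl("^ID_1\\b", sl[1])) sl <- sl[-(1:2)]
  samples <- vapply(strsplit(trimws(sl), "\\s+"), `[[`, "", 1)
  missing <- setdiff(samples, names(panel_assignments))
  if (length(missing) > 0)
    stop("sample(s) absent from panel_assignments: ", paste(missing, collapse = ", "))

  hl <- readLines(hap_path)
  hl <- hl[nzchar(trimws(hl))]
  if (length(hl) != nrow(leg))
    stop("hap rows (", length(hl), ") != legend rows (", nrow(leg), ")")
  toks <- strsplit(trimws(hl), "\\s+")
  ncols <- lengths(toks)
  if (any(ncols != 2L * length(samples)))
    stop("hap columns (", ncols[which(ncols != 2L * length(samples))[1]],
         ") != 2 x samples (", 2L * length(samples), ")")
  flat <- unlist(toks, use.names = FALSE)
  if (!all(flat %in% c("0", "1"))) stop("non-binary allele in hap file")
  # flat is row-major over SNPs: each hap-file row becomes one matrix column
  alleles <- matrix(as.integer(flat), nrow = 2L * length(samples))

  ancestral <- rep("unknown", nrow(leg))
  if ("aa" %in% names(leg)) {
    aa <- toupper(as.character(leg$aa))
    ancestral[!is.na(aa) & aa == toupper(leg$a0)] <- "ref"
    ancestral[!is.na(aa) & aa == toupper(leg$a1)] <- "alt"
  }
  vt <- variant_table(chrom = rep(chrom, nrow(leg)), pos_bp = leg$position,
                      id = leg$id, ref = leg$a0, alt = leg$a1,
                      ancestral = ancestral)
  # hap-file columns are (sample1_hapA, sample1_hapB, sample2_hapA, ...)
  sample_of <- rep(samples, each = 2)
  haps <- haplotype_matrix(alleles, panel = unname(panel_assignments[sample_of]),
                           sample_of = sample_of)
  list(variants = vt, haplotypes = haps)
}

#' Read a HapMap-format genetic map
#'
#' Three whitespace-delimited columns after one header line: physical
#' position (bp), recombination rate (cM/Mb), cumulative map (cM).
#'
#' @param path map file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  m <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(m) < 3) stop("genetic map needs 3 columns: pos, rate, map_cm")
  genetic_map(m[[1]], m[[2]], m[[3]])
}

#' Read a panel file (sample id, population label)
#'
#' @param path two-column whitespace-delimited file, no header.
#' @return named character vector mapping sample id to population.
#' @export
read_panel_file <- function(path) {
  p <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.character(p[[2]]), as.character(p[[1]]))
}

#' Intersect the SNP sets of two panels
#'
#' SNPs are matched by (chrom, pos); a match is kept when the allele
#' sets agree, with panel B's coding flipped when its ref/alt are
#' swapped relative to panel A. Same-position SNPs with incompatible
#' allele sets are dropped and tallied, not errored.
#'
#' @param tableA,tableB [variant_table()]s sorted by (chrom, pos_bp).
#' @return list with `idxA`, `idxB` (matched row indices), `flipB`
#'   (logical: panel B allele coding must be flipped), and
#'   `n_discarded` (shared positions dropped for allele incompatibility).
#' @export
intersect_panels <- function(tableA, tableB) {
  keyA <- paste0(tableA$chrom, ":", tableA$pos_bp)
  keyB <- paste0(tableB$chrom, ":", tableB$pos_bp)
  m <- match(keyA, keyB)
  hit <- which(!is.na(m))
  ia <- hit; ib <- m[hit]
  same <- tableA$ref[ia] == tableB$ref[ib] & tableA$alt[ia] == tableB$alt[ib]
  swap <- tableA$ref[ia] == tableB$alt[ib] & tableA$alt[ia] == tableB$ref[ib] & !same
  keep <- same | swap
  list(idxA = ia[keep], idxB = ib[keep], flipB = swap[keep],
       n_discarded = sum(!keep))
}

#' Interpolate genetic positions for physical positions
#'
#' Piecewise-linear interpolation of the cumulative map; positions
#' before the first (after the last) map point take the first (last)
#' map value (constant extrapolation).
#'
#' @param map a [genetic_map()].
#' @param pos_bp physical positions to interpolate.
#' @return genetic positions in cM.
#' @export
interpolate_gpos <- function(map, pos_bp) {
  if (nrow(map) == 0L) stop("empty genetic map")
  if (nrow(map) == 1L) return(rep(map$map_cm, length(pos_bp)))
  stats::approx(x = map$pos_bp, y = map$map_cm, xout = pos_bp,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Thin an ordered SNP set, keeping the first of every block of k
#'
#' Retains the 1st, (k+1)th, (2k+1)th, ... element, i.e. `ceiling(N/k)`
#' SNPs out of N.
#'
#' @param n_or_index either a single integer N (thin `1:N`) or an
#'   ordered index vector to thin.
#' @param k block size, default 4.
#' @return the retained index vector.
#' @export
thin_snps <- function(n_or_index, k = 4L) {
  if (k < 1) stop("k must be >= 1")
  idx <- if (length(n_or_index) == 1L && n_or_index >= 0) seq_len(n_or_index) else n_or_index
  if (length(idx) == 0L) return(integer(0))
  idx[seq(1L, length(idx), by = as.integer(k))]
}
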