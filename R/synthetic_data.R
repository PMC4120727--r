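#' Configuration for the phased-haplotype simulator
#'
#' The generative model has three stages. (1) Per-SNP ancestral allele
#' frequencies are drawn from a U-shaped Beta(0.5, 0.5) spectrum, and a
#' single shared ancestral founder pool of `n_founders` haplotypes is
#' sampled from them; per 0.25 cM block, Dirichlet(`weight_alpha`)
#' founder-copy weights describe locus-specific coancestry (blocks
#' where few founders dominate have long shared haplotypes).
#' (2) Divergence acts on those weights, not on the haplotypes: each
#' population's per-block weights are an independent Dirichlet draw
#' centred on the shared weights with precision (1-F)/F, F =
#' `divergence_level` — the multivariate Balding-Nichols construction,
#' under which every SNP's population frequency drifts with parameter
#' F while all populations keep copying the identical haplotype
#' library, as closely related populations do. At F = 0 the weights are
#' shared unchanged (panmixia). (3) Every emitted haplotype is a
#' mosaic of the founders with Poisson(`switch_rate` per cM)
#' breakpoints along the genetic map, founder choice following its
#' population's block weights, so linkage disequilibrium decays with
#' genetic distance. For a three-population design, population 1 is
#' built as an admixture: each mosaic segment draws founders using the
#' population-2-like weights with probability `admixture_proportion`
#' and the population-3-like weights otherwise.
#'
#' @param n_haplotypes haplotypes per population (even; >= 2).
#' @param n_snps number of SNPs per chromosome (>= 2).
#' @param chrom_length_bp chromosome length in bp.
#' @param n_chrom number of chromosomes (each of `chrom_length_bp` with
#'   `n_snps` SNPs); labels "1".."n_chrom".
#' @param recomb_rate_cm_per_mb constant recombination rate, or a
#'   `data.frame(start_bp, rate_cm_per_mb)` for a piecewise map.
#' @param divergence_level Balding-Nichols F in [0, 1).
#' @param n_pops 2 or 3 populations.
#' @param admixture_proportion population 1's population-2 ancestry
#'   fraction (three-population designs only; `NA` = no admixture).
#' @param sweep optional list(pop, position_bp, selection_strength,
#'   final_frequency) applied by [impose_sweep()]; selection_strength
#'   is the expected one-sided swept-tract length in cM.
#' @param seed mandatory integer RNG seed.
#' @param pop_labels population labels.
#' @param n_founders founder-pool size per population.
#' @param switch_rate mosaic breakpoints per cM.
#' @param miscopy_rate per-allele copying error rate.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_haplotypes = 160, n_snps = 3000,
                       chrom_length_bp = 2.5e6, n_chrom = 1,
                       recomb_rate_cm_per_mb = 1,
                       divergence_level = 0.004, n_pops = 2,
                       admixture_proportion = NA, sweep = NULL, seed,
                       pop_labels = c("pop1", "pop2", "pop3"),
                       n_founders = 60, switch_rate = 6,
                       miscopy_rate = 0.003, weight_alpha = 0.1,
                       weight_block_cm = 0.25) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_haplotypes < 2 || n_snps < 2) stop("all counts must be >= 2")
  if (n_haplotypes %% 2 != 0) stop("n_haplotypes must be even (diploid samples)")
  if (divergence_level < 0 || divergence_level >= 1)
    stop("divergence_level must be in [0, 1)")
  if (!n_pops %in% c(2, 3)) stop("n_pops must be 2 or 3")
  if (!is.na(admixture_proportion) &&
      (n_pops != 3 || admixture_proportion < 0 || admixture_proportion > 1))
    stop("admixture_proportion needs n_pops = 3 and a value in [0, 1]")
  if (!is.null(sweep)) {
    need <- c("pop", "position_bp", "selection_strength", "final_frequency")
    if (!all(need %in% names(sweep)))
      stop("sweep needs fields: ", paste(need, collapse = ", "))
    if (sweep$final_frequency < 0 || sweep$final_frequency > 1)
      stop("sweep final_frequency must be in [0, 1]")
    flat <- is.data.frame(recomb_rate_cm_per_mb) &&
      all(recomb_rate_cm_per_mb$rate_cm_per_mb == 0) ||
      (!is.data.frame(recomb_rate_cm_per_mb) && all(recomb_rate_cm_per_mb == 0))
    if (flat) stop("infeasible config: sweep requested with zero recombination")
  }
  structure(list(n_haplotypes = n_haplotypes, n_snps = n_snps,
                 chrom_length_bp = chrom_length_bp, n_chrom = as.integer(n_chrom),
                 recomb_rate_cm_per_mb = recomb_rate_cm_per_mb,
                 divergence_level = divergence_level, n_pops = n_pops,
                 admixture_proportion = admixture_proportion, sweep = sweep,
                 seed = as.integer(seed), pop_labels = pop_labels,
                 n_founders = n_founders, switch_rate = switch_rate,
                 miscopy_rate = miscopy_rate, weight_alpha = weight_alpha,
                 weight_block_cm = weight_block_cm),
            class = "sim_config")
}

build_map <- function(config) {
  L <- config$chrom_length_bp
  r <- config$recomb_rate_cm_per_mb
  if (is.data.frame(r)) {
    starts <- c(r$start_bp, L)
    if (starts[1] != 1) stop("piecewise map must start at 1 bp")
    map_cm <- c(0, cumsum(diff(starts) * r$rate_cm_per_mb / 1e6))
    genetic_map(starts, c(r$rate_cm_per_mb, r$rate_cm_per_mb[nrow(r)]), map_cm)
  } else {
    pts <- unique(c(seq(1, L, by = 5e5), L))
    genetic_map(pts, rep(r, length(pts)), (pts - 1) * r / 1e6)
  }
}

mosaic_haps <- function(pool, gpos, n_hap, switch_rate, total_cm, miscopy,
                        weights, weight_block_cm, ancestry_prob = NULL) {
  # Each emitted haplotype is a founder mosaic with Poisson breakpoints
  # along the map. Founder choice within a segment follows the coancestry
  # weights (list of one or two matrices, block x founder: one per ancestry)
  # of the block holding the segment start, so local haplotype diversity
  # varies along the chromosome.
  nsnp <- length(gpos)
  K <- nrow(pool)
  H <- matrix(0L, nrow = n_hap, ncol = nsnp)
  for (i in seq_len(n_hap)) {
    nb <- rpois(1, switch_rate * total_cm)
    breaks <- sort(runif(nb, 0, total_cm))
    seg <- findInterval(gpos, breaks) + 1L
    nseg <- max(seg)
    seg_start_cm <- c(0, breaks)[seq_len(nseg)]
    blk <- pmin(floor(seg_start_cm / weight_block_cm) + 1L, nrow(weights[[1]]))
    anc <- if (is.null(ancestry_prob)) rep(1L, nseg)
           else 1L + rbinom(nseg, 1, 1 - ancestry_prob)
    fid <- vapply(seq_len(nseg), function(s)
      sample.int(K, 1, prob = weights[[anc[s]]][blk[s], ]), integer(1))
    hap <- pool[cbind(fid[seg], seq_len(nsnp))]
    flip <- runif(nsnp) < miscopy
    hap[flip] <- 1L - hap[flip]
    H[i, ] <- hap
  }
  H
}

#' Simulate neutral phased haplotype panels
#'
#' Draws SNP positions, builds the genetic map, derives per-population
#' allele frequencies by Balding-Nichols drift and emits
#' founder-mosaic haplotypes (see [sim_config()]). Deterministic under
#' the config seed. The ancestral allele is always the reference
#' allele in the emitted coding.
#'
#' @param config a [sim_config()] (the `sweep` field is ignored here;
#'   see [simulate_dataset()]).
#' @return list with `variants` ([variant_table()]), `haplotypes`
#'   ([haplotype_matrix()]), `map` ([genetic_map()]), and `truth`
#'   (per-SNP realized per-population frequencies + model frequencies;
#'   `sweep` attribute `NULL`).
#' @export
simulate_neutral <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  npop <- config$n_pops
  labels <- config$pop_labels[seq_len(npop)]
  nh <- config$n_haplotypes
  K <- config$n_founders
  F <- config$divergence_level
  admix <- !is.na(config$admixture_proportion)

  one_chrom <- function(chrom_label) {
    ns <- config$n_snps
    pos <- sort(sample.int(config$chrom_length_bp, ns))
    map <- build_map(config)
    gpos <- interpolate_gpos(map, pos)
    total_cm <- max(map$map_cm)

    p0 <- pmin(pmax(rbeta(ns, 0.5, 0.5), 0.02), 0.98)
    ancestral_pool <- matrix(rbinom(K * ns, 1, rep(p0, each = K)), nrow = K)

    # Locus-specific coancestry: per 0.25 cM block, Dirichlet founder-copy
    # weights shared by every population. Blocks where a few founders
    # dominate have low haplotype diversity (long shared haplotypes) in all
    # populations at once, as in real genomes, so neutral EHH extremes
    # coincide between populations instead of arising independently.
    nblk <- max(1L, ceiling(total_cm / config$weight_block_cm))
    w <- matrix(rgamma(nblk * K, shape = config$weight_alpha), nrow = nblk)
    weights <- w / rowSums(w)

    # Divergence acts on the coancestry weights, not on the haplotypes:
    # every population copies the same ancestral founder pool, but its
    # per-block founder-copy weights are an independent Dirichlet draw
    # centred on the shared weights with precision (1-F)/F — the
    # multivariate Balding-Nichols construction, so every SNP's
    # population frequency drifts with parameter F = divergence_level
    # while populations keep sharing the identical haplotype library,
    # as closely related populations do. F = 0 reuses the shared weights
    # unchanged (panmixia).
    pop_weights <- lapply(seq_len(npop), function(k) {
      if (F == 0) return(weights)
      w <- matrix(rgamma(nblk * K, shape = weights * (1 - F) / F),
                  nrow = nblk)
      bad <- rowSums(w) == 0
      w[bad, ] <- weights[bad, ]
      w / rowSums(w)
    })

    hap_blocks <- lapply(seq_len(npop), function(k) {
      if (k == 1 && admix)
        mosaic_haps(ancestral_pool, gpos, nh, config$switch_rate, total_cm,
                    config$miscopy_rate, pop_weights[c(2, 3)],
                    config$weight_block_cm,
                    ancestry_prob = config$admixture_proportion)
      else
        mosaic_haps(ancestral_pool, gpos, nh, config$switch_rate, total_cm,
                    config$miscopy_rate, pop_weights[k],
                    config$weight_block_cm)
    })

    base <- c("A", "C", "G", "T")
    ref <- sample(base, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(base, r), 1), character(1))
    # model frequency per SNP: its block's weights applied to the pool
    blk_of <- pmin(floor(gpos / config$weight_block_cm) + 1L, nblk)
    weight_freq <- function(w) {
      q <- numeric(ns)
      for (b in unique(blk_of)) {
        cols <- which(blk_of == b)
        q[cols] <- as.vector(w[b, ] %*% ancestral_pool[, cols, drop = FALSE])
      }
      q
    }
    model_freq <- lapply(seq_len(npop), function(k) {
      if (k == 1 && admix)
        config$admixture_proportion * weight_freq(pop_weights[[2]]) +
          (1 - config$admixture_proportion) * weight_freq(pop_weights[[3]])
      else weight_freq(pop_weights[[k]])
    })
    list(chrom = rep(chrom_label, ns), pos = pos, gpos = gpos, ref = ref,
         alt = alt, map = map, alleles = do.call(rbind, hap_blocks),
         model_freq = model_freq)
  }

  chroms <- as.character(seq_len(config$n_chrom))
  parts <- lapply(chroms, one_chrom)

  vt <- variant_table(chrom = unlist(lapply(parts, `[[`, "chrom")),
                      pos_bp = unlist(lapply(parts, `[[`, "pos")),
                      ref = unlist(lapply(parts, `[[`, "ref")),
                      alt = unlist(lapply(parts, `[[`, "alt")),
                      ancestral = "ref",
                      gpos_cm = unlist(lapply(parts, `[[`, "gpos")))
  alleles <- do.call(cbind, lapply(parts, `[[`, "alleles"))
  panel <- rep(labels, each = nh)
  sample_of <- paste0(rep(labels, each = nh), "_s",
                      rep(rep(seq_len(nh / 2), each = 2), npop))
  haps <- haplotype_matrix(alleles, panel, sample_of)
  maps <- setNames(lapply(parts, `[[`, "map"), chroms)

  truth <- data.frame(id = vt$id, chrom = vt$chrom, pos_bp = vt$pos_bp,
                      ancestral = "ref", stringsAsFactors = FALSE)
  for (k in seq_len(npop)) {
    truth[[paste0("freq_", labels[k])]] <- allele_frequency(haps, labels[k])
    truth[[paste0("model_freq_", labels[k])]] <-
      unlist(lapply(parts, function(p) p$model_freq[[k]]))
  }
  attr(truth, "sweep") <- NULL
  list(variants = vt, haplotypes = haps, map = maps, truth = truth,
       config = config)
}

#' Impose a hard selective sweep on one population
#'
#' Star-like sweep approximation: a core haplotype carrying the derived
#' allele at the sweep SNP is copied, over an Exponentially distributed
#' (mean `selection_strength` cM) tract on each side of the core, into
#' enough haplotypes of the target population to bring the derived
#' allele to `final_frequency`, erasing local diversity. The other
#' population(s) are untouched.
#'
#' @param sim output of [simulate_neutral()].
#' @param sweep list(pop, position_bp, selection_strength,
#'   final_frequency, and optionally chrom — default the first
#'   chromosome).
#' @return the modified sim; `attr(sim$truth, "sweep")` records the
#'   core SNP and the bp interval covering the expected swept tract.
#' @export
impose_sweep <- function(sim, sweep) {
  f <- sweep$final_frequency
  if (f < 0 || f > 1) stop("final_frequency must be in [0,1]")
  if (f == 0) return(sim)
  chrom <- if (is.null(sweep$chrom)) sim$variants$chrom[1] else as.character(sweep$chrom)
  on_chr <- which(sim$variants$chrom == chrom)
  if (length(on_chr) == 0) stop("sweep chromosome not simulated: ", chrom)
  rows <- which(sim$haplotypes$panel == sweep$pop)
  if (length(rows) == 0) stop("no haplotypes in target population ", sweep$pop)
  n_target <- round(f * length(rows))
  if (n_target > length(rows))
    stop("final_frequency incompatible with panel size")
  if (n_target == 0) return(sim)
  core <- on_chr[which.min(abs(sim$variants$pos_bp[on_chr] - sweep$position_bp))]
  gpos <- sim$variants$gpos_cm
  H <- sim$haplotypes$alleles

  carriers <- rows[H[rows, core] == 1L]
  core_row <- if (length(carriers) > 0) carriers[1] else rows[1]
  if (length(carriers) == 0) H[core_row, core] <- 1L
  swept <- unique(c(core_row,
                    carriers[seq_len(min(length(carriers), n_target))],
                    sample(rows, length(rows))))  # deterministic order then fill
  swept <- swept[swept %in% rows][seq_len(n_target)]

  core_hap <- H[core_row, ]
  for (r in swept) {
    lo_cm <- gpos[core] - rexp(1, 1 / sweep$selection_strength)
    hi_cm <- gpos[core] + rexp(1, 1 / sweep$selection_strength)
    cols <- on_chr[gpos[on_chr] >= lo_cm & gpos[on_chr] <= hi_cm]
    H[r, cols] <- core_hap[cols]
    H[r, core] <- 1L
  }
  if (f == 1 && any(H[rows, core] != 1L)) H[rows, core] <- 1L

  sim$haplotypes$alleles <- H
  for (lab in unique(sim$haplotypes$panel)) {
    col <- paste0("freq_", lab)
    if (col %in% names(sim$truth))
      sim$truth[[col]] <- allele_frequency(sim$haplotypes, lab)
  }
  half_cm <- 2 * sweep$selection_strength
  map <- sim$map[[chrom]]
  inv <- function(g) stats::approx(map$map_cm, map$pos_bp, xout = g,
                                   rule = 2, ties = "ordered")$y
  attr(sim$truth, "sweep") <- list(
    pop = sweep$pop, chrom = chrom, core_snp = core,
    core_pos_bp = sim$variants$pos_bp[core],
    start_bp = floor(inv(gpos[core] - half_cm)),
    end_bp = ceiling(inv(gpos[core] + half_cm)),
    final_frequency = f)
  sim
}

#' Simulate a full dataset (neutral panels plus optional sweep)
#'
#' @param config a [sim_config()]; if its `sweep` field is set the
#'   sweep is imposed after the neutral stage, under the same seed
#'   stream.
#' @return same structure as [simulate_neutral()].
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_neutral(config)
  if (!is.null(config$sweep)) sim <- impose_sweep(sim, config$sweep)
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits a phased VCF (with AA tags), one HapMap-format genetic map per
#' chromosome, a two-column panel file and the truth table as TSV; the
#' VCF/map/panel files round-trip losslessly through
#' [read_phased_vcf()], [read_genetic_map()] and [read_panel_file()].
#'
#' @param sim output of [simulate_dataset()].
#' @param dir existing output directory.
#' @param prefix file-name prefix (default `"sim"`).
#' @return named vector of the written paths, invisibly.
#' @export
emit_dataset <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) stop("missing output directory: ", dir)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             panel = file.path(dir, paste0(prefix, ".panel.txt")),
             truth = file.path(dir, paste0(prefix, ".truth.tsv")))
  write_phased_vcf(sim$variants, sim$haplotypes, paths["vcf"])
  for (ch in names(sim$map)) {
    p <- file.path(dir, paste0(prefix, ".map.chr", ch, ".txt"))
    write.table(data.frame(position = sim$map[[ch]]$pos_bp,
                           rate_cM_Mb = sim$map[[ch]]$rate_cm_per_mb,
                           map_cM = sim$map[[ch]]$map_cm),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("map_chr", ch)] <- p
  }
  samples <- unique(sim$haplotypes$sample_of)
  pops <- sim$haplotypes$panel[match(samples, sim$haplotypes$sample_of)]
  write.table(data.frame(samples, pops), paths["panel"], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
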