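test_that("config validation rejects infeasible designs", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, n_haplotypes = 1), "counts")
  expect_error(sim_config(seed = 1, n_haplotypes = 7), "even")
  expect_error(sim_config(seed = 1, divergence_level = 1), "divergence_level")
  expect_error(sim_config(seed = 1, admixture_proportion = 0.5), "n_pops = 3")
  expect_error(sim_config(seed = 1, recomb_rate_cm_per_mb = 0,
                          sweep = list(pop = "pop1", position_bp = 1,
                                       selection_strength = 1,
                                       final_frequency = 0.5)),
               "zero recombination")
})

test_that("simulation is deterministic under the seed", {
  a <- small_sim(17)
  b <- small_sim(17)
  c <- small_sim(18)
  expect_identical(a$haplotypes$alleles, b$haplotypes$alleles)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$haplotypes$alleles, c$haplotypes$alleles))
})

test_that("truth-table frequencies match the emitted panels", {
  sim <- small_sim(19)
  expect_equal(sim$truth$freq_pop1,
               unname(allele_frequency(sim$haplotypes, "pop1")))
  expect_equal(sim$truth$freq_pop2,
               unname(allele_frequency(sim$haplotypes, "pop2")))
})

test_that("divergence drives mean F_ST monotonically and vanishes under panmixia", {
  mean_fst <- function(d) {
    out <- numeric(4)
    for (i in 1:4) {
      sim <- simulate_neutral(sim_config(seed = 400 + i, n_haplotypes = 80,
                                         n_snps = 500, chrom_length_bp = 1e6,
                                         divergence_level = d))
      out[i] <- mean(fst_two_pop(sim$truth$freq_pop1, sim$truth$freq_pop2))
    }
    mean(out)
  }
  f0 <- mean_fst(0); f1 <- mean_fst(0.008); f2 <- mean_fst(0.02); f3 <- mean_fst(0.06)
  expect_lt(f0, 0.02)   # sampling noise only
  expect_lt(f0, f1); expect_lt(f1, f2); expect_lt(f2, f3)
})

test_that("linkage disequilibrium decays with genetic distance", {
  r2_by_bin <- matrix(NA_real_, 3, 3)
  for (i in 1:3) {
    sim <- simulate_neutral(sim_config(seed = 500 + i, n_haplotypes = 80,
                                       n_snps = 800, chrom_length_bp = 2e6,
                                       divergence_level = 0))
    m <- sim$haplotypes$alleles
    g <- sim$variants$gpos_cm
    poly <- which(apply(m, 2, sd) > 0)
    set.seed(i)
    pairs <- cbind(sample(poly, 4000, TRUE), sample(poly, 4000, TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], ]
    d <- abs(g[pairs[, 1]] - g[pairs[, 2]])
    r2 <- (apply(pairs, 1, function(p) cor(m[, p[1]], m[, p[2]])))^2
    bin <- cut(d, c(0, 0.01, 0.1, 1), labels = FALSE)
    for (b in 1:3) r2_by_bin[i, b] <- mean(r2[which(bin == b)], na.rm = TRUE)
  }
  avg <- colMeans(r2_by_bin)
  expect_gt(avg[1], avg[2])
  expect_gt(avg[2], avg[3])
})

test_that("an imposed sweep homogenizes the target population locally", {
  cfg <- sim_config(seed = 33, n_haplotypes = 60, n_snps = 800,
                    chrom_length_bp = 2e6, divergence_level = 0.02)
  sim <- simulate_neutral(cfg)
  spec <- list(pop = "pop1", position_bp = 1e6, selection_strength = 0.4,
               final_frequency = 1.0)
  swept <- impose_sweep(sim, spec)
  sw <- attr(swept$truth, "sweep")
  expect_equal(sw$pop, "pop1")
  # fixation at the core in the target population only
  expect_equal(unname(allele_frequency(swept$haplotypes, "pop1", sw$core_snp)), 1)
  expect_lt(allele_frequency(swept$haplotypes, "pop2", sw$core_snp), 1)
  # the untouched population is bit-identical
  p2 <- sim$haplotypes$panel == "pop2"
  expect_identical(swept$haplotypes$alleles[p2, ], sim$haplotypes$alleles[p2, ])
  # EHH at the core is higher in the swept population at every offset nearby
  core <- sw$core_snp
  g <- swept$variants$gpos_cm
  rows1 <- which(swept$haplotypes$panel == "pop1")
  rows2 <- which(swept$haplotypes$panel == "pop2")
  for (t in core + c(-20, -5, 5, 20)) {
    e1 <- ehh_at(swept$haplotypes, rows1, core, t)
    e2 <- ehh_at(swept$haplotypes, rows2, core, t)
    expect_gte(e1, e2)
  }
  # final_frequency 0 leaves the panel untouched
  same <- impose_sweep(sim, modifyList(spec, list(final_frequency = 0)))
  expect_identical(same$haplotypes$alleles, sim$haplotypes$alleles)
})

test_that("emitted datasets round-trip through the readers", {
  sim <- simulate_dataset(sim_config(seed = 44, n_haplotypes = 20, n_snps = 120,
                                     chrom_length_bp = 5e5, n_chrom = 2,
                                     divergence_level = 0.02))
  d <- withr::local_tempdir()
  paths <- emit_dataset(sim, d)
  pa <- read_panel_file(paths["panel"])
  back <- read_phased_vcf(paths["vcf"], pa)
  expect_equal(back$haplotypes$alleles, sim$haplotypes$alleles,
               ignore_attr = TRUE)
  expect_equal(back$haplotypes$panel, sim$haplotypes$panel)
  expect_equal(back$variants$pos_bp, sim$variants$pos_bp)
  expect_equal(back$variants$chrom, sim$variants$chrom)
  expect_equal(back$variants$ancestral, sim$variants$ancestral)
  m1 <- read_genetic_map(paths["map_chr1"])
  expect_equal(m1$map_cm, sim$map[["1"]]$map_cm)
  tt <- read.table(paths["truth"], header = TRUE, stringsAsFactors = FALSE)
  expect_equal(tt$freq_pop1, sim$truth$freq_pop1)
  expect_error(emit_dataset(sim, file.path(d, "missing_dir")),
               "missing output directory")
})
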