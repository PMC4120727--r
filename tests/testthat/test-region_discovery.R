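# Build a minimal normalized score track for discovery tests.
score_track <- function(pos, norm, chrom = "1") {
  data.frame(chrom = chrom, pos_bp = pos, id = as.character(pos),
             norm_ihs = norm, norm_xpehh = norm, stringsAsFactors = FALSE)
}

flat_track <- function(n, chrom = "1", spacing = 1000) {
  score_track(seq(spacing, by = spacing, length.out = n), rep(0, n), chrom)
}

test_that("threshold container enforces tier ordering and range", {
  thr <- criterion_thresholds()
  expect_equal(thr$fst_discovery_pct, 0.1)
  expect_equal(thr$xpehh_discovery_pct, 0.01)
  expect_error(criterion_thresholds(fst_discovery_pct = 2, fst_validation_pct = 1),
               "discovery tier must be <=")
  expect_error(criterion_thresholds(ihs_discovery_pct = 0), "percentages")
})

test_that("F_ST window discovery returns exactly the top-ranked fraction", {
  n <- 2000
  w <- data.frame(chrom = "1", start_bp = (0:(n - 1)) * 1e5,
                  end_bp = (1:n) * 1e5, window_size = 1e5,
                  n_snps = 10L, n_extreme = 0L,
                  binom_p = seq(0.001, 1, length.out = n),
                  stringsAsFactors = FALSE)
  w$genome_rank <- rank(w$binom_p)
  w$genome_rank_pct <- 100 * w$genome_rank / n
  out <- discover_fst_regions(w, NULL)
  expect_equal(nrow(out), 2)  # top 0.1% of 2000
  expect_equal(out$start_bp, c(0, 1e5))
  expect_equal(out$discovery_metric, rep("FST", 2))
  # nothing qualifies when no window reaches the tier
  w$genome_rank_pct <- w$genome_rank_pct + 50
  expect_equal(nrow(discover_fst_regions(w, NULL)), 0)
})

test_that("iHS discovery applies the other-population exclusion and merges neighbours", {
  n <- 2000
  a <- flat_track(n)
  b <- flat_track(n)
  a$norm_ihs[1000] <- 6  # the single top-0.1% SNP (floor(2000*0.001) = 2 slots)
  a$norm_ihs[1004] <- 5.5  # 4 kb away: second slot, same padded region
  out <- discover_ihs_regions(a, b, region_pad = 1e4)
  expect_equal(nrow(out), 1)  # merged into one region
  expect_equal(out$direction, "pop1")
  expect_equal(out$n_support_snps, 2L)
  expect_equal(out$start_bp, a$pos_bp[1000] - 1 - 1e4)

  # exclusion: a top-1% SNP of the other population inside the pad kills it
  b2 <- b; b2$norm_ihs[1010] <- 6
  expect_equal(nrow(discover_ihs_regions(a, b2, region_pad = 1e4)), 0)
  # ... but a far-away one does not (it seeds its own opposite-direction
  # region instead, since the spike is b's genome-wide maximum)
  b3 <- b; b3$norm_ihs[1500] <- 6
  out3 <- discover_ihs_regions(a, b3, region_pad = 1e4)
  expect_true(any(out3$direction == "pop1" & out3$start_bp < a$pos_bp[1000]))
})

test_that("XP-EHH discovery seeds regions from either extreme with sign-based direction", {
  n <- 20000
  x <- flat_track(n)
  x$norm_xpehh[5000] <- -8
  x$norm_xpehh[15000] <- 8
  out <- discover_xpehh_regions(x, region_pad = 1e4)
  expect_equal(nrow(out), 2)
  expect_equal(out$direction[order(out$start_bp)], c("pop1", "pop2"))
  expect_equal(nrow(discover_xpehh_regions(flat_track(n))), 0)
  # a cluster of extreme SNPs merges into a single region
  x2 <- flat_track(n)
  x2$norm_xpehh[5000 + 0:1] <- -8   # floor(2e4 * 1e-4) = 2 slots
  out2 <- discover_xpehh_regions(x2, region_pad = 1e4)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$n_support_snps, 2L)
})

test_that("cross-validation keeps only two-of-three regions and inherits direction", {
  n <- 2000
  cand <- data.frame(chrom = "1", start_bp = 100000, end_bp = 200000,
                     discovery_metric = "FST", discovery_detail = "100kb",
                     direction = "none", n_support_snps = 5L,
                     stringsAsFactors = FALSE)
  ihs_a <- flat_track(n); ihs_b <- flat_track(n)
  xp <- flat_track(n)
  empty_w <- NULL
  # no supporting metric -> dropped
  out <- cross_validate(cand, empty_w, empty_w, ihs_a, ihs_b, xp)
  expect_equal(nrow(out), 0)
  # one XP-EHH SNP in the top 0.5% of the negative extreme inside -> kept,
  # direction inherited from the sign (negative = pop1)
  xp2 <- xp; xp2$norm_xpehh[150] <- -9  # pos 150000 inside the window
  out2 <- cross_validate(cand, empty_w, empty_w, ihs_a, ihs_b, xp2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$validations, "XPEHH")
  expect_equal(out2$direction, "pop1")
  # iHS validation requires one population only (xor)
  ihs_a2 <- ihs_a; ihs_a2$norm_ihs[150] <- 9
  out3 <- cross_validate(cand, empty_w, empty_w, ihs_a2, ihs_b, xp)
  expect_equal(out3$validations, "iHS")
  ihs_b2 <- ihs_b; ihs_b2$norm_ihs[160] <- 9
  out4 <- cross_validate(cand, empty_w, empty_w, ihs_a2, ihs_b2, xp)
  expect_equal(nrow(out4), 0)  # both populations extreme -> no iHS validation
  # the discovery metric itself never counts as validation
  w <- data.frame(chrom = "1", start_bp = 100000, end_bp = 200000,
                  window_size = 1e5, n_snps = 10L, n_extreme = 9L,
                  binom_p = 1e-12, genome_rank = 1L, genome_rank_pct = 0.05,
                  stringsAsFactors = FALSE)
  out5 <- cross_validate(cand, w, NULL, ihs_a, ihs_b, xp)
  expect_equal(nrow(out5), 0)
})

test_that("raising a discovery threshold never adds regions", {
  set.seed(31)
  n <- 4000
  a <- score_track(seq(1000, by = 1000, length.out = n), rnorm(n))
  b <- score_track(seq(1000, by = 1000, length.out = n), rnorm(n))
  loose <- criterion_thresholds(ihs_discovery_pct = 0.5)
  tight <- criterion_thresholds(ihs_discovery_pct = 0.1)
  r_loose <- discover_ihs_regions(a, b, loose)
  r_tight <- discover_ihs_regions(a, b, tight)
  expect_lte(nrow(r_tight), nrow(r_loose))
  # every tight region is contained in some loose region
  if (nrow(r_tight) > 0 && nrow(r_loose) > 0) {
    for (i in seq_len(nrow(r_tight))) {
      expect_true(any(r_loose$start_bp <= r_tight$start_bp[i] &
                        r_loose$end_bp >= r_tight$end_bp[i]))
    }
  }
})
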