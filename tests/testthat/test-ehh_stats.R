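test_that("ehh_at equals the brute-force pair-enumeration oracle", {
  # worked toy: 4 carriers forming two identical pairs over the interval
  m <- rbind(c(0, 1, 0), c(0, 1, 0), c(1, 1, 0), c(1, 1, 0))
  haps <- toy_haps(m)
  expect_equal(ehh_at(haps, 1:4, 2, 1), 1 / 3)
  expect_equal(ehh_at(haps, 1:2, 2, 2), 1)     # target = core, allele class
  expect_equal(ehh_at(haps, 1:2, 2, 3), 1)     # identical over the interval
  expect_error(ehh_at(haps, 1, 1, 1), "at least 2 carriers")

  # randomized equivalence on panels up to 20 x 50
  set.seed(99)
  for (rep in 1:50) {
    nh <- sample(seq(4, 20, by = 2), 1); ns <- sample(5:50, 1)
    m <- matrix(rbinom(nh * ns, 1, runif(1, 0.2, 0.8)), nh, ns)
    haps <- toy_haps(m)
    carriers <- sample(nh, sample(2:nh, 1))
    core <- sample(ns, 1); target <- sample(ns, 1)
    expect_equal(ehh_at(haps, carriers, core, target),
                 ehh_oracle(m, carriers, core, target))
  }
})

test_that("EHH curves start at 1 for allele classes and never increase outward", {
  sim <- small_sim(3)
  carriers <- which(sim$haplotypes$alleles[, 200] == 1)
  for (side in c("up", "down")) {
    cv <- ehh_curve(sim$haplotypes, carriers, 200, sim$variants$gpos_cm, side)
    expect_equal(cv$ehh[1], 1)
    expect_true(all(diff(cv$ehh) <= 1e-12))
    expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
  }
})

test_that("iHH integration follows the hand trapezoid sum and flags edge cases", {
  pts <- data.frame(offset_cm = c(0, 0.1, 0.2), ehh = c(1, 0.5, 0.04))
  a <- integrate_ihh(pts)
  expect_equal(as.numeric(a), 0.075 + 0.027)
  expect_equal(attr(a, "status"), "ok")
  # truncation: points past the first sub-cutoff SNP are ignored
  pts2 <- rbind(pts, data.frame(offset_cm = 0.3, ehh = 0.9))
  expect_equal(as.numeric(integrate_ihh(pts2)), 0.102)
  # never decays -> edge; single point -> edge
  flat <- data.frame(offset_cm = c(0, 0.1, 0.2), ehh = c(1, 1, 1))
  expect_true(is.na(integrate_ihh(flat)))
  expect_equal(attr(integrate_ihh(flat), "status"), "edge")
  expect_true(is.na(integrate_ihh(pts[1, ])))
})

test_that("raw iHS is antisymmetric in the ancestral annotation and catches sweeps", {
  sim <- small_sim(5)
  ihs <- ihs_scan(sim$haplotypes, sim$variants, "pop1")
  ok <- ihs$skip_reason == "ok"
  expect_gt(sum(ok), 50)
  expect_true(all(is.finite(ihs$raw_ihs[ok])))
  expect_true(all(ihs$bin_id %in% 1:20, na.rm = TRUE))
  expect_equal(ihs$bin_id[ok], pmin(pmax(floor(ihs$daf[ok] / 0.05) + 1, 1), 20))

  # swapping the ancestral annotation negates raw_ihs (daf mirrors too)
  vflip <- sim$variants
  vflip$ancestral <- "alt"
  flip <- ihs_scan(sim$haplotypes, vflip, "pop1")
  both <- ok & flip$skip_reason == "ok"
  expect_equal(flip$raw_ihs[both], -ihs$raw_ihs[both])

  # derived carriers all identical over a long span vs diverse ancestral -> raw_ihs < 0
  set.seed(2)
  n <- 10; ns <- 41
  m <- matrix(rbinom(n * ns, 1, 0.5), n, ns)
  core <- 21
  span <- 11:31  # derived carriers share one haplotype over the middle only
  m[1:5, span] <- matrix(rep(rbinom(length(span), 1, 0.5), each = 5), 5)
  m[1:5, core] <- 1; m[6:10, core] <- 0
  haps <- toy_haps(m)
  vt <- toy_variants(ns, spacing = 2000, rate = 50)
  rec <- ihs_scan(haps, vt, "pop1", min_daf = 0.01, max_daf = 0.99)
  expect_equal(rec$skip_reason[core], "ok")
  expect_lt(rec$raw_ihs[core], 0)
  # oracle for the same quantity via ehh_curve + integrate_ihh
  for (cls in list(which(m[, core] == 1), which(m[, core] == 0))) {
    up <- integrate_ihh(ehh_curve(haps, cls, core, vt$gpos_cm, "up"))
    dn <- integrate_ihh(ehh_curve(haps, cls, core, vt$gpos_cm, "down"))
    lab <- if (m[cls[1], core] == 1) "ihh_d" else "ihh_a"
    expect_equal(rec[[lab]][core], as.numeric(up) + as.numeric(dn))
  }
})

test_that("iHS skip rules fire for unknown ancestry, DAF bounds and carriers", {
  sim <- small_sim(6)
  v <- sim$variants
  v$ancestral[1:10] <- "unknown"
  rec <- ihs_scan(sim$haplotypes, v, "pop1")
  expect_true(all(rec$skip_reason[1:10] == "no_ancestral"))
  daf <- rec$daf
  expect_true(all(rec$skip_reason[which(daf < 0.05 | daf > 0.95)] %in%
                    c("daf", "no_ancestral")))
})

test_that("iHS normalization hits exact zero-mean unit-sd moments per DAF bin", {
  rec <- data.frame(chrom = "1", pos_bp = 1:9, id = as.character(1:9),
                    daf = c(rep(0.12, 3), rep(0.52, 4), rep(0.93, 2)),
                    ihh_a = 1, ihh_d = 1,
                    raw_ihs = c(-1, 0, 1, 2, 4, 6, 8, 5, 5),
                    bin_id = c(3, 3, 3, 11, 11, 11, 11, 19, 19),
                    skip_reason = "ok", stringsAsFactors = FALSE)
  out <- normalize_ihs(rec)
  expect_equal(out$norm_ihs[1:3], c(-1, 0, 1))
  for (b in c(3, 11)) {
    i <- out$bin_id == b
    expect_equal(mean(out$norm_ihs[i]), 0)
    expect_equal(sd(out$norm_ihs[i]), 1)
  }
  # zero-spread bin is flagged unnormalized, not scored
  expect_true(all(out$unnormalized[out$bin_id == 19]))
  expect_true(all(is.na(out$norm_ihs[out$bin_id == 19])))
})

test_that("XP-EHH is antisymmetric under population swap and signs sweeps in pop1 negative", {
  sim <- small_sim(8)
  xp12 <- xpehh_scan(sim$haplotypes, sim$variants, "pop1", "pop2")
  xp21 <- xpehh_scan(sim$haplotypes, sim$variants, "pop2", "pop1")
  ok <- xp12$skip_reason == "ok"
  expect_gt(sum(ok), 100)
  expect_equal(xp12$raw_xpehh[ok], -xp21$raw_xpehh[ok])
  expect_equal(xp12$ihh_pop1[ok], xp21$ihh_pop2[ok])

  # identical panels -> raw 0
  h2 <- haplotype_matrix(rbind(sim$haplotypes$alleles[sim$haplotypes$panel == "pop1", ],
                               sim$haplotypes$alleles[sim$haplotypes$panel == "pop1", ]),
                         rep(c("a", "b"), each = sum(sim$haplotypes$panel == "pop1")),
                         paste0("s", rep(seq_len(sum(sim$haplotypes$panel == "pop1")), 2)))
  same <- xpehh_scan(h2, sim$variants, "a", "b")
  expect_equal(same$raw_xpehh[same$skip_reason == "ok"],
               rep(0, sum(same$skip_reason == "ok")))

  # pop1 fixed for one long haplotype, pop2 diverse -> raw < 0 (longer haps in pop1)
  set.seed(4)
  ns <- 41
  base <- rbinom(ns, 1, 0.5)
  m1 <- matrix(rep(base, each = 8), 8, ns)
  flip <- matrix(runif(8 * ns) < 0.08, 8, ns)  # nearly fixed, not perfectly
  m1[flip] <- 1L - m1[flip]
  m2 <- matrix(rbinom(8 * ns, 1, 0.5), 8, ns)
  haps <- haplotype_matrix(rbind(m1, m2), rep(c("p1", "p2"), each = 8),
                           paste0("s", rep(1:8, each = 2)))
  vt <- toy_variants(ns, spacing = 2000, rate = 50)
  xp <- xpehh_scan(haps, vt, "p1", "p2")
  mid <- xp$skip_reason == "ok"
  expect_true(any(mid))
  expect_true(all(xp$raw_xpehh[mid] < 0))
})

test_that("XP-EHH normalization is a single genome-wide standardization", {
  rec <- data.frame(chrom = "1", pos_bp = 1:3, id = as.character(1:3),
                    ihh_pop1 = 1, ihh_pop2 = 1, raw_xpehh = c(-2, 0, 2),
                    skip_reason = "ok", stringsAsFactors = FALSE)
  out <- normalize_xpehh(rec)
  expect_equal(out$norm_xpehh, c(-2, 0, 2) / sqrt(8 / 3))
  expect_equal(mean(out$norm_xpehh), 0)
  expect_equal(mean(out$norm_xpehh^2), 1)
  rec$raw_xpehh <- c(1, 1, 1)
  expect_error(normalize_xpehh(rec), "zero variance")
})

test_that("whole-scan normalization moments are exact on simulated data", {
  sim <- small_sim(13)
  ihs <- normalize_ihs(ihs_scan(sim$haplotypes, sim$variants, "pop1"))
  sc <- ihs[!is.na(ihs$norm_ihs), ]
  for (b in unique(sc$bin_id)) {
    expect_equal(mean(sc$norm_ihs[sc$bin_id == b]), 0, tolerance = 1e-9)
    expect_equal(sd(sc$norm_ihs[sc$bin_id == b]), 1, tolerance = 1e-9)
  }
  xp <- normalize_xpehh(xpehh_scan(sim$haplotypes, sim$variants, "pop1", "pop2"))
  z <- xp$norm_xpehh[!is.na(xp$norm_xpehh)]
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(mean(z^2), 1, tolerance = 1e-9)
})
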