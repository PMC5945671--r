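test_that("het-SNP selection applies the inclusive 0.3-0.7 band", {
  sites <- data.frame(chrom = "c", pos = 1:5,
                      normal_af = c(0.5, 0.29, 0.3, 0.7, 0.71))
  expect_equal(select_het_snps(sites)$pos, c(1, 3, 4))
  set.seed(9)
  sites2 <- data.frame(chrom = "c", pos = 1:100, normal_af = runif(100))
  n_in <- sum(sites2$normal_af >= 0.3 & sites2$normal_af <= 0.7)
  expect_equal(nrow(select_het_snps(sites2)), n_in)
})

test_that("allelic-state classification separates balanced/imbalanced", {
  set.seed(11)
  bal <- rbinom(100, 60, 0.5) / 60
  expect_equal(classify_allelic_state(bal)$class, "balanced")

  # B = 2 of CN 3 at purity 1: peaks at 1/3 and 2/3
  which_hap <- runif(200) < 0.5
  p <- ifelse(which_hap, 2 / 3, 1 / 3)
  imb <- rbinom(200, 100, p) / 100
  cl <- classify_allelic_state(imb)
  expect_equal(cl$class, "imbalanced")
  expect_equal(cl$mean_baf, 2 / 3, tolerance = 0.03)

  # unimodal off-center: ambiguous
  amb <- rbinom(100, 400, 0.62) / 400
  expect_equal(classify_allelic_state(amb)$class, "ambiguous")

  expect_equal(classify_allelic_state(rep(0.5, 19))$class, "insufficient")
})

test_that("B-allele read count is coverage times BAF", {
  expect_equal(b_allele_read_count(100, 0.6667), 66.67)
  expect_equal(b_allele_read_count(80, 0.5), 40)
  expect_error(b_allele_read_count(100, NA), "missing")
  # agrees with the direct mean of per-SNP B reads on simulation
  set.seed(12)
  depth <- rpois(500, 100)
  b <- rbinom(500, depth, 2 / 3)
  seg_estimate <- b_allele_read_count(mean(depth), mean(pmax(b / depth,
                                                             1 - b / depth)))
  expect_equal(seg_estimate, mean(pmax(b, depth - b)), tolerance = 3)
})

test_that("coverage-ratio model and its inversion are mutual inverses", {
  expect_equal(expected_coverage_ratio(2, 0.7, 2), 1)
  expect_equal(expected_coverage_ratio(1, 1, 2), 0.5)
  expect_equal(expected_coverage_ratio(4, 0.5, 2), 1.5)
  grid <- expand.grid(cn = seq(0, 8, by = 0.5),
                      tcc = seq(0.15, 1, by = 0.05),
                      ploidy = seq(1, 6.5, by = 0.25))
  r <- expected_coverage_ratio(grid$cn, grid$tcc, grid$ploidy)
  back <- cn_from_ratio(r, grid$tcc, grid$ploidy)
  expect_equal(back, grid$cn, tolerance = 1e-9)
})

test_that("allele-specific copy numbers follow the mixture inversion", {
  bal <- allele_specific_cn(2, 0.8, "balanced")
  expect_equal(c(bal$a, bal$b, bal$dh), c(1, 1, 0))

  # hand inversion: tcc 0.5, cn 1, baf 2/3 -> (1, 0), dh 1
  imb <- allele_specific_cn(1, 0.5, "imbalanced", mean_baf = 2 / 3)
  expect_equal(c(imb$a, imb$b, imb$dh), c(1, 0, 1), tolerance = 1e-12)

  # pure tumor closed form: cn 3, baf 2/3 -> (2, 1), dh 1/3
  imb2 <- allele_specific_cn(3, 1, "imbalanced", mean_baf = 2 / 3)
  expect_equal(c(imb2$a, imb2$b, imb2$dh), c(2, 1, 1 / 3), tolerance = 1e-12)

  expect_true(allele_specific_cn(-0.2, 0.5, "imbalanced",
                                 mean_baf = 0.8)$excluded)
  expect_error(allele_specific_cn(2, 0.5, "imbalanced"), "mean_baf")
})

test_that("grid objective excludes infeasible combinations with reasons", {
  # BAF beyond the feasible bound forces a minor allele below -neg_tol
  seg <- data.frame(length = c(1e7, 1e7),
                    coverage_ratio = c(1, 1),
                    allelic_class = c("balanced", "imbalanced"),
                    mean_baf = c(NA, 0.99))
  o <- tcc_ploidy_objective(seg, tcc = 0.5, ploidy = 2)
  expect_true(o$excluded)
  expect_equal(o$reason, "negative copy number")

  # minor in (-0.5, -0.25) at cn 1: DH rule fires, negativity rule does not
  seg2 <- data.frame(length = 1e7, coverage_ratio = 0.75,
                     allelic_class = "imbalanced", mean_baf = 0.767)
  o2 <- tcc_ploidy_objective(seg2, tcc = 0.5, ploidy = 2)
  expect_true(o2$excluded)
  expect_equal(o2$reason, "DH > 1")

  # feasible case is not excluded
  o3 <- tcc_ploidy_objective(seg2, tcc = 1, ploidy = 2)
  expect_false(o3$excluded)
})

test_that("objective is order-invariant and length-weighting is consistent", {
  seg <- data.frame(length = c(2e7, 1e7, 3e7),
                    coverage_ratio = c(1, 0.8, 1.15),
                    allelic_class = c("balanced", "imbalanced", "imbalanced"),
                    mean_baf = c(NA, 0.7, 0.6))
  o1 <- tcc_ploidy_objective(seg, 0.6, 2.2)
  o2 <- tcc_ploidy_objective(seg[c(3, 1, 2), ], 0.6, 2.2)
  expect_equal(o1$objective, o2$objective)
  # doubling a segment's length equals duplicating the segment
  seg_dup <- rbind(seg, seg[2, ])
  seg_wt <- seg
  seg_wt$length[2] <- 2 * seg_wt$length[2]
  expect_equal(tcc_ploidy_objective(seg_dup, 0.6, 2.2)$objective,
               tcc_ploidy_objective(seg_wt, 0.6, 2.2)$objective)
})

test_that("purity/ploidy fit recovers planted genomes", {
  # pure diploid, all balanced at ratio 1: (1.0, 2.0) among zero minima
  seg <- data.frame(length = rep(2e7, 4), coverage_ratio = 1,
                    allelic_class = "balanced", mean_baf = NA)
  fits <- fit_tcc_ploidy(seg)
  hit <- fits[abs(fits$tcc - 1) < 1e-9 & abs(fits$ploidy - 2) < 1e-9, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$objective, 1e-9)

  # noise-free imbalanced genome: exact recovery as a zero-objective minimum
  cfg <- sim_config(seed = 21, tcc = 0.6, ploidy = 2.0, coverage_sigma = 0)
  g <- simulate_genome(cfg)
  ann <- annotate_segments(g$segments, g$snps)
  fits2 <- fit_tcc_ploidy(ann)
  hit2 <- fits2[abs(fits2$tcc - 0.6) < 1e-9 & abs(fits2$ploidy - 2) < 1e-9, ]
  expect_equal(nrow(hit2), 1L)
  expect_lt(hit2$objective, 1e-6)

  # reported per-segment calls satisfy A >= B >= 0 and dh in [0, 1]
  ps <- attr(fits2, "per_segment")
  expect_true(all(ps$a >= ps$b - 1e-9))
  expect_true(all(ps$dh >= 0 & ps$dh <= 1 + 1e-9))
  bal <- ps$allelic_class == "balanced"
  expect_true(all(ps$dh[bal] == 0))

  # all-excluded grid errors
  seg_bad <- data.frame(length = 1e7, coverage_ratio = 0.1,
                        allelic_class = "imbalanced", mean_baf = 0.999)
  expect_error(fit_tcc_ploidy(seg_bad, tcc_grid = c(0.5, 0.55),
                              ploidy_grid = c(2, 2.05)), "excluded")
})

test_that("segment_calls rounds to a consistent integer profile", {
  cfg <- sim_config(seed = 22, tcc = 0.7, ploidy = 2.0, coverage_sigma = 0)
  g <- simulate_genome(cfg)
  ann <- annotate_segments(g$segments, g$snps)
  calls <- segment_calls(ann, 0.7, g$truth$ploidy)
  expect_true(all(calls$a_cn + calls$b_cn == calls$total_cn))
  expect_true(all(calls$a_cn >= calls$b_cn))
  k <- g$truth$karyotype
  expect_equal(calls$total_cn, k$a + k$b)
  expect_equal(calls$a_cn, pmax(k$a, k$b))
})

test_that("MAF-based purity estimation halves the density mode", {
  set.seed(30)
  expect_equal(tcc_from_maf(rep(0.5, 50))$tcc_maf, 1)
  pure <- rbinom(300, 80, 0.5) / 80
  expect_lt(abs(tcc_from_maf(pure)$tcc_maf - 1), 0.05)
  half <- rbinom(300, 80, 0.25) / 80
  expect_lt(abs(tcc_from_maf(half)$tcc_maf - 0.5), 0.05)
  low <- rbinom(200, 50, 0.15) / 50
  expect_lt(abs(tcc_from_maf(low)$tcc_maf - 0.3), 0.05)
  expect_warning(est <- tcc_from_maf(rep(0.25, 5)), "unreliable")
  expect_true(est$uncertain)
})
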