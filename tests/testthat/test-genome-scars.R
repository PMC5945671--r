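test_that("smoothing merges same-state neighbors within the deviation", {
  p <- rbind(seg_row("chr1", 1, 2e7, 2L, 1L, 1L, 2.05),
             seg_row("chr1", 2e7 + 1, 5e7, 2L, 1L, 1L, 2.10))
  sm <- smooth_profile(p)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$start, 1)
  expect_equal(sm$end, 5e7)
  # length-weighted real copy number
  expect_equal(sm$real_cn, (2.05 * 2e7 + 2.10 * 3e7) / 5e7)

  # differing allele-specific states are never merged
  q <- rbind(seg_row("chr1", 1, 2e7, 2L, 1L, 1L),
             seg_row("chr1", 2e7 + 1, 5e7, 2L, 2L, 0L))
  expect_equal(nrow(smooth_profile(q)), 2L)

  # same state but real_cn gap above 0.3: kept apart
  r <- rbind(seg_row("chr1", 1, 2e7, 2L, 1L, 1L, 1.8),
             seg_row("chr1", 2e7 + 1, 5e7, 2L, 1L, 1L, 2.2))
  expect_equal(nrow(smooth_profile(r)), 2L)
})

test_that("small segments are absorbed into the more similar neighbor", {
  p <- rbind(seg_row("chr6", 1, 5e7, 2L, 1L, 1L, 2.0),
             seg_row("chr6", 5e7 + 1, 5.2e7, 3L, 2L, 1L, 2.8),
             seg_row("chr6", 5.2e7 + 1, 1.02e8, 3L, 2L, 1L, 3.0))
  sm <- smooth_profile(p)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$total_cn, c(2L, 3L))
  expect_equal(sm$start[2], 5e7 + 1)
  # whole-chromosome singleton below 3 Mb survives
  single <- seg_row("chrZ", 1, 2e6, 2L, 1L, 1L)
  expect_equal(nrow(smooth_profile(single)), 1L)
  # empty profile passes through
  expect_equal(nrow(smooth_profile(single[0, ])), 0L)
})

test_that("smoothing preserves the genomic span and is idempotent", {
  set.seed(5)
  starts <- cumsum(c(1, rep(4e6, 24)))
  p <- do.call(rbind, lapply(1:24, function(i) {
    tot <- sample(1:4, 1)
    a <- sample(ceiling(tot / 2):tot, 1)
    seg_row("chr2", starts[i], starts[i + 1] - 1, tot, a, tot - a,
            tot + runif(1, -0.2, 0.2))
  }))
  sm <- smooth_profile(p)
  expect_equal(sum(sm$end - sm$start + 1), sum(p$end - p$start + 1))
  expect_equal(smooth_profile(sm), sm)
})

test_that("scores are invariant to splitting a segment and re-smoothing", {
  case <- scar_cases()$interstitial_loh
  p <- case$profile
  mid <- floor((p$start[2] + p$end[2]) / 2)
  split <- rbind(p[1, ],
                 transform(p[2, ], end = mid),
                 transform(p[2, ], start = mid + 1),
                 p[3, ])
  sm <- smooth_profile(split)
  expect_equal(count_lst(sm)$lst, case$lst)
  expect_equal(count_hrd_loh(sm)$hrd_loh, case$hrd)
})

test_that("hand-constructed profiles give hand-counted scores", {
  for (name in names(scar_cases())) {
    case <- scar_cases()[[name]]
    sm <- smooth_profile(case$profile)
    expect_equal(count_lst(sm)$lst, case$lst, label = paste("LST", name))
    expect_equal(count_hrd_loh(sm)$hrd_loh, case$hrd,
                 label = paste("HRD", name))
  }
})

test_that("adding a qualifying event increments the matching score by 1", {
  base <- scar_cases()$interstitial_loh$profile
  sm <- smooth_profile(base)
  lst0 <- count_lst(sm)$lst
  hrd0 <- count_hrd_loh(sm)$hrd_loh
  # append an independent chromosome carrying one LOH and its two mid-arm
  # junctions (the junction into/out of the LOH block adds 2 LSTs)
  extra <- rbind(seg_row("chr9", 1, 2e7, 2L, 1L, 1L),
                 seg_row("chr9", 2e7 + 1, 3.61e7, 2L, 2L, 0L),
                 seg_row("chr9", 3.61e7 + 1, 4.65e7, 2L, 1L, 1L))
  p2 <- rbind(base, extra)
  sm2 <- smooth_profile(p2)
  expect_equal(count_hrd_loh(sm2)$hrd_loh, hrd0 + 1L)
  expect_equal(count_lst(sm2)$lst, lst0 + 2L)
})

test_that("single-copy fallback replaces the LOH criterion", {
  p <- rbind(seg_row("chr7", 1, 3e7, 1L, NA, NA, 1),
             seg_row("chr7", 3e7 + 1, 159138663, 2L, NA, NA, 2))
  expect_error(count_hrd_loh(p), "single_copy_mode")
  expect_equal(count_hrd_loh(p, single_copy_mode = TRUE)$hrd_loh, 1L)
  # copy-neutral LOH is invisible in single-copy mode
  q <- rbind(seg_row("chr7", 1, 3e7, 2L, 2L, 0L),
             seg_row("chr7", 3e7 + 1, 159138663, 2L, 1L, 1L))
  expect_equal(count_hrd_loh(q)$hrd_loh, 1L)
  expect_equal(count_hrd_loh(q, single_copy_mode = TRUE)$hrd_loh, 0L)
})

test_that("LST requires an arm map and known chromosomes", {
  p <- seg_row("chrUn", 1, 5e7, 2L, 1L, 1L)
  p2 <- rbind(p, seg_row("chrUn", 5e7 + 1, 9e7, 3L, 2L, 1L, 3))
  expect_error(count_lst(p2), "no arm definition")
  expect_error(count_hrd_loh(p2), "chromosome length")
  expect_error(count_lst(p2, arms = NULL), "arm map")
})
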