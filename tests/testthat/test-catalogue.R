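test_that("classify_snv maps pyrimidine and purine context correctly", {
  expect_equal(classify_snv("C", "A", "A", "A"), "A[C>A]A")
  expect_equal(classify_snv("G", "T", "T", "T"), "A[C>A]A")
  # flank swap on reverse complement: 5'T ref G alt A 3'C -> G[C>T]A
  expect_equal(classify_snv("G", "A", "T", "C"), "G[C>T]A")
  expect_error(classify_snv("C", "C", "A", "A"), "differ")
  expect_error(classify_snv("N", "A", "A", "A"), "invalid base")
})

test_that("all 192 substitution/context combinations hit each channel twice", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = bases, alt = bases, c5 = bases, c3 = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  ch <- classify_snv(combos$ref, combos$alt, combos$c5, combos$c3)
  tab <- table(ch)
  expect_equal(length(tab), 96L)
  expect_true(all(tab == 2L))
  expect_setequal(names(tab), channel_labels())
})

test_that("channel ordering is substitution-major with sorted flanks", {
  labs <- channel_labels()
  expect_equal(labs[1], "A[C>A]A")
  expect_equal(labs[2], "A[C>A]C")
  expect_equal(labs[17], "A[C>G]A")
  expect_equal(labs[96], "T[T>G]T")
  expect_equal(channel_index("A[C>A]A"), 1L)
  expect_error(channel_index("A[A>C]A"), "unknown channel")
})

test_that("strand-bias filter removes weakly supported SNVs in biased channels", {
  # biased channel: pooled 60 fwd / 3 rev; A has 1 rev, B has 2 rev
  biased <- rbind(
    make_variants(alt_fwd = 30, alt_rev = 1, pos = 1),
    make_variants(alt_fwd = 30, alt_rev = 2, pos = 2))
  res <- strand_bias_filter(biased)
  expect_equal(nrow(res$variants), 1L)
  expect_equal(res$variants$pos, 2)
  expect_true(res$report$biased)
  expect_equal(res$report$opposite_strand, "rev")
  expect_equal(res$report$n_removed, 1L)

  # unbiased channel keeps a zero-rev variant
  unb <- rbind(
    make_variants(alt_fwd = 25, alt_rev = 24, pos = 1),
    make_variants(alt_fwd = 25, alt_rev = 24, pos = 2),
    make_variants(alt_fwd = 4, alt_rev = 0, pos = 3))
  expect_equal(nrow(strand_bias_filter(unb)$variants), 3L)

  # single symmetric variant: kept
  expect_equal(nrow(strand_bias_filter(make_variants())$variants), 1L)

  # empty input
  empty <- make_variants()[0, ]
  expect_equal(nrow(strand_bias_filter(empty)$variants), 0L)

  # missing strand counts must error, not guess
  nostrand <- make_variants()
  nostrand$alt_fwd <- NA
  expect_error(strand_bias_filter(nostrand), "per-strand")
})

test_that("strand-bias filter is idempotent", {
  set.seed(42)
  v <- do.call(rbind, lapply(1:30, function(i) {
    biased <- i %% 3 == 0
    fwd <- if (biased) sample(10:40, 1) else sample(3:10, 1)
    rev <- if (biased) sample(0:2, 1) else fwd + sample(-1:1, 1)
    make_variants(ref = sample(c("C", "T"), 1),
                  alt_fwd = fwd, alt_rev = max(rev, 0),
                  context5 = sample(c("A", "C", "G", "T"), 1),
                  depth = 100, pos = i)
  }))
  once <- strand_bias_filter(v)$variants
  twice <- strand_bias_filter(once)$variants
  expect_equal(twice, once)
})

test_that("functional filter keeps exactly the functional classes", {
  v <- make_variants(n = 6)
  v$func_class <- c("nonsynonymous", "splice_site", "stopgain", "stoploss",
                    "synonymous", "other")
  kept <- functional_filter(v)
  expect_setequal(kept$func_class,
                  c("nonsynonymous", "splice_site", "stopgain", "stoploss"))
  # idempotent, subset
  expect_equal(functional_filter(kept), kept)
  v$func_class[2] <- NA
  expect_error(functional_filter(v), "missing")
  v$func_class[2] <- "weird"
  expect_error(functional_filter(v), "unknown func_class")
})

test_that("build_catalogue counts channels and preserves totals", {
  v <- make_variants()
  cat1 <- build_catalogue(v)
  expect_equal(dim(cat1), c(96L, 1L))
  expect_equal(cat1["A[C>A]A", 1], 1)
  expect_equal(sum(cat1), 1)

  empty <- make_variants()[0, ]
  cat0 <- build_catalogue(empty, sample_ids = c("a", "b"))
  expect_equal(dim(cat0), c(96L, 2L))
  expect_true(all(cat0 == 0))

  expect_error(build_catalogue(v, sample_ids = "other"), "not in sample_ids")

  # multinomial draw recovered exactly
  set.seed(1)
  labs <- channel_labels()
  p <- rgamma(96, 1); p <- p / sum(p)
  draw <- as.integer(rmultinom(1, 500, p))
  idx <- rep(seq_len(96), draw)
  v2 <- data.frame(chrom = "chr1", pos = seq_along(idx),
                   ref = substr(labs[idx], 3, 3),
                   alt = substr(labs[idx], 5, 5),
                   context5 = substr(labs[idx], 1, 1),
                   context3 = substr(labs[idx], 7, 7),
                   sample_id = "S", stringsAsFactors = FALSE)
  cat2 <- build_catalogue(v2)
  expect_equal(sum(cat2), 500)
  expect_equal(unname(cat2[, 1]), as.numeric(draw))
})

test_that("triplet correction rescales channels and preserves totals", {
  trip <- pyrimidine_triplets()
  genome <- setNames(rep(100, 32), trip)
  set.seed(2)
  cat <- matrix(rpois(96 * 2, 20), 96, 2,
                dimnames = list(channel_labels(), c("s1", "s2")))

  # identical tables: unchanged
  expect_equal(triplet_correction(cat, genome, genome), cat)

  # target with half the relative ACA frequency: correction factor for the
  # three ACA channels is exactly 2 before column rescaling
  target <- setNames(rep(63, 32), trip)
  target["ACA"] <- 31  # rel freq 31/1984 = half of 1/32
  f <- (genome / sum(genome)) / (target / sum(target))
  expect_equal(unname(f["ACA"]), 2)
  corr <- triplet_correction(cat, genome, target)
  hand <- cat * as.numeric(f[channel_triplets(rownames(cat))])
  hand <- sweep(hand, 2, colSums(cat) / colSums(hand), `*`)
  expect_equal(corr, hand, tolerance = 1e-12)
  expect_equal(colSums(corr), colSums(cat), tolerance = 1e-9)

  # all counts in one channel: column total preserved exactly
  cat1 <- matrix(0, 96, 1, dimnames = list(channel_labels(), "s"))
  cat1[5, 1] <- 123
  expect_equal(sum(triplet_correction(cat1, genome, target)), 123)

  expect_error(triplet_correction(cat, genome, target[-1]), "cover")
  bad <- target; bad["ACA"] <- 0
  expect_error(triplet_correction(cat, genome, bad), "positive")
})

test_that("small-indel counting applies inclusive 2-10 bp bounds", {
  ind <- data.frame(chrom = "chr1", pos = 1:5,
                    ref = c("AT", "ATT", "A", "ACGTACGTACG", "ACGTACGTACGT"),
                    alt = c("A", "A", "AT", "A", "A"),
                    sample_id = "S1", stringsAsFactors = FALSE)
  # lengths: 1 (no), 2 (yes), 1 (no), 10 (yes), 11 (no)
  expect_equal(count_small_indels(ind), c(S1 = 2L))
  # planted 7 qualifying vs 3 not
  ind2 <- data.frame(chrom = "chr1", pos = 1:10,
                     ref = c(rep("ACGTA", 7), rep("AC", 3)),
                     alt = "A", sample_id = "S2", stringsAsFactors = FALSE)
  expect_equal(count_small_indels(ind2), c(S2 = 7L))
  snv <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "C",
                    sample_id = "S1")
  expect_error(count_small_indels(snv), "non-indels")
})
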