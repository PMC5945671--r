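# Independent oracles and shared fixture builders ---------------------------

# Brute-force NNLS: enumerate all supports, solve the unconstrained
# least-squares subproblem on each, keep feasible (non-negative) solutions.
brute_nnls <- function(A, b) {
  n <- ncol(A)
  best_obj <- sum(b^2)
  best_x <- numeric(n)
  for (s in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(s, 2^(seq_len(n) - 1L)) > 0)
    if (!length(S)) next
    co <- qr.coef(qr(A[, S, drop = FALSE]), b)
    co[is.na(co)] <- 0
    if (all(co >= -1e-12)) {
      r <- sum((b - A[, S, drop = FALSE] %*% co)^2)
      if (r < best_obj) {
        best_obj <- r
        best_x <- numeric(n)
        best_x[S] <- co
      }
    }
  }
  list(x = best_x, objective = best_obj)
}

cosine_sim <- function(a, b) {
  if (sum(a^2) == 0 || sum(b^2) == 0) return(NA_real_)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Variant-table builder with sensible defaults.
make_variants <- function(n = 1, ref = "C", alt = "A", context5 = "A",
                          context3 = "A", alt_fwd = 5, alt_rev = 5,
                          depth = 60, func_class = "nonsynonymous",
                          sample_id = "S1", chrom = "chr1",
                          pos = seq_len(n) * 100) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             context5 = context5, context3 = context3,
             alt_fwd = alt_fwd, alt_rev = alt_rev, depth = depth,
             func_class = func_class, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

# Copy-number profile row builder.
seg_row <- function(chrom, start, end, total, a, b, real = total) {
  data.frame(chrom = chrom, start = start, end = end, total_cn = total,
             a_cn = a, b_cn = b, real_cn = real, stringsAsFactors = FALSE)
}

# Hand-constructed scar-score profiles with hand-counted expectations.
# Coordinates refer to the built-in hg19 arm map.
scar_cases <- function() {
  list(
    uniform_diploid = list(
      profile = seg_row("chr1", 1, 249250621, 2L, 1L, 1L),
      lst = 0L, hrd = 0L),
    midarm_junction = list(
      profile = rbind(
        seg_row("chr1", 1000001, 31000000, 2L, 1L, 1L),
        seg_row("chr1", 31000001, 61000000, 3L, 2L, 1L, 3)),
      lst = 1L, hrd = 0L),
    whole_chrom_loh = list(
      profile = seg_row("chr21", 1, 48129895, 1L, 1L, 0L, 1),
      lst = 0L, hrd = 0L),
    interstitial_loh = list(
      profile = rbind(
        seg_row("chr1", 1, 50000000, 2L, 1L, 1L),
        seg_row("chr1", 50000001, 70000000, 1L, 1L, 0L, 1),
        seg_row("chr1", 70000001, 121535434, 2L, 1L, 1L)),
      lst = 2L, hrd = 1L),
    loh_size_bounds = list(
      # 14 Mb LOH (below), 16.3 Mb copy-neutral LOH (counts)
      profile = rbind(
        seg_row("chr2", 1, 40000000, 2L, 1L, 1L),
        seg_row("chr2", 40000001, 54000000, 1L, 1L, 0L, 1),
        seg_row("chr2", 54000001, 76000000, 2L, 1L, 1L),
        seg_row("chr2", 76000001, 92326171, 2L, 2L, 0L)),
      lst = 3L, hrd = 1L),
    whole_arm_switch = list(
      # breakpoint at the centromere between two full arms: excluded
      profile = rbind(
        seg_row("chr3", 1, 90504854, 2L, 1L, 1L),
        seg_row("chr3", 93504855, 198022430, 3L, 2L, 1L, 3)),
      lst = 0L, hrd = 0L),
    homozygous_deletion = list(
      # q-arm deletion, away from the chr4 centromere (49.7-52.7 Mb)
      profile = rbind(
        seg_row("chr4", 1, 110000000, 2L, 1L, 1L),
        seg_row("chr4", 110000001, 130000000, 0L, 0L, 0L, 0),
        seg_row("chr4", 130000001, 191154276, 2L, 1L, 1L)),
      lst = 2L, hrd = 0L),
    oversegmented = list(
      # ten jittered diploid pieces then a 30 Mb LOH: smoothing required
      profile = rbind(
        do.call(rbind, lapply(0:9, function(i) {
          seg_row("chr5", i * 1e7 + 1, (i + 1) * 1e7, 2L, 1L, 1L,
                  2 + 0.02 * (i %% 3))
        })),
        seg_row("chr5", 100000001, 130000000, 1L, 1L, 0L, 1)),
      lst = 1L, hrd = 1L),
    small_absorbed = list(
      # 2 Mb piece (real 2.8) absorbed into the cn-3 neighbor
      profile = rbind(
        seg_row("chr6", 1, 50000000, 2L, 1L, 1L, 2.0),
        seg_row("chr6", 50000001, 52000000, 3L, 2L, 1L, 2.8),
        seg_row("chr6", 52000001, 102000000, 3L, 2L, 1L, 3.0)),
      lst = 1L, hrd = 0L),
    copy_neutral_loh_large = list(
      profile = rbind(
        seg_row("chr8", 1, 43838887, 2L, 2L, 0L),
        seg_row("chr8", 46838888, 146364022, 2L, 1L, 1L)),
      # both segments are full arms; q-arm LOH-free; p-arm 43.8 Mb LOH
      lst = 0L, hrd = 1L)
  )
}
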