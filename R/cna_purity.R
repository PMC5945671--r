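# Tumor cell content, ploidy and allele-specific copy number ---------------

#' Select germline-heterozygous SNP sites
#'
#' @param sites Data.frame of SNP sites with a `normal_af` column (alternate
#'   allele fraction in the matched normal).
#' @param band Inclusive heterozygosity band on `normal_af`.
#' @return The heterozygous subset.
#' @export
select_het_snps <- function(sites, band = c(0.3, 0.7)) {
  stopifnot(is.data.frame(sites), "normal_af" %in% names(sites))
  if (anyNA(sites$normal_af)) stop("normal_af contains NA", call. = FALSE)
  keep <- sites$normal_af >= band[1] & sites$normal_af <= band[2]
  sites[keep, , drop = FALSE]
}

# Local maxima of a density estimate; a peak must reach `prominence` of the
# global maximum. Endpoints count as maxima.
.density_peaks <- function(x, bw = "nrd0", prominence = 0.05) {
  d <- stats::density(x, bw = bw)
  y <- d$y
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  is_peak <- y > left & y >= right
  is_peak <- is_peak & y >= prominence * max(y)
  list(x = d$x[is_peak], y = y[is_peak], mode = d$x[which.max(y)])
}

#' Classify the allelic state of a segment from het-SNP allele fractions
#'
#' A kernel-density estimate of the tumor alternate-allele fractions is
#' inspected: a global maximum inside `balanced_band` calls the segment
#' balanced; otherwise a single density peak calls it ambiguous (excluded
#' downstream) and two or more peaks call it imbalanced. Imbalanced
#' segments get a mean folded B-allele frequency, the per-SNP mean of
#' `max(f, 1 - f)` (the allele with the higher read count acts as B-allele).
#'
#' @param tumor_af Numeric vector of tumor alternate-allele fractions at
#'   germline-het SNPs in the segment.
#' @param min_snps Segments with fewer SNPs are classed `insufficient`.
#' @param bw Kernel bandwidth (Silverman's rule by default).
#' @param prominence Peak height threshold as a fraction of the global
#'   density maximum.
#' @param balanced_band Allele-fraction interval whose global maximum calls
#'   a balanced segment.
#' @return List with `class` (`balanced`, `imbalanced`, `ambiguous` or
#'   `insufficient`), `mean_baf` (NA unless imbalanced), `n_snps`, `peaks`.
#' @export
classify_allelic_state <- function(tumor_af, min_snps = 20L, bw = "nrd0",
                                   prominence = 0.05,
                                   balanced_band = c(0.45, 0.55)) {
  tumor_af <- tumor_af[!is.na(tumor_af)]
  n <- length(tumor_af)
  if (n < min_snps) {
    return(list(class = "insufficient", mean_baf = NA_real_, n_snps = n,
                peaks = numeric()))
  }
  if (stats::sd(tumor_af) < 1e-12) {
    # degenerate (noise-free) input: one point mass
    v <- tumor_af[1]
    if (v >= balanced_band[1] && v <= balanced_band[2]) {
      return(list(class = "balanced", mean_baf = NA_real_, n_snps = n,
                  peaks = v))
    }
    # a point mass off 0.5 implies its mirrored allele too: imbalanced
    return(list(class = "imbalanced", mean_baf = max(v, 1 - v), n_snps = n,
                peaks = sort(c(v, 1 - v))))
  }
  pk <- .density_peaks(tumor_af, bw = bw, prominence = prominence)
  cls <- if (pk$mode >= balanced_band[1] && pk$mode <= balanced_band[2]) {
    "balanced"
  } else if (length(pk$x) <= 1L) {
    "ambiguous"
  } else {
    "imbalanced"
  }
  mean_baf <- if (cls == "imbalanced") mean(pmax(tumor_af, 1 - tumor_af)) else
    NA_real_
  list(class = cls, mean_baf = mean_baf, n_snps = n, peaks = pk$x)
}

#' Mean B-allele read count of an imbalanced segment
#'
#' @param mean_coverage Mean total read coverage over the segment's SNPs.
#' @param mean_baf Mean folded B-allele frequency of the segment.
#' @return `mean_coverage * mean_baf`.
#' @export
b_allele_read_count <- function(mean_coverage, mean_baf) {
  if (anyNA(mean_baf)) stop("mean_baf is missing", call. = FALSE)
  mean_coverage * mean_baf
}

#' Expected tumor/normal coverage ratio under the purity mixture model
#'
#' A segment at total copy number `cn_total` in a tumor of purity `tcc` and
#' tumor ploidy `ploidy`, against a diploid normal admixture, has expected
#' normalized coverage ratio
#' `(tcc * cn_total + 2 (1 - tcc)) / (tcc * ploidy + 2 (1 - tcc))`.
#'
#' @param cn_total Real-valued total copy number.
#' @param tcc Tumor cell content in `(0, 1]`.
#' @param ploidy Mean tumor total copy number (> 0).
#' @return Expected coverage ratio.
#' @export
expected_coverage_ratio <- function(cn_total, tcc, ploidy) {
  stopifnot(all(tcc > 0 & tcc <= 1), all(ploidy > 0))
  (tcc * cn_total + 2 * (1 - tcc)) / (tcc * ploidy + 2 * (1 - tcc))
}

#' Invert a coverage ratio to a real-valued total copy number
#'
#' Exact inverse of [expected_coverage_ratio()].
#'
#' @param ratio Observed coverage ratio (linear scale).
#' @inheritParams expected_coverage_ratio
#' @return Real-valued total copy number (may be negative for infeasible
#'   `(tcc, ploidy)` combinations).
#' @export
cn_from_ratio <- function(ratio, tcc, ploidy) {
  stopifnot(all(tcc > 0 & tcc <= 1), all(ploidy > 0))
  (ratio * (tcc * ploidy + 2 * (1 - tcc)) - 2 * (1 - tcc)) / tcc
}

#' Allele-specific copy numbers and decrease of heterozygosity
#'
#' Balanced segments split the total evenly (`A = B = cn_total / 2`,
#' `dh = 0`). For imbalanced segments the major allele copy number is
#' recovered from the folded BAF by inverting the mixture model:
#' `major = (baf * (tcc * cn_total + 2 (1 - tcc)) - (1 - tcc)) / tcc`,
#' the minor allele is `cn_total - major`, and
#' `dh = |major - minor| / cn_total`.
#'
#' @param cn_total Real-valued total copy number of the segment.
#' @param tcc Tumor cell content.
#' @param allelic_class `"balanced"` or `"imbalanced"`.
#' @param mean_baf Folded BAF (required when imbalanced).
#' @return List with `a` (major), `b` (minor), `dh`, and `excluded`
#'   (TRUE with a `reason` when `cn_total <= 0` for an imbalanced segment).
#' @export
allele_specific_cn <- function(cn_total, tcc, allelic_class,
                               mean_baf = NA_real_) {
  if (allelic_class == "balanced") {
    return(list(a = cn_total / 2, b = cn_total / 2, dh = 0, excluded = FALSE,
                reason = NA_character_))
  }
  if (allelic_class != "imbalanced") {
    stop("allele_specific_cn requires a balanced or imbalanced segment",
         call. = FALSE)
  }
  if (is.na(mean_baf)) stop("mean_baf required for imbalanced segments",
                            call. = FALSE)
  if (cn_total <= 0) {
    return(list(a = NA_real_, b = NA_real_, dh = NA_real_, excluded = TRUE,
                reason = "negative copy number"))
  }
  major <- (mean_baf * (tcc * cn_total + 2 * (1 - tcc)) - (1 - tcc)) / tcc
  minor <- cn_total - major
  dh <- abs(major - minor) / cn_total
  list(a = max(major, minor), b = min(major, minor), dh = dh,
       excluded = FALSE, reason = NA_character_)
}

# Distance to nearest allowed integer state.
.dist_even <- function(x) abs(x - pmax(2 * round(x / 2), 0))
.dist_int <- function(x) abs(x - pmax(round(x), 0))

#' Evaluate the copy-number objective at one (TCC, ploidy) grid point
#'
#' Coverage ratios are inverted to real total copy numbers; allele-specific
#' copies and DH are derived for imbalanced segments. The objective is the
#' segment-length-weighted mean distance to the nearest allowed integer
#' state: the nearest even total for balanced segments; the mean of the
#' distances of total, major and minor copy to the nearest non-negative
#' integer for imbalanced segments. Grid points requiring negative copy
#' number states (any value below `-neg_tol`, i.e. rounding to a negative
#' state) or a DH above `1 + neg_tol` are excluded with a reason.
#'
#' @param segments Data.frame with columns `length` (bp weight),
#'   `coverage_ratio`, `allelic_class` (balanced/imbalanced) and `mean_baf`
#'   (for imbalanced rows).
#' @param tcc,ploidy The grid point.
#' @param neg_tol Feasibility slack; a value below `-neg_tol` would round to
#'   a negative state.
#' @return List with `objective`, `excluded`, `reason` and a `per_segment`
#'   data.frame (`cn`, `a`, `b`, `dh`, `dist`).
#' @export
tcc_ploidy_objective <- function(segments, tcc, ploidy, neg_tol = 0.5) {
  bal <- segments$allelic_class == "balanced"
  imb <- segments$allelic_class == "imbalanced"
  use <- bal | imb
  seg <- segments[use, , drop = FALSE]
  bal <- bal[use]; imb <- imb[use]
  if (!nrow(seg)) stop("no balanced or imbalanced segments", call. = FALSE)
  cn <- cn_from_ratio(seg$coverage_ratio, tcc, ploidy)
  a <- b <- dh <- rep(NA_real_, nrow(seg))
  a[bal] <- b[bal] <- cn[bal] / 2
  dh[bal] <- 0
  if (any(imb)) {
    baf <- seg$mean_baf[imb]
    major <- (baf * (tcc * cn[imb] + 2 * (1 - tcc)) - (1 - tcc)) / tcc
    minor <- cn[imb] - major
    a[imb] <- pmax(major, minor)
    b[imb] <- pmin(major, minor)
    dh[imb] <- ifelse(cn[imb] > 0, abs(major - minor) / cn[imb], Inf)
  }
  reason <- NA_character_
  if (any(cn < -neg_tol) || any(b[imb] < -neg_tol) ||
      any(imb & cn <= 0)) {
    reason <- "negative copy number"
  } else if (any(dh[imb] > 1 + neg_tol)) {
    reason <- "DH > 1"
  }
  d <- numeric(nrow(seg))
  d[bal] <- .dist_even(cn[bal])
  d[imb] <- (.dist_int(cn[imb]) + .dist_int(a[imb]) + .dist_int(b[imb])) / 3
  w <- seg$length
  list(objective = sum(w * d) / sum(w),
       excluded = !is.na(reason), reason = reason,
       per_segment = data.frame(cn = cn, a = a, b = b, dh = dh, dist = d))
}

#' Grid-search estimation of tumor cell content and ploidy
#'
#' Evaluates [tcc_ploidy_objective()] over a rectangular grid, excludes
#' infeasible combinations, and reports local minima of the objective:
#' grid points not exceeded by any of their 8 neighbors, with
#' equal-objective runs along the ploidy axis collapsed to their
#' lowest-ploidy member. Candidates are ranked by objective.
#'
#' @param segments Segment table as in [tcc_ploidy_objective()]; ambiguous
#'   and insufficient segments are dropped.
#' @param tcc_grid,ploidy_grid Candidate values (defaults: TCC 0.15-1.0
#'   step 0.01, ploidy 1-6.5 step 0.05).
#' @param neg_tol Feasibility slack, see [tcc_ploidy_objective()].
#' @param max_candidates Cap on the number of reported minima.
#' @return Data.frame of candidate fits (`tcc`, `ploidy`, `objective`),
#'   ranked by objective; attribute `"per_segment"` holds the segment-level
#'   calls of the best fit, attribute `"n_excluded"` the number of excluded
#'   grid points.
#' @export
fit_tcc_ploidy <- function(segments,
                           tcc_grid = seq(0.15, 1.0, by = 0.01),
                           ploidy_grid = seq(1, 6.5, by = 0.05),
                           neg_tol = 0.5, max_candidates = 50L) {
  use <- segments$allelic_class %in% c("balanced", "imbalanced")
  if (!any(use)) stop("no usable (balanced/imbalanced) segments", call. = FALSE)
  seg <- segments[use, , drop = FALSE]
  nt <- length(tcc_grid); np <- length(ploidy_grid)
  obj <- matrix(NA_real_, nt, np)
  for (i in seq_len(nt)) {
    for (j in seq_len(np)) {
      o <- tcc_ploidy_objective(seg, tcc_grid[i], ploidy_grid[j],
                                neg_tol = neg_tol)
      if (!o$excluded) obj[i, j] <- o$objective
    }
  }
  if (all(is.na(obj))) {
    stop("all (tcc, ploidy) grid points excluded; no feasible solution",
         call. = FALSE)
  }
  # neighbor minima: obj <= all 8 neighbors (NA neighbors ignored)
  pad <- matrix(Inf, nt + 2L, np + 2L)
  filled <- obj
  filled[is.na(filled)] <- Inf
  pad[2:(nt + 1L), 2:(np + 1L)] <- filled
  is_min <- matrix(TRUE, nt, np)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      nb <- pad[(2:(nt + 1L)) + di, (2:(np + 1L)) + dj]
      is_min <- is_min & (filled <= nb)
    }
  }
  is_min <- is_min & !is.na(obj)
  # collapse equal-objective runs along ploidy (per tcc) to lowest ploidy
  for (i in seq_len(nt)) {
    for (j in seq_len(np)[-1]) {
      if (is_min[i, j] && is_min[i, j - 1L] &&
          isTRUE(abs(obj[i, j] - obj[i, j - 1L]) < 1e-12)) {
        is_min[i, j] <- FALSE
      }
    }
  }
  idx <- which(is_min, arr.ind = TRUE)
  fits <- data.frame(tcc = tcc_grid[idx[, 1L]],
                     ploidy = ploidy_grid[idx[, 2L]],
                     objective = obj[idx])
  fits <- fits[order(fits$objective, -fits$tcc, fits$ploidy), , drop = FALSE]
  rownames(fits) <- NULL
  if (nrow(fits) > max_candidates) fits <- fits[seq_len(max_candidates), ]
  best <- tcc_ploidy_objective(seg, fits$tcc[1], fits$ploidy[1],
                               neg_tol = neg_tol)
  attr(fits, "per_segment") <- cbind(seg, best$per_segment)
  attr(fits, "n_excluded") <- sum(is.na(obj))
  fits
}

#' Integer segment calls at a chosen (TCC, ploidy) solution
#'
#' Rounds the real-valued copy numbers of [tcc_ploidy_objective()] to an
#' integer allele-specific profile suitable for genomic-scar scoring:
#' balanced segments round to the nearest even total split evenly,
#' imbalanced segments round total and major allele with the minor taking
#' the remainder.
#'
#' @param segments Segment table with `chrom`, `start`, `end`, `length`,
#'   `coverage_ratio`, `allelic_class`, `mean_baf`.
#' @param tcc,ploidy The chosen solution.
#' @return Data.frame (`chrom`, `start`, `end`, `total_cn`, `a_cn`, `b_cn`,
#'   `real_cn`, `dh`, `allelic_class`).
#' @export
segment_calls <- function(segments, tcc, ploidy) {
  use <- segments$allelic_class %in% c("balanced", "imbalanced")
  seg <- segments[use, , drop = FALSE]
  o <- tcc_ploidy_objective(seg, tcc, ploidy)
  ps <- o$per_segment
  bal <- seg$allelic_class == "balanced"
  total <- integer(nrow(seg)); a <- integer(nrow(seg))
  total[bal] <- pmax(2L * as.integer(round(ps$cn[bal] / 2)), 0L)
  a[bal] <- total[bal] %/% 2L
  imb <- !bal
  total[imb] <- pmax(as.integer(round(ps$cn[imb])), 0L)
  a[imb] <- pmin(pmax(as.integer(round(ps$a[imb])), 0L), total[imb])
  b <- total - a
  swap <- b > a
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
             total_cn = total, a_cn = a, b_cn = b,
             real_cn = ps$cn, dh = ps$dh,
             allelic_class = seg$allelic_class,
             stringsAsFactors = FALSE)
}

#' Purity estimate from the somatic mutant-allele-fraction distribution
#'
#' Under the clonal-heterozygous-diploid approximation a clonal somatic SNV
#' has expected MAF `tcc / 2`, so `tcc = min(1, 2 * mode(MAF))` where the
#' mode is located on a kernel-density estimate.
#'
#' @param somatic_mafs Numeric vector of somatic mutant allele fractions.
#' @param min_snvs Below this count the estimate is flagged as
#'   wide-uncertainty (with a warning).
#' @param bw Kernel bandwidth.
#' @return List with `tcc_maf`, `maf_mode`, `n_snvs`, `uncertain`.
#' @export
tcc_from_maf <- function(somatic_mafs, min_snvs = 10L, bw = "nrd0") {
  somatic_mafs <- somatic_mafs[!is.na(somatic_mafs)]
  uncertain <- length(somatic_mafs) < min_snvs
  if (uncertain) {
    warning("fewer than ", min_snvs,
            " somatic SNVs; MAF-based TCC estimate is unreliable",
            call. = FALSE)
  }
  if (length(somatic_mafs) < 2L) {
    return(list(tcc_maf = NA_real_, maf_mode = NA_real_,
                n_snvs = length(somatic_mafs), uncertain = TRUE))
  }
  mode <- if (stats::sd(somatic_mafs) < 1e-12) {
    somatic_mafs[1]
  } else {
    d <- stats::density(somatic_mafs, bw = bw)
    d$x[which.max(d$y)]
  }
  list(tcc_maf = min(1, 2 * mode), maf_mode = mode,
       n_snvs = length(somatic_mafs), uncertain = uncertain)
}

#' Annotate coverage segments with allelic state from SNP data
#'
#' Selects germline-het SNPs, assigns them to segments by position, and
#' classifies each segment's allelic state.
#'
#' @param segments Data.frame with `chrom`, `start`, `end`,
#'   `coverage_ratio`.
#' @param snps Data.frame with `chrom`, `pos`, `normal_af`, `tumor_depth`,
#'   `tumor_alt_reads`.
#' @param ... Passed to [classify_allelic_state()].
#' @return `segments` with added `length`, `n_het_snps`, `allelic_class`,
#'   `mean_baf`, `mean_coverage` columns.
#' @export
annotate_segments <- function(segments, snps, ...) {
  het <- select_het_snps(snps)
  n <- nrow(segments)
  segments$length <- segments$end - segments$start + 1
  segments$n_het_snps <- integer(n)
  segments$allelic_class <- character(n)
  segments$mean_baf <- rep(NA_real_, n)
  segments$mean_coverage <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    in_seg <- het$chrom == segments$chrom[i] &
      het$pos >= segments$start[i] & het$pos <= segments$end[i]
    s <- het[in_seg, , drop = FALSE]
    af <- ifelse(s$tumor_depth > 0, s$tumor_alt_reads / s$tumor_depth, NA)
    cl <- classify_allelic_state(af, ...)
    segments$n_het_snps[i] <- cl$n_snps
    segments$allelic_class[i] <- cl$class
    segments$mean_baf[i] <- cl$mean_baf
    segments$mean_coverage[i] <- if (nrow(s)) mean(s$tumor_depth) else NA_real_
  }
  segments
}
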