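# Genomic scar scores: HRD-LOH and LST --------------------------------------

.HG19_CHROM <- c(paste0("chr", 1:22), "chrX", "chrY")
.HG19_LEN <- c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560, 59373566)
.HG19_CEN_START <- c(121535434, 92326171, 90504854, 49660117, 46405641,
                     58830166, 58054331, 43838887, 47367679, 39254935,
                     51644205, 34856694, 16000000, 16000000, 17000000,
                     35335801, 22263006, 15460898, 24681782, 26369569,
                     11288129, 13000000, 58632012, 10104553)
.HG19_CEN_END <- c(124535434, 95326171, 93504854, 52660117, 49405641,
                   61830166, 61054331, 46838887, 50367679, 42254935,
                   54644205, 37856694, 19000000, 19000000, 20000000,
                   38335801, 25263006, 18460898, 27681782, 29369569,
                   14288129, 16000000, 61632012, 13104553)

#' Built-in hg19/GRCh37 chromosome arm map
#'
#' Arms are derived from the UCSC centromere (acen) annotation: the p-arm
#' runs from position 1 to the centromere start, the q-arm from the
#' centromere end to the chromosome end.
#'
#' @return Data.frame with `chrom`, `arm` (`p`/`q`), `start`, `end`
#'   (1-based inclusive), and attribute `"centromere"` (per-chromosome
#'   centromere interval).
#' @export
hg19_arm_map <- function() {
  arms <- rbind(
    data.frame(chrom = .HG19_CHROM, arm = "p", start = 1,
               end = .HG19_CEN_START, stringsAsFactors = FALSE),
    data.frame(chrom = .HG19_CHROM, arm = "q", start = .HG19_CEN_END + 1,
               end = .HG19_LEN, stringsAsFactors = FALSE))
  arms <- arms[order(match(arms$chrom, .HG19_CHROM), arms$start), ]
  rownames(arms) <- NULL
  attr(arms, "centromere") <- data.frame(
    chrom = .HG19_CHROM, start = .HG19_CEN_START, end = .HG19_CEN_END,
    stringsAsFactors = FALSE)
  arms
}

#' Built-in hg19/GRCh37 chromosome lengths
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
hg19_chrom_lengths <- function() {
  stats::setNames(.HG19_LEN, .HG19_CHROM)
}

.check_profile <- function(profile) {
  need <- c("chrom", "start", "end", "total_cn", "a_cn", "b_cn")
  missing <- setdiff(need, names(profile))
  if (length(missing)) {
    stop("copy-number profile lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"real_cn" %in% names(profile)) profile$real_cn <- profile$total_cn
  if (any(profile$a_cn + profile$b_cn != profile$total_cn, na.rm = TRUE)) {
    stop("a_cn + b_cn must equal total_cn", call. = FALSE)
  }
  profile <- profile[order(profile$chrom, profile$start), , drop = FALSE]
  rownames(profile) <- NULL
  profile
}

.merge_rows <- function(profile, i, j, state_from = i) {
  # merge row j into row i (adjacent); keep the integer state of state_from
  len_i <- profile$end[i] - profile$start[i] + 1
  len_j <- profile$end[j] - profile$start[j] + 1
  profile$real_cn[i] <- (profile$real_cn[i] * len_i +
                           profile$real_cn[j] * len_j) / (len_i + len_j)
  profile$total_cn[i] <- profile$total_cn[state_from]
  profile$a_cn[i] <- profile$a_cn[state_from]
  profile$b_cn[i] <- profile$b_cn[state_from]
  profile$start[i] <- min(profile$start[i], profile$start[j])
  profile$end[i] <- max(profile$end[i], profile$end[j])
  profile[-j, , drop = FALSE]
}

.smooth_chrom <- function(p, max_dev, min_len) {
  repeat {
    changed <- FALSE
    # pass 1: merge neighbors with identical integer state and close real_cn
    i <- 1L
    while (i < nrow(p)) {
      same <- p$total_cn[i] == p$total_cn[i + 1L] &&
        p$a_cn[i] == p$a_cn[i + 1L] && p$b_cn[i] == p$b_cn[i + 1L] &&
        abs(p$real_cn[i] - p$real_cn[i + 1L]) <= max_dev
      if (same) {
        p <- .merge_rows(p, i, i + 1L)
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    # pass 2: absorb sub-threshold segments into the more similar neighbor
    repeat {
      len <- p$end - p$start + 1
      small <- which(len < min_len)
      if (!length(small) || nrow(p) == 1L) break
      k <- small[which.min(len[small])]
      left <- if (k > 1L) abs(p$real_cn[k] - p$real_cn[k - 1L]) else Inf
      right <- if (k < nrow(p)) abs(p$real_cn[k] - p$real_cn[k + 1L]) else Inf
      if (left <= right) {
        p <- .merge_rows(p, k - 1L, k, state_from = k - 1L)
      } else {
        p <- .merge_rows(p, k, k + 1L, state_from = k + 1L)
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  p
}

#' Smooth a copy-number profile to reduce oversegmentation
#'
#' Two merge rules are iterated to a joint fixpoint, per chromosome:
#' (1) adjacent segments with the same integer (total, A, B) state whose
#' real-valued copy numbers differ by at most `max_dev` are merged;
#' (2) any segment shorter than `min_len` is merged into whichever
#' neighbor has the closer real-valued copy number (the neighbor's integer
#' state is kept), unless it is a whole-chromosome singleton. Merged
#' real-valued copy numbers are length-weighted means.
#'
#' @param profile Copy-number profile data.frame (`chrom`, `start`, `end`,
#'   `total_cn`, `a_cn`, `b_cn`, optionally `real_cn`).
#' @param max_dev Maximum real-copy-number deviation for rule (1).
#' @param min_len Minimum segment length in bp for rule (2).
#' @return The smoothed profile, sorted, same columns.
#' @export
smooth_profile <- function(profile, max_dev = 0.3, min_len = 3e6) {
  if (nrow(profile) == 0L) return(profile)
  profile <- .check_profile(profile)
  out <- do.call(rbind, lapply(split(profile, profile$chrom),
                               .smooth_chrom, max_dev = max_dev,
                               min_len = min_len))
  out <- out[order(match(out$chrom, unique(profile$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.is_full_arm <- function(start, end, arms_chr, tol) {
  any(abs(start - arms_chr$start) <= tol & abs(end - arms_chr$end) <= tol)
}

#' Count large-scale state transitions (LST)
#'
#' A breakpoint between two adjacent segments counts as an LST when both
#' flanking segments exceed `min_seg`, their (total, A, B) states differ,
#' neither flanking segment coincides with a full chromosome arm (within
#' `arm_tol` of both arm limits), and the breakpoint does not fall at the
#' centromere (within `arm_tol` of the centromere interval).
#'
#' @param profile Smoothed copy-number profile.
#' @param arms Arm map as returned by [hg19_arm_map()] (or any data.frame
#'   with `chrom`, `arm`, `start`, `end` and a `"centromere"` attribute).
#' @param min_seg Minimum flanking segment length (strict, default 10 Mb).
#' @param arm_tol Tolerance for arm-boundary / centromere matching.
#' @return List with `lst` (count) and `events` (data.frame of counted
#'   breakpoints).
#' @export
count_lst <- function(profile, arms = hg19_arm_map(), min_seg = 1e7,
                      arm_tol = 3e6) {
  if (is.null(arms)) stop("an arm map is required", call. = FALSE)
  profile <- .check_profile(profile)
  cen <- attr(arms, "centromere")
  events <- list()
  for (chr in unique(profile$chrom)) {
    p <- profile[profile$chrom == chr, , drop = FALSE]
    arms_chr <- arms[arms$chrom == chr, , drop = FALSE]
    if (!nrow(arms_chr)) {
      stop("no arm definition for chromosome ", chr, call. = FALSE)
    }
    cen_chr <- cen[cen$chrom == chr, , drop = FALSE]
    if (nrow(p) < 2L) next
    for (i in seq_len(nrow(p) - 1L)) {
      len_l <- p$end[i] - p$start[i] + 1
      len_r <- p$end[i + 1L] - p$start[i + 1L] + 1
      if (len_l <= min_seg || len_r <= min_seg) next
      state_differs <- p$total_cn[i] != p$total_cn[i + 1L] ||
        p$a_cn[i] != p$a_cn[i + 1L] || p$b_cn[i] != p$b_cn[i + 1L]
      if (!state_differs) next
      bp <- p$end[i]
      if (nrow(cen_chr) &&
          bp >= cen_chr$start[1] - arm_tol && bp <= cen_chr$end[1] + arm_tol) {
        next
      }
      if (.is_full_arm(p$start[i], p$end[i], arms_chr, arm_tol) ||
          .is_full_arm(p$start[i + 1L], p$end[i + 1L], arms_chr, arm_tol)) {
        next
      }
      events[[length(events) + 1L]] <- data.frame(
        chrom = chr, breakpoint = bp,
        left_state = paste(p$total_cn[i], p$a_cn[i], p$b_cn[i], sep = "/"),
        right_state = paste(p$total_cn[i + 1L], p$a_cn[i + 1L],
                            p$b_cn[i + 1L], sep = "/"),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(), breakpoint = numeric(),
               left_state = character(), right_state = character(),
               stringsAsFactors = FALSE)
  list(lst = nrow(events), events = events)
}

#' Count HRD-LOH events
#'
#' Counts segments longer than `min_len` but shorter than their chromosome
#' that show loss of heterozygosity (minor allele copy number 0 with total
#' copy number at least 1). With `single_copy_mode = TRUE` (fallback for
#' samples without allele-specific calls) the LOH criterion is replaced by
#' total copy number exactly 1.
#'
#' @param profile Smoothed copy-number profile.
#' @param chrom_lengths Named vector of chromosome lengths (default hg19).
#' @param min_len Minimum segment length (strict, default 15 Mb).
#' @param single_copy_mode Use the total-copy-1 criterion instead of LOH.
#' @return List with `hrd_loh` (count) and `events` (counted segments).
#' @export
count_hrd_loh <- function(profile, chrom_lengths = hg19_chrom_lengths(),
                          min_len = 1.5e7, single_copy_mode = FALSE) {
  profile <- .check_profile(profile)
  missing_chr <- setdiff(unique(profile$chrom), names(chrom_lengths))
  if (length(missing_chr)) {
    stop("no chromosome length for: ", paste(missing_chr, collapse = ", "),
         call. = FALSE)
  }
  if (!single_copy_mode && (anyNA(profile$a_cn) || anyNA(profile$b_cn))) {
    stop("allele-specific copy numbers unavailable; use single_copy_mode",
         call. = FALSE)
  }
  len <- profile$end - profile$start + 1
  chr_len <- chrom_lengths[profile$chrom]
  loh <- if (single_copy_mode) {
    profile$total_cn == 1L
  } else {
    profile$b_cn == 0L & profile$total_cn >= 1L
  }
  hit <- loh & len > min_len & len < chr_len
  list(hrd_loh = sum(hit),
       events = profile[hit, , drop = FALSE])
}
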