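# Mutational catalogue construction -----------------------------------------

#' Validate a table of variant calls
#'
#' A variant-call table is a plain `data.frame` with one row per called
#' variant and columns `chrom`, `pos`, `ref`, `alt`, `context5`, `context3`,
#' `alt_fwd`, `alt_rev`, `depth`, `func_class`, `sample_id`. Indels carry
#' `NA` flanking context. `alt_fwd`/`alt_rev` are alt-supporting read counts
#' on the forward/reverse sequencing strand.
#'
#' @param df A data.frame of variant calls.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "pos", "ref", "alt", "sample_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("context5", "context3", "alt_fwd", "alt_rev", "depth",
                "func_class")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  }
  if (any(df$ref == df$alt)) stop("ref == alt in variant table", call. = FALSE)
  strand_known <- !is.na(df$alt_fwd) & !is.na(df$alt_rev) & !is.na(df$depth)
  over <- strand_known & (df$alt_fwd + df$alt_rev > df$depth)
  if (any(over)) stop("alt_fwd + alt_rev exceeds depth", call. = FALSE)
  df
}

#' Subset a variant table to single-nucleotide variants
#' @param variants Variant-call data.frame.
#' @return Rows with single-base ref and alt.
#' @export
is_snv <- function(variants) {
  nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
}

#' Filter SNVs in strand-biased channels
#'
#' For each of the 96 channels the pooled alt-supporting read counts on the
#' forward and reverse strand are tested for imbalance with a two-sided
#' exact binomial test against p = 0.5. A channel is flagged as biased when
#' the p-value falls below `p_threshold` and the pooled alt count reaches
#' `min_pooled`. Within a biased channel, the opposite strand is the strand
#' with the smaller pooled alt count; SNVs with fewer than `min_opposite`
#' alt reads on that strand are removed. SNVs in unbiased channels pass
#' unchanged.
#'
#' @param variants Variant-call data.frame (SNVs; context required).
#' @param p_threshold Binomial-test significance level for calling bias.
#' @param min_pooled Minimum pooled alt reads before a channel can be
#'   flagged (avoids flagging sparsely populated channels).
#' @param min_opposite Minimum opposite-strand alt support an SNV in a
#'   biased channel needs to survive.
#' @return List with `variants` (surviving rows) and `report` (one row per
#'   observed channel: pooled counts, p-value, bias flag, removals).
#' @export
strand_bias_filter <- function(variants, p_threshold = 0.05,
                               min_pooled = 10L, min_opposite = 2L) {
  variants <- variant_calls(variants)
  report0 <- data.frame(channel = character(), n = integer(),
                        alt_fwd = integer(), alt_rev = integer(),
                        p_value = numeric(), biased = logical(),
                        opposite_strand = character(),
                        n_removed = integer(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(list(variants = variants, report = report0))
  if (!all(is_snv(variants))) stop("strand_bias_filter expects SNVs only",
                                   call. = FALSE)
  if (any(is.na(variants$alt_fwd) | is.na(variants$alt_rev))) {
    stop("per-strand alt read counts are required for strand-bias filtering",
         call. = FALSE)
  }
  ch <- classify_snv(variants$ref, variants$alt,
                     variants$context5, variants$context3)
  fwd <- tapply(variants$alt_fwd, ch, sum)
  rev <- tapply(variants$alt_rev, ch, sum)
  channels <- names(fwd)
  pval <- vapply(seq_along(channels), function(i) {
    tot <- fwd[i] + rev[i]
    if (tot == 0) return(1)
    stats::binom.test(round(fwd[i]), round(tot), p = 0.5)$p.value
  }, numeric(1))
  biased <- pval < p_threshold & (fwd + rev) >= min_pooled
  opposite <- ifelse(fwd <= rev, "fwd", "rev")
  idx <- match(ch, channels)
  opp_count <- ifelse(opposite[idx] == "fwd", variants$alt_fwd,
                      variants$alt_rev)
  keep <- !biased[idx] | opp_count >= min_opposite
  report <- data.frame(channel = channels,
                       n = as.integer(table(ch)[channels]),
                       alt_fwd = as.integer(fwd), alt_rev = as.integer(rev),
                       p_value = as.numeric(pval),
                       biased = as.logical(biased),
                       opposite_strand = ifelse(biased, opposite, NA_character_),
                       n_removed = as.integer(tapply(!keep, ch, sum)[channels]),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(variants = variants[keep, , drop = FALSE], report = report)
}

#' Keep functional SNVs only
#'
#' Functional means nonsynonymous, splice-site, stop-gain or stop-loss.
#'
#' @param variants Variant-call data.frame with `func_class` populated.
#' @return The functional subset.
#' @export
functional_filter <- function(variants) {
  variants <- variant_calls(variants)
  if (nrow(variants) == 0L) return(variants)
  if (anyNA(variants$func_class)) {
    stop("func_class is missing for some variants; annotate before filtering",
         call. = FALSE)
  }
  bad <- !(variants$func_class %in% .VALID_FUNC_CLASSES)
  if (any(bad)) {
    stop("unknown func_class value(s): ",
         paste(unique(variants$func_class[bad]), collapse = ", "),
         call. = FALSE)
  }
  variants[variants$func_class %in% .FUNCTIONAL_CLASSES, , drop = FALSE]
}

#' Build a 96-channel mutational catalogue
#'
#' @param variants Variant-call data.frame of SNVs with flanking context.
#' @param sample_ids Optional sample ordering; defaults to order of first
#'   appearance. Variants from samples not listed raise an error.
#' @return Numeric 96 x m matrix, rows named by [channel_labels()], columns
#'   by sample. Column sums equal per-sample SNV counts.
#' @export
build_catalogue <- function(variants, sample_ids = NULL) {
  variants <- variant_calls(variants)
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  if (nrow(variants) > 0L) {
    if (!all(is_snv(variants))) stop("catalogue input must be SNVs",
                                     call. = FALSE)
    unknown <- setdiff(unique(variants$sample_id), sample_ids)
    if (length(unknown)) {
      stop("sample(s) not in sample_ids: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  labels <- channel_labels()
  if (nrow(variants) == 0L) {
    m <- matrix(0, 96L, length(sample_ids),
                dimnames = list(labels, sample_ids))
    return(m)
  }
  ch <- classify_snv(variants$ref, variants$alt,
                     variants$context5, variants$context3)
  tab <- table(factor(ch, levels = labels),
               factor(variants$sample_id, levels = sample_ids))
  m <- matrix(as.numeric(tab), 96L, length(sample_ids),
              dimnames = list(labels, sample_ids))
  m
}

.check_triplet_freq <- function(freq, what) {
  need <- pyrimidine_triplets()
  if (is.null(names(freq)) || !all(need %in% names(freq))) {
    stop(what, " triplet frequencies must be named and cover all 32 ",
         "pyrimidine-centered trinucleotides", call. = FALSE)
  }
  if (any(freq[need] <= 0)) {
    stop(what, " triplet frequencies must all be positive", call. = FALSE)
  }
  freq[need]
}

#' Correct a catalogue for target-capture triplet content
#'
#' Each channel count is multiplied by
#' `f(t) = (genome(t)/sum(genome)) / (target(t)/sum(target))` where `t` is
#' the channel's central trinucleotide, making exome-derived catalogues
#' comparable to genome-derived signature matrices. Columns are then
#' rescaled so that per-sample totals are preserved and exposures remain in
#' mutation-count units.
#'
#' @param cat 96 x m catalogue matrix.
#' @param genome,target Named positive vectors of occurrence counts of the
#'   32 pyrimidine-centered trinucleotides in the whole genome and in the
#'   capture target.
#' @return Corrected catalogue (real-valued), same dimnames, same column
#'   sums.
#' @export
triplet_correction <- function(cat, genome, target) {
  stopifnot(is.matrix(cat), nrow(cat) == 96L)
  genome <- .check_triplet_freq(genome, "genome")
  target <- .check_triplet_freq(target, "target")
  trip <- channel_triplets(rownames(cat))
  f <- (genome[trip] / sum(genome)) / (target[trip] / sum(target))
  out <- cat * as.numeric(f)
  tot0 <- colSums(cat)
  tot1 <- colSums(out)
  scale <- ifelse(tot1 > 0, tot0 / tot1, 0)
  sweep(out, 2L, scale, `*`)
}

#' Count small insertions and deletions per sample
#'
#' @param indels Variant-call data.frame of indels (`nchar(ref) != nchar(alt)`).
#' @param min_len,max_len Inclusive bounds on `|nchar(ref) - nchar(alt)|`.
#' @param sample_ids Optional sample ordering (zero counts included).
#' @return Named integer vector of per-sample qualifying indel counts.
#' @export
count_small_indels <- function(indels, min_len = 2L, max_len = 10L,
                               sample_ids = NULL) {
  indels <- variant_calls(indels)
  if (is.null(sample_ids)) sample_ids <- unique(indels$sample_id)
  if (nrow(indels) == 0L) {
    return(stats::setNames(integer(length(sample_ids)), sample_ids))
  }
  len <- abs(nchar(indels$ref) - nchar(indels$alt))
  if (any(len == 0L)) stop("input contains non-indels (ref/alt same length)",
                           call. = FALSE)
  qual <- len >= min_len & len <= max_len
  tab <- table(factor(indels$sample_id[qual], levels = sample_ids))
  stats::setNames(as.integer(tab), sample_ids)
}
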