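# 96-channel single-base-substitution alphabet ------------------------------

.BASES <- c("A", "C", "G", "T")
.SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.FUNCTIONAL_CLASSES <- c("nonsynonymous", "splice_site", "stopgain", "stoploss")
.VALID_FUNC_CLASSES <- c(.FUNCTIONAL_CLASSES, "synonymous", "other")

#' Canonical 96 mutation-channel labels
#'
#' Channels are ordered substitution-major (C>A, C>G, C>T, T>A, T>C, T>G),
#' then by 5' flanking base (A, C, G, T), then by 3' flanking base, the
#' convention used by COSMIC v2 signature matrices. Labels have the form
#' `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(channel_labels())
channel_labels <- function() {
  subs <- rep(.SUBSTITUTIONS, each = 16L)
  five <- rep(rep(.BASES, each = 4L), times = 6L)
  three <- rep(.BASES, times = 24L)
  paste0(five, "[", subs, "]", three)
}

#' Pyrimidine-centered trinucleotide of each channel
#'
#' @param labels Channel labels as produced by [channel_labels()].
#' @return Character vector of trinucleotides, e.g. `"ACA"` for `"A[C>A]A"`.
#' @export
channel_triplets <- function(labels = channel_labels()) {
  paste0(substr(labels, 1L, 1L), substr(labels, 3L, 3L), substr(labels, 7L, 7L))
}

#' The 32 pyrimidine-centered trinucleotides
#' @return Character vector of length 32.
#' @export
pyrimidine_triplets <- function() {
  sort(unique(channel_triplets()))
}

.check_bases <- function(x, what) {
  bad <- !(x %in% .BASES)
  if (any(bad)) {
    stop("invalid base(s) in ", what, ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify an SNV into its 96-channel mutation category
#'
#' Substitutions with a purine reference base are reverse-complemented
#' (reference, alternate and both flanking bases, with the flanks swapped)
#' so that every channel is reported with a pyrimidine (C or T) reference.
#' All arguments are vectorized and recycled to a common length.
#'
#' @param ref,alt Reference and alternate base (single characters in ACGT).
#' @param context5,context3 Reference base immediately 5' and 3' of the SNV.
#' @return Character vector of channel labels (`"A[C>A]A"` style).
#' @export
#' @examples
#' classify_snv("C", "A", "A", "A")  # "A[C>A]A"
#' classify_snv("G", "T", "T", "T")  # also "A[C>A]A" (reverse complement)
classify_snv <- function(ref, alt, context5, context3) {
  n <- max(length(ref), length(alt), length(context5), length(context3))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  context5 <- rep_len(as.character(context5), n)
  context3 <- rep_len(as.character(context3), n)
  .check_bases(ref, "ref"); .check_bases(alt, "alt")
  .check_bases(context5, "context5"); .check_bases(context3, "context3")
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, .COMPLEMENT[ref], ref)
  a <- ifelse(flip, .COMPLEMENT[alt], alt)
  c5 <- ifelse(flip, .COMPLEMENT[context3], context5)
  c3 <- ifelse(flip, .COMPLEMENT[context5], context3)
  unname(paste0(c5, "[", r, ">", a, "]", c3))
}

#' Index of a channel label in the canonical ordering
#' @param label Character vector of channel labels.
#' @return Integer vector of 1-based indices into [channel_labels()].
#' @export
channel_index <- function(label) {
  idx <- match(label, channel_labels())
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}
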