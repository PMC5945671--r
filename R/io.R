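# Readers and writers for interchange formats -------------------------------
# All TSVs use 1-based inclusive coordinates (VCF convention).

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a mutational catalogue to TSV
#'
#' 96 rows labeled by channel, one column per sample.
#' @param cat Catalogue matrix.
#' @param path Output path.
#' @export
write_catalogue <- function(cat, path) {
  stopifnot(is.matrix(cat), nrow(cat) == 96L)
  df <- data.frame(channel = rownames(cat), cat, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a mutational catalogue from TSV
#' @param path Path to a TSV written by [write_catalogue()].
#' @return 96 x m matrix, rows in canonical channel order.
#' @export
read_catalogue <- function(path) {
  df <- .read_tsv(path)
  if (!"channel" %in% names(df)) stop("catalogue TSV needs a 'channel' column",
                                      call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "channel"), drop = FALSE])
  rownames(m) <- df$channel
  channel_index(rownames(m))  # errors on unknown labels
  if (anyDuplicated(rownames(m)) || nrow(m) != 96L) {
    stop("catalogue TSV must contain each of the 96 channels exactly once",
         call. = FALSE)
  }
  m[channel_labels(), , drop = FALSE]
}

#' Read a COSMIC-style signature matrix
#'
#' Expects columns `Substitution Type` and `Trinucleotide` plus one column
#' per signature. Rows are re-ordered to the canonical channel order;
#' missing or duplicated channels are an error. Column sums are validated
#' to 1 within `tol` and renormalized exactly.
#'
#' @param path TSV path.
#' @param cutoffs Optional cutoff vector attached to the returned set.
#' @param tol Column-sum validation tolerance.
#' @return A `signature_set`.
#' @export
read_signature_matrix <- function(path, cutoffs = 0, tol = 1e-3) {
  df <- .read_tsv(path)
  need <- c("Substitution Type", "Trinucleotide")
  if (!all(need %in% names(df))) {
    stop("signature TSV needs 'Substitution Type' and 'Trinucleotide' columns",
         call. = FALSE)
  }
  labels <- paste0(substr(df$Trinucleotide, 1, 1), "[",
                   df$`Substitution Type`, "]",
                   substr(df$Trinucleotide, 3, 3))
  if (anyDuplicated(labels)) stop("duplicate channel rows in signature file",
                                  call. = FALSE)
  idx <- match(channel_labels(), labels)
  if (anyNA(idx)) {
    stop("signature file is missing channel(s): ",
         paste(utils::head(channel_labels()[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  sig_cols <- setdiff(names(df), need)
  W <- as.matrix(df[idx, sig_cols, drop = FALSE])
  rownames(W) <- channel_labels()
  cs <- colSums(W)
  if (any(abs(cs - 1) > tol)) {
    stop("signature column(s) do not sum to 1 within ", tol, call. = FALSE)
  }
  W <- sweep(W, 2L, cs, `/`)
  signature_set(W, cutoffs = cutoffs)
}

#' Write a signature set in COSMIC-style TSV layout
#' @param sig A `signature_set`.
#' @param path Output path.
#' @param digits Significant digits to keep (controls file size).
#' @export
write_signature_matrix <- function(sig, path, digits = 6) {
  W <- .sig_W(sig)
  labels <- rownames(W)
  df <- data.frame(
    `Substitution Type` = paste0(substr(labels, 3, 3), ">",
                                 substr(labels, 5, 5)),
    Trinucleotide = channel_triplets(labels),
    signif(W, digits), check.names = FALSE)
  .write_tsv(df, path)
}

#' Read triplet occurrence frequencies
#'
#' Two-column TSV (`triplet`, `count`) over the 32 pyrimidine-centered
#' trinucleotides.
#' @param path TSV path.
#' @return Named numeric vector.
#' @export
read_triplet_frequencies <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("triplet", "count") %in% names(df))) {
    stop("triplet TSV needs 'triplet' and 'count' columns", call. = FALSE)
  }
  freq <- stats::setNames(as.numeric(df$count), df$triplet)
  .check_triplet_freq(freq, "file")
}

#' Write triplet occurrence frequencies
#' @param freq Named numeric vector over the 32 triplets.
#' @param path Output path.
#' @export
write_triplet_frequencies <- function(freq, path) {
  .write_tsv(data.frame(triplet = names(freq), count = as.numeric(freq)),
             path)
}

#' Read a SEG-like segment table
#'
#' Columns: `sample` (optional), `chrom`, `start`, `end`,
#' `coverage_ratio` (linear tumor/normal ratio).
#' @param path TSV path.
#' @return Data.frame of segments.
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path)
  need <- c("chrom", "start", "end", "coverage_ratio")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("segment TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read SNP allele-count sites
#'
#' Columns: `chrom`, `pos`, `normal_af`, `tumor_depth`, `tumor_alt_reads`.
#' @param path TSV path.
#' @return Data.frame of SNP sites.
#' @export
read_snp_sites <- function(path) {
  df <- .read_tsv(path)
  need <- c("chrom", "pos", "normal_af", "tumor_depth", "tumor_alt_reads")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("SNP TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$tumor_alt_reads > df$tumor_depth)) {
    stop("tumor_alt_reads exceeds tumor_depth", call. = FALSE)
  }
  df
}

#' Read a sample sheet
#'
#' Columns: `sample_id` (unique), `patient_id`, `compartment`
#' (tumor/thrombus/normal), plus optional file-path columns (validated for
#' existence when `check_files` is TRUE).
#' @param path TSV path.
#' @param check_files Validate that referenced files exist.
#' @return Data.frame.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  df <- .read_tsv(path)
  need <- c("sample_id", "patient_id", "compartment")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  bad <- !(df$compartment %in% c("tumor", "thrombus", "normal"))
  if (any(bad)) stop("compartment must be tumor/thrombus/normal",
                     call. = FALSE)
  path_cols <- grep("_path$|^file", names(df), value = TRUE)
  if (check_files && length(path_cols)) {
    for (col in path_cols) {
      p <- df[[col]][!is.na(df[[col]]) & nzchar(df[[col]])]
      gone <- p[!file.exists(p)]
      if (length(gone)) {
        stop("sample sheet references missing file(s): ",
             paste(gone, collapse = ", "), call. = FALSE)
      }
    }
  }
  df
}

#' Read a MAF-style variant table and apply the mutation-load filter
#'
#' @param path TSV path.
#' @param min_snvs Samples with at most this many SNVs are dropped (with a
#'   message); default 25.
#' @param col_map Named list mapping the required logical fields (`sample`,
#'   `chrom`, `pos`, `ref`, `alt`, `context`) to file column names. The
#'   context column holds the reference trinucleotide around the variant.
#' @return List with `variants` (a variant-call data.frame) and `dropped`
#'   (per-sample SNV counts of removed samples).
#' @export
read_maf_table <- function(path, min_snvs = 25,
                           col_map = list(sample = "Tumor_Sample_Barcode",
                                          chrom = "Chromosome",
                                          pos = "Start_Position",
                                          ref = "Reference_Allele",
                                          alt = "Tumor_Seq_Allele2",
                                          context = "ref_context")) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L) {
    warning("empty MAF table", call. = FALSE)
    return(list(variants = variant_calls(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), sample_id = character())),
      dropped = stats::setNames(integer(), character())))
  }
  missing <- setdiff(unlist(col_map), names(df))
  if (length(missing)) {
    stop("MAF table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctx <- df[[col_map$context]]
  mid <- (nchar(ctx) + 1L) %/% 2L
  variants <- data.frame(
    chrom = df[[col_map$chrom]],
    pos = df[[col_map$pos]],
    ref = df[[col_map$ref]],
    alt = df[[col_map$alt]],
    context5 = toupper(substr(ctx, mid - 1L, mid - 1L)),
    context3 = toupper(substr(ctx, mid + 1L, mid + 1L)),
    sample_id = df[[col_map$sample]],
    stringsAsFactors = FALSE)
  snv <- is_snv(variants)
  load <- table(factor(variants$sample_id[snv],
                       levels = unique(variants$sample_id)))
  keep_samples <- names(load)[load > min_snvs]
  dropped <- load[load <= min_snvs]
  if (length(dropped)) {
    message(length(dropped), " sample(s) dropped by the >", min_snvs,
            "-SNV load filter")
  }
  list(variants = variant_calls(
    variants[variants$sample_id %in% keep_samples, , drop = FALSE]),
    dropped = stats::setNames(as.integer(dropped), names(dropped)))
}

#' Read somatic variant calls from a VCF
#'
#' Uses the VariantAnnotation package (a suggested dependency).
#' Multi-allelic records are split into one call per alternate allele.
#' Per-strand alt read counts come from a DP4-style INFO field
#' (ref-fwd, ref-rev, alt-fwd, alt-rev); flanking context from a
#' trinucleotide INFO key; functional class from an annotation INFO key.
#' Records without strand information get `NA` strand fields, on which
#' [strand_bias_filter()] errors rather than guessing.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample_id Sample label for the resulting calls.
#' @param info_keys Named list: `strand` (DP4-style 4-vector), `context`
#'   (trinucleotide), `func` (functional class).
#' @return Variant-call data.frame.
#' @export
read_vcf_somatic <- function(path, sample_id,
                             info_keys = list(strand = "DP4",
                                              context = "CTX",
                                              func = "FUNC")) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf_somatic requires the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (length(vcf) == 0L) {
    return(variant_calls(data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), sample_id = character())))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_along(vcf), n_alt)
  get_info <- function(key, default = NA) {
    if (!is.null(key) && key %in% names(info)) info[[key]] else
      rep(default, length(vcf))
  }
  ctx <- as.character(get_info(info_keys$context, NA_character_))
  func <- as.character(get_info(info_keys$func, NA_character_))
  strand <- info[[info_keys$strand]]
  alt_fwd <- alt_rev <- depth <- rep(NA_real_, length(vcf))
  if (!is.null(strand)) {
    sm <- t(vapply(seq_along(vcf), function(i) {
      v <- suppressWarnings(as.numeric(unlist(strand[i])))
      if (length(v) == 4L && !anyNA(v)) c(v[3], v[4], sum(v)) else
        c(NA_real_, NA_real_, NA_real_)
    }, numeric(3)))
    alt_fwd <- sm[, 1]; alt_rev <- sm[, 2]; depth <- sm[, 3]
  }
  mid <- (nchar(ctx) + 1L) %/% 2L
  variant_calls(data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[rec],
    pos = GenomicRanges::start(rr)[rec],
    ref = as.character(VariantAnnotation::ref(vcf))[rec],
    alt = as.character(unlist(alt_list)),
    context5 = substr(ctx, mid - 1L, mid - 1L)[rec],
    context3 = substr(ctx, mid + 1L, mid + 1L)[rec],
    alt_fwd = alt_fwd[rec], alt_rev = alt_rev[rec], depth = depth[rec],
    func_class = func[rec],
    sample_id = sample_id,
    stringsAsFactors = FALSE))
}
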