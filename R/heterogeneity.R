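# Primary-tumor vs thrombus mutation sharing --------------------------------

#' Classify gene-level mutation sharing between tumor and thrombus
#'
#' Per patient, a gene carrying at least one functional variant is
#' `tumor_only` when mutated in one or more primary-tumor samples but no
#' thrombus sample, `thrombus_only` in the symmetric case, and `shared`
#' otherwise. Cohort totals sum gene-per-patient events, so the same gene
#' mutated in two patients counts twice. Patients lacking samples from one
#' compartment are excluded with a warning.
#'
#' @param variants Data.frame with columns `patient`, `sample`,
#'   `compartment` (`tumor`/`thrombus`) and `gene`; one row per mutated
#'   gene-sample pair (functional variants only).
#' @param min_support Optional minimum `alt_reads` column value for a row
#'   to count as mutated (default 1; ignored if the column is absent).
#' @return List with `per_patient` (data.frame of per-patient counts),
#'   `cohort` (named totals incl. `n_heterogeneous` and
#'   `frac_heterogeneous`), and `genes` (per patient-gene classification).
#' @export
classify_sharing <- function(variants, min_support = 1L) {
  need <- c("patient", "sample", "compartment", "gene")
  missing <- setdiff(need, names(variants))
  if (length(missing)) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(variants$compartment %in% c("tumor", "thrombus"))
  if (any(bad)) {
    stop("compartment must be 'tumor' or 'thrombus'", call. = FALSE)
  }
  if ("alt_reads" %in% names(variants)) {
    variants <- variants[variants$alt_reads >= min_support, , drop = FALSE]
  }
  per_patient <- list()
  genes <- list()
  for (pt in unique(variants$patient)) {
    v <- variants[variants$patient == pt, , drop = FALSE]
    comps <- unique(v$compartment)
    if (!all(c("tumor", "thrombus") %in% comps)) {
      warning("patient ", pt, " lacks samples from one compartment; excluded",
              call. = FALSE)
      next
    }
    g <- unique(v$gene)
    in_tumor <- g %in% v$gene[v$compartment == "tumor"]
    in_thr <- g %in% v$gene[v$compartment == "thrombus"]
    class <- ifelse(in_tumor & in_thr, "shared",
                    ifelse(in_tumor, "tumor_only", "thrombus_only"))
    genes[[pt]] <- data.frame(patient = pt, gene = g, class = class,
                              stringsAsFactors = FALSE)
    per_patient[[pt]] <- data.frame(
      patient = pt,
      n_genes = length(g),
      n_shared = sum(class == "shared"),
      n_tumor_only = sum(class == "tumor_only"),
      n_thrombus_only = sum(class == "thrombus_only"),
      stringsAsFactors = FALSE)
  }
  if (!length(per_patient)) {
    stop("no patient with samples from both compartments", call. = FALSE)
  }
  pp <- do.call(rbind, per_patient)
  rownames(pp) <- NULL
  pp$n_heterogeneous <- pp$n_tumor_only + pp$n_thrombus_only
  cohort <- c(n_genes_total = sum(pp$n_genes),
              n_shared = sum(pp$n_shared),
              n_tumor_only = sum(pp$n_tumor_only),
              n_thrombus_only = sum(pp$n_thrombus_only))
  cohort["n_heterogeneous"] <- cohort["n_tumor_only"] +
    cohort["n_thrombus_only"]
  cohort <- c(cohort, frac_heterogeneous =
                unname(cohort["n_heterogeneous"] / cohort["n_genes_total"]))
  list(per_patient = pp, cohort = cohort,
       genes = do.call(rbind, c(genes, list(make.row.names = FALSE))))
}

#' Test the association between AC3 exposure and small-indel burden
#'
#' Samples are split into AC3-positive (exposure > 0) and AC3-negative
#' groups and their small-indel counts compared with a two-sided Wilcoxon
#' rank-sum test (exact null when the combined sample size is at most
#' `exact_max_n` and there are no ties; normal approximation with tie and
#' continuity correction otherwise).
#'
#' @param indel_counts Integer vector of per-sample 2-10 bp indel counts.
#' @param ac3_exposures Numeric vector of per-sample AC3 exposures, aligned
#'   with `indel_counts`.
#' @param exact_max_n Combined-size limit for the exact null distribution.
#' @return List with `testable`, group sizes and medians, `statistic`
#'   (Mann-Whitney U of the AC3-positive group), `p_value`, `method`.
#' @export
ac3_indel_association <- function(indel_counts, ac3_exposures,
                                  exact_max_n = 25L) {
  if (length(indel_counts) != length(ac3_exposures)) {
    stop("indel_counts and ac3_exposures must be aligned", call. = FALSE)
  }
  pos <- ac3_exposures > 0
  x <- indel_counts[pos]
  y <- indel_counts[!pos]
  if (!length(x) || !length(y)) {
    warning("one AC3 group is empty; association untestable", call. = FALSE)
    return(list(testable = FALSE, n_pos = length(x), n_neg = length(y),
                median_pos = NA_real_, median_neg = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                method = NA_character_))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max_n && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  list(testable = TRUE, n_pos = length(x), n_neg = length(y),
       median_pos = stats::median(x), median_neg = stats::median(y),
       statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}
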