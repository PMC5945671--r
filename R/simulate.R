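# Synthetic data with known ground truth ------------------------------------

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators with defaults
#' describing a small multiregion renal-tumor cohort: 5 patients with
#' paired primary-tumor and thrombus compartments, exome-scale mutation
#' loads, 60x coverage, and sharing fractions mirroring a cohort in which
#' 106 of 483 mutated genes are compartment-private.
#'
#' @param seed Integer master seed.
#' @param n_samples Samples per simulated catalogue cohort.
#' @param mutations_per_sample SNVs per sample.
#' @param n_active_range Range of the number of active signatures drawn per
#'   sample.
#' @param min_rel_exposure Minimum relative exposure of an active signature.
#' @param tcc Tumor cell content of the simulated genome.
#' @param ploidy Target mean total copy number used to design a karyotype.
#' @param read_depth Mean sequencing depth at SNP sites.
#' @param snp_per_mb Heterozygous-SNP density.
#' @param coverage_sigma Lognormal sd of segment coverage-ratio noise.
#' @param n_somatic_snvs Somatic SNVs for the MAF-based purity estimate.
#' @param n_patients,samples_per_compartment Multiregion cohort layout.
#' @param genes_total Total mutated gene-per-patient events in the cohort.
#' @param n_tumor_only,n_thrombus_only Planted private gene events; the
#'   remainder is shared.
#' @param indel_rate_neg,indel_rate_pos Poisson means of 2-10 bp indel
#'   counts in AC3-negative / AC3-positive samples.
#' @param frac_ac3_patients Fraction of patients carrying AC3 exposure.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 20L,
                       mutations_per_sample = 1000L,
                       n_active_range = c(3L, 5L),
                       min_rel_exposure = 0.1,
                       tcc = 0.6,
                       ploidy = 2.0,
                       read_depth = 60,
                       snp_per_mb = 10,
                       coverage_sigma = 0.01,
                       n_somatic_snvs = 200L,
                       n_patients = 5L,
                       samples_per_compartment = 3L,
                       genes_total = 483L,
                       n_tumor_only = 63L,
                       n_thrombus_only = 43L,
                       indel_rate_neg = 5,
                       indel_rate_pos = 15,
                       frac_ac3_patients = 0.6) {
  structure(as.list(environment()), class = "sim_config")
}

#' Deterministic synthetic 30-signature set
#'
#' A stand-in for the 30 published COSMIC-style signatures, which are not
#' redistributable here: 96-channel column-stochastic profiles drawn from a
#' sparse Dirichlet (gamma shape 0.3) under a fixed internal seed, named
#' AC1..AC30. The set is synthetic - profiles do not reproduce the
#' published signatures - but has comparable sparsity and mutual
#' distinguishability.
#'
#' @param k Number of signatures.
#' @param seed Internal seed (fixed default so the set is a package
#'   constant).
#' @param cutoffs Cutoff vector passed to [signature_set()].
#' @return A `signature_set`.
#' @export
synthetic_signature_set <- function(k = 30L, seed = 20180510L, cutoffs = 0) {
  W <- with_seed(seed, {
    m <- matrix(stats::rgamma(96L * k, shape = 0.3), 96L, k)
    sweep(m, 2L, colSums(m), `/`)
  })
  rownames(W) <- channel_labels()
  colnames(W) <- paste0("AC", seq_len(k))
  signature_set(W, cutoffs = cutoffs)
}

#' Synthetic genome / target-capture triplet frequencies
#'
#' Occurrence counts of the 32 pyrimidine-centered trinucleotides. The
#' `genome` scope is near-uniform at whole-genome scale; the
#' `target_capture` scope distorts each triplet by a lognormal factor,
#' emulating the GC-skewed composition of exome capture designs.
#'
#' @param scope `"genome"` or `"target_capture"`.
#' @param seed Internal seed.
#' @return Named numeric vector over [pyrimidine_triplets()], with a
#'   `"scope"` attribute.
#' @export
synthetic_triplet_frequencies <- function(scope = c("genome",
                                                    "target_capture"),
                                          seed = 20180510L) {
  scope <- match.arg(scope)
  trip <- pyrimidine_triplets()
  freq <- with_seed(seed + (scope == "target_capture"), {
    base <- stats::rlnorm(32L, meanlog = log(1e8), sdlog = 0.2)
    if (scope == "target_capture") {
      base <- base * stats::rlnorm(32L, meanlog = log(1e-3), sdlog = 0.4)
    }
    round(base)
  })
  structure(stats::setNames(freq, trip), scope = scope)
}

#' Simulate mutational catalogues from known signature exposures
#'
#' Each sample activates between `n_active_range[1]` and
#' `n_active_range[2]` signatures with relative exposures of at least
#' `min_rel_exposure`; channel counts are drawn multinomially from the
#' resulting mixture profile.
#'
#' @param config A [sim_config()].
#' @param W A `signature_set`.
#' @return List with `catalogue` (96 x n matrix), `exposures` (true k x n
#'   absolute exposures) and `presence` (true logical k x n).
#' @export
simulate_catalogue <- function(config = sim_config(),
                               W = synthetic_signature_set()) {
  Wm <- .sig_W(W)
  k <- ncol(Wm)
  n <- config$n_samples
  mu <- config$mutations_per_sample
  with_seed(config$seed, {
    cat <- matrix(0, 96L, n, dimnames = list(rownames(Wm),
                                             sprintf("S%02d", seq_len(n))))
    H <- matrix(0, k, n, dimnames = list(colnames(Wm), colnames(cat)))
    for (j in seq_len(n)) {
      n_act <- sample(seq(config$n_active_range[1], config$n_active_range[2]),
                      1L)
      act <- sample(k, n_act)
      raw <- stats::rgamma(n_act, shape = 1)
      rel <- config$min_rel_exposure +
        raw / sum(raw) * (1 - n_act * config$min_rel_exposure)
      if (any(rel < 0)) stop("min_rel_exposure too large for n_active")
      H[act, j] <- rel * mu
      if (mu > 0) {
        p <- Wm %*% H[, j]
        cat[, j] <- stats::rmultinom(1L, mu, p / sum(p))
      }
    }
    list(catalogue = cat, exposures = H, presence = H > 0)
  })
}

#' Design a toy karyotype hitting a target mean ploidy
#'
#' Builds `n_seg` equal-length segments whose integer total copy numbers
#' average exactly `ploidy` (requires `n_seg * ploidy` integral), with a
#' mix of balanced and at least three distinct imbalanced allele splits
#' whenever the totals allow.
#'
#' @param ploidy Target mean total copy number.
#' @param n_seg Number of segments (default 10).
#' @param seg_len Segment length in bp.
#' @param chrom_prefix Chromosome naming prefix; segments are laid out two
#'   per chromosome.
#' @return Data.frame with `chrom`, `start`, `end`, `a`, `b`.
#' @export
design_karyotype <- function(ploidy, n_seg = 10L, seg_len = 2e7,
                             chrom_prefix = "sim") {
  total_sum <- ploidy * n_seg
  if (abs(total_sum - round(total_sum)) > 1e-9) {
    stop("ploidy * n_seg must be an integer", call. = FALSE)
  }
  total_sum <- as.integer(round(total_sum))
  base <- total_sum %/% n_seg
  n_up <- total_sum - base * n_seg
  totals <- c(rep(base + 1L, n_up), rep(base, n_seg - n_up))
  # widen the state spectrum (preserving the sum) so that at least three
  # distinct imbalanced allele splits exist even at integer ploidies
  if (n_seg >= 4L) {
    tab <- table(totals[totals >= 1L])
    if (length(tab)) {
      t_mode <- as.integer(names(tab)[which.max(tab)])
      eq <- which(totals == t_mode)
      if (t_mode >= 1L && length(eq) >= 2L) {
        totals[eq[1L]] <- t_mode - 1L
        totals[eq[2L]] <- t_mode + 1L
      }
    }
  }
  # allele splits: alternate between maximally imbalanced and balanced-ish
  split_for <- function(t, i) {
    if (t == 0L) return(c(0L, 0L))
    choices <- lapply(0:(t %/% 2L), function(b) c(t - b, b))
    choices[[1L + (i %% length(choices))]]
  }
  ab <- t(vapply(seq_along(totals),
                 function(i) split_for(totals[i], i - 1L), integer(2)))
  n_chrom <- ceiling(n_seg / 2)
  chrom <- paste0(chrom_prefix, rep(seq_len(n_chrom), each = 2L))[seq_len(n_seg)]
  pos_in_chr <- ((seq_len(n_seg) - 1L) %% 2L)
  data.frame(chrom = chrom,
             start = pos_in_chr * seg_len + 1,
             end = (pos_in_chr + 1) * seg_len,
             a = ab[, 1L], b = ab[, 2L], stringsAsFactors = FALSE)
}

#' Simulate a segmented tumor genome with known purity and ploidy
#'
#' Emits noisy coverage ratios per segment (lognormal noise on the purity
#' mixture expectation), binomial B-allele read counts at heterozygous SNPs
#' (each SNP's alternate allele sits on a random parental haplotype), and
#' somatic mutant allele fractions drawn at the clonal heterozygous-diploid
#' expectation `tcc / 2`.
#'
#' @param config A [sim_config()]; `tcc`, `ploidy`, `read_depth`,
#'   `snp_per_mb`, `coverage_sigma`, `n_somatic_snvs` are used. Setting
#'   `coverage_sigma = 0` switches the whole generator to a noise-free
#'   idealization: coverage ratios, allele fractions and MAFs take their
#'   exact expectations (read counts may then be non-integer), so every
#'   downstream estimate is exact.
#' @param karyotype Optional karyotype data.frame (`chrom`, `start`, `end`,
#'   `a`, `b`); defaults to [design_karyotype()] at the configured ploidy.
#' @return List with `segments` (incl. noisy `coverage_ratio`), `snps`,
#'   `somatic_mafs` and `truth` (tcc, realized ploidy, karyotype).
#' @export
simulate_genome <- function(config = sim_config(), karyotype = NULL) {
  if (is.null(karyotype)) karyotype <- design_karyotype(config$ploidy)
  tcc <- config$tcc
  exact <- config$coverage_sigma == 0
  len <- karyotype$end - karyotype$start + 1
  total <- karyotype$a + karyotype$b
  ploidy_true <- sum(len * total) / sum(len)
  with_seed(config$seed + 1L, {
    ratio0 <- expected_coverage_ratio(total, tcc, ploidy_true)
    noise <- if (!exact) {
      stats::rlnorm(nrow(karyotype), 0, config$coverage_sigma)
    } else rep(1, nrow(karyotype))
    segments <- data.frame(chrom = karyotype$chrom,
                           start = karyotype$start, end = karyotype$end,
                           length = len,
                           coverage_ratio = ratio0 * noise,
                           stringsAsFactors = FALSE)
    snps <- do.call(rbind, lapply(seq_len(nrow(karyotype)), function(i) {
      n_snp <- max(1L, round(len[i] / 1e6 * config$snp_per_mb))
      pos <- sort(sample.int(len[i], n_snp)) + karyotype$start[i] - 1
      a <- karyotype$a[i]; b <- karyotype$b[i]
      on_a <- stats::runif(n_snp) < 0.5
      alt_copies <- ifelse(on_a, a, b)
      denom <- tcc * (a + b) + 2 * (1 - tcc)
      # homozygously deleted segment in a pure tumor: no tumor DNA at all
      p_alt <- if (denom > 0) {
        (tcc * alt_copies + (1 - tcc)) / denom
      } else rep(0.5, n_snp)
      if (exact) {
        depth <- rep(config$read_depth, n_snp)
        alt <- depth * p_alt
        normal_af <- rep(0.5, n_snp)
      } else {
        depth <- stats::rpois(n_snp, config$read_depth)
        depth[depth == 0L] <- 1L
        alt <- stats::rbinom(n_snp, depth, p_alt)
        norm_depth <- stats::rpois(n_snp, config$read_depth)
        norm_depth[norm_depth == 0L] <- 1L
        normal_af <- stats::rbinom(n_snp, norm_depth, 0.5) / norm_depth
      }
      data.frame(chrom = karyotype$chrom[i], pos = pos,
                 normal_af = normal_af,
                 tumor_depth = depth, tumor_alt_reads = alt,
                 stringsAsFactors = FALSE)
    }))
    mafs <- if (exact) {
      rep(tcc / 2, config$n_somatic_snvs)
    } else {
      maf_depth <- stats::rpois(config$n_somatic_snvs, config$read_depth)
      maf_depth[maf_depth == 0L] <- 1L
      stats::rbinom(config$n_somatic_snvs, maf_depth, tcc / 2) / maf_depth
    }
    list(segments = segments, snps = snps, somatic_mafs = mafs,
         truth = list(tcc = tcc, ploidy = ploidy_true,
                      karyotype = karyotype))
  })
}

#' Simulate a multiregion cohort with planted mutation sharing
#'
#' Gene-per-patient events are planted as shared, tumor-only or
#' thrombus-only according to the configured counts; per-sample 2-10 bp
#' indel counts are Poisson with a rate depending on the patient-level AC3
#' label.
#'
#' @param config A [sim_config()].
#' @return List with `variants` (patient, sample, compartment, gene rows),
#'   `samples` (sample sheet), `indels` (per-sample counts with AC3
#'   labels), and `truth` (planted counts).
#' @export
simulate_multiregion <- function(config = sim_config()) {
  n_shared <- config$genes_total - config$n_tumor_only -
    config$n_thrombus_only
  if (n_shared < 0) stop("private gene counts exceed genes_total",
                         call. = FALSE)
  with_seed(config$seed + 2L, {
    n_pat <- config$n_patients
    spc <- config$samples_per_compartment
    patients <- sprintf("P%02d", seq_len(n_pat))
    samples <- do.call(rbind, lapply(patients, function(pt) {
      data.frame(sample_id = paste0(pt, "_",
                                    c(paste0("T", seq_len(spc)),
                                      paste0("V", seq_len(spc)))),
                 patient_id = pt,
                 compartment = rep(c("tumor", "thrombus"), each = spc),
                 stringsAsFactors = FALSE)
    }))
    classes <- c(rep("shared", n_shared),
                 rep("tumor_only", config$n_tumor_only),
                 rep("thrombus_only", config$n_thrombus_only))
    gene_pat <- rep_len(patients, config$genes_total)
    classes <- sample(classes)
    variants <- list()
    for (g in seq_len(config$genes_total)) {
      pt <- gene_pat[g]
      gene <- sprintf("G%04d", g)
      sheet <- samples[samples$patient_id == pt, , drop = FALSE]
      pick <- function(comp) {
        s <- sheet$sample_id[sheet$compartment == comp]
        hit <- stats::runif(length(s)) < 0.6
        if (!any(hit)) hit[sample.int(length(s), 1L)] <- TRUE
        s[hit]
      }
      hit_samples <- switch(classes[g],
                            shared = c(pick("tumor"), pick("thrombus")),
                            tumor_only = pick("tumor"),
                            thrombus_only = pick("thrombus"))
      variants[[g]] <- data.frame(
        patient = pt, sample = hit_samples,
        compartment = sheet$compartment[match(hit_samples, sheet$sample_id)],
        gene = gene, stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, variants)
    n_ac3 <- round(config$frac_ac3_patients * n_pat)
    ac3_patients <- patients[seq_len(n_ac3)]
    indels <- data.frame(
      sample_id = samples$sample_id,
      patient_id = samples$patient_id,
      compartment = samples$compartment,
      ac3_positive = samples$patient_id %in% ac3_patients,
      stringsAsFactors = FALSE)
    indels$n_indels <- stats::rpois(
      nrow(indels),
      ifelse(indels$ac3_positive, config$indel_rate_pos,
             config$indel_rate_neg))
    list(variants = variants, samples = samples, indels = indels,
         truth = list(n_shared = n_shared,
                      n_tumor_only = config$n_tumor_only,
                      n_thrombus_only = config$n_thrombus_only,
                      ac3_patients = ac3_patients))
  })
}
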