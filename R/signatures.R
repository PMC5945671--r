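# Supervised mutational-signature decomposition -----------------------------

#' Construct a signature set
#'
#' @param W Non-negative matrix, one column per signature; columns must sum
#'   to 1 within `tol`. Rows should be named by channel label.
#' @param names Signature names (default column names).
#' @param cutoffs Per-signature relative-exposure cutoffs in `[0, 1)`;
#'   recycled to the number of signatures.
#' @param tol Tolerance on column sums.
#' @return Object of class `signature_set`: list with `W`, `names`,
#'   `cutoffs`.
#' @export
signature_set <- function(W, names = colnames(W), cutoffs = 0,
                          tol = 1e-6) {
  stopifnot(is.matrix(W))
  if (is.null(names)) names <- paste0("S", seq_len(ncol(W)))
  if (any(W < 0)) stop("signature matrix must be non-negative", call. = FALSE)
  cs <- colSums(W)
  if (any(abs(cs - 1) > tol)) {
    stop("signature columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")", call. = FALSE)
  }
  cutoffs <- rep_len(as.numeric(cutoffs), ncol(W))
  if (any(cutoffs < 0 | cutoffs >= 1)) {
    stop("cutoffs must lie in [0, 1)", call. = FALSE)
  }
  colnames(W) <- names
  structure(list(W = W, names = names,
                 cutoffs = stats::setNames(cutoffs, names)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", ncol(x$W), "signatures x", nrow(x$W), "channels\n")
  cat("  names:", paste(utils::head(x$names, 5), collapse = ", "),
      if (length(x$names) > 5) "...", "\n")
  cat("  nonzero cutoffs:", sum(x$cutoffs > 0), "\n")
  invisible(x)
}

.sig_W <- function(W) {
  if (inherits(W, "signature_set")) W$W else W
}
.sig_cutoffs <- function(W, k) {
  if (inherits(W, "signature_set")) W$cutoffs else rep(0, k)
}

# Lawson-Hanson active-set non-negative least squares.
.nnls_lh <- function(A, b, tol = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(tol)) {
    tol <- 10 * .Machine$double.eps * max(colSums(abs(A))) * max(1, max(abs(b)))
  }
  x <- numeric(n)
  P <- rep(FALSE, n)
  it <- 0L
  max_it <- 30L * n
  repeat {
    w <- drop(crossprod(A, b - A %*% x))
    cand <- which(!P & w > tol)
    if (!length(cand) || it >= max_it) break
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      it <- it + 1L
      idx <- which(P)
      s <- qr.coef(qr(A[, idx, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s > 1e-12)) {
        x[] <- 0
        x[idx] <- s
        break
      }
      neg <- s <= 1e-12
      denom <- x[idx][neg] - s[neg]
      alpha <- suppressWarnings(min(x[idx][neg][denom > 0] / denom[denom > 0]))
      if (!is.finite(alpha)) alpha <- 0
      x[idx] <- x[idx] + alpha * (s - x[idx])
      drop_i <- idx[x[idx] <= 1e-12]
      P[drop_i] <- FALSE
      x[drop_i] <- 0
      if (it >= max_it) {
        x[] <- 0
        x[idx] <- pmax(s, 0)
        break
      }
    }
  }
  pmax(x, 0)
}

#' Non-negative least-squares decomposition of a catalogue column
#'
#' Solves `min_{h >= 0} || v - W h ||_2` with the Lawson-Hanson active-set
#' algorithm.
#'
#' @param v Non-negative count vector (one catalogue column); its length
#'   must equal `nrow(W)`.
#' @param W A `signature_set` or a plain non-negative matrix.
#' @return List with `exposures` (named by signature) and `residual`
#'   (Euclidean norm of `v - W h`).
#' @export
nnls_decompose <- function(v, W) {
  Wm <- .sig_W(W)
  v <- as.numeric(v)
  if (length(v) != nrow(Wm)) {
    stop("length(v) must equal nrow(W)", call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) stop("v contains NA/NaN/Inf",
                                           call. = FALSE)
  if (any(v < 0)) stop("v must be non-negative", call. = FALSE)
  h <- .nnls_lh(Wm, v)
  names(h) <- colnames(Wm)
  list(exposures = h, residual = sqrt(sum((v - Wm %*% h)^2)))
}

#' Two-pass supervised exposures with signature-specific cutoffs
#'
#' Pass 1 fits all signatures by NNLS; signatures whose relative exposure
#' (exposure over the exposure total) does not exceed their cutoff are
#' discarded, and pass 2 refits the retained signatures only. Discarded
#' signatures receive exposure exactly 0.
#'
#' @inheritParams nnls_decompose
#' @param cutoffs Per-signature cutoffs on the relative-exposure scale;
#'   defaults to the cutoffs stored in the `signature_set` (0 for a plain
#'   matrix).
#' @return List with `exposures` (final, named), `pass1` exposures,
#'   `kept` (logical per signature), `residual` and `residual_pass1`.
#' @export
supervised_exposures <- function(v, W, cutoffs = NULL) {
  Wm <- .sig_W(W)
  k <- ncol(Wm)
  if (is.null(cutoffs)) cutoffs <- .sig_cutoffs(W, k)
  cutoffs <- rep_len(as.numeric(cutoffs), k)
  p1 <- nnls_decompose(v, Wm)
  h1 <- p1$exposures
  tot <- sum(h1)
  zero <- stats::setNames(numeric(k), colnames(Wm))
  if (tot <= 0) {
    return(list(exposures = zero, pass1 = h1, kept = rep(FALSE, k),
                residual = p1$residual, residual_pass1 = p1$residual))
  }
  kept <- (h1 / tot) > cutoffs
  if (!any(kept)) {
    return(list(exposures = zero, pass1 = h1, kept = kept,
                residual = sqrt(sum(as.numeric(v)^2)),
                residual_pass1 = p1$residual))
  }
  p2 <- nnls_decompose(v, Wm[, kept, drop = FALSE])
  h <- zero
  h[kept] <- p2$exposures
  list(exposures = h, pass1 = h1, kept = kept,
       residual = p2$residual, residual_pass1 = p1$residual)
}

#' Supervised exposures for a whole catalogue
#'
#' Applies [supervised_exposures()] column-wise.
#'
#' @param cat 96 x m catalogue matrix with channel rownames in canonical
#'   order (see [channel_labels()]).
#' @param W `signature_set` (or matrix) of predefined signatures.
#' @param cutoffs Optional cutoff override.
#' @return Object of class `exposure_matrix`: list with `H` (k x m absolute
#'   exposures, mutation-count units), `relative` (column-normalized; all
#'   zero columns stay zero), `residuals` (per sample), `presence`
#'   (logical k x m, exposure > 0).
#' @export
cohort_exposures <- function(cat, W, cutoffs = NULL) {
  Wm <- .sig_W(W)
  if (!is.matrix(cat) || nrow(cat) != nrow(Wm)) {
    stop("catalogue must be a matrix with ", nrow(Wm), " rows", call. = FALSE)
  }
  if (!is.null(rownames(cat)) && !is.null(rownames(Wm)) &&
      !identical(rownames(cat), rownames(Wm))) {
    stop("catalogue channels do not match signature matrix rows; ",
         "reorder with channel_index()", call. = FALSE)
  }
  k <- ncol(Wm); m <- ncol(cat)
  H <- matrix(0, k, m, dimnames = list(colnames(Wm), colnames(cat)))
  resid <- stats::setNames(numeric(m), colnames(cat))
  for (j in seq_len(m)) {
    fit <- supervised_exposures(cat[, j], W, cutoffs = cutoffs)
    H[, j] <- fit$exposures
    resid[j] <- fit$residual
  }
  tot <- colSums(H)
  rel <- sweep(H, 2L, ifelse(tot > 0, tot, 1), `/`)
  structure(list(H = H, relative = rel, residuals = resid, presence = H > 0),
            class = "exposure_matrix")
}

#' @export
print.exposure_matrix <- function(x, ...) {
  cat("exposure_matrix:", nrow(x$H), "signatures x", ncol(x$H), "samples\n")
  cat("  mean residual:", format(mean(x$residuals), digits = 4), "\n")
  cat("  signatures called present in >=1 sample:",
      sum(rowSums(x$presence) > 0), "\n")
  invisible(x)
}

#' Calibrate signature-specific cutoffs by ROC analysis
#'
#' For each signature, pass-1 relative exposures on a labeled training
#' cohort are swept as candidate cutoffs; the cutoff maximizing Youden's J
#' (sensitivity + specificity - 1) for predicting the known
#' presence/absence is chosen, with ties broken toward the larger cutoff.
#' Signatures whose truth labels are single-class get cutoff 0 with a
#' warning.
#'
#' @param cat Training catalogue (96 x m matrix).
#' @param truth Logical k x m matrix of true signature presence per sample.
#' @param W `signature_set` or matrix of the k signatures.
#' @return Named numeric vector of k cutoffs, with the achieved Youden J per
#'   signature in attribute `"youden"`.
#' @export
calibrate_cutoffs <- function(cat, truth, W) {
  Wm <- .sig_W(W)
  k <- ncol(Wm)
  truth <- matrix(as.logical(truth), k, ncol(cat))
  rel <- matrix(0, k, ncol(cat))
  for (j in seq_len(ncol(cat))) {
    h <- nnls_decompose(cat[, j], Wm)$exposures
    tot <- sum(h)
    rel[, j] <- if (tot > 0) h / tot else 0
  }
  cutoffs <- stats::setNames(numeric(k), colnames(Wm))
  youden <- stats::setNames(rep(NA_real_, k), colnames(Wm))
  single_class <- character()
  for (i in seq_len(k)) {
    y <- truth[i, ]
    x <- rel[i, ]
    if (all(y) || all(!y)) {
      single_class <- c(single_class, colnames(Wm)[i])
      cutoffs[i] <- 0
      next
    }
    cand <- sort(unique(c(0, x)))
    J <- vapply(cand, function(t) {
      pred <- x > t
      sens <- sum(pred & y) / sum(y)
      spec <- sum(!pred & !y) / sum(!y)
      sens + spec - 1
    }, numeric(1))
    best <- max(J)
    cutoffs[i] <- max(cand[J >= best - 1e-12])
    youden[i] <- best
  }
  if (length(single_class)) {
    warning("single-class truth for signature(s) ",
            paste(single_class, collapse = ", "), "; cutoff set to 0",
            call. = FALSE)
  }
  attr(cutoffs, "youden") <- youden
  cutoffs
}

#' Drop low-mutation-load samples from a catalogue
#'
#' @param cat Catalogue matrix.
#' @param min_snvs Samples with column sum strictly greater than this
#'   survive (default 25, the conventional exome load filter).
#' @return The filtered catalogue.
#' @export
min_load_filter <- function(cat, min_snvs = 25) {
  stopifnot(is.matrix(cat))
  cat[, colSums(cat) > min_snvs, drop = FALSE]
}
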