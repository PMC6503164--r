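#' Factor vector: one global normalization factor per sample
#'
#' @param method method label (e.g. `"TMM"`).
#' @param factors positive numeric vector named by sample id.
#' @param standardized logical; `TRUE` asserts geometric mean 1 (checked to
#'   1e-9 relative tolerance).
#' @return an object of class `factor_vector`.
#' @export
factor_vector <- function(method, factors, standardized = FALSE) {
  if (is.null(names(factors)) || any(names(factors) == ""))
    stopf("factors must be named by sample id")
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    bad <- names(factors)[!is.finite(factors) | factors <= 0][1]
    stopf("method %s: non-positive or non-finite factor for sample '%s'",
          method, bad)
  }
  if (standardized && abs(geomean(factors) - 1) > 1e-9)
    stopf("factors flagged standardized but geometric mean is %.12g",
          geomean(factors))
  structure(list(method = method, factors = factors,
                 standardized = standardized),
            class = "factor_vector")
}

#' @export
print.factor_vector <- function(x, ...) {
  cat(sprintf("factor_vector '%s' (%d samples%s): ", x$method,
              length(x$factors), if (x$standardized) ", standardized" else ""))
  cat(format(head(unname(x$factors), 5), digits = 4), "...\n")
  invisible(x)
}

#' Library sizes under the four library-size definitions
#'
#' `NR` sums nuclear genes only; `CR` nuclear + mitochondrial; `TC` adds the
#' spike-in genes (`TC = CR + ERCC`); `TN` is the externally supplied total
#' aligned read count per sample.
#'
#' @param cm a [count_matrix].
#' @param mode one of `"TN"`, `"TC"`, `"CR"`, `"NR"`.
#' @param annotation optional [gene_annotation]; genes without annotation
#'   count as nuclear (so with no annotation NR = CR = TC = column sum).
#' @param total_reads positive numeric per sample (required for `TN`).
#' @return named positive numeric vector of per-sample library sizes.
#' @export
library_size <- function(cm, mode = c("NR", "CR", "TC", "TN"),
                         annotation = NULL, total_reads = NULL) {
  mode <- match.arg(mode)
  cm <- as_count_matrix(cm)
  x <- cm$values
  if (mode == "TN") {
    if (is.null(total_reads))
      stopf("TN requires a per-sample total_reads vector")
    tr <- total_reads
    if (!is.null(names(tr))) tr <- tr[cm$sample_ids]
    if (length(tr) != ncol(x) || any(!is.finite(tr)))
      stopf("total_reads must supply one finite value per sample")
    N <- setNames(as.numeric(tr), cm$sample_ids)
  } else {
    cls <- classes_for(cm, annotation)
    keep <- switch(mode,
      NR = cls == "nuclear",
      CR = cls %in% c("nuclear", "mitochondrial"),
      TC = cls %in% c("nuclear", "mitochondrial", "spike_in"))
    N <- colSums(x[keep, , drop = FALSE])
  }
  if (any(N <= 0))
    stopf("%s library size is zero for sample '%s'", mode,
          names(N)[N <= 0][1])
  N
}

#' Library-size normalization factors (TN/TC/CR/NR)
#'
#' @inheritParams library_size
#' @return unstandardized [factor_vector] with \eqn{f_j = 10^6 / N_j}
#'   (counts-per-million scale).
#' @export
size_based_factors <- function(cm, mode = c("NR", "CR", "TC", "TN"),
                               annotation = NULL, total_reads = NULL) {
  mode <- match.arg(mode)
  N <- library_size(cm, mode, annotation, total_reads)
  factor_vector(mode, 1e6 / N)
}

#' Control-set normalization factors (HG7, ERCC, GAPDH, custom)
#'
#' The summed expression of the control genes acts as a pseudo library size
#' \eqn{N^*_j}; \eqn{f_j = 10^6 / N^*_j}. A sample in which every control
#' gene is zero makes the method inapplicable (the typical failure of GAPDH
#' on single-cell data) and raises an error naming the sample.
#'
#' @param cm a [count_matrix].
#' @param set a control-set name (`"HG7"`, `"ERCC"`, `"GAPDH"`, or any set
#'   in `annotation$control_sets`) or a character vector of gene ids.
#' @param annotation optional [gene_annotation] providing named sets.
#' @return unstandardized [factor_vector] labelled by the set name.
#' @export
control_set_factors <- function(cm, set, annotation = NULL) {
  cm <- as_count_matrix(cm)
  ids <- resolve_control_set(cm, set, annotation)
  label <- if (is.character(set) && length(set) == 1) set else "custom"
  Nstar <- colSums(cm$values[ids, , drop = FALSE])
  if (any(Nstar <= 0))
    stopf("%s: zero control-set counts in sample '%s'", label,
          names(Nstar)[Nstar <= 0][1])
  factor_vector(label, 1e6 / Nstar)
}

# zero-ignoring median-of-ratios pseudo library sizes, the common core of
# DESeq and RLE. reference_i = geometric mean of gene i over its positive
# samples; N*_j = median_i{x_ij / reference_i : x_ij > 0}
median_of_ratios_sizes <- function(cm) {
  x <- cm_values(cm)
  pos <- x > 0
  npos <- rowSums(pos)
  logx <- ifelse(pos, log(x), 0)
  ref <- exp(rowSums(logx) / pmax(npos, 1))
  usable <- npos > 0
  vapply(seq_len(ncol(x)), function(j) {
    sel <- pos[, j] & usable
    if (!any(sel))
      stopf("sample '%s' has no usable gene for median-of-ratios",
            colnames(x)[j])
    median(x[sel, j] / ref[sel])
  }, numeric(1)) -> Nstar
  setNames(Nstar, colnames(x))
}

#' DESeq (median-of-ratios) factors, zero-ignoring
#'
#' Per-gene reference = geometric mean over samples with a positive count;
#' the per-sample pseudo size is the median of positive-count ratios to the
#' reference; the factor is its reciprocal (scale is fixed later by
#' [standardize_geomean], after which DESeq and RLE are identical).
#'
#' @param cm a [count_matrix].
#' @return unstandardized [factor_vector] `"DESeq"`.
#' @export
deseq_factors <- function(cm) {
  Nstar <- median_of_ratios_sizes(cm)
  factor_vector("DESeq", 1 / Nstar)
}

#' RLE factors, zero-ignoring
#'
#' edgeR-style scaling \eqn{s_j = N^*_j / N_j} over the NR library size,
#' converted to a global factor \eqn{10^6/(N_j s_j) = 10^6/N^*_j}. After
#' geometric-mean standardization this coincides with [deseq_factors].
#'
#' @param cm a [count_matrix].
#' @param annotation optional [gene_annotation] for the NR library size.
#' @return unstandardized [factor_vector] `"RLE"`.
#' @export
rle_factors <- function(cm, annotation = NULL) {
  Nstar <- median_of_ratios_sizes(cm)
  factor_vector("RLE", 1e6 / Nstar)
}

#' Upper-quartile factors, zero-ignoring
#'
#' \eqn{s_j} = third quartile (type-7 interpolation) of the positive counts
#' scaled by the NR library size; \eqn{f_j = 10^6/(N_j s_j)}, which
#' simplifies to \eqn{10^6} over the Q75 of the raw positive counts.
#'
#' @param cm a [count_matrix].
#' @param annotation optional [gene_annotation] for the NR library size.
#' @return unstandardized [factor_vector] `"UQ"`.
#' @export
uq_factors <- function(cm, annotation = NULL) {
  cm <- as_count_matrix(cm)
  x <- cm$values
  N <- library_size(cm, "NR", annotation)
  s <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    v <- v[v > 0]
    if (!length(v)) stopf("sample '%s' is all zero", colnames(x)[j])
    q75(v / N[j])
  }, numeric(1))
  factor_vector("UQ", setNames(1e6 / (N * s), cm$sample_ids))
}

#' Trimmed mean of M-values factors, zero-ignoring
#'
#' The reference sample is the one whose Q75 of positive relative counts is
#' closest to the mean of those Q75s (ties to the lowest sample index). For
#' each sample, genes positive in both sample and reference contribute
#' \eqn{M_i = \log_2\frac{x_{ij}/N_j}{x_{ir}/N_r}} and
#' \eqn{A_i = \frac12 \log_2\left(\frac{x_{ij}}{N_j}\cdot\frac{x_{ir}}{N_r}\right)};
#' the extreme `trim_M` fraction by M and `trim_A` fraction by A are
#' discarded on both ends, and \eqn{s_j = 2^{\bar M_w}} with
#' inverse-asymptotic-variance weights
#' \eqn{1/v_i,\; v_i = \frac{N_j-x_{ij}}{N_j x_{ij}} + \frac{N_r-x_{ir}}{N_r x_{ir}}}.
#' The global factor is \eqn{10^6/(N_j s_j)}.
#'
#' @param cm a [count_matrix].
#' @param annotation optional [gene_annotation] for the NR library sizes.
#' @param trim_M,trim_A two-sided trimming fractions (defaults 0.3 / 0.05).
#' @return unstandardized [factor_vector] `"TMM"`.
#' @export
tmm_factors <- function(cm, annotation = NULL, trim_M = 0.3, trim_A = 0.05) {
  cm <- as_count_matrix(cm)
  x <- cm$values
  n <- ncol(x)
  if (n < 2) stopf("TMM needs at least two samples")
  N <- library_size(cm, "NR", annotation)
  relq <- vapply(seq_len(n), function(j) {
    v <- x[, j]
    v <- v[v > 0]
    if (!length(v)) stopf("sample '%s' is all zero", colnames(x)[j])
    q75(v / N[j])
  }, numeric(1))
  r <- which.min(abs(relq - mean(relq)))
  s <- vapply(seq_len(n), function(j) {
    tmm_scaling(x[, j], x[, r], N[j], N[r], trim_M, trim_A)
  }, numeric(1))
  factor_vector("TMM", setNames(1e6 / (N * s), cm$sample_ids))
}

# pairwise TMM scaling of sample vs reference (both as raw count vectors)
tmm_scaling <- function(xj, xr, Nj, Nr, trim_M, trim_A) {
  keep <- xj > 0 & xr > 0
  if (!any(keep)) {
    warnf("no gene shared with the TMM reference; s = 1")
    return(1)
  }
  xj <- xj[keep]; xr <- xr[keep]
  M <- log2((xj / Nj) / (xr / Nr))
  A <- 0.5 * log2((xj / Nj) * (xr / Nr))
  v <- (Nj - xj) / (Nj * xj) + (Nr - xr) / (Nr * xr)
  ng <- length(M)
  loM <- floor(ng * trim_M); loA <- floor(ng * trim_A)
  rM <- rank(M, ties.method = "average")
  rA <- rank(A, ties.method = "average")
  keep2 <- rM > loM & rM <= ng - loM & rA > loA & rA <= ng - loA
  if (!any(keep2)) {
    warnf("no gene survives TMM trimming; s = 1")
    return(1)
  }
  w <- 1 / v[keep2]
  # weight degenerates when x == N (single-gene library); guard, matching
  # the inverse-variance intent
  w[!is.finite(w) | w <= 0] <- max(w[is.finite(w) & w > 0], 1)
  2^(sum(w * M[keep2]) / sum(w))
}

#' Total Ubiquitous factors
#'
#' Pseudo library size = sum of the ubiquitous genes'
#' ([ubiquitous_genes]) counts; \eqn{f_j = 10^6 / N^*_j}.
#'
#' @param cm a [count_matrix] (raw counts).
#' @param params a [trim_params], or a precomputed `gene_set` to bypass the
#'   selection.
#' @return unstandardized [factor_vector] `"TU"`.
#' @export
tu_factors <- function(cm, params) {
  cm <- as_count_matrix(cm)
  gs <- if (inherits(params, "gene_set")) params
        else ubiquitous_genes(cm, params)
  if (!length(gs$gene_ids))
    stopf("empty ubiquitous gene set; widen the trimming parameters")
  Nstar <- colSums(cm$values[gs$gene_ids, , drop = FALSE])
  if (any(Nstar <= 0))
    stopf("zero ubiquitous-gene sum in sample '%s'",
          names(Nstar)[Nstar <= 0][1])
  fv <- factor_vector("TU", 1e6 / Nstar)
  fv$gene_set <- gs
  fv
}

#' Standardize a factor vector to geometric mean 1
#'
#' Idempotent; every method's factors are standardized this way before
#' comparison so that only relative scale matters.
#'
#' @param fv a [factor_vector].
#' @return the standardized [factor_vector].
#' @export
standardize_geomean <- function(fv) {
  stopifnot(inherits(fv, "factor_vector"))
  out <- fv
  out$factors <- fv$factors / geomean(fv$factors)
  out$standardized <- TRUE
  # re-validate the geometric-mean contract
  factor_vector(out$method, out$factors, standardized = TRUE)
  out
}

#' Apply factors to a count matrix
#'
#' Multiplies each sample column by its factor; zeros stay zero.
#'
#' @param cm a [count_matrix].
#' @param fv a [factor_vector] whose names cover the matrix's samples.
#' @return the normalized [count_matrix].
#' @export
apply_factors <- function(cm, fv) {
  cm <- as_count_matrix(cm)
  stopifnot(inherits(fv, "factor_vector"))
  if (!all(cm$sample_ids %in% names(fv$factors)))
    stopf("factor vector does not cover samples: %s",
          paste(setdiff(cm$sample_ids, names(fv$factors)), collapse = ", "))
  f <- fv$factors[cm$sample_ids]
  count_matrix(sweep(cm$values, 2, f, `*`))
}

# unit-factor baseline ("None"): the raw data, trivially standardized
none_factors <- function(cm) {
  cm <- as_count_matrix(cm)
  factor_vector("None", setNames(rep(1, length(cm$sample_ids)),
                                 cm$sample_ids),
                standardized = TRUE)
}
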