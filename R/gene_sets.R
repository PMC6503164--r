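#' Trimming parameters for ubiquitous-gene selection
#'
#' @param occurrence_rate minimal fraction of per-sample trimmed sets a gene
#'   must appear in; in (0, 1]. 1 means the strict intersection.
#' @param lower,upper percentile trimming bounds on each sample's non-zero
#'   expression distribution; `lower` in [0, 0.5), `upper` in (0.5, 1].
#' @return an object of class `trim_params`.
#' @export
trim_params <- function(occurrence_rate = 1, lower = 0.05, upper = 0.95) {
  if (!is.numeric(occurrence_rate) || occurrence_rate <= 0 ||
      occurrence_rate > 1)
    stopf("occurrence_rate must be in (0, 1]")
  if (lower < 0 || lower >= 0.5) stopf("lower must be in [0, 0.5)")
  if (upper <= 0.5 || upper > 1) stopf("upper must be in (0.5, 1]")
  structure(list(occurrence_rate = occurrence_rate,
                 lower = lower, upper = upper),
            class = "trim_params")
}

new_gene_set <- function(ids, provenance = list()) {
  structure(list(gene_ids = unique(as.character(ids)),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes\n", length(x$gene_ids)))
  invisible(x)
}

#' Per-gene non-zero ratio
#'
#' Fraction of samples in which each gene has a positive value.
#'
#' @param cm a [count_matrix] (or a named matrix).
#' @return named numeric vector in [0, 1], one entry per gene.
#' @export
non_zero_ratio <- function(cm) {
  x <- cm_values(cm)
  rowMeans(x > 0)
}

#' Genes passing a non-zero-ratio cutoff
#'
#' @param cm a [count_matrix].
#' @param nzr_cutoff fraction in (0, 1]; genes with non-zero ratio >= this
#'   value are kept.
#' @return a `gene_set`.
#' @export
eligible_genes <- function(cm, nzr_cutoff) {
  if (nzr_cutoff <= 0 || nzr_cutoff > 1)
    stopf("nzr_cutoff must be in (0, 1]")
  nzr <- non_zero_ratio(cm)
  ids <- names(nzr)[nzr >= nzr_cutoff]
  if (!length(ids))
    cn_log("no gene passes non-zero-ratio cutoff %.3g", nzr_cutoff)
  new_gene_set(ids, list(nzr_cutoff = nzr_cutoff))
}

#' Percentile-trimmed non-zero gene set of one sample
#'
#' Excludes zero-valued genes, ranks the remaining k genes ascending by
#' expression (ties broken by gene id), and keeps ranks r with
#' `floor(lower*k) < r <= floor(upper*k)`.
#'
#' @param values named numeric vector: one sample's expression per gene.
#' @param lower,upper trimming fractions, `lower < upper`.
#' @return a `gene_set`.
#' @export
trimmed_set <- function(values, lower, upper) {
  if (lower >= upper) stopf("lower must be < upper")
  if (is.null(names(values))) stopf("values must be named by gene id")
  nz <- values[values > 0]
  k <- length(nz)
  if (k == 0) {
    warnf("all-zero sample: empty trimmed set")
    return(new_gene_set(character(0), list(lower = lower, upper = upper)))
  }
  ord <- order(nz, names(nz))
  lo <- floor(lower * k)
  hi <- floor(upper * k)
  ids <- if (hi > lo) names(nz)[ord][(lo + 1):hi] else character(0)
  new_gene_set(ids, list(lower = lower, upper = upper))
}

#' Ubiquitous genes by occurrence rate over trimmed sets
#'
#' Builds the per-sample trimmed sets from the raw matrix and keeps genes
#' appearing in at least `ceil(occurrence_rate * n)` of the n sets. With
#' occurrence rate 1 this is the intersection across all samples.
#'
#' @param cm a [count_matrix] (raw counts; ubiquitous genes are always
#'   derived from the raw matrix and reused to evaluate every method).
#' @param params a [trim_params].
#' @return a `gene_set` with provenance recording the parameters.
#' @export
ubiquitous_genes <- function(cm, params) {
  stopifnot(inherits(params, "trim_params"))
  x <- cm_values(cm)
  n <- ncol(x)
  counts <- integer(nrow(x))
  names(counts) <- rownames(x)
  for (j in seq_len(n)) {
    ts <- suppressWarnings(trimmed_set(x[, j], params$lower, params$upper))
    counts[ts$gene_ids] <- counts[ts$gene_ids] + 1L
  }
  thr <- as.integer(ceiling(params$occurrence_rate * n))
  ids <- names(counts)[counts >= thr]
  if (!length(ids))
    cn_log("empty ubiquitous set at occurrence=%.2f lower=%.2f upper=%.2f",
           params$occurrence_rate, params$lower, params$upper)
  new_gene_set(ids, list(occurrence_rate = params$occurrence_rate,
                         lower = params$lower, upper = params$upper))
}
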