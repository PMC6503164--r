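#' Raw coefficient of variation of one gene
#'
#' Sample standard deviation (n-1 denominator) over the mean, across ALL
#' samples including zeros. Undefined (NA) when the mean is not positive;
#' such genes are treated as not uniform.
#'
#' @param values numeric vector of one gene's expression over samples.
#' @return non-negative scalar, or `NA_real_`.
#' @export
cv_raw <- function(values) {
  if (length(values) < 2) stopf("CV needs at least two samples")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  sd(values) / m
}

#' Zero-ignoring log2 coefficient of variation of one gene
#'
#' Dispersion of `log2(x)` over the gene's positive entries divided by their
#' mean; the number of positive entries `n_star` excludes zeros. Genes with
#' fewer than two positive values or a non-positive log2 mean have no
#' defined CV (`cv = NA`) and are excluded from threshold curves.
#'
#' @param values numeric vector of one gene's expression over samples.
#' @return list with elements `cv` and `n_star`.
#' @export
cv_log2 <- function(values) {
  pos <- values[values > 0]
  ns <- length(pos)
  if (ns < 2) return(list(cv = NA_real_, n_star = ns))
  l <- log2(pos)
  mu <- mean(l)
  if (mu <= 0) return(list(cv = NA_real_, n_star = ns))
  list(cv = sd(l) / mu, n_star = ns)
}

# vectorized cv_log2 over all rows of a matrix; returns numeric vector with
# NA where undefined
cv_log2_rows <- function(x) {
  pos <- x > 0
  ns <- rowSums(pos)
  l <- matrix(0, nrow(x), ncol(x))
  l[pos] <- log2(x[pos])
  s1 <- rowSums(l)
  s2 <- rowSums(l * l)
  mu <- s1 / ns
  vv <- (s2 - ns * mu^2) / (ns - 1)
  vv[vv < 0] <- 0  # guard tiny negative from cancellation
  cv <- sqrt(vv) / mu
  cv[ns < 2 | mu <= 0] <- NA_real_
  setNames(cv, rownames(x))
}

#' Min-max normalize a vector of CVs to [0, 1]
#'
#' @param cvs numeric vector (NAs allowed; propagated).
#' @return vector with min mapped to 0 and max to 1; all-identical input
#'   maps to all zeros (degenerate, logged).
#' @export
normalize_cvs <- function(cvs) {
  ok <- is.finite(cvs)
  if (sum(ok) < 2) stopf("need at least two finite CVs")
  lo <- min(cvs[ok]); hi <- max(cvs[ok])
  out <- rep(NA_real_, length(cvs))
  if (hi == lo) {
    cn_log("all CVs identical; normalized CVs set to 0")
    out[ok] <- 0
  } else {
    out[ok] <- (cvs[ok] - lo) / (hi - lo)
  }
  names(out) <- names(cvs)
  out
}

#' CV threshold curve
#'
#' For the genes passing the non-zero-ratio cutoff and having a defined
#' zero-ignoring log2 CV, min-max normalizes the CVs and counts, at each
#' cutoff `t/grid_size` (t = 1..grid_size), how many genes fall at or below
#' it ("uniform genes").
#'
#' @param cm a normalized [count_matrix].
#' @param nzr_cutoff non-zero-ratio eligibility cutoff in (0, 1].
#' @param grid_size number of evenly spaced cutoffs (default 1000).
#' @return an object of class `cv_curve` with `cutoffs`, `counts`,
#'   `n_eligible` (genes entering the min-max normalization) and
#'   `grid_size`.
#' @export
cv_threshold_curve <- function(cm, nzr_cutoff, grid_size = 1000L) {
  x <- cm_values(cm)
  grid_size <- as.integer(grid_size)
  if (grid_size < 1) stopf("grid_size must be >= 1")
  elig <- non_zero_ratio(x) >= nzr_cutoff
  cvs <- cv_log2_rows(x[elig, , drop = FALSE])
  cvs <- cvs[is.finite(cvs)]
  if (length(cvs) < 2)
    stopf("fewer than two eligible genes with a defined CV")
  ncv <- normalize_cvs(cvs)
  # first grid index at which each gene counts as uniform
  first <- pmax(ceiling(ncv * grid_size - 1e-9), 1L)
  counts <- cumsum(tabulate(first, nbins = grid_size))
  structure(list(cutoffs = seq_len(grid_size) / grid_size,
                 counts = as.integer(counts),
                 n_eligible = length(cvs),
                 grid_size = grid_size),
            class = "cv_curve")
}

#' Area under the CV threshold curve
#'
#' The mean fraction of uniform genes over the cutoff grid:
#' `sum(counts) / (grid_size * n_eligible)`, a number in [0, 1]. Higher
#' means more genes are stable after normalization.
#'
#' @param curve a `cv_curve` from [cv_threshold_curve].
#' @return scalar in [0, 1].
#' @export
aucvc <- function(curve) {
  stopifnot(inherits(curve, "cv_curve"))
  if (curve$n_eligible == 0) stopf("empty curve")
  sum(curve$counts) / (curve$grid_size * curve$n_eligible)
}

# one-call convenience used by the TU search and evaluation loops
aucvc_of <- function(cm, nzr_cutoff, grid_size = 1000L) {
  aucvc(cv_threshold_curve(cm, nzr_cutoff, grid_size))
}

#' Median Spearman correlation of sampled ubiquitous gene pairs
#'
#' Draws distinct unordered pairs of ubiquitous genes (all pairs when the
#' total is at most `n_pairs`, otherwise a seeded uniform sample without
#' replacement), computes Spearman's rank correlation of the two genes'
#' normalized expression profiles across all samples, and returns the
#' median. Pairs involving a gene constant across samples are dropped (with
#' a logged count). Values near 0 indicate successful normalization.
#'
#' @param cm a normalized [count_matrix].
#' @param ubiq a `gene_set` or character vector of gene ids.
#' @param n_pairs maximum number of pairs (default 1e6).
#' @param seed integer seed for pair sampling (default 1); sampling uses a
#'   private RNG stream and does not disturb the global seed.
#' @return scalar in [-1, 1].
#' @export
mscc <- function(cm, ubiq, n_pairs = 1e6, seed = 1L) {
  x <- cm_values(cm)
  ids <- if (inherits(ubiq, "gene_set")) ubiq$gene_ids else as.character(ubiq)
  ids <- intersect(ids, rownames(x))
  g <- length(ids)
  if (g < 2) stopf("need at least two ubiquitous genes present in the matrix")
  total <- g * (g - 1) / 2
  if (total <= n_pairs) {
    idx <- seq_len(total)
  } else {
    idx <- withr_seed(seed, sample.int(total, n_pairs))
  }
  # unrank: pairs (i, j), i < j, ordered by i then j
  cum <- cumsum(seq(g - 1, 1))              # pairs with first element <= i
  i <- findInterval(idx - 1, c(0, cum), rightmost.closed = FALSE,
                    left.open = FALSE)
  i <- pmin(i, g - 1)                       # guard fp edge
  j <- i + (idx - c(0, cum)[i]) + 0
  r <- t(apply(x[ids, , drop = FALSE], 1, rank))
  rc <- r - rowMeans(r)
  ss <- rowSums(rc * rc)
  num <- rowSums(rc[i, , drop = FALSE] * rc[j, , drop = FALSE])
  den <- sqrt(ss[i] * ss[j])
  scc <- ifelse(den > 0, num / den, NA_real_)
  dropped <- sum(!is.finite(scc))
  if (dropped > 0)
    cn_log("mscc: dropped %d pairs with a constant gene profile", dropped)
  scc <- scc[is.finite(scc)]
  if (!length(scc)) stopf("no pair with a defined Spearman correlation")
  median(scc)
}

# evaluate an expression under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# relative log expression over positive entries: log(x_ij) minus the
# per-gene median of log over that gene's positive samples
rle_values <- function(x) {
  pos <- x > 0
  keep <- rowSums(pos) > 0
  x <- x[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  l <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  l[pos] <- log(x[pos])
  med <- apply(l, 1, median, na.rm = TRUE)
  l - med
}

#' Distributional RLE metrics
#'
#' `rle_med` is the mean over samples of the squared per-sample median of
#' relative log expression; `rle_iqr` is the variance over samples of the
#' per-sample RLE inter-quartile range. Both are exactly 0 when all columns
#' are identical; natural logarithm, positive entries only.
#'
#' @param cm a normalized [count_matrix].
#' @return non-negative scalar.
#' @export
rle_med <- function(cm) {
  stats <- rle_sample_stats(cm_values(cm))
  mean(stats$med^2)
}

#' @rdname rle_med
#' @export
rle_iqr <- function(cm) {
  stats <- rle_sample_stats(cm_values(cm))
  var(stats$iqr)
}

rle_sample_stats <- function(x) {
  rl <- rle_values(x)
  med <- numeric(ncol(rl)); iqr <- numeric(ncol(rl))
  for (j in seq_len(ncol(rl))) {
    v <- rl[, j]
    v <- v[is.finite(v)]
    if (length(v) < 2)
      stopf("sample '%s' has fewer than two positive genes", colnames(rl)[j])
    med[j] <- median(v)
    iqr[j] <- IQR(v, type = 7)
  }
  list(med = med, iqr = iqr)
}

#' Hierarchical clustering of factor vectors by rank-correlation distance
#'
#' Pairwise distance `1 - SCC` between methods' (standardized) factor
#' vectors, average linkage. Methods with a constant factor vector have no
#' defined rank correlation and are excluded with a warning.
#'
#' @param factors list of [factor_vector] objects on the same samples.
#' @return an [stats::hclust] tree with method names as labels.
#' @export
cluster_factors <- function(factors) {
  if (length(factors) < 2) stopf("need at least two factor vectors")
  ids <- names(factors[[1]]$factors)
  mat <- vapply(factors, function(f) {
    if (!identical(names(f$factors), ids))
      stopf("factor vectors are not aligned on the same samples")
    f$factors
  }, numeric(length(ids)))
  colnames(mat) <- vapply(factors, function(f) f$method, character(1))
  keep <- apply(mat, 2, function(v) length(unique(v)) > 1)
  if (any(!keep)) {
    warnf("excluding constant factor vectors: %s",
          paste(colnames(mat)[!keep], collapse = ", "))
    mat <- mat[, keep, drop = FALSE]
  }
  if (ncol(mat) < 2) stopf("fewer than two non-constant factor vectors")
  scc <- cor(mat, method = "spearman")
  hclust(as.dist(1 - scc), method = "average")
}

#' Export a factor dendrogram in Newick format
#' @param tree an [stats::hclust] from [cluster_factors].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
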