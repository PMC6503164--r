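#' Search configuration for the TU parameter grid
#'
#' @param occurrence_grid occurrence-rate values to test, each in (0, 1].
#' @param lower_grid lower trimming cutoffs, each in [0, 0.5).
#' @param upper_grid upper trimming cutoffs, each in (0.5, 1].
#' @param min_ubiquitous minimum ubiquitous-set size a combination must
#'   produce to be scored; with `strict = TRUE` (default) the constraint is
#'   "more than", i.e. the set must exceed `min_ubiquitous`.
#' @param strict logical; see `min_ubiquitous`.
#' @param nzr_cutoff non-zero-ratio cutoff at which AUCVC is scored during
#'   the search.
#' @param nzr_cutoffs cutoff grid used by the evaluation modes.
#' @param grid_size CV-curve grid resolution.
#' @return an object of class `search_config`.
#' @export
search_config <- function(occurrence_grid = seq(0.2, 0.6, by = 0.1),
                          lower_grid = seq(0.05, 0.40, by = 0.05),
                          upper_grid = seq(0.60, 0.95, by = 0.05),
                          min_ubiquitous = 100L, strict = TRUE,
                          nzr_cutoff = 0.5,
                          nzr_cutoffs = seq(0.2, 0.9, by = 0.1),
                          grid_size = 1000L) {
  if (!length(occurrence_grid) || !length(lower_grid) || !length(upper_grid))
    stopf("parameter grids must be non-empty")
  if (any(occurrence_grid <= 0 | occurrence_grid > 1))
    stopf("occurrence_grid values must be in (0, 1]")
  if (any(lower_grid < 0 | lower_grid >= 0.5))
    stopf("lower_grid values must be in [0, 0.5)")
  if (any(upper_grid <= 0.5 | upper_grid > 1))
    stopf("upper_grid values must be in (0.5, 1]")
  if (min_ubiquitous < 2) stopf("min_ubiquitous must be >= 2")
  structure(list(occurrence_grid = occurrence_grid,
                 lower_grid = lower_grid,
                 upper_grid = upper_grid,
                 min_ubiquitous = as.integer(min_ubiquitous),
                 strict = isTRUE(strict),
                 nzr_cutoff = nzr_cutoff,
                 nzr_cutoffs = nzr_cutoffs,
                 grid_size = as.integer(grid_size)),
            class = "search_config")
}

#' Preset search configurations
#'
#' `"scrna"`: occurrence rates 0.2-0.6 (step 0.1), trimming 5-40% / 60-95%
#' (step 5%), more than 100 ubiquitous genes required, non-zero-ratio grid
#' 0.2-0.9. `"bulk"`: occurrence rate fixed at 1 (strict intersection), more
#' than 1000 ubiquitous genes, non-zero-ratio grid 0.7-1.
#'
#' @param preset `"scrna"` or `"bulk"`.
#' @param ... overrides passed to [search_config].
#' @return a `search_config`.
#' @export
search_preset <- function(preset = c("scrna", "bulk"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    scrna = list(occurrence_grid = seq(0.2, 0.6, by = 0.1),
                 min_ubiquitous = 100L,
                 nzr_cutoff = 0.5,
                 nzr_cutoffs = seq(0.2, 0.9, by = 0.1)),
    bulk  = list(occurrence_grid = 1,
                 min_ubiquitous = 1000L,
                 nzr_cutoff = 0.8,
                 nzr_cutoffs = seq(0.7, 1.0, by = 0.1)))
  do.call(search_config, modifyList(base, list(...)))
}

#' Exhaustive TU parameter search maximizing AUCVC
#'
#' Enumerates the full occurrence x lower x upper grid. For each
#' combination the ubiquitous set is derived from the raw matrix; sets at or
#' below the size constraint are skipped with a recorded reason. Surviving
#' combinations are scored by the AUCVC of the TU-normalized matrix at
#' `config$nzr_cutoff`. Ties on AUCVC prefer the larger ubiquitous set, then
#' the lexicographically smallest (occurrence, lower, upper).
#'
#' @param cm a raw [count_matrix].
#' @param config a [search_config].
#' @return an object of class `search_result`: `best_params`
#'   ([trim_params]), `best_aucvc`, `ubiquitous` (gene_set), `factors`
#'   (standardized TU [factor_vector]) and `trace` (data.frame in grid
#'   order with columns occurrence, lower, upper, n_ubiquitous, aucvc,
#'   status).
#' @export
tu_search <- function(cm, config) {
  stopifnot(inherits(config, "search_config"))
  cm <- as_count_matrix(cm)
  x <- cm$values
  n <- ncol(x)
  m <- nrow(x)
  # per-sample ordering of non-zero genes (value, then gene id) computed
  # once; a trimmed set for any (lower, upper) is a contiguous slice
  orders <- lapply(seq_len(n), function(j) {
    nz <- which(x[, j] > 0)
    nz[order(x[nz, j], rownames(x)[nz])]
  })
  ks <- lengths(orders)
  min_needed <- config$min_ubiquitous + if (config$strict) 1L else 0L

  # membership counts memoized per (lower, upper)
  member_counts <- function(lower, upper) {
    idx <- unlist(lapply(seq_len(n), function(j) {
      k <- ks[j]
      lo <- floor(lower * k); hi <- floor(upper * k)
      if (hi > lo) orders[[j]][(lo + 1):hi] else integer(0)
    }), use.names = FALSE)
    tabulate(idx, nbins = m)
  }

  grid <- expand.grid(upper = config$upper_grid,
                      lower = config$lower_grid,
                      occurrence = config$occurrence_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # grid order: occurrence outermost, then lower, then upper
  grid <- grid[, c("occurrence", "lower", "upper")]

  counts_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(grid))
  best <- NULL
  for (k in seq_len(nrow(grid))) {
    occ <- grid$occurrence[k]; lo <- grid$lower[k]; up <- grid$upper[k]
    key <- sprintf("%.10g_%.10g", lo, up)
    cnt <- counts_cache[[key]]
    if (is.null(cnt)) {
      cnt <- member_counts(lo, up)
      counts_cache[[key]] <- cnt
    }
    thr <- as.integer(ceiling(occ * n))
    ub_idx <- which(cnt >= thr)
    n_ub <- length(ub_idx)
    if (n_ub < min_needed) {
      rows[[k]] <- data.frame(occurrence = occ, lower = lo, upper = up,
                              n_ubiquitous = n_ub, aucvc = NA_real_,
                              status = sprintf("skipped: %d ubiquitous genes (need %s%d)",
                                               n_ub,
                                               if (config$strict) ">" else ">=",
                                               config$min_ubiquitous))
      next
    }
    Nstar <- colSums(x[ub_idx, , drop = FALSE])
    if (any(Nstar <= 0)) {
      rows[[k]] <- data.frame(occurrence = occ, lower = lo, upper = up,
                              n_ubiquitous = n_ub, aucvc = NA_real_,
                              status = "skipped: zero ubiquitous-gene sum")
      next
    }
    f <- 1e6 / Nstar
    f <- f / geomean(f)
    norm <- sweep(x, 2, f, `*`)
    a <- aucvc_of(count_matrix(norm), config$nzr_cutoff, config$grid_size)
    rows[[k]] <- data.frame(occurrence = occ, lower = lo, upper = up,
                            n_ubiquitous = n_ub, aucvc = a, status = "ok")
    better <- is.null(best) || a > best$aucvc ||
      (a == best$aucvc && n_ub > best$n_ub)
    # grid order already encodes the lexicographic tie-break
    if (better) best <- list(aucvc = a, n_ub = n_ub, k = k, idx = ub_idx)
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  if (is.null(best))
    stopf(paste("every parameter combination was skipped;",
                "widen the grids or lower min_ubiquitous"))
  bp <- trim_params(grid$occurrence[best$k], grid$lower[best$k],
                    grid$upper[best$k])
  gs <- new_gene_set(rownames(x)[best$idx],
                     list(occurrence_rate = bp$occurrence_rate,
                          lower = bp$lower, upper = bp$upper,
                          nzr_cutoff = config$nzr_cutoff))
  fv <- standardize_geomean(tu_factors(cm, gs))
  structure(list(best_params = bp, best_aucvc = best$aucvc,
                 ubiquitous = gs, factors = fv, trace = trace),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  bp <- x$best_params
  cat(sprintf(paste0("TU search: best AUCVC %.4f at occurrence=%.2f ",
                     "lower=%.2f upper=%.2f (%d ubiquitous genes; ",
                     "%d/%d combinations scored)\n"),
              x$best_aucvc, bp$occurrence_rate, bp$lower, bp$upper,
              length(x$ubiquitous$gene_ids),
              sum(x$trace$status == "ok"), nrow(x$trace)))
  invisible(x)
}

#' Write a TU search trace as TSV
#' @param result a `search_result`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  write.table(result$trace, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
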