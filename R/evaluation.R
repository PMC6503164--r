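#' Compute standardized factors for a set of methods
#'
#' Runs each requested method, standardizes to geometric mean 1, and
#' records methods that fail (e.g. a control gene with zero counts in some
#' sample) as unavailable instead of aborting.
#'
#' @param cm a raw [count_matrix].
#' @param annotation optional [gene_annotation].
#' @param total_reads optional per-sample totals (enables TN).
#' @param methods character vector of method labels; default is the
#'   simple-evaluation set.
#' @param tu_config optional [search_config] (required when `"TU"` is in
#'   `methods`).
#' @return list with `factors` (named list of standardized
#'   [factor_vector]s), `unavailable` (named list of failure reasons) and,
#'   when TU was run, `tu_result` (the [tu_search] result).
#' @export
compute_method_factors <- function(cm, annotation = NULL,
                                   total_reads = NULL,
                                   methods = c("HG7", "GAPDH", "ERCC", "TN",
                                               "TC", "CR", "NR",
                                               "DESeq(RLE)", "UQ", "TMM"),
                                   tu_config = NULL) {
  cm <- as_count_matrix(cm)
  out <- list(factors = list(), unavailable = list(), tu_result = NULL)
  for (mth in methods) {
    fv <- tryCatch({
      raw <- switch(mth,
        "HG7"   = control_set_factors(cm, "HG7", annotation),
        "GAPDH" = control_set_factors(cm, "GAPDH", annotation),
        "ERCC"  = control_set_factors(cm, "ERCC", annotation),
        "TN"    = size_based_factors(cm, "TN", annotation, total_reads),
        "TC"    = size_based_factors(cm, "TC", annotation),
        "CR"    = size_based_factors(cm, "CR", annotation),
        "NR"    = size_based_factors(cm, "NR", annotation),
        "DESeq(RLE)" = deseq_factors(cm),
        "DESeq" = deseq_factors(cm),
        "RLE"   = rle_factors(cm, annotation),
        "UQ"    = uq_factors(cm, annotation),
        "TMM"   = tmm_factors(cm, annotation),
        "None"  = none_factors(cm),
        "TU"    = {
          if (is.null(tu_config)) stopf("TU requires a search_config")
          res <- tu_search(cm, tu_config)
          out$tu_result <- res
          res$factors
        },
        stopf("unknown method '%s'", mth))
      raw$method <- mth
      standardize_geomean(raw)
    }, error = function(e) conditionMessage(e))
    if (inherits(fv, "factor_vector")) out$factors[[mth]] <- fv
    else out$unavailable[[mth]] <- fv
  }
  out
}

#' Mode 1: normalize with TU, no evaluation
#'
#' Runs the TU parameter search, standardizes the winning factors and
#' applies them to the matrix.
#'
#' @param cm a raw [count_matrix].
#' @param config a [search_config].
#' @param out_dir optional directory; when given, the factor table,
#'   normalized matrix, ubiquitous set and search trace are written there.
#' @return list with `normalized` ([count_matrix]), `factors`
#'   (standardized [factor_vector]) and `search` (the [tu_search] result).
#' @export
run_mode1 <- function(cm, config = search_preset("scrna"), out_dir = NULL) {
  cm <- as_count_matrix(cm)
  res <- tu_search(cm, config)
  norm <- apply_factors(cm, res$factors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_factors(list(res$factors), file.path(out_dir, "factors.tsv"))
    write_counts(norm, file.path(out_dir, "normalized.tsv"))
    write_gene_set(res$ubiquitous, file.path(out_dir, "ubiquitous.txt"))
    write_trace(res, file.path(out_dir, "tu_trace.tsv"))
  }
  list(normalized = norm, factors = res$factors, search = res)
}

#' Mode 2: simple evaluation by AUCVC
#'
#' Computes factors for the library-size, control-set and average-bulk
#' methods plus the raw-data baseline (`None`), scores each by AUCVC over
#' the non-zero-ratio cutoff grid, and selects the method with the highest
#' mean AUCVC. TU is deliberately excluded here (it belongs to modes 1
#' and 3); TN and ERCC are attempted only when their inputs are available,
#' and any failing method is reported as unavailable rather than fatal.
#'
#' @param cm a raw [count_matrix].
#' @param annotation optional [gene_annotation].
#' @param total_reads optional per-sample totals (enables TN).
#' @param config a [search_config] (supplies `nzr_cutoffs` and
#'   `grid_size`).
#' @param extra_methods further method labels to include.
#' @return an `evaluation_table`: list with `methods`, `aucvc` (long
#'   data.frame method x cutoff), `best_method`, `mean_aucvc`, `factors`,
#'   `unavailable`.
#' @export
run_mode2 <- function(cm, annotation = NULL, total_reads = NULL,
                      config = search_preset("scrna"),
                      extra_methods = character(0)) {
  cm <- as_count_matrix(cm)
  methods <- c("HG7", "GAPDH", "ERCC", "TN", "TC", "CR", "NR",
               "DESeq(RLE)", "UQ", "TMM", "None", extra_methods)
  if (is.null(total_reads)) methods <- setdiff(methods, "TN")
  mf <- compute_method_factors(cm, annotation, total_reads, methods)
  tab <- aucvc_table(cm, mf$factors, config$nzr_cutoffs, config$grid_size)
  mean_auc <- tapply(tab$aucvc, tab$method, mean)
  mean_auc <- mean_auc[order(-mean_auc, names(mean_auc))]
  structure(list(methods = names(mf$factors), aucvc = tab,
                 best_method = names(mean_auc)[1],
                 mean_aucvc = mean_auc,
                 factors = mf$factors, unavailable = mf$unavailable,
                 metrics = NULL, ranks = NULL, consistency = NULL),
            class = "evaluation_table")
}

# AUCVC for every (method, cutoff) pair; the eligible-gene set at a cutoff
# is shared by construction since positive factors preserve zero patterns
aucvc_table <- function(cm, factors, nzr_cutoffs, grid_size) {
  rows <- list()
  for (mth in names(factors)) {
    norm <- apply_factors(cm, factors[[mth]])
    for (cz in nzr_cutoffs) {
      rows[[length(rows) + 1L]] <-
        data.frame(method = mth, nzr_cutoff = cz,
                   aucvc = aucvc_of(norm, cz, grid_size))
    }
  }
  do.call(rbind, rows)
}

#' Mode 3: complete evaluation (AUCVC + mSCC + RLE metrics)
#'
#' Extends mode 2 with the TU method (a fresh parameter search per
#' non-zero-ratio cutoff), the median Spearman correlation of ubiquitous
#' gene pairs, and the distributional RLE metrics. The ubiquitous set for
#' mSCC is derived once from the raw matrix (at the first cutoff's optimal
#' TU parameters) and shared by all methods. Methods are ranked by AUCVC
#' descending and mSCC ascending; the consistency report groups methods
#' into three performance tiers per metric and flags methods whose AUCVC
#' and mSCC tiers disagree.
#'
#' @inheritParams run_mode2
#' @param n_pairs gene pairs sampled for mSCC.
#' @param seed seed for mSCC pair sampling.
#' @return an `evaluation_table` with `metrics` (per-method mscc, rle_med,
#'   rle_iqr), `ranks`, `consistency`, `tu_results` and the mode-2 fields.
#' @export
run_mode3 <- function(cm, annotation = NULL, total_reads = NULL,
                      config = search_preset("scrna"),
                      n_pairs = 1e6, seed = 1L) {
  cm <- as_count_matrix(cm)
  ev <- run_mode2(cm, annotation, total_reads, config)

  # TU: one search per evaluation cutoff, scored at that cutoff
  tu_rows <- list()
  tu_results <- list()
  for (cz in config$nzr_cutoffs) {
    cfg <- config
    cfg$nzr_cutoff <- cz
    res <- tryCatch(tu_search(cm, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      ev$unavailable[[sprintf("TU@%.2g", cz)]] <- conditionMessage(res)
      next
    }
    tu_results[[as.character(cz)]] <- res
    tu_rows[[length(tu_rows) + 1L]] <-
      data.frame(method = "TU", nzr_cutoff = cz, aucvc = res$best_aucvc)
  }
  if (length(tu_rows)) {
    ev$aucvc <- rbind(ev$aucvc, do.call(rbind, tu_rows))
    first <- tu_results[[1]]
    ev$factors$TU <- first$factors
    ev$methods <- c(ev$methods, "TU")
  }

  # shared ubiquitous set from the raw matrix
  ubiq <- if (length(tu_results)) tu_results[[1]]$ubiquitous
          else eligible_genes(cm, min(config$nzr_cutoffs))
  met_rows <- list()
  for (mth in names(ev$factors)) {
    norm <- apply_factors(cm, ev$factors[[mth]])
    met_rows[[length(met_rows) + 1L]] <- data.frame(
      method = mth,
      mscc = mscc(norm, ubiq, n_pairs = n_pairs, seed = seed),
      rle_med = rle_med(norm),
      rle_iqr = rle_iqr(norm))
  }
  ev$metrics <- do.call(rbind, met_rows)
  ev$ubiquitous <- ubiq
  ev$tu_results <- tu_results

  mean_auc <- tapply(ev$aucvc$aucvc, ev$aucvc$method, mean)
  score <- data.frame(method = names(mean_auc),
                      aucvc = as.numeric(mean_auc))
  score <- merge(score, ev$metrics, by = "method", sort = TRUE)
  ev$ranks <- data.frame(
    method = score$method,
    aucvc_rank = rank_with_ties(-score$aucvc, score$method),
    mscc_rank = rank_with_ties(score$mscc, score$method),
    rle_med_rank = rank_with_ties(score$rle_med, score$method),
    rle_iqr_rank = rank_with_ties(score$rle_iqr, score$method))
  ga <- consistency_groups(setNames(score$aucvc, score$method),
                           higher_better = TRUE)
  gm <- consistency_groups(setNames(score$mscc, score$method),
                           higher_better = FALSE)
  ev$consistency <- data.frame(
    method = score$method,
    aucvc_group = ga[score$method],
    mscc_group = gm[score$method],
    consistent = ifelse(ga[score$method] == gm[score$method],
                        "consistent", "inconsistent"))
  mean_auc <- mean_auc[order(-mean_auc, names(mean_auc))]
  ev$mean_aucvc <- mean_auc
  ev$best_method <- names(mean_auc)[1]
  ev
}

# deterministic competition ranks with lexicographic tie-break on name
rank_with_ties <- function(values, names) {
  ord <- order(values, names)
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  r
}

# split scores into (up to) three performance tiers by 1-D average-linkage
# clustering; tier 1 = best. |mSCC| ordering is NOT used: signed values,
# ascending, as in the ranking convention.
consistency_groups <- function(scores, higher_better = TRUE) {
  k <- min(3L, length(unique(scores)))
  if (length(scores) < 2 || k < 2)
    return(setNames(rep(1L, length(scores)), names(scores)))
  hc <- hclust(stats::dist(scores), method = "average")
  grp <- cutree(hc, k = k)
  # order groups best -> poorest by mean score
  mg <- tapply(scores, grp, mean)
  ord <- order(if (higher_better) -mg else mg)
  relabel <- setNames(seq_along(ord), names(mg)[ord])
  out <- relabel[as.character(grp)]
  setNames(as.integer(out), names(scores))
}

#' Rank methods under one metric
#'
#' AUCVC ranks descending (higher is better); mSCC, RLE_MED and RLE_IQR
#' ascending. Ties break lexicographically by method name. For AUCVC the
#' ranking uses the mean over the cutoff grid; per-cutoff ranks are in the
#' `per_cutoff` attribute.
#'
#' @param eval an `evaluation_table`.
#' @param metric one of `"aucvc"`, `"mscc"`, `"rle_med"`, `"rle_iqr"`.
#' @return character vector of methods, best first.
#' @export
rank_methods <- function(eval, metric = c("aucvc", "mscc", "rle_med",
                                          "rle_iqr")) {
  metric <- match.arg(metric)
  if (metric == "aucvc") {
    sc <- tapply(eval$aucvc$aucvc, eval$aucvc$method, mean)
    vals <- -as.numeric(sc)
    nms <- names(sc)
  } else {
    if (is.null(eval$metrics))
      stopf("metric '%s' requires a mode-3 evaluation", metric)
    vals <- eval$metrics[[metric]]
    nms <- eval$metrics$method
  }
  out <- nms[order(vals, nms)]
  if (metric == "aucvc") {
    per <- lapply(split(eval$aucvc, eval$aucvc$nzr_cutoff), function(d)
      d$method[order(-d$aucvc, d$method)])
    attr(out, "per_cutoff") <- per
  }
  out
}

#' @export
print.evaluation_table <- function(x, ...) {
  cat(sprintf("evaluation_table: %d methods, best by mean AUCVC: %s\n",
              length(x$methods), x$best_method))
  print(round(x$mean_aucvc, 4))
  if (length(x$unavailable))
    cat("unavailable:", paste(names(x$unavailable), collapse = ", "), "\n")
  invisible(x)
}
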