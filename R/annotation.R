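#' @rdname gene_annotation
#' @format NULL
#' @export
HG7_GENES <- c("UBC", "HMBS", "TBP", "GAPDH", "HPRT1", "RPL13A", "ACTB")

GENE_CLASSES <- c("nuclear", "mitochondrial", "spike_in")

#' Gene annotation: classes and control sets
#'
#' Classifies each gene as `nuclear`, `mitochondrial` or `spike_in` and
#' carries named control sets used by control-set normalization. The
#' built-in `HG7` set (seven housekeeping genes: UBC, HMBS, TBP, GAPDH,
#' HPRT1, RPL13A, ACTB) and the single-gene `GAPDH` set are auto-populated
#' when absent; an `ERCC` set defaults to all `spike_in` genes.
#'
#' @param gene_class named character vector mapping gene id to one of
#'   `nuclear`, `mitochondrial`, `spike_in`.
#' @param control_sets named list of character vectors of gene ids.
#' @return An object of class `gene_annotation` with elements `gene_class`
#'   and `control_sets`.
#' @export
gene_annotation <- function(gene_class, control_sets = list()) {
  gene_class <- unlist(gene_class)
  if (is.null(names(gene_class)) || any(names(gene_class) == ""))
    stopf("gene_class must be a named vector (gene id -> class)")
  bad <- setdiff(unique(gene_class), GENE_CLASSES)
  if (length(bad))
    stopf("unknown gene class '%s' (allowed: %s)", bad[1],
          paste(GENE_CLASSES, collapse = ", "))
  dup <- names(gene_class)[duplicated(names(gene_class))]
  if (length(dup))
    stopf("duplicated gene id in annotation: %s", dup[1])
  if (!"HG7" %in% names(control_sets))
    control_sets$HG7 <- HG7_GENES
  if (!"GAPDH" %in% names(control_sets))
    control_sets$GAPDH <- "GAPDH"
  if (!"ERCC" %in% names(control_sets)) {
    spikes <- names(gene_class)[gene_class == "spike_in"]
    if (length(spikes)) control_sets$ERCC <- spikes
  }
  structure(list(gene_class = gene_class, control_sets = control_sets),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  tab <- table(factor(x$gene_class, levels = GENE_CLASSES))
  cat("gene_annotation:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = " "), "\n")
  cat("  control sets:", paste(sprintf("%s(%d)", names(x$control_sets),
                                       lengths(x$control_sets)),
                               collapse = " "), "\n")
  invisible(x)
}

# class vector aligned to a matrix's genes; unannotated genes default to
# nuclear (the overwhelmingly common case)
classes_for <- function(cm, annotation = NULL) {
  ids <- cm$gene_ids
  cls <- rep("nuclear", length(ids))
  names(cls) <- ids
  if (!is.null(annotation)) {
    hit <- intersect(ids, names(annotation$gene_class))
    cls[hit] <- annotation$gene_class[hit]
  }
  cls
}

# resolve a control set against a matrix; error listing unresolved ids when
# nothing matches
resolve_control_set <- function(cm, set, annotation = NULL) {
  if (is.character(set) && length(set) == 1 && !is.null(annotation) &&
      set %in% names(annotation$control_sets)) {
    ids <- annotation$control_sets[[set]]
  } else if (is.character(set) && length(set) == 1 &&
             set %in% names(default_control_sets())) {
    ids <- default_control_sets()[[set]]
  } else if (is.character(set)) {
    ids <- set
  } else {
    stopf("control set must be a set name or a character vector of gene ids")
  }
  present <- intersect(ids, cm$gene_ids)
  if (!length(present))
    stopf("control set resolves to no gene in the matrix (unresolved: %s)",
          paste(head(setdiff(ids, cm$gene_ids), 10), collapse = ", "))
  present
}

default_control_sets <- function() list(HG7 = HG7_GENES, GAPDH = "GAPDH")
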