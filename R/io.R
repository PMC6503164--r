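#' Read a count matrix from delimited text or MatrixMarket
#'
#' TSV/CSV files carry the gene id in the first column and sample ids in the
#' header. MatrixMarket (`.mtx`) files are accompanied by `<stem>.rownames`
#' and `<stem>.colnames` sidecars, one identifier per line. Delimiter is
#' inferred from the extension unless `format` is given.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`.
#' @param transpose transpose after reading (for samples-as-rows input).
#' @return a [count_matrix].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    rn_path <- paste0(stem, ".rownames")
    cn_path <- paste0(stem, ".colnames")
    if (!file.exists(rn_path) || !file.exists(cn_path))
      stopf("mtx sidecars missing: need %s and %s", rn_path, cn_path)
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rn_path)
    cn <- readLines(cn_path)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stopf("mtx dimensions (%d x %d) do not match sidecar name counts (%d, %d)",
            nrow(m), ncol(m), length(rn), length(cn))
    vals <- m
    dimnames(vals) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    if (ncol(dt) < 2) stopf("expected gene id column plus >=1 sample column")
    ids <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(vals)) stopf("non-numeric entries in %s", path)
    dimnames(vals) <- list(ids, colnames(dt)[-1])
  }
  if (transpose) vals <- t(vals)
  count_matrix(vals)
}

#' Write a count matrix
#'
#' @param cm a [count_matrix].
#' @param path destination; `.csv` selects comma, `.mtx` MatrixMarket with
#'   name sidecars, anything else tab.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  cm <- as_count_matrix(cm)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(cm$values, sparse = TRUE), path)
    writeLines(cm$gene_ids, paste0(stem, ".rownames"))
    writeLines(cm$sample_ids, paste0(stem, ".colnames"))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- data.frame(gene_id = cm$gene_ids, cm$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = sep)
  }
  invisible(path)
}

#' Read a gene annotation file
#'
#' Format: tab-separated `gene_id<TAB>class` lines with class one of
#' `nuclear`, `mitochondrial`, `spike_in`; optional control-set blocks
#' introduced by a `#set:<name>` line followed by one gene id per line.
#' Built-in HG7/GAPDH sets are filled in when the file omits them.
#'
#' @param path file path.
#' @return a [gene_annotation].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty annotation file: %s", path)
  classes <- character(0)
  sets <- list()
  current <- NULL
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (startsWith(ln, "#set:")) {
      current <- trimws(sub("^#set:", "", ln))
      sets[[current]] <- character(0)
      next
    }
    if (startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) >= 2) {
      cls <- trimws(fields[2])
      if (!cls %in% GENE_CLASSES)
        stopf("line %d: unknown gene class '%s'", k, cls)
      classes[trimws(fields[1])] <- cls
      current <- NULL
    } else if (!is.null(current)) {
      sets[[current]] <- c(sets[[current]], trimws(fields[1]))
    } else {
      stopf("line %d: expected 'gene_id<TAB>class' or a #set: block", k)
    }
  }
  if (!length(classes)) stopf("no gene class rows in %s", path)
  gene_annotation(classes, sets)
}

#' Write a gene annotation file
#' @param annotation a [gene_annotation].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  cls <- annotation$gene_class
  lines <- paste(names(cls), cls, sep = "\t")
  for (nm in names(annotation$control_sets)) {
    lines <- c(lines, paste0("#set:", nm), annotation$control_sets[[nm]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a table of factor vectors
#'
#' Samples as rows, methods as columns, full double precision; `#` header
#' comments record whether each column is standardized.
#'
#' @param factors list of [factor_vector] objects on the same samples.
#' @param path destination (TSV).
#' @return `path`, invisibly.
#' @export
write_factors <- function(factors, path) {
  if (!length(factors)) stopf("empty factor list")
  if (inherits(factors, "factor_vector")) factors <- list(factors)
  methods <- vapply(factors, function(f) f$method, character(1))
  ids <- names(factors[[1]]$factors)
  for (f in factors) {
    if (!identical(names(f$factors), ids))
      stopf("factor vectors are not aligned on the same samples")
  }
  std <- vapply(factors, function(f) f$standardized, logical(1))
  header <- c(
    sprintf("# countnorm factor table: %d methods x %d samples",
            length(factors), length(ids)),
    sprintf("# standardized: %s",
            paste(sprintf("%s=%s", methods, std), collapse = " ")))
  mat <- vapply(factors, function(f) f$factors, numeric(length(ids)))
  df <- data.frame(sample_id = ids, mat, check.names = FALSE)
  colnames(df) <- c("sample_id", methods)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a factor table written by [write_factors]
#' @param path TSV path.
#' @return list of [factor_vector] objects (standardization flag recovered
#'   from the header comment; defaults to `FALSE`).
#' @export
read_factors <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  std_line <- grep("^# standardized:", lines, value = TRUE)
  std <- logical(0)
  if (length(std_line)) {
    toks <- strsplit(sub("^# standardized:\\s*", "", std_line[1]), " ")[[1]]
    kv <- strsplit(toks, "=", fixed = TRUE)
    std <- setNames(vapply(kv, function(p) as.logical(p[2]), logical(1)),
                    vapply(kv, `[`, character(1), 1))
  }
  body <- lines[!startsWith(lines, "#")]
  df <- read.table(text = body, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  lapply(colnames(df)[-1], function(m) {
    factor_vector(m, setNames(as.numeric(df[[m]]), ids),
                  standardized = isTRUE(unname(std[m])))
  })
}

#' Export a gene set as text
#' @param gs a `gene_set` (see [ubiquitous_genes]).
#' @param path destination; ids one per line under a `#provenance` header.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  prov <- gs$provenance %||% list()
  header <- sprintf("#provenance %s",
                    paste(sprintf("%s=%s", names(prov),
                                  vapply(prov, format, character(1))),
                          collapse = " "))
  writeLines(c(header, sort(gs$gene_ids)), path)
  invisible(path)
}

#' Export a CV threshold curve as two-column TSV
#' @param curve a `cv_curve` (see [cv_threshold_curve]).
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(cutoff = curve$cutoffs, count = curve$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_eligible=%d aucvc=%.12g",
                     curve$n_eligible, aucvc(curve)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report
#'
#' Emits the AUCVC table (method x non-zero-ratio cutoff) and, when present,
#' the mSCC / RLE_MED / RLE_IQR table and the per-metric rankings, as
#' sectioned TSV (`#table:<name>` headers).
#'
#' @param eval an `evaluation_table` from [run_mode2] or [run_mode3].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_report <- function(eval, path) {
  if (!length(eval$methods)) stopf("report with no methods")
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(name, df) {
    writeLines(sprintf("#table:%s", name), con)
    write.table(format(df, digits = 15, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  emit("aucvc", eval$aucvc)
  if (!is.null(eval$metrics)) emit("metrics", eval$metrics)
  if (!is.null(eval$ranks)) emit("ranks", eval$ranks)
  if (!is.null(eval$consistency)) emit("consistency", eval$consistency)
  if (length(eval$unavailable)) {
    writeLines("#table:unavailable", con)
    writeLines(paste(names(eval$unavailable), unlist(eval$unavailable),
                     sep = "\t"), con)
  }
  invisible(path)
}
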