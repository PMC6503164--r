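#' Simulation configuration
#'
#' Negative-binomial count generator with multiplicative per-sample depth
#' factors, a minority of differentially expressed genes, mean-dependent
#' dropout, and dedicated spike-in / housekeeping / mitochondrial rows, so
#' that every normalization method and metric can be exercised against a
#' known ground truth.
#'
#' @param n_genes,n_samples matrix dimensions (special rows included in
#'   `n_genes`).
#' @param depth_range range of the log-uniform true depth factors `d_j`.
#' @param de_fraction fraction of ordinary genes with a two-group
#'   fold-change effect.
#' @param dropout zero-inflation ceiling; entry-wise dropout probability is
#'   `dropout * exp(-mu/5)`, vanishing for well-expressed genes. 0 disables.
#' @param n_spikein,n_hk,n_mito counts of spike-in, housekeeping and
#'   mitochondrial rows. The first seven housekeeping rows take the HG7
#'   gene names so control-set methods resolve.
#' @param dispersion negative-binomial dispersion (1/size) of expressed
#'   ordinary genes; housekeeping rows use a quarter of it.
#' @param mean_log_mean,mean_log_sd log-normal parameters of expressed
#'   baseline gene means.
#' @param off_fraction fraction of ordinary genes that are essentially
#'   unexpressed ("off": mean `off_mean`), the main source of zeros --
#'   expression in a given cell population is bimodal, with roughly half of
#'   the annotated genes undetected.
#' @param off_mean mean count of off genes.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 20L,
                       depth_range = c(0.25, 4),
                       de_fraction = 0.1, dropout = 0.3,
                       n_spikein = 20L, n_hk = 7L, n_mito = 10L,
                       dispersion = 0.25,
                       mean_log_mean = log(100), mean_log_sd = 1.0,
                       off_fraction = 0.57, off_mean = 0.001,
                       seed = 1L) {
  if (n_spikein + n_hk + n_mito >= n_genes)
    stopf("special rows must be fewer than n_genes")
  if (de_fraction < 0 || de_fraction > 1 || dropout < 0 || dropout > 1)
    stopf("fractions must be in [0, 1]")
  if (de_fraction >= 1)
    stopf("a simulation with every gene differentially expressed is degenerate")
  if (off_fraction < 0 || off_fraction >= 1)
    stopf("off_fraction must be in [0, 1)")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 depth_range = depth_range, de_fraction = de_fraction,
                 dropout = dropout, n_spikein = as.integer(n_spikein),
                 n_hk = as.integer(n_hk), n_mito = as.integer(n_mito),
                 dispersion = dispersion,
                 mean_log_mean = mean_log_mean, mean_log_sd = mean_log_sd,
                 off_fraction = off_fraction, off_mean = off_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset simulation configurations
#'
#' `"scrna"` emulates a moderately sparse Smart-seq2-like single-cell
#' matrix: bimodal expression with 57% of ordinary genes off, dropout 0.3,
#' dispersion 0.25; overall zero fraction lands in the 40-80% band.
#' `"bulk"` emulates a deep bulk library: almost all genes detected, no
#' dropout, dispersion 0.08; zero fraction below 10%.
#'
#' @param preset `"scrna"` or `"bulk"`.
#' @param ... overrides passed to [sim_config].
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("scrna", "bulk"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    scrna = list(),  # sim_config defaults ARE the scrna preset
    bulk  = list(n_samples = 18L, dropout = 0, dispersion = 0.08,
                 mean_log_mean = log(150), mean_log_sd = 1.3,
                 off_fraction = 0.05, off_mean = 0.01))
  do.call(sim_config, modifyList(base, list(...)))
}

#' Simulate a count matrix with known ground truth
#'
#' Ordinary (nuclear and mitochondrial) genes: counts are
#' NB(mean = mu_i * e_ij * d_j) with log-uniform depths d_j and two-group
#' fold changes e_ij for the DE minority; an `off_fraction` of genes has
#' mean `off_mean` (essentially never observed), and entries are zeroed
#' with probability `dropout * exp(-mean/5)`. Spike-in rows follow a fixed
#' geometric concentration ladder scaled by an independent per-sample
#' spike depth (mimicking fixed-volume ERCC addition, so spike-in and
#' cellular library sizes can disagree). Housekeeping rows are non-DE with
#' low dispersion. Total reads are column sums plus a simulated unassigned
#' remainder.
#'
#' @param config a [sim_config].
#' @return list with `counts` ([count_matrix]), `annotation`
#'   ([gene_annotation]), `total_reads` (named numeric) and `truth` (list:
#'   `true_depths`, `true_factors` standardized 1/d, `de_gene_ids`,
#'   `spike_depths`).
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; n <- config$n_samples
  n_ord <- ng - config$n_spikein - config$n_hk - config$n_mito

  gene_ids <- c(
    if (config$n_spikein) sprintf("ERCC-%05d", seq_len(config$n_spikein)),
    if (config$n_hk) c(HG7_GENES, sprintf("HK%02d", seq_len(max(0, config$n_hk - 7))))[seq_len(config$n_hk)],
    if (config$n_mito) sprintf("MT-%04d", seq_len(config$n_mito)),
    sprintf("G%05d", seq_len(n_ord)))
  classes <- c(rep("spike_in", config$n_spikein),
               rep("nuclear", config$n_hk),
               rep("mitochondrial", config$n_mito),
               rep("nuclear", n_ord))
  sample_ids <- sprintf("S%03d", seq_len(n))

  d <- exp(runif(n, log(config$depth_range[1]), log(config$depth_range[2])))
  names(d) <- sample_ids
  group <- rep(c(1L, 2L), length.out = n)

  # ordinary genes (mitochondrial rows behave like ordinary genes)
  n_main <- config$n_mito + n_ord
  mu <- rlnorm(n_main, config$mean_log_mean, config$mean_log_sd)
  n_off <- round(config$off_fraction * n_main)
  if (n_off) {
    off_idx <- sample.int(n_main, n_off)
    mu[off_idx] <- rlnorm(n_off, log(config$off_mean), 0.5)
  }
  n_de <- round(config$de_fraction * n_main)
  de_idx <- if (n_de) sample.int(n_main, n_de) else integer(0)
  lfc <- numeric(n_main)
  lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * runif(n_de, 1, 2)
  eff <- outer(lfc, as.numeric(group == 2L)) # log2 effect, group 2 only
  mu_mat <- mu * 2^eff
  mean_mat <- sweep(mu_mat, 2, d, `*`)
  size <- 1 / config$dispersion
  main <- matrix(rnbinom(n_main * n, mu = mean_mat, size = size), n_main, n)
  if (config$dropout > 0) {
    pdrop <- config$dropout * exp(-mean_mat / 5)
    main[matrix(runif(n_main * n), n_main, n) < pdrop] <- 0L
  }

  # housekeeping rows: non-DE, tight dispersion, solidly expressed
  hk <- NULL
  if (config$n_hk) {
    mu_hk <- rlnorm(config$n_hk, log(60), 0.5)
    mean_hk <- outer(mu_hk, d)
    hk <- matrix(rnbinom(config$n_hk * n, mu = mean_hk,
                         size = 4 / config$dispersion),
                 config$n_hk, n)
  }

  # spike-ins: geometric concentration ladder, independent spike depth
  sp <- NULL
  spike_depths <- NULL
  if (config$n_spikein) {
    conc <- 4 * 2^(seq_len(config$n_spikein) / 2)
    spike_depths <- rlnorm(n, 0, 0.15)
    names(spike_depths) <- sample_ids
    mean_sp <- outer(conc, spike_depths)
    sp <- matrix(rnbinom(config$n_spikein * n, mu = mean_sp, size = 20),
                 config$n_spikein, n)
  }

  vals <- rbind(sp, hk, main)
  dimnames(vals) <- list(gene_ids, sample_ids)
  cm <- count_matrix(vals)

  annotation <- gene_annotation(setNames(classes, gene_ids))
  # unassigned reads: roughly 10% of the assigned mass
  unassigned <- rpois(n, 0.1 * colSums(vals))
  total_reads <- colSums(vals) + unassigned

  tf <- (1 / d) / geomean(1 / d)
  de_ids <- gene_ids[config$n_spikein + config$n_hk + de_idx]
  # exact first/second moments of the pre-dropout counts, for
  # law-of-large-numbers checks
  mean_all <- rbind(if (config$n_spikein) mean_sp,
                    if (config$n_hk) mean_hk,
                    mean_mat)
  sizes <- c(rep(20, config$n_spikein),
             rep(4 / config$dispersion, config$n_hk),
             rep(size, n_main))
  var_all <- mean_all + mean_all^2 / sizes
  list(counts = cm, annotation = annotation, total_reads = total_reads,
       truth = list(true_depths = d, true_factors = tf,
                    de_gene_ids = de_ids, spike_depths = spike_depths,
                    expected_colsums = colSums(mean_all),
                    colsum_sds = sqrt(colSums(var_all))))
}

#' Write a simulated dataset to disk
#'
#' Emits `counts.tsv`, `annotation.tsv`, `total_reads.tsv` and
#' `truth.tsv` (per-sample true depths and standardized true factors) in
#' the package's text formats.
#'
#' @param sim output of [simulate_counts].
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  write_annotation(sim$annotation, file.path(out_dir, "annotation.tsv"))
  write.table(data.frame(sample_id = names(sim$total_reads),
                         total_reads = sim$total_reads),
              file.path(out_dir, "total_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(sim$truth$true_depths),
                         true_depth = sim$truth$true_depths,
                         true_factor = sim$truth$true_factors),
              file.path(out_dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read a per-sample total-reads file
#' @param path two-column TSV `sample_id<TAB>total_reads` with header.
#' @return named numeric vector.
#' @export
read_total_reads <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
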