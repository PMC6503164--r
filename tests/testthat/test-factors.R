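test_that("library sizes follow the class definitions and TC = CR + spike", {
  x <- rbind(n1 = c(400, 10), n2 = c(500, 20), mt = c(50, 5),
             sp = c(100, 65))
  colnames(x) <- c("s1", "s2")
  cm <- count_matrix(x)
  ann <- gene_annotation(c(n1 = "nuclear", n2 = "nuclear",
                           mt = "mitochondrial", sp = "spike_in"))
  expect_equal(unname(library_size(cm, "NR", ann)), c(900, 30))
  expect_equal(unname(library_size(cm, "CR", ann)), c(950, 35))
  expect_equal(unname(library_size(cm, "TC", ann)), c(1050, 100))
  spike_sum <- colSums(x["sp", , drop = FALSE])
  expect_identical(library_size(cm, "TC", ann) - library_size(cm, "CR", ann),
                   spike_sum)
  expect_equal(unname(library_size(cm, "TN", ann,
                                   total_reads = c(s1 = 2e6, s2 = 1e5))),
               c(2e6, 1e5))
  expect_error(library_size(cm, "TN", ann), "total_reads")
  # no mitochondrial genes -> CR equals NR
  ann2 <- gene_annotation(c(n1 = "nuclear", n2 = "nuclear", sp = "spike_in"))
  cm2 <- count_matrix(x[c("n1", "n2", "sp"), ])
  expect_equal(library_size(cm2, "CR", ann2), library_size(cm2, "NR", ann2))
})

test_that("size-based factors are 1e6/N and scale-equivariant", {
  cm <- tiny_cm()
  fv <- size_based_factors(cm, "NR")
  expect_equal(unname(fv$factors), unname(1e6 / colSums(cm$values)))
  scaled <- cm$values
  scaled[, "s2"] <- scaled[, "s2"] * 2
  f2 <- size_based_factors(count_matrix(scaled), "NR")
  expect_equal(f2$factors[["s2"]], fv$factors[["s2"]] / 2)
  expect_equal(f2$factors[["s1"]], fv$factors[["s1"]])
  # N = 2e6 -> f = 0.5
  big <- count_matrix(matrix(c(2e6, 1), 1, 2,
                             dimnames = list("g", c("a", "b"))))
  expect_equal(size_based_factors(big, "NR")$factors[["a"]], 0.5)
})

test_that("control-set factors use the pseudo library size", {
  x <- rbind(UBC = c(200, 1), ACTB = c(300, 2), other = c(1000, 1000))
  colnames(x) <- c("s1", "s2")
  cm <- count_matrix(x)
  fv <- control_set_factors(cm, "HG7")
  expect_equal(unname(fv$factors), c(1e6 / 500, 1e6 / 3))
  # a zero-count control gene in one sample kills a single-gene set
  x2 <- rbind(GAPDH = c(5, 0), other = c(1, 1))
  colnames(x2) <- c("s1", "s2")
  expect_error(control_set_factors(count_matrix(x2), "GAPDH"),
               "sample 's2'")
  expect_error(control_set_factors(cm, "ERCC"), "no gene")
  # control genes covering every row reproduce the total-count sum
  fv_all <- control_set_factors(cm, rownames(x))
  expect_equal(unname(fv_all$factors), unname(1e6 / colSums(x)))
})

test_that("DESeq median-of-ratios matches direct enumeration", {
  # column2 = 2 x column1, all positive: ratios are c/geomean constants
  x <- cbind(s1 = c(4, 9, 25), s2 = c(8, 18, 50))
  rownames(x) <- paste0("g", 1:3)
  cm <- count_matrix(x)
  fv <- deseq_factors(cm)
  # oracle: ref_i = sqrt(x1*x2); N*_j = median(x_ij/ref_i)
  ref <- sqrt(x[, 1] * x[, 2])
  Ns <- c(median(x[, 1] / ref), median(x[, 2] / ref))
  expect_equal(unname(fv$factors), 1 / Ns)
  expect_equal(fv$factors[["s1"]] / fv$factors[["s2"]], 2)
  # identical columns -> equal factors
  xi <- cbind(s1 = c(3, 7), s2 = c(3, 7)); rownames(xi) <- c("a", "b")
  expect_equal(diff(unname(deseq_factors(count_matrix(xi))$factors)), 0)
})

test_that("standardized RLE is identical to standardized DESeq", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rand_counts(sample(20:80, 1), sample(3:8, 1),
                     zero_frac = runif(1, 0, 0.4))
    x <- x[rowSums(x) > 0, , drop = FALSE]
    cm <- count_matrix(x)
    d <- standardize_geomean(deseq_factors(cm))$factors
    r <- standardize_geomean(rle_factors(cm))$factors
    expect_lt(max(abs(d - r)), 1e-10)
  }
  # column2 = 3 x column1 -> standardized factors (sqrt(3), 1/sqrt(3))
  x <- cbind(s1 = c(2, 5, 11), s2 = 3 * c(2, 5, 11))
  rownames(x) <- paste0("g", 1:3)
  std <- standardize_geomean(rle_factors(count_matrix(x)))$factors
  expect_equal(unname(std), c(sqrt(3), 1 / sqrt(3)))
})

test_that("UQ factor is 1e6 over the Q75 of raw non-zero counts", {
  set.seed(8)
  x <- rand_counts(50, 4, zero_frac = 0.3)
  x <- x[rowSums(x > 0) > 0, ]
  cm <- count_matrix(x)
  fv <- uq_factors(cm)
  manual <- sapply(seq_len(ncol(x)), function(j)
    1e6 / quantile(x[, j][x[, j] > 0], 0.75, names = FALSE, type = 7))
  expect_equal(unname(fv$factors), manual)
  # known Q75: non-zero counts 2,4,6,8 -> Q75 = 6.5
  xq <- cbind(s1 = c(2, 4, 6, 8), s2 = c(2, 4, 6, 8))
  rownames(xq) <- paste0("g", 1:4)
  expect_equal(unname(uq_factors(count_matrix(xq))$factors),
               rep(1e6 / 6.5, 2))
  # equivariance: scaling a column divides its factor
  x2 <- x; x2[, 2] <- x2[, 2] * 5
  fv2 <- uq_factors(count_matrix(x2))
  expect_equal(fv2$factors[[2]], fv$factors[[2]] / 5)
})

test_that("TMM matches the brute-force sort-trim-weight oracle", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rand_counts(50, 4)
    cm <- count_matrix(x)
    fv <- tmm_factors(cm)
    orc <- oracle_tmm(x)
    expect_lt(max(abs(unname(fv$factors) - 1e6 / (orc$N * orc$s))), 1e-10)
  }
})

test_that("TMM closed forms: proportional and identical columns", {
  x1 <- rand_counts(40, 1, seed = 77)
  x <- cbind(s1 = x1[, 1], s2 = 2 * x1[, 1])
  cm <- count_matrix(x)
  # N2 = 2 N1 so all M are exactly 0 -> s = 1, f = 1e6/N
  fv <- tmm_factors(cm)
  expect_equal(unname(fv$factors), unname(1e6 / colSums(x)))
  xi <- cbind(s1 = x1[, 1], s2 = x1[, 1], s3 = x1[, 1])
  fvi <- tmm_factors(count_matrix(xi))
  expect_equal(unname(fvi$factors * colSums(xi)), rep(1e6, 3))
})

test_that("TU factors sum the ubiquitous genes", {
  x <- rbind(a = c(100, 200), b = c(150, 300), c = c(1, 1e6))
  colnames(x) <- c("s1", "s2")
  cm <- count_matrix(x)
  gs <- structure(list(gene_ids = c("a", "b"), provenance = list()),
                  class = "gene_set")
  fv <- tu_factors(cm, gs)
  expect_equal(unname(fv$factors), c(1e6 / 250, 1e6 / 500))
  one <- matrix(c(250000, 2.5e5), 1, 2,
                dimnames = list("g", c("s1", "s2")))
  expect_equal(tu_factors(count_matrix(one),
    structure(list(gene_ids = "g"), class = "gene_set"))$factors[["s1"]], 4)
  # params admitting every gene reduce TU to total-count normalization
  pos <- rand_counts(20, 3, seed = 2)
  cmp <- count_matrix(pos)
  fv_all <- tu_factors(cmp, trim_params(1, 0, 1))
  expect_equal(unname(fv_all$factors), unname(1e6 / colSums(pos)))
  # a sample with zero ubiquitous-gene sum errors
  gs_c <- structure(list(gene_ids = "c"), class = "gene_set")
  x0 <- x; x0["c", 1] <- 0
  expect_error(tu_factors(count_matrix(x0), gs_c), "sample 's1'")
})

test_that("geometric-mean standardization contract holds for all methods", {
  expect_equal(unname(standardize_geomean(
    factor_vector("t", c(a = 1, b = 4)))$factors), c(0.5, 2))
  set.seed(55)
  for (rep in 1:15) {
    x <- rand_counts(40, 5, zero_frac = runif(1, 0, 0.5))
    x <- x[rowSums(x > 0) >= 2, ]
    cm <- count_matrix(x)
    fvs <- list(size_based_factors(cm, "NR"), deseq_factors(cm),
                uq_factors(cm), tmm_factors(cm),
                tu_factors(cm, trim_params(0.5, 0.1, 0.9)))
    for (fv in fvs) {
      std <- standardize_geomean(fv)
      expect_lt(abs(geomean(std$factors) - 1), 1e-9)
      # idempotence
      expect_equal(standardize_geomean(std)$factors, std$factors)
    }
  }
})

test_that("factor methods are invariant to gene-row permutation", {
  set.seed(66)
  x <- rand_counts(60, 5, zero_frac = 0.3)
  x <- x[rowSums(x > 0) >= 2, ]
  perm <- sample(nrow(x))
  cm1 <- count_matrix(x); cm2 <- count_matrix(x[perm, ])
  for (fn in list(function(m) size_based_factors(m, "NR"), deseq_factors,
                  uq_factors, tmm_factors,
                  function(m) tu_factors(m, trim_params(0.5, 0.1, 0.9)))) {
    expect_equal(fn(cm1)$factors, fn(cm2)$factors)
  }
})

test_that("apply_factors multiplies columns and preserves zeros", {
  x <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  fv <- factor_vector("f", c(s1 = 2, s2 = 0.5))
  out <- apply_factors(count_matrix(x), fv)
  expect_equal(unname(out$values), matrix(c(2, 6, 1, 2), 2, 2))
  xz <- x; xz[1, 1] <- 0
  outz <- apply_factors(count_matrix(xz), fv)
  expect_identical(outz$values[1, 1], 0)
  expect_error(apply_factors(count_matrix(x),
                             factor_vector("f", c(q1 = 1, q2 = 1))),
               "cover")
  # unit factors are the identity
  unit <- factor_vector("u", c(s1 = 1, s2 = 1))
  expect_equal(apply_factors(count_matrix(x), unit)$values, x)
})
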