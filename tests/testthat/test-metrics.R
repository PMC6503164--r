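test_that("cv_raw evaluates the all-samples CV", {
  expect_equal(cv_raw(c(4, 4, 4)), 0)
  expect_equal(cv_raw(c(1, 3)), sqrt(2) / 2)
  expect_equal(cv_raw(c(0, 0, 6)), sqrt(3))
  expect_true(is.na(cv_raw(c(0, 0, 0))))
  expect_error(cv_raw(5), "two samples")
})

test_that("cv_log2 ignores zeros and handles degenerate genes", {
  expect_equal(cv_log2(c(4, 4, 4))$cv, 0)
  r <- cv_log2(c(2, 4))
  expect_equal(r$cv, sqrt(0.5) / 1.5)
  expect_identical(r$n_star, 2L)
  expect_equal(cv_log2(c(0, 4, 4))$cv, 0)  # zeros dropped, n* = 2
  expect_true(is.na(cv_log2(c(0, 0, 4))$cv))  # n* < 2
  expect_true(is.na(cv_log2(c(0.5, 0.25))$cv))  # log2 mean <= 0
})

test_that("vectorized row CVs agree with the scalar oracle", {
  set.seed(12)
  x <- rand_counts(80, 7, zero_frac = 0.3)
  fast <- countnorm:::cv_log2_rows(x)
  slow <- apply(x, 1, oracle_cv_log2)
  expect_equal(unname(fast), unname(slow), tolerance = 1e-12)
})

test_that("normalize_cvs min-max scales with the degenerate rule", {
  expect_equal(unname(normalize_cvs(c(0.2, 0.4, 0.6))), c(0, 0.5, 1))
  v <- c(0, 0.3, 1)
  expect_equal(unname(normalize_cvs(v)), v)
  expect_equal(unname(suppressMessages(normalize_cvs(c(2, 2, 2)))),
               c(0, 0, 0))
  expect_error(normalize_cvs(c(1, NA)), "two finite")
})

test_that("cv_threshold_curve counts uniform genes per cutoff", {
  # three genes whose normalized CVs are exactly 0, 0.5, 1
  x <- rbind(flat = c(8, 8, 8, 8),          # cv 0
             mid = c(4, 8, 16, 8),          # some middling cv
             wild = c(2, 64, 1024, 4))      # the largest cv
  colnames(x) <- paste0("s", 1:4)
  cvs <- countnorm:::cv_log2_rows(x)
  ncv <- normalize_cvs(cvs)
  curve <- cv_threshold_curve(count_matrix(x), nzr_cutoff = 0.5,
                              grid_size = 4)
  manual <- sapply(c(0.25, 0.5, 0.75, 1), function(t) sum(ncv <= t + 1e-12))
  expect_equal(curve$counts, as.integer(manual))
  expect_true(all(diff(curve$counts) >= 0))
  expect_identical(curve$counts[4], curve$n_eligible)
  expect_error(cv_threshold_curve(count_matrix(x[1, , drop = FALSE]), 0.5),
               "fewer than two")
})

test_that("aucvc equals the direct grid mean and the worked micro-example", {
  micro <- structure(list(cutoffs = c(0.25, 0.5, 0.75, 1),
                          counts = c(1L, 2L, 2L, 3L),
                          n_eligible = 3L, grid_size = 4L),
                     class = "cv_curve")
  expect_equal(aucvc(micro), 8 / 12)
  full <- structure(list(cutoffs = 1, counts = 5L, n_eligible = 5L,
                         grid_size = 1L), class = "cv_curve")
  expect_equal(aucvc(full), 1)
})

test_that("aucvc matches the gene x cutoff double-loop oracle", {
  set.seed(91)
  for (rep in 1:8) {
    x <- rand_counts(50, 6, zero_frac = runif(1, 0.1, 0.5))
    got <- countnorm:::aucvc_of(count_matrix(x), nzr_cutoff = 0.3,
                                grid_size = 40)
    expect_equal(got, oracle_aucvc(x, 0.3, 40), tolerance = 1e-12)
  }
})

test_that("mscc endpoints are exact and sampling is seed-reproducible", {
  # identical rank order -> median SCC exactly 1
  x <- rbind(a = c(1, 5, 9, 20), b = c(2, 30, 40, 90))
  colnames(x) <- paste0("s", 1:4)
  expect_identical(mscc(count_matrix(x), c("a", "b")), 1)
  # reversed ranks -> exactly -1
  xr <- rbind(a = c(1, 5, 9, 20), b = c(90, 40, 30, 2))
  colnames(xr) <- paste0("s", 1:4)
  expect_identical(mscc(count_matrix(xr), c("a", "b")), -1)
  # fixed seed is bit-reproducible; different seed samples other pairs
  set.seed(3)
  y <- count_matrix(rand_counts(40, 10))
  ids <- rownames(y$values)
  m1 <- mscc(y, ids, n_pairs = 100, seed = 42)
  m2 <- mscc(y, ids, n_pairs = 100, seed = 42)
  expect_identical(m1, m2)
  # constant-gene pairs are dropped
  xc <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(4, 3, 2, 1))
  colnames(xc) <- paste0("s", 1:4)
  expect_message(res <- mscc(count_matrix(xc), c("a", "b", "c")),
                 "dropped 2 pairs")
  expect_identical(res, -1)
})

test_that("mscc is invariant under strictly monotone per-gene transforms", {
  set.seed(17)
  x <- rand_counts(30, 8)
  cmx <- count_matrix(x)
  ids <- rownames(x)
  base <- mscc(cmx, ids, n_pairs = 200, seed = 5)
  xt <- t(apply(x, 1, function(v) exp(v / max(v)) * 3))
  dimnames(xt) <- dimnames(x)
  expect_equal(mscc(count_matrix(xt), ids, n_pairs = 200, seed = 5), base)
})

test_that("RLE metrics match the direct-definition oracle", {
  set.seed(23)
  x <- rand_counts(30, 5, zero_frac = 0.2)
  x <- x[rowSums(x > 0) > 0, ]
  cm <- count_matrix(x)
  orc <- oracle_rle_metrics(x)
  expect_equal(rle_med(cm), orc$rle_med, tolerance = 1e-10)
  expect_equal(rle_iqr(cm), orc$rle_iqr, tolerance = 1e-10)
})

test_that("RLE metrics are zero for identical columns and grow on scaling", {
  x1 <- rand_counts(25, 1, seed = 44)
  x <- cbind(s1 = x1[, 1], s2 = x1[, 1], s3 = x1[, 1])
  cm <- count_matrix(x)
  expect_equal(rle_med(cm), 0)
  expect_equal(rle_iqr(cm), 0)
  xs <- x; xs[, 2] <- xs[, 2] * 3
  expect_gt(rle_med(count_matrix(xs)), rle_med(cm))
})

test_that("factor clustering pairs rank-identical methods first", {
  f1 <- factor_vector("m1", c(a = 1, b = 2, c = 3, d = 4))
  f2 <- factor_vector("m2", c(a = 10, b = 20, c = 31, d = 45))  # same ranks
  f3 <- factor_vector("m3", c(a = 4, b = 3, c = 2, d = 1))      # reversed
  tree <- cluster_factors(list(f1, f2, f3))
  # first merge joins the two rank-identical vectors at height 0
  expect_equal(tree$height[1], 0)
  first_pair <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first_pair, c("m1", "m2"))
  # constant vectors are excluded with a warning
  f4 <- factor_vector("m4", c(a = 1, b = 1, c = 1, d = 1))
  expect_warning(cluster_factors(list(f1, f2, f4)), "m4")
  # newick export produces a readable tree
  path <- withr_tmp("tree.nwk")
  write_tree_newick(tree, path)
  expect_match(readLines(path), "m3")
})

test_that("cv_log2 under common scaling follows the exact mean-shift law", {
  set.seed(29)
  v <- rlnorm(10, log(50), 1)
  c0 <- 7.3
  got <- cv_log2(c0 * v)$cv
  expected <- sd(log2(v)) / (mean(log2(v)) + log2(c0))
  expect_equal(got, expected)
})
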