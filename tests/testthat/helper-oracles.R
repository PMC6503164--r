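# Independent oracle implementations and fixture builders. These are kept
# deliberately naive (explicit loops, explicit sorting) so they share no
# code path with the package internals they check.

rand_counts <- function(m, n, zero_frac = 0, integer = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rlnorm(m * n, log(50), 1), m, n)
  if (integer) x <- matrix(rpois(m * n, x), m, n)
  if (zero_frac > 0) x[runif(m * n) < zero_frac] <- 0
  dimnames(x) <- list(sprintf("g%04d", seq_len(m)),
                      sprintf("s%03d", seq_len(n)))
  x
}

# brute-force zero-ignoring log2 CV of one gene, scalar arithmetic only
oracle_cv_log2 <- function(v) {
  pos <- v[v > 0]
  if (length(pos) < 2) return(NA_real_)
  l <- log2(pos)
  mu <- sum(l) / length(l)
  if (mu <= 0) return(NA_real_)
  s2 <- sum((l - mu)^2) / (length(l) - 1)
  sqrt(s2) / mu
}

# gene x cutoff double loop; independent of the package's tabulate/cumsum
oracle_aucvc <- function(x, nzr_cutoff, grid_size) {
  n <- ncol(x)
  cvs <- c()
  for (i in seq_len(nrow(x))) {
    nz <- sum(x[i, ] > 0)
    if (nz / n < nzr_cutoff) next
    cv <- oracle_cv_log2(x[i, ])
    if (is.finite(cv)) cvs <- c(cvs, cv)
  }
  stopifnot(length(cvs) >= 2)
  lo <- min(cvs); hi <- max(cvs)
  ncv <- if (hi > lo) (cvs - lo) / (hi - lo) else rep(0, length(cvs))
  total <- 0
  for (t in seq_len(grid_size)) {
    cutoff <- t / grid_size
    for (g in seq_along(ncv)) if (ncv[g] <= cutoff + 1e-12) total <- total + 1
  }
  total / (grid_size * length(ncv))
}

# explicit sort-and-slice pairwise TMM; distinct-value inputs assumed
oracle_tmm <- function(x, trim_M = 0.3, trim_A = 0.05) {
  N <- colSums(x)
  q75s <- sapply(seq_len(ncol(x)), function(j) {
    v <- x[, j][x[, j] > 0]
    quantile(v / N[j], 0.75, names = FALSE, type = 7)
  })
  r <- which.min(abs(q75s - mean(q75s)))
  s <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    keep <- x[, j] > 0 & x[, r] > 0
    xj <- x[keep, j]; xr <- x[keep, r]
    M <- log2((xj / N[j]) / (xr / N[r]))
    A <- 0.5 * log2((xj / N[j]) * (xr / N[r]))
    v <- (N[j] - xj) / (N[j] * xj) + (N[r] - xr) / (N[r] * xr)
    ng <- length(M)
    loM <- floor(ng * trim_M); loA <- floor(ng * trim_A)
    okM <- okA <- rep(FALSE, ng)
    okM[order(M)[(loM + 1):(ng - loM)]] <- TRUE
    okA[order(A)[(loA + 1):(ng - loA)]] <- TRUE
    sel <- okM & okA
    w <- 1 / v[sel]
    s[j] <- 2^(sum(w * M[sel]) / sum(w))
  }
  list(s = s, ref = r, N = N)
}

# direct-definition RLE metrics (loops, na.rm medians)
oracle_rle_metrics <- function(x) {
  l <- matrix(NA_real_, nrow(x), ncol(x))
  l[x > 0] <- log(x[x > 0])
  med_g <- apply(l, 1, function(v) median(v[!is.na(v)]))
  meds <- iqrs <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    rle_j <- l[, j] - med_g
    rle_j <- rle_j[!is.na(rle_j)]
    meds[j] <- median(rle_j)
    iqrs[j] <- quantile(rle_j, 0.75, type = 7) - quantile(rle_j, 0.25, type = 7)
  }
  list(rle_med = mean(meds^2), rle_iqr = var(iqrs))
}

tiny_cm <- function() {
  count_matrix(matrix(c(1, 3, 5, 2, 6, 10), nrow = 3,
                      dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
}

# scratch file path inside the session tempdir
withr_tmp <- function(name) {
  d <- file.path(tempdir(), "countnorm-tests")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  file.path(d, name)
}
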