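# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# progress / bookkeeping notes go to stderr so piped output stays clean
cn_log <- function(fmt, ...) message(sprintf(fmt, ...))

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return exp(mean(log(x))).
#' @export
geomean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("geometric mean requires finite positive values")
  exp(mean(log(x)))
}

# third quartile, linear interpolation between order statistics (type 7);
# UQ factors depend on this convention so it is pinned here
q75 <- function(x) stats::quantile(x, probs = 0.75, names = FALSE, type = 7)

`%||%` <- function(a, b) if (is.null(a)) b else a
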