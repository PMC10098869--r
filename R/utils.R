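#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' global seed through a counter-based mixing scheme, so that a stage can be
#' re-run in isolation and still reproduce its output bit for bit.
#'
#' @param seed integer global seed.
#' @param stage integer counter (one per stage / participant / block).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  for (k in c(stage + 1, 12345)) {
    s <- (s * 48271 + k * 16807) %% m
  }
  as.integer(s %% (m - 2L) + 1L)
}

#' @keywords internal
.assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

## symmetric inverse square root with an eigenvalue floor
#' @keywords internal
.inv_sqrt_sym <- function(M, floor = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor * max(abs(e$values), .Machine$double.eps))
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

## upper-quantile order statistic used for permutation thresholds:
## k = ceiling(p * (n + 1)) capped at n, so that an independent draw falls
## below the threshold with probability ~ p (exact permutation calibration).
#' @keywords internal
.perm_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  k <- min(n, ceiling(p * (n + 1)))
  x[k]
}
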