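#' Estimate a sensor noise covariance
#'
#' Sample covariance (1/n, channel means removed) over one or more
#' noise-dominated segments, followed by diagonal loading
#' `eps * trace(C)/P * I` to guarantee positive definiteness.
#'
#' @param segments a `P x T` matrix, a `recording`, or a list of either.
#' @param diag_loading loading fraction `eps` (default 0.01).
#' @return symmetric positive-definite `P x P` matrix.
#' @export
estimate_noise_covariance <- function(segments, diag_loading = 0.01) {
  as_mat <- function(s) if (inherits(s, "recording")) s$data else s
  if (!is.list(segments) || inherits(segments, "recording")) {
    segments <- list(segments)
  }
  mats <- lapply(segments, as_mat)
  if (length(mats) == 0 || sum(vapply(mats, ncol, 0L)) == 0) {
    stop("empty noise segments")
  }
  x <- do.call(cbind, mats)
  p <- nrow(x)
  if (ncol(x) < p) stop("need at least P samples to estimate the covariance")
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / ncol(x)
  C + diag(diag_loading * sum(diag(C)) / p, p)
}

#' sLORETA inverse kernel
#'
#' Minimum-norm kernel `T = G' (G G' + alpha C)^-1` standardized per source
#' location by the 3 x 3 orientation block of the resolution matrix
#' `S_j = T_j G_j`: the returned kernel rows for location `j` are
#' `S_j^{-1/2} T_j` (symmetric inverse square root), so that
#' `||(K x)_j||^2` is the sLORETA standardized power. In the noiseless,
#' weakly regularized limit this estimator has zero localization error for a
#' single active source.
#'
#' @param leadfield a [gen_leadfield()] object (or any list with `gain`).
#' @param noise_cov sensor noise covariance `C` (defaults to identity).
#' @param alpha regularization; `NULL` picks `alpha` such that
#'   `alpha * trace(C) / trace(G G') = 0.1`.
#' @return object of class `inverse_kernel` with `kernel` (Q x P), `alpha`
#'   and `noise_cov`.
#' @export
sloreta_kernel <- function(leadfield, noise_cov = NULL, alpha = NULL) {
  G <- leadfield$gain
  P <- nrow(G)
  if (is.null(noise_cov)) noise_cov <- diag(P)
  if (!is.null(alpha) && alpha < 0) stop("alpha must be non-negative")
  GGt <- tcrossprod(G)
  if (is.null(alpha)) {
    alpha <- 0.1 * sum(diag(GGt)) / sum(diag(noise_cov))
  }
  M <- GGt + alpha * noise_cov
  Minv <- tryCatch(solve(M), error = function(e) {
    stop("singular regularized Gram matrix (G G' + alpha C)")
  })
  Tmn <- crossprod(G, Minv) # Q x P
  Q <- ncol(G)
  if (Q %% 3 != 0) stop("gain must have 3 columns per location")
  K <- matrix(0, Q, P)
  for (j in seq_len(Q / 3)) {
    idx <- (j - 1L) * 3L + 1:3
    Sj <- Tmn[idx, , drop = FALSE] %*% G[, idx, drop = FALSE]
    K[idx, ] <- .inv_sqrt_sym(Sj) %*% Tmn[idx, , drop = FALSE]
  }
  structure(
    list(kernel = K, alpha = alpha, noise_cov = noise_cov),
    class = "inverse_kernel"
  )
}

#' @export
print.inverse_kernel <- function(x, ...) {
  cat(sprintf(
    "sLORETA kernel: %d source signals x %d channels (alpha = %.4g)\n",
    nrow(x$kernel), ncol(x$kernel), x$alpha
  ))
  invisible(x)
}

#' ROI scouting matrix
#'
#' Averaging operator from the `Q` source signals to `3 F` representative
#' signals (three orientation components per ROI): the row of ROI `i` and
#' orientation `a` holds `1 / R_i` at the orientation-`a` slots of that ROI's
#' `R_i` sources and 0 elsewhere, so every row sums to 1.
#'
#' @param leadfield a [gen_leadfield()] object.
#' @return object of class `scouting_matrix`: `U` (`3F x Q`), `roi` labels and
#'   per-ROI source counts `R`.
#' @export
build_scouting_matrix <- function(leadfield) {
  roi <- leadfield$roi_map
  labs <- levels(roi)
  counts <- table(roi)
  empty <- labs[counts == 0]
  if (length(empty) > 0) {
    stop(sprintf("empty ROI(s): %s", paste(empty, collapse = ", ")))
  }
  Q <- ncol(leadfield$gain)
  U <- matrix(0, 3L * length(labs), Q)
  for (i in seq_along(labs)) {
    loc <- which(roi == labs[i])
    for (a in 1:3) {
      U[(i - 1L) * 3L + a, (loc - 1L) * 3L + a] <- 1 / length(loc)
    }
  }
  rownames(U) <- paste0(rep(labs, each = 3), ".", c("x", "y", "z"))
  structure(
    list(U = U, roi = labs, R = as.integer(counts)),
    class = "scouting_matrix"
  )
}

#' Project a recording into ROI-averaged source space
#'
#' `y_t = U K x_t` per sample: the full standardized source estimate reduced
#' to one representative signal per ROI and orientation. The composite
#' operator `U K` is formed once.
#'
#' @param recording a `recording` (or bare `P x T` matrix).
#' @param kernel an [sloreta_kernel()] result.
#' @param scouting a [build_scouting_matrix()] result.
#' @return `3F x T` feature matrix with ROI.component row names.
#' @export
project_features <- function(recording, kernel, scouting) {
  x <- if (inherits(recording, "recording")) recording$data else recording
  K <- kernel$kernel
  U <- scouting$U
  if (ncol(U) != nrow(K)) stop("scouting/kernel dimension mismatch")
  if (ncol(K) != nrow(x)) stop("kernel/recording dimension mismatch")
  out <- (U %*% K) %*% x
  rownames(out) <- rownames(U)
  out
}

#' Standardized source power per location
#'
#' Convenience for localization checks: mean over time of
#' `||(K x)_location||^2` for every source location.
#'
#' @param x `P x T` sensor matrix.
#' @param kernel an [sloreta_kernel()] result.
#' @return vector of length `Q/3`.
#' @export
source_power <- function(x, kernel) {
  J <- kernel$kernel %*% x
  Q <- nrow(J)
  pow <- rowMeans(J^2)
  colSums(matrix(pow, nrow = 3))
}
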