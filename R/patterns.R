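#' Model-specific global field power
#'
#' Scalar normalizer for decoding patterns: per permutation a single
#' within-trial time point is drawn, the source-projected sample is averaged
#' over the (equal-length) trials, and the standard deviation over voxels is
#' taken; the GFP is the median of this distribution over permutations.
#' Averaging over trials commutes with the linear projection, so the trial
#' mean is projected once.
#'
#' @param sensor_trials list of equal-length `P x T` sensor matrices (the
#'   training pool split by trial).
#' @param kernel an [sloreta_kernel()] object, or a bare `Q x P` matrix.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return the scalar GFP `g`.
#' @export
model_gfp <- function(sensor_trials, kernel, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.list(sensor_trials)) sensor_trials <- list(sensor_trials)
  lens <- vapply(sensor_trials, ncol, 0L)
  if (length(unique(lens)) != 1) {
    stop("GFP requires equal-length trials")
  }
  K <- if (inherits(kernel, "inverse_kernel")) kernel$kernel else kernel
  meanX <- Reduce(`+`, sensor_trials) / length(sensor_trials)
  Jm <- K %*% meanX
  set.seed(derive_seed(seed, 77L))
  tpick <- sample.int(ncol(Jm), n_perm, replace = TRUE)
  sds <- vapply(tpick, function(t) stats::sd(Jm[, t]), 0)
  stats::median(sds)
}

#' Forward-model decoding pattern
#'
#' Transforms decoder weights into an interpretable forward pattern:
#' `A = (1/g) Sigma_Y W Sigma_Z^{-1/2}`, where `W` is the feature-to-
#' kinematic map of the decoder (`d x 6`), `Sigma_Y` and `Sigma_Z` are the
#' properly normalized (1/n) covariances of the training features and
#' extended kinematics - not the raw inner products of the covariance
#' recursion - and the inverse square root is the symmetric one. Unlike the
#' decoder weights, the pattern columns are proportional to the forward
#' mixing of the corresponding kinematic and may be read spatially.
#'
#' @param model a `rewpls`/`traj_decoder` model, or a bare `d x m` weight
#'   matrix.
#' @param Sigma_Y `d x d` feature covariance; @param Sigma_Z `m x m`
#'   kinematics covariance (positive definite).
#' @param g positive GFP scalar from [model_gfp()].
#' @return object of class `decoding_pattern`: `A` (`d x m`), `g` and the
#'   inputs' dimensions.
#' @export
decoding_pattern <- function(model, Sigma_Y, Sigma_Z, g = 1) {
  W <- if (inherits(model, "traj_decoder")) {
    model$pls$B
  } else if (inherits(model, "rewpls")) {
    model$B
  } else {
    .assert_matrix(model)
    model
  }
  if (!is.finite(g) || g <= 0) stop("degenerate GFP (g must be > 0)")
  ev <- eigen((Sigma_Z + t(Sigma_Z)) / 2, symmetric = TRUE,
    only.values = TRUE
  )$values
  if (min(ev) <= 0) stop("kinematics covariance must be positive definite")
  A <- (Sigma_Y %*% W %*% .inv_sqrt_sym(Sigma_Z)) / g
  rownames(A) <- rownames(Sigma_Y)
  structure(
    list(A = A, g = g, d = nrow(A), m = ncol(A)),
    class = "decoding_pattern"
  )
}

#' @export
print.decoding_pattern <- function(x, ...) {
  cat(sprintf(
    "Decoding pattern: %d features x %d kinematics (GFP = %.4g)\n",
    x$d, x$m, x$g
  ))
  invisible(x)
}

#' Aggregate pattern magnitudes by ROI
#'
#' Sums `|A|` over the features of each ROI (all orientation components and
#' lags, or one lag when `lag` is given). The per-ROI sums conserve the total
#' summed magnitude.
#'
#' @param pattern a [decoding_pattern()] whose feature rows are labelled
#'   `ROI.component@lag` (as produced by the source-space pipeline).
#' @param lag optional single lag to restrict to (e.g. `0`).
#' @return data frame with columns `roi`, `kinematic`, `value`.
#' @export
pattern_by_roi <- function(pattern, lag = NULL) {
  A <- pattern$A
  lab <- rownames(A)
  if (is.null(lab)) stop("pattern rows carry no feature labels")
  roi <- sub("\\..*$", "", lab)
  lag_of <- sub("^.*@lag", "", lab)
  if (!is.null(lag)) {
    keep <- lag_of == as.character(as.integer(lag))
    A <- A[keep, , drop = FALSE]
    roi <- roi[keep]
  }
  kin <- colnames(A)
  if (is.null(kin)) kin <- sprintf("k%d", seq_len(ncol(A)))
  out <- expand.grid(
    roi = unique(roi), kinematic = kin,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out$value <- mapply(function(rr, kk) {
    sum(abs(A[roi == rr, match(kk, kin), drop = FALSE]))
  }, out$roi, out$kinematic)
  out
}

#' Embed a pattern collection in two dimensions (t-SNE)
#'
#' Each pattern vector is normalized by its maximum absolute entry and the
#' collection is embedded with exact t-distributed stochastic neighbour
#' embedding (per-point bandwidths matched to the target perplexity by
#' bisection, early exaggeration, momentum gradient descent, fixed seed).
#' Collections here are small (one pattern per model and participant), so
#' the exact quadratic algorithm is the appropriate tool. Call once per
#' kinematic.
#'
#' @param patterns `n x d` matrix, one pattern vector per row (`n >= 3`).
#' @param perplexity target perplexity (reduced automatically to at most
#'   `(n - 1) / 3`).
#' @param seed integer seed; @param n_iter gradient iterations.
#' @return `n x 2` matrix of embedding coordinates.
#' @export
embed_patterns <- function(patterns, perplexity = 30, seed = 1L,
                           n_iter = 1000L) {
  .assert_matrix(patterns)
  n <- nrow(patterns)
  if (n < 3) stop("need at least 3 patterns")
  mx <- apply(abs(patterns), 1, max)
  if (any(mx == 0)) stop("all-zero pattern cannot be normalized")
  X <- patterns / mx
  perplexity <- min(perplexity, (n - 1) / 3)

  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P / sum(P), 1e-12)

  set.seed(derive_seed(seed, 99L))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Qd <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Qd) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

## per-point conditional affinities at a target perplexity (bisection on the
## Gaussian precision)
#' @keywords internal
.tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf
    hi <- Inf
    beta <- 1
    for (iter in 1:60) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) {
        H <- 0
        p[] <- 0
      } else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < 1e-6) break
      if (H > target) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}
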