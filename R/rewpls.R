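#' Initialize a recursive covariance state
#'
#' The recursive exponentially weighted PLS decoder never stores raw samples:
#' all it keeps between batches are the (non-normalized) inner-product
#' matrices `C_yy = (Y Y')_t` and `C_yz = (Y Z')_t`, the matching weighted
#' sums of features and responses, and the weighted sample count. With
#' forgetting factor `lambda = 1` the state after any sequence of batches
#' equals the inner products of the concatenated data.
#'
#' @param d feature dimension, @param m response dimension.
#' @param lambda default forgetting factor in (0, 1].
#' @return object of class `cov_state`.
#' @export
cov_state <- function(d, m, lambda = 1) {
  stopifnot(d >= 1, m >= 1, lambda > 0, lambda <= 1)
  structure(
    list(
      C_yy = matrix(0, d, d), C_yz = matrix(0, d, m),
      s_y = numeric(d), s_z = numeric(m), n_w = 0, lambda = lambda,
      n_batches = 0L
    ),
    class = "cov_state"
  )
}

#' Recursive exponentially weighted covariance update
#'
#' One batch update: the previous state is discounted once by `lambda`, then
#' the batch inner products are added:
#' `C_yy <- lambda * C_yy + Y Y'`, `C_yz <- lambda * C_yz + Y Z'`, and the
#' running sums and weighted count are updated consistently (per-sample
#' weighting within a batch is uniform).
#'
#' @param state a [cov_state()].
#' @param Y features, `d x n` (columns are samples).
#' @param Z responses, `m x n`, column-paired with `Y`.
#' @param lambda forgetting factor for this update (defaults to the state's).
#' @return the updated `cov_state`.
#' @export
cov_update <- function(state, Y, Z, lambda = state$lambda) {
  .assert_matrix(Y)
  .assert_matrix(Z)
  if (ncol(Y) != ncol(Z)) stop("Y and Z batches must be column-paired")
  if (nrow(Y) != nrow(state$C_yy) || nrow(Z) != ncol(state$C_yz)) {
    stop("batch dimensions differ from the covariance state")
  }
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  state$C_yy <- lambda * state$C_yy + tcrossprod(Y)
  state$C_yz <- lambda * state$C_yz + tcrossprod(Y, Z)
  state$s_y <- lambda * state$s_y + rowSums(Y)
  state$s_z <- lambda * state$s_z + rowSums(Z)
  state$n_w <- lambda * state$n_w + ncol(Y)
  state$n_batches <- state$n_batches + 1L
  state
}

#' Combine or subtract lambda = 1 covariance states
#'
#' At `lambda = 1` the state is an additive sufficient statistic, so pooled
#' states (leave-one-participant-out, cross-validation folds) can be formed
#' by matrix addition/subtraction without revisiting the data.
#'
#' @param a,b `cov_state` objects of matching dimensions.
#' @return a `cov_state`.
#' @export
cov_combine <- function(a, b) {
  a$C_yy <- a$C_yy + b$C_yy
  a$C_yz <- a$C_yz + b$C_yz
  a$s_y <- a$s_y + b$s_y
  a$s_z <- a$s_z + b$s_z
  a$n_w <- a$n_w + b$n_w
  a$n_batches <- a$n_batches + b$n_batches
  a
}

#' @rdname cov_combine
#' @export
cov_subtract <- function(a, b) {
  b$C_yy <- -b$C_yy
  b$C_yz <- -b$C_yz
  b$s_y <- -b$s_y
  b$s_z <- -b$s_z
  b$n_w <- -b$n_w
  b$n_batches <- -b$n_batches
  cov_combine(a, b)
}

## centered covariance pair from a state (weighted means removed)
#' @keywords internal
.center_state <- function(state) {
  n <- state$n_w
  if (n <= 0) stop("empty covariance state")
  my <- state$s_y / n
  mz <- state$s_z / n
  list(
    Cyy = state$C_yy - n * tcrossprod(my),
    Cyz = state$C_yz - n * tcrossprod(my, mz),
    my = my, mz = mz, n = n
  )
}

#' Fit a PLS model from a covariance state (kernel algorithm)
#'
#' Covariance-only PLS fit in the style of the modified kernel algorithm #2:
#' the state is centered using its running weighted means, then per component
#' `a` the weight `w_a` is the dominant left singular vector of the current
#' (deflated) cross-covariance, `r_a` is `w_a` orthogonalized against the
#' previous loadings, loadings are
#' `p_a = C_yy r_a / (r_a' C_yy r_a)` and `q_a = C_yz' r_a / (r_a' C_yy r_a)`,
#' and the cross-covariance is deflated by `t_a t_a' . p_a q_a'`. The
#' regression map is `B = sum_a r_a q_a'` and the latent projection is
#' `E = R' (y - mean)`. At `lambda = 1` the result equals a direct batch PLS
#' fit on the concatenated raw data.
#'
#' @param state a [cov_state()] after at least one update.
#' @param A number of latent components; truncated with a warning if it
#'   exceeds the numerical rank of the centered covariances.
#' @return object of class `rewpls` with elements `R` (d x A), `P`, `Qm`
#'   (m x A), `B` (d x m), `W` (A x d latent weights), `means`, `A`, `lambda`.
#' @export
rewpls_fit <- function(state, A) {
  if (A < 1) stop("A must be >= 1")
  cs <- .center_state(state)
  d <- nrow(cs$Cyy)
  m <- ncol(cs$Cyz)
  A <- min(A, d, floor(cs$n))
  Cyz <- cs$Cyz
  Rm <- matrix(0, d, A)
  Pm <- matrix(0, d, A)
  Qm <- matrix(0, m, A)
  tol <- 1e-12 * max(diag(cs$Cyy), .Machine$double.eps)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- if (m == 1) Cyz[, 1] else svd(Cyz, nu = 1, nv = 0)$u[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < sqrt(tol) * 1e-3) break
    w <- w / nw
    r <- w
    if (a > 1) {
      for (j in seq_len(a - 1L)) {
        r <- r - drop(crossprod(Pm[, j], w)) * Rm[, j]
      }
    }
    tt <- drop(crossprod(r, cs$Cyy %*% r))
    if (!is.finite(tt) || tt < tol) break
    p <- drop(cs$Cyy %*% r) / tt
    q <- drop(crossprod(Cyz, r)) / tt
    Cyz <- Cyz - tt * tcrossprod(p, q)
    Rm[, a] <- r
    Pm[, a] <- p
    Qm[, a] <- q
    a_used <- a
  }
  if (a_used < A) {
    warning(sprintf(
      "requested %d components but rank supports %d; truncated", A, a_used
    ))
    A <- max(a_used, 1L)
    Rm <- Rm[, seq_len(A), drop = FALSE]
    Pm <- Pm[, seq_len(A), drop = FALSE]
    Qm <- Qm[, seq_len(A), drop = FALSE]
  }
  B <- tcrossprod(Rm, Qm)
  structure(
    list(
      R = Rm, P = Pm, Qm = Qm, B = B, W = t(Rm),
      means = list(y = cs$my, z = cs$mz), A = A, lambda = state$lambda,
      n_w = state$n_w, d = d, m = m
    ),
    class = "rewpls"
  )
}

#' Fit recursive exponentially weighted PLS from data
#'
#' Convenience wrapper: accumulates the covariance state over the supplied
#' batch list (or a single matrix pair) and fits [rewpls_fit()]. When `A` is
#' `NULL` the component count is chosen by [select_components()].
#'
#' @param Y features `d x n` or list of batches; `Z` responses likewise.
#' @param Z see `Y`.
#' @param A latent components (`NULL` = knee-selected).
#' @param lambda forgetting factor.
#' @param ... passed to [select_components()] when `A` is `NULL`.
#' @return a `rewpls` model.
#' @export
rewpls <- function(Y, Z, A = NULL, lambda = 1, ...) {
  if (!is.list(Y)) {
    Y <- list(Y)
    Z <- list(Z)
  }
  st <- cov_state(nrow(Y[[1]]), nrow(Z[[1]]), lambda)
  for (i in seq_along(Y)) st <- cov_update(st, Y[[i]], Z[[i]])
  if (is.null(A)) {
    A <- select_components(do.call(cbind, Y), do.call(cbind, Z),
      lambda = lambda, ...
    )$A
  }
  rewpls_fit(st, A)
}

#' Predict from a fitted PLS model
#'
#' @param object a `rewpls` model.
#' @param newdata features `d x n`.
#' @param type `"response"` for predicted kinematics (`m x n`), `"scores"`
#'   for latent features `E = W (y - mean)` (`A x n`), `"both"` for a list.
#' @param ... unused.
#' @return matrix or list according to `type`.
#' @export
predict.rewpls <- function(object, newdata,
                           type = c("response", "scores", "both"), ...) {
  type <- match.arg(type)
  .assert_matrix(newdata)
  if (nrow(newdata) != object$d) stop("feature dimension mismatch")
  yc <- newdata - object$means$y
  if (type %in% c("response", "both")) {
    zhat <- crossprod(object$B, yc) + object$means$z
    rownames(zhat) <- names(object$means$z)
  }
  if (type %in% c("scores", "both")) {
    scores <- object$W %*% yc
  }
  switch(type,
    response = zhat,
    scores = scores,
    both = list(response = zhat, scores = scores)
  )
}

#' @export
coef.rewpls <- function(object, ...) {
  rbind(`(Intercept)` = object$means$z - drop(crossprod(
    object$B,
    object$means$y
  )), t(object$B))[, , drop = FALSE]
}

#' @export
summary.rewpls <- function(object, ...) {
  out <- list(
    A = object$A, d = object$d, m = object$m, lambda = object$lambda,
    n_w = object$n_w,
    response_loadings = t(object$Qm)
  )
  class(out) <- "summary.rewpls"
  out
}

#' @export
print.summary.rewpls <- function(x, ...) {
  cat(sprintf(
    "REW-PLS: %d features -> %d responses, %d components (lambda = %g, weighted n = %g)\n",
    x$d, x$m, x$A, x$lambda, x$n_w
  ))
  cat("Response loadings per component:\n")
  print(round(x$response_loadings, 4))
  invisible(x)
}

#' @export
print.rewpls <- function(x, ...) {
  cat(sprintf(
    "REW-PLS model: %d features -> %d responses, %d latent components (lambda = %g, n_w = %g)\n",
    x$d, x$m, x$A, x$lambda, x$n_w
  ))
  invisible(x)
}

#' Knee point of a curve by maximal chord distance
#'
#' Distance of each point from the chord joining the curve endpoints; ties
#' (including the exactly linear curve, where all distances vanish) resolve
#' to the smallest index.
#'
#' @param y curve values at x = 1..length(y).
#' @return integer index of the knee.
#' @export
knee_point <- function(y) {
  n <- length(y)
  if (n == 1) {
    return(1L)
  }
  x <- seq_len(n)
  dx <- n - 1
  dy <- y[n] - y[1]
  dist <- abs(dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  which.max(dist > max(dist) - 1e-12) # first index attaining the max
}

#' Cross-validated selection of the number of PLS components
#'
#' Builds the curve of mean Pearson correlation of the PLS-predicted linear
#' kinematics (rows `kin_rows`) versus component count `A = 1..A_max` under
#' k-fold cross-validation with contiguous folds, and returns the knee of the
#' curve ([knee_point()]). Fold states are formed by subtracting the fold's
#' inner products from the total (`lambda = 1` algebra), so each fold is fit
#' once at `A_max` and the per-`A` predictions accumulate component by
#' component.
#'
#' @param Y features `d x n`; @param Z responses `m x n`.
#' @param A_max largest component count tried (default 50).
#' @param folds number of folds (default 10).
#' @param kin_rows response rows entering the correlation curve (default the
#'   first 4, the linear kinematics).
#' @param lambda forgetting factor used for the states.
#' @return list with `A` (selected), `curve` (mean correlation per A) and
#'   `folds`.
#' @export
select_components <- function(Y, Z, A_max = 50L, folds = 10L,
                              kin_rows = NULL, lambda = 1) {
  .assert_matrix(Y)
  .assert_matrix(Z)
  n <- ncol(Y)
  if (A_max < 2) stop("A_max must be >= 2")
  if (n < 2 * folds) stop("not enough samples for the requested folds")
  if (is.null(kin_rows)) kin_rows <- seq_len(min(4L, nrow(Z)))
  A_max <- min(A_max, nrow(Y), n - ceiling(n / folds) - 1L)

  total <- cov_update(cov_state(nrow(Y), nrow(Z), lambda), Y, Z)
  fold_id <- rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]
  rsum <- matrix(0, A_max, length(kin_rows))
  rcnt <- 0L
  for (f in seq_len(folds)) {
    v <- which(fold_id == f)
    fold_state <- cov_update(cov_state(nrow(Y), nrow(Z), lambda),
      Y[, v, drop = FALSE], Z[, v, drop = FALSE]
    )
    tr <- cov_subtract(total, fold_state)
    fit <- suppressWarnings(rewpls_fit(tr, A_max))
    scores <- fit$W %*% (Y[, v, drop = FALSE] - fit$means$y) # A x nv
    pred <- matrix(fit$means$z, nrow(Z), length(v))
    for (a in seq_len(A_max)) {
      if (a <= fit$A) {
        pred <- pred + tcrossprod(fit$Qm[, a], scores[a, ])
      }
      for (ki in seq_along(kin_rows)) {
        r <- suppressWarnings(stats::cor(
          pred[kin_rows[ki], ],
          Z[kin_rows[ki], v]
        ))
        rsum[a, ki] <- rsum[a, ki] + ifelse(is.finite(r), r, 0)
      }
    }
    rcnt <- rcnt + 1L
  }
  curve <- rowMeans(rsum / rcnt)
  if (max(curve) - min(curve) < 1e-12) {
    warning("degenerate (constant) cross-validation curve; A = 1")
    return(list(A = 1L, curve = curve, folds = folds))
  }
  list(A = knee_point(curve), curve = curve, folds = folds)
}
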