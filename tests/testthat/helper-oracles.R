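# Independent oracle implementations used to cross-check the package's
# covariance-based algorithms. These operate on raw data matrices and follow
# textbook formulations, deliberately sharing no code with the package.

# Batch PLS2 on raw centered data with X-deflation (classical NIPALS-style
# algorithm written via the exact SVD of the deflated cross-product).
# X: n x d, Y: n x m. Returns the d x m regression coefficient matrix.
oracle_batch_pls <- function(X, Y, A) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  E <- Xc
  Ws <- Ps <- Qs <- vector("list", A)
  for (a in seq_len(A)) {
    S <- crossprod(E, Yc)
    w <- svd(S, nu = 1, nv = 0)$u[, 1]
    t_ <- E %*% w
    tt <- drop(crossprod(t_))
    p <- crossprod(E, t_) / tt
    q <- crossprod(Yc, t_) / tt
    E <- E - t_ %*% t(p)
    Ws[[a]] <- w
    Ps[[a]] <- p
    Qs[[a]] <- q
  }
  W <- do.call(cbind, Ws)
  P <- do.call(cbind, Ps)
  Q <- do.call(cbind, Qs)
  R <- W %*% solve(crossprod(P, W))
  R %*% t(Q)
}

# Conventional (full-covariance) Kalman filter for a linear-Gaussian system.
oracle_kalman <- function(F, H, Q, R, P0, x0, E) {
  x <- x0
  P <- P0
  out <- matrix(0, length(x0), ncol(E))
  for (t in seq_len(ncol(E))) {
    x <- F %*% x
    P <- F %*% P %*% t(F) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (E[, t] - H %*% x)
    P <- P - K %*% H %*% P
    out[, t] <- x
  }
  out
}

# Mean silhouette width for a 2-group labelling of 2-D points.
oracle_silhouette <- function(xy, labels) {
  D <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(xy)) != i])
    b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, 0)
  mean(sil)
}
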