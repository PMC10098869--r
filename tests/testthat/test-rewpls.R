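rand_data <- function(n = 200, d = 20, m = 6, seed = 1, noise = 0.5) {
  set.seed(seed)
  Y <- matrix(rnorm(d * n), d, n)
  C <- matrix(rnorm(d * m), d, m)
  Z <- crossprod(C, Y) + noise * matrix(rnorm(m * n), m, n)
  list(Y = Y, Z = Z)
}

test_that("covariance recursion matches hand-unrolled and batch algebra", {
  dd <- rand_data()
  Y <- dd$Y
  Z <- dd$Z
  ## lambda = 1: two batches equal the single-batch computation
  st <- cov_state(20, 6)
  st <- cov_update(st, Y[, 1:70], Z[, 1:70])
  st <- cov_update(st, Y[, 71:200], Z[, 71:200])
  st1 <- cov_update(cov_state(20, 6), Y, Z)
  expect_lt(max(abs(st$C_yy - st1$C_yy)) / max(abs(st1$C_yy)), 1e-12)
  expect_lt(max(abs(st$C_yz - st1$C_yz)) / max(abs(st1$C_yz)), 1e-12)

  ## lambda = 0 limit keeps only the newest batch
  st0 <- cov_update(cov_state(20, 6), Y[, 1:50], Z[, 1:50], lambda = 1)
  st0 <- cov_update(st0, Y[, 51:60], Z[, 51:60], lambda = 1e-300)
  ref <- cov_update(cov_state(20, 6), Y[, 51:60], Z[, 51:60])
  expect_equal(st0$C_yy, ref$C_yy, tolerance = 1e-10)

  ## hand-unrolled recursion: lambda = 0.5, two single-sample batches
  y1 <- Y[, 1, drop = FALSE]
  y2 <- Y[, 2, drop = FALSE]
  z1 <- Z[, 1, drop = FALSE]
  z2 <- Z[, 2, drop = FALSE]
  sth <- cov_update(cov_state(20, 6, lambda = 0.5), y1, z1)
  sth <- cov_update(sth, y2, z2)
  expect_equal(sth$C_yy, 0.5 * tcrossprod(y1) + tcrossprod(y2),
    tolerance = 1e-12
  )
  expect_equal(sth$C_yz, 0.5 * tcrossprod(y1, z1) + tcrossprod(y2, z2),
    tolerance = 1e-12
  )
  expect_error(cov_update(st, Y[1:3, ], Z), "dimension")
})

test_that("batch-order invariance holds at lambda = 1", {
  dd <- rand_data(n = 120, seed = 3)
  cuts <- list(c(120), c(40, 80), c(10, 30, 80), rep(12, 10))
  ref <- cov_update(cov_state(20, 6), dd$Y, dd$Z)
  for (sizes in cuts) {
    st <- cov_state(20, 6)
    i0 <- 0
    for (sz in cumsum(sizes)) {
      idx <- (i0 + 1):sz
      st <- cov_update(st, dd$Y[, idx, drop = FALSE],
        dd$Z[, idx, drop = FALSE]
      )
      i0 <- sz
    }
    expect_lt(max(abs(st$C_yy - ref$C_yy)) / max(abs(ref$C_yy)), 1e-10)
    expect_lt(max(abs(st$C_yz - ref$C_yz)) / max(abs(ref$C_yz)), 1e-10)
  }
})

test_that("covariance fit matches a direct batch PLS on raw data", {
  dd <- rand_data(n = 200, d = 20, m = 6, seed = 7)
  fit <- rewpls(dd$Y, dd$Z, A = 5)
  B_oracle <- oracle_batch_pls(t(dd$Y), t(dd$Z), 5)
  expect_lt(max(abs(fit$B - B_oracle)), 1e-8)
})

test_that("full-component fit equals ordinary least squares", {
  dd <- rand_data(n = 300, d = 15, m = 4, seed = 9)
  fit <- rewpls(dd$Y, dd$Z, A = 15)
  Xc <- scale(t(dd$Y), scale = FALSE)
  Zc <- scale(t(dd$Z), scale = FALSE)
  B_ols <- solve(crossprod(Xc), crossprod(Xc, Zc))
  expect_lt(max(abs(fit$B - B_ols)), 1e-6)
})

test_that("single response, one component gives the classical direction", {
  dd <- rand_data(n = 150, d = 12, m = 1, seed = 5)
  fit <- rewpls(dd$Y, dd$Z, A = 1)
  st <- cov_update(cov_state(12, 1), dd$Y, dd$Z)
  cyz <- st$C_yz - st$n_w * tcrossprod(st$s_y / st$n_w, st$s_z / st$n_w)
  w <- fit$R[, 1]
  cosang <- abs(sum(w * cyz) / sqrt(sum(w^2) * sum(cyz^2)))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("prediction honours the centering identity and contracts", {
  dd <- rand_data(seed = 11)
  fit <- rewpls(dd$Y, dd$Z, A = 4)
  mu <- matrix(fit$means$y, 20, 1)
  expect_equal(drop(predict(fit, mu)), fit$means$z, tolerance = 1e-10)
  both <- predict(fit, dd$Y[, 1:7], type = "both")
  expect_equal(nrow(both$scores), 4)
  expect_equal(dim(both$response), c(6, 7))
  expect_error(predict(fit, dd$Y[1:3, ]), "mismatch")
})

test_that("noiseless exactly-linear data is recovered at the true rank", {
  set.seed(13)
  d <- 10
  n <- 400
  L <- matrix(rnorm(d * 3), d, 3)
  lat <- matrix(rnorm(3 * n), 3, n)
  Y <- L %*% lat
  Z <- matrix(rnorm(3 * 4), 4, 3) %*% lat
  fit <- suppressWarnings(rewpls(Y, Z, A = 3))
  pred <- predict(fit, Y)
  expect_lt(max(abs(pred - Z)) / max(abs(Z)), 1e-8)
})

test_that("requesting more components than the rank truncates with warning", {
  set.seed(15)
  lat <- matrix(rnorm(2 * 100), 2, 100)
  Y <- matrix(rnorm(8 * 2), 8, 2) %*% lat
  Z <- matrix(rnorm(3 * 2), 3, 2) %*% lat
  expect_warning(fit <- rewpls(Y, Z, A = 6), "truncated")
  expect_lte(fit$A, 2)
})

test_that("memory contract: fitting consumes only the covariance state", {
  ## stream many batches; the state size never grows with the sample count
  st <- cov_state(10, 4)
  sz0 <- object.size(st)
  set.seed(17)
  C <- matrix(rnorm(10 * 4), 10, 4)
  for (i in 1:50) {
    Y <- matrix(rnorm(10 * 500), 10, 500)
    Z <- crossprod(C, Y) + 0.1 * matrix(rnorm(4 * 500), 4, 500)
    st <- cov_update(st, Y, Z)
  }
  expect_equal(as.numeric(object.size(st)), as.numeric(sz0))
  fit <- rewpls_fit(st, 3)
  expect_equal(fit$n_w, 25000)
  expect_equal(dim(fit$B), c(10, 4))
})

test_that("knee detection finds plateaus and respects the tie rule", {
  ## constructed ground truth: three informative latent directions
  set.seed(19)
  d <- 15
  n <- 600
  L <- qr.Q(qr(matrix(rnorm(d * 3), d, 3))) * 5
  lat <- matrix(rnorm(3 * n), 3, n)
  Y <- L %*% lat + 0.05 * matrix(rnorm(d * n), d, n)
  Z <- rbind(
    lat + 0.02 * matrix(rnorm(3 * n), 3, n),
    lat[1, , drop = FALSE]
  )
  sel <- select_components(Y, Z, A_max = 8, folds = 10)
  ## brute-force knee over the computed curve
  curve <- sel$curve
  chord <- function(y) {
    n <- length(y)
    dy <- y[n] - y[1]
    dx <- n - 1
    abs(dy * (seq_len(n) - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  }
  expect_equal(sel$A, which.max(chord(curve)))
  expect_equal(sel$A, 3)
  ## strictly linear curve: all chord distances 0, smallest index wins
  expect_equal(knee_point(c(1, 2, 3, 4, 5)), 1L)
  ## monotone CV fit up to the true rank on near-noiseless data
  expect_true(all(diff(curve[1:3]) > -1e-6))
})

test_that("cross-validation folds partition the samples", {
  n <- 100
  folds <- 10
  fold_id <- rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]
  expect_equal(
    sort(unname(unlist(split(seq_len(n), fold_id)))), seq_len(n)
  )
  expect_equal(length(unique(table(fold_id))), 1)
})
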