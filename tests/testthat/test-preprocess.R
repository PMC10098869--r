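make_rec <- function(data, fs = 200, trials = NULL) {
  structure(
    list(
      data = data, fs = fs,
      channels = sprintf("CH%02d", seq_len(nrow(data))),
      trials = if (is.null(trials)) cbind(0L, ncol(data)) else trials
    ),
    class = "recording"
  )
}

test_that("filter chain removes DC, crushes 10 Hz and lands at 20 Hz", {
  n <- 12000 # 60 s at 200 Hz, long against the 0.18 Hz cutoff period
  t <- (0:(n - 1)) / 200
  ## constant offset: high-pass removes it (to < 1% away from the edges)
  rec <- make_rec(matrix(50, 2, n))
  out <- filter_chain(rec)
  core <- out$data[, 120:1080]
  expect_lt(mean(abs(core)), 0.5)
  expect_equal(out$fs, 20)
  expect_equal(ncol(out$data), 1200, tolerance = 1, ignore_attr = TRUE)

  ## 10 Hz sine: the analytic magnitude of the 4th-order Butterworth
  ## low-pass at 3 Hz is 1/sqrt(1 + (10/3)^8) ~ -42 dB single-pass;
  ## the chain must deliver at least the 20 dB the response promises
  h_an <- 1 / sqrt(1 + (10 / 3)^8)
  expect_lt(20 * log10(h_an), -20)
  rec10 <- make_rec(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)))
  out10 <- filter_chain(rec10)
  core10 <- out10$data[, 120:1080]
  expect_lt(sqrt(mean(core10^2)) / sqrt(0.5), 0.1)

  expect_error(
    filter_chain(make_rec(matrix(0, 2, 100)), lp_hz = 60), "Nyquist"
  )
  expect_error(
    filter_chain(make_rec(matrix(0, 2, 100)), hp_hz = 150), "Nyquist"
  )
})

test_that("the conditioning chain is linear", {
  set.seed(4)
  n <- 1200
  x1 <- matrix(rnorm(2 * n), 2, n)
  x2 <- matrix(rnorm(2 * n), 2, n)
  a <- 1.7
  b <- -0.6
  f <- function(x) filter_chain(make_rec(x))$data
  lhs <- f(a * x1 + b * x2)
  rhs <- a * f(x1) + b * f(x2)
  ## round-off accrues at the scale of the unfiltered input inside the
  ## narrow high-pass recursion; measure the mismatch against that scale
  ## the 0.18 Hz recursion at 200 Hz (normalized cutoff 1.8e-3) leaves
  ## ~2e-8 of double-precision round-off at that scale
  expect_lt(max(abs(lhs - rhs)) / max(abs(a * x1 + b * x2)), 5e-8)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)
})

test_that("trial boundaries rescale with the rate", {
  n <- 4000
  tr <- rbind(c(0L, 2000L), c(2000L, 4000L))
  out <- filter_chain(make_rec(matrix(rnorm(2 * n), 2, n), trials = tr))
  expect_equal(out$trials, rbind(c(0, 200), c(200, 400)),
    ignore_attr = TRUE
  )
})

test_that("common average reference zeroes channel means and projects", {
  x <- matrix(c(1, 3, 2, 4), 2, 2, byrow = FALSE)
  rec <- make_rec(rbind(c(1, 2), c(3, 4)), fs = 20)
  out <- common_average_reference(rec)
  expect_equal(out$data, rbind(c(-1, -1), c(1, 1)))
  expect_equal(colMeans(out$data), c(0, 0), tolerance = 1e-10)
  out2 <- common_average_reference(out)
  expect_equal(out2$data, out$data)
  expect_error(
    common_average_reference(make_rec(matrix(1, 1, 5), fs = 20)),
    ">= 2 channels"
  )
})

test_that("lag expansion has the contracted shape and index bookkeeping", {
  ## 84 source features with 7 lags give 588 rows
  x84 <- matrix(rnorm(84 * 40), 84, 40)
  expect_equal(nrow(lag_expand(x84, 0:-6)$data), 588)
  ## identity case
  x <- matrix(rnorm(3 * 10), 3, 10)
  le0 <- lag_expand(x, 0L)
  expect_equal(le0$data, x, ignore_attr = TRUE)
  ## brute-force index oracle: 1 feature, T = 10, lags 0..-2
  v <- matrix(1:10, 1, 10)
  le <- lag_expand(v, 0:-2)
  expect_equal(dim(le$data), c(3, 8))
  ## row for lag -2, first retained column (t = sample index 2, 0-based)
  ## must be input sample 0
  expect_equal(unname(le$data[3, 1]), 1)
  oracle <- rbind(3:10, 2:9, 1:8)
  expect_equal(le$data, oracle, ignore_attr = TRUE)
  expect_error(lag_expand(v, c(1L, 0L)), "non-positive")
})

test_that("per-trial embedding drops lag-window samples in every trial", {
  x <- matrix(seq_len(20), 1, 20)
  tr <- rbind(c(0L, 10L), c(10L, 20L))
  le <- lag_expand(x, 0:-3, trials = tr)
  expect_equal(ncol(le$data), 14) # 2 trials x (10 - 3)
  expect_equal(le$keep, c(4:10, 14:20))
  ## no cross-trial leakage: the first column of trial 2 reaches back only
  ## to that trial's first sample
  expect_equal(unname(le$data[, 8]), c(14, 13, 12, 11))
})

test_that("feature/kinematics pairing survives the chain via a marker", {
  ## inject a kinematic-locked marker channel and confirm the lag-expanded
  ## features at lag 0 stay aligned with the subset kinematics
  st <- tiny_shared()
  blk <- st$study$data[[1]][[1]][["0"]]
  kin <- kinematics_matrix(blk$kinematics)
  marker <- kin[2, seq(1, ncol(kin), by = 10)] # v_hor at 20 Hz
  feats <- rbind(marker, 0.5 * marker)
  le <- lag_expand(feats, 0:-2, trials = cbind(0L, length(marker)))
  expect_equal(le$data[1, ], marker[le$keep], ignore_attr = TRUE)
})
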