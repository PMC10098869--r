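test_that("extended kinematics append the stated radicals", {
  z <- rbind(
    p_hor = c(3, 1, 0), v_hor = c(0, 1, 0),
    p_ver = c(4, 1, 0), v_ver = c(0, 1, 0)
  )
  ez <- extend_kinematics(z)
  expect_equal(unname(ez["d", 1]), 5)
  expect_equal(unname(ez["d", 2]), sqrt(2), tolerance = 1e-8)
  expect_equal(unname(ez["s", 3]), 0)
  expect_equal(rownames(ez), c("p_hor", "v_hor", "p_ver", "v_ver", "d", "s"))
})

test_that("pearson correlation follows the definition and its edge cases", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  ## manual arithmetic oracle for (1,2,3,4) vs (2,1,4,3):
  ## covariance sum = 4, sd sums = sqrt(5)*sqrt(5) -> r = 0.6
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_equal(pearson_r(1:5, 6:10), pearson_r(6:10, 1:5))
  expect_warning(r <- pearson_r(rep(1, 5), 1:5), "constant")
  expect_true(is.nan(r))
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("decoding SNR uses 1/n conventions and truth-first asymmetry", {
  set.seed(31)
  x <- rnorm(500)
  ## predicting the mean gives exactly 0 dB under 1/n normalization
  expect_equal(snr_db(x, rep(mean(x), 500)), 0)
  ## scaling the noise by 10 costs exactly 20 dB
  e <- rnorm(500)
  s1 <- snr_db(x, x + 0.1 * e)
  s2 <- snr_db(x, x + 1.0 * e)
  expect_equal(s1 - s2, 20)
  expect_equal(snr_db(x, x), Inf)
  expect_warning(s <- snr_db(rep(2, 9), rnorm(9)), "constant")
  expect_true(is.nan(s))
  ## asymmetric fixture: swapping arguments changes the answer
  y <- 3 * x + 1
  expect_false(isTRUE(all.equal(snr_db(x, y), snr_db(y, x))))
})

test_that("trial shuffling preserves content while breaking pairing", {
  set.seed(33)
  n_tr <- 5
  len <- 40
  Z <- matrix(rnorm(6 * n_tr * len), 6)
  trial_id <- rep(seq_len(n_tr), each = len)
  trials <- split(seq_along(trial_id), trial_id)
  perm <- sample(n_tr)
  idx <- unlist(trials[perm], use.names = FALSE)
  Zp <- Z[, idx]
  ## multiset of trial segments unchanged
  orig <- lapply(trials, function(ii) Z[, ii])
  shuf <- lapply(seq_len(n_tr), function(i) {
    Zp[, ((i - 1) * len + 1):(i * len)]
  })
  for (s in shuf) {
    expect_true(any(vapply(orig, function(o) identical(o, s), TRUE)))
  }
  expect_equal(sort(as.vector(Zp)), sort(as.vector(Z)))
})

test_that("chance threshold errors without enough equal-length trials", {
  Y <- matrix(rnorm(4 * 60), 4)
  Z <- matrix(rnorm(6 * 60), 6)
  expect_error(
    chance_threshold(Y, Z, rep(1, 60), list(), A = 2),
    "at least 2 trials"
  )
  expect_error(
    chance_threshold(Y, Z, rep(c(1, 2), c(20, 40)), list(), A = 2),
    "equal length"
  )
})

test_that("thresholds are monotone in the percentile", {
  x <- c(0.05, 0.12, 0.4, 0.3, 0.21, 0.18, 0.07, 0.33)
  q <- vapply(
    c(0.5, 0.8, 0.95), function(p) trajdec:::.perm_quantile(x, p), 0
  )
  expect_true(all(diff(q) >= 0))
  ## the permutation order statistic: an independent exchangeable draw
  ## falls below the k-th order statistic with probability k/(n+1)
  expect_equal(trajdec:::.perm_quantile(x, 0.95), max(x))
})

test_that("paper-scale chance bookkeeping: 9000 shuffled models", {
  design <- study_design(n_participants = 10)
  n_models <- length(enumerate_unique_models(design))
  expect_equal(n_models, 9)
  expect_equal(10 * 100 * n_models, 9000)
})

test_that("wilcoxon comparisons match exhaustive enumeration and BH", {
  ## differences (+1..+5): exact one-sided p = 1/32, two-sided = 1/16
  d <- c(1, 2, 3, 4, 5)
  p2 <- stats::wilcox.test(d, exact = TRUE)$p.value
  ## brute-force enumeration over all 2^5 sign patterns
  ranks <- rank(abs(d))
  stat_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  stats_all <- as.matrix(signs) %*% ranks
  p_one <- mean(stats_all >= stat_obs)
  expect_equal(p_one, 1 / 32)
  expect_equal(p2, 1 / 16)

  ## manual BH oracle
  p_raw <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p_raw, "BH"), rep(0.04, 4))
})

test_that("strategy comparison table is built and adjusted per family", {
  set.seed(35)
  grid <- expand.grid(
    participant = 1:6, session = 1:2, block = c("0", "50"),
    strategy = c("Gen", "Ind"), space = "sensor",
    kinematic = c("p_hor", "v_hor", "d"), stringsAsFactors = FALSE
  )
  grid$r <- ifelse(grid$strategy == "Ind", 0.5, 0.1) + rnorm(nrow(grid), 0, 0.05)
  grid$snr <- ifelse(grid$strategy == "Ind", -3, -5) + rnorm(nrow(grid), 0, 0.3)
  out <- compare_strategies(grid)
  expect_true(all(c("metric", "group", "p", "p_adj") %in% names(out)))
  expect_true(all(out$p_adj >= out$p - 1e-15))
  ## the strong Ind advantage is detected after FDR adjustment
  pos <- out[out$metric == "abs_r" & out$group == "position", ]
  expect_lt(pos$p_adj, 0.01)
  ## identical distributions yield no rejections
  grid2 <- grid
  grid2$r <- 0.3
  out2 <- compare_strategies(grid2, metrics = "abs_r")
  expect_true(all(is.nan(out2$p)))
})

test_that("block metrics carry identifiers and absolute correlations", {
  set.seed(37)
  truth <- extend_kinematics(kinematics_matrix(gen_snake(10, 20, seed = 1)))
  dec <- truth + matrix(rnorm(length(truth), sd = 0.3), nrow(truth))
  mt <- block_metrics(truth, dec, meta = list(participant = 4, block = "50"))
  expect_equal(nrow(mt), 6)
  expect_equal(mt$abs_r, abs(mt$r))
  expect_true(all(mt$participant == 4))
  expect_true(all(mt$r >= -1 & mt$r <= 1))
  expect_equal(
    as.character(kinematic_group(c("p_hor", "v_ver", "s"))),
    c("position", "velocity", "nonlinear")
  )
})
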