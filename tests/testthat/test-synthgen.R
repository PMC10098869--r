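test_that("lead field has the contracted geometry and ROI structure", {
  lf <- tiny_leadfield()
  expect_equal(dim(lf$gain), c(16, 360))
  expect_equal(nlevels(lf$roi_map), 28)
  expect_true(all(table(lf$roi_map) >= 1))
  expect_true(all(colSums(abs(lf$gain)) > 0))
  ## electrodes on the surface, sources strictly inside
  expect_equal(rowSums(lf$electrode_positions^2), rep(1, 16))
  expect_true(all(rowSums(lf$source_positions^2) <= 0.9^2 + 1e-12))
  ## paper-scale dimensional contract: 60 channels x 5000 locations gives
  ## 15000 source signals
  lf_dims <- gen_leadfield(60, 5000, seed = 1)
  expect_equal(dim(lf_dims$gain), c(60, 15000))
})

test_that("a unit source maps to its gain column and peaks near it", {
  lf <- tiny_leadfield()
  ## single location, unit-amplitude source along y: sensor vector is the
  ## gain column exactly (linearity of the forward model with no noise)
  j <- 17
  src <- rep(0, ncol(lf$gain))
  src[(j - 1) * 3 + 2] <- 1
  expect_equal(drop(lf$gain %*% src), lf$gain[, (j - 1) * 3 + 2])

  ## brute-force distance oracle: for each source, the electrode with the
  ## largest |gain| (over its 3 orientation columns) is among the 5 nearest
  near5 <- function(jloc) {
    d2 <- colSums((t(lf$electrode_positions) -
      lf$source_positions[jloc, ])^2)
    order(d2)[1:5]
  }
  bad <- 0
  for (jloc in seq_len(nrow(lf$source_positions))) {
    g <- abs(lf$gain[, (jloc - 1) * 3 + 1:3])
    peak <- which.max(apply(g, 1, max))
    if (!(peak %in% near5(jloc))) bad <- bad + 1
  }
  expect_lte(bad / nrow(lf$source_positions), 0.02)
})

test_that("lead field errors on invalid configuration", {
  expect_error(gen_leadfield(4, 120), "at least 8")
  expect_error(gen_leadfield(16, 20), "fewer than the 28 ROIs")
})

test_that("snake trajectory is band-limited with exact derivative pairing", {
  fs <- 20
  k <- gen_snake(60, fs, band_hz = c(0.1, 1), seed = 2)
  expect_equal(nrow(k), 1200)
  ## spectral differentiation oracle: the trajectory is periodic over the
  ## block by construction, so the FFT derivative is exact on the grid
  spec_deriv <- function(p, fs) {
    n <- length(p)
    f <- c(0:(n / 2), -((n / 2 - 1):1)) * fs / n
    Re(fft(fft(p) * 2i * pi * f, inverse = TRUE)) / n
  }
  vnum <- spec_deriv(k$p_hor, fs)
  expect_lt(max(abs(vnum - k$v_hor)), 1e-6 * max(abs(k$v_hor)))

  ## periodogram oracle: >= 99% of positional power inside the band
  pw <- Mod(fft(k$p_ver - mean(k$p_ver)))^2
  f <- (seq_along(pw) - 1) / length(pw) * fs
  f <- pmin(f, fs - f)
  inband <- f >= 0.1 - 1e-9 & f <= 1 + 1e-9
  expect_gt(sum(pw[inband]) / sum(pw), 0.99)
  expect_error(gen_snake(-5, 20), "positive")
})

test_that("study regeneration is bit-identical and sample counts are exact", {
  d <- tiny_design()
  s1 <- tiny_shared()$study
  s2 <- gen_study(d, "shared", snr_db = 10, seed = 5)
  expect_identical(
    s1$data[[2]][[1]][["50"]]$recording$data,
    s2$data[[2]][[1]][["50"]]$recording$data
  )
  expect_identical(s1$truth$B, s2$truth$B)
  total <- sum(vapply(
    unlist(unlist(s1$data, recursive = FALSE), recursive = FALSE),
    function(b) ncol(b$recording$data), 0
  ))
  expect_equal(
    total,
    d$duration_s * d$fs * length(d$blocks) * d$n_sessions * d$n_participants
  )
})

test_that("coupling modes control the ground-truth coupling matrices", {
  s_shared <- tiny_shared()$study
  expect_identical(s_shared$truth$B[[1]], s_shared$truth$B[[2]])
  s_ind <- gen_study(tiny_design(), "participant_specific",
    snr_db = 10, seed = 5
  )
  expect_gt(max(abs(s_ind$truth$B[[1]] - s_ind$truth$B[[2]])), 0.01)
  expect_error(
    gen_study(tiny_design(), "drifting", snr_db = 10, seed = 1),
    "arg"
  )
})

test_that("noise-free sensors are exact mixtures of lagged kinematics", {
  st <- tiny_clean()
  blk <- st$data[[1]][[1]][["0"]]
  X <- blk$recording$data
  ## X = G_c B Zlag exactly; its rank is bounded by the lagged-kinematics
  ## rank (12 regressors)
  sv <- svd(X, nu = 0, nv = 0)$d
  expect_lt(sv[13] / sv[1], 1e-9)
})

test_that("sensor noise realizes the requested SNR within 0.5 dB", {
  d <- tiny_design()
  lf <- tiny_leadfield()
  noisy <- gen_study(d, "shared", snr_db = 6, seed = 9, leadfield = lf)
  clean <- gen_study(d, "shared", snr_db = Inf, seed = 9, leadfield = lf)
  xn <- noisy$data[[1]][[1]][["0"]]$recording$data
  xc <- clean$data[[1]][[1]][["0"]]$recording$data
  snr_meas <- 10 * log10(mean(xc^2) / mean((xn - xc)^2))
  expect_lt(abs(snr_meas - 6), 0.5)
})

test_that("background has a 1/f-shaped spectrum", {
  set.seed(1)
  x <- trajdec:::.bg_sensor_noise(matrix(1, 1, 1), 2^14, 200, 45)[1, ]
  pw <- Mod(fft(x))^2
  f <- (seq_along(pw) - 1) / length(pw) * 200
  band_power <- function(lo, hi) mean(pw[f >= lo & f <= hi])
  ## power ~ 1/f: a decade apart means a factor ~10
  ratio <- band_power(0.5, 1) / band_power(5, 10)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
  expect_lt(band_power(50, 80) / band_power(0.5, 1), 1e-6)
  expect_equal(sd(x), 1, tolerance = 0.2)
})

test_that("an OLS decoder transfers across participants when coupling is shared", {
  ## positive control with a strong shared coupling: ordinary least squares
  ## (normal equations) fitted on participant 1 decodes participant 2
  st <- gen_study(tiny_design(coupling_strength = 1), "shared",
    snr_db = 10, seed = 13
  )
  fs <- prepare_features(st, "sensor")
  p1 <- lapply(c("0", "50", "100"), function(b) fs$blocks[[1]][[1]][[b]])
  tr <- list(
    Y = do.call(cbind, lapply(p1, `[[`, "Y")),
    Z = do.call(cbind, lapply(p1, `[[`, "Z"))
  )
  te <- fs$blocks[[2]][[1]][["0"]]
  Xc <- t(tr$Y - rowMeans(tr$Y))
  Zc <- t(tr$Z - rowMeans(tr$Z))
  B <- solve(
    crossprod(Xc) + diag(1e-8 * sum(Xc^2) / ncol(Xc), ncol(Xc)),
    crossprod(Xc, Zc)
  )
  pred <- t(te$Y - rowMeans(tr$Y)) %*% B
  r <- cor(pred[, 2], te$Z["v_hor", ])
  expect_gt(abs(r), 0.8)
})

test_that("a study round-trips through the directory tree", {
  d <- study_design(
    n_participants = 2, n_sessions = 1, n_channels = 8,
    n_locations = 60, n_trials = 2, trial_s = 4
  )
  st <- gen_study(d, "shared", snr_db = 10, seed = 3)
  dir <- tempfile("study")
  write_study(st, dir)
  st2 <- read_study(dir)
  expect_equal(
    st2$data[[1]][[1]][["0"]]$recording$data,
    st$data[[1]][[1]][["0"]]$recording$data,
    tolerance = 1e-12
  )
  expect_equal(
    st2$data[[2]][[1]][["100"]]$kinematics$p_hor,
    st$data[[2]][[1]][["100"]]$kinematics$p_hor,
    tolerance = 1e-12
  )
  expect_equal(st2$leadfield$gain, st$leadfield$gain,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_equal(as.character(st2$leadfield$roi_map),
    as.character(st$leadfield$roi_map))
  unlink(dir, recursive = TRUE)
})
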