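#' Generate a band-limited random pursuit trajectory ("snake")
#'
#' The on-screen target of a pursuit tracking task is modelled as a sum of
#' random-phase sinusoids whose frequencies are drawn inside `band_hz` and
#' snapped to the discrete Fourier grid of the block (`k / duration_s`), so
#' that the trajectory is periodic over the block and its analytic derivative
#' is exact on the sampling grid. Horizontal and vertical dimensions are
#' independent.
#'
#' @param duration_s block duration in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param band_hz length-2 frequency band (Hz); upper edge must be < `fs / 2`.
#' @param seed integer seed.
#' @param n_components sinusoids per dimension.
#' @return object of class `kinematics`: a data frame with columns
#'   `t, p_hor, v_hor, p_ver, v_ver` and attributes `fs` and `trials`
#'   (positions in screen units, velocities in screen units/s).
#' @export
gen_snake <- function(duration_s, fs, band_hz = c(0.1, 1), seed = 1L,
                      n_components = 12L) {
  if (duration_s <= 0) stop("duration must be positive")
  if (band_hz[2] >= fs / 2) stop("band upper edge must be below Nyquist")
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs

  set.seed(derive_seed(seed, 1L))
  one_dim <- function() {
    ## frequencies on the DFT grid of the block
    kmin <- max(1, ceiling(band_hz[1] * duration_s))
    kmax <- floor(band_hz[2] * duration_s)
    if (kmax < kmin) stop("band too narrow for this block duration")
    k <- sample(seq(kmin, kmax), n_components, replace = TRUE)
    f <- k / duration_s
    amp <- stats::runif(n_components, 0.3, 1) / sqrt(n_components)
    ph <- stats::runif(n_components, 0, 2 * pi)
    w <- 2 * pi * f
    p <- drop(sin(outer(tt, w) + rep(ph, each = n)) %*% amp)
    v <- drop(cos(outer(tt, w) + rep(ph, each = n)) %*% (amp * w))
    list(p = p, v = v)
  }
  hor <- one_dim()
  ver <- one_dim()

  out <- data.frame(
    t = tt, p_hor = hor$p, v_hor = hor$v, p_ver = ver$p, v_ver = ver$v
  )
  attr(out, "fs") <- fs
  class(out) <- c("kinematics", "data.frame")
  out
}

#' Kinematics as a 4 x T matrix (p_hor, v_hor, p_ver, v_ver)
#' @param k a `kinematics` data frame.
#' @return numeric matrix with one row per kinematic.
#' @export
kinematics_matrix <- function(k) {
  m <- t(as.matrix(k[, c("p_hor", "v_hor", "p_ver", "v_ver")]))
  rownames(m) <- c("p_hor", "v_hor", "p_ver", "v_ver")
  m
}
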