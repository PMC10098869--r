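#' Signal-conditioning chain for low-frequency trajectory decoding
#'
#' Applies, in order: zero-phase 4th-order Butterworth high-pass at
#' `hp_hz`, polyphase resampling to `mid_fs`, zero-phase 4th-order
#' Butterworth low-pass at `lp_hz`, and polyphase resampling to `out_fs`.
#' Defaults follow the standard low-frequency decoding chain
#' (0.18 Hz high-pass at 200 Hz, 3 Hz low-pass at 100 Hz, output at 20 Hz).
#' Filtering is forward-backward (`signal::filtfilt`) so the chain has no
#' group delay and the sample pairing with the kinematics is preserved.
#' Trial boundaries are rescaled to the output rate.
#'
#' @param recording a `recording` (list with `data` P x T, `fs`, `trials`).
#' @param hp_hz,lp_hz high-/low-pass cutoffs (Hz).
#' @param mid_fs,out_fs intermediate and output sampling rates (Hz).
#' @param order Butterworth order (applied twice by filtfilt).
#' @return the filtered `recording` at `out_fs`.
#' @export
filter_chain <- function(recording, hp_hz = 0.18, mid_fs = 100,
                         lp_hz = 3, out_fs = 20, order = 4L) {
  x <- recording$data
  fs <- recording$fs
  if (hp_hz >= fs / 2) stop("high-pass cutoff at or above Nyquist")
  if (mid_fs > fs) stop("cannot upsample in this chain")
  if (lp_hz >= mid_fs / 2) stop("low-pass cutoff at or above Nyquist")
  if (out_fs > mid_fs) stop("cannot upsample in this chain")

  hp <- signal::butter(order, hp_hz / (fs / 2), type = "high")
  x <- t(apply(x, 1, function(ch) signal::filtfilt(hp, ch)))
  x <- .resample_rows(x, mid_fs, fs)
  lp <- signal::butter(order, lp_hz / (mid_fs / 2), type = "low")
  x <- t(apply(x, 1, function(ch) signal::filtfilt(lp, ch)))
  x <- .resample_rows(x, out_fs, mid_fs)
  if (any(!is.finite(x))) stop("non-finite samples after filtering")

  out <- recording
  out$data <- x
  out$fs <- out_fs
  out$trials <- .rescale_trials(recording$trials, fs, out_fs, ncol(x))
  out
}

## polyphase resampling of each row by the integer ratio to_fs/from_fs
#' @keywords internal
.resample_rows <- function(x, to_fs, from_fs) {
  if (to_fs == from_fs) {
    return(x)
  }
  q <- from_fs / to_fs
  if (abs(q - round(q)) > 1e-9) stop("non-integer resampling ratio")
  t(apply(x, 1, function(ch) signal::resample(ch, p = 1, q = round(q))))
}

#' @keywords internal
.rescale_trials <- function(trials, from_fs, to_fs, n_out) {
  if (is.null(trials)) {
    return(NULL)
  }
  tr <- round(trials * to_fs / from_fs)
  tr[, 2] <- pmin(tr[, 2], n_out)
  tr
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every sample, the
#' usual re-referencing step before source imaging. It is a projection, hence
#' idempotent.
#'
#' @param recording a `recording` with at least 2 channels.
#' @return the re-referenced `recording`.
#' @export
common_average_reference <- function(recording) {
  x <- recording$data
  if (nrow(x) < 2) stop("common average reference needs >= 2 channels")
  recording$data <- sweep(x, 2, colMeans(x))
  recording
}

#' Lag-expand a feature series
#'
#' Stacks each feature vector with its past: column `t` of the output holds
#' the features at `t, t-1, ..., t-(L-1)` (rows grouped by lag, lag 0 first).
#' The embedding is per trial: the first `L - 1` samples of every trial are
#' dropped rather than padded, and the indices of retained columns are
#' returned so the paired kinematics can be subset identically.
#'
#' @param x features as an `F x T` matrix.
#' @param lags non-positive integer lag offsets in samples (default `0:-6`,
#'   i.e. 0 to -300 ms at 20 Hz).
#' @param trials optional trial boundary matrix (0-based half-open); when
#'   `NULL` the whole series is one trial.
#' @return list with `data` (`(L*F) x T_valid` matrix), `keep` (1-based
#'   indices of retained input columns) and `lags`.
#' @export
lag_expand <- function(x, lags = 0:-6, trials = NULL) {
  .assert_matrix(x)
  if (any(lags > 0)) stop("lags must be non-positive (anti-causal)")
  lags <- as.integer(lags)
  lmax <- max(-lags)
  if (lmax >= ncol(x)) stop("largest lag exceeds series length")
  if (is.null(trials)) trials <- cbind(0L, ncol(x))

  keep <- integer(0)
  for (i in seq_len(nrow(trials))) {
    a <- trials[i, 1] + 1L
    b <- trials[i, 2]
    if (b - a + 1L <= lmax) {
      stop(sprintf("trial %d shorter than the lag window", i))
    }
    keep <- c(keep, seq(a + lmax, b))
  }
  out <- matrix(0, length(lags) * nrow(x), length(keep))
  for (j in seq_along(lags)) {
    rows <- (j - 1L) * nrow(x) + seq_len(nrow(x))
    out[rows, ] <- x[, keep + lags[j], drop = FALSE]
  }
  lab <- rownames(x)
  if (is.null(lab)) lab <- sprintf("f%d", seq_len(nrow(x)))
  rownames(out) <- paste0(rep(lab, times = length(lags)),
    "@lag", rep(lags, each = nrow(x))
  )
  list(data = out, keep = keep, lags = lags)
}
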