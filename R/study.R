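#' Study design for the synthetic generator
#'
#' Desk-scale defaults: 8 participants, 3 sessions of 3 blocks (0%, 50% and
#' 100% feedback), 32 channels at 200 Hz, 500 source locations and 5 trials of
#' 24 s per block. The feedback percentage is a block label only: offline, all
#' blocks are generated by the same law and the label decides how the blocks
#' are used by the update strategies.
#'
#' @param n_participants,n_sessions,n_channels,n_locations study sizes.
#' @param blocks block labels within each session.
#' @param fs acquisition rate (Hz).
#' @param n_trials,trial_s trials per block and trial length (s); the block
#'   duration is their product.
#' @param band_hz kinematic band of the snake trajectory.
#' @param coupling_rois ROI labels whose sources carry the kinematic coupling.
#' @param coupling_strength standard deviation of coupled source activity
#'   relative to the unit-variance background.
#' @param drift_angle_deg per-session rotation of the coupling matrix used by
#'   `coupling_mode = "session_drift"`.
#' @param bg_max_hz upper edge of the 1/f background spectrum (Hz).
#' @return a list of class `study_design`.
#' @export
study_design <- function(n_participants = 8L, n_sessions = 3L,
                         blocks = c("0", "50", "100"),
                         n_channels = 32L, n_locations = 500L, fs = 200,
                         n_trials = 5L, trial_s = 24,
                         band_hz = c(0.1, 1),
                         coupling_rois = c(
                           "L_PCL", "R_PCL", "L_aPCU", "R_aPCU",
                           "L_pPCU", "R_pPCU", "L_CU", "R_CU"
                         ),
                         coupling_strength = 0.25,
                         drift_angle_deg = 15, bg_max_hz = 45) {
  d <- list(
    n_participants = as.integer(n_participants),
    n_sessions = as.integer(n_sessions), blocks = as.character(blocks),
    n_channels = as.integer(n_channels),
    n_locations = as.integer(n_locations), fs = fs,
    n_trials = as.integer(n_trials), trial_s = trial_s,
    duration_s = as.integer(n_trials) * trial_s,
    band_hz = band_hz, coupling_rois = coupling_rois,
    coupling_strength = coupling_strength,
    drift_angle_deg = drift_angle_deg, bg_max_hz = bg_max_hz,
    gen_lags_s = c(0, -0.15, -0.3)
  )
  class(d) <- "study_design"
  d
}

## Sensor-level 1/f background: every background source carries independent
## unit-variance Gaussian noise with an f^-1 power spectrum inside
## [1/duration, bg_max_hz]. Because the mixing is linear, the sources'
## Hermitian half-spectra are drawn, mixed through the gain matrix in the
## frequency domain and inverse-transformed once per channel - identically
## distributed to per-source time-domain synthesis, at a fraction of the
## cost.
#' @keywords internal
.bg_sensor_noise <- function(G_bg, n, fs, bg_max_hz) {
  P <- nrow(G_bg)
  m <- ncol(G_bg)
  kmax <- min(floor(bg_max_hz * n / fs), floor(n / 2) - 1L)
  k <- seq_len(kmax)
  g <- 1 / sqrt(k) # amplitude ~ f^(-1/2) -> power ~ 1/f
  g <- g / sqrt(4 * sum(g^2) / n^2) # unit variance per source
  ## half-spectra of all background sources: kmax x m complex
  H <- matrix(complex(
    real = stats::rnorm(kmax * m), imaginary = stats::rnorm(kmax * m)
  ), kmax, m) * g
  Xf <- matrix(0 + 0i, n, P)
  Hs <- G_bg %*% t(H) # P x kmax mixed spectra
  Xf[k + 1L, ] <- t(Hs)
  Xf[n + 1L - k, ] <- Conj(t(Hs))
  t(Re(stats::mvfft(Xf, inverse = TRUE)) / n)
}

## lag-embed the 4 kinematics circularly at generator lags (samples)
#' @keywords internal
.gen_lagged_kin <- function(kin_mat, lag_samples) {
  n <- ncol(kin_mat)
  do.call(rbind, lapply(lag_samples, function(l) {
    idx <- ((seq_len(n) - 1 + l) %% n) + 1
    kin_mat[, idx, drop = FALSE]
  }))
}

## random coupling matrix: coupled source signals x lagged kinematics
#' @keywords internal
.random_coupling <- function(n_src, n_reg) {
  B <- matrix(stats::rnorm(n_src * n_reg), n_src, n_reg)
  B / sqrt(rowSums(B^2)) # unit-norm rows -> unit-variance activity for
  # whitened regressors (approximately; rescaled per block below)
}

## rotate coupling coefficients by an angle in successive coordinate planes
#' @keywords internal
.rotate_coupling <- function(B, angle_deg) {
  th <- angle_deg * pi / 180
  n <- ncol(B)
  for (j in seq(1, n - 1, by = 2)) {
    cj <- B[, j]
    sj <- B[, j + 1]
    B[, j] <- cos(th) * cj - sin(th) * sj
    B[, j + 1] <- sin(th) * cj + cos(th) * sj
  }
  B
}

#' Generate a synthetic multi-participant, multi-session study
#'
#' Implements the generative sensor model `X = G J + n`: source activity `J`
#' is a linear read-out of lagged snake kinematics inside the designated
#' coupling ROIs and 1/f-shaped Gaussian background elsewhere; sensor noise is
#' white and scaled to a requested SNR against the noiseless sensor signal.
#' The coupling matrix is shared across participants, drawn independently per
#' participant, or rotated per session, which is the knob that makes
#' across-participant and across-session transfer succeed or fail by
#' construction.
#'
#' @param design a [study_design()].
#' @param coupling_mode one of `"shared"`, `"participant_specific"`,
#'   `"session_drift"`.
#' @param snr_db sensor SNR in dB (`Inf` disables sensor noise).
#' @param seed integer seed; regeneration with the same seed is bit-identical.
#' @param leadfield optional pre-built [gen_leadfield()] result.
#' @param background if `FALSE`, the 1/f background source activity is
#'   suppressed and the sensors carry only the coupled sources (plus sensor
#'   noise); useful for exact-linearity checks.
#' @return object of class `synth_study`: `design`, `leadfield`, `truth`
#'   (coupling matrices, noise levels, seed) and
#'   `data[[participant]][[session]][[block]]`, each holding a `recording`
#'   (list: `data` P x T, `fs`, `channels`, `trials` 0-based half-open) and a
#'   `kinematics` frame.
#' @export
gen_study <- function(design = study_design(),
                      coupling_mode = c(
                        "shared", "participant_specific", "session_drift"
                      ),
                      snr_db = 10, seed = 1L, leadfield = NULL,
                      background = TRUE) {
  coupling_mode <- match.arg(coupling_mode)
  d <- design
  if (is.null(leadfield)) {
    leadfield <- gen_leadfield(d$n_channels, d$n_locations,
      seed = derive_seed(seed, 100L)
    )
  }
  G <- leadfield$gain
  coupled_cols <- .roi_columns(leadfield, d$coupling_rois)
  if (length(coupled_cols) == 0) stop("no sources in the coupling ROIs")
  bg_cols <- setdiff(seq_len(ncol(G)), coupled_cols)
  lag_samples <- round(d$gen_lags_s * d$fs)
  n_reg <- 4L * length(lag_samples)

  ## ground-truth couplings
  set.seed(derive_seed(seed, 200L))
  B_shared <- .random_coupling(length(coupled_cols), n_reg)
  truth_B <- vector("list", d$n_participants)
  for (p in seq_len(d$n_participants)) {
    truth_B[[p]] <- switch(coupling_mode,
      shared = B_shared,
      participant_specific = .random_coupling(length(coupled_cols), n_reg),
      session_drift = B_shared
    )
  }

  n_samp <- round(d$duration_s * d$fs)
  trial_len <- round(d$trial_s * d$fs)
  trials <- cbind(
    start = (seq_len(d$n_trials) - 1L) * trial_len,
    end = seq_len(d$n_trials) * trial_len
  )
  chan_labels <- sprintf("CH%02d", seq_len(d$n_channels))
  noise_sd <- matrix(NA_real_, d$n_participants,
    d$n_sessions * length(d$blocks),
    dimnames = list(NULL, NULL)
  )

  data <- vector("list", d$n_participants)
  blk_counter <- 0L
  for (p in seq_len(d$n_participants)) {
    data[[p]] <- vector("list", d$n_sessions)
    for (s in seq_len(d$n_sessions)) {
      Bp <- truth_B[[p]]
      if (coupling_mode == "session_drift" && s > 1) {
        Bp <- .rotate_coupling(Bp, d$drift_angle_deg * (s - 1))
      }
      data[[p]][[s]] <- vector("list", length(d$blocks))
      names(data[[p]][[s]]) <- d$blocks
      for (b in seq_along(d$blocks)) {
        blk_counter <- blk_counter + 1L
        kin <- gen_snake(d$duration_s, d$fs, d$band_hz,
          seed = derive_seed(seed, 1000L + blk_counter)
        )
        Zl <- .gen_lagged_kin(kinematics_matrix(kin), lag_samples)
        ## whiten regressors so coupled activity has unit scale, then apply
        ## the coupling strength
        Zl <- Zl / pmax(apply(Zl, 1, stats::sd), .Machine$double.eps)
        Jc <- (Bp %*% Zl) * d$coupling_strength

        set.seed(derive_seed(seed, 5000L + blk_counter))
        X <- G[, coupled_cols, drop = FALSE] %*% Jc
        if (background) {
          X <- X + .bg_sensor_noise(
            G[, bg_cols, drop = FALSE], n_samp, d$fs, d$bg_max_hz
          )
        }
        if (is.finite(snr_db)) {
          p_sig <- mean(X^2)
          sd_n <- sqrt(p_sig * 10^(-snr_db / 10))
          X <- X + matrix(
            stats::rnorm(length(X), sd = sd_n), nrow(X), ncol(X)
          )
        } else {
          sd_n <- 0
        }
        noise_sd[p, (s - 1L) * length(d$blocks) + b] <- sd_n
        rec <- list(
          data = X, fs = d$fs, channels = chan_labels, trials = trials
        )
        class(rec) <- "recording"
        kin$trial <- rep(seq_len(d$n_trials), each = trial_len)
        attr(kin, "trials") <- trials
        data[[p]][[s]][[b]] <- list(recording = rec, kinematics = kin)
      }
    }
  }

  structure(
    list(
      design = d, leadfield = leadfield,
      truth = list(
        coupling_mode = coupling_mode, B = truth_B,
        coupled_columns = coupled_cols, snr_db = snr_db,
        noise_sd = noise_sd, seed = seed
      ),
      data = data
    ),
    class = "synth_study"
  )
}

#' @export
print.synth_study <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    paste0(
      "Synthetic pursuit-tracking study\n",
      "  %d participants x %d sessions x %d blocks (%s%% feedback)\n",
      "  %d channels @ %g Hz, %d source locations, %d x %g s trials/block\n",
      "  coupling: %s in %d ROIs, sensor SNR %g dB, seed %d\n"
    ),
    d$n_participants, d$n_sessions, length(d$blocks),
    paste(d$blocks, collapse = "/"), d$n_channels, d$fs, d$n_locations,
    d$n_trials, d$trial_s, x$truth$coupling_mode,
    length(d$coupling_rois), x$truth$snr_db, x$truth$seed
  ))
  invisible(x)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "Recording: %d channels x %d samples @ %g Hz, %d trials\n",
    nrow(x$data), ncol(x$data), x$fs, nrow(x$trials)
  ))
  invisible(x)
}
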