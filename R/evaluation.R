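#' Extend linear kinematics with distance and speed
#'
#' Appends the non-directional kinematics `d = sqrt(p_hor^2 + p_ver^2)` and
#' `s = sqrt(v_hor^2 + v_ver^2)` to the 4 linear kinematics.
#'
#' @param z `4 x T` matrix with rows `p_hor, v_hor, p_ver, v_ver` (or a
#'   `kinematics` frame).
#' @return `6 x T` matrix with rows `p_hor, v_hor, p_ver, v_ver, d, s`.
#' @export
extend_kinematics <- function(z) {
  if (inherits(z, "kinematics")) z <- kinematics_matrix(z)
  .assert_matrix(z)
  if (nrow(z) != 4) stop("expected 4 linear kinematics")
  out <- rbind(
    z,
    d = sqrt(z[1, ]^2 + z[3, ]^2),
    s = sqrt(z[2, ]^2 + z[4, ]^2)
  )
  rownames(out) <- c("p_hor", "v_hor", "p_ver", "v_ver", "d", "s")
  out
}

#' Pearson correlation between a decoded and a true signal
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return correlation in `[-1, 1]`; `NaN` with a warning when either input
#'   is constant.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for constant input")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Decoding SNR in decibels
#'
#' `10 log10(var(x) / MSE(x, y))` with both the variance and the mean squared
#' error normalized by `1/n`, so that predicting the constant mean of the
#' truth gives exactly 0 dB. The truth is the first argument; the measure is
#' deliberately asymmetric.
#'
#' @param x_truth ground-truth signal; @param y_decoded decoded signal.
#' @return SNR in dB; `Inf` when the decoding is exact, `NaN` with a warning
#'   when the truth is constant.
#' @export
snr_db <- function(x_truth, y_decoded) {
  if (length(x_truth) != length(y_decoded) || length(x_truth) < 2) {
    stop("inputs must have equal length >= 2")
  }
  v <- mean((x_truth - mean(x_truth))^2)
  mse <- mean((x_truth - y_decoded)^2)
  if (v == 0) {
    warning("SNR undefined for constant truth")
    return(NaN)
  }
  if (mse == 0) {
    return(Inf)
  }
  10 * log10(v / mse)
}

#' Trial-shuffled chance-level thresholds for one decoder
#'
#' Breaks the feature-kinematics relationship by permuting the assignment of
#' whole kinematic trials to feature trials (trials must have equal length),
#' retrains the PLS + SR-UKF cascade on each shuffled pairing (with the
#' matched model's component count; no per-shuffle knee re-selection) and
#' applies it to the evaluation blocks. Because the features are untouched,
#' the feature autocovariance and the response means are permutation
#' invariant; only the cross-covariance is recomputed per repeat, which keeps
#' the procedure fast. Per kinematic, the per-repeat statistic is the median
#' |r| over evaluation blocks; the threshold is the upper permutation
#' quantile (order statistic `ceiling(p (n+1))`) over repeats.
#'
#' @param Ytr,Ztr training features (`d x n`) and extended kinematics
#'   (`6 x n`).
#' @param trial_id integer trial label per training column.
#' @param eval_blocks list of evaluation blocks, each `list(Y = , Z = )`.
#' @param A component count of the matched model.
#' @param n_repeats shuffles (default 100); @param percentile threshold
#'   percentile (default 95).
#' @param seed integer seed; @param lambda forgetting factor.
#' @param q_scale process-noise scale reused from the matched model (like
#'   `A`, not re-calibrated per shuffle; `NULL` re-calibrates).
#' @return list with `thresholds` (per kinematic), `dist`
#'   (`n_repeats x 6` matrix of chance statistics) and `n_repeats`.
#' @export
chance_threshold <- function(Ytr, Ztr, trial_id, eval_blocks, A,
                             n_repeats = 100L, percentile = 95,
                             seed = 1L, lambda = 1, q_scale = NULL) {
  trials <- split(seq_along(trial_id), trial_id)
  if (length(trials) < 2) stop("need at least 2 trials to permute")
  len <- lengths(trials)
  if (length(unique(len)) != 1) stop("trials must have equal length")

  state0 <- cov_update(cov_state(nrow(Ytr), nrow(Ztr), lambda), Ytr, Ztr)
  kin <- rownames(Ztr)
  if (is.null(kin)) kin <- sprintf("k%d", seq_len(nrow(Ztr)))
  dist <- matrix(NA_real_, n_repeats, nrow(Ztr), dimnames = list(NULL, kin))
  set.seed(derive_seed(seed, 42L))
  for (rep_i in seq_len(n_repeats)) {
    perm <- sample(length(trials))
    idx <- unlist(trials[perm], use.names = FALSE)
    Zp <- Ztr[, idx, drop = FALSE]
    st <- state0
    st$C_yz <- tcrossprod(Ytr, Zp) # features fixed; cross term refreshed
    st$s_z <- rowSums(Zp)
    model <- tryCatch(
      {
        pls <- suppressWarnings(rewpls_fit(st, A))
        E <- predict(pls, Ytr, type = "scores")
        list(pls = pls, ukf = srukf(E, Zp, q_scale = q_scale))
      },
      error = function(e) NULL
    )
    if (is.null(model)) next
    rr <- sapply(eval_blocks, function(b) {
      sc <- predict(model$pls, b$Y, type = "scores")
      zh <- suppressWarnings(predict(model$ukf, sc))
      vapply(seq_len(nrow(b$Z)), function(k) {
        abs(suppressWarnings(pearson_r(b$Z[k, ], zh[k, ])))
      }, 0)
    })
    dist[rep_i, ] <- apply(matrix(rr, nrow = nrow(Ztr)), 1, stats::median,
      na.rm = TRUE
    )
  }
  ok <- stats::complete.cases(dist)
  thr <- apply(dist[ok, , drop = FALSE], 2, .perm_quantile,
    p = percentile / 100
  )
  list(thresholds = thr, dist = dist, n_repeats = n_repeats,
    percentile = percentile
  )
}

#' Group-level chance thresholds across participants
#'
#' Applies [chance_threshold()] to each participant's matched training pool
#' and evaluation blocks and takes the median across participants, the
#' group-level chance definition used throughout the evaluation.
#'
#' @param per_participant list (one element per participant) of lists with
#'   `Ytr, Ztr, trial_id, eval_blocks, A` (optionally `q_scale`).
#' @param ... passed to [chance_threshold()].
#' @param seed integer seed (fanned out per participant).
#' @return list with `group` (median threshold per kinematic) and
#'   `participant` (matrix participants x kinematics).
#' @export
chance_level <- function(per_participant, ..., seed = 1L) {
  per <- lapply(seq_along(per_participant), function(i) {
    p <- per_participant[[i]]
    chance_threshold(p$Ytr, p$Ztr, p$trial_id, p$eval_blocks, p$A,
      seed = derive_seed(seed, 7000L + i), q_scale = p$q_scale, ...
    )$thresholds
  })
  pm <- do.call(rbind, per)
  list(group = apply(pm, 2, stats::median), participant = pm)
}

#' Metric table over decoded blocks
#'
#' @param truth,decoded `6 x T` matrices of extended kinematics.
#' @param meta named list of identifying columns (participant, session, ...).
#' @return data frame with one row per kinematic and columns `r`, `abs_r`,
#'   `snr`.
#' @export
block_metrics <- function(truth, decoded, meta = list()) {
  kin <- rownames(truth)
  rows <- lapply(seq_len(nrow(truth)), function(k) {
    r <- suppressWarnings(pearson_r(truth[k, ], decoded[k, ]))
    data.frame(
      kinematic = kin[k], r = r, abs_r = abs(r),
      snr = suppressWarnings(snr_db(truth[k, ], decoded[k, ]))
    )
  })
  out <- do.call(rbind, rows)
  for (nm in rev(names(meta))) out <- cbind(stats::setNames(
    data.frame(meta[[nm]]), nm
  ), out)
  out
}

#' Kinematic grouping used for strategy comparisons
#' @param kinematic character vector of kinematic names.
#' @return factor with levels position, velocity, nonlinear.
#' @export
kinematic_group <- function(kinematic) {
  g <- ifelse(kinematic %in% c("p_hor", "p_ver"), "position",
    ifelse(kinematic %in% c("v_hor", "v_ver"), "velocity", "nonlinear")
  )
  factor(g, levels = c("position", "velocity", "nonlinear"))
}

#' Pairwise strategy comparisons (Wilcoxon signed rank + FDR)
#'
#' For each metric and kinematic group, every pair of strategy x feature
#' space conditions is compared with a two-tailed paired Wilcoxon signed-rank
#' test over the common (participant, session, block, kinematic) cells
#' (absolute correlations for `r`), and the p-values are Benjamini-Hochberg
#' adjusted within the family of all pairwise comparisons of that metric and
#' kinematic group. Degenerate all-zero-difference pairs report `NaN`.
#'
#' @param metric_table data frame from [block_metrics()] rows with columns
#'   `participant, session, block, strategy, space, kinematic, r, snr`.
#' @param metrics which metrics to compare.
#' @return data frame with columns `metric, group, cond1, cond2, p, p_adj`.
#' @export
compare_strategies <- function(metric_table, metrics = c("abs_r", "snr")) {
  mt <- metric_table
  if (!"abs_r" %in% names(mt)) mt$abs_r <- abs(mt$r)
  mt$kin_group <- kinematic_group(mt$kinematic)
  mt$cond <- paste(mt$strategy, mt$space, sep = ".")
  key <- c("participant", "session", "block", "kinematic")
  out <- NULL
  for (metric in metrics) {
    for (g in levels(mt$kin_group)) {
      sub <- mt[mt$kin_group == g, , drop = FALSE]
      conds <- sort(unique(sub$cond))
      if (length(conds) < 2) next
      rows <- NULL
      for (i in seq_along(conds)) {
        for (j in seq_along(conds)) {
          if (j <= i) next
          a <- sub[sub$cond == conds[i], c(key, metric)]
          b <- sub[sub$cond == conds[j], c(key, metric)]
          mrg <- merge(a, b, by = key)
          d <- mrg[[paste0(metric, ".x")]] - mrg[[paste0(metric, ".y")]]
          d <- d[is.finite(d)]
          p <- if (length(d) < 1 || all(d == 0)) {
            NaN
          } else {
            suppressWarnings(stats::wilcox.test(d, exact = NULL)$p.value)
          }
          rows <- rbind(rows, data.frame(
            metric = metric, group = g, cond1 = conds[i], cond2 = conds[j],
            n = length(d), p = p
          ))
        }
      }
      rows$p_adj <- stats::p.adjust(rows$p, method = "BH")
      out <- rbind(out, rows)
    }
  }
  out
}
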