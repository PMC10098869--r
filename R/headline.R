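#' Run the transfer-learning headline protocol on a synthetic study
#'
#' End-to-end positive/negative control for across-participant transfer:
#' generates a study under the requested coupling mode, extracts
#' sensor-space features, and for every participant trains the
#' leave-one-participant-out model, runs the `Gen` and (optionally) `Ind`
#' strategies, and estimates the trial-shuffled chance thresholds of the
#' generalized model. Reported are the group medians of the absolute
#' correlations of the four linear kinematics and the group-median chance
#' threshold.
#'
#' With `coupling_mode = "participant_specific"` the generalized model has
#' nothing transferable to learn and its median falls below the chance
#' threshold while the individual models stay above it; with
#' `coupling_mode = "shared"` the generalized model itself beats chance.
#'
#' @param coupling_mode passed to [gen_study()].
#' @param seed integer seed.
#' @param design a [study_design()]; defaults to the desk-scale design.
#' @param strategies strategies to run (subset of `Gen`, `GenC`, `Ind`,
#'   `IndC`).
#' @param n_repeats chance shuffles per participant.
#' @param space feature space.
#' @return list with `gen_median`, `ind_median` (linear kinematics, 50%/100%
#'   blocks; `NA` when `Ind` not run), `chance_median`, per-participant
#'   thresholds and the full metric table.
#' @export
run_headline <- function(coupling_mode, seed = 1L, design = study_design(),
                         strategies = c("Gen", "Ind"), n_repeats = 20L,
                         space = "sensor") {
  study <- gen_study(design, coupling_mode, snr_db = 10, seed = seed)
  fstudy <- prepare_features(study, space)
  rm(study)
  mt <- NULL
  thr <- NULL
  for (p in seq_len(design$n_participants)) {
    lopo <- train_lopo(fstudy, p)
    runs <- lapply(strategies, function(s) {
      run_strategy(fstudy, p, s, lopo)
    })
    mt <- rbind(mt, strategy_metrics(runs))
    eval_blocks <- unlist(lapply(seq_len(design$n_sessions), function(s) {
      lapply(design$blocks, function(b) {
        fstudy$blocks[[p]][[s]][[b]][c("Y", "Z")]
      })
    }), recursive = FALSE)
    ch <- chance_threshold(
      lopo$pool$Y, lopo$pool$Z, lopo$pool$trial_id, eval_blocks,
      A = lopo$model$A, n_repeats = n_repeats,
      seed = derive_seed(seed, 600L + p),
      q_scale = lopo$model$ukf$q_scale
    )
    thr <- rbind(thr, ch$thresholds)
  }
  lin <- c("p_hor", "v_hor", "p_ver", "v_ver")
  group_thr <- apply(thr, 2, stats::median)
  gen_median <- stats::median(
    mt[mt$strategy == "Gen" & mt$kinematic %in% lin, "abs_r"]
  )
  ind_median <- if ("Ind" %in% strategies) {
    stats::median(mt[
      mt$strategy == "Ind" & mt$kinematic %in% lin & mt$block != "0",
      "abs_r"
    ])
  } else {
    NA_real_
  }
  list(
    coupling_mode = coupling_mode,
    gen_median = gen_median, ind_median = ind_median,
    chance_median = stats::median(group_thr[lin]),
    chance_thresholds = thr, metrics = mt
  )
}

#' Monte-Carlo calibration of the trial-shuffled chance threshold
#'
#' Replicates a null experiment in which features and kinematics are
#' independent by construction: per replicate, a matched cascade is trained
#' on an (identity-paired) feature/kinematics set and its per-kinematic
#' statistic is compared against the [chance_threshold()] built from
#' `n_repeats` trial shuffles of the same data. Under exchangeability the
#' matched statistic falls below the threshold with probability
#' `k / (n_repeats + 1)` where `k` is the threshold order statistic; with
#' the upper permutation quantile at the 95th percentile the expected
#' coverage is close to 0.95.
#'
#' @param n_replicates number of independent null replicates.
#' @param n_repeats shuffles per replicate.
#' @param seed integer seed.
#' @param A components of every fitted cascade.
#' @return list with `coverage` (proportion of matched statistics below
#'   threshold, pooled over kinematics) and the per-replicate matrix.
#' @export
chance_calibration <- function(n_replicates = 200L, n_repeats = 20L,
                               seed = 1L, A = 3L) {
  one <- function(rep_seed) {
    set.seed(rep_seed)
    n_tr <- 6L
    len <- 100L
    n <- n_tr * len
    d <- 12L
    smooth_noise <- function(nc) {
      t(apply(matrix(stats::rnorm(d * nc), d, nc), 1, function(x) {
        stats::filter(x, rep(1, 5) / 5, circular = TRUE)
      }))
    }
    Y <- smooth_noise(n)
    Z <- extend_kinematics(gen_snake(n / 20, 20, seed = rep_seed + 1e5))
    trial_id <- rep(seq_len(n_tr), each = len)
    eval_blocks <- lapply(1:2, function(i) {
      list(
        Y = smooth_noise(200),
        Z = extend_kinematics(gen_snake(10, 20, seed = rep_seed + i * 2e5))
      )
    })
    ch <- chance_threshold(Y, Z, trial_id, eval_blocks,
      A = A,
      n_repeats = n_repeats, seed = rep_seed
    )
    st <- cov_update(cov_state(d, 6L), Y, Z)
    pls <- rewpls_fit(st, A)
    ukf <- srukf(predict(pls, Y, type = "scores"), Z)
    rr <- sapply(eval_blocks, function(b) {
      zh <- suppressWarnings(
        predict(ukf, predict(pls, b$Y, type = "scores"))
      )
      vapply(seq_len(6), function(k) {
        abs(suppressWarnings(pearson_r(b$Z[k, ], zh[k, ])))
      }, 0)
    })
    matched <- apply(rr, 1, stats::median)
    matched < ch$thresholds
  }
  below <- vapply(
    seq_len(n_replicates),
    function(i) one(derive_seed(seed, 3000L + i)), logical(6)
  )
  list(
    coverage = mean(below), per_replicate = t(below),
    n_replicates = n_replicates, n_repeats = n_repeats
  )
}
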