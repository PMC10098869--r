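#' Prepare decoder features for every block of a study
#'
#' Runs the signal-conditioning chain and common average reference on every
#' recording, extracts sensor-space (preprocessed channels) or source-space
#' (sLORETA + ROI scouting, see [project_features()]) features, lag-expands
#' them per trial, and pairs them sample-by-sample with the extended snake
#' kinematics (downsampled to the feature rate by strided decimation, which
#' is exact for the band-limited snake). The result is the unit every update
#' strategy operates on.
#'
#' @param study a [gen_study()] result.
#' @param space `"sensor"` or `"source"`.
#' @param lags lag offsets in samples at the output rate (default `0:-6`).
#' @param noise_cov sensor noise covariance for the inverse kernel (identity
#'   when `NULL`).
#' @param alpha sLORETA regularization (`NULL` = SNR heuristic).
#' @param out_fs feature sampling rate after the chain (Hz).
#' @return object of class `feature_study`: `design`, `space` and
#'   `blocks[[participant]][[session]][[block]]`, each with `Y` (d x T
#'   lag-expanded features), `Z` (6 x T extended kinematics) and `trial_id`.
#' @export
prepare_features <- function(study, space = c("sensor", "source"),
                             lags = 0:-6, noise_cov = NULL, alpha = NULL,
                             out_fs = 20) {
  space <- match.arg(space)
  d <- study$design
  kernel <- scouting <- NULL
  if (space == "source") {
    kernel <- sloreta_kernel(study$leadfield, noise_cov, alpha)
    scouting <- build_scouting_matrix(study$leadfield)
  }
  dec <- round(d$fs / out_fs)
  blocks <- lapply(study$data, function(psess) {
    lapply(psess, function(sblocks) {
      lapply(sblocks, function(blk) {
        rec <- filter_chain(blk$recording, out_fs = out_fs)
        rec <- common_average_reference(rec)
        feat <- if (space == "sensor") {
          x <- rec$data
          rownames(x) <- rec$channels
          x
        } else {
          project_features(rec, kernel, scouting)
        }
        kin <- kinematics_matrix(blk$kinematics)
        kin <- kin[, seq(1, ncol(kin), by = dec), drop = FALSE]
        n <- min(ncol(feat), ncol(kin))
        le <- lag_expand(feat[, seq_len(n), drop = FALSE],
          lags = lags, trials = .rescale_trials(rec$trials, 1, 1, n)
        )
        Z <- extend_kinematics(kin[, le$keep, drop = FALSE])
        trial_len <- rec$trials[1, 2] - rec$trials[1, 1]
        trial_id <- findInterval(le$keep - 1L, rec$trials[, 1])
        list(Y = le$data, Z = Z, trial_id = trial_id)
      })
    })
  })
  structure(
    list(design = d, space = space, blocks = blocks, lags = lags,
      kernel = kernel, scouting = scouting, out_fs = out_fs
    ),
    class = "feature_study"
  )
}

## pool selected blocks of a feature study into one Y/Z/trial_id triple;
## sel is a data frame with columns p, s, b
#' @keywords internal
.pool_blocks <- function(fstudy, sel) {
  Ys <- list()
  Zs <- list()
  tid <- list()
  off <- 0L
  for (i in seq_len(nrow(sel))) {
    blk <- fstudy$blocks[[sel$p[i]]][[sel$s[i]]][[as.character(sel$b[i])]]
    Ys[[i]] <- blk$Y
    Zs[[i]] <- blk$Z
    tid[[i]] <- blk$trial_id + off
    off <- off + max(blk$trial_id)
  }
  list(
    Y = do.call(cbind, Ys), Z = do.call(cbind, Zs),
    trial_id = unlist(tid)
  )
}

#' Train the leave-one-participant-out generalized decoder
#'
#' Pools the calibration (0% feedback) block of the first session of every
#' participant except the held-out one, accumulates the covariance state at
#' `lambda = 1` and fits the cascade with a knee-selected component count.
#'
#' @param fstudy a [prepare_features()] result.
#' @param held_out participant index excluded from the pool.
#' @param A fixed component count (`NULL` = knee selection).
#' @param A_max,folds passed to [select_components()].
#' @return list with `model` (a `traj_decoder`) and the training `pool`
#'   (`Y`, `Z`, `trial_id`).
#' @export
train_lopo <- function(fstudy, held_out, A = NULL, A_max = 50L,
                       folds = 10L) {
  np <- fstudy$design$n_participants
  if (np < 2) stop("leave-one-participant-out needs >= 2 participants")
  if (!held_out %in% seq_len(np)) stop("held-out participant not in study")
  sel <- data.frame(
    p = setdiff(seq_len(np), held_out), s = 1L,
    b = fstudy$design$blocks[1]
  )
  pool <- .pool_blocks(fstudy, sel)
  model <- traj_decoder(pool$Y, pool$Z, A = A, A_max = A_max, folds = folds)
  list(model = model, pool = pool)
}

#' Names of the unique decoder models in a study design
#'
#' The four update strategies share refits: the generalized model `Gen`, its
#' cumulative updates `GenC1..GenCS`, the per-session individual models
#' `Ind1..IndS`, and the cumulative individual models `IndC2..IndCS`
#' (`IndC1` coincides with `Ind1` and is not counted twice). A 3-session
#' design yields 9 unique models.
#'
#' @param design a [study_design()] (only `n_sessions` is used).
#' @return character vector of model names.
#' @export
enumerate_unique_models <- function(design) {
  S <- design$n_sessions
  c(
    "Gen", paste0("GenC", seq_len(S)), paste0("Ind", seq_len(S)),
    if (S >= 2) paste0("IndC", 2:S)
  )
}

#' Run one update strategy for one participant
#'
#' Simulates the online session sequence: every 0% feedback block is decoded
#' with the model carried in from before that block, the model is then
#' updated at the end of the 0% block according to the strategy, and the
#' updated model decodes the remaining blocks of the session and the next
#' session's 0% block.
#'
#' * `Gen` - the LOPO model everywhere, never updated.
#' * `GenC` - the LOPO pool cumulatively extended (`lambda = 1`) with the
#'   participant's own 0% blocks; refit after each.
#' * `Ind` - a fresh model from the current session's 0% block alone.
#' * `IndC` - a model from the participant's 0% blocks of sessions 1..s.
#'
#' Both cascade stages are refit from the cumulative pool at every update,
#' with the component count re-selected at the knee (unless `A` is fixed).
#'
#' @param fstudy a [prepare_features()] result.
#' @param participant participant index.
#' @param strategy one of `"Gen", "GenC", "Ind", "IndC"`.
#' @param lopo result of [train_lopo()] for this participant.
#' @param A fixed component count (`NULL` = knee selection at every refit).
#' @param A_max,folds passed to [select_components()].
#' @return object of class `strategy_run`: `decoded` (per block: `zhat`,
#'   `truth`, `model` name), `registry` (named list of fitted models) and
#'   `training` (named list of training pools per model).
#' @export
run_strategy <- function(fstudy, participant,
                         strategy = c("Gen", "GenC", "Ind", "IndC"),
                         lopo, A = NULL, A_max = 50L, folds = 10L) {
  strategy <- match.arg(strategy)
  d <- fstudy$design
  blocks <- d$blocks
  refit <- function(pool) {
    traj_decoder(pool$Y, pool$Z, A = A, A_max = A_max, folds = folds)
  }
  model <- lopo$model
  model_name <- "Gen"
  registry <- list(Gen = model)
  training <- list(Gen = lopo$pool)
  own <- list() # the participant's 0% pools, in session order
  decoded <- list()

  for (s in seq_len(d$n_sessions)) {
    for (b in blocks) {
      blk <- fstudy$blocks[[participant]][[s]][[b]]
      zhat <- predict(model, blk$Y)
      decoded[[sprintf("s%d.b%s", s, b)]] <- list(
        zhat = zhat, truth = blk$Z, model = model_name,
        session = s, block = b
      )
      if (b == blocks[1]) {
        ## end of the calibration block: update per strategy
        own[[s]] <- blk
        new_name <- switch(strategy,
          Gen = model_name,
          GenC = sprintf("GenC%d", s),
          Ind = sprintf("Ind%d", s),
          IndC = if (s == 1) "Ind1" else sprintf("IndC%d", s)
        )
        if (strategy != "Gen") {
          pool <- switch(strategy,
            GenC = {
              sel_own <- lapply(own, function(o) o[c("Y", "Z", "trial_id")])
              .merge_pools(c(list(lopo$pool), sel_own))
            },
            Ind = list(Y = blk$Y, Z = blk$Z, trial_id = blk$trial_id),
            IndC = .merge_pools(
              lapply(own, function(o) o[c("Y", "Z", "trial_id")])
            )
          )
          model <- refit(pool)
          model_name <- new_name
          registry[[new_name]] <- model
          training[[new_name]] <- pool
        }
      }
    }
  }
  structure(
    list(
      participant = participant, strategy = strategy, space = fstudy$space,
      decoded = decoded, registry = registry, training = training
    ),
    class = "strategy_run"
  )
}

#' @keywords internal
.merge_pools <- function(pools) {
  off <- 0L
  tid <- list()
  for (i in seq_along(pools)) {
    tid[[i]] <- pools[[i]]$trial_id + off
    off <- off + max(pools[[i]]$trial_id)
  }
  list(
    Y = do.call(cbind, lapply(pools, `[[`, "Y")),
    Z = do.call(cbind, lapply(pools, `[[`, "Z")),
    trial_id = unlist(tid)
  )
}

#' Metric table for one or more strategy runs
#'
#' @param runs a `strategy_run` or list of them.
#' @return data frame with one row per (block, kinematic): identifiers,
#'   `r`, `abs_r`, `snr`.
#' @export
strategy_metrics <- function(runs) {
  if (inherits(runs, "strategy_run")) runs <- list(runs)
  out <- lapply(runs, function(run) {
    do.call(rbind, lapply(run$decoded, function(blk) {
      block_metrics(blk$truth, blk$zhat, meta = list(
        participant = run$participant, session = blk$session,
        block = blk$block, strategy = run$strategy, space = run$space,
        model = blk$model
      ))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
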