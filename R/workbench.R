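#' Default pipeline configuration
#'
#' Nested configuration for an end-to-end run. Every stochastic stage draws
#' its seed from the single global `seed` via [derive_seed()].
#'
#' @param seed global seed.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    study = list(
      n_participants = 8L, n_sessions = 3L, n_channels = 32L,
      n_locations = 500L, n_trials = 5L, trial_s = 24,
      coupling_mode = "shared", snr_db = 10
    ),
    preprocess = list(
      hp_hz = 0.18, mid_fs = 100, lp_hz = 3, out_fs = 20, lags = 0:-6
    ),
    inverse = list(alpha = NULL, diag_loading = 0.01),
    decoder = list(A = NULL, A_max = 50L, folds = 10L, lambda = 1),
    evaluation = list(
      n_repeats = 100L, percentile = 95, fdr_q = 0.05,
      chance_models = "Gen"
    ),
    pattern = list(n_perm = 10000L, perplexity = 30, enabled = TRUE),
    spaces = "sensor",
    strategies = c("Gen", "GenC", "Ind", "IndC")
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the nested structure against [default_config()]: unknown keys are
#' rejected, known keys replace the defaults. Validation happens before any
#' computation.
#'
#' @param cfg a (partial) configuration list.
#' @return the merged, validated `run_config`.
#' @export
validate_config <- function(cfg) {
  ref <- unclass(default_config())
  merge_into <- function(base, user, path = "") {
    for (nm in names(user)) {
      if (!nm %in% names(base)) {
        stop(sprintf("unknown configuration key: %s%s", path, nm))
      }
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        merge_into_res <- merge_into(
          base[[nm]], as.list(user[[nm]]),
          paste0(path, nm, ".")
        )
        base[[nm]] <- merge_into_res
      } else {
        base[[nm]] <- user[[nm]]
      }
    }
    base
  }
  out <- merge_into(ref, unclass(cfg))
  stopifnot(
    is.numeric(out$seed),
    out$study$n_participants >= 2,
    all(out$spaces %in% c("sensor", "source")),
    all(out$strategies %in% c("Gen", "GenC", "Ind", "IndC"))
  )
  class(out) <- c("run_config", "list")
  out
}

#' Read a configuration from YAML or JSON
#' @param path file path ending in .yaml/.yml or .json.
#' @return validated `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

#' @keywords internal
.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full simulated transfer-learning pipeline
#'
#' Simulate a study, prepare features for the requested spaces, run every
#' requested update strategy for every participant, compute the metric
#' table, the trial-shuffled chance thresholds, the pairwise strategy
#' comparisons and (optionally) the decoding patterns with their 2-D
#' embedding, and write everything to `out_dir` as tidy CSV/JSON together
#' with a manifest recording the configuration hash and seeds.
#'
#' @param cfg a configuration ([default_config()] / [validate_config()]).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `metrics`, `chance`, `comparisons`,
#'   `patterns`, `manifest`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = tempfile("run")) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  design <- study_design(
    n_participants = cfg$study$n_participants,
    n_sessions = cfg$study$n_sessions,
    n_channels = cfg$study$n_channels,
    n_locations = cfg$study$n_locations,
    n_trials = cfg$study$n_trials, trial_s = cfg$study$trial_s
  )
  study <- gen_study(design,
    coupling_mode = cfg$study$coupling_mode,
    snr_db = cfg$study$snr_db, seed = derive_seed(seed, 1L)
  )

  metrics <- NULL
  chance <- list()
  pattern_rows <- NULL
  embeddings <- list()
  for (space in cfg$spaces) {
    fstudy <- prepare_features(study,
      space = space, lags = cfg$preprocess$lags,
      alpha = cfg$inverse$alpha, out_fs = cfg$preprocess$out_fs
    )
    runs <- list()
    lopos <- list()
    for (p in seq_len(design$n_participants)) {
      lopos[[p]] <- train_lopo(fstudy, p,
        A = cfg$decoder$A,
        A_max = cfg$decoder$A_max, folds = cfg$decoder$folds
      )
      for (strat in cfg$strategies) {
        runs[[length(runs) + 1L]] <- run_strategy(
          fstudy, p, strat, lopos[[p]],
          A = cfg$decoder$A,
          A_max = cfg$decoder$A_max, folds = cfg$decoder$folds
        )
      }
    }
    metrics <- rbind(metrics, strategy_metrics(runs))

    if ("Gen" %in% cfg$evaluation$chance_models) {
      per <- lapply(seq_len(design$n_participants), function(p) {
        eval_blocks <- unlist(lapply(
          seq_len(design$n_sessions),
          function(s) {
            lapply(design$blocks, function(b) {
              fstudy$blocks[[p]][[s]][[b]][c("Y", "Z")]
            })
          }
        ), recursive = FALSE)
        list(
          Ytr = lopos[[p]]$pool$Y, Ztr = lopos[[p]]$pool$Z,
          trial_id = lopos[[p]]$pool$trial_id,
          eval_blocks = eval_blocks, A = lopos[[p]]$model$A,
          q_scale = lopos[[p]]$model$ukf$q_scale
        )
      })
      chance[[space]] <- chance_level(per,
        n_repeats = cfg$evaluation$n_repeats,
        percentile = cfg$evaluation$percentile,
        seed = derive_seed(seed, 3L)
      )
    }

    if (isTRUE(cfg$pattern$enabled)) {
      for (i in seq_along(runs)) {
        run <- runs[[i]]
        for (nm in names(run$registry)) {
          tr <- run$training[[nm]]
          n <- ncol(tr$Y)
          Yc <- tr$Y - rowMeans(tr$Y)
          Zc <- tr$Z - rowMeans(tr$Z)
          pat <- decoding_pattern(
            run$registry[[nm]],
            tcrossprod(Yc) / n, tcrossprod(Zc) / n
          )
          pattern_rows <- rbind(pattern_rows, data.frame(
            participant = run$participant, strategy = run$strategy,
            space = space, model = nm,
            t(as.vector(pat$A))
          ))
        }
      }
    }
  }

  comparisons <- compare_strategies(metrics)

  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
    row.names = FALSE
  )
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
    row.names = FALSE
  )
  if (length(chance) > 0) {
    jsonlite::write_json(
      lapply(chance, function(ch) as.list(ch$group)),
      file.path(out_dir, "chance_thresholds.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(pattern_rows)) {
    key <- pattern_rows[, 1:4]
    pm <- as.matrix(pattern_rows[, -(1:4)])
    if (nrow(pm) >= 3) {
      emb <- embed_patterns(pm,
        perplexity = cfg$pattern$perplexity,
        seed = derive_seed(seed, 4L)
      )
      embeddings <- cbind(key, dim1 = emb[, 1], dim2 = emb[, 2])
      utils::write.csv(embeddings, file.path(out_dir, "embeddings.csv"),
        row.names = FALSE
      )
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("trajdec")),
    config = unclass(cfg), config_hash = .config_hash(unclass(cfg)),
    seed = seed, created = "run"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    metrics = metrics, chance = chance, comparisons = comparisons,
    patterns = pattern_rows, embeddings = embeddings, manifest = manifest,
    out_dir = out_dir
  ))
}
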