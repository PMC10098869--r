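#' Write a synthetic study to a directory tree
#'
#' Plain-text layout: `manifest.json` (design, truth metadata, seed),
#' `leadfield/` (gain, positions and ROI map as CSV) and one directory per
#' participant/session/block with the recording (`eeg.csv`, channels x
#' samples, with a JSON sidecar for rate/labels/trials) and the kinematics
#' (`kinematics.csv` with columns `trial, t, p_hor, v_hor, p_ver, v_ver`).
#'
#' @param study a [gen_study()] result.
#' @param dir target directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- study$design
  jsonlite::write_json(
    list(
      design = d[setdiff(names(d), "band_hz")],
      band_hz = d$band_hz,
      coupling_mode = study$truth$coupling_mode,
      snr_db = study$truth$snr_db, seed = study$truth$seed
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  lf <- study$leadfield
  lfd <- file.path(dir, "leadfield")
  dir.create(lfd, showWarnings = FALSE)
  utils::write.csv(lf$gain, file.path(lfd, "gain.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(lf$source_positions, roi = as.character(lf$roi_map)),
    file.path(lfd, "positions.csv"),
    row.names = FALSE
  )
  utils::write.csv(data.frame(lf$electrode_positions),
    file.path(lfd, "electrodes.csv"),
    row.names = FALSE
  )
  for (p in seq_along(study$data)) {
    for (s in seq_along(study$data[[p]])) {
      for (b in names(study$data[[p]][[s]])) {
        bd <- file.path(dir, sprintf("p%02d", p), sprintf("s%d", s), b)
        dir.create(bd, showWarnings = FALSE, recursive = TRUE)
        blk <- study$data[[p]][[s]][[b]]
        utils::write.csv(blk$recording$data, file.path(bd, "eeg.csv"),
          row.names = FALSE
        )
        jsonlite::write_json(
          list(
            fs = blk$recording$fs, channels = blk$recording$channels,
            trials = blk$recording$trials
          ),
          file.path(bd, "eeg.json"),
          auto_unbox = TRUE, digits = NA
        )
        kin <- as.data.frame(blk$kinematics)
        utils::write.csv(
          kin[, c("trial", "t", "p_hor", "v_hor", "p_ver", "v_ver")],
          file.path(bd, "kinematics.csv"),
          row.names = FALSE
        )
      }
    }
  }
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory produced by [write_study()].
#' @return a `synth_study` (without the generator's ground-truth coupling
#'   matrices, which live only in memory).
#' @export
read_study <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  lfd <- file.path(dir, "leadfield")
  gain <- as.matrix(utils::read.csv(file.path(lfd, "gain.csv")))
  pos <- utils::read.csv(file.path(lfd, "positions.csv"))
  elec <- as.matrix(utils::read.csv(file.path(lfd, "electrodes.csv")))
  lf <- structure(
    list(
      gain = unname(gain) * 1, source_positions = as.matrix(pos[, 1:3]),
      electrode_positions = elec,
      roi_map = factor(pos$roi, levels = roi_labels()),
      orientations = diag(3)
    ),
    class = "leadfield"
  )
  colnames(lf$gain) <- colnames(gain)
  d <- man$design
  class(d) <- "study_design"
  d$band_hz <- man$band_hz
  data <- vector("list", d$n_participants)
  for (p in seq_len(d$n_participants)) {
    data[[p]] <- vector("list", d$n_sessions)
    for (s in seq_len(d$n_sessions)) {
      data[[p]][[s]] <- stats::setNames(
        vector("list", length(d$blocks)), d$blocks
      )
      for (b in d$blocks) {
        bd <- file.path(dir, sprintf("p%02d", p), sprintf("s%d", s), b)
        side <- jsonlite::read_json(file.path(bd, "eeg.json"),
          simplifyVector = TRUE
        )
        rec <- list(
          data = unname(as.matrix(utils::read.csv(
            file.path(bd, "eeg.csv")
          ))) * 1,
          fs = side$fs, channels = side$channels,
          trials = matrix(as.integer(side$trials), ncol = 2,
            dimnames = list(NULL, c("start", "end"))
          )
        )
        class(rec) <- "recording"
        kin <- utils::read.csv(file.path(bd, "kinematics.csv"))
        attr(kin, "fs") <- side$fs
        class(kin) <- c("kinematics", "data.frame")
        data[[p]][[s]][[b]] <- list(recording = rec, kinematics = kin)
      }
    }
  }
  structure(
    list(
      design = d, leadfield = lf,
      truth = list(
        coupling_mode = man$coupling_mode, snr_db = man$snr_db,
        seed = man$seed
      ),
      data = data
    ),
    class = "synth_study"
  )
}

#' Write decoded kinematics as CSV
#'
#' Mirrors the kinematics schema with the decoded extended kinematics:
#' columns `t, p_hor, v_hor, p_ver, v_ver, d, s`.
#'
#' @param zhat `6 x T` decoded matrix from [predict.traj_decoder()].
#' @param path output CSV path; @param fs sampling rate for the time column.
#' @return `path`, invisibly.
#' @export
write_decoded <- function(zhat, path, fs = 20) {
  df <- data.frame(t = (seq_len(ncol(zhat)) - 1) / fs, t(zhat))
  names(df) <- c("t", rownames(zhat))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
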