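#' Region-of-interest labels used by the synthetic head model
#'
#' 14 regions per hemisphere around the central medial cortex: cuneus (CU),
#' paracentral lobule (PCL), superior frontal gyrus (SFG, anterior/posterior),
#' precentral and postcentral gyri (medial/lateral), superior parietal lobule
#' (anterior/posterior), precuneus (anterior/posterior) and occipital gyri
#' (superior/inferior).
#'
#' @return character vector of 28 ROI labels (prefix `L_` / `R_`).
#' @export
roi_labels <- function() {
  base <- c(
    "CU", "PCL", "aSFG", "pSFG", "mPreCG", "lPreCG", "mPoCG", "lPoCG",
    "aSPL", "pSPL", "aPCU", "pPCU", "sOG", "iOG"
  )
  c(paste0("L_", base), paste0("R_", base))
}

## quasi-even points on the unit sphere (Fibonacci lattice)
#' @keywords internal
.fib_sphere <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  # hemisphere: z in (0, 1]; full: z in (-1, 1)
  z <- if (hemisphere) i / n else 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate a synthetic lead field
#'
#' Builds a dipole-like gain matrix on a unit sphere: electrodes sit on the
#' upper surface, free-orientation sources on an interior shell, and each of
#' the three canonical orientations of a source contributes
#' `gain = (r - s)_axis / |r - s|^3` to an electrode at `r`. Sources are
#' partitioned into 28 contiguous angular patches labelled with the ROI set of
#' [roi_labels()]. This is a qualitatively EEG-like stand-in for a boundary
#' element forward model; no anatomy is involved.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param n_locations number of source locations (>= 28); each location
#'   carries 3 directional components, so the gain has `3 * n_locations`
#'   columns.
#' @param seed integer seed controlling the radial jitter of the source shell.
#' @param shell_radius radius of the source shell (sources stay at <= 0.9).
#' @return an object of class `leadfield` with elements `gain`
#'   (`n_channels x 3 n_locations`), `source_positions`, `electrode_positions`,
#'   `roi_map` (factor of length `n_locations`) and `orientations`.
#' @export
gen_leadfield <- function(n_channels, n_locations, seed = 1L,
                          shell_radius = 0.8) {
  if (n_channels < 8) stop("need at least 8 channels")
  labs <- roi_labels()
  if (n_locations < length(labs)) {
    stop(sprintf(
      "n_locations = %d is fewer than the %d ROIs", n_locations, length(labs)
    ))
  }
  if (shell_radius > 0.9) stop("sources must stay at radius <= 0.9")

  elec <- .fib_sphere(n_channels, hemisphere = TRUE)
  set.seed(derive_seed(seed, 0L))
  radii <- shell_radius * (1 - 0.1 * stats::runif(n_locations))
  src <- .fib_sphere(n_locations) * radii

  ## ROI patches: 28 quasi-even patch centres, sources assigned to nearest
  ## centre; each centre first claims its closest source so no ROI is empty.
  centres <- .fib_sphere(length(labs)) * shell_radius
  d2 <- outer(rowSums(src^2), rep(1, nrow(centres))) -
    2 * src %*% t(centres) + outer(rep(1, nrow(src)), rowSums(centres^2))
  assign <- max.col(-d2)
  for (i in seq_along(labs)) {
    j <- which.min(d2[, i])
    assign[j] <- i
  }
  roi_map <- factor(labs[assign], levels = labs)

  ## dipole-like kernel, vectorised over electrodes x locations
  gain <- matrix(0, n_channels, 3L * n_locations)
  for (a in 1:3) {
    diff_a <- outer(elec[, a], src[, a], "-")
    d2es <- outer(elec[, 1], src[, 1], "-")^2 +
      outer(elec[, 2], src[, 2], "-")^2 +
      outer(elec[, 3], src[, 3], "-")^2
    gain[, seq(a, by = 3L, length.out = n_locations)] <- diff_a / d2es^1.5
  }
  colnames(gain) <- paste0(
    rep(as.character(roi_map), each = 3), ".",
    rep(seq_len(n_locations), each = 3), ".", c("x", "y", "z")
  )
  if (any(colSums(abs(gain)) == 0)) stop("degenerate lead field column")

  structure(
    list(
      gain = gain, source_positions = src, electrode_positions = elec,
      roi_map = roi_map, orientations = diag(3), seed = seed
    ),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf(
    "Synthetic lead field: %d channels x %d source signals (%d locations, %d ROIs)\n",
    nrow(x$gain), ncol(x$gain), nrow(x$source_positions),
    nlevels(x$roi_map)
  ))
  invisible(x)
}

## column indices of the gain matrix for a set of ROI labels
#' @keywords internal
.roi_columns <- function(leadfield, rois) {
  loc <- which(leadfield$roi_map %in% rois)
  as.vector(t(outer(3L * (loc - 1L), 1:3, "+")))
}
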