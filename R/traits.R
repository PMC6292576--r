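#' Integrate one recording into a trait row
#'
#' Collapses per-frame segmentation measures and the recording's band
#' energies into one per-timepoint phenome row: size statistics over
#' valid frames (min/max/mean area), gross movement (summed Euclidean
#' centroid displacement over consecutive valid-frame pairs, scaled to
#' micrometres when a scale is set), the per-step mean distance moved,
#' and total/band spectral energies. A recording with zero valid
#' frames yields an all-NaN row so the time axis stays aligned.
#'
#' @param frame_measures Data frame from [segment_sequence()].
#' @param band_energy Optional [band_energies()] result for the
#'   recording (typically of the whole-ROI level-1 signal).
#' @param scale Micrometres per pixel, or `NA` for pixel units.
#' @param time_h Recording time in hours since experiment start.
#' @return One-row data frame of per-timepoint traits.
#' @export
integrate_timepoint <- function(frame_measures, band_energy = NULL,
                                scale = NA_real_, time_h = NA_real_) {
  fm <- frame_measures
  v <- which(fm$valid %in% TRUE)
  a2 <- if (is.na(scale)) 1 else scale^2   # px^2 -> um^2
  a1 <- if (is.na(scale)) 1 else scale     # px   -> um
  if (length(v) == 0L) {
    row <- data.frame(time_h = time_h, n_frames = nrow(fm),
                      n_valid = 0L, area_min = NaN, area_max = NaN,
                      area_mean = NaN, movement = NaN,
                      mean_distance_moved = NaN, n_steps = 0L)
  } else {
    areas <- fm$area_px[v] * a2
    # displacements between frames adjacent in the full sequence with
    # both members valid
    ok_pair <- fm$valid[-nrow(fm)] %in% TRUE & fm$valid[-1L] %in% TRUE
    dr <- diff(fm$centroid_row); dc <- diff(fm$centroid_col)
    steps <- sqrt(dr[ok_pair]^2 + dc[ok_pair]^2) * a1
    mv <- if (length(steps)) sum(steps) else 0
    row <- data.frame(time_h = time_h, n_frames = nrow(fm),
                      n_valid = length(v),
                      area_min = min(areas), area_max = max(areas),
                      area_mean = mean(areas), movement = mv,
                      mean_distance_moved = if (length(steps))
                        mv / length(steps) else 0,
                      n_steps = length(steps))
  }
  if (!is.null(band_energy)) {
    row$total_energy <- band_energy$total_energy
    if (isTRUE(band_energy$available)) {
      be <- as.list(band_energy$energy)
      names(be) <- sprintf("energy_%g_%g", band_energy$band_lo,
                           band_energy$band_hi)
      row <- cbind(row, as.data.frame(be, check.names = FALSE))
    }
  }
  row
}

#' Growth rate of an embryo
#'
#' Ordinary least-squares slope of mean area against time in hours,
#' excluding NaN timepoints pairwise. Units are area units per hour
#' (µm²/h when the traits are scaled, px²/h otherwise).
#'
#' @param traits Trait table with `time_h` and `area_mean` columns (or
#'   a [phenome_dataset()]).
#' @return List with `slope`, `stderr`, `intercept`, `n`, and `reason`
#'   (NULL, or why the rate is undefined).
#' @export
growth_rate <- function(traits) {
  if (inherits(traits, "phenome_dataset")) traits <- traits$traits
  ok <- is.finite(traits$time_h) & is.finite(traits$area_mean)
  if (sum(ok) < 3L)
    return(list(slope = NaN, stderr = NaN, intercept = NaN, n = sum(ok),
                reason = "fewer than 3 finite timepoints"))
  fit <- stats::lm(area_mean ~ time_h, data = traits[ok, ])
  # exact test series fit perfectly; the stderr warning is expected
  s <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(s["time_h", "Estimate"]),
       stderr = unname(s["time_h", "Std. Error"]),
       intercept = unname(s["(Intercept)", "Estimate"]),
       n = sum(ok), reason = NULL)
}

#' Cumulative movement of an embryo
#'
#' Running total of per-timepoint gross movement; NaN timepoints are
#' skipped and counted.
#'
#' @param traits Trait table with a `movement` column (or a
#'   [phenome_dataset()]).
#' @return List with `total` (µm or px), `n_missing`, and the running
#'   `cumulative` series (NaN entries carried as the last total).
#' @export
cumulative_movement <- function(traits) {
  if (inherits(traits, "phenome_dataset")) traits <- traits$traits
  mv <- traits$movement
  ok <- is.finite(mv)
  run <- cumsum(ifelse(ok, mv, 0))
  list(total = sum(mv[ok]), n_missing = sum(!ok), cumulative = run)
}
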