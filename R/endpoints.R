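#' Detect a lethal end point from an area spike
#'
#' Early-stage embryos that die of osmotic failure show a rapid
#' increase and subsequent decrease in apparent area. The series is
#' smoothed with a rolling median (window 3); a lethal peak is an
#' interior local maximum at least `(1 + delta)` times the median of
#' the preceding baseline that is followed by a sustained decline
#' below the peak (every subsequent smoothed value lower, and the
#' post-peak minimum at or below the pre-peak baseline level). Death
#' time is the time of the peak; with no qualifying peak the embryo is
#' censored.
#'
#' @param area Per-timepoint mean areas.
#' @param time_h Times in hours (defaults to `0:(n-1)`).
#' @param delta Required fractional exceedance over baseline
#'   (default 0.3).
#' @return List with `death_time_h` (NA when censored), `censored`,
#'   `index`, and `diagnostics` (peak-to-baseline ratio).
#' @export
detect_endpoint_area_peak <- function(area, time_h = NULL, delta = 0.3) {
  n <- length(area)
  if (n < 5L) stop("need at least 5 timepoints", call. = FALSE)
  if (is.null(time_h)) time_h <- seq_len(n) - 1
  x <- area
  ok <- is.finite(x)
  if (sum(ok) < 5L)
    return(list(death_time_h = NA_real_, censored = TRUE, index = NA,
                diagnostics = list(reason = "too few finite timepoints")))
  xs <- stats::runmed(ifelse(ok, x, stats::median(x[ok])), k = 3L,
                      endrule = "median")
  for (i in 2:(n - 1L)) {
    if (!ok[i]) next
    if (xs[i] < xs[i - 1L] || xs[i] < xs[i + 1L]) next   # not a local max
    base <- stats::median(xs[seq_len(i - 1L)])
    if (!is.finite(base) || base <= 0) next
    ratio <- xs[i] / base
    if (ratio < 1 + delta) next
    post <- xs[(i + 1L):n]
    # the smoothed peak may plateau for one step; sustained decline
    # means nothing later exceeds the peak and the series comes back
    # down toward baseline
    if (all(post <= xs[i]) && min(post) <= base * (1 + delta / 2)) {
      return(list(death_time_h = time_h[i], censored = FALSE, index = i,
                  diagnostics = list(peak_ratio = ratio)))
    }
  }
  list(death_time_h = NA_real_, censored = TRUE, index = NA,
       diagnostics = list(peak_ratio = NA_real_))
}

#' Detect a lethal end point from a spectral-energy drop
#'
#' Later-stage embryos die by cessation of periodic activity
#' (heartbeat, movement), visible as a collapse of energy in the
#' physiological frequency bands. The baseline is the median of the
#' first `k` timepoints; death is called at the first timepoint where
#' the summed band energy stays below `theta * baseline` for `m`
#' consecutive timepoints, and censored otherwise.
#'
#' @param energy Per-timepoint summed band energies.
#' @param time_h Times in hours (defaults to `0:(n-1)`).
#' @param theta Drop threshold as a fraction of baseline
#'   (default 0.25).
#' @param m Persistence requirement in timepoints (default 3).
#' @param k Baseline window length in timepoints (default 6).
#' @return List with `death_time_h` (NA when censored), `censored`,
#'   `index`, `diagnostics` (baseline and energy ratio at the call),
#'   and `undetermined` when the baseline cannot be formed.
#' @export
detect_endpoint_energy_drop <- function(energy, time_h = NULL,
                                        theta = 0.25, m = 3L, k = 6L) {
  n <- length(energy)
  if (n < 5L) stop("need at least 5 timepoints", call. = FALSE)
  if (k > n) stop("baseline window k exceeds the series length",
                  call. = FALSE)
  if (is.null(time_h)) time_h <- seq_len(n) - 1
  base_vals <- energy[seq_len(k)]
  if (all(!is.finite(base_vals)))
    return(list(death_time_h = NA_real_, censored = FALSE,
                undetermined = TRUE, index = NA,
                diagnostics = list(reason = "baseline all-NaN")))
  base <- stats::median(base_vals[is.finite(base_vals)])
  below <- is.finite(energy) & energy < theta * base
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= m) {
      idx <- i - m + 1L
      return(list(death_time_h = time_h[idx], censored = FALSE,
                  undetermined = FALSE, index = idx,
                  diagnostics = list(baseline = base,
                                     energy_ratio = energy[idx] / base)))
    }
  }
  # a trailing shorter run that persists to the end of observation is
  # still transient by the rule: censored
  list(death_time_h = NA_real_, censored = TRUE, undetermined = FALSE,
       index = NA, diagnostics = list(baseline = base))
}

#' Identify the lethal end point of one embryo
#'
#' Applies the stage-appropriate detector: early (E3) embryos use the
#' osmotic area-spike rule with the energy-drop rule as fallback (a
#' combination of the two); later stages (E7, E9, E11) use the
#' energy-drop rule alone. The method actually used is recorded.
#'
#' @param traits Trait table with `time_h`, `area_mean` and the energy
#'   column, or a [phenome_dataset()].
#' @param stage Developmental stage label: `"E3"`, `"E7"`, `"E9"` or
#'   `"E11"`.
#' @param energy_col Column holding the summed band energy
#'   (default `"total_energy"`).
#' @param area_params,energy_params Lists of parameter overrides for
#'   the two detectors.
#' @return One-row data frame (class `endpoint_result`): `embryo_id`,
#'   `stage`, `death_time_h`, `censored`, `method`, `diagnostic`.
#' @export
identify_lethal_endpoints <- function(traits, stage,
                                      energy_col = "total_energy",
                                      area_params = list(),
                                      energy_params = list()) {
  embryo_id <- "unknown"
  if (inherits(traits, "phenome_dataset")) {
    embryo_id <- traits$embryo_id
    traits <- traits$traits
  }
  stages <- c("E3", "E7", "E9", "E11")
  if (!is.character(stage) || length(stage) != 1L || !stage %in% stages)
    stop("unknown developmental stage label: ", stage,
         " (expected one of ", paste(stages, collapse = ", "), ")",
         call. = FALSE)
  energy <- traits[[energy_col]]
  if (is.null(energy) && stage != "E3")
    stop("traits lack the '", energy_col, "' column needed for the ",
         "energy-drop rule", call. = FALSE)
  run_energy <- function() {
    r <- do.call(detect_endpoint_energy_drop,
                 c(list(energy = energy, time_h = traits$time_h),
                   energy_params))
    list(r = r, method = "energy_drop",
         diag = if (!is.null(r$diagnostics$energy_ratio))
           r$diagnostics$energy_ratio else NA_real_)
  }
  if (stage == "E3") {
    r <- do.call(detect_endpoint_area_peak,
                 c(list(area = traits$area_mean, time_h = traits$time_h),
                   area_params))
    if (!r$censored) {
      res <- list(r = r, method = "area_peak",
                  diag = r$diagnostics$peak_ratio)
    } else if (!is.null(energy)) {
      res <- run_energy()
      if (!res$r$censored && !isTRUE(res$r$undetermined))
        res$method <- "combined"
    } else {
      res <- list(r = r, method = "area_peak",
                  diag = r$diagnostics$peak_ratio)
    }
  } else {
    res <- run_energy()
  }
  out <- data.frame(embryo_id = embryo_id, stage = stage,
                    death_time_h = if (isTRUE(res$r$censored)) NA_real_
                      else res$r$death_time_h,
                    censored = isTRUE(res$r$censored),
                    undetermined = isTRUE(res$r$undetermined),
                    method = res$method,
                    diagnostic = if (is.null(res$diag)) NA_real_
                      else as.numeric(res$diag),
                    stringsAsFactors = FALSE)
  class(out) <- c("endpoint_result", "data.frame")
  out
}

#' Cohort survival curve
#'
#' Empirical proportion surviving on a time grid. All embryos share
#' the same observation window, so the curve is the simple fraction of
#' the cohort not yet dead at each grid time; censored embryos remain
#' in the risk set to their last observation.
#'
#' @param death_times_h Numeric vector, one per embryo; `NA` =
#'   censored (survived the window).
#' @param time_grid_h Evaluation grid in hours; defaults to the sorted
#'   unique death times prefixed with 0.
#' @return An object of class `survival_curve`: `time_h`,
#'   `proportion_surviving` (starts at 1, non-increasing), and
#'   `n_at_risk`.
#' @export
survival_curve <- function(death_times_h, time_grid_h = NULL) {
  n <- length(death_times_h)
  if (n < 1L) stop("need at least one embryo", call. = FALSE)
  deaths <- sort(death_times_h[!is.na(death_times_h)])
  if (is.null(time_grid_h))
    time_grid_h <- unique(c(0, deaths))
  time_grid_h <- sort(unique(time_grid_h))
  ndead <- vapply(time_grid_h, function(t) sum(deaths <= t), 0)
  structure(list(time_h = time_grid_h,
                 proportion_surviving = 1 - ndead / n,
                 n_at_risk = n - ndead, n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d, %d grid times, final survival %.2f\n",
              x$n, length(x$time_h),
              x$proportion_surviving[length(x$time_h)]))
  invisible(x)
}

#' Lethal-time percentiles from a survival curve
#'
#' `LTp` is the exposure duration at which `p`% of the cohort has
#' died, read from the survival curve under the step convention: the
#' first grid time at which the surviving proportion has reached
#' `1 - p/100` or below. The empirical curve is a step function that
#' jumps exactly at death times, so the first crossing is itself a
#' grid time whenever the grid contains the death times (the default);
#' on coarser grids the call resolves to the first grid time past the
#' crossing, i.e. to the recording interval. Levels never reached are
#' NaN.
#'
#' @param curve A [survival_curve()].
#' @param levels Percent mortality levels in `(0, 100)`.
#' @return Named numeric vector of times in hours.
#' @export
lt_percentiles <- function(curve, levels = c(25, 50, 75)) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(levels <= 0 | levels >= 100))
    stop("levels must lie strictly between 0 and 100", call. = FALSE)
  s <- curve$proportion_surviving
  t <- curve$time_h
  out <- vapply(levels, function(p) {
    target <- 1 - p / 100
    hit <- which(s <= target)
    if (!length(hit)) return(NaN)
    t[hit[1L]]
  }, 0)
  names(out) <- paste0("LT", levels)
  out
}
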