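#' Synthetic embryo recording specification
#'
#' Parameterizes a seeded synthetic dark-field recording: a static
#' bright egg-capsule ring on a dark background, containing a growing,
#' moving, bright embryo ellipse with a localized heart disc whose
#' intensity oscillates sinusoidally at the cardiac frequency. The
#' defaults emulate a pond-snail-like embryo recorded in hourly
#' 600-frame bursts at 20 fps with a 1.5 Hz heart; every stochastic
#' element is governed by `seed` and reported as ground truth by the
#' generators.
#'
#' @param frame_size Square frame side in pixels.
#' @param capsule List: `center` (row, col), `semi_axes` (a, b),
#'   `angle` (deg), `thickness` (ring width, px), `intensity`.
#' @param embryo List: `area0_px` (area at time 0), `growth_px2_h`
#'   (linear area growth), `axis_ratio` (a/b), `intensity`.
#' @param movement List: `step_px` (per-frame random-walk step SD),
#'   `tp_step_px` (between-recording drift SD), `rotation_deg_h`.
#' @param heart List: `offset_frac` (heart centre as a fraction of the
#'   embryo semi-axes), `radius_px`, `amplitude` (intensity), `f0_hz`,
#'   `drift_hz_h` (linear ontogeny), `breakpoint` (NULL or
#'   `list(time_h, slope_after)` for a segmented ontogeny).
#' @param diapause NULL, or a list of `c(start_h, end_h)` windows with
#'   the heart silent.
#' @param death List: `mode` (`"none"`, `"osmotic"`,
#'   `"cardiac_cessation"`), `time_h`, `spike` (osmotic area factor).
#' @param noise List: `sigma` (Gaussian intensity SD).
#' @param schedule A [recording_schedule()].
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(frame_size = 128L,
                           capsule = list(),
                           embryo = list(),
                           movement = list(),
                           heart = list(),
                           diapause = NULL,
                           death = list(),
                           noise = list(),
                           schedule = recording_schedule(600L, 20, 60, 25L),
                           seed = 1L) {
  merge_def <- function(x, def) utils::modifyList(def, x)
  frame_size <- as.integer(frame_size)
  ctr <- (frame_size - 1) / 2
  capsule <- merge_def(capsule, list(
    center = c(ctr, ctr), semi_axes = c(0.38, 0.33) * frame_size,
    angle = 0, thickness = 3, intensity = 1500))
  embryo <- merge_def(embryo, list(
    area0_px = 0.08 * frame_size^2, growth_px2_h = 0.0016 * frame_size^2,
    axis_ratio = 1.5, intensity = 3000))
  movement <- merge_def(movement, list(
    step_px = 0.6, tp_step_px = 3, rotation_deg_h = 10))
  heart <- merge_def(heart, list(
    offset_frac = c(0.35, 0.2), radius_px = max(3, frame_size / 26),
    amplitude = 700, f0_hz = 1.5, drift_hz_h = 0, breakpoint = NULL))
  death <- merge_def(death, list(mode = "none", time_h = NA_real_,
                                 spike = 1.6))
  noise <- merge_def(noise, list(sigma = 30))
  death$mode <- match.arg(death$mode,
                          c("none", "osmotic", "cardiac_cessation"))
  if (death$mode != "none") {
    if (!is.finite(death$time_h) || death$time_h < 0 ||
        death$time_h > schedule$duration_h)
      stop("death time must lie within the experiment duration",
           call. = FALSE)
  }
  spec <- structure(
    list(frame_size = frame_size, capsule = capsule, embryo = embryo,
         movement = movement, heart = heart, diapause = diapause,
         death = death, noise = noise, schedule = schedule,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  fmax <- max(vapply(seq_len(schedule$n_timepoints) - 1L, function(tp)
    .heart_freq(spec, tp * schedule$repeat_interval / 60), 0))
  if (fmax >= schedule$frame_rate / 2)
    stop("heart frequency (", format(fmax), " Hz) must stay below the ",
         "Nyquist rate ", format(schedule$frame_rate / 2), " Hz",
         call. = FALSE)
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %dpx frames, heart %.2f Hz, death %s%s, seed %d\n",
              x$frame_size, x$heart$f0_hz, x$death$mode,
              if (x$death$mode == "none") ""
              else sprintf(" @ %g h", x$death$time_h), x$seed))
  print(x$schedule)
  invisible(x)
}

#' Preset synthetic specifications
#'
#' `"radix"`: hourly 600-frame bursts at 20 fps, 1.5 Hz heart (pond
#' snail, typical maximum rate at 20 deg C). `"orchestia"`: hourly
#' 2100-frame bursts at 38 fps, 3.5 Hz heart with a linear ontogeny
#' (amphipod).
#'
#' @param preset `"radix"` or `"orchestia"`.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = c("radix", "orchestia"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "radix") {
    defaults <- list(schedule = recording_schedule(600L, 20, 60, 25L),
                     heart = list(f0_hz = 1.5))
  } else {
    defaults <- list(schedule = recording_schedule(2100L, 38, 60, 24L),
                     heart = list(f0_hz = 3.5, drift_hz_h = 0.01))
  }
  for (nm in names(defaults)) {
    if (nm %in% names(args)) {
      if (is.list(defaults[[nm]]) && is.list(args[[nm]]))
        args[[nm]] <- utils::modifyList(defaults[[nm]], args[[nm]])
    } else args[[nm]] <- defaults[[nm]]
  }
  do.call(synthetic_spec, args)
}

# instantaneous cardiac frequency at time t (hours)
.heart_freq <- function(spec, t_h) {
  h <- spec$heart
  f <- h$f0_hz + h$drift_hz_h * t_h
  if (!is.null(h$breakpoint)) {
    bp <- h$breakpoint
    if (t_h > bp$time_h)
      f <- h$f0_hz + h$drift_hz_h * bp$time_h +
        bp$slope_after * (t_h - bp$time_h)
  }
  f
}

.in_diapause <- function(spec, t_h) {
  if (is.null(spec$diapause)) return(FALSE)
  any(vapply(spec$diapause,
             function(w) t_h >= w[1] && t_h <= w[2], TRUE))
}

# derived 31-bit RNG seed for one stream of one spec
.stream_seed <- function(spec, stream) {
  as.integer((as.numeric(spec$seed) * 1000003 + stream * 7919) %%
             2147483647)
}

# deterministic between-recording centroid path (one start per timepoint)
.embryo_path <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.stream_seed(spec, 0L))
  n <- spec$schedule$n_timepoints
  lim <- spec$capsule$semi_axes * 0.45
  pos <- matrix(0, n, 2)
  p <- c(0, 0)                               # offset from capsule centre
  for (i in seq_len(n)) {
    p <- p + stats::rnorm(2, 0, spec$movement$tp_step_px)
    p <- pmin(pmax(p, -lim), lim)
    pos[i, ] <- p
  }
  sweep(pos, 2, spec$capsule$center, `+`)
}

# per-timepoint developmental state (area, death bookkeeping)
.tp_state <- function(spec, timepoint) {
  t_h <- timepoint * spec$schedule$repeat_interval / 60
  area <- spec$embryo$area0_px + spec$embryo$growth_px2_h * t_h
  alive <- TRUE
  heart_on <- !.in_diapause(spec, t_h)
  moving <- TRUE
  if (spec$death$mode != "none" && t_h >= spec$death$time_h) {
    alive <- FALSE; heart_on <- FALSE; moving <- FALSE
    area_at_death <- spec$embryo$area0_px +
      spec$embryo$growth_px2_h * spec$death$time_h
    if (spec$death$mode == "osmotic") {
      dt <- spec$schedule$repeat_interval / 60
      # spike spans the two recordings at/after the event, then 40% shrink
      if (t_h < spec$death$time_h + 2 * dt) {
        area <- area_at_death * spec$death$spike
      } else {
        area <- area_at_death * 0.6
      }
    } else {
      area <- area_at_death                  # cessation: size stable
    }
  }
  f <- .heart_freq(spec, t_h)
  list(t_h = t_h, area_px = area, alive = alive, heart_on = heart_on,
       moving = moving, heart_hz = f,
       angle = spec$capsule$angle + spec$movement$rotation_deg_h * t_h)
}

#' Generate one synthetic recording
#'
#' Renders the frames of one timepoint of a [synthetic_spec()] and
#' returns them with the exact ground truth used to draw them
#' (per-frame embryo centroid, analytic ellipse area, instantaneous
#' cardiac frequency, alive flag). Bit-identical for identical spec
#' and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param timepoint Zero-based recording index.
#' @param embryo_id Identity attached to the returned sequence.
#' @return List with `sequence` (an [image_sequence()]) and `truth`
#'   (list: per-frame data frame plus the timepoint-level state).
#' @export
generate_sequence <- function(spec, timepoint = 0L, embryo_id = "SYN01") {
  stopifnot(inherits(spec, "synthetic_spec"))
  timepoint <- as.integer(timepoint)
  if (timepoint < 0L || timepoint >= spec$schedule$n_timepoints)
    stop("timepoint out of schedule range", call. = FALSE)
  st <- .tp_state(spec, timepoint)
  path <- .embryo_path(spec)
  start <- path[timepoint + 1L, ]
  n <- spec$schedule$frames_per_sequence
  fs <- spec$schedule$frame_rate
  sz <- spec$frame_size
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.stream_seed(spec, timepoint + 1L))
  # within-recording random walk (zero when dead / not moving)
  steps <- if (st$moving)
    matrix(stats::rnorm(2 * n, 0, spec$movement$step_px), n, 2)
  else matrix(0, n, 2)
  steps[1L, ] <- 0
  lim <- spec$capsule$semi_axes * 0.45
  cent <- matrix(0, n, 2)
  p <- start
  for (i in seq_len(n)) {
    p <- p + steps[i, ]
    p <- pmin(pmax(p, spec$capsule$center - lim),
              spec$capsule$center + lim)
    cent[i, ] <- p
  }
  # embryo ellipse axes from area and aspect ratio
  a <- sqrt(st$area_px * spec$embryo$axis_ratio / pi)
  b <- a / spec$embryo$axis_ratio
  ring <- .ellipse_mask(sz, sz, spec$capsule$center,
                        spec$capsule$semi_axes + spec$capsule$thickness,
                        spec$capsule$angle) &
          !.ellipse_mask(sz, sz, spec$capsule$center,
                         spec$capsule$semi_axes, spec$capsule$angle)
  t0_s <- timepoint * spec$schedule$repeat_interval * 60
  t_frame <- t0_s + (seq_len(n) - 1) / fs
  th <- st$angle * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  hoff <- as.vector(rot %*% (spec$heart$offset_frac * c(a, b)))
  amp <- if (st$heart_on) spec$heart$amplitude else 0
  frames <- array(0, c(sz, sz, n))
  bg <- 200
  for (i in seq_len(n)) {
    img <- matrix(bg, sz, sz)
    img[ring] <- spec$capsule$intensity
    emb <- .ellipse_mask(sz, sz, cent[i, ], c(a, b), st$angle)
    img[emb] <- spec$embryo$intensity
    if (amp > 0) {
      hc <- cent[i, ] + hoff
      hm <- .ellipse_mask(sz, sz, hc,
                          rep(spec$heart$radius_px, 2), 0) & emb
      img[hm] <- spec$embryo$intensity +
        amp * sin(2 * pi * st$heart_hz * t_frame[i])
    }
    if (spec$noise$sigma > 0)
      img <- img + stats::rnorm(sz * sz, 0, spec$noise$sigma)
    frames[, , i] <- pmin(pmax(round(img), 0), 65535)
  }
  seq_obj <- image_sequence(frames, t_frame, embryo_id = embryo_id,
                            timepoint = timepoint,
                            timestamp_source = "metadata")
  truth_frames <- data.frame(
    frame = seq_len(n), time_s = t_frame,
    centroid_row = cent[, 1], centroid_col = cent[, 2],
    heart_row = if (amp > 0) cent[, 1] + hoff[1] else NaN,
    heart_col = if (amp > 0) cent[, 2] + hoff[2] else NaN,
    area_px = pi * a * b,
    heart_hz = if (amp > 0) st$heart_hz else NaN,
    alive = st$alive)
  list(sequence = seq_obj,
       truth = list(frames = truth_frames, time_h = st$t_h,
                    area_px = pi * a * b, semi_axes = c(a, b),
                    angle = st$angle, heart_hz = st$heart_hz,
                    heart_on = st$heart_on, alive = st$alive,
                    capsule_center = spec$capsule$center,
                    capsule_outer = spec$capsule$semi_axes +
                      spec$capsule$thickness))
}

#' Generate a whole synthetic experiment tree
#'
#' Writes, for each embryo spec, one multipage 16-bit TIFF plus JSON
#' metadata sidecar per timepoint, laid out as
#' `out_dir/<embryo>/T<index>.tif` — the same shape as a video
#' microscope acquisition tree — together with a `config.yaml`
#' experiment layout and a `manifest.csv` of all ground-truth
#' parameters and death times.
#'
#' @param specs Named list of [synthetic_spec()] (names are embryo
#'   ids); all schedules must agree.
#' @param out_dir Output directory.
#' @param scale Micrometres per pixel recorded in the layout.
#' @param species Species label recorded in the layout.
#' @return The [experiment_layout()], invisibly, with attributes
#'   `manifest` (data frame) and `dir`.
#' @export
generate_experiment <- function(specs, out_dir, scale = 0.75,
                                species = "synthetic") {
  stopifnot(length(specs) >= 1L, !is.null(names(specs)))
  sched <- specs[[1L]]$schedule
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (id in names(specs)) {
    spec <- specs[[id]]
    edir <- file.path(out_dir, id)
    dir.create(edir, showWarnings = FALSE)
    for (tp in seq_len(spec$schedule$n_timepoints) - 1L) {
      g <- generate_sequence(spec, tp, embryo_id = id)
      write_sequence(g$sequence,
                     file.path(edir, sprintf("T%03d.tif", tp)),
                     frame_rate = spec$schedule$frame_rate)
      manifest[[length(manifest) + 1L]] <- data.frame(
        embryo_id = id, timepoint = tp, time_h = g$truth$time_h,
        area_px = g$truth$area_px, heart_hz = g$truth$heart_hz,
        heart_on = g$truth$heart_on, alive = g$truth$alive,
        death_mode = spec$death$mode, death_time_h = spec$death$time_h,
        growth_px2_h = spec$embryo$growth_px2_h, seed = spec$seed)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  layout <- experiment_layout(names(specs), sched, scale = scale,
                              species = species,
                              roi_size = specs[[1L]]$frame_size)
  yaml::write_yaml(list(
    embryos = names(specs),
    schedule = list(frames_per_sequence = sched$frames_per_sequence,
                    frame_rate = sched$frame_rate,
                    repeat_interval = sched$repeat_interval,
                    n_timepoints = sched$n_timepoints),
    scale = scale, species = species,
    roi_size = specs[[1L]]$frame_size),
    file.path(out_dir, "config.yaml"))
  attr(layout, "manifest") <- manifest
  attr(layout, "dir") <- out_dir
  invisible(layout)
}

#' Generate a seeded trait-level synthetic cohort
#'
#' Emulates the per-timepoint trait tables the image pipeline produces
#' — mean-area and summed band-energy series — for a cohort with known
#' death times, without rendering frames. Healthy embryos grow
#' linearly with multiplicative noise and hold a stable energy
#' baseline; osmotic deaths spike the area (then shrink 40%) and kill
#' the energy; cardiac-cessation deaths collapse the energy while the
#' area stays stable. Used to validate the end point detectors and
#' survival summaries at cohort scale.
#'
#' @param n_embryos Cohort size.
#' @param schedule A [recording_schedule()] (its burst structure is
#'   ignored; only the timepoint grid matters).
#' @param death_times_h Numeric vector of death times (NA = survives),
#'   or NULL to draw them from `death_model`.
#' @param death_model List: `delay_h` (lethal effects need a latency
#'   after exposure start before the first deaths; embryos are alive
#'   and provide a baseline at the start of the window) plus
#'   `rate_per_h` for exponential death times after the latency (times
#'   past the window become censored), and `mode` (`"osmotic"`,
#'   `"cardiac_cessation"`, or `"mixed"`).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   observation noise.
#' @param seed Integer seed.
#' @return List with `traits` (named list of per-embryo trait tables
#'   with `time_h`, `area_mean`, `total_energy`) and `truth` (data
#'   frame: `embryo_id`, `death_time_h`, `death_mode`).
#' @export
generate_trait_cohort <- function(n_embryos,
                                  schedule = recording_schedule(600L, 20, 60, 25L),
                                  death_times_h = NULL,
                                  death_model = list(rate_per_h = 0.08,
                                                     delay_h = 4,
                                                     mode = "mixed"),
                                  noise_cv = 0.03, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  tgrid <- (seq_len(schedule$n_timepoints) - 1L) *
    schedule$repeat_interval / 60
  dt <- schedule$repeat_interval / 60
  if (is.null(death_times_h)) {
    if (is.null(death_model$delay_h)) death_model$delay_h <- 4
    raw <- death_model$delay_h +
      stats::rexp(n_embryos, death_model$rate_per_h)
    # deaths snap to the recording grid; beyond the window = censored
    death_times_h <- ifelse(raw > max(tgrid), NA_real_,
                            round(raw / dt) * dt)
  }
  mode_of <- function(i) {
    if (death_model$mode != "mixed") return(death_model$mode)
    if (i %% 2L == 0L) "osmotic" else "cardiac_cessation"
  }
  traits <- list(); truth <- list()
  for (i in seq_len(n_embryos)) {
    id <- sprintf("SYN%03d", i)
    td <- death_times_h[i]
    md <- if (is.na(td)) "none" else mode_of(i)
    area0 <- stats::runif(1, 800, 1200)
    g <- stats::runif(1, 15, 30)
    e0 <- stats::runif(1, 50, 150)
    area <- area0 + g * tgrid
    energy <- rep(e0, length(tgrid))
    if (!is.na(td)) {
      dead <- tgrid >= td
      a_td <- area0 + g * td
      if (md == "osmotic") {
        spike_win <- dead & tgrid < td + 2 * dt
        area[spike_win] <- a_td * 1.6
        area[dead & !spike_win] <- a_td * 0.6
      } else {
        area[dead] <- a_td
      }
      energy[dead] <- e0 * 0.02
    }
    area <- area * (1 + stats::rnorm(length(tgrid), 0, noise_cv))
    energy <- pmax(energy * (1 + stats::rnorm(length(tgrid), 0, noise_cv)),
                   0)
    traits[[id]] <- data.frame(time_h = tgrid, area_mean = area,
                               total_energy = energy)
    truth[[i]] <- data.frame(embryo_id = id, death_time_h = td,
                             death_mode = md, area0 = area0,
                             growth = g, energy0 = e0)
  }
  list(traits = traits, truth = do.call(rbind, truth))
}
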