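#' Recording schedule
#'
#' Describes one repeating acquisition block: a burst of
#' `frames_per_sequence` frames captured at `frame_rate` frames per
#' second, repeated every `repeat_interval` minutes, `n_timepoints`
#' times in total. The number of timepoints is always declared
#' explicitly, never inferred from the experiment duration, because
#' inclusive vs exclusive endpoint conventions differ between
#' experimental designs.
#'
#' @param frames_per_sequence Number of frames in one recording (>= 2).
#' @param frame_rate Acquisition rate in frames per second.
#' @param repeat_interval Minutes between the starts of consecutive
#'   recordings.
#' @param n_timepoints Number of recordings per embryo (>= 1).
#' @return An object of class `recording_schedule`.
#' @examples
#' recording_schedule(600, 20, 60, 25)  # hourly 30 s bursts at 20 fps
#' @export
recording_schedule <- function(frames_per_sequence, frame_rate,
                               repeat_interval, n_timepoints) {
  frames_per_sequence <- as.integer(frames_per_sequence)
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(frames_per_sequence) || frames_per_sequence < 2L)
    stop("frames_per_sequence must be >= 2", call. = FALSE)
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be > 0", call. = FALSE)
  if (is.na(n_timepoints) || n_timepoints < 1L)
    stop("n_timepoints must be >= 1", call. = FALSE)
  if (!is.finite(repeat_interval) || repeat_interval <= 0)
    stop("repeat_interval must be > 0", call. = FALSE)
  if (frames_per_sequence / frame_rate >= repeat_interval * 60)
    stop("sequence duration (frames_per_sequence / frame_rate) must be ",
         "shorter than the repeat interval", call. = FALSE)
  structure(
    list(frames_per_sequence = frames_per_sequence,
         frame_rate = frame_rate,
         repeat_interval = repeat_interval,
         n_timepoints = n_timepoints,
         duration_h = (n_timepoints - 1L) * repeat_interval / 60),
    class = "recording_schedule")
}

#' @export
print.recording_schedule <- function(x, ...) {
  cat(sprintf(
    "<recording_schedule> %d frames @ %g fps, every %g min, %d timepoints (%g h span)\n",
    x$frames_per_sequence, x$frame_rate, x$repeat_interval,
    x$n_timepoints, x$duration_h))
  invisible(x)
}

#' Experiment layout
#'
#' The static description of an experiment: the embryo roster with
#' treatment labels, the recording schedule, the optical scale and the
#' square region-of-interest size used at acquisition.
#'
#' @param embryos Character vector of unique embryo ids.
#' @param schedule A [recording_schedule()].
#' @param scale Micrometres per pixel (> 0), or `NA` for unscaled
#'   pixel units.
#' @param species Free-text species label.
#' @param roi_size Side of the square acquisition ROI in pixels.
#' @param treatments Optional character vector of treatment labels,
#'   one per embryo (recycled if length 1).
#' @return An object of class `experiment_layout`.
#' @export
experiment_layout <- function(embryos, schedule, scale = NA_real_,
                              species = "unspecified", roi_size = 750L,
                              treatments = NULL) {
  embryos <- as.character(embryos)
  if (anyDuplicated(embryos))
    stop("duplicate embryo ids: ",
         paste(unique(embryos[duplicated(embryos)]), collapse = ", "),
         call. = FALSE)
  if (!inherits(schedule, "recording_schedule"))
    stop("schedule must be a recording_schedule", call. = FALSE)
  if (!is.na(scale) && (!is.finite(scale) || scale <= 0))
    stop("scale must be > 0 (um per pixel)", call. = FALSE)
  roi_size <- as.integer(roi_size)
  if (is.na(roi_size) || roi_size <= 0L)
    stop("roi_size must be a positive pixel count", call. = FALSE)
  if (is.null(treatments)) treatments <- rep("none", length(embryos))
  if (length(treatments) == 1L) treatments <- rep(treatments, length(embryos))
  if (length(treatments) != length(embryos))
    stop("treatments must match the embryo roster length", call. = FALSE)
  structure(
    list(embryos = embryos, treatments = as.character(treatments),
         schedule = schedule, scale = scale, species = species,
         roi_size = roi_size),
    class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat(sprintf("<experiment_layout> %d embryos, species '%s', scale %s um/px, ROI %d px\n",
              length(x$embryos), x$species,
              ifelse(is.na(x$scale), "unset", format(x$scale)), x$roi_size))
  print(x$schedule)
  invisible(x)
}

.layout_keys <- c("embryos", "treatments", "schedule", "scale", "species",
                  "roi_size", "data_dir")
.schedule_keys <- c("frames_per_sequence", "frame_rate", "repeat_interval",
                    "n_timepoints")

#' Load an experiment configuration
#'
#' Reads a YAML (or JSON) configuration declaring the recording
#' schedule, optical scale, species and either an explicit embryo
#' roster or a data directory whose sub-directories name the embryos.
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param config_path Path to the configuration file.
#' @return A validated [experiment_layout()].
#' @export
load_experiment <- function(config_path) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_path)
  }
  unknown <- setdiff(names(cfg), .layout_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$schedule))
    stop("configuration must declare a schedule", call. = FALSE)
  unknown_s <- setdiff(names(cfg$schedule), .schedule_keys)
  if (length(unknown_s))
    stop("unknown schedule keys: ", paste(unknown_s, collapse = ", "),
         call. = FALSE)
  sched <- do.call(recording_schedule, cfg$schedule)
  embryos <- cfg$embryos
  if (is.null(embryos)) {
    if (is.null(cfg$data_dir))
      stop("configuration must declare embryos or a data_dir to scan",
           call. = FALSE)
    embryos <- sort(list.dirs(cfg$data_dir, recursive = FALSE,
                              full.names = FALSE))
  }
  experiment_layout(
    embryos = as.character(unlist(embryos)),
    schedule = sched,
    scale = if (is.null(cfg$scale)) NA_real_ else cfg$scale,
    species = if (is.null(cfg$species)) "unspecified" else cfg$species,
    roi_size = if (is.null(cfg$roi_size)) 750L else cfg$roi_size,
    treatments = if (is.null(cfg$treatments)) NULL
                 else as.character(unlist(cfg$treatments)))
}

#' Expected number of images for a schedule
#'
#' The acquisition bookkeeping identity: an experiment acquires
#' `n_embryos * frames_per_sequence * n_timepoints` images. Useful for
#' verifying a storage tree is complete before analysis.
#'
#' @param n_embryos Number of embryos imaged.
#' @param schedule A [recording_schedule()].
#' @return Total expected image count (double, to stay exact above
#'   `.Machine$integer.max`).
#' @examples
#' expected_image_count(48, recording_schedule(600, 20, 60, 25)) # 720000
#' @export
expected_image_count <- function(n_embryos, schedule) {
  n_embryos <- as.numeric(n_embryos)
  if (is.na(n_embryos) || n_embryos < 0)
    stop("n_embryos must be >= 0", call. = FALSE)
  n_embryos * schedule$frames_per_sequence * schedule$n_timepoints
}

#' Image sequence container
#'
#' One recording: an ordered stack of 16-bit grayscale frames with one
#' timestamp per frame (seconds since the start of the experiment,
#' strictly increasing) and identity metadata.
#'
#' @param frames Numeric array `rows x cols x n_frames` (a single
#'   matrix is promoted to one frame). Values in `[0, 65535]`.
#' @param timestamps Numeric vector, seconds, one per frame, strictly
#'   increasing.
#' @param embryo_id Embryo identifier.
#' @param timepoint Zero-based recording index.
#' @param timestamp_source `"metadata"` or `"synthesized"`.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, timestamps, embryo_id = "unknown",
                           timepoint = 0L,
                           timestamp_source = "metadata") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L)
    stop("frames must be a rows x cols x n array", call. = FALSE)
  n <- dim(frames)[3L]
  if (length(timestamps) != n)
    stop("need one timestamp per frame (", n, " frames, ",
         length(timestamps), " timestamps)", call. = FALSE)
  if (n > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (max(frames, na.rm = TRUE) > 65535 || min(frames, na.rm = TRUE) < 0)
    stop("frame intensities must lie in [0, 65535] (<= 16-bit)",
         call. = FALSE)
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         embryo_id = as.character(embryo_id),
         timepoint = as.integer(timepoint),
         timestamp_source = timestamp_source),
    class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence> embryo %s, timepoint %d: %d frames of %dx%d (timestamps %s)\n",
              x$embryo_id, x$timepoint, d[3], d[1], d[2], x$timestamp_source))
  invisible(x)
}

#' Read one recording from disk
#'
#' Accepts either a multipage 16-bit TIFF or a directory of
#' single-frame TIFFs in lexicographic frame-index order. A JSON
#' metadata sidecar (same path with `_metadata.json` appended, or
#' `metadata.json` inside a frame directory) supplies per-frame elapsed
#' milliseconds in the style of MicroManager (`elapsed_ms`); without a
#' sidecar, timestamps are synthesized from the nominal frame rate and
#' flagged as such.
#'
#' @param path Multipage TIFF file or directory of numbered TIFFs.
#' @param frame_rate Nominal fps used to synthesize timestamps when no
#'   metadata sidecar is present.
#' @param embryo_id,timepoint Identity attached to the sequence;
#'   defaults are taken from the metadata sidecar when present.
#' @return An [image_sequence()].
#' @export
read_sequence <- function(path, frame_rate = NULL, embryo_id = NULL,
                          timepoint = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF frames found in ", path, call. = FALSE)
    mats <- vector("list", length(files))
    for (i in seq_along(files)) {
      m <- tryCatch(tiff::readTIFF(files[i]),
                    error = function(e)
                      stop("unreadable frame at index ", i, " (",
                           basename(files[i]), "): ", conditionMessage(e),
                           call. = FALSE))
      mats[[i]] <- m
    }
    meta_path <- file.path(path, "metadata.json")
  } else {
    if (!file.exists(path)) stop("no such sequence: ", path, call. = FALSE)
    mats <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(mats)) mats <- list(mats)
    meta_path <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE),
                        "_metadata.json")
  }
  shapes <- vapply(mats, function(m) paste(dim(m)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    stop("mixed frame shapes within one sequence: ",
         paste(unique(shapes), collapse = ", "), call. = FALSE)
  # readTIFF returns [0,1]-normalized intensities; restore 16-bit counts
  d <- dim(mats[[1L]])[1:2]
  frames <- array(0, c(d, length(mats)))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]   # collapse accidental channels
    frames[, , i] <- round(m * 65535)
  }
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else NULL
  if (!is.null(meta$elapsed_ms) &&
      length(meta$elapsed_ms) == length(mats)) {
    ts <- as.numeric(meta$elapsed_ms) / 1000
    src <- "metadata"
  } else {
    if (is.null(frame_rate) && !is.null(meta$frame_rate))
      frame_rate <- meta$frame_rate
    if (is.null(frame_rate))
      stop("no metadata timestamps and no frame_rate to synthesize them",
           call. = FALSE)
    ts <- (seq_along(mats) - 1) / frame_rate
    src <- "synthesized"
  }
  if (is.null(embryo_id))
    embryo_id <- if (!is.null(meta$embryo_id)) meta$embryo_id else "unknown"
  if (is.null(timepoint))
    timepoint <- if (!is.null(meta$timepoint)) meta$timepoint else 0L
  image_sequence(frames, ts, embryo_id = embryo_id, timepoint = timepoint,
                 timestamp_source = src)
}

#' Write one recording to disk as a multipage 16-bit TIFF
#'
#' Companion to [read_sequence()]; writes the frames plus a JSON
#' metadata sidecar carrying per-frame elapsed milliseconds, the frame
#' rate, and the sequence identity.
#'
#' @param sequence An [image_sequence()].
#' @param path Output `.tif` path.
#' @param frame_rate Nominal fps recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(sequence, path, frame_rate = NULL) {
  n <- dim(sequence$frames)[3L]
  pages <- lapply(seq_len(n), function(i) {
    m <- sequence$frames[, , i] / 65535
    m[!is.finite(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(embryo_id = sequence$embryo_id,
               timepoint = sequence$timepoint,
               n_frames = n,
               frame_rate = frame_rate,
               elapsed_ms = round(sequence$timestamps * 1000, 6))
  jsonlite::write_json(meta,
                       paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE),
                              "_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
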