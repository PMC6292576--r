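#' Run the full quantification pipeline over an experiment tree
#'
#' For every embryo in the layout: locates the egg ROI (from the first
#' readable recording), applies any ROI overrides, then for every
#' timepoint segments all frames, extracts blockwise signals and Welch
#' spectra, computes band energies and a cardiac-frequency estimate,
#' and integrates the per-timepoint trait row. Results are written as
#' one [phenome_dataset()] per embryo. Failures are isolated per
#' embryo — one bad embryo never aborts the run — and summarized in
#' the returned manifest.
#'
#' @param layout An [experiment_layout()] (or path to a config file
#'   for [load_experiment()]).
#' @param input_dir Acquisition tree: one sub-directory per embryo
#'   containing `T<index>.tif` recordings (as written by
#'   [generate_experiment()]).
#' @param out_dir Output directory for per-embryo datasets.
#' @param levels Block grid levels.
#' @param band Cardiac physiological band, Hz.
#' @param band_edges Band edges for energies (NULL = 0.5 Hz bins).
#' @param overrides_file Optional ROI override CSV.
#' @param exclude Character vector of embryo ids to exclude (the
#'   bookkeeping for manually removed / abnormal embryos).
#' @return An object of class `run_manifest`: per-embryo status table
#'   plus counts (`analysed + failed + excluded = total`), written
#'   even on partial failure, and `exit_code` (0 all analysed, 3
#'   partial, 1 none).
#' @export
run_pipeline <- function(layout, input_dir, out_dir,
                         levels = c(1L, 2L, 4L, 8L, 16L),
                         band = c(0.5, 5), band_edges = NULL,
                         overrides_file = NULL, exclude = character(0)) {
  if (is.character(layout)) layout <- load_experiment(layout)
  if (!dir.exists(input_dir) ||
      !length(list.files(input_dir, recursive = TRUE)))
    stop("empty or missing input tree: ", input_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sched <- layout$schedule
  status <- character(0); notes <- character(0)
  for (id in layout$embryos) {
    if (id %in% exclude) {
      status[id] <- "excluded"; notes[id] <- "user exclusion list"
      next
    }
    res <- tryCatch({
      .quantify_embryo(id, layout, input_dir, out_dir, levels, band,
                       band_edges, overrides_file)
      "analysed"
    }, error = function(e) {
      message("embryo ", id, " failed: ", conditionMessage(e))
      notes[id] <<- conditionMessage(e)
      "failed"
    })
    status[id] <- res
    if (is.na(notes[id])) notes[id] <- ""
  }
  counts <- c(analysed = sum(status == "analysed"),
              failed = sum(status == "failed"),
              excluded = sum(status == "excluded"))
  exit_code <- if (counts["analysed"] == length(layout$embryos)) 0L
               else if (counts["analysed"] > 0L) 3L else 1L
  manifest <- structure(
    list(table = data.frame(embryo_id = layout$embryos,
                            status = unname(status[layout$embryos]),
                            note = unname(notes[layout$embryos]),
                            stringsAsFactors = FALSE),
         counts = counts, total = length(layout$embryos),
         exit_code = exit_code,
         package_version = as.character(utils::packageVersion("embryovision"))),
    class = "run_manifest")
  .write_table(manifest$table, file.path(out_dir, "run_manifest.csv"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d embryos: %d analysed, %d failed, %d excluded (exit %d)\n",
              x$total, x$counts["analysed"], x$counts["failed"],
              x$counts["excluded"], x$exit_code))
  invisible(x)
}

.quantify_embryo <- function(id, layout, input_dir, out_dir, levels,
                             band, band_edges, overrides_file) {
  edir <- file.path(input_dir, id)
  files <- sort(list.files(edir, pattern = "^T\\d+\\.tiff?$",
                           full.names = TRUE))
  if (!length(files)) stop("no recordings found for embryo ", id)
  sched <- layout$schedule
  first <- read_sequence(files[1L], frame_rate = sched$frame_rate)
  roi <- locate_egg(first)
  rois <- stats::setNames(list(roi), id)
  if (!is.null(overrides_file))
    rois <- apply_roi_overrides(rois, overrides_file,
                                frame_dim = dim(first$frames)[1:2])
  roi <- rois[[id]]
  trait_rows <- list(); cardiac_rows <- list()
  sp_freq <- NULL; sp_psd <- list()
  n_tp <- sched$n_timepoints
  for (tp in seq_len(n_tp) - 1L) {
    f <- file.path(edir, sprintf("T%03d.tif", tp))
    t_h <- tp * sched$repeat_interval / 60
    if (!file.exists(f)) {
      trait_rows[[tp + 1L]] <- integrate_timepoint(.na_measures(),
                                                   time_h = t_h)
      cardiac_rows[[tp + 1L]] <- data.frame(time_h = t_h,
                                            frequency = NaN, power = NaN,
                                            quality = 0,
                                            n_blocks_used = 0L)
      next
    }
    seqn <- read_sequence(f, frame_rate = sched$frame_rate,
                          embryo_id = id, timepoint = tp)
    fm <- segment_sequence(seqn, roi)
    blocks <- blockwise_signals(seqn, roi, levels = levels)
    spectra <- block_spectra(blocks)
    be <- band_energies(spectra$spectra[[1L]][[1L]], band_edges)
    est <- identify_cardiac_frequency(spectra, band = band)
    trait_rows[[tp + 1L]] <- integrate_timepoint(fm, be,
                                                 scale = layout$scale,
                                                 time_h = t_h)
    cardiac_rows[[tp + 1L]] <- data.frame(time_h = t_h,
                                          frequency = est$frequency,
                                          power = est$power,
                                          quality = est$quality,
                                          n_blocks_used = est$n_blocks_used)
  }
  traits <- do.call(rbind, trait_rows)
  cardiac <- do.call(rbind, cardiac_rows)
  units <- list(time_h = "h", movement = if (is.na(layout$scale)) "px"
                else "um",
                area_mean = if (is.na(layout$scale)) "px^2" else "um^2",
                frequency = "Hz", total_energy = "intensity^2")
  ds <- phenome_dataset(id, traits = traits, cardiac = cardiac,
                        meta = list(units = units,
                                    species = layout$species,
                                    scale_um_px = layout$scale,
                                    roi = unclass(roi)))
  write_dataset(ds, file.path(out_dir, id))
  invisible(ds)
}

#' Per-embryo summary report
#'
#' Writes a one-page PDF with the embryo's developmental time series:
#' mean area, per-recording movement, total spectral energy, relative
#' band energies, and the cardiac-frequency series. Returns the
#' plotted arrays so report content can be asserted against the
#' dataset without pixel comparisons.
#'
#' @param dataset A [phenome_dataset()].
#' @param out Output PDF path.
#' @return List of the plotted data arrays (one entry per panel),
#'   invisibly; NULL when the dataset has no timepoints (report
#'   skipped).
#' @export
generate_summary_report <- function(dataset, out) {
  stopifnot(inherits(dataset, "phenome_dataset"))
  tr <- dataset$traits
  if (is.null(tr) || !nrow(tr)) {
    message("report skipped for embryo ", dataset$embryo_id,
            ": dataset has no timepoints")
    return(invisible(NULL))
  }
  ecols <- grep("^energy_", names(tr), value = TRUE)
  panels <- list(
    area = tr[, c("time_h", "area_mean")],
    movement = tr[, c("time_h", "movement")],
    total_energy = if ("total_energy" %in% names(tr))
      tr[, c("time_h", "total_energy")] else NULL,
    band_energy = if (length(ecols)) tr[, c("time_h", ecols)] else NULL,
    cardiac = if (!is.null(dataset$cardiac))
      dataset$cardiac[, c("time_h", "frequency")] else NULL)
  grDevices::pdf(out, width = 8, height = 10)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(3, 2), mar = c(4, 4, 2, 1))
  plot_panel <- function(d, ylab, main, col = "steelblue") {
    if (is.null(d)) return()
    graphics::plot(d[[1L]], d[[2L]], type = "b", pch = 16, col = col,
                   xlab = "time (h)", ylab = ylab, main = main)
  }
  plot_panel(panels$area, "mean area", "Growth")
  plot_panel(panels$movement, "movement per recording", "Movement",
             "darkorange")
  plot_panel(panels$total_energy, "total energy", "Total spectral energy",
             "firebrick")
  if (!is.null(panels$band_energy) && length(ecols)) {
    em <- as.matrix(panels$band_energy[, ecols, drop = FALSE])
    graphics::matplot(panels$band_energy$time_h, em, type = "l", lty = 1,
                      xlab = "time (h)", ylab = "band energy",
                      main = "Frequency-band energies")
  }
  if (!is.null(panels$cardiac)) {
    plot_panel(panels$cardiac, "cardiac rate (Hz)", "Cardiac frequency",
               "purple")
    if (!is.null(dataset$cardiac_model) &&
        is.null(dataset$cardiac_model$reason)) {
      tt <- seq(min(tr$time_h), max(tr$time_h), length.out = 100)
      graphics::lines(tt, predict(dataset$cardiac_model, tt), lwd = 2)
    }
  }
  graphics::mtext(paste("Embryo", dataset$embryo_id), outer = TRUE,
                  line = -1.5, cex = 1.1)
  invisible(panels)
}

#' Export per-embryo summary rows to CSV
#'
#' One row per embryo: growth rate, mean distance moved, mean heart
#' rate and end point call — the cohort-level export shape used for
#' downstream statistics.
#'
#' @param datasets Named list of [phenome_dataset()].
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_summary_csv <- function(datasets, path) {
  rows <- lapply(datasets, function(d) {
    gr <- growth_rate(d)
    mdm <- if (!is.null(d$traits$mean_distance_moved))
      mean(d$traits$mean_distance_moved, na.rm = TRUE) else NaN
    hr <- if (!is.null(d$cardiac))
      mean(d$cardiac$frequency[is.finite(d$cardiac$frequency)]) else NaN
    data.frame(embryo_id = d$embryo_id,
               growth_rate = gr$slope,
               mean_distance_moved = mdm,
               mean_heart_rate_hz = hr,
               death_time_h = if (!is.null(d$endpoints))
                 d$endpoints$death_time_h[1L] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
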