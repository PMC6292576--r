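#' Per-embryo phenome dataset
#'
#' The hierarchical result container for one embryo, mirroring the
#' pipeline's groups: `traits` (per-timepoint trait table), `spectra`
#' (block-resolved Welch spectra, one `block x frequency x time` array
#' per grid level), `cardiac` (per-timepoint cardiac estimates and the
#' fitted ontogeny model), and `endpoints` (lethal end point calls).
#' All stored variables carry units in `meta$units`.
#'
#' @param embryo_id Embryo identifier.
#' @param traits Per-timepoint data frame; must contain `time_h`.
#' @param spectra Optional list with `levels` (integer vector), `freq`
#'   (list of frequency grids, Hz, one per level) and `psd` (list of
#'   `block x frequency x time` arrays, one per level).
#' @param cardiac Optional per-timepoint cardiac estimate table.
#' @param cardiac_model Optional fitted [fit_cardiac_model()] result.
#' @param endpoints Optional end point result table.
#' @param meta List of metadata; `units` is a named list mapping
#'   variable names to unit strings.
#' @return An object of class `phenome_dataset`.
#' @export
phenome_dataset <- function(embryo_id, traits = NULL, spectra = NULL,
                            cardiac = NULL, cardiac_model = NULL,
                            endpoints = NULL, meta = list()) {
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    if (nrow(traits) && !"time_h" %in% names(traits))
      stop("traits must carry a shared time_h axis", call. = FALSE)
  }
  if (!is.null(spectra)) {
    stopifnot(is.list(spectra),
              all(c("levels", "freq", "psd") %in% names(spectra)))
    for (i in seq_along(spectra$levels)) {
      a <- spectra$psd[[i]]
      if (length(dim(a)) != 3L)
        stop("each spectra$psd entry must be block x frequency x time",
             call. = FALSE)
      if (dim(a)[2L] != length(spectra$freq[[i]]))
        stop("frequency axis mismatch at level ", spectra$levels[i],
             call. = FALSE)
    }
  }
  if (is.null(meta$units))
    meta$units <- list(time_h = "h", area_mean = "px^2", movement = "px")
  structure(
    list(embryo_id = as.character(embryo_id), traits = traits,
         spectra = spectra, cardiac = cardiac,
         cardiac_model = cardiac_model, endpoints = endpoints,
         meta = meta, format_version = 1L),
    class = "phenome_dataset")
}

#' @export
print.phenome_dataset <- function(x, ...) {
  cat(sprintf("<phenome_dataset> embryo %s: %s timepoints", x$embryo_id,
              if (is.null(x$traits)) 0L else nrow(x$traits)))
  if (!is.null(x$spectra))
    cat(sprintf(", spectra levels {%s}",
                paste(x$spectra$levels, collapse = ",")))
  if (!is.null(x$cardiac)) cat(", cardiac")
  if (!is.null(x$endpoints)) cat(", endpoints")
  cat("\n")
  invisible(x)
}

# Full-precision numeric serialization: %.17g round-trips IEEE doubles
# exactly through as.numeric(), and preserves the NA / NaN distinction.
.num_to_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out[is.nan(x)] <- "NaN"
  out
}
.chr_to_num <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "NaN"] <- NaN
  out
}

.write_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- .num_to_chr(out[[nm]])
  }
  cls <- vapply(df, function(c) class(c)[1L], "")
  data.table::fwrite(out, path, quote = TRUE, na = "NA")
  cls
}

.read_table <- function(path, cls) {
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  df <- as.data.frame(dt)
  for (nm in names(df)) {
    df[[nm]] <- switch(cls[[nm]],
      numeric = .chr_to_num(df[[nm]]),
      integer = {v <- df[[nm]]; v[v == "NA"] <- NA; as.integer(v)},
      logical = {v <- df[[nm]]; v[v == "NA"] <- NA; as.logical(v)},
      character = {v <- df[[nm]]; v[v == "NA"] <- NA_character_; v},
      df[[nm]])
  }
  df
}

#' Write a phenome dataset to disk
#'
#' Serializes the dataset as a version-stamped directory: JSON metadata
#' plus one full-precision CSV per group (`traits.csv`, `cardiac.csv`,
#' `endpoints.csv`, and `spectra_L<level>.csv` with one row per
#' block/time pair and one column per frequency). Floating-point values
#' are written with 17 significant digits so the round trip is
#' bit-exact, and NaN-masked failed frames survive the round trip.
#'
#' @param dataset A [phenome_dataset()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "phenome_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = dataset$format_version,
               embryo_id = dataset$embryo_id,
               meta = dataset$meta,
               groups = list())
  for (grp in c("traits", "cardiac", "endpoints")) {
    df <- dataset[[grp]]
    if (!is.null(df)) {
      cls <- .write_table(df, file.path(path, paste0(grp, ".csv")))
      meta$groups[[grp]] <- list(colclasses = as.list(cls))
    }
  }
  if (!is.null(dataset$spectra)) {
    sp <- dataset$spectra
    meta$groups$spectra <- list(
      levels = sp$levels,
      freq = lapply(sp$freq, .num_to_chr),
      dims = lapply(sp$psd, dim))
    for (i in seq_along(sp$levels)) {
      a <- sp$psd[[i]]                       # block x freq x time
      d <- dim(a)
      flat <- matrix(aperm(a, c(2L, 1L, 3L)), nrow = d[1L] * d[3L],
                     ncol = d[2L], byrow = TRUE)
      df <- data.frame(block = rep(seq_len(d[1L]), times = d[3L]),
                       time_index = rep(seq_len(d[3L]), each = d[1L]))
      psd_chr <- matrix(.num_to_chr(flat), nrow = nrow(flat))
      colnames(psd_chr) <- paste0("f", seq_len(d[2L]))
      data.table::fwrite(cbind(df, as.data.frame(psd_chr)),
                         file.path(path,
                                   paste0("spectra_L", sp$levels[i], ".csv")),
                         quote = TRUE)
    }
  }
  if (!is.null(dataset$cardiac_model))
    meta$cardiac_model <- rapply(unclass(dataset$cardiac_model),
                                 .num_to_chr, classes = "numeric",
                                 how = "replace")
  jsonlite::write_json(meta, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a phenome dataset from disk
#'
#' Inverse of [write_dataset()]. Files written by an incompatible
#' format version raise an explicit migration error rather than being
#' misread.
#'
#' @param path Dataset directory written by [write_dataset()].
#' @return A [phenome_dataset()].
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "dataset.json")
  if (!file.exists(meta_path))
    stop("not a phenome dataset directory: ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stop("dataset written by incompatible format version ",
         meta$format_version, "; migrate before reading", call. = FALSE)
  grab <- function(grp) {
    f <- file.path(path, paste0(grp, ".csv"))
    if (!file.exists(f)) return(NULL)
    .read_table(f, meta$groups[[grp]]$colclasses)
  }
  spectra <- NULL
  if (!is.null(meta$groups$spectra)) {
    levels <- as.integer(meta$groups$spectra$levels)
    # jsonlite may simplify per-level lists of equal length to matrices
    as_rows <- function(x) {
      if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
      else if (is.list(x)) x else list(x)
    }
    freq <- lapply(as_rows(meta$groups$spectra$freq), .chr_to_num)
    dims <- as_rows(meta$groups$spectra$dims)
    psd <- vector("list", length(levels))
    for (i in seq_along(levels)) {
      df <- as.data.frame(data.table::fread(
        file.path(path, paste0("spectra_L", levels[i], ".csv")),
        colClasses = "character", na.strings = NULL))
      d <- as.integer(unlist(dims[[i]]))
      vals <- matrix(.chr_to_num(as.matrix(df[, -(1:2), drop = FALSE])),
                     nrow = nrow(df))
      a <- array(NA_real_, d)
      ti_idx <- as.integer(df$time_index)
      for (ti in seq_len(d[3L]))
        a[, , ti] <- vals[ti_idx == ti, , drop = FALSE]
      psd[[i]] <- a
    }
    spectra <- list(levels = levels, freq = freq, psd = psd)
  }
  cm <- if (!is.null(meta$cardiac_model)) {
    # numeric leaves were %.17g-encoded at write time; text leaves
    # (model kind, reason codes) pass through untouched
    thaw <- function(s) {
      v <- suppressWarnings(as.numeric(s))
      if (all(!is.na(v) | s %in% c("NA", "NaN"))) .chr_to_num(s) else s
    }
    m <- rapply(meta$cardiac_model, thaw, classes = "character",
                how = "replace")
    class(m) <- "cardiac_model"
    m
  } else NULL
  units <- meta$meta$units
  m2 <- meta$meta
  m2$units <- as.list(units)
  phenome_dataset(embryo_id = meta$embryo_id,
                  traits = grab("traits"),
                  spectra = spectra,
                  cardiac = grab("cardiac"),
                  cardiac_model = cm,
                  endpoints = grab("endpoints"),
                  meta = m2)
}
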