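#' Multiresolution blockwise mean-intensity signals
#'
#' Overlays square grids of 1x1, 2x2, 4x4, 8x8 and 16x16 blocks on the
#' egg ROI bounding box and records, for every frame, the mean pixel
#' intensity of each block over the pixels inside both the block and
#' the ROI ellipse. The grid is anchored to the (static) egg ROI, not
#' the moving embryo, so block identity is stable across frames and
#' block signals are valid inputs for frequency analysis. Grid edges
#' at level `L` are `round(i * side / L)`, so coarser grids are exact
#' unions of finer ones and the pixel-count-weighted mean of a block's
#' children reproduces the parent signal exactly.
#'
#' @param sequence An [image_sequence()].
#' @param roi An [egg_roi()].
#' @param levels Grid levels, a subset of `c(1, 2, 4, 8, 16)`.
#' @return An object of class `block_signal_set`: per level a
#'   `block x frame` matrix of means (blocks in row-major grid order;
#'   blocks with no ROI pixels are NaN), plus pixel counts, the grid
#'   geometry and the frame timestamps.
#' @export
blockwise_signals <- function(sequence, roi, levels = c(1L, 2L, 4L, 8L, 16L)) {
  levels <- sort(unique(as.integer(levels)))
  if (!all(levels %in% c(1L, 2L, 4L, 8L, 16L)))
    stop("levels must be a subset of {1, 2, 4, 8, 16}", call. = FALSE)
  d <- dim(sequence$frames)
  bb <- .roi_bbox(roi, d[1:2])
  h <- unname(bb["height"]); w <- unname(bb["width"])
  rows <- (bb["top"] + 1):(bb["top"] + h)
  cols <- (bb["left"] + 1):(bb["left"] + w)
  mask <- .ellipse_mask(h, w, roi$center - c(bb["top"], bb["left"]),
                        roi$semi_axes, roi$angle)
  mvec <- as.vector(mask)
  n <- d[3L]
  # masked pixel values for all frames at once: npix x n
  flat <- matrix(sequence$frames[rows, cols, , drop = FALSE], nrow = h * w)
  vm <- flat[mvec, , drop = FALSE]
  ri <- ((row(mask) - 1L))[mask]           # 0-based local coords of ROI px
  ci <- ((col(mask) - 1L))[mask]
  signals <- counts <- vector("list", length(levels))
  names(signals) <- names(counts) <- paste0("L", levels)
  for (k in seq_along(levels)) {
    L <- levels[k]
    redge <- round(seq(0, h, length.out = L + 1))
    cedge <- round(seq(0, w, length.out = L + 1))
    rb <- findInterval(ri, redge, rightmost.closed = TRUE)
    cb <- findInterval(ci, cedge, rightmost.closed = TRUE)
    idx <- (rb - 1L) * L + cb               # row-major block index
    cnt <- tabulate(idx, nbins = L * L)
    sums <- rowsum(vm, group = idx, reorder = TRUE)
    out <- matrix(NaN, L * L, n)
    present <- sort(unique(idx))
    out[present, ] <- sums / cnt[present]
    signals[[k]] <- out
    counts[[k]] <- cnt
  }
  structure(
    list(levels = levels, signals = signals, counts = counts,
         bbox = bb, roi = roi, timestamps = sequence$timestamps,
         frame_rate = if (n > 1)
           1 / stats::median(diff(sequence$timestamps)) else NA_real_,
         embryo_id = sequence$embryo_id, timepoint = sequence$timepoint),
    class = "block_signal_set")
}

#' @export
print.block_signal_set <- function(x, ...) {
  cat(sprintf("<block_signal_set> levels {%s}, %d frames, bbox %dx%d\n",
              paste(x$levels, collapse = ","), length(x$timestamps),
              x$bbox["height"], x$bbox["width"]))
  invisible(x)
}

# Welch segment length: largest power of two <= 2N/3 (capped at 256)
# guarantees at least two 50%-overlapping segments.
.welch_nperseg <- function(n) {
  if (n < 8L) return(NA_integer_)
  min(256L, 2L^floor(log2(2 * n / 3)))
}

#' Welch power spectral density
#'
#' One-sided Welch PSD estimate with fixed conventions: Hann window,
#' segment length `min(256, 2^floor(log2(2N/3)))` (so at least two
#' segments always contribute), 50% overlap, per-segment constant
#' detrend, density normalization (`sum(PSD) * df` approximates the
#' signal variance). NaN gaps of up to `max_gap` samples (failed
#' frames) are linearly interpolated; longer gaps or too-short signals
#' yield a spectrum-unavailable marker (`available = FALSE`) rather
#' than an error, which downstream traits propagate as NaN.
#'
#' @param x Numeric signal (may contain NaN gaps).
#' @param fs Sampling rate, Hz.
#' @param nperseg Segment length override.
#' @param max_gap Longest NaN run that is interpolated (default 5).
#' @return An object of class `welch_spectrum`: `freq` (Hz, 0 to
#'   Nyquist), `psd` (power per Hz), `df`, `available`, and the
#'   estimation parameters.
#' @export
welch_psd <- function(x, fs, nperseg = NULL, max_gap = 5L) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  x <- as.numeric(x)
  n <- length(x)
  unavailable <- function(reason) {
    structure(list(freq = NA_real_, psd = NA_real_, df = NA_real_,
                   available = FALSE, reason = reason, fs = fs,
                   nperseg = NA_integer_),
              class = "welch_spectrum")
  }
  bad <- !is.finite(x)
  if (all(bad)) return(unavailable("all samples missing"))
  if (any(bad)) {
    runs <- rle(bad)
    if (max(runs$lengths[runs$values]) > max_gap || bad[1L] || bad[n])
      return(unavailable("gap too long to interpolate"))
    ok <- which(!bad)
    x[bad] <- stats::approx(ok, x[ok], xout = which(bad))$y
  }
  if (is.null(nperseg)) nperseg <- .welch_nperseg(n)
  if (is.na(nperseg) || n < 1.5 * nperseg)
    return(unavailable("signal too short for two Welch segments"))
  step <- nperseg %/% 2L
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1L)) / nperseg)  # periodic Hann
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + Re(sp * Conj(sp))
  }
  psd <- acc / length(starts) / (fs * sum(w^2))
  # one-sided: double everything except DC and (even nperseg) Nyquist
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (nperseg %% 2L == 0L) dbl[nf] <- 1
  psd <- psd * dbl
  structure(list(freq = (0:(nf - 1L)) * fs / nperseg, psd = psd,
                 df = fs / nperseg, available = TRUE, reason = NULL,
                 fs = fs, nperseg = as.integer(nperseg)),
            class = "welch_spectrum")
}

#' @export
print.welch_spectrum <- function(x, ...) {
  if (!x$available) {
    cat("<welch_spectrum> unavailable:", x$reason, "\n")
  } else {
    cat(sprintf("<welch_spectrum> %d bins, df = %.4g Hz, Nyquist %.4g Hz\n",
                length(x$freq), x$df, max(x$freq)))
  }
  invisible(x)
}

#' Welch spectra for every block of a block-signal set
#'
#' @param blocks A [blockwise_signals()] result.
#' @param ... Passed to [welch_psd()].
#' @return An object of class `spectrum_set`: per level a list of
#'   `welch_spectrum` (one per block, row-major), plus the shared
#'   frequency grid per level.
#' @export
block_spectra <- function(blocks, ...) {
  stopifnot(inherits(blocks, "block_signal_set"))
  fs <- blocks$frame_rate
  spectra <- vector("list", length(blocks$levels))
  names(spectra) <- names(blocks$signals)
  for (k in seq_along(blocks$levels)) {
    m <- blocks$signals[[k]]
    spectra[[k]] <- lapply(seq_len(nrow(m)),
                           function(b) welch_psd(m[b, ], fs, ...))
  }
  structure(list(levels = blocks$levels, spectra = spectra, fs = fs,
                 embryo_id = blocks$embryo_id,
                 timepoint = blocks$timepoint),
            class = "spectrum_set")
}

#' Frequency-band energies of a spectrum
#'
#' Integrates the PSD over contiguous frequency bands (trapezoid rule
#' on the Welch frequency grid). `total_energy` is the sum over all
#' bands — the power in intensity fluctuations at all resolved
#' temporal frequencies — and `relative_energy` is each band's share
#' of it.
#'
#' @param spectrum A [welch_psd()] result.
#' @param band_edges Ascending band edges in Hz within `(0, Nyquist]`;
#'   band `i` covers `(edges[i], edges[i+1]]`. Defaults to contiguous
#'   0.5 Hz bins from 0 to Nyquist.
#' @return An object of class `band_energy` with `band_lo`, `band_hi`,
#'   `energy`, `relative_energy`, `total_energy`.
#' @export
band_energies <- function(spectrum, band_edges = NULL) {
  if (!inherits(spectrum, "welch_spectrum"))
    stop("spectrum must be a welch_spectrum", call. = FALSE)
  if (!spectrum$available) {
    return(structure(list(band_lo = NA_real_, band_hi = NA_real_,
                          energy = NA_real_, relative_energy = NA_real_,
                          total_energy = NaN, available = FALSE),
                     class = "band_energy"))
  }
  nyq <- max(spectrum$freq)
  if (is.null(band_edges))
    band_edges <- seq(0, nyq, by = 0.5)
  band_edges <- as.numeric(band_edges)
  if (is.unsorted(band_edges, strictly = TRUE))
    stop("band edges must be strictly ascending", call. = FALSE)
  if (min(band_edges) < 0 || max(band_edges) > nyq + 1e-9)
    stop("band edges must lie within [0, Nyquist = ", format(nyq), "] Hz",
         call. = FALSE)
  nb <- length(band_edges) - 1L
  if (nb < 1L) stop("need at least two band edges", call. = FALSE)
  f <- spectrum$freq; p <- spectrum$psd
  energy <- numeric(nb)
  for (i in seq_len(nb)) {
    lo <- band_edges[i]; hi <- band_edges[i + 1L]
    # trapezoid over the grid restricted to [lo, hi], with interpolated
    # endpoints so refining a partition preserves the total
    fs_in <- f[f > lo & f < hi]
    xs <- c(lo, fs_in, hi)
    ys <- stats::approx(f, p, xout = xs, rule = 2)$y
    energy[i] <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  }
  total <- sum(energy)
  rel <- if (total > 0) energy / total else rep(NaN, nb)
  structure(list(band_lo = band_edges[-length(band_edges)],
                 band_hi = band_edges[-1L], energy = energy,
                 relative_energy = rel, total_energy = total,
                 available = TRUE),
            class = "band_energy")
}

#' @export
print.band_energy <- function(x, ...) {
  if (isFALSE(x$available)) {
    cat("<band_energy> unavailable\n"); return(invisible(x))
  }
  cat(sprintf("<band_energy> %d bands, total energy %.4g\n",
              length(x$energy), x$total_energy))
  invisible(x)
}
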