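#' Identify the cardiac frequency from block spectra
#'
#' The heart occupies only part of the embryo and is not visible in
#' every recording, so the cardiac rate is sought across all blocks of
#' the spectrum set: each block contributes its in-band PSD peak and
#' its prominence (peak over the block's in-band median PSD). A block
#' qualifies when (a) its prominence reaches `quality_floor` and at
#' least `rel_floor` of the most prominent block's, and (b) its peak
#' rises above the spectral continuum just below the band: gross
#' embryo movement has a monotonically decaying (roughly 1/f-squared)
#' spectrum whose in-band maximum sits at the band edge and continues
#' upward below it, whereas a cardiac line stands clear of the
#' continuum. The reported frequency is the prominence-squared-
#' weighted median of the qualifying blocks' peak frequencies. Prominence, not raw power,
#' carries the weight because gross embryo movement dumps broadband
#' low-frequency power into blocks at the embryo's edge, whereas a
#' beating heart is a narrow spectral line; weighting by the
#' normalized line height singles it out. When no block qualifies the
#' estimate is NaN (heart obscured), never a clipped band edge.
#'
#' @param spectra A [block_spectra()] result.
#' @param band `(fmin, fmax)` physiological band in Hz, inside
#'   `(0, Nyquist)`. Default 0.5–5 Hz spans typical embryonic rates
#'   (about 1.5 Hz for *R. balthica*, 3.5 Hz for *O. gammarellus*).
#' @param quality_floor Peak-to-median PSD ratio a block must exceed
#'   to qualify (default 3).
#' @param rel_floor Fraction of the best block's prominence a block
#'   must also reach (default 0.25).
#' @return One-row data frame (class `cardiac_estimate`): `frequency`
#'   (Hz or NaN), `power`, `source_level`, `source_block`, `quality`
#'   in `[0, 1]` (1 - median/peak of the best block), `n_blocks_used`.
#' @export
identify_cardiac_frequency <- function(spectra, band = c(0.5, 5),
                                       quality_floor = 3,
                                       rel_floor = 0.25) {
  stopifnot(inherits(spectra, "spectrum_set"))
  if (length(band) != 2L || band[1] >= band[2] || band[1] <= 0)
    stop("band must be (fmin, fmax) with 0 < fmin < fmax", call. = FALSE)
  nyq <- spectra$fs / 2
  if (band[2] >= nyq)
    stop("band must lie strictly below the Nyquist frequency (",
         format(nyq), " Hz)", call. = FALSE)
  peaks <- list()
  for (k in seq_along(spectra$levels)) {
    for (b in seq_along(spectra$spectra[[k]])) {
      sp <- spectra$spectra[[k]][[b]]
      if (!isTRUE(sp$available)) next
      sel <- sp$freq >= band[1] & sp$freq <= band[2]
      if (!any(sel)) next
      p <- sp$psd[sel]; f <- sp$freq[sel]
      pk <- max(p)
      if (!is.finite(pk) || pk <= 0) next
      # reject peaks sitting on the low-frequency motion continuum
      below <- sp$psd[sp$freq < band[1] &
                      sp$freq >= band[1] - 4 * sp$df & sp$freq > 0]
      if (length(below) && pk <= max(below)) next
      med <- stats::median(p)
      ratio <- if (med > 0) pk / med else Inf
      peaks[[length(peaks) + 1L]] <- data.frame(
        level = spectra$levels[k], block = b,
        freq = f[which.max(p)], power = pk, prominence = ratio,
        quality = 1 - 1 / max(ratio, 1), qualify = ratio >= quality_floor)
    }
  }
  empty <- data.frame(timepoint = spectra$timepoint, frequency = NaN,
                      power = NaN, source_level = NA_integer_,
                      source_block = NA_integer_, quality = 0,
                      n_blocks_used = 0L)
  class(empty) <- c("cardiac_estimate", "data.frame")
  if (!length(peaks)) return(empty)
  pk <- do.call(rbind, peaks)
  pk$qualify <- pk$qualify &
    pk$prominence >= rel_floor * max(pk$prominence)
  q <- pk[pk$qualify, , drop = FALSE]
  if (!nrow(q)) return(empty)
  w <- pmin(q$prominence, 1e12)^2
  freq <- .weighted_median(q$freq, w)
  best <- q[which.max(w), ]
  out <- data.frame(timepoint = spectra$timepoint, frequency = freq,
                    power = best$power,
                    source_level = as.integer(best$level),
                    source_block = as.integer(best$block),
                    quality = best$quality, n_blocks_used = nrow(q))
  class(out) <- c("cardiac_estimate", "data.frame")
  out
}

# weighted median: smallest x with cumulative weight >= half the total
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

#' Fit a cardiac ontogeny model
#'
#' Heart rate typically changes through development either linearly or
#' with a distinct change of pace; per embryo the per-timepoint rate
#' series is fitted with either an ordinary linear regression or a
#' continuous single-breakpoint piecewise-linear (segmented) model.
#' The segmented breakpoint is chosen by exhaustive search over the
#' interior observed timepoints, minimizing residual sum of squares —
#' deterministic, and its own brute-force reference.
#'
#' @param time_h Times in hours.
#' @param frequency Cardiac rate estimates in Hz (NaN allowed).
#' @param kind `"linear"` or `"segmented"`.
#' @return An object of class `cardiac_model`. Linear fits carry
#'   `intercept`, `slope` (Hz/h), `stderr`; segmented fits carry
#'   `breakpoint_h`, `slope_left`, `slope_right`, `value_at_break`,
#'   `intercept`. Both carry `rss`, `n`, and a `reason` when the fit
#'   is undefined.
#' @export
fit_cardiac_model <- function(time_h, frequency,
                              kind = c("linear", "segmented")) {
  kind <- match.arg(kind)
  ok <- is.finite(time_h) & is.finite(frequency)
  t <- time_h[ok]; f <- frequency[ok]
  need <- if (kind == "linear") 5L else 7L
  fail <- function(reason)
    structure(list(kind = kind, n = sum(ok), reason = reason),
              class = "cardiac_model")
  if (sum(ok) < need)
    return(fail(sprintf("need >= %d finite estimates, have %d", need,
                        sum(ok))))
  if (kind == "linear") {
    fit <- stats::lm(f ~ t)
    s <- suppressWarnings(summary(fit))$coefficients
    return(structure(
      list(kind = "linear", intercept = unname(coef(fit)[1L]),
           slope = unname(coef(fit)[2L]),
           stderr = unname(s["t", "Std. Error"]),
           rss = sum(stats::residuals(fit)^2), n = length(t),
           reason = NULL),
      class = "cardiac_model"))
  }
  # segmented: candidate breakpoints are interior observed timepoints
  ts <- sort(unique(t))
  cand <- ts[ts > min(ts) & ts < max(ts)]
  best <- NULL; best_rss <- Inf
  for (bp in cand) {
    X <- cbind(1, t, pmax(t - bp, 0))
    fit <- stats::lm.fit(X, f)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- list(bp = bp, coef = fit$coefficients)
    }
  }
  if (is.null(best)) return(fail("no interior breakpoint candidates"))
  b <- best$coef
  structure(
    list(kind = "segmented", breakpoint_h = best$bp,
         intercept = unname(b[1L]), slope_left = unname(b[2L]),
         slope_right = unname(b[2L] + b[3L]),
         value_at_break = unname(b[1L] + b[2L] * best$bp),
         rss = best_rss, n = length(t), reason = NULL),
    class = "cardiac_model")
}

#' @export
print.cardiac_model <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("<cardiac_model %s> undefined: %s\n", x$kind, x$reason))
  } else if (x$kind == "linear") {
    cat(sprintf("<cardiac_model linear> f = %.4g + %.4g * t (Hz, h); n = %d, RSS = %.3g\n",
                x$intercept, x$slope, x$n, x$rss))
  } else {
    cat(sprintf("<cardiac_model segmented> break at %.3g h; slopes %.4g -> %.4g Hz/h; n = %d, RSS = %.3g\n",
                x$breakpoint_h, x$slope_left, x$slope_right, x$n, x$rss))
  }
  invisible(x)
}

#' Predict from a cardiac ontogeny model
#'
#' @param object A [fit_cardiac_model()] result.
#' @param time_h Times (hours) at which to evaluate the model.
#' @param ... Unused.
#' @return Predicted cardiac rate in Hz.
#' @export
predict.cardiac_model <- function(object, time_h, ...) {
  if (!is.null(object$reason)) return(rep(NaN, length(time_h)))
  if (object$kind == "linear")
    return(object$intercept + object$slope * time_h)
  object$intercept + object$slope_left * time_h +
    (object$slope_right - object$slope_left) *
      pmax(time_h - object$breakpoint_h, 0)
}

#' Per-embryo heart-rate report
#'
#' Summarizes each embryo's cardiac series and fitted ontogeny model
#' into one row: rate at first detected heart function, mean rate,
#' model kind, and the model parameters (slope(s), breakpoint).
#' Deterministic for fixed input.
#'
#' @param cardiac_series Named list (by embryo id) of data frames with
#'   `time_h` and `frequency` columns.
#' @param kind Ontogeny model for every embryo: `"linear"` or
#'   `"segmented"`.
#' @return Data frame with one row per embryo.
#' @export
heart_rate_report <- function(cardiac_series,
                              kind = c("linear", "segmented")) {
  kind <- match.arg(kind)
  rows <- lapply(names(cardiac_series), function(id) {
    cs <- cardiac_series[[id]]
    ok <- is.finite(cs$frequency)
    model <- fit_cardiac_model(cs$time_h, cs$frequency, kind)
    data.frame(
      embryo_id = id,
      n_estimates = sum(ok),
      first_rate_hz = if (any(ok)) cs$frequency[which(ok)[1L]] else NaN,
      first_rate_time_h = if (any(ok)) cs$time_h[which(ok)[1L]] else NaN,
      mean_rate_hz = if (any(ok)) mean(cs$frequency[ok]) else NaN,
      model_kind = kind,
      slope_hz_h = if (is.null(model$reason)) {
        if (kind == "linear") model$slope else model$slope_right
      } else NaN,
      breakpoint_h = if (kind == "segmented" && is.null(model$reason))
        model$breakpoint_h else NA_real_,
      rss = if (is.null(model$reason)) model$rss else NaN,
      reason = if (is.null(model$reason)) "" else model$reason,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
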