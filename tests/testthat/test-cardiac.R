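# hand-built spectrum_set with two synthetic block spectra
two_block_spectra <- function(f_strong = 1.5, f_weak = 3.1,
                              strong_power = 10, weak_power = 1,
                              fs = 20, floor_psd = 0.01) {
  freq <- seq(0, fs / 2, by = fs / 256)
  mk <- function(fpk, pk) {
    psd <- rep(floor_psd, length(freq))
    psd[which.min(abs(freq - fpk))] <- pk
    structure(list(freq = freq, psd = psd, df = fs / 256,
                   available = TRUE, reason = NULL, fs = fs,
                   nperseg = 256L), class = "welch_spectrum")
  }
  structure(list(levels = 2L,
                 spectra = list(L2 = list(mk(f_strong, strong_power),
                                          mk(f_weak, weak_power))),
                 fs = fs, embryo_id = "X", timepoint = 0L),
            class = "spectrum_set")
}

test_that("the stronger pulsing block decides the cardiac frequency", {
  sp <- two_block_spectra(strong_power = 10, weak_power = 1)
  est <- identify_cardiac_frequency(sp)
  expect_equal(est$frequency, sp$spectra$L2[[1]]$freq[
    which.min(abs(sp$spectra$L2[[1]]$freq - 1.5))])
  expect_equal(est$n_blocks_used, 1L)   # the weak block is outclassed
  expect_gt(est$quality, 0.9)
})

test_that("a silent scene yields an NaN estimate with zero quality", {
  sq <- constant_sequence(800, size = 48L, n = 96L)
  roi <- egg_roi(c(23.5, 23.5), c(20, 18))
  sp <- block_spectra(blockwise_signals(sq, roi))
  est <- identify_cardiac_frequency(sp)
  expect_true(is.nan(est$frequency))
  expect_equal(est$quality, 0)
  expect_equal(est$n_blocks_used, 0L)
})

test_that("band arguments are validated against the Nyquist range", {
  sp <- two_block_spectra()
  expect_error(identify_cardiac_frequency(sp, band = c(5, 0.5)), "band")
  expect_error(identify_cardiac_frequency(sp, band = c(0.5, 10)), "Nyquist")
  expect_error(identify_cardiac_frequency(sp, band = c(-1, 5)), "band")
})

test_that("estimates stay inside the physiological band or are NaN", {
  set.seed(15)
  for (i in 1:8) {
    freq <- seq(0, 10, by = 20 / 256)
    psd <- rexp(length(freq)) * 10^runif(1, -3, 3)
    sp <- structure(list(levels = 1L, spectra = list(L1 = list(
      structure(list(freq = freq, psd = psd, df = 20 / 256,
                     available = TRUE, fs = 20, nperseg = 256L),
                class = "welch_spectrum"))), fs = 20,
      embryo_id = "X", timepoint = 0L), class = "spectrum_set")
    est <- identify_cardiac_frequency(sp, band = c(0.5, 5))
    expect_true(is.nan(est$frequency) ||
                (est$frequency >= 0.5 && est$frequency <= 5))
  }
})

test_that("the full pipeline recovers a 1.5 Hz heart to one Welch bin", {
  spec <- small_spec(frames = 384L, n_tp = 2L, heart = list(f0_hz = 1.5))
  g <- generate_sequence(spec, 0L)
  roi <- locate_egg(g$sequence)
  sp <- block_spectra(blockwise_signals(g$sequence, roi))
  est <- identify_cardiac_frequency(sp, band = c(0.5, 5))
  expect_lt(abs(est$frequency - 1.5), 20 / 256 + 1e-9)
})

test_that("linear ontogeny fits recover an exact line to machine precision", {
  t <- seq(0, 20, by = 2)
  f <- 0.2 + 0.05 * t
  m <- fit_cardiac_model(t, f, "linear")
  expect_equal(m$intercept, 0.2, tolerance = 1e-10)
  expect_equal(m$slope, 0.05, tolerance = 1e-10)
  expect_lt(m$rss, 1e-20)
  expect_equal(predict(m, c(0, 10)), c(0.2, 0.7), tolerance = 1e-10)
})

test_that("insufficient finite estimates yield a reasoned undefined fit", {
  m <- fit_cardiac_model(0:3, c(1, NaN, 1.2, 1.3), "linear")
  expect_false(is.null(m$reason))
  expect_true(all(is.nan(predict(m, 0:3))))
  m2 <- fit_cardiac_model(0:5, rep(1, 6), "segmented")
  expect_match(m2$reason, "7")
})

test_that("segmented fits recover a known breakpoint within one spacing", {
  t <- 0:80
  bp_true <- 40
  f_true <- 0.3 + 0.01 * t + (0.04 - 0.01) * pmax(t - bp_true, 0)
  set.seed(33)
  f <- f_true + rnorm(length(t), 0, 0.01)
  m <- fit_cardiac_model(t, f, "segmented")
  expect_lte(abs(m$breakpoint_h - bp_true), 1)
  expect_equal(m$slope_left, 0.01, tolerance = 0.25)
  expect_equal(m$slope_right, 0.04, tolerance = 0.25)
  # continuity at the breakpoint
  eps <- 1e-9
  expect_equal(predict(m, m$breakpoint_h - eps),
               predict(m, m$breakpoint_h + eps), tolerance = 1e-6)
  # the exhaustive grid is its own brute-force oracle
  brute <- vapply(t[t > min(t) & t < max(t)], function(bp) {
    X <- cbind(1, t, pmax(t - bp, 0))
    sum(lm.fit(X, f)$residuals^2)
  }, 0)
  expect_equal(m$rss, min(brute), tolerance = 1e-12)
})

test_that("segmented fits nest linear fits", {
  set.seed(44)
  for (i in 1:6) {
    t <- 0:24
    f <- 0.5 + 0.02 * t + rnorm(25, 0, 0.05)
    lin <- fit_cardiac_model(t, f, "linear")
    seg <- fit_cardiac_model(t, f, "segmented")
    expect_lte(seg$rss, lin$rss + 1e-12)
  }
  # exactly linear data: both segment slopes agree
  t <- 0:20
  seg <- fit_cardiac_model(t, 1 + 0.03 * t, "segmented")
  expect_equal(seg$slope_left, seg$slope_right, tolerance = 1e-8)
})

test_that("the heart-rate report summarizes one row per embryo", {
  set.seed(2)
  series <- lapply(1:8, function(i) {
    t <- 0:23
    data.frame(time_h = t,
               frequency = 3 + 0.01 * t + rnorm(24, 0, 0.05))
  })
  names(series) <- sprintf("O%02d", 1:8)
  rep1 <- heart_rate_report(series, "linear")
  expect_equal(nrow(rep1), 8)
  expect_true(all(is.finite(rep1$slope_hz_h)))
  expect_true(all(abs(rep1$slope_hz_h - 0.01) < 0.02))
  rep2 <- heart_rate_report(series, "linear")
  expect_identical(rep1, rep2)               # deterministic

  series$O01$frequency <- NaN
  rep3 <- heart_rate_report(series, "linear")
  expect_true(is.nan(rep3$slope_hz_h[1]))
  expect_match(rep3$reason[1], "finite")
})
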