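test_that("constant scenes give constant block signals at every level", {
  sq <- constant_sequence(500, size = 48L, n = 20L)
  roi <- egg_roi(c(23.5, 23.5), c(20, 17))
  bl <- blockwise_signals(sq, roi)
  for (lv in names(bl$signals)) {
    s <- bl$signals[[lv]]
    expect_true(all(s[is.finite(s)] == 500), label = lv)
  }
  # NaN exactly where a block holds no ROI pixels
  expect_identical(which(is.nan(bl$signals$L16[, 1])),
                   which(bl$counts$L16 == 0))
})

test_that("block means match brute-force per-pixel averaging", {
  set.seed(21)
  fr <- matrix(runif(64 * 64, 0, 4000), 64, 64)
  sq <- image_sequence(array(fr, c(64, 64, 2)), c(0, 0.05))
  roi <- egg_roi(c(31.5, 31.5), c(27, 24), angle = 20)
  bl <- blockwise_signals(sq, roi)
  for (L in c(1L, 2L, 4L, 8L, 16L)) {
    expect_equal(bl$signals[[paste0("L", L)]][, 1],
                 brute_block_means(fr, roi, L),
                 tolerance = 1e-12, label = paste("level", L))
  }
})

test_that("a grid-aligned checkerboard resolves at level 2 but not level 1", {
  # ROI bounding box spans rows/cols 16..47 (0-based); 16 px quadrants
  # align with the level-2 grid
  fr <- matrix(100, 64, 64)
  fr[33:48, 17:32] <- 300   # one quadrant high, diagonal pattern
  fr[17:32, 33:48] <- 300
  sq <- image_sequence(array(fr, c(64, 64, 1)), 0)
  roi <- egg_roi(c(31.5, 31.5), c(15.5, 15.5))
  bl <- blockwise_signals(sq, roi, levels = c(1L, 2L))
  l2 <- bl$signals$L2[, 1]
  expect_equal(sort(unique(round(l2))), c(100, 300))
  w <- bl$counts$L2
  expect_equal(bl$signals$L1[1, 1], sum(l2 * w) / sum(w), tolerance = 1e-12)
})

test_that("every level is the pixel-weighted mean of its children", {
  spec <- small_spec(frames = 12L, n_tp = 2L)
  g <- generate_sequence(spec, 0L)
  roi <- locate_egg(g$sequence)
  bl <- blockwise_signals(g$sequence, roi)
  for (parent in c(1L, 2L, 4L, 8L)) {
    child <- 2L * parent
    ps <- bl$signals[[paste0("L", parent)]]
    cs <- bl$signals[[paste0("L", child)]]
    cw <- bl$counts[[paste0("L", child)]]
    for (pr in seq_len(parent)) for (pc in seq_len(parent)) {
      kids <- c((2 * pr - 2) * child + (2 * pc - 1),
                (2 * pr - 2) * child + (2 * pc),
                (2 * pr - 1) * child + (2 * pc - 1),
                (2 * pr - 1) * child + (2 * pc))
      w <- cw[kids]
      if (sum(w) == 0) next
      agg <- colSums(cs[kids, , drop = FALSE] * w, na.rm = TRUE) / sum(w)
      expect_equal(ps[(pr - 1) * parent + pc, ], agg, tolerance = 1e-9,
                   label = sprintf("parent L%d block (%d,%d)", parent,
                                   pr, pc))
    }
  }
})

test_that("Welch spectra match an independent reference implementation", {
  # frozen one-sided PSD values computed with an independent Welch
  # implementation (Hann window, nperseg 256, 50% overlap, constant
  # detrend, density scaling) on the identical deterministic signal
  t <- (0:599) / 20
  x <- sin(2 * pi * 1.3 * t) + 0.25 * cos(2 * pi * 4.7 * t) +
    0.1 * sin(2 * pi * 0.3 * t + 1)
  sp <- welch_psd(x, fs = 20)
  expect_true(sp$available)
  expect_equal(sp$nperseg, 256L)
  idx <- c(1, 6, 18, 41, 61, 129)
  expect_equal(sp$freq[idx],
               c(0, 0.390625, 1.328125, 3.125, 4.6875, 10), tolerance = 1e-12)
  expect_equal(sp$psd[idx],
               c(0.0010679416362045526, 0.006258018924223552,
                 3.6047713091820968, 2.250008432254634e-09,
                 0.2579913035003425, 1.2454759555314098e-13),
               tolerance = 1e-9)
  expect_equal(sum(sp$psd), 6.8656258824764675, tolerance = 1e-9)

  sp2 <- welch_psd(x[1:120], fs = 20)   # adaptive segment length: 64
  expect_equal(sp2$nperseg, 64L)
  expect_equal(sp2$psd[c(1, 5, 10, 33)],
               c(0.0027204688505127203, 1.0319926279809364,
                 2.1658165962149924e-06, 1.777590421638875e-11),
               tolerance = 1e-9)
})

test_that("a constant signal has essentially zero PSD", {
  sp <- welch_psd(rep(1234.5, 600), fs = 20)
  expect_true(all(sp$psd < 1e-12 * 1234.5^2))
})

test_that("pure tones peak in the DFT-oracle frequency bin", {
  for (fs in c(20, 38)) {
    freqs <- seq(2.5 * fs / 256, fs / 2 - 2.5 * fs / 256, length.out = 7)
    for (f0 in freqs) {
      x <- sin(2 * pi * f0 * (0:599) / fs)
      sp <- welch_psd(x, fs = fs)
      welch_peak <- sp$freq[which.max(sp$psd)]
      oracle <- dft_peak(x, fs)
      expect_lt(abs(welch_peak - oracle), sp$df + 1e-12,
                label = sprintf("f0=%.3f fs=%g", f0, fs))
      expect_lt(abs(welch_peak - f0), sp$df + 1e-12)
    }
  }
})

test_that("integrated PSD approximates the sample variance", {
  set.seed(5)
  x <- rnorm(2048, 0, 3)
  sp <- welch_psd(x, fs = 20)
  expect_lt(abs(sum(sp$psd) * sp$df - var(x)) / var(x), 0.1)
})

test_that("NaN gaps are interpolated up to the gap limit, then refused", {
  x <- sin(2 * pi * 1.5 * (0:599) / 20)
  x_short_gap <- x; x_short_gap[100:104] <- NaN     # 5-frame gap
  expect_true(welch_psd(x_short_gap, fs = 20)$available)
  x_long_gap <- x; x_long_gap[100:105] <- NaN       # 6-frame gap
  sp <- welch_psd(x_long_gap, fs = 20)
  expect_false(sp$available)
  expect_match(sp$reason, "gap")
  expect_false(welch_psd(rep(NaN, 600), fs = 20)$available)
  expect_false(welch_psd(x[1:6], fs = 20)$available)
  expect_error(welch_psd(x, fs = 0), "fs")
})

test_that("band energies localize a tone and normalize correctly", {
  x <- sin(2 * pi * 1.5 * (0:599) / 20)
  sp <- welch_psd(x, fs = 20)
  be <- band_energies(sp, seq(0, 10, by = 0.5))
  expect_equal(sum(be$relative_energy), 1, tolerance = 1e-9)
  expect_equal(be$total_energy, sum(be$energy), tolerance = 1e-12)
  peak_band <- which(be$band_lo < 1.5 & be$band_hi >= 1.484)
  neighbourhood <- unique(pmin(pmax(c(peak_band - 1, peak_band,
                                      peak_band + 1), 1),
                               length(be$energy)))
  expect_gt(sum(be$relative_energy[neighbourhood]), 0.9)
})

test_that("energy scales quadratically with amplitude", {
  x <- sin(2 * pi * 2.2 * (0:599) / 20) + 0.1 * cos(2 * pi * 4 * (0:599) / 20)
  b1 <- band_energies(welch_psd(x, fs = 20))
  b2 <- band_energies(welch_psd(2 * x, fs = 20))
  expect_equal(b2$total_energy / b1$total_energy, 4, tolerance = 1e-9)
  expect_equal(b2$relative_energy, b1$relative_energy, tolerance = 1e-9)
})

test_that("refining the band partition preserves the total energy", {
  set.seed(8)
  sp <- welch_psd(rnorm(600), fs = 20)
  coarse <- band_energies(sp, seq(0, 10, by = 1))
  fine <- band_energies(sp, seq(0, 10, by = 0.25))
  expect_equal(coarse$total_energy, fine$total_energy, tolerance = 1e-9)
})

test_that("band edges outside (0, Nyquist] are rejected", {
  sp <- welch_psd(rnorm(600), fs = 20)
  expect_error(band_energies(sp, c(0, 5, 11)), "Nyquist")
  expect_error(band_energies(sp, c(3, 2)), "ascending")
  be <- band_energies(structure(list(available = FALSE),
                                class = "welch_spectrum"))
  expect_false(be$available)
  expect_true(is.nan(be$total_energy))
})
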