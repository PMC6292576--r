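# shared fixtures: small, seeded synthetic scenes kept cheap enough to
# regenerate inside individual tests

# short schedule used wherever full-length recordings are not needed
short_schedule <- function(frames = 96L, fps = 20, n_tp = 5L)
  recording_schedule(frames, fps, 60, n_tp)

# quiet, small synthetic spec (96 px frames)
small_spec <- function(..., frames = 96L, fps = 20, n_tp = 5L, seed = 1L) {
  synthetic_spec(frame_size = 96L,
                 schedule = short_schedule(frames, fps, n_tp),
                 seed = seed, ...)
}

# a plain filled-ellipse frame on dark background (no generator)
ellipse_frame <- function(size = 128L, center = c(63.5, 63.5),
                          semi_axes = c(40, 25), angle = 0,
                          fg = 3000, bg = 200) {
  m <- matrix(bg, size, size)
  msk <- embryovision:::.ellipse_mask(size, size, center, semi_axes, angle)
  m[msk] <- fg
  m
}

# constant-intensity sequence
constant_sequence <- function(value = 500, size = 32L, n = 96L, fps = 20)
  image_sequence(array(value, c(size, size, n)), (seq_len(n) - 1) / fps)

# independent DFT peak oracle: argmax of the plain periodogram over
# positive frequencies of the mean-removed signal
dft_peak <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  k <- 2:floor(n / 2)
  (k[which.max(sp[k])] - 1) * fs / n
}

# pixel-level brute-force block means (independent of blockwise_signals)
brute_block_means <- function(frame, roi, level) {
  bb <- embryovision:::.roi_bbox(roi, dim(frame))
  h <- unname(bb["height"]); w <- unname(bb["width"])
  sub <- frame[(bb["top"] + 1):(bb["top"] + h),
               (bb["left"] + 1):(bb["left"] + w), drop = FALSE]
  mask <- embryovision:::.ellipse_mask(h, w,
                                       roi$center - c(bb["top"], bb["left"]),
                                       roi$semi_axes, roi$angle)
  redge <- round(seq(0, h, length.out = level + 1))
  cedge <- round(seq(0, w, length.out = level + 1))
  out <- rep(NaN, level * level)
  for (rb in seq_len(level)) for (cb in seq_len(level)) {
    rows <- (redge[rb] + 1):(redge[rb + 1])
    cols <- (cedge[cb] + 1):(cedge[cb + 1])
    if (redge[rb] == redge[rb + 1] || cedge[cb] == cedge[cb + 1]) next
    vals <- sub[rows, cols][mask[rows, cols]]
    if (length(vals)) out[(rb - 1) * level + cb] <- mean(vals)
  }
  out
}
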