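test_that("the egg capsule is recovered from a synthetic recording", {
  spec <- small_spec(frames = 40L, n_tp = 2L)
  g <- generate_sequence(spec, 0L)
  roi <- locate_egg(g$sequence)
  expect_s3_class(roi, "egg_roi")
  expect_equal(roi$source, "auto")
  truth_center <- g$truth$capsule_center
  truth_axes <- g$truth$capsule_outer
  expect_lt(max(abs(roi$center - truth_center)), 2)
  expect_lt(max(abs(roi$semi_axes - truth_axes) / truth_axes), 0.05)
})

test_that("egg location is translation-equivariant", {
  spec <- small_spec(frames = 40L, n_tp = 2L,
                     noise = list(sigma = 0),
                     capsule = list(semi_axes = c(26, 22)))
  g <- generate_sequence(spec, 0L)
  fr <- g$sequence$frames
  d <- dim(fr)
  dr <- 10L; dc <- -7L
  shifted <- array(200, d)   # background fill
  shifted[(1 + dr):d[1], 1:(d[2] + dc), ] <- fr[1:(d[1] - dr),
                                                (1 - dc):d[2], ]
  roi0 <- locate_egg(image_sequence(fr, g$sequence$timestamps))
  roi1 <- locate_egg(image_sequence(shifted, g$sequence$timestamps))
  expect_equal(unname(roi1$center - roi0$center), c(dr, dc))
  expect_equal(unname(roi1$semi_axes), unname(roi0$semi_axes))
})

test_that("empty scenes yield an egg-not-found error", {
  blank <- image_sequence(array(0, c(32, 32, 12)), (0:11) / 20)
  expect_error(locate_egg(blank), "egg not found")
  set.seed(7)
  noise <- image_sequence(array(pmin(pmax(rnorm(32 * 32 * 12, 200, 30),
                                          0), 65535), c(32, 32, 12)),
                          (0:11) / 20)
  expect_error(locate_egg(noise), "egg not found")
  expect_error(locate_egg(image_sequence(array(0, c(8, 8, 3)), 0:2)),
               "at least 10 frames")
})

test_that("segmented area matches the analytic ellipse area", {
  fr <- ellipse_frame(semi_axes = c(40, 25))
  roi <- egg_roi(c(63.5, 63.5), c(55, 55))
  fm <- segment_embryo(fr, roi)
  expect_true(fm$valid)
  analytic <- pi * 40 * 25
  expect_lt(abs(fm$area_px - analytic) / analytic, 0.02)
  # oracle: pixel count of the noiseless analytic mask
  mask_count <- sum(embryovision:::.ellipse_mask(128, 128, c(63.5, 63.5),
                                                 c(40, 25), 0))
  expect_lt(abs(fm$area_px - mask_count) / mask_count, 0.02)
  expect_gt(fm$solidity, 0.95)
  expect_lte(fm$solidity, 1)
})

test_that("blank ROIs soft-fail with NaN measures", {
  fr <- matrix(200, 64, 64)
  fm <- segment_embryo(fr, egg_roi(c(31.5, 31.5), c(25, 25)))
  expect_false(fm$valid)
  expect_true(is.nan(fm$area_px))
  expect_true(is.nan(fm$centroid_row))
})

test_that("size measures are translation-invariant, position equivariant", {
  fr1 <- ellipse_frame(center = c(60, 55), semi_axes = c(20, 14))
  fr2 <- ellipse_frame(center = c(60, 60), semi_axes = c(20, 14))
  roi <- egg_roi(c(60, 58), c(45, 45))
  m1 <- segment_embryo(fr1, roi)
  m2 <- segment_embryo(fr2, roi)
  expect_equal(m1$area_px, m2$area_px)
  expect_equal(m1$perimeter_px, m2$perimeter_px)
  expect_equal(m1$solidity, m2$solidity)
  expect_equal(m2$centroid_col - m1$centroid_col, 5)
  expect_equal(m2$centroid_row, m1$centroid_row)
})

test_that("segmentation is invariant to order-preserving intensity rescaling", {
  set.seed(3)
  fr <- ellipse_frame(semi_axes = c(30, 20)) + rnorm(128 * 128, 0, 20)
  fr <- pmin(pmax(fr, 0), 65535)
  roi <- egg_roi(c(63.5, 63.5), c(55, 55))
  m1 <- segment_embryo(fr, roi)
  m2 <- segment_embryo(pmin(fr * 1.8 + 500, 65535), roi)
  expect_equal(m1$area_px, m2$area_px)
  expect_equal(m1$centroid_row, m2$centroid_row)
})

test_that("areas increase monotonically along a noiseless growth series", {
  roi <- egg_roi(c(63.5, 63.5), c(58, 58))
  areas <- vapply(seq(12, 36, by = 4), function(a) {
    segment_embryo(ellipse_frame(semi_axes = c(a, a / 1.5)), roi)$area_px
  }, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("ROI overrides replace selected embryos only and are validated", {
  rois <- list(A = egg_roi(c(40, 40), c(20, 18)),
               B = egg_roi(c(42, 41), c(21, 17)))
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(embryo_id = "A", center_row = 45, center_col = 44,
                       semi_a = 22, semi_b = 19, angle_deg = 5), f,
            row.names = FALSE)
  out <- apply_roi_overrides(rois, f, frame_dim = c(96, 96))
  expect_equal(out$A$source, "override")
  expect_equal(out$A$center, c(45, 44))
  expect_identical(out$B, rois$B)

  write.csv(data.frame(embryo_id = "A", center_row = 90, center_col = 44,
                       semi_a = 22, semi_b = 19, angle_deg = 0), f,
            row.names = FALSE)
  expect_error(apply_roi_overrides(rois, f, frame_dim = c(96, 96)),
               "outside the frame")
})

test_that("an override equal to the auto ROI changes nothing downstream", {
  spec <- small_spec(frames = 20L, n_tp = 2L)
  g <- generate_sequence(spec, 0L)
  auto <- locate_egg(g$sequence)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(embryo_id = "X", center_row = auto$center[1],
                       center_col = auto$center[2],
                       semi_a = auto$semi_axes[1],
                       semi_b = auto$semi_axes[2],
                       angle_deg = auto$angle), f, row.names = FALSE)
  over <- apply_roi_overrides(list(X = auto), f)$X
  m_auto <- segment_embryo(g$sequence$frames[, , 1], auto)
  m_over <- segment_embryo(g$sequence$frames[, , 1], over)
  expect_equal(m_over, m_auto)
})

test_that("overlay export writes one deterministic PNG per embryo", {
  spec <- small_spec(frames = 20L, n_tp = 2L)
  g <- generate_sequence(spec, 0L)
  fr <- g$sequence$frames[, , 1]
  roi <- locate_egg(g$sequence)
  frames <- list(A = fr, B = fr, C = fr)
  rois <- list(A = roi, B = roi, C = roi)
  d1 <- file.path(withr::local_tempdir(), "ov1")
  d2 <- file.path(withr::local_tempdir(), "ov2")
  p1 <- export_roi_overlays(frames, rois, d1)
  p2 <- export_roi_overlays(frames, rois, d2)
  expect_length(list.files(d1, pattern = "\\.png$"), 3)
  expect_identical(basename(p1), c("A_roi.png", "B_roi.png", "C_roi.png"))
  expect_identical(readBin(p1[1], "raw", 1e6), readBin(p2[1], "raw", 1e6))
  # degenerate: blank frame keeps the ROI ring but logs no contour
  expect_message(
    export_roi_overlays(list(Z = matrix(200, 96, 96)),
                        list(Z = egg_roi(c(47, 47), c(30, 26))),
                        file.path(withr::local_tempdir(), "ov3")),
    "no embryo contour")
})
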