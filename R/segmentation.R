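#' Elliptical egg region of interest
#'
#' @param center `(row, col)` ellipse centre in pixels (0-based frame
#'   coordinates, origin top-left).
#' @param semi_axes `(a, b)` semi-axes in pixels, both > 0.
#' @param angle Rotation of the `a` axis away from the row axis,
#'   degrees.
#' @param source `"auto"` (fitted) or `"override"` (user supplied).
#' @param frame_dim Optional `(rows, cols)`; when given, the ellipse
#'   must lie fully inside the frame.
#' @return An object of class `egg_roi`.
#' @export
egg_roi <- function(center, semi_axes, angle = 0, source = "auto",
                    frame_dim = NULL) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("ellipse semi-axes must be > 0", call. = FALSE)
  roi <- structure(
    list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
         angle = as.numeric(angle), source = match.arg(source,
                                                       c("auto", "override"))),
    class = "egg_roi")
  if (!is.null(frame_dim)) {
    ext <- .roi_extent(roi)
    lo <- roi$center - ext
    hi <- roi$center + ext
    if (any(lo < 0) || hi[1] > frame_dim[1] - 1 || hi[2] > frame_dim[2] - 1)
      stop("egg ROI extends outside the frame bounds", call. = FALSE)
  }
  roi
}

#' @export
print.egg_roi <- function(x, ...) {
  cat(sprintf("<egg_roi %s> centre (%.1f, %.1f), semi-axes (%.1f, %.1f), angle %.1f deg\n",
              x$source, x$center[1], x$center[2], x$semi_axes[1],
              x$semi_axes[2], x$angle))
  invisible(x)
}

# half-extent of the rotated ellipse along (row, col)
.roi_extent <- function(roi) {
  th <- roi$angle * pi / 180
  a <- roi$semi_axes[1]; b <- roi$semi_axes[2]
  c(sqrt((a * cos(th))^2 + (b * sin(th))^2),
    sqrt((a * sin(th))^2 + (b * cos(th))^2))
}

# logical mask of pixels (centres, 0-based) inside the ellipse
.ellipse_mask <- function(nrow, ncol, center, semi_axes, angle = 0) {
  th <- angle * pi / 180
  r <- matrix(seq_len(nrow) - 1, nrow, ncol) - center[1]
  cc <- matrix(seq_len(ncol) - 1, nrow, ncol, byrow = TRUE) - center[2]
  u <- r * cos(th) + cc * sin(th)
  v <- -r * sin(th) + cc * cos(th)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

# integer bounding box (top, left, height, width), 0-based, clipped
.roi_bbox <- function(roi, frame_dim) {
  ext <- .roi_extent(roi)
  top <- max(0L, floor(roi$center[1] - ext[1]))
  left <- max(0L, floor(roi$center[2] - ext[2]))
  bot <- min(frame_dim[1] - 1, ceiling(roi$center[1] + ext[1]))
  right <- min(frame_dim[2] - 1, ceiling(roi$center[2] + ext[2]))
  c(top = top, left = left, height = bot - top + 1, width = right - left + 1)
}

.norm01 <- function(m) {
  rng <- range(m, finite = TRUE)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' Locate the egg capsule in a recording
#'
#' Finds the elliptical region containing the egg by combining a
#' max-intensity projection (the bright capsule wall) with a temporal
#' variance map (the moving embryo inside the static capsule), taken
#' over an even subsample of frames. The combined map is thresholded
#' (Otsu), hole-filled, morphologically opened, and the largest
#' connected component is summarized by its moment ellipse (centroid
#' and 2-sigma principal axes). Deterministic for fixed input.
#'
#' @param sequence An [image_sequence()] with at least 10 frames.
#' @param max_sample Maximum number of frames used for the projection
#'   maps.
#' @return An [egg_roi()] with `source = "auto"`.
#' @export
locate_egg <- function(sequence, max_sample = 40L) {
  d <- dim(sequence$frames)
  if (d[3L] < 10L)
    stop("need at least 10 frames to locate the egg", call. = FALSE)
  idx <- unique(round(seq(1L, d[3L], length.out = min(max_sample, d[3L]))))
  sub <- sequence$frames[, , idx, drop = FALSE]
  maxproj <- apply(sub, c(1, 2), max)
  mu <- apply(sub, c(1, 2), mean)
  varmap <- apply(sub, c(1, 2), function(v) mean(v^2)) - mu^2
  combined <- pmax(.norm01(maxproj), .norm01(varmap))
  if (diff(range(combined)) == 0)
    stop("egg not found: no signal above background; flag this embryo ",
         "for an ROI override", call. = FALSE)
  # require real structure: the brightest signal must stand far above
  # the background spread, else this is a noise-only scene
  med <- stats::median(combined)
  spread <- stats::mad(combined)
  if (max(combined) < med + 8 * max(spread, 1e-6))
    stop("egg not found: no candidate region above background; flag ",
         "this embryo for an ROI override", call. = FALSE)
  # dark-field: background sits at the low end; take everything a
  # quarter of the way up from the background level
  mask <- combined > med + 0.25 * (max(combined) - med)
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3L, "disc"))
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < 0.005 * d[1L] * d[2L])
    stop("egg not found: no candidate region above background; flag ",
         "this embryo for an ROI override", call. = FALSE)
  comp <- which(lab == which.max(sizes), arr.ind = TRUE) - 1  # 0-based
  ctr <- colMeans(comp)
  cv <- stats::cov(comp) * (nrow(comp) - 1) / nrow(comp)
  eg <- eigen(cv, symmetric = TRUE)
  semi <- 2 * sqrt(pmax(eg$values, 1e-9))
  ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  roi <- structure(list(center = ctr, semi_axes = semi, angle = ang,
                        source = "auto"), class = "egg_roi")
  # shrink, if needed, so the ROI stays inside the frame
  ext <- .roi_extent(roi)
  shrink <- min(1,
                (roi$center[1]) / ext[1], (d[1] - 1 - roi$center[1]) / ext[1],
                (roi$center[2]) / ext[2], (d[2] - 1 - roi$center[2]) / ext[2])
  roi$semi_axes <- roi$semi_axes * max(shrink, 0.01)
  roi
}

#' Apply user ROI overrides
#'
#' Replaces automatically fitted egg ROIs with user-supplied ellipse
#' parameters from a CSV file with columns `embryo_id, center_row,
#' center_col, semi_a, semi_b, angle_deg`. This is the non-interactive
#' counterpart of visually validating and editing egg ROIs: overridden
#' embryos carry `source = "override"`.
#'
#' @param rois Named list of [egg_roi()] (names are embryo ids).
#' @param overrides_file CSV of overrides.
#' @param frame_dim Optional `(rows, cols)` used to validate that each
#'   override lies inside the frame.
#' @return The updated named list of ROIs.
#' @export
apply_roi_overrides <- function(rois, overrides_file, frame_dim = NULL) {
  ov <- utils::read.csv(overrides_file, stringsAsFactors = FALSE)
  need <- c("embryo_id", "center_row", "center_col", "semi_a", "semi_b",
            "angle_deg")
  if (!all(need %in% names(ov)))
    stop("overrides file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(ov))) {
    id <- as.character(ov$embryo_id[i])
    rois[[id]] <- egg_roi(c(ov$center_row[i], ov$center_col[i]),
                          c(ov$semi_a[i], ov$semi_b[i]),
                          angle = ov$angle_deg[i], source = "override",
                          frame_dim = frame_dim)
  }
  rois
}

.na_measures <- function(valid = FALSE) {
  data.frame(area_px = NaN, centroid_row = NaN, centroid_col = NaN,
             perimeter_px = NaN, bbox_top = NA_integer_,
             bbox_left = NA_integer_, bbox_height = NA_integer_,
             bbox_width = NA_integer_, solidity = NaN,
             boundary_touch = NA, valid = valid)
}

#' Segment the embryo in one frame
#'
#' Within the egg ROI, intensities are median-filtered (3x3), an
#' automatic (Otsu) global threshold separates the bright embryo from
#' the dark-field background, the binary mask is opened (radius-1
#' disc), and the embryo is taken as the largest connected component
#' at or above a minimum-size floor (ties broken by distance to the
#' ROI centre). Area is the pixel-count of the component, i.e. the
#' polygon area of its traced pixel-edge boundary, matching the
#' contour-area convention used for manual outline validation. When no
#' component reaches the floor the frame soft-fails (`valid = FALSE`,
#' all measures NaN) rather than erroring.
#'
#' @param frame `rows x cols` intensity matrix.
#' @param roi An [egg_roi()] valid for the frame shape.
#' @param min_size_frac Minimum component size as a fraction of the
#'   ROI pixel area (default 0.1%).
#' @return One-row data frame of frame measures: `area_px`,
#'   `centroid_row`, `centroid_col`, `perimeter_px`, `bbox_*`,
#'   `solidity`, `boundary_touch`, `valid`.
#' @export
segment_embryo <- function(frame, roi, min_size_frac = 0.001) {
  d <- dim(frame)
  bb <- .roi_bbox(roi, d)
  rows <- (bb["top"] + 1):(bb["top"] + bb["height"])
  cols <- (bb["left"] + 1):(bb["left"] + bb["width"])
  sub <- frame[rows, cols, drop = FALSE]
  if (anyNA(sub)) return(.na_measures())
  mask_roi <- .ellipse_mask(bb["height"], bb["width"],
                            roi$center - c(bb["top"], bb["left"]),
                            roi$semi_axes, roi$angle)
  if (!any(mask_roi)) return(.na_measures())
  med <- EBImage::medianFilter(pmin(pmax(sub / 65535, 0), 1), size = 1L)
  vals <- med[mask_roi]
  if (diff(range(vals)) == 0) return(.na_measures())
  th <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1L)),
                      range = range(vals), levels = 256L)
  bin <- med > th & mask_roi
  bin <- EBImage::opening(bin, EBImage::makeBrush(3L, "disc"))
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  floor_px <- max(5, min_size_frac * sum(mask_roi))
  ok <- which(sizes >= floor_px)
  if (!length(ok)) return(.na_measures())
  if (length(ok) > 1L) {
    # largest wins; exact ties broken by proximity to the ROI centre
    best_size <- max(sizes[ok])
    cand <- ok[sizes[ok] == best_size]
    if (length(cand) > 1L) {
      ctr_local <- roi$center - c(bb["top"], bb["left"])
      dists <- vapply(cand, function(k) {
        px <- which(lab == k, arr.ind = TRUE) - 1
        sum((colMeans(px) - ctr_local)^2)
      }, 0)
      chosen <- cand[which.min(dists)]
    } else chosen <- cand
  } else chosen <- ok
  comp <- lab == chosen
  px <- which(comp, arr.ind = TRUE) - 1          # 0-based local coords
  area <- nrow(px)
  centroid <- colMeans(px) + c(bb["top"], bb["left"])
  shp <- EBImage::computeFeatures.shape(matrix(as.integer(comp),
                                               nrow(comp), ncol(comp)))
  perim <- unname(shp[1L, "s.perimeter"])
  # solidity: pixel area over the convex hull of the pixel squares
  corners <- rbind(px + rep(c(-0.5, -0.5), each = area),
                   px + rep(c(-0.5, 0.5), each = area),
                   px + rep(c(0.5, -0.5), each = area),
                   px + rep(c(0.5, 0.5), each = area))
  h <- grDevices::chull(corners)
  hp <- corners[h, , drop = FALSE]
  hull_area <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                       hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
  solidity <- min(1, area / max(hull_area, area))
  eroded <- EBImage::erode(mask_roi, EBImage::makeBrush(3L, "box"))
  touch <- any(comp & !eroded)
  bpx <- apply(px, 2, range)
  data.frame(area_px = area, centroid_row = unname(centroid[1]),
             centroid_col = unname(centroid[2]), perimeter_px = perim,
             bbox_top = as.integer(bpx[1, 1] + bb["top"]),
             bbox_left = as.integer(bpx[1, 2] + bb["left"]),
             bbox_height = as.integer(diff(bpx[, 1]) + 1),
             bbox_width = as.integer(diff(bpx[, 2]) + 1),
             solidity = solidity, boundary_touch = touch, valid = TRUE)
}

#' Segment every frame of a recording
#'
#' @param sequence An [image_sequence()].
#' @param roi An [egg_roi()].
#' @param ... Passed to [segment_embryo()].
#' @return Data frame with one row per frame (plus `time_s`).
#' @export
segment_sequence <- function(sequence, roi, ...) {
  n <- dim(sequence$frames)[3L]
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- segment_embryo(sequence$frames[, , i], roi, ...)
  out <- do.call(rbind, rows)
  out <- cbind(time_s = sequence$timestamps, out)
  rownames(out) <- NULL
  out
}

#' Export ROI overlay images
#'
#' Writes one PNG per embryo showing the first frame with the egg ROI
#' ellipse (green) and, when segmentation succeeds, the embryo
#' component boundary (red). A non-interactive stand-in for visually
#' validating egg ROIs; output bytes are deterministic for fixed
#' input.
#'
#' @param first_frames Named list of `rows x cols` matrices (first
#'   frame per embryo).
#' @param rois Named list of [egg_roi()] matching `first_frames`.
#' @param out_dir Output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
export_roi_overlays <- function(first_frames, rois, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(first_frames)) {
    fr <- first_frames[[id]]
    roi <- rois[[id]]
    g <- .norm01(fr)
    rgb <- array(g, c(dim(fr), 3L))
    ring <- .ellipse_mask(nrow(fr), ncol(fr), roi$center,
                          roi$semi_axes + 1, roi$angle) &
            !.ellipse_mask(nrow(fr), ncol(fr), roi$center,
                           pmax(roi$semi_axes - 1, 0.5), roi$angle)
    rgb[, , 1][ring] <- 0; rgb[, , 2][ring] <- 1; rgb[, , 3][ring] <- 0
    fm <- segment_embryo(fr, roi)
    if (isTRUE(fm$valid)) {
      bb <- .roi_bbox(roi, dim(fr))
      rows <- (bb["top"] + 1):(bb["top"] + bb["height"])
      cols <- (bb["left"] + 1):(bb["left"] + bb["width"])
      sub <- fr[rows, cols, drop = FALSE]
      mask_roi <- .ellipse_mask(bb["height"], bb["width"],
                                roi$center - c(bb["top"], bb["left"]),
                                roi$semi_axes, roi$angle)
      med <- EBImage::medianFilter(pmin(pmax(sub / 65535, 0), 1), size = 1L)
      th <- EBImage::otsu(EBImage::Image(matrix(med[mask_roi], ncol = 1L)),
                          range = range(med[mask_roi]), levels = 256L)
      bin <- EBImage::opening(med > th & mask_roi,
                              EBImage::makeBrush(3L, "disc"))
      edge <- bin & !EBImage::erode(bin, EBImage::makeBrush(3L, "box"))
      full <- matrix(FALSE, nrow(fr), ncol(fr))
      full[rows, cols] <- edge
      rgb[, , 1][full] <- 1; rgb[, , 2][full] <- 0; rgb[, , 3][full] <- 0
    } else {
      message("overlay for embryo ", id,
              ": no embryo contour (segmentation invalid on first frame)")
    }
    p <- file.path(out_dir, paste0(id, "_roi.png"))
    png::writePNG(rgb, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
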