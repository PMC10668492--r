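#' Extract the three orthogonal maximal-cross-section views of a nodule
#'
#' For each body axis the slice maximising the in-plane mask area is selected
#' (ties broken towards the lowest slice index); the view is the smallest
#' square crop containing the in-plane mask boundary, expanded by `margin_px`
#' and padded with `pad_value` where the square leaves the grid. Axis naming
#' follows the scan convention: x = left-right, y = anterior-posterior,
#' z = superior-inferior.
#'
#' @param volume 3-D numeric array.
#' @param mask nonempty mask (logical array or `region_mask`) on the same grid.
#' @param margin_px margin added on every side of the bounding square.
#' @param slice_index optional named vector/list `x`,`y`,`z` forcing the slice
#'   indices (used to pull a second structure, e.g. the spine, from the same
#'   slices as the nodule views).
#' @param crop_box optional list of per-axis crop squares (as returned in
#'   `$boxes`) forcing the crop windows, e.g. to crop the baseline scan with
#'   the follow-up scan's windows.
#' @param pad_value fill for out-of-grid pixels (default: the volume minimum).
#' @return object of class `view_set`: `views` (named list of square
#'   matrices), `mask_views`, `slice_index`, `boxes` (per-axis
#'   `c(lo1, hi1, lo2, hi2)` in slice coordinates, possibly out of grid).
#' @export
extract_views <- function(volume, mask, margin_px = 4L, slice_index = NULL,
                          crop_box = NULL, pad_value = NULL) {
  m <- as_mask_array(mask)
  if (!any(m)) stop("extract_views: empty mask")
  if (!identical(dim(volume), dim(m))) stop("extract_views: shape mismatch")
  if (is.null(pad_value)) pad_value <- min(volume)
  axes <- c("x", "y", "z")
  views <- list(); mviews <- list(); sidx <- integer(3); boxes <- list()
  for (a in 1:3) {
    areas <- apply(m, a, sum)
    si <- if (!is.null(slice_index)) as.integer(slice_index[[axes[a]]]) else which.max(areas)
    sl <- switch(a, volume[si, , ], volume[, si, ], volume[, , si])
    msl <- switch(a, m[si, , ], m[, si, ], m[, , si])
    if (!is.null(crop_box)) {
      box <- crop_box[[axes[a]]]
    } else {
      box <- square_box(msl, margin_px)
    }
    views[[axes[a]]] <- crop_pad(sl, box, pad_value)
    mviews[[axes[a]]] <- crop_pad(msl * 1, box, 0) > 0.5
    sidx[a] <- si
    boxes[[axes[a]]] <- box
  }
  structure(list(views = views, mask_views = mviews,
                 slice_index = stats::setNames(sidx, axes), boxes = boxes),
            class = "view_set")
}

# smallest centred square covering the TRUE pixels of a 2-D mask, plus margin;
# returns c(lo1, hi1, lo2, hi2), possibly extending beyond the grid
square_box <- function(msl, margin_px) {
  idx <- which(msl, arr.ind = TRUE)
  if (!nrow(idx)) stop("extract_views: empty in-plane mask")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  side <- max(hi - lo + 1L) + 2L * margin_px
  cen <- (lo + hi) / 2
  lo1 <- floor(cen[1] - (side - 1) / 2); lo2 <- floor(cen[2] - (side - 1) / 2)
  c(lo1, lo1 + side - 1L, lo2, lo2 + side - 1L)
}

# union of two square boxes, re-squared
union_box <- function(b1, b2, margin_px = 0L) {
  lo <- c(min(b1[1], b2[1]), min(b1[3], b2[3]))
  hi <- c(max(b1[2], b2[2]), max(b1[4], b2[4]))
  side <- max(hi - lo + 1L) + 2L * margin_px
  cen <- (lo + hi) / 2
  lo1 <- floor(cen[1] - (side - 1) / 2); lo2 <- floor(cen[2] - (side - 1) / 2)
  c(lo1, lo1 + side - 1L, lo2, lo2 + side - 1L)
}

crop_pad <- function(sl, box, pad_value) {
  d <- dim(sl)
  r <- box[1]:box[2]; cc <- box[3]:box[4]
  out <- matrix(pad_value, length(r), length(cc))
  rv <- r[r >= 1 & r <= d[1]]; cv <- cc[cc >= 1 & cc <= d[2]]
  if (length(rv) && length(cv))
    out[match(rv, r), match(cv, cc)] <- sl[rv, cv]
  out
}

#' Extract paired baseline/follow-up views sharing crop windows
#'
#' The follow-up scan is the fixed image: its maximal-cross-section slices
#' define the view planes; the baseline (moving) scan is sliced at its own
#' mask maxima (absorbing out-of-plane shift) but cropped with the union crop
#' window of both timepoints, so in-plane motion remains observable by the
#' registration stage.
#'
#' @param pair a `phantom_pair` (or any list with `baseline_volume`,
#'   `followup_volume`, `baseline_mask`, `followup_mask`).
#' @param margin_px crop margin in pixels.
#' @return list with `fixed` and `moving` `view_set`s.
#' @export
extract_view_pair <- function(pair, margin_px = 4L) {
  mf <- as_mask_array(pair$followup_mask)
  mb <- as_mask_array(pair$baseline_mask)
  axes <- c("x", "y", "z")
  fsl <- vapply(1:3, function(a) which.max(apply(mf, a, sum)), integer(1))
  bsl <- vapply(1:3, function(a) which.max(apply(mb, a, sum)), integer(1))
  boxes <- lapply(1:3, function(a) {
    msf <- switch(a, mf[fsl[a], , ], mf[, fsl[a], ], mf[, , fsl[a]])
    msb <- switch(a, mb[bsl[a], , ], mb[, bsl[a], ], mb[, , bsl[a]])
    union_box(square_box(msf, margin_px), square_box(msb, margin_px))
  })
  names(boxes) <- axes
  fixed <- extract_views(pair$followup_volume, mf,
                         slice_index = stats::setNames(as.list(fsl), axes),
                         crop_box = boxes)
  moving <- extract_views(pair$baseline_volume, mb,
                          slice_index = stats::setNames(as.list(bsl), axes),
                          crop_box = boxes)
  list(fixed = fixed, moving = moving)
}

#' Extract spine-landmark crops from given slices
#'
#' Thresholds the volume at `hu_threshold` to locate high-attenuation bone and
#' crops its bounding square in the requested slices (typically the slices of
#' the nodule views). Returns `NULL` when no bone is present in a slice. When
#' a `crop_box` is supplied (e.g. the union of the baseline and follow-up bone
#' boxes, so a registration pair shares one coordinate window and in-plane
#' motion stays observable) it overrides the per-slice bounding square.
#'
#' @param volume 3-D HU array.
#' @param slice_index named `x`,`y`,`z` slice indices.
#' @param hu_threshold bone attenuation threshold (default 150 HU).
#' @param margin_px crop margin.
#' @param crop_box optional named list of per-axis crop squares.
#' @return named list of square matrices (or `NULL` per axis) with the boxes
#'   used in attribute `"boxes"`.
#' @export
extract_spine_views <- function(volume, slice_index, hu_threshold = 150,
                                margin_px = 4L, crop_box = NULL) {
  axes <- c("x", "y", "z")
  out <- list(); boxes <- list()
  for (a in 1:3) {
    si <- as.integer(slice_index[[axes[a]]])
    sl <- switch(a, volume[si, , ], volume[, si, ], volume[, , si])
    bone <- sl > hu_threshold
    if (!any(bone)) { out[axes[a]] <- list(NULL); boxes[axes[a]] <- list(NULL); next }
    box <- if (!is.null(crop_box) && !is.null(crop_box[[axes[a]]]))
      crop_box[[axes[a]]] else square_box(bone, margin_px)
    out[[axes[a]]] <- crop_pad(sl, box, min(volume))
    boxes[[axes[a]]] <- box
  }
  attr(out, "boxes") <- boxes
  out
}

#' Extract an aligned baseline/follow-up spine crop pair
#'
#' Crops the spine landmark from the same slices as the nodule views of both
#' scans, using one shared crop window (the union of the two bone bounding
#' squares), so the spine crops live in a common coordinate frame and the
#' inter-scan rigid motion remains observable.
#'
#' @param pair scan pair (volumes under `followup_volume`/`baseline_volume`).
#' @param fixed_slice_index,moving_slice_index named slice indices (typically
#'   `view_set$slice_index` of the follow-up and baseline views).
#' @param hu_threshold,margin_px see [extract_spine_views()].
#' @return list `fixed`, `moving`: named lists of square matrices (NULL per
#'   axis when no bone is visible).
#' @export
spine_crop_pair <- function(pair, fixed_slice_index, moving_slice_index,
                            hu_threshold = 150, margin_px = 4L) {
  f0 <- extract_spine_views(pair$followup_volume, fixed_slice_index,
                            hu_threshold, margin_px)
  m0 <- extract_spine_views(pair$baseline_volume, moving_slice_index,
                            hu_threshold, margin_px)
  fb <- attr(f0, "boxes"); mb <- attr(m0, "boxes")
  shared <- lapply(c(x = "x", y = "y", z = "z"), function(a) {
    if (is.null(fb[[a]]) || is.null(mb[[a]])) NULL else union_box(fb[[a]], mb[[a]])
  })
  list(fixed = extract_spine_views(pair$followup_volume, fixed_slice_index,
                                   hu_threshold, margin_px, crop_box = shared),
       moving = extract_spine_views(pair$baseline_volume, moving_slice_index,
                                    hu_threshold, margin_px, crop_box = shared))
}
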