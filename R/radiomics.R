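#' Radiomics extraction configuration
#'
#' @param bin_width gray-level discretisation bin width in HU (fixed bin
#'   width, default 25 HU — a common chest-CT setting).
#' @param wavelet compute the 744 wavelet-filtered features (8 sub-bands x 93
#'   non-shape features) in addition to the 107 original-image features.
#' @param resample_mm isotropic target spacing (mm) for trilinear resampling
#'   before extraction, or `NULL` to extract at native spacing.
#' @param gldm_alpha gray-level dependence similarity tolerance.
#' @param max_gray_levels cap on the number of discretised levels; if the
#'   fixed bin width would exceed it (possible on wavelet sub-bands), the bin
#'   width is widened to span the range in `max_gray_levels` bins.
#' @param crop_margin_vox bounding-box crop margin (voxels) applied before
#'   filtering/extraction, for speed.
#' @return list of class `radiomics_config`.
#' @export
radiomics_config <- function(bin_width = 25, wavelet = TRUE, resample_mm = NULL,
                             gldm_alpha = 0, max_gray_levels = 256,
                             crop_margin_vox = 4L) {
  structure(list(bin_width = bin_width, wavelet = wavelet,
                 resample_mm = resample_mm, gldm_alpha = gldm_alpha,
                 max_gray_levels = max_gray_levels,
                 crop_margin_vox = as.integer(crop_margin_vox)),
            class = "radiomics_config")
}

#' The full feature inventory
#'
#' @param wavelet include the wavelet-filtered entries.
#' @return data frame with columns `name`, `image_type`, `family`; 851 rows at
#'   defaults (14 shape + 18 first-order + 24 GLCM + 14 GLDM + 16 GLRLM +
#'   16 GLSZM + 5 NGTDM on the original image, plus 93 non-shape features on
#'   each of the 8 wavelet sub-bands).
#' @export
feature_inventory <- function(wavelet = TRUE) {
  fam <- list(shape = shape_feature_names,
              firstorder = firstorder_feature_names,
              glcm = glcm_feature_names,
              gldm = gldm_feature_names,
              glrlm = glrlm_feature_names,
              glszm = glszm_feature_names,
              ngtdm = ngtdm_feature_names)
  rows <- do.call(rbind, lapply(names(fam), function(f)
    data.frame(name = paste0("original_", f, "_", fam[[f]]),
               image_type = "original", family = f, stringsAsFactors = FALSE)))
  if (wavelet) {
    bands <- c("LLL", "LLH", "LHL", "HLL", "LHH", "HLH", "HHL", "HHH")
    nonshape <- setdiff(names(fam), "shape")
    wrows <- do.call(rbind, lapply(bands, function(b)
      do.call(rbind, lapply(nonshape, function(f)
        data.frame(name = paste0("wavelet-", b, "_", f, "_", fam[[f]]),
                   image_type = paste0("wavelet-", b), family = f,
                   stringsAsFactors = FALSE)))))
    rows <- rbind(rows, wrows)
  }
  rows
}

#' Discretise region intensities to gray levels
#'
#' Fixed-bin-width discretisation: level = floor(x / w) - floor(min(x) / w) + 1.
#' @param values numeric vector of in-region intensities.
#' @param bin_width bin width in intensity units.
#' @param max_levels widen the bin width if more than this many levels result.
#' @return integer vector of levels in 1..Ng.
#' @export
discretize_gray <- function(values, bin_width, max_levels = 256) {
  rng <- max(values) - min(values)
  if (rng > bin_width * max_levels) bin_width <- rng / max_levels
  lev <- floor(values / bin_width) - floor(min(values) / bin_width) + 1
  as.integer(lev)
}

crop_to_mask <- function(volume, m, margin) {
  idx <- which(m, arr.ind = TRUE)
  d <- dim(m)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(volume = volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

resample_iso <- function(volume, m, sp, target) {
  if (all(abs(sp - target) < 1e-9)) return(list(volume = volume, mask = m, spacing = sp))
  d <- dim(volume)
  newd <- pmax(2L, as.integer(round((d - 1) * sp / target)) + 1L)
  gx <- seq(1, d[1], length.out = newd[1])
  gy <- seq(1, d[2], length.out = newd[2])
  gz <- seq(1, d[3], length.out = newd[3])
  G <- expand.grid(x = gx, y = gy, z = gz)
  vol <- array(trilinear(volume, G$x, G$y, G$z), newd)
  msk <- array(trilinear(array(as.numeric(m), d), G$x, G$y, G$z) >= 0.5, newd)
  list(volume = vol, mask = msk, spacing = rep(target, 3))
}

# the 93 non-shape features of one (possibly filtered) image restricted to a mask
nonshape_block <- function(volume, m, cfg, voxel_volume) {
  vals <- volume[m]
  disc <- discretize_gray(vals, cfg$bin_width, cfg$max_gray_levels)
  img <- array(0L, dim(volume))
  img[m] <- disc
  dims <- as.integer(dim(volume))
  np <- length(vals)
  c(stats::setNames(compute_firstorder_features(vals, disc, voxel_volume),
                    paste0("firstorder_", firstorder_feature_names)),
    stats::setNames(compute_glcm_features(cpp_glcm(as.vector(img), dims)),
                    paste0("glcm_", glcm_feature_names)),
    stats::setNames(compute_gldm_features(cpp_gldm(as.vector(img), dims, cfg$gldm_alpha)),
                    paste0("gldm_", gldm_feature_names)),
    stats::setNames(compute_glrlm_features(cpp_glrlm(as.vector(img), dims), np),
                    paste0("glrlm_", glrlm_feature_names)),
    stats::setNames(compute_glszm_features(cpp_glszm(as.vector(img), dims), np),
                    paste0("glszm_", glszm_feature_names)),
    stats::setNames(compute_ngtdm_features(cpp_ngtdm(as.vector(img), dims)),
                    paste0("ngtdm_", ngtdm_feature_names)))
}

#' Extract the radiomics feature vector of one region
#'
#' Computes the full IBSI-style inventory on a volume restricted to a region
#' mask: 14 shape, 18 first-order and 75 texture features on the original
#' image, plus (by default) the same 93 non-shape features on each of the 8
#' one-level 3-D wavelet sub-bands — 851 named features in total. Extraction
#' is deterministic for fixed input and configuration.
#'
#' @param volume 3-D numeric array (HU).
#' @param mask `region_mask` (or logical array) on the same grid.
#' @param config a [radiomics_config()].
#' @param spacing_mm voxel spacing override when `mask` is a bare array.
#' @return named numeric vector (class `feature_vector`) with attributes
#'   `region_tag`, `rater_id` carried over from the mask.
#' @export
extract_features <- function(volume, mask, config = radiomics_config(),
                             spacing_mm = NULL) {
  sp <- mask_spacing(mask, spacing_mm)
  m <- as_mask_array(mask)
  if (!identical(dim(volume), dim(m))) stop("extract_features: shape mismatch")
  if (sum(m) <= 1) stop("extract_features: mask must contain more than one voxel")
  cr <- crop_to_mask(volume, m, config$crop_margin_vox)
  vol <- cr$volume; msk <- cr$mask
  if (!is.null(config$resample_mm)) {
    rs <- resample_iso(vol, msk, sp, config$resample_mm)
    vol <- rs$volume; msk <- rs$mask; sp <- rs$spacing
    if (sum(msk) <= 1) stop("extract_features: mask vanished under resampling")
  }
  vv <- prod(sp)
  out <- c(
    stats::setNames(compute_shape_features(msk, sp),
                    paste0("original_shape_", shape_feature_names)),
    stats::setNames(nonshape_block(vol, msk, config, vv), NULL))
  inv <- feature_inventory(wavelet = FALSE)
  names(out) <- inv$name
  if (isTRUE(config$wavelet)) {
    bands <- wavelet_subbands(vol)
    wout <- unlist(lapply(names(bands), function(b) {
      stats::setNames(nonshape_block(bands[[b]], msk, config, vv), NULL)
    }))
    winv <- feature_inventory(wavelet = TRUE)
    wnames <- winv$name[winv$image_type != "original"]
    names(wout) <- wnames
    out <- c(out, wout)
  }
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite features: ", paste(head(bad, 5), collapse = ", "))
  }
  structure(out, class = c("feature_vector", "numeric"),
            region_tag = if (inherits(mask, "region_mask")) mask$region_tag else NA_character_,
            rater_id = if (inherits(mask, "region_mask")) mask$rater_id else NA_character_)
}

#' Min-max normalisation fitted on a row subset
#'
#' Fits per-feature ranges on `fit_rows` only (the training split) and applies
#' the transform `x' = (x - min) / (max - min)` to all rows; held-out rows may
#' therefore fall outside \[0, 1\]. Constant features map to 0 with a warning.
#'
#' @param table numeric matrix or data frame, samples x features.
#' @param fit_rows integer indices of the rows used to fit the ranges
#'   (default: all rows).
#' @return list of class `minmax_norm` with `values` (normalised matrix),
#'   `ranges` (data frame `feature`, `min`, `max`) and `constant` (names of
#'   flagged constant features).
#' @export
minmax_normalize <- function(table, fit_rows = NULL) {
  x <- as.matrix(table)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(x))
  if (!length(fit_rows)) stop("minmax_normalize: fit_rows is empty")
  mins <- apply(x[fit_rows, , drop = FALSE], 2, min)
  maxs <- apply(x[fit_rows, , drop = FALSE], 2, max)
  const <- maxs - mins <= 0
  if (any(const))
    warning("minmax_normalize: ", sum(const), " constant feature(s) set to 0")
  rng <- ifelse(const, 1, maxs - mins)
  vals <- sweep(sweep(x, 2, mins, `-`), 2, rng, `/`)
  vals[, const] <- 0
  structure(list(values = vals,
                 ranges = data.frame(feature = colnames(x) %||% as.character(seq_len(ncol(x))),
                                     min = mins, max = maxs, row.names = NULL),
                 constant = (colnames(x) %||% as.character(seq_len(ncol(x))))[const]),
            class = "minmax_norm")
}

#' Apply or invert a fitted min-max transform
#' @param norm a `minmax_norm` object.
#' @param table new samples x features data (apply) or normalised data (invert).
#' @return numeric matrix.
#' @export
minmax_apply <- function(norm, table) {
  x <- as.matrix(table)
  rng <- ifelse(norm$ranges$max - norm$ranges$min <= 0, 1, norm$ranges$max - norm$ranges$min)
  out <- sweep(sweep(x, 2, norm$ranges$min, `-`), 2, rng, `/`)
  out[, norm$ranges$max - norm$ranges$min <= 0] <- 0
  out
}

#' @rdname minmax_apply
#' @export
minmax_invert <- function(norm, table) {
  x <- as.matrix(table)
  rng <- ifelse(norm$ranges$max - norm$ranges$min <= 0, 1, norm$ranges$max - norm$ranges$min)
  sweep(sweep(x, 2, rng, `*`), 2, norm$ranges$min, `+`)
}
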