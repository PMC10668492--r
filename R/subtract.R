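#' Spine-landmark fallback registration
#'
#' When direct nodule registration is unreliable (fast or strongly
#' anisotropic growth changes the nodule's appearance too much), the rigid
#' transform is estimated on spine crops taken from the same slices — the
#' spine is rigid and unaffected by tumour growth — and then applied to the
#' nodule view. Only a rigid transform (no scale) is estimated, and rotation
#' is applied about the view centre, so the fallback is exact for
#' translation-dominant inter-scan motion.
#'
#' @param fixed_spine,moving_spine spine crops (matrices of the same shape)
#'   from the follow-up and baseline scans.
#' @param moving_nodule_view the baseline nodule view to realign.
#' @param fixed_nodule_view follow-up nodule view (for the reported SSIM).
#' @param method intensity metric used on the spine crops.
#' @return `registration_result` with `fallback_used = TRUE` and the warped
#'   nodule view in `warped_image`.
#' @export
spine_fallback_register <- function(fixed_spine, moving_spine, moving_nodule_view,
                                    fixed_nodule_view = NULL,
                                    method = c("monomodal_intensity", "multimodal_mi")) {
  method <- match.arg(method)
  if (is.null(fixed_spine) || is.null(moving_spine))
    stop("spine_fallback_register: spine crops unavailable")
  if (!identical(dim(fixed_spine), dim(moving_spine)))
    stop("spine_fallback_register: spine crops differ in shape")
  sreg <- register(fixed_spine, moving_spine, method = method, transform = "rigid")
  w <- apply_transform2d(moving_nodule_view, sreg$transform,
                         fill = min(moving_nodule_view))
  s1 <- if (!is.null(fixed_nodule_view)) ssim(fixed_nodule_view, w$image) else NA_real_
  s0 <- if (!is.null(fixed_nodule_view)) ssim(fixed_nodule_view, moving_nodule_view) else NA_real_
  res <- registration_result(paste0(method, "+spine"), sreg$transform, w$image,
                             s1, s0, TRUE)
  res
}

#' Subtract a warped baseline view from the follow-up view
#'
#' Elementwise difference (follow-up minus warped baseline), then — for the
#' CNN input — symmetric clipping at `clip_hu`, linear rescaling to [0, 1]
#' (a zero difference maps to 0.5) and bilinear resizing to `out_size`.
#'
#' @param warped_baseline,followup_view matrices of the same shape.
#' @param clip_hu symmetric clipping bound for the HU difference (default 200).
#' @param out_size CNN input size (default 64 x 64; 227 x 227 mirrors the
#'   classic AlexNet input).
#' @return list `raw` (unscaled difference) and `image` (normalised, resized).
#' @export
subtract_views <- function(warped_baseline, followup_view, clip_hu = 200,
                           out_size = c(64L, 64L)) {
  if (!identical(dim(warped_baseline), dim(followup_view)))
    stop("subtract_views: shape mismatch")
  raw <- followup_view - warped_baseline
  clipped <- pmin(pmax(raw, -clip_hu), clip_hu)
  norm <- (clipped + clip_hu) / (2 * clip_hu)
  list(raw = raw, image = resize2d(norm, out_size))
}

#' Build the per-subject delta-image set
#'
#' Runs the full view pipeline for one scan pair: extract the three
#' orthogonal maximal-cross-section view pairs (shared crop windows),
#' register baseline onto follow-up per view, fall back to spine-landmark
#' registration when the direct SSIM drops below `fallback_threshold` (or
#' keypoint matching fails), and subtract to produce three normalised delta
#' images.
#'
#' @param pair a `phantom_pair`-like list of volumes and masks.
#' @param method registration method for the direct attempt.
#' @param fallback_threshold direct-registration SSIM below which the spine
#'   fallback is attempted (default 0.5).
#' @param clip_hu,out_size passed to [subtract_views()].
#' @param margin_px view crop margin.
#' @return object of class `delta_image_set`: `images` (named list of x/y/z
#'   matrices in [0,1]), `raw` (unscaled differences), `log` (per-axis data
#'   frame with method, ssim, fallback_used).
#' @export
delta_image_set <- function(pair, method = "monomodal_intensity",
                            fallback_threshold = 0.5, clip_hu = 200,
                            out_size = c(64L, 64L), margin_px = 4L) {
  vp <- extract_view_pair(pair, margin_px = margin_px)
  axes <- c("x", "y", "z")
  images <- list(); raws <- list(); logs <- list()
  for (a in axes) {
    fixed <- vp$fixed$views[[a]]; moving <- vp$moving$views[[a]]
    reg <- register(fixed, moving, method = method)
    used <- reg
    if (reg$fallback_needed || reg$ssim < fallback_threshold) {
      sp <- spine_crop_pair(pair, vp$fixed$slice_index, vp$moving$slice_index)
      fsp <- sp$fixed[[a]]; msp <- sp$moving[[a]]
      if (!is.null(fsp) && !is.null(msp)) {
        fb <- try(spine_fallback_register(fsp, msp, moving, fixed), silent = TRUE)
        if (!inherits(fb, "try-error") && (is.na(reg$ssim) || fb$ssim >= reg$ssim))
          used <- fb
      }
    }
    sub <- subtract_views(used$warped_image, fixed, clip_hu, out_size)
    images[[a]] <- sub$image
    raws[[a]] <- sub$raw
    logs[[a]] <- data.frame(axis = a, method = used$method,
                            ssim = used$ssim, ssim_unregistered = used$ssim_unregistered,
                            fallback_used = used$fallback_used)
  }
  structure(list(images = images, raw = raws, log = do.call(rbind, logs),
                 subject_id = pair$subject_id %||% NA_character_),
            class = "delta_image_set")
}

#' Write a delta-image (or any [0,1] matrix) as an 8-bit PNG with a CSV sidecar
#'
#' The PNG stores `round(255 * x)`; the lossless numeric values go to
#' `<path>.csv` alongside.
#'
#' @param img matrix with values in [0, 1].
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
write_delta_png <- function(img, path) {
  if (requireNamespace("png", quietly = TRUE)) {
    png::writePNG(pmin(pmax(t(img), 0), 1), path)
  }
  utils::write.table(img, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
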