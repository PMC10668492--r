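#' Construct a region mask
#'
#' Wraps a binary voxel array with its spacing and provenance tags. The two
#' region tags mirror the two volumes of interest used throughout the package:
#' the intratumoral mask and the 3 mm peritumoral ring.
#'
#' @param array logical (or 0/1) 3-D array.
#' @param spacing_mm per-axis voxel size in mm.
#' @param region_tag `"intratumoral"` or `"peritumoral"`.
#' @param rater_id,repeat_id optional provenance tags for reproducibility
#'   (ICC) analyses.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(array, spacing_mm = c(1, 1, 1),
                        region_tag = c("intratumoral", "peritumoral"),
                        rater_id = NA_character_, repeat_id = NA_integer_) {
  region_tag <- match.arg(region_tag)
  stopifnot(length(dim(array)) == 3)
  structure(list(array = array(as.logical(array), dim(array)),
                 spacing_mm = as.numeric(spacing_mm),
                 region_tag = region_tag, rater_id = rater_id,
                 repeat_id = repeat_id),
            class = "region_mask")
}

as_mask_array <- function(mask) {
  if (inherits(mask, "region_mask")) mask$array else array(as.logical(mask), dim(mask))
}

mask_spacing <- function(mask, spacing_mm = NULL) {
  if (!is.null(spacing_mm)) return(as.numeric(spacing_mm))
  if (inherits(mask, "region_mask")) mask$spacing_mm else c(1, 1, 1)
}

#' Spacing-aware Euclidean distance transform
#'
#' Distance (mm) from every voxel to the nearest `TRUE` voxel, honouring
#' anisotropic voxel spacing (exact, via the separable lower-envelope
#' algorithm).
#'
#' @param mask logical array or `region_mask`.
#' @param spacing_mm voxel spacing; taken from the mask if it carries one.
#' @return numeric array of distances in mm.
#' @export
distance_transform <- function(mask, spacing_mm = NULL) {
  sp <- mask_spacing(mask, spacing_mm)
  m <- as_mask_array(mask)
  d <- dim(m)
  if (!any(m)) return(array(Inf, d))
  array(sqrt(cpp_edt_sq(as.vector(m), as.integer(d), sp)), d)
}

#' Morphological operation with a metric (mm) structuring element
#'
#' Erode, dilate, open or close a binary mask with a Euclidean ball of radius
#' `radius_mm`. The structuring element is defined in millimetres, so results
#' honour anisotropic voxel spacing.
#'
#' @param mask logical array or `region_mask`.
#' @param op one of `"erode"`, `"dilate"`, `"open"`, `"close"`.
#' @param radius_mm ball radius in mm (>= 0; 0 is the identity).
#' @param spacing_mm voxel spacing override.
#' @return object of the same kind as `mask` (array in, array out).
#' @export
morph_op <- function(mask, op, radius_mm, spacing_mm = NULL) {
  if (!op %in% c("erode", "dilate", "open", "close"))
    stop("unknown morphological operation: ", op)
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  sp <- mask_spacing(mask, spacing_mm)
  m <- as_mask_array(mask)
  res <- morph_apply(m, op, radius_mm, sp)
  if (inherits(mask, "region_mask")) {
    out <- mask
    out$array <- res
    out
  } else res
}

morph_apply <- function(m, op, radius_mm, sp) {
  if (radius_mm == 0) return(m)
  dil <- function(x) {
    if (!any(x)) return(x)
    array(cpp_edt_sq(as.vector(x), as.integer(dim(x)), sp) <= radius_mm^2 + 1e-9, dim(x))
  }
  ero <- function(x) !dil(!x)
  switch(op,
         dilate = dil(m),
         erode = ero(m),
         open = dil(ero(m)),
         close = ero(dil(m)))
}

#' Derive the peritumoral ring around a tumour mask
#'
#' Voxels whose Euclidean distance (mm, spacing-aware) to the tumour lies in
#' `(0, width_mm]`; tumour voxels are excluded by construction, so the ring
#' and the intratumoral mask are always disjoint.
#'
#' @param mask tumour mask (logical array or `region_mask`).
#' @param width_mm ring width in mm (default 3, the peritumoral margin used
#'   throughout the package).
#' @param spacing_mm voxel spacing override.
#' @return `region_mask` tagged `"peritumoral"`.
#' @export
peritumoral_ring <- function(mask, width_mm = 3, spacing_mm = NULL) {
  sp <- mask_spacing(mask, spacing_mm)
  m <- as_mask_array(mask)
  if (!any(m)) stop("peritumoral_ring: tumour mask is empty")
  d2 <- cpp_edt_sq(as.vector(m), as.integer(dim(m)), sp)
  ring <- array(d2 > 0 & d2 <= width_mm^2 + 1e-9, dim(m))
  region_mask(ring, sp, region_tag = "peritumoral")
}

#' Apply a binary mask to a volume
#'
#' Voxels outside the mask are set to `background_fill` (elementwise product
#' semantics when the fill is 0).
#'
#' @param volume numeric array.
#' @param mask logical array or `region_mask` on the same grid.
#' @param background_fill value for voxels outside the mask.
#' @return numeric array.
#' @export
apply_mask <- function(volume, mask, background_fill = 0) {
  m <- as_mask_array(mask)
  if (!identical(dim(volume), dim(m))) stop("apply_mask: shape mismatch")
  out <- array(background_fill, dim(volume))
  out[m] <- volume[m]
  out
}

#' Refine an initial mask with a region-based active contour
#'
#' Morphological Chan-Vese-type refinement: at each iteration the inside and
#' outside mean intensities are recomputed and voxels in a one-voxel band
#' around the current boundary are reassigned to the closer region mean;
#' `smoothing` rounds of a median-style (open-close) regularisation follow.
#' This is the batch stand-in for interactive snake initialisation: the
#' initial mask may come from a truth mask, a threshold seed, or a user
#' delineation.
#'
#' @param volume numeric array.
#' @param init_mask initial mask (nonempty, overlapping the object).
#' @param iterations maximum refinement sweeps (default 100; stops early on
#'   convergence).
#' @param smoothing regularisation rounds per sweep (default 1).
#' @param spacing_mm voxel spacing.
#' @param verbose log the Dice overlap between the initial and refined mask.
#' @return `region_mask` tagged `"intratumoral"`.
#' @export
refine_mask <- function(volume, init_mask, iterations = 100, smoothing = 1,
                        spacing_mm = NULL, verbose = FALSE) {
  sp <- mask_spacing(init_mask, spacing_mm)
  m <- as_mask_array(init_mask)
  if (!any(m)) stop("refine_mask: initial mask is empty")
  if (!identical(dim(volume), dim(m))) stop("refine_mask: shape mismatch")
  u <- m
  r1 <- min(sp)  # one-voxel-scale structuring radius, in mm
  for (it in seq_len(iterations)) {
    c1 <- mean(volume[u]); c2 <- mean(volume[!u])
    band <- morph_apply(u, "dilate", r1, sp) & !morph_apply(u, "erode", r1, sp)
    u_new <- u
    u_new[band] <- (volume[band] - c1)^2 < (volume[band] - c2)^2
    for (s in seq_len(smoothing)) {
      u_new <- morph_apply(morph_apply(u_new, "open", r1, sp), "close", r1, sp)
    }
    if (!any(u_new)) stop("refine_mask: contour collapsed to an empty region")
    if (identical(u_new, u)) { u <- u_new; break }
    u <- u_new
  }
  dice <- dice_coef(m, u)
  if (verbose) message(sprintf("refine_mask: Dice(init, refined) = %.3f", dice))
  if (dice == 0)
    warning("refine_mask: refined mask no longer overlaps the initial mask")
  region_mask(u, sp, region_tag = "intratumoral")
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays or `region_mask` objects.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coef <- function(a, b) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Simulate repeated delineations by multiple raters
#'
#' Emulates inter-observer and intra-observer segmentation variability by
#' random morphological jitter of a truth mask: each delineation is the truth
#' mask eroded or dilated by a rater- and repeat-specific random radius plus a
#' random sub-voxel shift of the structuring scale. Used to drive ICC
#' reproducibility analyses on phantoms.
#'
#' @param mask truth mask (logical array or `region_mask`).
#' @param n_raters number of raters.
#' @param n_repeats delineations per rater.
#' @param jitter_mm scale of the random boundary perturbation in mm.
#' @param spacing_mm voxel spacing.
#' @param seed RNG seed.
#' @return list of lists: `[[rater]][[repeat]]` each a `region_mask` with
#'   `rater_id`/`repeat_id` set.
#' @export
simulate_raters <- function(mask, n_raters = 2, n_repeats = 2, jitter_mm = 0.8,
                            spacing_mm = NULL, seed = 1L) {
  sp <- mask_spacing(mask, spacing_mm)
  m <- as_mask_array(mask)
  set.seed(seed)
  lapply(seq_len(n_raters), function(r) {
    bias <- runif(1, -jitter_mm, jitter_mm)  # rater-level systematic tendency
    lapply(seq_len(n_repeats), function(k) {
      delta <- bias + runif(1, -jitter_mm / 2, jitter_mm / 2)
      out <- if (delta >= 0) morph_apply(m, "dilate", delta, sp)
             else morph_apply(m, "erode", -delta, sp)
      if (!any(out)) out <- m
      region_mask(out, sp, rater_id = sprintf("R%d", r), repeat_id = k)
    })
  })
}

#' Read / write region masks as NIfTI
#'
#' The region tag is encoded in the filename suffix (`_intra`, `_peri3mm`).
#' @param mask `region_mask` to write.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_mask` returns the path invisibly; `read_mask` returns a
#'   `region_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  RNifti::writeNifti(RNifti::asNifti(mask$array * 1L, pixdim = mask$spacing_mm), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  tag <- if (grepl("_peri", basename(path))) "peritumoral" else "intratumoral"
  region_mask(array(as.array(img) > 0.5, dim(img)),
              spacing_mm = RNifti::pixdim(img)[seq_len(3)], region_tag = tag)
}
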