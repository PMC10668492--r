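#' Specification of a synthetic longitudinal nodule phantom
#'
#' Describes one subject's simulated chest-CT anatomy: an ellipsoidal textured
#' nodule in low-attenuation lung parenchyma, an optional high-attenuation
#' spine landmark, per-axis growth between the baseline and follow-up scans,
#' drift of intra-nodule heterogeneity, inter-scan rigid body motion and
#' additive acquisition noise. Phantom pairs generated from a spec are the test
#' substrate for every downstream stage (no patient data ship with the
#' package).
#'
#' Growth is multiplicative per day by default: semi-axis \eqn{i} at time t is
#' \eqn{r_i(t) = r_{i0} \exp(g_i t)}. A linear model
#' (\eqn{r_i(t) = r_{i0}(1 + g_i t)}) is available via `growth_model`.
#' Intra-nodule texture is a fixed per-subject smooth random field scaled by a
#' time-dependent amplitude `texture_sd_hu + heterogeneity_drift_per_day * t`,
#' so the same anatomy is seen at both timepoints (up to growth, motion and
#' fresh noise).
#'
#' @param grid_shape integer length 3, voxels per axis (x, y, z).
#' @param spacing_mm numeric length 3, voxel size in mm.
#' @param nodule_center_mm nodule centre in mm (defaults to the grid centre).
#' @param radii_mm baseline ellipsoid semi-axes in mm (all > 0).
#' @param growth_rates_per_day per-axis relative growth rate (1/day).
#' @param growth_model `"exponential"` (default) or `"linear"`.
#' @param texture_sd_hu intra-nodule intensity heterogeneity at baseline (HU).
#' @param heterogeneity_drift_per_day change of `texture_sd_hu` per day.
#' @param motion list with `translation_mm` (length 3) and `rotation_deg`
#'   (length 3, rotations about the x, y, z axes through the grid centre)
#'   applied to the whole anatomy between the scans.
#' @param noise_sd_hu additive Gaussian noise standard deviation (HU).
#' @param interval_days follow-up minus baseline acquisition time, > 0.
#' @param include_spine include the rigid spine landmark block.
#' @param seed integer RNG seed controlling texture field and noise.
#' @param hu_lung,hu_nodule,hu_spine tissue attenuation levels (HU).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(1, 1, 1),
                         nodule_center_mm = NULL,
                         radii_mm = c(5, 5, 5),
                         growth_rates_per_day = c(0.002, 0.002, 0.002),
                         growth_model = c("exponential", "linear"),
                         texture_sd_hu = 30,
                         heterogeneity_drift_per_day = 0,
                         motion = list(translation_mm = c(0, 0, 0),
                                       rotation_deg = c(0, 0, 0)),
                         noise_sd_hu = 5,
                         interval_days = 90,
                         include_spine = TRUE,
                         seed = 1L,
                         hu_lung = -800, hu_nodule = -50, hu_spine = 300) {
  growth_model <- match.arg(growth_model)
  extent <- grid_shape * spacing_mm
  if (is.null(nodule_center_mm)) nodule_center_mm <- extent / 2
  stopifnot(length(grid_shape) == 3, length(spacing_mm) == 3,
            length(radii_mm) == 3, length(growth_rates_per_day) == 3)
  if (any(radii_mm <= 0)) stop("radii_mm must be positive")
  if (interval_days <= 0) stop("interval_days must be positive")
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    nodule_center_mm = as.numeric(nodule_center_mm),
    radii_mm = as.numeric(radii_mm),
    growth_rates_per_day = as.numeric(growth_rates_per_day),
    growth_model = growth_model,
    texture_sd_hu = texture_sd_hu,
    heterogeneity_drift_per_day = heterogeneity_drift_per_day,
    motion = list(translation_mm = as.numeric(motion$translation_mm %||% c(0, 0, 0)),
                  rotation_deg = as.numeric(motion$rotation_deg %||% c(0, 0, 0))),
    noise_sd_hu = noise_sd_hu, interval_days = interval_days,
    include_spine = isTRUE(include_spine), seed = as.integer(seed),
    hu_lung = hu_lung, hu_nodule = hu_nodule, hu_spine = hu_spine
  ), class = "phantom_spec")
  check_containment(spec)
  spec
}

radii_at <- function(spec, time_days) {
  if (spec$growth_model == "exponential") {
    spec$radii_mm * exp(spec$growth_rates_per_day * time_days)
  } else {
    spec$radii_mm * (1 + spec$growth_rates_per_day * time_days)
  }
}

texture_sd_at <- function(spec, time_days) {
  max(0, spec$texture_sd_hu + spec$heterogeneity_drift_per_day * time_days)
}

check_containment <- function(spec) {
  extent <- spec$grid_shape * spec$spacing_mm
  rf <- radii_at(spec, spec$interval_days)
  shift <- abs(spec$motion$translation_mm)
  lo <- spec$nodule_center_mm - rf - shift
  hi <- spec$nodule_center_mm + rf + shift
  if (any(lo < 0) || any(hi > extent))
    stop("nodule (after growth and motion) exceeds the image grid")
  invisible(TRUE)
}

# spine landmark: a rigid rectangular block, posterior to the nodule,
# spanning the full z extent (baseline frame, mm)
spine_box <- function(spec) {
  extent <- spec$grid_shape * spec$spacing_mm
  cx <- extent[1] / 2
  list(x = c(cx - 6, cx + 6),
       y = c(0.80 * extent[2], 0.95 * extent[2]),
       z = c(0, extent[3]))
}

# per-subject smooth standard texture field (mean 0, sd 1), fixed by seed
texture_field <- function(spec) {
  set.seed(derive_seed(spec$seed, 1L))
  f <- array(rnorm(prod(spec$grid_shape)), spec$grid_shape)
  f <- gauss_smooth3d(f, 1.5)
  (f - mean(f)) / sd(f)
}

# rigid motion helpers: the anatomy point p (baseline frame, mm) is observed
# at M(p) = R (p - c) + c + t in the follow-up scan, c = grid centre.
rotation_matrix <- function(rotation_deg) {
  th <- rotation_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Render one phantom scan
#'
#' Renders the anatomy of `spec` at time `time_days` after baseline. The mask
#' is the analytic ellipsoid of the grown radii (no segmentation circularity in
#' the truth data). When `apply_motion = TRUE` the spec's rigid inter-scan
#' motion is applied to the whole anatomy (nodule, spine and texture field),
#' which is how the follow-up member of a pair is rendered.
#'
#' @param spec a [phantom_spec()].
#' @param time_days time since baseline (days); 0 renders the baseline scan.
#' @param apply_motion apply the spec's rigid motion to the anatomy.
#' @return list with `volume` (HU array), `mask` (logical array),
#'   `spacing_mm`, and `time_days`.
#' @export
generate_volume <- function(spec, time_days = 0, apply_motion = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$spacing_mm
  extent <- d * sp
  # voxel-centre world coordinates (mm); voxel i covers [(i-1), i) * spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  if (apply_motion &&
      (any(spec$motion$translation_mm != 0) || any(spec$motion$rotation_deg != 0))) {
    cen <- extent / 2
    R <- rotation_matrix(spec$motion$rotation_deg)
    tr <- spec$motion$translation_mm
    # inverse motion: baseline-frame coordinate of each observed voxel
    P <- cbind(as.vector(X) - cen[1] - tr[1],
               as.vector(Y) - cen[2] - tr[2],
               as.vector(Z) - cen[3] - tr[3]) %*% R  # = t(R^T %*% p)
    X0 <- array(P[, 1] + cen[1], d)
    Y0 <- array(P[, 2] + cen[2], d)
    Z0 <- array(P[, 3] + cen[3], d)
  } else {
    X0 <- X; Y0 <- Y; Z0 <- Z
  }
  rt <- radii_at(spec, time_days)
  cn <- spec$nodule_center_mm
  mask <- ((X0 - cn[1]) / rt[1])^2 + ((Y0 - cn[2]) / rt[2])^2 +
    ((Z0 - cn[3]) / rt[3])^2 <= 1
  vol <- array(spec$hu_lung, d)
  if (spec$include_spine) {
    sb <- spine_box(spec)
    spine <- X0 >= sb$x[1] & X0 <= sb$x[2] & Y0 >= sb$y[1] & Y0 <= sb$y[2] &
      Z0 >= sb$z[1] & Z0 <= sb$z[2]
    vol[spine] <- spec$hu_spine
  }
  sd_t <- texture_sd_at(spec, time_days)
  if (any(mask)) {
    if (sd_t > 0) {
      fld <- texture_field(spec)
      # sample the fixed material texture field at baseline-frame coordinates
      vx <- X0[mask] / sp[1] + 1; vy <- Y0[mask] / sp[2] + 1; vz <- Z0[mask] / sp[3] + 1
      vol[mask] <- spec$hu_nodule + sd_t * trilinear(fld, vx, vy, vz)
    } else {
      vol[mask] <- spec$hu_nodule
    }
  }
  if (spec$noise_sd_hu > 0) {
    set.seed(derive_seed(spec$seed, 100L + round(time_days)))
    vol <- vol + array(rnorm(prod(d), 0, spec$noise_sd_hu), d)
  }
  list(volume = vol, mask = mask, spacing_mm = sp, time_days = time_days)
}

#' Generate a baseline/follow-up phantom scan pair
#'
#' The baseline scan renders the anatomy at day 0; the follow-up scan renders
#' the grown nodule after the spec's rigid motion, with fresh noise.
#'
#' @param spec a [phantom_spec()].
#' @param label optional class label (0/1) attached to the pair.
#' @return object of class `phantom_pair` with elements `baseline_volume`,
#'   `followup_volume`, `baseline_mask`, `followup_mask`, `spacing_mm`,
#'   `times_days`, `label`, and `truth` (the spec).
#' @export
generate_pair <- function(spec, label = NA) {
  b <- generate_volume(spec, 0, apply_motion = FALSE)
  f <- generate_volume(spec, spec$interval_days, apply_motion = TRUE)
  stopifnot(any(b$mask), any(f$mask))
  structure(list(
    baseline_volume = b$volume, followup_volume = f$volume,
    baseline_mask = b$mask, followup_mask = f$mask,
    spacing_mm = spec$spacing_mm,
    times_days = c(0, spec$interval_days),
    label = label, truth = spec
  ), class = "phantom_pair")
}

#' Default class recipes for cohort simulation
#'
#' Returns the pair of per-class spec generators used by [generate_cohort()].
#' Both classes share the same follow-up marginal distributions of size,
#' texture amplitude and follow-up interval; they differ only in growth
#' dynamics: the negative class grows isotropically with constant
#' heterogeneity, the positive class grows anisotropically and its
#' heterogeneity drifts upward towards the (class-matched) follow-up
#' amplitude. The signal therefore lives in the change between scans, not in
#' any single scan.
#'
#' @param noise_sd_hu acquisition noise level passed to every subject.
#' @param motion_mm half-range of the uniform per-axis inter-scan translation.
#' @return named list of functions `positive(seed)` and `negative(seed)`, each
#'   returning a [phantom_spec()].
#' @export
default_class_recipes <- function(noise_sd_hu = 5, motion_mm = 3) {
  # The follow-up (pre-surgical) state is drawn from the SAME distribution
  # for both classes — follow-up radii, texture amplitude, interval, motion
  # and total volume-growth rate — and the baseline state is derived by
  # inverse growth. The classes therefore differ only in their dynamics:
  # negatives grow isotropically with constant heterogeneity, positives
  # split the same volume growth anisotropically across axes and their
  # heterogeneity drifts upward to the follow-up amplitude. Any single
  # timepoint is uninformative by construction.
  draw_common <- function() {
    list(radii_f = runif(3, 4.5, 7.5),
         sd_followup = runif(1, 20, 40),
         interval = runif(1, 30, 180),
         gv = runif(1, 0.0015, 0.009),  # volume growth rate, 1/day
         translation = runif(3, -motion_mm, motion_mm))
  }
  make_spec <- function(cm, g_axes, sd_b, drift, seed) {
    phantom_spec(radii_mm = cm$radii_f * exp(-g_axes * cm$interval),
                 growth_rates_per_day = g_axes,
                 texture_sd_hu = sd_b, heterogeneity_drift_per_day = drift,
                 motion = list(translation_mm = cm$translation,
                               rotation_deg = c(0, 0, 0)),
                 noise_sd_hu = noise_sd_hu, interval_days = cm$interval,
                 seed = seed)
  }
  list(
    negative = function(seed) {
      set.seed(seed)
      cm <- draw_common()
      make_spec(cm, rep(cm$gv / 3, 3), cm$sd_followup, 0, seed)
    },
    positive = function(seed) {
      set.seed(seed)
      cm <- draw_common()
      w <- runif(3, 0.05, 1)
      g <- cm$gv * w / sum(w)           # anisotropic split of the same growth
      drift <- runif(1, 0.05, 0.15)
      sd_b <- max(5, cm$sd_followup - drift * cm$interval)
      drift <- (cm$sd_followup - sd_b) / cm$interval
      make_spec(cm, g, sd_b, drift, seed)
    }
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws `n` subjects with exactly `round(n * prevalence)` positives, using
#' per-class spec recipes; per-subject seeds are derived reproducibly from the
#' master seed so the cohort is bit-reproducible.
#'
#' @param n number of subjects (>= 2).
#' @param class_recipes list of functions `positive(seed)` / `negative(seed)`
#'   returning [phantom_spec()] objects; see [default_class_recipes()].
#' @param prevalence fraction of positive subjects in (0, 1); default mirrors a
#'   typical STAS cohort prevalence of 24.4%.
#' @param seed master RNG seed.
#' @return list of `phantom_pair` objects; each carries `subject_id` and
#'   `label` (1 = positive).
#' @export
generate_cohort <- function(n, class_recipes = default_class_recipes(),
                            prevalence = 0.244, seed = 1L) {
  if (n < 2) stop("n must be at least 2")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  n_pos <- round(n * prevalence)
  set.seed(derive_seed(seed, 2L))
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  lapply(seq_len(n), function(i) {
    sseed <- derive_seed(seed, 10L + i)
    recipe <- if (labels[i] == 1L) class_recipes$positive else class_recipes$negative
    pair <- generate_pair(recipe(sseed), label = labels[i])
    pair$subject_id <- sprintf("S%03d", i)
    pair
  })
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' @param cohort list of `phantom_pair` objects from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest data frame (subject id, file paths, t_b and
#'   t_f in days, label).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    id <- p$subject_id %||% "S000"
    paths <- file.path(dir, paste0(id, c("_baseline.nii.gz", "_followup.nii.gz",
                                         "_baseline_mask.nii.gz", "_followup_mask.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(p$baseline_volume, pixdim = p$spacing_mm), paths[1])
    RNifti::writeNifti(RNifti::asNifti(p$followup_volume, pixdim = p$spacing_mm), paths[2])
    RNifti::writeNifti(RNifti::asNifti(p$baseline_mask * 1L, pixdim = p$spacing_mm), paths[3])
    RNifti::writeNifti(RNifti::asNifti(p$followup_mask * 1L, pixdim = p$spacing_mm), paths[4])
    data.frame(subject_id = id, baseline = paths[1], followup = paths[2],
               baseline_mask = paths[3], followup_mask = paths[4],
               t_baseline_days = p$times_days[1], t_followup_days = p$times_days[2],
               label = p$label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
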