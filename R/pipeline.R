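#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param out_dir run directory for tables, models and reports.
#' @param input_manifest path to a cohort manifest CSV (see [write_cohort()]);
#'   `NULL` simulates a phantom cohort instead.
#' @param n_subjects,prevalence simulated cohort size and positive fraction
#'   (used when `input_manifest` is `NULL`).
#' @param seed master seed; every stage derives its randomness from it.
#' @param stages character subset of
#'   `c("classic", "delta", "deltadl")` — which feature blocks to build.
#' @param registration_method,fallback_threshold view registration settings.
#' @param icc_threshold reproducibility gate (applied only when rater
#'   simulations are enabled via `n_raters > 1`).
#' @param n_raters,n_repeats simulated delineations for the ICC stage
#'   (1/1 disables it).
#' @param wavelet extract wavelet features (TRUE gives the 851-feature
#'   inventory per region/timepoint).
#' @param selector,classifier registry entry names for the final model
#'   (defaults mirror the LASSO + linear-SVM optimum).
#' @param folds,replications cross-validation scheme.
#' @param interval_group optional `"A"`, `"B"` or `"C"` cohort filter by
#'   follow-up interval.
#' @param cnn_epochs delta-DL training epochs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("dualdelta_run_"),
                            input_manifest = NULL, n_subjects = 40,
                            prevalence = 0.244, seed = 1L,
                            stages = c("classic", "delta", "deltadl"),
                            registration_method = "monomodal_intensity",
                            fallback_threshold = 0.5, icc_threshold = 0.75,
                            n_raters = 1L, n_repeats = 1L, wavelet = TRUE,
                            selector = "enet_a0.5_min",
                            classifier = "svm_linear_c1", folds = 5,
                            replications = 5, interval_group = NULL,
                            cnn_epochs = 15L) {
  cfg <- as.list(environment())
  if (!length(stages)) stop("pipeline_config: at least one stage must be enabled")
  bad <- setdiff(stages, c("classic", "delta", "deltadl"))
  if (length(bad)) stop("pipeline_config: unknown stages: ", paste(bad, collapse = ", "))
  if (!is.null(interval_group) && !interval_group %in% c("A", "B", "C"))
    stop("pipeline_config: interval_group must be A, B or C")
  structure(cfg, class = "pipeline_config")
}

#' Extract the four per-cohort feature blocks
#'
#' For every subject: refine/accept the masks, derive the 3 mm peritumoral
#' ring, extract the radiomics inventory for both regions at both timepoints,
#' and compute the time-slope delta block. Classic blocks are the follow-up
#' scan's features.
#'
#' @param cohort list of `phantom_pair`-like objects.
#' @param config a [radiomics_config()].
#' @param ring_mm peritumoral ring width (mm).
#' @return list of matrices `classic_intra`, `classic_peri`, `delta_intra`,
#'   `delta_peri` (subjects x features) plus `interval_days`.
#' @export
cohort_feature_tables <- function(cohort, config = radiomics_config(), ring_mm = 3) {
  ids <- vapply(seq_along(cohort), function(i)
    cohort[[i]]$subject_id %||% sprintf("S%03d", i), character(1))
  one <- function(p) {
    sp <- p$spacing_mm
    mb <- region_mask(p$baseline_mask, sp)
    mf <- region_mask(p$followup_mask, sp)
    rb <- peritumoral_ring(mb, ring_mm)
    rf <- peritumoral_ring(mf, ring_mm)
    fb_i <- extract_features(p$baseline_volume, mb, config)
    ff_i <- extract_features(p$followup_volume, mf, config)
    fb_p <- extract_features(p$baseline_volume, rb, config)
    ff_p <- extract_features(p$followup_volume, rf, config)
    dt <- p$times_days
    list(ci = ff_i, cp = ff_p,
         di = delta_slope(fb_i, ff_i, dt[1], dt[2]),
         dp = delta_slope(fb_p, ff_p, dt[1], dt[2]),
         interval = dt[2] - dt[1])
  }
  res <- lapply(cohort, one)
  bind <- function(fld) {
    m <- do.call(rbind, lapply(res, function(r) as.numeric(r[[fld]])))
    colnames(m) <- names(res[[1]][[fld]])
    rownames(m) <- ids
    m
  }
  list(classic_intra = bind("ci"), classic_peri = bind("cp"),
       delta_intra = bind("di"), delta_peri = bind("dp"),
       interval_days = vapply(res, `[[`, numeric(1), "interval"))
}

#' Delta-image sets and deep features for a cohort
#'
#' Builds the per-subject delta images, trains the feature CNN on a held-out
#' training half (so downstream cross-validation of the deep features is not
#' trained on its own test subjects), and extracts the 30 delta-DL features
#' for every subject.
#'
#' @param cohort list of pairs with labels.
#' @param method,fallback_threshold registration settings.
#' @param input_size CNN input side.
#' @param epochs,seed training settings.
#' @return list: `features` (subjects x 30 matrix), `net`, `curves`,
#'   `dsets` (delta-image sets), `train_idx`.
#' @export
cohort_deep_features <- function(cohort, method = "monomodal_intensity",
                                 fallback_threshold = 0.5, input_size = 64L,
                                 epochs = 15L, seed = 1L) {
  dsets <- lapply(cohort, delta_image_set, method = method,
                  fallback_threshold = fallback_threshold,
                  out_size = c(input_size, input_size))
  labels <- vapply(cohort, function(p) as.integer(p$label), integer(1))
  set.seed(derive_seed(seed, 77L))
  train_idx <- sort(unlist(lapply(split(seq_along(labels), labels), function(ix)
    sample(ix, ceiling(length(ix) / 2)))))
  imgs <- list(); tags <- numeric(0); ys <- integer(0)
  for (i in train_idx) {
    for (a in c("x", "y", "z")) {
      imgs[[length(imgs) + 1]] <- dsets[[i]]$images[[a]]
      tags <- c(tags, view_tag_value(a))
      ys <- c(ys, labels[i])
    }
  }
  net <- build_feature_cnn(network_spec(input_size = input_size),
                           seed = derive_seed(seed, 78L))
  tr <- train_cnn(net, imgs, tags, ys, epochs = epochs,
                  seed = derive_seed(seed, 79L))
  feats <- do.call(rbind, lapply(dsets, function(d) extract_deep_features(tr$net, d)))
  rownames(feats) <- vapply(seq_along(cohort), function(i)
    cohort[[i]]$subject_id %||% sprintf("S%03d", i), character(1))
  list(features = feats, net = tr$net, curves = tr$curves, dsets = dsets,
       train_idx = train_idx)
}

#' Run the full dual-delta pipeline
#'
#' Simulate (or load) a cohort, build the enabled feature blocks, optionally
#' gate by ICC over simulated repeated delineations, train the delta-DL
#' network, and evaluate the configured selector/classifier by repeated
#' stratified cross-validation. All tables, curves and reports are written
#' under `config$out_dir` together with a manifest carrying the config hash
#' and seed; re-running with an identical config reproduces identical tables.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (overrides simulation/manifest).
#' @return list of class `pipeline_result`: `tables`, `labels`, `report`
#'   (final `evaluation_report`), `deep` (delta-DL artifacts or NULL),
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) {
    if (!is.null(config$input_manifest)) {
      cohort <- read_cohort(config$input_manifest)
    } else {
      cohort <- generate_cohort(config$n_subjects, prevalence = config$prevalence,
                                seed = config$seed)
    }
  }
  labels <- vapply(cohort, function(p) as.integer(p$label), integer(1))
  intervals <- vapply(cohort, function(p) diff(p$times_days), numeric(1))
  if (!is.null(config$interval_group)) {
    keep <- !is.na(group_by_interval(intervals)) &
      group_by_interval(intervals) == config$interval_group
    cohort <- cohort[keep]; labels <- labels[keep]; intervals <- intervals[keep]
    if (length(unique(labels)) < 2)
      stop("run_pipeline: interval-group filter removed a whole class")
  }
  rcfg <- radiomics_config(wavelet = config$wavelet)
  ft <- cohort_feature_tables(cohort, rcfg)
  blocks <- list(
    classic_intra = if ("classic" %in% config$stages) ft$classic_intra else NULL,
    classic_peri = if ("classic" %in% config$stages) ft$classic_peri else NULL,
    delta_intra = if ("delta" %in% config$stages) ft$delta_intra else NULL,
    delta_peri = if ("delta" %in% config$stages) ft$delta_peri else NULL)
  dual <- assemble_dual_table(blocks$classic_intra, blocks$classic_peri,
                              blocks$delta_intra, blocks$delta_peri)
  icc_report <- NULL
  if (config$n_raters > 1 || config$n_repeats > 1) {
    icc_report <- cohort_icc_report(cohort, rcfg, n_raters = max(2L, config$n_raters),
                                    n_repeats = max(2L, config$n_repeats),
                                    threshold = config$icc_threshold,
                                    seed = config$seed)
    keep_cols <- sub("^[a-z_]+\\.", "", colnames(dual)) %in%
      icc_report$feature[icc_report$pass]
    if (any(keep_cols)) dual <- dual[, keep_cols, drop = FALSE]
    write.csv(icc_report, file.path(config$out_dir, "icc_report.csv"),
              row.names = FALSE)
  }
  deep <- NULL
  if ("deltadl" %in% config$stages) {
    deep <- cohort_deep_features(cohort, method = config$registration_method,
                                 fallback_threshold = config$fallback_threshold,
                                 epochs = config$cnn_epochs, seed = config$seed)
    dual <- cbind(dual, deep$features)
    write.csv(deep$curves, file.path(config$out_dir, "training_curves.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, lapply(deep$dsets, `[[`, "log")),
              file.path(config$out_dir, "registration_log.csv"), row.names = FALSE)
  }
  write.csv(data.frame(subject_id = rownames(dual), label = labels,
                       interval_days = intervals),
            file.path(config$out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(as.data.frame(dual), file.path(config$out_dir, "dual_table.csv"))
  selectors <- default_selector_registry()
  classifiers <- default_classifier_registry()
  if (!config$selector %in% names(selectors))
    stop("run_pipeline: unknown selector ", config$selector)
  if (!config$classifier %in% names(classifiers))
    stop("run_pipeline: unknown classifier ", config$classifier)
  report <- crossval_auc(selectors[[config$selector]],
                         classifiers[[config$classifier]], dual, labels,
                         folds = config$folds, replications = config$replications,
                         seed = config$seed)
  manifest <- list(config_hash = object_hash(unclass(config)[setdiff(names(config), "out_dir")]),
                   seed = config$seed, n_subjects = length(cohort),
                   n_features = ncol(dual),
                   mean_auc = report$mean_auc, ci = report$ci,
                   package_version = as.character(utils::packageVersion("dualdelta")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(mean_auc = report$mean_auc, ci = report$ci,
                            auc = report$auc,
                            accuracy = report$confusion$accuracy,
                            sensitivity = report$confusion$sensitivity,
                            specificity = report$confusion$specificity),
                       file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(report$roc, file.path(config$out_dir, "roc_points.csv"), row.names = FALSE)
  structure(list(tables = c(blocks[!vapply(blocks, is.null, logical(1))],
                            list(dual = dual)),
                 labels = labels, report = report, deep = deep,
                 icc_report = icc_report, manifest = manifest,
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

# ICC report over simulated repeated delineations on a cohort subsample
# (follow-up scan, intratumoral region; delta features inherit the gate of
# their parent features by name)
cohort_icc_report <- function(cohort, rcfg, n_raters = 2L, n_repeats = 2L,
                              threshold = 0.75, seed = 1L, max_subjects = 12L) {
  sub <- cohort[seq_len(min(length(cohort), max_subjects))]
  per_subject <- lapply(seq_along(sub), function(i) {
    p <- sub[[i]]
    rat <- simulate_raters(p$followup_mask, n_raters, n_repeats,
                           spacing_mm = p$spacing_mm,
                           seed = derive_seed(seed, 500L + i))
    lapply(rat, function(rr) lapply(rr, function(m)
      extract_features(p$followup_volume, m, rcfg)))
  })
  fnames <- names(per_subject[[1]][[1]][[1]])
  arrs <- lapply(fnames, function(fn) {
    a <- array(0, c(length(sub), n_raters, n_repeats))
    for (i in seq_along(sub)) for (r in seq_len(n_raters)) for (k in seq_len(n_repeats))
      a[i, r, k] <- per_subject[[i]][[r]][[k]][[fn]]
    a
  })
  names(arrs) <- fnames
  compute_icc(arrs, threshold = threshold)
}

#' Read a cohort back from a manifest CSV
#'
#' @param manifest_path path to a `manifest.csv` written by [write_cohort()].
#' @return list of `phantom_pair`-like subjects.
#' @export
read_cohort <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    r <- man[i, ]
    b <- read_scan(r$baseline); f <- read_scan(r$followup)
    mb <- read_mask(r$baseline_mask); mf <- read_mask(r$followup_mask)
    structure(list(baseline_volume = b$volume, followup_volume = f$volume,
                   baseline_mask = mb$array, followup_mask = mf$array,
                   spacing_mm = b$spacing_mm,
                   times_days = c(r$t_baseline_days, r$t_followup_days),
                   label = r$label, subject_id = r$subject_id),
              class = "phantom_pair")
  })
}

#' Read a CT scan volume
#'
#' NIfTI files are read with HU values and spacing taken from the header; the
#' acquisition date comes from `date` (ISO string, typically supplied by a
#' cohort manifest to avoid anonymisation pitfalls). DICOM series directories
#' are not supported by this build and give an explicit error. Axis
#' convention: x = left-right, y = anterior-posterior, z = superior-inferior.
#'
#' @param path `.nii` / `.nii.gz` file.
#' @param date optional ISO-8601 acquisition date string.
#' @param require_date error when no date is available.
#' @return list: `volume` (3-D HU array), `spacing_mm`, `acquisition_date`
#'   (`NA` when absent and not required).
#' @export
read_scan <- function(path, date = NULL, require_date = FALSE) {
  if (dir.exists(path))
    stop("read_scan: DICOM series directories are not supported; ",
         "convert to NIfTI and supply dates via the manifest")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("read_scan: expected a 3-D volume")
  if (require_date && is.null(date))
    stop("read_scan: acquisition date required but not provided")
  list(volume = array(as.numeric(img), dim(img)),
       spacing_mm = RNifti::pixdim(img)[seq_len(3)],
       acquisition_date = date %||% NA_character_)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `dualdelta` Rscript
#' (`inst/cli/dualdelta.R`). Subcommands: `simulate` (write a phantom cohort
#' + manifest), `run` (full pipeline), and the stage shortcuts `extract`,
#' `delta`, `classify`, `evaluate` which run the pipeline with the matching
#' stage toggles.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `c("simulate", "--n", "10", "--out", "dir")`).
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dualdelta <simulate|run|extract|delta|classify|evaluate> [options]",
    "  simulate --n N --prevalence P --seed S --out DIR",
    "  run      --n N [--manifest CSV] --seed S --out DIR [--group A|B|C]",
    "           [--no-wavelet] [--stages classic,delta,deltadl]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out <- opt("--out", "dualdelta_out")
  seed <- as.integer(opt("--seed", "1"))
  n <- as.integer(opt("--n", "20"))
  if (cmd == "simulate") {
    coh <- generate_cohort(n, prevalence = as.numeric(opt("--prevalence", "0.244")),
                           seed = seed)
    man <- write_cohort(coh, out)
    message("wrote ", nrow(man), " subjects to ", out)
    return(invisible(0L))
  }
  if (cmd %in% c("run", "extract", "delta", "classify", "evaluate")) {
    stages <- switch(cmd,
                     extract = "classic",
                     delta = c("classic", "delta"),
                     strsplit(opt("--stages", "classic,delta,deltadl"), ",")[[1]])
    cfg <- pipeline_config(out_dir = out, input_manifest = opt("--manifest"),
                           n_subjects = n, seed = seed, stages = stages,
                           wavelet = !("--no-wavelet" %in% args),
                           interval_group = opt("--group"))
    res <- run_pipeline(cfg)
    message(sprintf("pipeline complete: %d subjects, %d features, mean CV AUC %.3f",
                    length(res$labels), ncol(res$tables$dual), res$report$mean_auc))
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd, "\n", usage)
  invisible(1L)
}
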