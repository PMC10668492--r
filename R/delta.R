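#' Time-slope delta-radiomics features
#'
#' The delta value of each feature is its slope over the follow-up interval,
#' `(I_followup - I_baseline) / (t_followup - t_baseline)`, in feature units
#' per day. Time is measured in days throughout the package.
#'
#' @param baseline,followup named numeric feature vectors with identical names.
#' @param t_b_days,t_f_days acquisition times in days, `t_f_days > t_b_days`.
#' @return named numeric vector of slopes with attribute `interval_days`.
#' @export
delta_slope <- function(baseline, followup, t_b_days, t_f_days) {
  if (t_f_days <= t_b_days) stop("delta_slope: t_followup must exceed t_baseline")
  nb <- names(baseline); nf <- names(followup)
  if (is.null(nb) || is.null(nf) || !identical(nb, nf))
    stop("delta_slope: feature names must match")
  out <- (as.numeric(followup) - as.numeric(baseline)) / (t_f_days - t_b_days)
  structure(stats::setNames(out, nb), interval_days = t_f_days - t_b_days)
}

#' Assemble the dual classic + delta feature table
#'
#' Binds the four feature blocks — classic intratumoral, classic peritumoral,
#' delta intratumoral, delta peritumoral — into one table with
#' block-disambiguated column names (prefixes `classic_intra.`,
#' `classic_peri.`, `delta_intra.`, `delta_peri.`). Classic blocks are the
#' follow-up (latest pre-surgical) scan's features. With the full 851-feature
#' inventory per block the table has 4 x 851 = 3404 columns; blocks may be
#' omitted via `NULL`.
#'
#' @param classic_intra,classic_peri,delta_intra,delta_peri numeric matrices
#'   (subjects x features) with identical, ordered row names (subject ids), or
#'   `NULL` to omit a block.
#' @return numeric matrix subjects x (851 per included block).
#' @export
assemble_dual_table <- function(classic_intra, classic_peri, delta_intra, delta_peri) {
  blocks <- list(classic_intra = classic_intra, classic_peri = classic_peri,
                 delta_intra = delta_intra, delta_peri = delta_peri)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (!length(blocks)) stop("assemble_dual_table: all blocks omitted")
  blocks <- lapply(blocks, as.matrix)
  ids <- rownames(blocks[[1]])
  for (b in blocks) {
    if (!identical(rownames(b), ids))
      stop("assemble_dual_table: subject ids differ between blocks")
  }
  out <- do.call(cbind, lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    colnames(b) <- paste0(nm, ".", colnames(b))
    b
  }))
  rownames(out) <- ids
  out
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from the
#' standard ANOVA mean-squares decomposition:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n subjects (rows) and k raters/repeats (columns). A table with zero
#' total variance (all measurements equal) is defined as ICC = 1 with a
#' warning, since agreement is perfect.
#'
#' @param m numeric matrix, subjects x raters (or repeats).
#' @return ICC estimate (may fall below 0 for discordant data).
#' @export
icc21 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("icc21: need >= 3 subjects and >= 2 measurements")
  if (stats::var(as.vector(m)) == 0) {
    warning("icc21: zero variance; ICC defined as 1")
    return(1)
  }
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Per-feature reproducibility report (intra- and inter-rater ICC)
#'
#' `measurements` is a 3-D array subjects x raters x repeats for a single
#' feature, or a named list of such arrays (one per feature). Intra-rater ICC
#' is computed per rater across repeats (and averaged over raters); inter-rater
#' ICC across raters using each rater's first repeat (or repeat means when
#' `use_repeat_means = TRUE`).
#'
#' @param measurements array `[subject, rater, repeat]` or named list thereof.
#' @param threshold pass threshold; a feature passes when **both** ICCs exceed
#'   it strictly (default 0.75).
#' @param use_repeat_means average repeats before the inter-rater ICC.
#' @return data frame of class `icc_report`: `feature`, `intra_icc`,
#'   `inter_icc`, `pass`.
#' @export
compute_icc <- function(measurements, threshold = 0.75, use_repeat_means = FALSE) {
  if (!is.list(measurements)) measurements <- list(feature = measurements)
  rows <- lapply(names(measurements), function(nm) {
    a <- measurements[[nm]]
    stopifnot(length(dim(a)) == 3)
    n_raters <- dim(a)[2]; n_rep <- dim(a)[3]
    intra <- if (n_rep >= 2) {
      mean(vapply(seq_len(n_raters), function(r)
        suppressWarnings(icc21(a[, r, ])), numeric(1)))
    } else NA_real_
    inter <- if (n_raters >= 2) {
      m <- if (use_repeat_means && n_rep > 1) apply(a, c(1, 2), mean) else a[, , 1]
      suppressWarnings(icc21(m))
    } else NA_real_
    data.frame(feature = nm, intra_icc = intra, inter_icc = inter,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  rep_df$pass <- with(rep_df,
                      (is.na(intra_icc) | intra_icc > threshold) &
                        (is.na(inter_icc) | inter_icc > threshold) &
                        !(is.na(intra_icc) & is.na(inter_icc)))
  class(rep_df) <- c("icc_report", "data.frame")
  attr(rep_df, "threshold") <- threshold
  rep_df
}

#' Filter a feature table by an ICC reproducibility report
#'
#' Retains exactly the columns whose report row passes at the threshold
#' (both ICCs strictly greater), preserving column order.
#'
#' @param table numeric matrix, samples x features.
#' @param report an `icc_report` from [compute_icc()] covering all columns.
#' @param threshold overrides the report's threshold if given.
#' @return the filtered matrix.
#' @export
icc_filter <- function(table, report, threshold = NULL) {
  x <- as.matrix(table)
  if (!all(colnames(x) %in% report$feature))
    stop("icc_filter: report does not cover all table columns")
  rep_idx <- match(colnames(x), report$feature)
  if (is.null(threshold)) {
    keep <- report$pass[rep_idx]
  } else {
    keep <- (is.na(report$intra_icc[rep_idx]) | report$intra_icc[rep_idx] > threshold) &
      (is.na(report$inter_icc[rep_idx]) | report$inter_icc[rep_idx] > threshold)
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stop("icc_filter: no feature survives the threshold (",
         sum(!keep), " filtered); inspect the ICC report")
  }
  x[, keep, drop = FALSE]
}
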