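# Correlation of per-methyl combined-shift trajectories with variant-level
# biochemical activities, summarized per covariance cluster.

#' Pearson correlation with domain guards
#'
#' Standard product-moment correlation; inputs must be equal-length vectors
#' of at least 3 points. A constant input makes the correlation undefined
#' and returns `NA` (reported as missing downstream).
#'
#' @param x,y Numeric vectors.
#' @return Correlation in \[-1, 1\], or `NA_real_` for constant input.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3) stop("need at least 3 points for a correlation")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Correlate shift trajectories with activities
#'
#' For every methyl, computes the Pearson correlation of its combined shift
#' across the variant panel against each activity column, the mean over the
#' three core activities (hydrolysis, dimerization, exonuclease), and a
#' "meaningful" flag at `|mean_RP| > threshold` (default 0.65; the
#' absolute-mean rule subsumes anticorrelated clusters). A one-sided
#' any-activity variant (`any |RP_core| > threshold`) is reported alongside.
#' Records with an undefined core correlation are flagged missing and
#' excluded from the meaningful gate (with a message). With a 4-variant
#' panel the correlations are descriptive; `n` is reported with every
#' record.
#'
#' @param st The panel `shift_table`.
#' @param activities Data.frame with a `variant` column plus numeric
#'   activity columns; must cover every panel variant. Core columns:
#'   `hydrolysis` (k_cat/K_M), `dimerization` (fraction dimer),
#'   `exonuclease` (relative fluorescence, +ATP condition).
#' @param clusters Optional `chesca_clustering` (or its `assignment`
#'   data.frame) to attach cluster ids.
#' @param threshold Gate on `|mean_RP|`, default 0.65.
#' @param core Names of the three core activity columns.
#' @return Data.frame with one row per methyl: `R_P_<activity>` columns,
#'   `mean_RP`, `meaningful`, `meaningful_any`, `cluster`, `n`.
#' @export
activity_correlations <- function(st, activities, clusters = NULL,
                                  threshold = 0.65,
                                  core = c("hydrolysis", "dimerization",
                                           "exonuclease")) {
  variants <- attr(st, "variants")
  if (!"variant" %in% names(activities))
    stop("activities table needs a 'variant' column")
  if (length(setdiff(variants, activities$variant)))
    stop("activities table missing variant(s): ",
         paste(setdiff(variants, activities$variant), collapse = ", "))
  missing_core <- setdiff(core, names(activities))
  if (length(missing_core))
    stop("activities table missing core column(s): ",
         paste(missing_core, collapse = ", "))
  act_cols <- setdiff(names(activities), "variant")
  act <- activities[match(variants, activities$variant), , drop = FALSE]
  m <- shift_matrix(st)
  out <- data.frame(methyl = rownames(m))
  for (a in act_cols)
    out[[paste0("R_P_", a)]] <- apply(m, 1, function(x) pearson(x, act[[a]]))
  core_rp <- as.matrix(out[paste0("R_P_", core)])
  out$mean_RP <- rowMeans(core_rp)
  out$meaningful <- ifelse(is.na(out$mean_RP), NA, abs(out$mean_RP) > threshold)
  out$meaningful_any <- ifelse(apply(is.na(core_rp), 1, any), NA,
                               apply(abs(core_rp) > threshold, 1, any))
  if (anyNA(out$mean_RP))
    message("activity_correlations: ", sum(is.na(out$mean_RP)),
            " record(s) with undefined core correlation marked missing")
  if (!is.null(clusters)) {
    asn <- if (inherits(clusters, "chesca_clustering")) clusters$assignment
           else clusters
    out$cluster <- asn$cluster[match(out$methyl, asn$methyl)]
  } else {
    out$cluster <- NA_integer_
  }
  out$n <- length(variants)
  rownames(out) <- NULL
  out
}

#' Per-cluster sign summary of activity correlations
#'
#' Counts, per covariance cluster, how many methyls pass the meaningful
#' gate and what fraction of those correlate positively vs. negatively with
#' activity -- the readout that distinguishes coherently coupled clusters.
#'
#' @param records Output of [activity_correlations()].
#' @return Data.frame with columns `cluster`, `n_methyls`, `n_meaningful`,
#'   `n_meaningful_any`, `frac_positive`, `frac_negative` (fractions of the
#'   meaningful set; `NaN` when no methyl is meaningful).
#' @export
cluster_sign_summary <- function(records) {
  key <- ifelse(is.na(records$cluster), "unclustered",
                as.character(records$cluster))
  groups <- split(records, key)
  rows <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    mf <- g$meaningful %in% TRUE
    data.frame(cluster = k,
               n_methyls = nrow(g),
               n_meaningful = sum(mf),
               n_meaningful_any = sum(g$meaningful_any %in% TRUE),
               frac_positive = if (any(mf)) mean(g$mean_RP[mf] > 0) else NaN,
               frac_negative = if (any(mf)) mean(g$mean_RP[mf] < 0) else NaN)
  })
  out <- do.call(rbind, rows)
  num <- suppressWarnings(as.numeric(out$cluster))
  out <- out[order(is.na(num), num), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue annotation export for structure colouring
#'
#' Flattens correlation records into a residue-level table (residue number,
#' meaningful flag, mean correlation) for colouring structures in external
#' viewers. Stereo pairs of the same residue are aggregated by the largest
#' `|mean_RP|`.
#'
#' @param records Output of [activity_correlations()].
#' @param st The `shift_table` (supplies residue numbers).
#' @return Data.frame with columns `residue_number`, `meaningful`,
#'   `mean_RP`.
#' @export
residue_annotation <- function(records, st) {
  res <- st$residue_number[match(records$methyl, st$methyl)]
  rows <- lapply(split(seq_len(nrow(records)), res), function(idx) {
    g <- records[idx, ]
    best <- which.max(abs(g$mean_RP))
    if (!length(best)) best <- 1L
    data.frame(residue_number = res[idx][1],
               meaningful = g$meaningful[best],
               mean_RP = g$mean_RP[best])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  out
}
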