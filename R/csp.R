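# Combined weighted methyl chemical shifts and MAD-based significance
# filtering across a mutant panel.

#' BMRB-derived combined-shift weights
#'
#' Per-class weights used to merge the 13C and 1H shifts of a methyl group
#' into one scalar, `delta_methyl = delta_C / w_C + delta_H / w_H`. The
#' defaults are the standard deviations of methyl 13C and 1H shifts in the
#' Biological Magnetic Resonance Data Bank:
#' w_C = (1.65, 1.60, 1.40, 1.54) and w_H = (0.29, 0.28, 0.27, 0.41) for
#' Ile delta1, Leu delta, Val gamma and Met epsilon respectively.
#'
#' @return A data.frame with columns `residue_class`, `w_C`, `w_H` (ppm).
#' @export
methyl_weights <- function() {
  data.frame(residue_class = c("Ile", "Leu", "Val", "Met"),
             w_C = c(1.65, 1.60, 1.40, 1.54),
             w_H = c(0.29, 0.28, 0.27, 0.41))
}

#' Combined weighted methyl chemical shift
#'
#' `delta_methyl = delta_C / w_C + delta_H / w_H`, in weighted-ppm units.
#' Vectorized over all arguments.
#'
#' @param delta_C 13C chemical shift(s), ppm.
#' @param delta_H 1H chemical shift(s), ppm.
#' @param residue_class Residue class per shift (`"Ile"`, `"Leu"`, `"Val"`,
#'   `"Met"`).
#' @param weights Weight table, default [methyl_weights()]. All weights must
#'   be positive.
#' @return Numeric vector of combined shifts.
#' @examples
#' combined_shift(10, 1, "Ile")  # 10/1.65 + 1/0.29
#' @export
combined_shift <- function(delta_C, delta_H, residue_class,
                           weights = methyl_weights()) {
  if (any(weights$w_C <= 0) || any(weights$w_H <= 0))
    stop("combined-shift weights must be positive")
  idx <- match(residue_class, weights$residue_class)
  if (anyNA(idx))
    stop("no combined-shift weights for class: ",
         paste(unique(residue_class[is.na(idx)]), collapse = ", "))
  delta_C / weights$w_C[idx] + delta_H / weights$w_H[idx]
}

#' Build the per-methyl, per-variant combined shift table
#'
#' The central object of the CSP / covariance-clustering / correlation
#' stages: one row per methyl, one numeric column per variant holding its
#' combined weighted shift.
#'
#' @param panel A `variant_panel` from [build_panel()].
#' @param weights Weight table, default [methyl_weights()].
#' @return A data.frame of class `shift_table` with identifier columns
#'   (`methyl`, `residue_number`, `residue_class`, `methyl_position`) and one
#'   column per variant; attributes `variants` and `reference_variant`.
#' @export
shift_table <- function(panel, weights = methyl_weights()) {
  stopifnot(inherits(panel, "variant_panel"))
  pk <- panel$peaks
  pk$delta_methyl <- combined_shift(pk$delta_C, pk$delta_H, pk$residue_class,
                                    weights)
  ids <- unique(pk[, c("methyl", "residue_number", "residue_class",
                       "methyl_position")])
  wide <- ids
  for (v in panel$variants) {
    sub <- pk[pk$variant == v, c("methyl", "delta_methyl")]
    wide[[v]] <- sub$delta_methyl[match(wide$methyl, sub$methyl)]
  }
  if (anyNA(wide[panel$variants]))
    stop("shift table incomplete: rebuild the panel with require_complete = TRUE")
  wide <- wide[order(wide$residue_number, wide$methyl_position), , drop = FALSE]
  rownames(wide) <- NULL
  structure(wide, variants = panel$variants,
            reference_variant = panel$reference_variant,
            class = c("shift_table", "data.frame"))
}

#' Extract the numeric shift matrix from a shift table
#'
#' @param st A `shift_table`.
#' @return Numeric matrix, rows named by methyl, columns by variant.
#' @export
shift_matrix <- function(st) {
  stopifnot(inherits(st, "shift_table"))
  m <- as.matrix(as.data.frame(st)[, attr(st, "variants"), drop = FALSE])
  rownames(m) <- st$methyl
  m
}

#' MAD modified Z-scores of per-methyl shift variation
#'
#' Flags methyls whose combined shift varies across the variant panel more
#' than typical. For each methyl the standard deviation `s_i` of its
#' `delta_methyl` values over variants is computed; with `m = median(s)` and
#' `MAD = median(|s - m|)`, the signed modified Z-score is
#' `z_i = 0.6745 (s_i - m) / MAD` (Iglewicz-Hoaglin convention). Only
#' larger-than-median variation exceeds positive thresholds. If `MAD = 0`
#' all scores are 0.
#'
#' @param st A `shift_table` with at least 4 methyls, each complete over at
#'   least 2 variants.
#' @param threshold Working significance gate on z, default 0.25.
#' @param tiers Additional reporting tiers, default `c(0.25, 1.5, 2.5)`
#'   (used for structure-colouring exports).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (n - 1).
#' @param consistency Consistency factor, default 0.6745 (set to 1 to drop
#'   it).
#' @param signed If `FALSE`, use `|s_i - m|` in the numerator (two-sided).
#' @return Data.frame with columns `methyl`, `stdev`, `z_score`,
#'   `range_ppm`, `significant` (z > threshold) and `tier` (highest tier
#'   exceeded, 0 if none).
#' @export
mad_zscores <- function(st, threshold = 0.25, tiers = c(0.25, 1.5, 2.5),
                        sd_type = c("population", "sample"),
                        consistency = 0.6745, signed = TRUE) {
  sd_type <- match.arg(sd_type)
  m <- shift_matrix(st)
  if (nrow(m) < 4)
    stop("need at least 4 methyls for a meaningful median/MAD")
  if (ncol(m) < 2) stop("need at least 2 variants to compute a stdev")
  s <- apply(m, 1, function(x) {
    mu <- mean(x)
    ss <- sum((x - mu)^2)
    sqrt(ss / if (sd_type == "population") length(x) else (length(x) - 1))
  })
  med <- median(s)
  mad_s <- median(abs(s - med))
  dev <- if (signed) s - med else abs(s - med)
  z <- if (mad_s == 0) rep(0, length(s)) else consistency * dev / mad_s
  rng <- apply(m, 1, function(x) max(x) - min(x))
  tier <- vapply(z, function(zi) {
    passed <- tiers[zi > tiers]
    if (length(passed)) max(passed) else 0
  }, numeric(1))
  data.frame(methyl = rownames(m), stdev = unname(s), z_score = unname(z),
             range_ppm = unname(rng), significant = unname(z > threshold),
             tier = unname(tier))
}

#' Per-methyl combined-shift range across the panel
#'
#' `max - min` of `delta_methyl` over variants, the quantity compared
#' against the 0.13 ppm gate in the dynamics classification.
#'
#' @param st A `shift_table`.
#' @return Named numeric vector (names = methyl labels).
#' @export
csp_range <- function(st) {
  m <- shift_matrix(st)
  apply(m, 1, function(x) max(x) - min(x))
}

#' Order variants along the shift trajectory
#'
#' Orders panel variants by how far their peaks have moved, on average, along
#' each significant methyl's shift direction -- the "general order of peaks"
#' used to sort activity bar charts. Per methyl, shifts are projected onto
#' the signed direction from the reference variant to its farthest variant;
#' variants are then ranked by the median projection over significant
#' methyls, reference first.
#'
#' @param st A `shift_table`.
#' @param significant Character vector of significant methyl labels (e.g.
#'   from [mad_zscores()]).
#' @return Character vector of variant labels, reference first.
#' @export
trajectory_order <- function(st, significant) {
  variants <- attr(st, "variants")
  ref <- attr(st, "reference_variant")
  m <- shift_matrix(st)
  significant <- intersect(significant, rownames(m))
  if (!length(significant)) stop("no significant methyls to order variants by")
  m <- m[significant, , drop = FALSE]
  proj <- t(apply(m, 1, function(x) {
    d <- x - x[ref]
    far <- which.max(abs(d))
    if (d[far] == 0) return(rep(NA_real_, length(x)))
    sign(d[far]) * d
  }))
  colnames(proj) <- colnames(m)
  if (all(is.na(proj))) {
    warning("all variants coincident; returning input order")
    return(variants)
  }
  med <- apply(proj, 2, median, na.rm = TRUE)
  ord <- names(sort(med[setdiff(variants, ref)]))
  c(ref, ord)
}
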