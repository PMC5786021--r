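# Biochemical observables: quadratic tight-binding isotherms, exact ternary
# competitive equilibria, Hill-Michaelis-Menten ATPase kinetics, phosphate
# standard-curve transforms, SEC dimer fractions, and exonuclease background
# correction.

#' Quadratic (tight-binding) isotherm
#'
#' Exact 1:1 binding signal when the fixed labelled species concentration is
#' comparable to `K_D`:
#' \deqn{F = F_0 + (F_{max}-F_0)\frac{(K_D+L+P) - \sqrt{(K_D+L+P)^2 - 4 L P}}{2L}}
#' with `P` the titrated species and `L` the fixed labelled species. The
#' model is monotone non-decreasing in `P` and bounded by `F_max`; `P = 0`
#' returns `F_0` exactly.
#'
#' @param P Titrated species concentration(s) (same units as `K_D`).
#' @param L Fixed labelled-species concentration.
#' @param K_D Dissociation constant.
#' @param F0,F_max Initial and final signal values.
#' @return Predicted signal(s).
#' @export
quadratic_binding <- function(P, L, K_D, F0, F_max) {
  stopifnot(L > 0, K_D > 0)
  b <- K_D + L + P
  disc <- pmax(b^2 - 4 * L * P, 0)
  frac <- (b - sqrt(disc)) / (2 * L)
  F0 + (F_max - F0) * frac
}

.half_point <- function(x, y) {
  # abscissa where y crosses halfway between its extremes; fit start heuristic
  yr <- (y - min(y)) / (max(y) - min(y))
  x[which.min(abs(yr - 0.5))]
}

#' Fit the quadratic binding isotherm
#'
#' Least-squares fit of signal vs. titrated-species concentration to
#' [quadratic_binding()], returning `K_D`, `F0`, `F_max` with covariance
#' uncertainties.
#'
#' @param conc Titrated species concentrations (>= 5 points).
#' @param signal Observed signal (polarization, FRET intensity, ...).
#' @param probe_conc Fixed labelled-species concentration, same units.
#' @return List of class `binding_fit` with elements `K_D`, `F0`, `F_max`,
#'   `K_D_err`, `F0_err`, `F_max_err`, `residual_rms`, `converged`.
#' @export
quadratic_binding_fit <- function(conc, signal, probe_conc) {
  stopifnot(length(conc) == length(signal))
  if (length(conc) < 5) stop("need at least 5 titration points")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  kd0 <- max(.half_point(conc, signal), probe_conc / 2, 1e-6)
  fit <- minpack.lm::nlsLM(
    signal ~ quadratic_binding(conc, probe_conc, K_D, F0, F_max),
    start = list(K_D = kd0, F0 = min(signal), F_max = max(signal)),
    lower = c(1e-12, -Inf, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(K_D = unname(est["K_D"]), F0 = unname(est["F0"]),
                 F_max = unname(est["F_max"]),
                 K_D_err = unname(se[1]), F0_err = unname(se[2]),
                 F_max_err = unname(se[3]),
                 residual_rms = sqrt(mean(resid(fit)^2)),
                 converged = isTRUE(fit$convInfo$isConv)),
            class = "binding_fit")
}

#' Exact ternary competitive-binding equilibrium
#'
#' Solves the free-protein concentration for one receptor binding a labelled
#' probe (`K_D`) and an unlabelled competitor (`K_I`) at the same site, from
#' the conservation relation
#' `P_t = P (1 + L_t/(K_D+P) + I_t/(K_I+P))`, which is monotone in free `P`.
#' The unique physical root is bracketed on `[0, P_t]` and polished by
#' Newton steps; all species concentrations are returned and satisfy their
#' conservation totals to near machine precision.
#'
#' @param P_total Total receptor concentration.
#' @param L_total Total labelled probe concentration.
#' @param I_total Total competitor concentration(s); vectorized.
#' @param K_D Probe dissociation constant.
#' @param K_I Competitor dissociation constant.
#' @return Data.frame with columns `I_total`, `P_free`, `L_free`, `I_free`,
#'   `PL`, `PI`, and `frac_probe_bound` (= PL / L_total).
#' @export
solve_competition <- function(P_total, L_total, I_total, K_D, K_I) {
  stopifnot(P_total >= 0, L_total >= 0, K_D > 0, K_I > 0, all(I_total >= 0))
  one <- function(It) {
    g <- function(P) P * (1 + L_total / (K_D + P) + It / (K_I + P)) - P_total
    if (P_total == 0) {
      P <- 0
    } else {
      P <- uniroot(g, c(0, P_total), tol = .Machine$double.eps)$root
      for (i in 1:3) { # Newton polish toward exact conservation
        gp <- 1 + L_total * K_D / (K_D + P)^2 + It * K_I / (K_I + P)^2
        P <- max(P - g(P) / gp, 0)
      }
    }
    PL <- P * L_total / (K_D + P)
    PI <- P * It / (K_I + P)
    c(P_free = P, L_free = L_total - PL, I_free = It - PI, PL = PL, PI = PI)
  }
  res <- t(vapply(I_total, one, numeric(5)))
  out <- data.frame(I_total = I_total, res)
  out$frac_probe_bound <- if (L_total > 0) out$PL / L_total else NA_real_
  out
}

#' Competition displacement signal model
#'
#' Predicted polarization of the labelled probe as competitor is titrated:
#' `F = F0 + (F_max - F0) * frac_probe_bound` with the bound fraction from
#' [solve_competition()]. At zero competitor this equals the no-competitor
#' quadratic isotherm.
#'
#' @inheritParams solve_competition
#' @param F0,F_max Signal of fully free / fully bound probe.
#' @return Predicted signal(s), vectorized over `I_total`.
#' @export
competition_signal <- function(I_total, P_total, L_total, K_D, K_I, F0, F_max) {
  eq <- solve_competition(P_total, L_total, I_total, K_D, K_I)
  F0 + (F_max - F0) * eq$frac_probe_bound
}

#' Fit the competitor dissociation constant K_I
#'
#' Fits displacement titration data (signal vs. unlabelled competitor
#' concentration) to the exact ternary equilibrium, with the probe `K_D`,
#' probe and protein concentrations fixed from a prior
#' [quadratic_binding_fit()]. By default the probe's `F0` / `F_max` are also
#' held fixed; set `fit_baseline = TRUE` to refloat them.
#'
#' @param conc Competitor concentrations.
#' @param signal Observed signal.
#' @param probe_K_D Probe dissociation constant (fixed).
#' @param probe_conc Total labelled probe concentration.
#' @param protein_conc Total receptor concentration.
#' @param F0,F_max Free / bound probe signal (fixed unless `fit_baseline`).
#' @param fit_baseline Also fit `F0` and `F_max` (default `FALSE`).
#' @return List of class `competition_fit`: `K_I`, `K_I_err`, `F0`, `F_max`,
#'   `residual_rms`, `converged`.
#' @export
competition_fit <- function(conc, signal, probe_K_D, probe_conc, protein_conc,
                            F0, F_max, fit_baseline = FALSE) {
  stopifnot(length(conc) == length(signal))
  if (length(conc) < 4) stop("need at least 4 displacement points")
  ki0 <- max(.half_point(conc, signal) / 10, 1e-6)
  if (fit_baseline) {
    fit <- minpack.lm::nlsLM(
      signal ~ competition_signal(conc, protein_conc, probe_conc, probe_K_D,
                                  K_I, F0, F_max),
      start = list(K_I = ki0, F0 = min(signal), F_max = max(signal)),
      lower = c(1e-12, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      signal ~ competition_signal(conc, protein_conc, probe_conc, probe_K_D,
                                  K_I, F0, F_max),
      start = list(K_I = ki0), lower = 1e-12,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  structure(list(K_I = unname(est["K_I"]), K_I_err = unname(se[1]),
                 F0 = if (fit_baseline) unname(est["F0"]) else F0,
                 F_max = if (fit_baseline) unname(est["F_max"]) else F_max,
                 residual_rms = sqrt(mean(resid(fit)^2)),
                 converged = isTRUE(fit$convInfo$isConv)),
            class = "competition_fit")
}

#' Hill-Michaelis-Menten rate law
#'
#' `v0 = V_max * S^n / (K_M^n + S^n)`; `n = 1` reduces to plain
#' Michaelis-Menten, and `S = K_M` gives `V_max / 2` for any `n`.
#'
#' @param S Substrate concentration(s).
#' @param V_max Maximal rate.
#' @param K_M Michaelis constant (same units as `S`).
#' @param n Hill coefficient.
#' @return Initial rate(s).
#' @export
hill_mm <- function(S, V_max, K_M, n = 1) {
  stopifnot(K_M > 0, n > 0)
  Sn <- ifelse(S == 0, 0, S^n)
  V_max * Sn / (K_M^n + Sn)
}

#' Fit Hill-Michaelis-Menten kinetics
#'
#' Least-squares fit of initial rates vs. substrate concentration to
#' [hill_mm()], optionally with the Hill coefficient fixed. When the enzyme
#' concentration and reaction volume are supplied, the turnover number is
#' reported as `k_cat = V_max / (enzyme nmol)` in 1/min (with `V_max` in
#' nmol/min and enzyme nmol = `enzyme_conc_uM * volume_ul / 1000`).
#'
#' @param atp_conc Substrate concentrations (uM), >= 5 points spanning low
#'   to near-saturating.
#' @param v0 Initial rates (nmol/min).
#' @param enzyme_conc_uM Optional enzyme concentration (uM).
#' @param volume_ul Reaction volume (uL), default 60.
#' @param fix_n Fix the Hill coefficient to this value (e.g. 1); default
#'   `NULL` (free).
#' @return List of class `kinetics_fit`: `V_max`, `K_M`, `n`, `k_cat`,
#'   errors, `residual_rms`, `converged`.
#' @export
mm_hill_fit <- function(atp_conc, v0, enzyme_conc_uM = NULL, volume_ul = 60,
                        fix_n = NULL) {
  stopifnot(length(atp_conc) == length(v0))
  if (length(atp_conc) < 5) stop("need at least 5 substrate concentrations")
  if (all(v0 == 0)) stop("all-zero rates; nothing to fit")
  vmax0 <- max(v0)
  km0 <- max(.half_point(atp_conc, v0), 1e-6)
  if (is.null(fix_n)) {
    fit <- minpack.lm::nlsLM(
      v0 ~ hill_mm(atp_conc, V_max, K_M, n),
      start = list(V_max = vmax0, K_M = km0, n = 1),
      lower = c(1e-12, 1e-12, 1e-3), upper = c(Inf, Inf, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    n_fixed <- fix_n
    fit <- minpack.lm::nlsLM(
      v0 ~ hill_mm(atp_conc, V_max, K_M, n_fixed),
      start = list(V_max = vmax0, K_M = km0),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  n_hat <- if (is.null(fix_n)) unname(est["n"]) else fix_n
  n_err <- if (is.null(fix_n)) unname(se[3]) else 0
  k_cat <- if (is.null(enzyme_conc_uM)) NA_real_ else
    unname(est["V_max"]) / (enzyme_conc_uM * volume_ul / 1000)
  structure(list(V_max = unname(est["V_max"]), K_M = unname(est["K_M"]),
                 n = n_hat, k_cat = k_cat,
                 V_max_err = unname(se[1]), K_M_err = unname(se[2]),
                 n_err = n_err,
                 residual_rms = sqrt(mean(resid(fit)^2)),
                 converged = isTRUE(fit$convInfo$isConv)),
            class = "kinetics_fit")
}

#' Transform raw absorbances into phosphate release rates
#'
#' Maps blank-subtracted A640 readings through a linear phosphate standard
#' curve and divides by the incubation time to obtain initial rates in nmol
#' PO4 / min. Corrected absorbances below the curve range are clipped to 0
#' with a warning.
#'
#' @param A640 Raw absorbances for the reactions.
#' @param blank Matched substrate-only absorbances (ATP degradation /
#'   phosphate contamination control), recycled if length 1.
#' @param standard_nmol,standard_A640 The phosphate standard curve (>= 3
#'   points, monotone increasing).
#' @param time_min Incubation time in minutes, default 60.
#' @return Numeric vector of rates `v0` (nmol/min).
#' @export
po4_transform <- function(A640, blank, standard_nmol, standard_A640,
                          time_min = 60) {
  stopifnot(length(standard_nmol) == length(standard_A640), time_min > 0)
  if (length(standard_nmol) < 3) stop("standard curve needs >= 3 points")
  o <- order(standard_nmol)
  if (is.unsorted(standard_A640[o], strictly = TRUE))
    stop("standard curve must be monotone increasing")
  cal <- lm(standard_A640 ~ standard_nmol)
  slope <- coef(cal)[["standard_nmol"]]
  icept <- coef(cal)[["(Intercept)"]]
  corrected <- A640 - blank
  nmol <- (corrected - icept) / slope
  below <- nmol < -1e-9 * max(abs(standard_nmol))  # beyond float noise
  if (any(below))
    warning(sum(below), " corrected absorbance(s) below standard curve ",
            "range; clipped to 0")
  pmax(nmol, 0) / time_min
}

#' Dimer fraction from a size-exclusion chromatogram
#'
#' Box-sum (rectangle-rule) integration of the absorbance trace inside fixed
#' monomer and dimer elution windows;
#' `fraction_dimer = dimer area / (monomer area + dimer area)`.
#'
#' @param volume Elution volumes (mL), increasing.
#' @param absorbance Absorbance trace (a.u.), same length.
#' @param monomer_window,dimer_window Length-2 numeric `c(lo, hi)` elution
#'   windows (mL); must be disjoint and within the elution range.
#' @return List of class `dimer_result`: `fraction_dimer`, `area_monomer`,
#'   `area_dimer`.
#' @export
dimer_fraction <- function(volume, absorbance, monomer_window, dimer_window) {
  stopifnot(length(volume) == length(absorbance),
            length(monomer_window) == 2, length(dimer_window) == 2)
  if (is.unsorted(volume, strictly = TRUE)) stop("volumes must be increasing")
  if (max(monomer_window[1], dimer_window[1]) <
      min(monomer_window[2], dimer_window[2]))
    stop("monomer and dimer windows must be disjoint")
  rng <- range(volume)
  if (min(monomer_window, dimer_window) < rng[1] ||
      max(monomer_window, dimer_window) > rng[2])
    stop("integration windows outside the elution range")
  dv <- c(diff(volume), diff(volume)[length(volume) - 1])
  box <- function(w) {
    sel <- volume >= w[1] & volume <= w[2]
    if (!any(sel)) stop("empty integration window [", w[1], ", ", w[2], "]")
    sum(absorbance[sel] * dv[sel])
  }
  a_m <- box(monomer_window)
  a_d <- box(dimer_window)
  if (a_m + a_d <= 0) stop("zero total peak area; cannot form a fraction")
  structure(list(fraction_dimer = a_d / (a_m + a_d),
                 area_monomer = a_m, area_dimer = a_d),
            class = "dimer_result")
}

#' Background-correct exonuclease fluorescence
#'
#' Subtracts the no-cofactor/no-nucleotide background signal from raw
#' relative fluorescence readings; negative corrected values are flagged
#' with a warning.
#'
#' @param raw_rfu Raw relative fluorescence unit readings.
#' @param background_rfu Background readings (recycled if length 1).
#' @return Corrected relative fluorescence, elementwise `raw - background`.
#' @export
exo_correct <- function(raw_rfu, background_rfu) {
  out <- raw_rfu - background_rfu
  if (any(out < 0))
    warning(sum(out < 0), " corrected fluorescence value(s) negative")
  out
}
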