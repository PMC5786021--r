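# Methyl 1H triple-quantum "forbidden" build-up analysis: the ratio model,
# nonlinear fitting of eta (intra-methyl 1H-1H dipolar cross-correlated
# relaxation rate), conversion to side-chain order parameters, and the
# shift/dynamics classification rules.

#' Default triple-quantum relaxation delays
#'
#' The relaxation delay grid used throughout: 2, 4, 7, 12, 17, 22, 27, 32,
#' 37 and 42 ms, returned in seconds.
#'
#' @return Numeric vector of delays (s).
#' @export
default_tq_delays <- function() {
  c(2, 4, 7, 12, 17, 22, 27, 32, 37, 42) * 1e-3
}

#' Triple-quantum build-up ratio model
#'
#' The expected `|I_forbid / I_allow|` intensity ratio at relaxation delay
#' `T`:
#' \deqn{C \eta \tanh(\sqrt{\eta^2+\delta^2} T) /
#'       (\sqrt{\eta^2+\delta^2} - \delta \tanh(\sqrt{\eta^2+\delta^2} T))}
#' where `eta` is the cross-correlated relaxation rate and `delta` accounts
#' for relaxation from external protons. The `eta = delta = 0` limit is 0 by
#' continuity. Monotone increasing in `T` and in `eta`.
#'
#' @param T Relaxation delay(s), seconds (>= 0).
#' @param eta Cross-correlated relaxation rate, 1/s.
#' @param delta External-proton relaxation rate, 1/s.
#' @param C Scaling constant, default 0.75.
#' @return Predicted ratio(s), dimensionless.
#' @export
tq_ratio_model <- function(T, eta, delta = 0, C = 0.75) {
  stopifnot(all(T >= 0))
  s <- sqrt(eta^2 + delta^2)
  if (s == 0) return(rep(0, length(T)))
  th <- tanh(s * T)
  C * eta * th / (s - delta * th)
}

#' Fit a triple-quantum build-up curve
#'
#' Bounded Levenberg-Marquardt least squares of the ratio data against
#' [tq_ratio_model()], with `eta >= 0` and `delta >= 0`. The starting `eta`
#' comes from the early-time slope (`ratio ~ C * eta * T` for small `T`);
#' starting `delta` is 1/s. Parameter uncertainties are taken from the
#' covariance matrix of the fit. When per-point uncertainties are supplied
#' the fit is weighted by `1 / ratio_error^2`.
#'
#' @param delays Relaxation delays, seconds (>= 4 points).
#' @param ratio Observed `|I_forbid / I_allow|` values.
#' @param ratio_error Optional per-point uncertainties.
#' @param C Scaling constant, default 0.75.
#' @return An object of class `eta_fit`: list with `eta`, `delta_ext`,
#'   `eta_err`, `delta_err` (1/s), `residual_rms`, `converged` and
#'   `degenerate` (all-zero data), plus `message` diagnostics on failure.
#' @export
fit_buildup <- function(delays, ratio, ratio_error = NULL, C = 0.75) {
  stopifnot(length(delays) == length(ratio))
  if (length(delays) < 4) stop("need at least 4 delay points")
  if (is.unsorted(delays, strictly = TRUE) || any(delays <= 0))
    stop("delays must be strictly positive and increasing")
  if (all(abs(ratio) < 1e-12)) {
    return(structure(list(eta = 0, delta_ext = 0, eta_err = NA_real_,
                          delta_err = NA_real_, residual_rms = 0,
                          converged = FALSE, degenerate = TRUE,
                          message = "all-zero ratios; eta -> 0"),
                     class = "eta_fit"))
  }
  k <- seq_len(min(3L, length(delays)))
  eta0 <- max(sum(ratio[k] * delays[k]) / sum(delays[k]^2) / C, 1e-2)
  # a short ladder of starts guards against singular gradients when the
  # build-up is saturated (large eta) or delta sits on its zero bound
  starts <- list(c(eta0, 1), c(eta0, 5), c(0.8 * eta0, 0.2), c(30, 1))
  fit <- NULL
  for (s0 in starts) {
    args <- list(
      ratio ~ tq_ratio_model(delays, eta, delta, C),
      start = list(eta = s0[1], delta = s0[2]),
      lower = c(0, 0), upper = c(1e3, 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(ratio_error)) args$weights <- 1 / ratio_error^2
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    # delta on its zero bound starves the numeric gradient; refit with the
    # external-proton term pinned at 0
    args0 <- list(
      ratio ~ tq_ratio_model(delays, eta, 0, C),
      start = list(eta = eta0), lower = 0, upper = 1e3,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(ratio_error)) args0$weights <- 1 / ratio_error^2
    fit0 <- tryCatch(do.call(minpack.lm::nlsLM, args0), error = function(e) e)
    if (inherits(fit0, "error")) {
      return(structure(list(eta = NA_real_, delta_ext = NA_real_,
                            eta_err = NA_real_, delta_err = NA_real_,
                            residual_rms = NA_real_, converged = FALSE,
                            degenerate = FALSE,
                            message = conditionMessage(fit)),
                       class = "eta_fit"))
    }
    se0 <- tryCatch(sqrt(diag(vcov(fit0))), error = function(e) NA_real_)
    return(structure(list(eta = unname(coef(fit0)["eta"]), delta_ext = 0,
                          eta_err = unname(se0[1]), delta_err = NA_real_,
                          residual_rms = sqrt(mean(resid(fit0)^2)),
                          converged = isTRUE(fit0$convInfo$isConv),
                          degenerate = FALSE,
                          message = "delta pinned at zero bound"),
                     class = "eta_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(list(eta = unname(est["eta"]), delta_ext = unname(est["delta"]),
                 eta_err = unname(se[1]), delta_err = unname(se[2]),
                 residual_rms = sqrt(mean(resid(fit)^2)),
                 converged = isTRUE(fit$convInfo$isConv),
                 degenerate = FALSE,
                 message = fit$convInfo$stopMessage),
            class = "eta_fit")
}

#' @export
print.eta_fit <- function(x, ...) {
  cat(sprintf("eta = %.3f +/- %.3f 1/s, delta_ext = %.3f +/- %.3f 1/s (rms %.2g, %s)\n",
              x$eta, x$eta_err, x$delta_ext, x$delta_err, x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a table of build-up curves
#'
#' Applies [fit_buildup()] per (methyl, variant) group of a long build-up
#' table. Ratios may be given directly (`ratio` column) or as intensities
#' (`I_forbid`, `I_allow`), in which case `|I_forbid / I_allow|` is used.
#'
#' @param buildup Data.frame with columns `methyl`, `variant`, `delay_s`,
#'   and either `ratio` or `I_forbid` + `I_allow` (optional `ratio_error`).
#' @param C Scaling constant, default 0.75.
#' @return Data.frame with one row per (methyl, variant): fitted parameters,
#'   uncertainties, rms and convergence flag.
#' @export
fit_buildup_table <- function(buildup, C = 0.75) {
  needed <- c("methyl", "variant", "delay_s")
  if (length(setdiff(needed, names(buildup))))
    stop("buildup table needs columns: ", paste(needed, collapse = ", "))
  if (!"ratio" %in% names(buildup)) {
    if (!all(c("I_forbid", "I_allow") %in% names(buildup)))
      stop("buildup table needs 'ratio' or 'I_forbid' + 'I_allow' columns")
    buildup$ratio <- abs(buildup$I_forbid / buildup$I_allow)
  }
  groups <- split(buildup, list(buildup$methyl, buildup$variant), drop = TRUE)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$delay_s), , drop = FALSE]
    f <- fit_buildup(g$delay_s, g$ratio, ratio_error = g$ratio_error, C = C)
    data.frame(methyl = g$methyl[1], variant = g$variant[1],
               eta = f$eta, delta_ext = f$delta_ext,
               eta_err = f$eta_err, delta_err = f$delta_err,
               residual_rms = f$residual_rms, converged = f$converged,
               degenerate = f$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intra-methyl 1H-1H dipolar cross-correlation constant
#'
#' The proportionality constant `k` in `eta = k * S2_axis * tau_c`,
#' assembled from physical constants:
#' `k = (9/10) * P2(cos theta)^2 * (mu0/4pi)^2 * gammaH^4 * hbar^2 / r_HH^6`
#' with the intra-methyl 1H-1H distance `r_HH = 1.813 Angstrom` and the
#' angle between the H-H vector and the methyl symmetry axis `theta = 90`
#' degrees (`P2 = -1/2`).
#'
#' @param r_hh Intra-methyl 1H-1H distance, metres. Default `1.813e-10`.
#' @param theta_deg Angle of the H-H vector to the methyl axis, degrees.
#' @return `k` in 1/s^2.
#' @export
methyl_hh_constant <- function(r_hh = 1.813e-10, theta_deg = 90) {
  mu0_4pi <- 1e-7            # T m / A
  gamma_h <- 2.6752218744e8  # rad / (s T)
  hbar <- 1.054571817e-34    # J s
  p2 <- 0.5 * (3 * cos(theta_deg * pi / 180)^2 - 1)
  (9 / 10) * p2^2 * mu0_4pi^2 * gamma_h^4 * hbar^2 / r_hh^6
}

#' Convert eta rates to methyl-axis order parameters
#'
#' `S2_axis = eta / (k * tau_c)`; a derived quantity that assumes isotropic
#' overall tumbling with correlation time `tau_c`. Values outside \[0, 1\]
#' are returned but flagged with a warning.
#'
#' @param eta Cross-correlated relaxation rate(s), 1/s.
#' @param tau_c Overall tumbling time, seconds (e.g. `30e-9`).
#' @param k Dipolar constant, default [methyl_hh_constant()].
#' @return `S2_axis` value(s), dimensionless.
#' @export
eta_to_s2 <- function(eta, tau_c, k = methyl_hh_constant()) {
  stopifnot(tau_c > 0, k > 0)
  s2 <- eta / (k * tau_c)
  if (any(s2 < 0 | s2 > 1, na.rm = TRUE))
    warning("S2_axis value(s) outside [0, 1]; check eta or tau_c")
  s2
}

#' Forward conversion from order parameter to eta
#'
#' @param s2 Methyl-axis order parameter(s).
#' @inheritParams eta_to_s2
#' @return `eta` in 1/s.
#' @export
s2_to_eta <- function(s2, tau_c, k = methyl_hh_constant()) {
  stopifnot(tau_c > 0, k > 0)
  k * s2 * tau_c
}

#' Classify methyls by shift-dynamics relationships
#'
#' Applies the classification rules for combining chemical shift
#' perturbation and dynamics data across the mutant panel. With `range` the
#' spread of `delta_methyl` over variants and `R_P` the Pearson correlation
#' of `eta` vs `delta_methyl`:
#' * `range > range_threshold` (0.13 ppm) and `|R_P| > r_threshold` (0.7):
#'   `"correlated_flexible"` if eta decreases upon mutation
#'   (`eta_WT > mean(eta_mutants)`, lower eta = more mobile), else
#'   `"correlated_rigid"`.
#' * `range < range_threshold` and `|eta_WT - mean(eta_mutants)| >
#'   delta_eta_threshold` (8 1/s): `"uncorrelated_flexible"` if
#'   `eta_WT > mean(eta_mutants)`, else `"uncorrelated_rigid"`.
#' * otherwise `"unchanged"`.
#'
#' Methyls missing an eta value for any panel variant are excluded with a
#' message.
#'
#' @param eta_table Data.frame with columns `methyl`, `variant`, `eta`
#'   (e.g. from [fit_buildup_table()]).
#' @param st The panel `shift_table`.
#' @param range_threshold Combined-shift range gate, ppm. Default 0.13.
#' @param r_threshold Correlation gate on `|R_P|`. Default 0.7.
#' @param delta_eta_threshold Gate on `|eta_WT - mean(eta_mutants)|`, 1/s.
#'   Default 8.
#' @return Data.frame with columns `methyl`, `range_ppm`, `R_P_eta_shift`,
#'   `delta_eta_wt_mut`, `category`.
#' @export
classify_dynamics <- function(eta_table, st, range_threshold = 0.13,
                              r_threshold = 0.7, delta_eta_threshold = 8) {
  variants <- attr(st, "variants")
  ref <- attr(st, "reference_variant")
  m <- shift_matrix(st)
  have <- vapply(split(eta_table$variant, eta_table$methyl),
                 function(v) all(variants %in% v), logical(1))
  usable <- intersect(rownames(m), names(have)[have])
  skipped <- setdiff(unique(eta_table$methyl), usable)
  if (length(skipped))
    message("classify_dynamics: excluded ", length(skipped),
            " methyl(s) with incomplete eta coverage")
  rows <- lapply(usable, function(mm) {
    sub <- eta_table[eta_table$methyl == mm, ]
    eta <- sub$eta[match(variants, sub$variant)]
    dm <- m[mm, variants]
    rng <- max(dm) - min(dm)
    rp <- if (sd(eta) == 0 || sd(dm) == 0) NA_real_ else cor(eta, dm)
    d_eta <- eta[variants == ref] - mean(eta[variants != ref])
    category <- if (rng > range_threshold && !is.na(rp) &&
                    abs(rp) > r_threshold) {
      if (d_eta > 0) "correlated_flexible" else "correlated_rigid"
    } else if (rng < range_threshold &&
               abs(d_eta) > delta_eta_threshold) {
      if (d_eta > 0) "uncorrelated_flexible" else "uncorrelated_rigid"
    } else "unchanged"
    data.frame(methyl = mm, range_ppm = rng, R_P_eta_shift = rp,
               delta_eta_wt_mut = d_eta, category = category)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
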