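# Synthetic-data generators. Every pipeline input can be produced from a
# two-state fast-exchange model with known ground truth, so parameter
# recovery is checkable end to end. All generators are pure functions of
# (parameters, seed).

.default_variants <- c("WT", "V156M", "V160M", "R805E")

# run code under a local RNG state so generators do not disturb the caller's.
# `seed` must be forced before the state snapshot: callers may compute it
# from the stream being snapshotted (e.g. seed = sample.int(...)).
.with_seed <- function(seed, code) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Two-state fast-exchange panel model
#'
#' Defines the ground truth for a synthetic mutant panel: each methyl has a
#' ground-state peak position and an excited-state offset, each variant an
#' excited-state population `p`, and the observed peak is the
#' population-weighted average plus Gaussian noise. Responder methyls are
#' organised in response groups; all members of a group share the group's
#' population vector (sign-coherent within the group), non-responders have
#' zero excited-state offset.
#'
#' The default design mirrors a realistic mutant-panel campaign: 4 variants
#' (WT, V156M, V160M, R805E), three responder groups of 25, 10 and 8
#' methyls plus 100 non-responders, group-1 populations (0, 0.2, 0.5, 0.9)
#' increasing along the panel, and per-dimension noise of 0.01 ppm (13C) /
#' 0.002 ppm (1H).
#'
#' Group geometry: for three groups to emerge as three distinct
#' complete-linkage clusters at a correlation-distance cut of 1.5, the three
#' response directions must be mutually anti-correlated at the extreme
#' admissible configuration r = -1/2 (three centered vectors cannot all be
#' pairwise more anti-correlated, since the variance of their sum is
#' non-negative). The default group-2 and group-3 population vectors are
#' therefore placed at 120 degrees from group 1 (and each other) in the
#' centered population space. In addition, each responder's effective
#' population vector is jittered around its group direction
#' (`member_jitter`), emulating methyls that sense slightly different
#' mixtures of several excited states; this member-level heterogeneity is
#' what pushes the empirical between-group complete-linkage separations
#' beyond the cut, as observed in real covariance dendrograms.
#'
#' @param n_groups Responder group sizes, default `c(25, 10, 8)`.
#' @param n_null Number of non-responders, default 100.
#' @param populations Matrix (groups x variants) of group excited-state
#'   population vectors in \[0, 1\]; default as described above.
#' @param member_jitter Sd of the member-level direction jitter (unit-less,
#'   relative to the unit group direction), default 0.12. Set to 0 to make
#'   every member share its group vector exactly.
#' @param noise_C,noise_H Gaussian noise sd per shift dimension, ppm.
#' @param seed Seed controlling the randomized model structure (residue
#'   identities, base shifts, offset magnitudes, member jitter).
#' @return List of class `two_state_model`: `methyls` (data.frame with
#'   ground-state shifts `dC0`, `dH0`, offsets `ddC`, `ddH` and `group`; 0 =
#'   non-responder), `populations` (group vectors), `member_populations`
#'   (n x variants matrix of effective per-methyl populations), `variants`,
#'   `noise_C`, `noise_H`.
#' @export
two_state_model <- function(n_groups = c(25, 10, 8), n_null = 100,
                            populations = NULL, member_jitter = 0.12,
                            noise_C = 0.01, noise_H = 0.002, seed = 1) {
  variants <- .default_variants
  if (is.null(populations)) {
    p1 <- c(0, 0.2, 0.5, 0.9)
    ctr <- mean(p1)
    g1c <- p1 - ctr
    e1 <- g1c / sqrt(sum(g1c^2))
    v2 <- c(1, -1, -0.5, 0.5)               # centered, orthogonal to g1c
    e2 <- v2 / sqrt(sum(v2^2))
    u2 <- -0.5 * e1 + sqrt(3) / 2 * e2      # 120 degrees from e1
    u3 <- -0.5 * e1 - sqrt(3) / 2 * e2
    populations <- rbind(p1, ctr + 0.45 * u2, ctr + 0.45 * u3)
    populations <- populations[seq_along(n_groups), , drop = FALSE]
  }
  stopifnot(nrow(populations) == length(n_groups),
            ncol(populations) == length(variants),
            all(populations >= 0 & populations <= 1))
  dimnames(populations) <- list(paste0("group", seq_along(n_groups)), variants)
  n <- sum(n_groups) + n_null
  .with_seed(seed, {
    classes <- sample(c("Ile", "Leu", "Val", "Met"), n, replace = TRUE,
                      prob = c(0.25, 0.4, 0.25, 0.1))
    pos <- vapply(classes, function(cl) switch(cl,
      Ile = "d1", Leu = sample(c("d1", "d2"), 1),
      Val = sample(c("g1", "g2"), 1), Met = "e"), character(1))
    resno <- sample(c(1:195, 709:882), n)  # construct numbering, unique
    base <- lapply(classes, function(cl) switch(cl,
      Ile = c(runif(1, 9, 15), runif(1, 0.4, 1.1)),
      Leu = c(runif(1, 21, 27), runif(1, 0.5, 1.1)),
      Val = c(runif(1, 18, 24), runif(1, 0.6, 1.2)),
      Met = c(runif(1, 14, 19), runif(1, 1.6, 2.2))))
    base <- do.call(rbind, base)
    group <- rep(c(seq_along(n_groups), 0), c(n_groups, n_null))
    # effective per-member population vectors: group direction + jitter
    member_pop <- matrix(0, n, length(variants),
                         dimnames = list(NULL, variants))
    for (i in which(group > 0)) {
      pg <- populations[group[i], ]
      pc <- pg - mean(pg)
      amp <- sqrt(sum(pc^2))
      if (amp < 1e-12 || member_jitter == 0) {
        member_pop[i, ] <- pg
      } else {
        z <- rnorm(length(pc))
        z <- z - mean(z)
        dir <- pc / amp + member_jitter * z
        dir <- dir / sqrt(sum(dir^2))
        member_pop[i, ] <- pmin(pmax(mean(pg) + amp * dir, 0), 1)
      }
    }
    w <- methyl_weights()
    wi <- match(classes, w$residue_class)
    # weighted-unit response magnitude, split across the two dimensions
    mag <- ifelse(group > 0, runif(n, 0.15, 0.6), 0)
    split_frac <- runif(n, 0.3, 0.7)
    ddC <- mag * split_frac * w$w_C[wi]
    ddH <- mag * (1 - split_frac) * w$w_H[wi]
    methyls <- data.frame(
      methyl = methyl_label(resno, classes, pos),
      residue_number = resno, residue_class = classes, methyl_position = pos,
      group = group, dC0 = base[, 1], dH0 = base[, 2], ddC = ddC, ddH = ddH)
  })
  rownames(member_pop) <- methyls$methyl
  structure(list(methyls = methyls, populations = populations,
                 member_populations = member_pop, variants = variants,
                 noise_C = noise_C, noise_H = noise_H),
            class = "two_state_model")
}

#' Generate a synthetic variant panel from a two-state model
#'
#' For every methyl and variant, the observed peak position is
#' `ground + p * offset + noise` in each shift dimension, where `p` is the
#' variant's excited-state population for the methyl's response group.
#' Identical seeds give bit-identical output.
#'
#' @param model A `two_state_model`.
#' @param seed Seed for the observation noise.
#' @return List with `panel` (a `variant_panel`) and `truth` (data.frame
#'   `methyl`, `group`, plus the model's population matrix as attribute
#'   `populations`).
#' @export
gen_panel <- function(model, seed = 1) {
  stopifnot(inherits(model, "two_state_model"))
  mm <- model$methyls
  peaks <- .with_seed(seed, {
    do.call(rbind, lapply(model$variants, function(v) {
      p <- ifelse(mm$group > 0, model$member_populations[, v], 0)
      data.frame(
        residue_number = mm$residue_number,
        residue_class = mm$residue_class,
        methyl_position = mm$methyl_position,
        variant = v,
        delta_C = mm$dC0 + p * mm$ddC + rnorm(nrow(mm), 0, model$noise_C),
        delta_H = mm$dH0 + p * mm$ddH + rnorm(nrow(mm), 0, model$noise_H))
    }))
  })
  panel <- build_panel(peaks, reference_variant = "WT",
                       require_complete = TRUE)
  truth <- data.frame(methyl = mm$methyl, group = mm$group)
  attr(truth, "populations") <- model$populations
  list(panel = panel, truth = truth)
}

#' Ground-truth side-chain dynamics for a panel model
#'
#' Generates per-methyl, per-variant true eta rates. Responder methyls get
#' eta affine in their group's population vector (slope of random sign), so
#' eta vs combined-shift correlations are planted by construction; a
#' fraction of non-responders get a WT-vs-mutant eta jump (the
#' uncorrelated-change categories), the rest are flat. External-proton
#' rates `delta_ext` are uniform on \[0, 8\] 1/s.
#'
#' @param model A `two_state_model`.
#' @param seed Seed.
#' @param eta_base_range Range of baseline eta, 1/s. Default `c(15, 55)`.
#' @param eta_slope_range Magnitude range of the population slope, 1/s.
#'   Default `c(10, 25)`.
#' @param frac_jump Fraction of non-responders given a WT-vs-mutant eta
#'   jump, default 0.1.
#' @param jump_range Magnitude range of that jump, 1/s. Default `c(10, 20)`.
#' @return Data.frame with columns `methyl`, `variant`, `eta`, `delta_ext`.
#' @export
gen_dynamics_truth <- function(model, seed = 1, eta_base_range = c(15, 55),
                               eta_slope_range = c(10, 25), frac_jump = 0.1,
                               jump_range = c(10, 20)) {
  stopifnot(inherits(model, "two_state_model"))
  mm <- model$methyls
  .with_seed(seed, {
    n <- nrow(mm)
    eta0 <- runif(n, eta_base_range[1], eta_base_range[2])
    slope <- sample(c(-1, 1), n, replace = TRUE) *
      runif(n, eta_slope_range[1], eta_slope_range[2])
    jump <- sample(c(-1, 1), n, replace = TRUE) *
      runif(n, jump_range[1], jump_range[2])
    has_jump <- mm$group == 0 & runif(n) < frac_jump
    delta_ext <- runif(n, 0, 8)
    do.call(rbind, lapply(model$variants, function(v) {
      p <- ifelse(mm$group > 0, model$member_populations[, v], 0)
      eta <- eta0 + ifelse(mm$group > 0, slope * p, 0) +
        ifelse(has_jump & v != "WT", jump, 0)
      data.frame(methyl = mm$methyl, variant = v,
                 eta = pmax(eta, 1), delta_ext = delta_ext)
    }))
  })
}

#' Generate triple-quantum build-up curves from dynamics ground truth
#'
#' Forward-evaluates [tq_ratio_model()] on a delay grid and applies
#' multiplicative Gaussian noise, `ratio * (1 + eps)`,
#' `eps ~ N(0, noise_frac)`. Identical seeds give bit-identical output.
#'
#' @param truth Data.frame from [gen_dynamics_truth()] (columns `methyl`,
#'   `variant`, `eta`, `delta_ext`).
#' @param delays Delay grid in seconds, default [default_tq_delays()].
#' @param noise_frac Multiplicative noise fraction, default 0.02.
#' @param seed Seed.
#' @param C Scaling constant, default 0.75.
#' @return Long data.frame: `methyl`, `variant`, `delay_s`, `ratio`.
#' @export
gen_buildup <- function(truth, delays = default_tq_delays(),
                        noise_frac = 0.02, seed = 1, C = 0.75) {
  stopifnot(all(delays > 0))
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      clean <- tq_ratio_model(delays, truth$eta[i], truth$delta_ext[i], C)
      data.frame(methyl = truth$methyl[i], variant = truth$variant[i],
                 delay_s = delays,
                 ratio = clean * (1 + rnorm(length(delays), 0, noise_frac)))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a binding titration
#'
#' Forward-evaluates the quadratic tight-binding isotherm on a protein
#' concentration grid (default 0-70 uM, probe 5 nM) and adds Gaussian noise
#' scaled to the signal range.
#'
#' @param K_D Dissociation constant, uM.
#' @param probe_conc Fixed labelled-species concentration, uM (default
#'   0.005, i.e. 5 nM).
#' @param protein_conc Titration grid, uM.
#' @param F0,F_max Baseline and saturating signal.
#' @param noise_frac Noise sd as a fraction of `F_max - F0`, default 0.01.
#' @param seed Seed.
#' @return Data.frame `conc`, `signal`.
#' @export
gen_titration <- function(K_D = 16.9, probe_conc = 0.005,
                          protein_conc = c(0, 0.5, 1, 2, 4, 7, 12, 20, 30,
                                           45, 60, 70),
                          F0 = 50, F_max = 200, noise_frac = 0.01, seed = 1) {
  .with_seed(seed, {
    clean <- quadratic_binding(protein_conc, probe_conc, K_D, F0, F_max)
    data.frame(conc = protein_conc,
               signal = clean + rnorm(length(protein_conc), 0,
                                      noise_frac * abs(F_max - F0)))
  })
}

#' Generate a competition displacement titration
#'
#' Forward-evaluates [competition_signal()] on a competitor grid (default
#' 0-1000 uM) under the probe-displacement geometry.
#'
#' @param K_I Competitor dissociation constant, uM.
#' @param probe_K_D Probe dissociation constant, uM.
#' @param probe_conc Labelled probe concentration, uM.
#' @param protein_conc Receptor concentration, uM (default 25).
#' @param competitor_conc Competitor grid, uM.
#' @param F0,F_max Free / bound probe signal.
#' @param noise_frac Noise sd as a fraction of `F_max - F0`, default 0.01.
#' @param seed Seed.
#' @return Data.frame `conc`, `signal`.
#' @export
gen_competition <- function(K_I = 2.3, probe_K_D = 16.9, probe_conc = 0.005,
                            protein_conc = 25,
                            competitor_conc = c(0, 0.25, 0.5, 1, 2, 4, 8, 16,
                                                32, 64, 125, 250, 500, 1000),
                            F0 = 50, F_max = 200, noise_frac = 0.01,
                            seed = 1) {
  .with_seed(seed, {
    clean <- competition_signal(competitor_conc, protein_conc, probe_conc,
                                probe_K_D, K_I, F0, F_max)
    data.frame(conc = competitor_conc,
               signal = clean + rnorm(length(competitor_conc), 0,
                                      noise_frac * abs(F_max - F0)))
  })
}

#' Generate ATPase kinetics data
#'
#' Forward-evaluates the Hill-Michaelis-Menten rate law on a substrate grid
#' (default 0-150 uM) with additive Gaussian noise scaled to `V_max`.
#'
#' @param V_max Maximal rate, nmol/min.
#' @param K_M Michaelis constant, uM.
#' @param n Hill coefficient.
#' @param atp_conc Substrate grid, uM.
#' @param noise_frac Noise sd as a fraction of `V_max`, default 0.02.
#' @param seed Seed.
#' @return Data.frame `atp_conc`, `v0`.
#' @export
gen_kinetics <- function(V_max = 1, K_M = 20, n = 1.5,
                         atp_conc = c(0, 2.5, 5, 10, 20, 35, 50, 75, 100,
                                      125, 150),
                         noise_frac = 0.02, seed = 1) {
  .with_seed(seed, {
    clean <- hill_mm(atp_conc, V_max, K_M, n)
    data.frame(atp_conc = atp_conc,
               v0 = clean + rnorm(length(atp_conc), 0, noise_frac * V_max))
  })
}

#' Generate a two-peak size-exclusion chromatogram
#'
#' Two Gaussian elution peaks (dimer earlier, monomer later) with a
#' specified dimer area fraction, on a uniform elution-volume grid, plus
#' additive baseline noise. Default positions and widths emulate an
#' analytical SEC column separating a ~160 kDa dimer from its monomer.
#'
#' @param fraction_dimer Target dimer area fraction of the two peaks.
#' @param total_area Total area of both peaks (absorbance x mL), default 1.
#' @param dimer_center,monomer_center Peak centres, mL.
#' @param peak_sd Gaussian peak sd, mL.
#' @param volume Elution grid, mL.
#' @param noise_sd Additive baseline noise sd, a.u.
#' @param seed Seed.
#' @return Data.frame `volume`, `absorbance`, with attribute `windows`
#'   (list of suggested `monomer`/`dimer` integration windows).
#' @export
gen_chromatogram <- function(fraction_dimer = 0.35, total_area = 1,
                             dimer_center = 10.2, monomer_center = 12.4,
                             peak_sd = 0.15, volume = seq(8, 16, by = 0.01),
                             noise_sd = 0, seed = 1) {
  stopifnot(fraction_dimer >= 0, fraction_dimer <= 1)
  .with_seed(seed, {
    g <- function(v, mu, area)
      area * exp(-(v - mu)^2 / (2 * peak_sd^2)) / (peak_sd * sqrt(2 * pi))
    a <- g(volume, dimer_center, total_area * fraction_dimer) +
      g(volume, monomer_center, total_area * (1 - fraction_dimer)) +
      rnorm(length(volume), 0, noise_sd)
    out <- data.frame(volume = volume, absorbance = a)
    attr(out, "windows") <- list(
      dimer = dimer_center + c(-4, 4) * peak_sd,
      monomer = monomer_center + c(-4, 4) * peak_sd)
    out
  })
}

#' Generate a synthetic activity profile for the panel
#'
#' Produces variant-level activities affine in the group-1 excited-state
#' population (the panel's main trajectory): catalytic efficiency, dimer
#' fraction and corrected exonuclease fluorescence all increase along the
#' trajectory order, mirroring the direction of the laboratory observations
#' the panel emulates. Dimer fractions are anchored at 35/64/57/79 percent
#' for WT/V156M/V160M/R805E.
#'
#' @param model A `two_state_model`.
#' @param noise_frac Relative Gaussian noise on each activity, default 0
#'   (noiseless profile).
#' @param seed Seed.
#' @return Data.frame `variant`, `hydrolysis`, `dimerization`,
#'   `exonuclease`.
#' @export
gen_activity_profile <- function(model, noise_frac = 0, seed = 1) {
  stopifnot(inherits(model, "two_state_model"))
  p <- model$populations[1, model$variants]
  .with_seed(seed, {
    hyd <- 0.02 + 0.08 * p   # k_cat/K_M, 1/(uM min)
    dim_anchor <- c(WT = 0.35, V156M = 0.64, V160M = 0.57, R805E = 0.79)
    dimf <- if (all(model$variants %in% names(dim_anchor)))
      dim_anchor[model$variants] else 0.3 + 0.5 * p
    exo <- 1 + 1.5 * p       # relative fluorescence vs WT
    jitter <- function(x) x * (1 + rnorm(length(x), 0, noise_frac))
    data.frame(variant = model$variants, hydrolysis = jitter(unname(hyd)),
               dimerization = jitter(unname(dimf)),
               exonuclease = jitter(unname(exo)))
  })
}
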