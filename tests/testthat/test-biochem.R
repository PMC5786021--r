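# Binding, competition, kinetics, phosphate transform, SEC integration,
# exonuclease correction

test_that("quadratic isotherm limits and shape", {
  expect_equal(quadratic_binding(0, 0.005, 16.9, 50, 200), 50)  # P = 0 -> F0
  P <- seq(0, 70, by = 0.5)
  F <- quadratic_binding(P, 0.005, 16.9, 50, 200)
  expect_true(all(diff(F) > 0))
  expect_true(all(F <= 200 + 1e-9))
  # tight-binding limit: KD << L gives the stoichiometric breakpoint curve
  L <- 10
  Fb <- quadratic_binding(c(2, 5, 8, 15, 30), L, 1e-6, 0, 1)
  expect_equal(Fb, pmin(c(2, 5, 8, 15, 30), L) / L, tolerance = 1e-3)
})

test_that("noiseless quadratic titrations invert to the generating K_D", {
  grid <- c(0, 0.5, 1, 2, 4, 7, 12, 20, 30, 45, 60, 70)
  for (kd in c(0.5, 16.9, 50)) {
    sim <- gen_titration(K_D = kd, protein_conc = grid, noise_frac = 0)
    fit <- quadratic_binding_fit(sim$conc, sim$signal, probe_conc = 0.005)
    expect_true(fit$converged)
    expect_lt(abs(fit$K_D - kd) / kd, 0.005)
    expect_lt(abs(fit$F0 - 50), 1e-3)
    expect_lt(abs(fit$F_max - 200), 0.5)
  }
  expect_error(quadratic_binding_fit(1:3, 1:3, 0.005), "at least 5")
})

test_that("ternary equilibrium conserves every species", {
  eq <- solve_competition(P_total = 25, L_total = 0.005,
                          I_total = c(0, 0.5, 2.3, 10, 100, 1000),
                          K_D = 16.9, K_I = 2.3)
  expect_true(all(abs(eq$P_free + eq$PL + eq$PI - 25) < 1e-10))
  expect_true(all(abs(eq$L_free + eq$PL - 0.005) < 1e-10))
  expect_true(all(abs(eq$I_free + eq$PI - eq$I_total) < 1e-10))
  # zero competitor reproduces the binary bound fraction
  b <- quadratic_binding(25, 0.005, 16.9, 0, 1)
  expect_equal(eq$frac_probe_bound[1], b, tolerance = 1e-9)
  # displacement is monotone in competitor
  expect_true(all(diff(eq$frac_probe_bound) < 0))
})

test_that("matched affinities displace the probe symmetrically", {
  # K_I = K_D: at competitor amounts far exceeding the probe, free-site
  # competition halves probe occupancy when I_free ~ K_I + P_free
  eq <- solve_competition(25, 0.005, c(0, 1e4), 16.9, 16.9)
  # probe is a tracer: occupancy ratio equals P/(K_D+P) with P from the
  # competitor-loaded equilibrium; cross-check via direct recomputation
  g <- function(P, It) P * (1 + 0.005 / (16.9 + P) + It / (16.9 + P)) - 25
  P_hi <- uniroot(g, c(0, 25), It = 1e4, tol = 1e-14)$root
  expect_equal(eq$frac_probe_bound[2], P_hi / (16.9 + P_hi), tolerance = 1e-6)
})

test_that("noiseless competition data invert to the generating K_I", {
  sim <- gen_competition(K_I = 2.3, noise_frac = 0)
  fit <- competition_fit(sim$conc, sim$signal, probe_K_D = 16.9,
                         probe_conc = 0.005, protein_conc = 25,
                         F0 = 50, F_max = 200)
  expect_true(fit$converged)
  expect_lt(abs(fit$K_I - 2.3) / 2.3, 0.01)
})

test_that("Hill-Michaelis-Menten identities and recovery", {
  # S = K_M gives V_max / 2 for any n
  for (n in c(0.5, 1, 2.7))
    expect_equal(hill_mm(20, 1, 20, n), 0.5, tolerance = 1e-12)
  grid <- c(0, 2.5, 5, 10, 20, 35, 50, 75, 100, 125, 150)
  sim <- gen_kinetics(V_max = 1, K_M = 20, n = 1.5, atp_conc = grid,
                      noise_frac = 0)
  fit <- mm_hill_fit(sim$atp_conc, sim$v0)
  expect_lt(abs(fit$V_max - 1), 1e-6)
  expect_lt(abs(fit$K_M - 20), 1e-4)
  expect_lt(abs(fit$n - 1.5), 1e-6)
  # n = 1 data: free fit returns n ~ 1 and agrees with the fixed-n fit
  sim1 <- gen_kinetics(V_max = 0.8, K_M = 30, n = 1, atp_conc = grid,
                       noise_frac = 0)
  free <- mm_hill_fit(sim1$atp_conc, sim1$v0)
  fixed <- mm_hill_fit(sim1$atp_conc, sim1$v0, fix_n = 1)
  expect_lt(abs(free$n - 1), 1e-3)
  expect_lt(abs(free$K_M - fixed$K_M), 1e-3)
  # k_cat: V_max nmol/min over enzyme nmol (conc uM x volume uL / 1000)
  fit_k <- mm_hill_fit(sim$atp_conc, sim$v0, enzyme_conc_uM = 0.5,
                       volume_ul = 60)
  expect_equal(fit_k$k_cat, fit_k$V_max / (0.5 * 60 / 1000), tolerance = 1e-9)
  expect_error(mm_hill_fit(grid, rep(0, length(grid))), "all-zero")
})

test_that("phosphate standard-curve transform inverts linear data", {
  std_n <- c(0, 5, 10, 20, 40)
  std_a <- 0.02 + 0.015 * std_n
  # absorbance equal to blank -> zero rate (zero-intercept standard curve)
  expect_equal(po4_transform(0.3, 0.3, std_n, 0.015 * std_n)[1], 0,
               tolerance = 1e-9)
  set.seed(41)
  for (i in 1:5) {
    slope <- runif(1, 0.005, 0.05); icept <- runif(1, 0, 0.1)
    nmol <- runif(6, 0, 40)
    a <- icept + slope * nmol
    v <- po4_transform(a + 0.25, 0.25, c(0, 10, 20, 40),
                       icept + slope * c(0, 10, 20, 40), time_min = 60)
    expect_equal(v, nmol / 60, tolerance = 1e-9)
  }
  expect_warning(po4_transform(0.1, 0.3, std_n, std_a), "clipped")
  expect_error(po4_transform(0.1, 0, c(1, 2), c(1, 2)), ">= 3")
  expect_error(po4_transform(0.1, 0, c(1, 2, 3), c(3, 2, 1)), "monotone")
})

test_that("box-sum dimer fractions match closed-form Gaussian areas", {
  # two identical peaks -> one half
  sim <- gen_chromatogram(fraction_dimer = 0.5, noise_sd = 0)
  w <- attr(sim, "windows")
  res <- dimer_fraction(sim$volume, sim$absorbance, w$monomer, w$dimer)
  expect_equal(res$fraction_dimer, 0.5, tolerance = 1e-3)
  # planted 79:21 area ratio
  sim79 <- gen_chromatogram(fraction_dimer = 0.79, noise_sd = 0)
  w <- attr(sim79, "windows")
  res79 <- dimer_fraction(sim79$volume, sim79$absorbance, w$monomer, w$dimer)
  expect_equal(res79$fraction_dimer, 0.79, tolerance = 5e-3)
  # no dimer absorbance -> 0
  sim0 <- gen_chromatogram(fraction_dimer = 0, noise_sd = 0)
  w <- attr(sim0, "windows")
  res0 <- dimer_fraction(sim0$volume, sim0$absorbance, w$monomer, w$dimer)
  expect_equal(res0$fraction_dimer, 0, tolerance = 1e-6)
  expect_error(dimer_fraction(sim0$volume, sim0$absorbance,
                              c(11, 13), c(12, 14)), "disjoint")
  expect_error(dimer_fraction(sim0$volume, sim0$absorbance,
                              c(1, 2), c(12, 13)), "outside")
})

test_that("exonuclease correction subtracts elementwise and flags negatives", {
  expect_equal(exo_correct(100, 100), 0)
  expect_equal(exo_correct(100, 0), 100)
  set.seed(42)
  raw <- runif(10, 50, 150); bg <- runif(10, 0, 40)
  expect_equal(exo_correct(raw, bg), raw - bg)
  expect_warning(exo_correct(10, 20), "negative")
})
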