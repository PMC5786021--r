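# Synthetic-data generators: ground-truth wiring and determinism

test_that("pure ground-state panels sit at the ground positions", {
  p0 <- matrix(0, 1, 4)
  model <- two_state_model(n_groups = 5, n_null = 3, populations = p0,
                           member_jitter = 0, noise_C = 0, noise_H = 0,
                           seed = 2)
  sim <- gen_panel(model, seed = 3)
  pk <- sim$panel$peaks
  mm <- model$methyls
  for (v in model$variants) {
    sub <- pk[pk$variant == v, ]
    expect_equal(sub$delta_C[match(mm$methyl, sub$methyl)], mm$dC0,
                 tolerance = 1e-12)
  }
})

test_that("saturated excited state adds the full offset", {
  p1 <- matrix(1, 1, 4)
  model <- two_state_model(n_groups = 5, n_null = 0, populations = p1,
                           member_jitter = 0, noise_C = 0, noise_H = 0,
                           seed = 2)
  sim <- gen_panel(model, seed = 3)
  pk <- sim$panel$peaks
  mm <- model$methyls
  sub <- pk[pk$variant == "R805E", ]
  expect_equal(sub$delta_C[match(mm$methyl, sub$methyl)], mm$dC0 + mm$ddC,
               tolerance = 1e-12)
  expect_equal(sub$delta_H[match(mm$methyl, sub$methyl)], mm$dH0 + mm$ddH,
               tolerance = 1e-12)
})

test_that("responder combined shifts are affine in the population", {
  p <- c(0, 0.2, 0.5, 0.9)
  model <- two_state_model(n_groups = 8, n_null = 2,
                           populations = matrix(p, 1), member_jitter = 0,
                           noise_C = 0, noise_H = 0, seed = 4)
  sim <- gen_panel(model, seed = 5)
  st <- shift_table(sim$panel)
  m <- shift_matrix(st)
  mm <- model$methyls
  w <- methyl_weights()
  for (i in which(mm$group > 0)) {
    row <- m[mm$methyl[i], ]
    wi <- w[w$residue_class == mm$residue_class[i], ]
    slope <- mm$ddC[i] / wi$w_C + mm$ddH[i] / wi$w_H
    fit <- lm(row ~ p)
    expect_equal(unname(coef(fit)[2]), slope, tolerance = 1e-9)
    expect_lt(max(abs(resid(fit))), 1e-12)
  }
})

test_that("generators are bit-identical under the same seed", {
  model <- two_state_model(seed = 11)
  a <- gen_panel(model, seed = 12)
  b <- gen_panel(model, seed = 12)
  expect_identical(a$panel$peaks, b$panel$peaks)
  c_ <- gen_panel(model, seed = 13)
  expect_false(identical(a$panel$peaks$delta_C, c_$panel$peaks$delta_C))

  truth <- data.frame(methyl = "I1-d1", variant = "WT", eta = 30,
                      delta_ext = 5)
  expect_identical(gen_buildup(truth, seed = 7), gen_buildup(truth, seed = 7))
  expect_identical(gen_titration(seed = 8), gen_titration(seed = 8))
  expect_identical(gen_kinetics(seed = 9), gen_kinetics(seed = 9))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(gen_panel(two_state_model(seed = 1), seed = 2))
  expect_identical(rnorm(1), before)
})

test_that("seeds computed from the caller's stream are honoured per call", {
  # replicate-style usage: seed = sample.int(...) must give fresh draws
  # each call, and the stream must advance past the sample.int itself
  set.seed(77)
  a <- gen_titration(seed = sample.int(1e6, 1))
  b <- gen_titration(seed = sample.int(1e6, 1))
  expect_false(identical(a$signal, b$signal))
})

test_that("noisy shifts average to the population-weighted position", {
  p <- matrix(c(0, 0.2, 0.5, 0.9), 1)
  model <- two_state_model(n_groups = 1, n_null = 0, populations = p,
                           member_jitter = 0, noise_C = 0.01,
                           noise_H = 0.002, seed = 6)
  mm <- model$methyls
  reps <- vapply(1:200, function(s) {
    pk <- gen_panel(model, seed = s)$panel$peaks
    pk$delta_C[pk$variant == "R805E"]
  }, numeric(1))
  want <- mm$dC0 + 0.9 * mm$ddC
  expect_lt(abs(mean(reps) - want), 4 * 0.01 / sqrt(200))
})

test_that("zero dynamics truth gives flat zero curves", {
  truth <- data.frame(methyl = "I1-d1", variant = "WT", eta = 0, delta_ext = 0)
  bu <- gen_buildup(truth, noise_frac = 0.05, seed = 3)
  expect_true(all(bu$ratio == 0))
})

test_that("dynamics truth is affine in the member populations", {
  model <- two_state_model(seed = 21)
  truth <- gen_dynamics_truth(model, seed = 22)
  mm <- model$methyls
  resp <- mm$methyl[mm$group > 0][1:10]
  for (mth in resp) {
    eta <- truth$eta[truth$methyl == mth][match(model$variants,
      truth$variant[truth$methyl == mth])]
    pv <- model$member_populations[mth, ]
    if (sd(pv) == 0) next
    expect_gt(abs(cor(eta, pv)), 0.999999)
  }
})

test_that("default model mirrors the planned panel design", {
  model <- two_state_model(seed = 1)
  expect_equal(sum(model$methyls$group > 0), 43)
  expect_equal(sum(model$methyls$group == 0), 100)
  expect_equal(model$variants, c("WT", "V156M", "V160M", "R805E"))
  expect_equal(unname(model$populations[1, ]), c(0, 0.2, 0.5, 0.9))
  # groups pairwise at correlation -1/2 (the extreme admissible geometry)
  cc <- cor(t(model$populations))
  expect_equal(unname(cc[upper.tri(cc)]), rep(-0.5, 3), tolerance = 1e-9)
  expect_true(all(model$populations >= 0 & model$populations <= 1))
})
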