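# Combined shifts and MAD modified Z-score filtering

test_that("combined shift applies the BMRB weights", {
  # Ile: 10/1.65 + 1/0.29
  expect_equal(combined_shift(10, 1, "Ile"), 10 / 1.65 + 1 / 0.29,
               tolerance = 1e-12)
  expect_equal(combined_shift(0, 0, "Met"), 0)
  # Val gamma: weights make each term exactly 1
  expect_equal(combined_shift(1.4, 0.27, "Val"), 2, tolerance = 1e-12)
  expect_error(combined_shift(1, 1, "Ala"), "no combined-shift weights")
})

test_that("combined shift is linear in each input", {
  set.seed(2)
  for (cl in c("Ile", "Leu", "Val", "Met")) {
    dc <- runif(5, 10, 25); dh <- runif(5, 0.3, 2)
    a <- runif(1, 0.5, 2)
    expect_equal(combined_shift(a * dc, dh, cl) - combined_shift(0, dh, cl),
                 a * combined_shift(dc, 0, cl), tolerance = 1e-12)
    w <- methyl_weights()
    wi <- w[w$residue_class == cl, ]
    # scaling the inputs by the weights gives unit slope in each term
    expect_equal(combined_shift(wi$w_C, wi$w_H, cl), 2, tolerance = 1e-12)
  }
})

test_that("MAD scores flag the planted outlier and only it", {
  # 9 methyls with stdev near 0.01, 1 with stdev 0.50 (population formula):
  # values mean +/- s for variants (c(-1, 1, -1, 1) * s has pop-sd s).
  # The inlier stdevs vary slightly so the MAD itself is nonzero.
  s_true <- c(seq(0.008, 0.012, length.out = 9), 0.5)
  m <- t(vapply(s_true, function(s) 10 + c(-1, 1, -1, 1) * s, numeric(4)))
  colnames(m) <- c("WT", "A", "B", "C")
  st <- matrix_shift_table(m)
  z <- mad_zscores(st)
  expect_equal(z$stdev, s_true, tolerance = 1e-12)
  expect_equal(which(z$z_score == max(z$z_score)), 10)
  expect_true(z$significant[10])
  # the outlier towers over every inlier score
  expect_gt(z$z_score[10], 50 * max(abs(z$z_score[1:9])))
  # cross-check against the brute-force oracle
  expect_equal(z$z_score, oracle_mad_z(shift_matrix(st)), tolerance = 1e-12)
})

test_that("MAD degenerate and below-median cases", {
  m <- matrix(10 + rep(c(-1, 1, -1, 1) * 0.05, each = 6), 6, 4)
  colnames(m) <- c("WT", "A", "B", "C")
  z0 <- mad_zscores(matrix_shift_table(m))
  expect_true(all(z0$z_score == 0))   # identical stdevs -> MAD 0 -> z 0
  expect_false(any(z0$significant))

  # a methyl with zero variation among varying others scores negative
  set.seed(9)
  m2 <- matrix(rnorm(40, 10, 0.05), 10, 4,
               dimnames = list(NULL, c("WT", "A", "B", "C")))
  m2[4, ] <- 12  # constant across variants
  z2 <- mad_zscores(matrix_shift_table(m2))
  expect_lt(z2$z_score[4], 0)
  expect_false(z2$significant[4])
})

test_that("MAD scores reproduce the brute-force oracle on random tables", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:40, 1)
    m <- matrix(rnorm(n * 4, 15, 0.3), n, 4,
                dimnames = list(NULL, c("WT", "A", "B", "C")))
    z <- mad_zscores(matrix_shift_table(m))
    expect_equal(z$z_score, oracle_mad_z(m), tolerance = 1e-12)
  }
})

test_that("joint translation of all variants leaves scores unchanged", {
  set.seed(4)
  m <- matrix(rnorm(32, 20, 0.2), 8, 4,
              dimnames = list(NULL, c("WT", "A", "B", "C")))
  z1 <- mad_zscores(matrix_shift_table(m))
  z2 <- mad_zscores(matrix_shift_table(m + 3.7))
  expect_equal(z1$z_score, z2$z_score, tolerance = 1e-10)
  # translating a single variant changes per-methyl stdevs
  m3 <- m; m3[, 2] <- m3[, 2] + 0.5
  z3 <- mad_zscores(matrix_shift_table(m3))
  expect_false(isTRUE(all.equal(z1$stdev, z3$stdev)))
})

test_that("sample-sd and unsigned variants are exposed", {
  set.seed(11)
  m <- matrix(rnorm(24, 15, 0.2), 6, 4,
              dimnames = list(NULL, c("WT", "A", "B", "C")))
  st <- matrix_shift_table(m)
  zp <- mad_zscores(st, sd_type = "population")
  zs <- mad_zscores(st, sd_type = "sample")
  expect_equal(zs$stdev, zp$stdev * sqrt(4 / 3), tolerance = 1e-12)
  za <- mad_zscores(st, signed = FALSE)
  expect_true(all(za$z_score >= 0))
})

test_that("shift range equals exhaustive max minus min", {
  m <- matrix(c(1.0, 1.1, 1.05, 1.13), 1, 4,
              dimnames = list(NULL, c("WT", "A", "B", "C")))
  m <- rbind(m, 2)  # identical values -> range 0
  st <- matrix_shift_table(m)
  expect_equal(unname(csp_range(st)), c(0.13, 0), tolerance = 1e-12)
  set.seed(7)
  m2 <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("WT", "A", "B", "C")))
  expect_equal(unname(csp_range(matrix_shift_table(m2))),
               apply(m2, 1, function(x) max(x) - min(x)))
})

test_that("trajectory order follows the planted populations", {
  p <- c(0, 0.2, 0.5, 0.9)
  model <- two_state_model(n_groups = 20, n_null = 10,
                           populations = matrix(p, 1), member_jitter = 0,
                           noise_C = 0, noise_H = 0, seed = 3)
  sim <- gen_panel(model, seed = 4)
  st <- shift_table(sim$panel)
  sig <- mad_zscores(st)
  ord <- trajectory_order(st, sig$methyl[sig$significant])
  expect_equal(ord, c("WT", "V156M", "V160M", "R805E"))

  # single methyl, monotone shifts
  m <- matrix(c(1, 1.2, 1.5, 2.0), 1, 4,
              dimnames = list(NULL, c("WT", "A", "B", "C")))
  st1 <- matrix_shift_table(m)
  expect_equal(trajectory_order(st1, st1$methyl), c("WT", "A", "B", "C"))

  # coincident variants: input order with a warning
  mc <- matrix(5, 2, 4, dimnames = list(NULL, c("WT", "A", "B", "C")))
  stc <- matrix_shift_table(mc)
  expect_warning(ordc <- trajectory_order(stc, stc$methyl), "coincident")
  expect_equal(ordc, c("WT", "A", "B", "C"))
})
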