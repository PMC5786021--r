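# Triple-quantum build-up model, eta fitting, order parameters,
# and the shift/dynamics classification rules

test_that("build-up ratio model limits and closed forms", {
  expect_equal(tq_ratio_model(0, eta = 37, delta = 4), 0)
  expect_equal(tq_ratio_model(c(0, 0.01, 0.05), 0, 0), c(0, 0, 0))
  # delta = 0 reduces to C * tanh(eta T)
  T <- default_tq_delays()
  expect_equal(tq_ratio_model(T, 25, 0), 0.75 * tanh(25 * T), tolerance = 1e-12)
  # independent arithmetic evaluation at eta 30, delta 5, T 20 ms
  s <- sqrt(30^2 + 5^2)
  th <- tanh(s * 0.02)
  expect_equal(tq_ratio_model(0.02, 30, 5),
               0.75 * 30 * th / (s - 5 * th), tolerance = 1e-12)
})

test_that("ratio model is monotone in T and eta and bounded", {
  T <- seq(1e-3, 0.2, length.out = 50)
  r <- tq_ratio_model(T, 30, 5)
  expect_true(all(diff(r) > 0))
  etas <- seq(5, 60, by = 5)
  at_t <- vapply(etas, function(e) tq_ratio_model(0.02, e, 5), numeric(1))
  expect_true(all(diff(at_t) > 0))
  s <- sqrt(30^2 + 5^2)
  expect_true(all(r < 0.75 * 30 / (s - 5) + 1e-12))
})

test_that("noiseless build-up curves invert to the generating parameters", {
  T <- default_tq_delays()
  for (eta in c(5, 20, 40, 60)) {
    for (delta in c(0, 4, 10)) {
      fit <- fit_buildup(T, tq_ratio_model(T, eta, delta))
      expect_true(fit$converged)
      expect_lt(abs(fit$eta - eta) / eta, 1e-3)
      if (delta > 0) expect_lt(abs(fit$delta_ext - delta) / delta, 0.05)
    }
  }
})

test_that("degenerate and failing fits are flagged, never silent", {
  T <- default_tq_delays()
  fit0 <- fit_buildup(T, rep(0, length(T)))
  expect_false(fit0$converged)
  expect_true(fit0$degenerate)
  expect_equal(fit0$eta, 0)
  expect_error(fit_buildup(T[1:3], rep(0.1, 3)), "at least 4")
  expect_error(fit_buildup(rev(T), rep(0.1, length(T))), "increasing")
})

test_that("reported eta uncertainty grows with injected noise", {
  T <- default_tq_delays()
  clean <- tq_ratio_model(T, 30, 5)
  errs <- vapply(c(0.01, 0.05, 0.1), function(nf) {
    set.seed(31)
    median(replicate(20, {
      fit <- fit_buildup(T, clean * (1 + rnorm(length(T), 0, nf)))
      fit$eta_err
    }))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("order-parameter conversion is a clean inverse", {
  expect_equal(eta_to_s2(0, 30e-9), 0)
  k <- methyl_hh_constant()
  # doubling tau_c halves S2 at fixed eta
  expect_equal(eta_to_s2(40, 60e-9), eta_to_s2(40, 30e-9) / 2,
               tolerance = 1e-12)
  for (s2 in c(0.1, 0.45, 0.9))
    expect_equal(eta_to_s2(s2_to_eta(s2, 30e-9), 30e-9), s2, tolerance = 1e-12)
  expect_warning(eta_to_s2(1e6, 30e-9), "outside")
  # the constant puts typical eta rates in a physical S2 range
  expect_gt(eta_to_s2(30, 30e-9), 0.1)
  expect_lt(eta_to_s2(30, 30e-9), 0.6)
})

test_that("classification follows the shift/dynamics rule table", {
  mk_eta <- function(e) data.frame(methyl = "I1-d1",
                                   variant = c("WT", "A", "B", "C"), eta = e)
  # large shift range, perfect correlation, eta falling upon mutation
  m <- matrix(c(0, 0.1, 0.2, 0.3), 1, 4,
              dimnames = list(NULL, c("WT", "A", "B", "C")))
  st <- matrix_shift_table(m)
  rec <- classify_dynamics(mk_eta(c(40, 35, 30, 20)), st)
  expect_equal(rec$category, "correlated_flexible")
  # small range, big WT-vs-mutant difference
  m2 <- matrix(c(0, 0.02, 0.04, 0.05), 1, 4,
               dimnames = list(NULL, c("WT", "A", "B", "C")))
  st2 <- matrix_shift_table(m2)
  rec2 <- classify_dynamics(mk_eta(c(40, 31, 30, 29)), st2)
  expect_equal(rec2$category, "uncorrelated_flexible")
  rec3 <- classify_dynamics(mk_eta(c(30, 40, 41, 39)), st2)
  expect_equal(rec3$category, "uncorrelated_rigid")
  # below both gates
  rec4 <- classify_dynamics(mk_eta(c(30, 31, 29, 30)), st2)
  expect_equal(rec4$category, "unchanged")
})

test_that("classification equals the brute-force rule oracle on random records", {
  set.seed(33)
  for (i in 1:200) {
    dm <- rnorm(4, 10, sample(c(0.01, 0.1), 1))
    eta <- rnorm(4, 35, sample(c(2, 8), 1))
    m <- matrix(dm, 1, 4, dimnames = list(NULL, c("WT", "A", "B", "C")))
    st <- matrix_shift_table(m)
    tab <- data.frame(methyl = "I1-d1", variant = c("WT", "A", "B", "C"),
                      eta = eta)
    got <- classify_dynamics(tab, st)
    rng <- max(dm) - min(dm)
    rp <- if (sd(eta) == 0 || sd(dm) == 0) NA else oracle_pearson(eta, dm)
    d_eta <- eta[1] - mean(eta[-1])
    expect_equal(got$category, oracle_classify(rng, rp, d_eta))
  }
})

test_that("incomplete eta coverage is excluded with a message", {
  m <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, c("WT", "A", "B", "C")))
  st <- matrix_shift_table(m)
  tab <- data.frame(methyl = rep(st$methyl, c(4, 3)),
                    variant = c("WT", "A", "B", "C", "WT", "A", "B"),
                    eta = rnorm(7, 30))
  expect_message(out <- classify_dynamics(tab, st), "excluded 1")
  expect_equal(nrow(out), 1)
})

test_that("table fitting groups by methyl and variant", {
  truth <- data.frame(methyl = rep(c("I1-d1", "L2-d1"), each = 2),
                      variant = rep(c("WT", "M"), 2),
                      eta = c(20, 30, 40, 50), delta_ext = c(2, 3, 4, 5))
  bu <- gen_buildup(truth, noise_frac = 0, seed = 1)
  fits <- fit_buildup_table(bu)
  expect_equal(nrow(fits), 4)
  merged <- merge(fits, truth, by = c("methyl", "variant"))
  expect_lt(max(abs(merged$eta.x - merged$eta.y) / merged$eta.y), 1e-3)
})
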