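test_that("segmented fit reproduces exact two-slope data", {
  f <- c(seq(0.01, 0.05, by = 0.01), seq(-0.05, -0.01, by = 0.01))
  e <- ifelse(f > 0, -3 * f, 1 * f)
  sf <- segmented_fit(f, e)
  expect_equal(sf$slope_pos, -3, tolerance = 1e-12)
  expect_equal(sf$slope_neg, 1, tolerance = 1e-12)
  expect_equal(sf$intercept_pos, 0, tolerance = 1e-12)
  expect_equal(sf$intercept_neg, 0, tolerance = 1e-12)
  expect_equal(sf$r2_pos, 1)
  expect_equal(sf$r2_neg, 1)
  expect_equal(slope_ratio(sf), 3, tolerance = 1e-12)
})

test_that("segmented fit matches lm on a noisy toy set, per side", {
  set.seed(5)
  f <- c(runif(5, 0.005, 0.05), runif(5, -0.05, -0.005))
  e <- ifelse(f > 0, -60 * f, 30 * f) + rnorm(10, 0, 0.2)
  sf <- segmented_fit(f, e)
  for (side in c(1, -1)) {
    i <- sign(f) == side
    ref <- lm(e[i] ~ f[i])
    slope <- if (side > 0) sf$slope_pos else sf$slope_neg
    icpt <- if (side > 0) sf$intercept_pos else sf$intercept_neg
    r2 <- if (side > 0) sf$r2_pos else sf$r2_neg
    expect_equal(slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(icpt, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(r2, summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("segmented fit enforces segment populations and excludes F = 0", {
  expect_error(segmented_fit(c(0.1, 0.2, 0.3), c(1, 2, 3)),
               "negative-field side")
  expect_error(segmented_fit(c(-0.1, -0.2, 0.3, 0.4), c(1, 2, 3, 4)) ,
               NA)
  sf <- segmented_fit(c(-0.1, -0.2, 0, 0, 0.3, 0.4), c(1, 2, 9, 9, 3, 4))
  expect_identical(sf$n_zero, 2L)
  expect_identical(sf$n_pos, 2L)
  expect_identical(sf$n_neg, 2L)
})

test_that("slope ratio is unsigned, scale invariant, and 1 for symmetry", {
  f <- c(-0.04, -0.02, -0.01, 0.01, 0.02, 0.04)
  e_sym <- -50 * abs(f)
  expect_equal(slope_ratio(segmented_fit(f, e_sym)), 1, tolerance = 1e-12)
  e <- ifelse(f > 0, -80 * f, 20 * f)
  expect_equal(slope_ratio(segmented_fit(f, 2 * e)),
               slope_ratio(segmented_fit(f, e)), tolerance = 1e-12)
})

test_that("EAC derivation inverts the dipole energy model exactly", {
  expect_identical(eac_from_slope(0, 1.14), 0)
  set.seed(9)
  f <- seq(-0.05, 0.05, length.out = 100)
  for (k in 1:10) {
    q_pos <- runif(1, 0.05, 0.4); q_neg <- -runif(1, 0.05, 0.4)
    l <- runif(1, 1.0, 1.3)
    m <- eac_model(q_pos, q_neg, l)
    fit <- eac_fit(f, eac_energy(m, f), bond_length = l, boot = 0)
    expect_equal(fit$model$q_pos, q_pos, tolerance = 1e-12)
    expect_equal(fit$model$q_neg, q_neg, tolerance = 1e-12)
    # consistency identity: k1/k2 equals |q_pos|/|q_neg|
    expect_equal(slope_ratio(fit), abs(q_pos) / abs(q_neg),
                 tolerance = 1e-10)
  }
})

test_that("EAC dipole energy follows the closed form and is stabilizing", {
  m <- eac_model(0.2541, -0.0843, 1.14, "MP2")
  expect_identical(eac_energy(m, 0), 0)
  expect_equal(eac_energy(m, 0.01), -332.0636 * 0.2541 * 0.01 * 1.14,
               tolerance = 1e-12)
  f <- seq(-0.05, 0.05, length.out = 201)
  expect_true(all(eac_energy(m, f) <= 0))
  # continuous at the segment boundary
  expect_lt(abs(eac_energy(m, 1e-12)), 1e-9)
  expect_lt(abs(eac_energy(m, -1e-12)), 1e-9)
  # positive-field branch slope is negative for q_pos > 0
  expect_lt(eac_energy(m, 0.02), eac_energy(m, 0.01))
})

test_that("eac_fit recovers generator charges within OLS uncertainty", {
  set.seed(77)
  n <- 10000
  truth_m <- eac_model(0.2541, -0.0843, 1.14, "MP2")
  sgn <- ifelse(runif(n) < 0.5, 1, -1)
  f <- sgn * abs(rnorm(n, 0, 0.02))
  e <- eac_energy(truth_m, f) + rnorm(n, 0, 0.1)
  fit <- eac_fit(f, e, boot = 0)
  for (side in c("pos", "neg")) {
    i <- if (side == "pos") f > 0 else f < 0
    se_slope <- 0.1 / sqrt(sum((f[i] - mean(f[i]))^2))
    se_q <- se_slope / (K_COUL * 1.14)
    q_hat <- fit$model[[paste0("q_", side)]]
    q_true <- truth_m[[paste0("q_", side)]]
    expect_lt(abs(q_hat - q_true), 3 * se_q)
  }
})

test_that("correction cancels the low-level model exactly in the noiseless limit", {
  low <- eac_model(0.1638, -0.1979, 1.14, "HF")
  high <- eac_model(0.2541, -0.0843, 1.14, "MP2")
  f <- seq(-0.04, 0.04, length.out = 101)
  e_low <- eac_energy(low, f)
  expect_equal(correct_energies(e_low, f, low, low), e_low)
  corrected <- correct_energies(e_low, f, low, high)
  expect_equal(corrected, eac_energy(high, f), tolerance = 1e-12)
  expect_error(correct_energies(e_low[-1], f, low, high), "length")
})

test_that("MUE of the corrected series approaches the Gaussian closed form", {
  set.seed(13)
  n <- 10000
  low <- eac_model(0.2196, -0.1222); high <- eac_model(0.2541, -0.0843)
  f <- ifelse(runif(n) < 0.5, 1, -1) * abs(rnorm(n, 0, 0.02))
  sigma <- 0.1
  e_low <- eac_energy(low, f) + rnorm(n, 0, sigma)
  corrected <- correct_energies(e_low, f, low, high)
  mue <- mean(abs(corrected - eac_energy(high, f)))
  expected <- sigma * sqrt(2 / pi)
  se_mue <- sigma * sqrt((1 - 2 / pi) / n)
  expect_lt(abs(mue - expected), 4 * se_mue)
})

test_that("agreement stats report Pearson r^2 with MUE as companion", {
  a <- c(0, 1, 2, 3)
  s_id <- agreement_stats(a, a)
  expect_equal(s_id$r_squared, 1)
  expect_equal(s_id$mue, 0)
  s <- agreement_stats(a, a + 0.5)
  expect_equal(s$r_squared, 1)
  expect_equal(s$mue, 0.5)
  # r^2 alone cannot certify agreement: a sign flip still correlates
  s_flip <- agreement_stats(a, -a)
  expect_equal(s_flip$r_squared, 1)
  expect_equal(s_flip$mue, mean(abs(2 * a)))
  expect_error(agreement_stats(a, rep(1, 4)), "variance")
})

test_that("agreement with the high-level truth degrades monotonically in noise", {
  low <- eac_model(0.1638, -0.1979); high <- eac_model(0.2541, -0.0843)
  n <- 4000
  set.seed(99)
  f <- ifelse(runif(n) < 0.5, 1, -1) * abs(rnorm(n, 0, 0.02))
  noise_unit <- rnorm(n)  # matched noise across sigma levels
  r2 <- vapply(c(0, 0.05, 0.1, 0.2), function(sigma) {
    e_low <- eac_energy(low, f) + sigma * noise_unit
    corrected <- correct_energies(e_low, f, low, high)
    agreement_stats(corrected, eac_energy(high, f))$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) <= 1e-12))
  expect_equal(r2[1], 1)
})

test_that("eac_fit methods expose the model surface coherently", {
  set.seed(3)
  m <- eac_model(0.22, -0.12, method_label = "toy")
  f <- c(runif(60, 0.001, 0.05), runif(60, -0.05, -0.001))
  e <- eac_energy(m, f) + rnorm(120, 0, 0.05)
  fit <- eac_fit(f, e, method_label = "toy", boot = 200, seed = 4)
  expect_s3_class(fit, "eac_fit")
  cf <- coef(fit)
  expect_identical(dim(cf), c(2L, 4L))
  expect_equal(unname(cf["field>0", "slope"]), fit$fit$slope_pos)
  expect_length(predict(fit), 120)
  expect_equal(residuals(fit), e - predict(fit))
  expect_length(fit$ratio_ci, 2)
  expect_true(fit$ratio_ci[1] < fit$ratio & fit$ratio < fit$ratio_ci[2])
  expect_output(print(fit), "slope ratio")
  expect_output(print(summary(fit)), "EAC")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))

  sims <- simulate(m, nsim = 2, seed = 8, field = f, sd = 0.05)
  sims2 <- simulate(m, nsim = 2, seed = 8, field = f, sd = 0.05)
  expect_identical(sims, sims2)
  expect_equal(dim(sims), c(120L, 2L))
})
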