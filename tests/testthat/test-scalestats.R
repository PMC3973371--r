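test_that("the hierarchical contact-area identity multiplies out correctly", {
  # highest-load reference means: 0.101 mm^2 x 0.132 /um^2 x 0.461 um^2
  expect_equal(real_contact_area(0.101, 0.132, 0.461), 6146, tolerance = 1e-3)
  expect_equal(real_contact_area(0, 0.1, 0.3), 0)
  expect_equal(real_contact_area(0.1, 0, 0.3), 0)
  expect_error(real_contact_area(-0.1, 0.1, 0.3), ">= 0")

  # growth across the load range: approximately an order of magnitude
  ratio <- real_contact_area(0.101, 0.132, 0.461) /
    real_contact_area(0.034, 0.071, 0.235)
  expect_equal(ratio, 10.8, tolerance = 0.01)
  expect_gte(ratio, 10)
})

test_that("noiseless power-law data are fitted exactly", {
  loads <- c(0.2, 0.5, 1, 2, 4)
  d <- tidyr::expand_grid(individual_id = sprintf("i%d", 1:4), load_mN = loads)
  offs <- c(i1 = -0.1, i2 = 0, i3 = 0.05, i4 = 0.2)
  d$y <- 0.08 * d$load_mN^0.362 * 10^offs[d$individual_id]
  fit <- fit_powerlaw_mixed(d, y)
  expect_equal(fit$slope, 0.362, tolerance = 1e-9)
  expect_equal(fit$r2_conditional, 1)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
})

test_that("mixed fits agree with an independent REML implementation", {
  skip_if_not_installed("nlme")
  d <- make_powerlaw_dataset(params = synth_params(seed = 21))
  fit <- fit_powerlaw_mixed(d, A_A_mm2)
  ref <- nlme::lme(log10(A_A_mm2) ~ log10(load_mN), random = ~ 1 | individual_id,
                   data = d, method = "REML")
  expect_equal(fit$slope, unname(nlme::fixef(ref)[2]), tolerance = 1e-5)
  expect_equal(fit$intercept, unname(nlme::fixef(ref)[1]), tolerance = 1e-5)
  expect_equal(fit$slope_se,
               sqrt(diag(stats::vcov(ref)))[[2]], tolerance = 1e-3)
  vc <- nlme::VarCorr(ref)
  expect_equal(fit$var_random, as.numeric(vc["(Intercept)", "Variance"]),
               tolerance = 1e-4)
})

test_that("generating exponents and variance components are recovered", {
  hits <- 0
  sds <- numeric(10)
  for (r in 1:10) {
    d <- make_powerlaw_dataset(params = synth_params(seed = 100 + r))
    fit <- fit_powerlaw_mixed(d, A_A_mm2)
    if (abs(fit$slope - 0.362) <= 3 * fit$slope_se) hits <- hits + 1
    sds[r] <- sqrt(fit$var_random)
    expect_gte(fit$r2_conditional, fit$r2_marginal)
  }
  expect_gte(hits, 9)
  # recovered between-individual sd near the generating 0.12 (log10 scale)
  expect_equal(mean(sds), 0.12, tolerance = 0.25)
})

test_that("non-positive responses are rejected with the offending rows named", {
  d <- tidyr::expand_grid(individual_id = c("a", "b"), load_mN = c(1, 2, 4))
  d$y <- c(1, 2, 3, 4, -1, 6)
  expect_error(fit_powerlaw_mixed(d, y), "offending rows: 5")
})

test_that("exponent composition sums the component scaling coefficients", {
  comp <- exponent_composition(0.362, 0.214, 0.226)
  expect_equal(comp$k_sum, 0.802)
  expect_true(comp$near_linear)
  expect_equal(exponent_composition(0, 0, 0)$k_sum, 0)

  # closure on synthetic data: directly fitted A_R slope within 2 SE of the sum
  d <- make_powerlaw_dataset(params = synth_params(seed = 31))
  f <- fit_all_powerlaws(d)
  comp2 <- exponent_composition(f$fits$projected_contact_area,
                                f$fits$acantha_density,
                                f$fits$acantha_contact_area)
  se <- sqrt(comp2$k_sum_se^2 + f$fits$real_contact_area$slope_se^2)
  expect_lt(abs(f$fits$real_contact_area$slope - comp2$k_sum), 2 * se)
  # composed prefactor: A_R at 1 mN in um^2
  expect_equal(comp2$prefactor_um2,
               10^(f$fits$projected_contact_area$intercept +
                     f$fits$acantha_density$intercept +
                     f$fits$acantha_contact_area$intercept) * 1e6)
})

test_that("the Friedman statistic matches a from-scratch rank computation", {
  m_id <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  out <- friedman_test(matrix(5, nrow = 3, ncol = 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  set.seed(10)
  for (i in 1:5) {
    m <- matrix(rnorm(12), nrow = 4, ncol = 3)
    got <- friedman_test(m)
    expect_equal(got$statistic, friedman_by_hand(m), tolerance = 1e-10)
    expect_equal(got$df, 2) # k = 3 conditions
  }

  # with ties (mid-ranks + tie correction)
  mt <- matrix(c(1, 1, 2, 3, 2, 2, 1, 1, 3, 3, 3, 2), nrow = 4)
  expect_equal(friedman_test(mt)$statistic, friedman_by_hand(mt),
               tolerance = 1e-10)

  # invariance under strictly monotone transforms
  m <- matrix(runif(12), nrow = 4)
  expect_equal(friedman_test(m)$statistic, friedman_test(exp(3 * m))$statistic)

  m_na <- m
  m_na[2, 2] <- NA
  expect_error(friedman_test(m_na), "missing")
  expect_error(friedman_test(matrix(1:3, 1)), "n >= 2")
})

test_that("repeated-measures eta^2 reflects the constructed variance share", {
  loads <- c(0.2, 0.5, 1, 2, 4)
  ids <- sprintf("i%02d", 1:10)

  # response independent of load: eta^2 near zero
  set.seed(2)
  d0 <- tidyr::expand_grid(individual_id = ids, load_mN = loads)
  d0$y <- rnorm(nrow(d0))
  out0 <- rm_effect_size(d0, y, n_boot = 100, seed = 1)
  expect_lt(out0$eta_sq, 0.15)

  # constructed half-share: load term built to carry 50% of total variance
  x <- scale(loads, scale = FALSE)[, 1]
  etas <- vapply(1:20, function(r) {
    set.seed(400 + r)
    d <- tidyr::expand_grid(individual_id = ids, load_mN = loads)
    noise <- rnorm(nrow(d), 0, 1)
    beta <- sd(noise) / (sd(x[match(d$load_mN, loads)]))
    d$y <- beta * x[match(d$load_mN, loads)] + noise
    rm_effect_size(d, y, n_boot = 20, seed = r)$eta_sq
  }, numeric(1))
  expect_equal(mean(etas), 0.5, tolerance = 0.05)

  d_bad <- d0[-1, ]
  expect_error(rm_effect_size(d_bad, y), "unbalanced")
})

test_that("eta^2 bootstrap CI brackets the point estimate", {
  loads <- c(1, 2, 4)
  set.seed(5)
  d <- tidyr::expand_grid(individual_id = sprintf("i%d", 1:8), load_mN = loads)
  d$y <- 0.5 * d$load_mN + rnorm(nrow(d), 0, 0.5)
  out <- rm_effect_size(d, y, n_boot = 200, seed = 3)
  expect_lt(out$ci_lower, out$eta_sq)
  expect_gt(out$ci_upper, out$eta_sq)
  expect_gt(out$eta_sq, 0.3)
})

test_that("t-based margins follow the closed form", {
  expect_equal(mean_t_ci(rep(3, 5))$margin, 0)
  x <- c(2.1, 3.5, 1.8, 4.2, 2.9, 3.3, 2.2, 4.8, 3.1, 2.6) # n = 10
  out <- mean_t_ci(x)
  expect_equal(out$margin / (sd(x) / sqrt(10)), qt(0.975, 9), tolerance = 1e-12)
  expect_equal(qt(0.975, 9), 2.2622, tolerance = 1e-4)
  expect_error(mean_t_ci(1), "at least 2")
})

test_that("median and raw MAD follow their definitions", {
  expect_equal(median_mad(c(1, 1, 1)), tibble::tibble(median = 1, mad = 0))
  expect_equal(median_mad(c(1, 2, 3, 4, 100)),
               tibble::tibble(median = 3, mad = 1))
  # even-n brute force
  x <- c(4, 8, 15, 16, 23, 42)
  med <- median(x)
  expect_equal(median_mad(x)$mad, median(abs(x - med)))
  expect_error(median_mad(numeric()), "non-empty")
})

test_that("per-load summaries report mean and t margin per measure", {
  d <- make_powerlaw_dataset(params = synth_params(seed = 12))
  s <- summarise_observations(d)
  expect_equal(nrow(s), 5)
  expect_true(all(c("A_A_mm2_mean", "A_A_mm2_margin", "A_R_um2_mean") %in%
                    names(s)))
  one_load <- d[d$load_mN == 1, ]
  expect_equal(s$A_A_mm2_mean[s$load_mN == 1], mean(one_load$A_A_mm2))
  expect_equal(s$A_A_mm2_margin[s$load_mN == 1],
               mean_t_ci(one_load$A_A_mm2)$margin)
})
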