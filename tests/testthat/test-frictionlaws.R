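test_that("the adhesion-extended fit inverts the published median line", {
  d <- tibble::tibble(load_mN = c(1, 2, 4),
                      friction_mN = 1.25 * c(1, 2, 4) + 2.42)
  fit <- fit_amonton_extended(d)
  expect_equal(fit$mu, 1.25, tolerance = 1e-12)
  expect_equal(fit$F0_mN, 2.42, tolerance = 1e-12)
  expect_equal(fit$F_adh_mN, 2.42 / 1.25, tolerance = 1e-12) # 1.936 ~ 1.94 mN
  expect_equal(round(fit$F_adh_mN, 2), 1.94)
})

test_that("pure Amonton and pathological slopes are handled", {
  d0 <- tibble::tibble(load_mN = c(1, 2, 4), friction_mN = 0.7 * c(1, 2, 4))
  fit0 <- fit_amonton_extended(d0)
  expect_equal(fit0$F0_mN, 0, tolerance = 1e-12)
  expect_equal(fit0$F_adh_mN, 0, tolerance = 1e-12)

  dneg <- tibble::tibble(load_mN = c(1, 2, 4), friction_mN = c(3, 2, 1))
  fitn <- fit_amonton_extended(dneg)
  expect_true(fitn$mu_nonpositive)
  expect_true(is.na(fitn$F_adh_mN))

  # arbitrary noiseless line: exact closed-form recovery
  d <- tibble::tibble(load_mN = c(0.2, 0.5, 1, 2, 4),
                      friction_mN = 3.7 * c(0.2, 0.5, 1, 2, 4) + 0.91)
  fit <- fit_amonton_extended(d)
  expect_equal(fit$mu, 3.7, tolerance = 1e-12)
  expect_equal(fit$F0_mN, 0.91, tolerance = 1e-12)
})

test_that("median collapsing matches the repeated-measures protocol", {
  d <- tidyr::expand_grid(individual_id = sprintf("i%d", 1:5),
                          load_mN = c(1, 2, 4))
  set.seed(3)
  d$friction_mN <- 2 * d$load_mN + rnorm(nrow(d))
  fit <- fit_amonton_extended(d)
  meds <- tapply(d$friction_mN, d$load_mN, median)
  oracle <- lm(meds ~ c(1, 2, 4))
  expect_equal(fit$mu, unname(coef(oracle)[2]), tolerance = 1e-12)
})

test_that("shear stress is friction per real contact area in MPa", {
  out <- shear_stress_series(tibble::tibble(friction_mN = 6.146,
                                            A_R_um2 = 6.146e3))
  expect_equal(out$tau$tau_MPa, 1)

  # exact tau * A_R data: constant stress, zero Friedman statistic
  # (powers of two keep the division exactly reversible in floating point)
  d <- tidyr::expand_grid(individual_id = sprintf("i%d", 1:4),
                          load_mN = c(0.5, 1, 2))
  d$A_R_um2 <- 512 * d$load_mN * rep(c(0.5, 1, 2, 4), each = 3)
  d$friction_mN <- synth_friction(d$A_R_um2, tau = 1.3, noise_sd = 0)
  out <- shear_stress_series(d)
  expect_equal(out$summary$median, 1.3, tolerance = 1e-9)
  expect_equal(out$summary$mad, 0, tolerance = 1e-9)
  expect_equal(out$friedman$statistic, 0)

  expect_error(shear_stress_series(tibble::tibble(friction_mN = 1, A_R_um2 = 0)),
               "zero real contact area")
})

test_that("the apparent friction coefficient decays as load^(k-1)", {
  # Amonton limit: k = 1 gives a constant coefficient
  flat <- apparent_mu(1, 2e-3, 1, c(0.5, 1, 2, 4))
  expect_equal(diff(range(flat$mu_app)), 0)
  expect_equal(flat$mu_app[1], 2) # 1 MPa x 2e-3 mm^2/mN x 1e3

  out <- apparent_mu(1, 2e-3, 0.802, c(0.2, 0.5, 1, 2, 4))
  expect_equal(attr(out, "exponent"), -0.198)
  slope <- unname(coef(lm(log10(out$mu_app) ~ log10(out$load_mN)))[2])
  expect_equal(slope, -0.198, tolerance = 1e-9)
  # inside the observed scaling interval for euplantulae
  expect_gt(-0.198, -0.92)
  expect_lt(-0.198, 0)
})

test_that("rigid-material friction is shear stress times growth rate", {
  expect_equal(rigid_mu(800, 1e-6), 0.8) # steel on steel
  expect_equal(rigid_mu(0, 5), 0)
  mu_pad <- rigid_mu(1, 2.1e-3)
  expect_equal(mu_pad, 2.1)
  expect_gte(mu_pad, 2) # printed effective-mu range over the load span
  expect_lte(mu_pad, 4)
})

test_that("contact growth rate is the OLS slope of A_R over load", {
  d <- tibble::tibble(load_mN = c(0.5, 1, 2, 4), A_R_mm2 = 2e-3 * c(0.5, 1, 2, 4))
  expect_equal(growth_rate_C(d), 2e-3, tolerance = 1e-12)

  steel <- tibble::tibble(load_mN = c(1, 2, 4), A_R_mm2 = 1e-6 * c(1, 2, 4))
  expect_equal(growth_rate_C(steel), 1e-6, tolerance = 1e-12)

  # composed reference means: growth rate of order 1e-3 mm^2/mN
  C_ref <- growth_rate_C(ref_means())
  expect_gt(C_ref, 5e-4)
  expect_lt(C_ref, 5e-3)
})

test_that("JKR contact reduces to Hertz without adhesion", {
  hertz <- jkr_params(R_um = 180, W_mN_per_m = 0, E_star_MPa = 1)
  out <- jkr_contact(c(0.5, 1, 2), hertz)
  a3 <- (180 / hertz$K_nN_per_um2) * c(0.5, 1, 2) * 1e6
  expect_equal(out$contact_radius_um, a3^(1 / 3), tolerance = 1e-12)
  expect_equal(jkr_contact(0, hertz)$contact_area_um2, 0)

  # continuity of the W -> 0 limit
  tiny <- jkr_params(R_um = 180, W_mN_per_m = 60e-12, E_star_MPa = 1)
  expect_equal(jkr_contact(1, tiny)$contact_radius_um,
               jkr_contact(1, hertz)$contact_radius_um, tolerance = 1e-6)
})

test_that("JKR pull-off and zero-load contact follow the closed forms", {
  p <- jkr_params() # R = 180 um, W = 60 mN/m, E* = 1 MPa
  expect_equal(p$pull_off_nN, 1.5 * pi * 60 * 180)
  expect_equal(p$pull_off_nN / 1e3, 50.9, tolerance = 1e-2) # ~50.9 uN

  at0 <- jkr_contact(0, p)
  expect_gt(at0$contact_area_um2, 0)
  grid <- jkr_contact(seq(0, 4, by = 0.25), p)
  expect_true(all(diff(grid$contact_area_um2) > 0))
  expect_error(jkr_contact(-0.1, p), "pull-off")

  # oracle: numeric root of the inverse relation F(a) = K a^3/R - sqrt(6 pi W K a^3)
  F_target <- 2e6 # 2 mN in nN
  f_of_a <- function(a) {
    p$K_nN_per_um2 * a^3 / p$R_um -
      sqrt(6 * pi * p$W_nN_per_um * p$K_nN_per_um2 * a^3)
  }
  a_closed <- jkr_contact(2, p)$contact_radius_um
  root <- uniroot(function(a) f_of_a(a) - F_target,
                  interval = c(p$zero_load_radius_um, 1e4), tol = 1e-10)$root
  expect_equal(a_closed, root, tolerance = 1e-6)
})

test_that("adhesion per unit area converts nN and um^2 to MPa", {
  expect_equal(adhesion_per_area(10, 0.2 * 0.2), 0.25) # gecko spatula
  expect_equal(adhesion_per_area(66, 0.2), 0.33)       # acantha, pi r^2 ~ 0.2
  expect_equal(adhesion_per_area(0, 1), 0)
  expect_error(adhesion_per_area(1, 0), "> 0")
})

test_that("the material comparison separates pads, metals and soft spheres", {
  curves <- figure9_curves(loads = seq(0, 4, by = 0.5))
  steel <- dplyr::filter(curves, material == "steel")
  expect_equal(steel$A_R_mm2, 1e-6 * steel$load_mN, tolerance = 1e-12)

  pad <- dplyr::filter(curves, material == "euplantula")
  expect_equal(pad$A_R_mm2[pad$load_mN == 0], 0) # negligible area at zero load
  expect_true(all(diff(pad$A_R_mm2) > 0))

  jkr <- dplyr::filter(curves, law == "jkr")
  expect_gt(jkr$A_R_mm2[jkr$load_mN == 0], 0) # finite contact at zero load

  expect_error(material_spec("x", "power_law"), "need")
  expect_error(material_spec("x", "linear_C"), "need")
})

test_that("tau times C reproduces both printed material examples", {
  expect_equal(rigid_mu(800, 1e-6), 0.8, tolerance = 1e-12)
  mu_eup <- rigid_mu(1, growth_rate_C(ref_means()))
  expect_gt(mu_eup, 1) # friction coefficient above 1 despite tau ~ 1 MPa
  expect_lt(mu_eup, 4)
})
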