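#' Reference mean contact measures for stick-insect euplantulae
#'
#' Published per-load group means (n = 10 Carausius morosus individuals) of
#' the three hierarchical contact measures: projected contact area (mm^2),
#' density of acanthae in contact (per um^2) and per-acantha (tip) contact
#' area (um^2), at the five standard normal loads. Used as desk-scale inputs
#' for the worked arithmetic (area ratios, growth-rate order of magnitude).
#'
#' @return Tibble with columns `load_mN`, `A_A_mm2`, `N_A_per_um2`, `A_Ac_um2`
#'   and the derived `A_R_um2`.
#' @export
reference_contact_means <- function() {
  tibble(
    load_mN = c(0.2, 0.5, 1, 2, 4),
    A_A_mm2 = c(0.034, 0.061, 0.08, 0.092, 0.101),
    N_A_per_um2 = c(0.071, 0.088, 0.107, 0.124, 0.132),
    A_Ac_um2 = c(0.235, 0.292, 0.326, 0.404, 0.461)
  ) %>%
    mutate(A_R_um2 = real_contact_area(.data$A_A_mm2, .data$N_A_per_um2,
                                       .data$A_Ac_um2))
}

#' Adhesion-extended Amonton fit of friction over load
#'
#' Ordinary least-squares regression of the per-load median friction values on
#' normal load: `F_F = mu * F_N + F_0`, where the intercept `F_0 = mu * F_A`
#' is the friction force at zero normal load and `F_A = F_0 / mu` the
#' adhesion-equivalent load. `F_0 = 0` recovers the pure Amonton law.
#'
#' @param data Tibble with columns `load_mN` and `friction_mN`. If several
#'   observations share a load (repeated measures), the per-load medians are
#'   used, as the friction-law comparison prescribes.
#' @param use_medians Collapse to per-load medians first (default TRUE).
#' @return A `friction_fit`: `mu`, `F0_mN`, `F_adh_mN` (NA and flagged when
#'   `mu <= 0`), residuals, and the points fitted.
#' @export
#' @examples
#' d <- tibble::tibble(load_mN = c(1, 2, 4),
#'                     friction_mN = 1.25 * c(1, 2, 4) + 2.42)
#' fit_amonton_extended(d) # mu = 1.25, F0 = 2.42, F_A ~ 1.94 mN
fit_amonton_extended <- function(data, use_medians = TRUE) {
  d <- as_tibble(data)
  if (!all(c("load_mN", "friction_mN") %in% names(d))) {
    abort("`data` needs columns `load_mN` and `friction_mN`.")
  }
  if (use_medians) {
    d <- d %>%
      group_by(.data$load_mN) %>%
      summarise(friction_mN = median(.data$friction_mN), .groups = "drop")
  }
  if (nrow(d) < 2) abort("need at least 2 load levels.")
  ols <- lm(friction_mN ~ load_mN, data = d)
  mu <- unname(coef(ols)[["load_mN"]])
  f0 <- unname(coef(ols)[["(Intercept)"]])
  structure(
    list(
      mu = mu, F0_mN = f0,
      F_adh_mN = if (mu > 0) f0 / mu else NA_real_,
      mu_nonpositive = mu <= 0,
      points = d, residuals = unname(stats::residuals(ols)), model = ols
    ),
    class = "friction_fit"
  )
}

#' @export
#' @method print friction_fit
print.friction_fit <- function(x, ...) {
  cat(sprintf(
    "<friction_fit> F_F = %.3g F_N + %.3g mN  (mu = %.3g, F_A = %.3g mN%s)\n",
    x$mu, x$F0_mN, x$mu, x$F_adh_mN,
    if (x$mu_nonpositive) ", mu <= 0: F_A undefined" else ""
  ))
  invisible(x)
}

#' @export
tidy.friction_fit <- function(x, ...) {
  tibble(term = c("mu", "F0_mN", "F_adh_mN"),
         estimate = c(x$mu, x$F0_mN, x$F_adh_mN))
}

#' @export
glance.friction_fit <- function(x, ...) {
  tibble(mu = x$mu, F0_mN = x$F0_mN, F_adh_mN = x$F_adh_mN,
         n = nrow(x$points))
}

#' Per-observation shear stress and constancy of the friction correction
#'
#' Divides friction by the real contact area (`tau = F_F / A_R`, converted to
#' MPa) and, when the observations carry the repeated-measures structure,
#' tests whether the corrected friction still depends on load with a Friedman
#' rank test. A shear stress that no longer varies with load means the growth
#' of real contact area fully explains the load dependence of friction.
#'
#' @param data Tibble with `friction_mN` and `A_R_um2` (plus `load_mN` and
#'   `individual_id` for the constancy test).
#' @return A list: `tau` (input tibble plus `tau_MPa`), `summary`
#'   (median +/- raw MAD of per-individual mean shear stress when the
#'   structure is present, otherwise of all observations), and `friedman`
#'   (tibble or NULL).
#' @export
shear_stress_series <- function(data) {
  d <- as_tibble(data)
  if (!all(c("friction_mN", "A_R_um2") %in% names(d))) {
    abort("`data` needs columns `friction_mN` and `A_R_um2`.")
  }
  if (any(d$A_R_um2 <= 0 & d$friction_mN > 0)) {
    abort("zero real contact area with non-zero friction.")
  }
  d$tau_MPa <- ifelse(d$A_R_um2 > 0,
                      shear_stress_mpa(d$friction_mN, d$A_R_um2), 0)
  has_structure <- all(c("load_mN", "individual_id") %in% names(d))
  friedman <- NULL
  if (has_structure) {
    wide <- d %>%
      select("individual_id", "load_mN", "tau_MPa") %>%
      tidyr::pivot_wider(names_from = "load_mN", values_from = "tau_MPa")
    mat <- as.matrix(wide[, -1])
    if (nrow(mat) >= 2 && ncol(mat) >= 2 && !anyNA(mat)) {
      friedman <- friedman_test(mat)
    }
    per_ind <- d %>%
      group_by(.data$individual_id) %>%
      summarise(tau_MPa = mean(.data$tau_MPa), .groups = "drop")
    summary <- median_mad(per_ind$tau_MPa)
  } else {
    summary <- median_mad(d$tau_MPa)
  }
  list(tau = d, summary = summary, friedman = friedman)
}

#' Apparent (load-dependent) friction coefficient of a power-law material
#'
#' For a material with constant shear stress `tau` and real contact area
#' `A_R = a * F_N^k` (a in mm^2 per mN^k), friction is `tau * a * F_N^k` and
#' the apparent friction coefficient `mu_app = F_F / F_N = tau * a *
#' F_N^(k-1)`: its log-log slope over load is `k - 1`, so any sub-linear
#' contact growth (k < 1) makes the friction coefficient fall with load.
#'
#' @param tau Shear stress, MPa.
#' @param a Contact-area prefactor, mm^2 at 1 mN.
#' @param k Contact-area scaling exponent.
#' @param F_N Normal loads, mN (> 0, vectorised).
#' @return Tibble with `load_mN`, `mu_app`, and the analytic load-scaling
#'   exponent `k - 1` as attribute `"exponent"`.
#' @export
apparent_mu <- function(tau, a, k, F_N) {
  if (any(F_N <= 0)) abort("`F_N` must be > 0.")
  mu <- mpa_to_kpa(tau) * a * F_N^(k - 1) # MPa x mm^2/mN = 1e3 dimensionless/1e3
  out <- tibble(load_mN = F_N, mu_app = mu)
  attr(out, "exponent") <- k - 1
  out
}

#' Friction coefficient of a rigid, linearly growing contact
#'
#' For rigid materials the real contact area grows linearly with load with
#' rate `C`, and the friction coefficient is the product of shear stress and
#' growth rate: `mu = tau * C` (1 MPa x 1 mm^2/mN = 1e3 mN/mm^2 x mm^2/mN,
#' dimensionless).
#'
#' @param tau Shear stress, MPa.
#' @param C Contact growth rate, mm^2/mN.
#' @return `mu`, dimensionless.
#' @export
#' @examples
#' rigid_mu(800, 1e-6) # ~0.8, steel on steel
rigid_mu <- function(tau, C) {
  if (any(tau < 0) || any(C < 0)) abort("`tau` and `C` must be >= 0.")
  mpa_to_kpa(tau) * C
}

#' Growth rate of real contact area with load
#'
#' OLS slope of real contact area (mm^2) over normal load (mN): the `C` of the
#' rigid-material friction law. Large `C` means small load changes produce
#' large contact-area changes, the route to friction coefficients above 1
#' without adhesion.
#'
#' @param data Tibble with columns `load_mN` and either `A_R_mm2` or
#'   `A_R_um2` (converted).
#' @return Slope `C` in mm^2/mN.
#' @export
growth_rate_C <- function(data) {
  d <- as_tibble(data)
  if (!"A_R_mm2" %in% names(d)) {
    if (!"A_R_um2" %in% names(d)) {
      abort("`data` needs `A_R_mm2` or `A_R_um2`.")
    }
    d$A_R_mm2 <- um2_to_mm2(d$A_R_um2)
  }
  if (nrow(d) < 2) abort("need at least 2 points.")
  unname(coef(lm(A_R_mm2 ~ load_mN, data = d))[["load_mN"]])
}

#' JKR adhesive-sphere parameters
#'
#' Parameters of the Johnson-Kendall-Roberts contact of a soft elastic sphere:
#' radius `R`, work of adhesion `W` and effective stiffness. The printed
#' "stiffness" is treated as the reduced modulus `E*`, with `K = (4/3) E*`.
#' Derived quantities: pull-off force `-(3/2) pi W R` and the zero-load
#' contact radius.
#'
#' @param R_um Sphere radius, um (> 0). Default 180, the size of a euplantula.
#' @param W_mN_per_m Work of adhesion, mN/m (>= 0). Default 60.
#' @param E_star_MPa Reduced modulus, MPa (> 0). Default 1 (a soft sphere).
#' @return A `jkr_params` list with unit-converted internals and the derived
#'   pull-off force (nN) and zero-load contact radius (um).
#' @export
jkr_params <- function(R_um = 180, W_mN_per_m = 60, E_star_MPa = 1) {
  if (R_um <= 0 || E_star_MPa <= 0) abort("`R_um` and `E_star_MPa` must be > 0.")
  if (W_mN_per_m < 0) abort("`W_mN_per_m` must be >= 0.")
  W <- W_mN_per_m # 1 mN/m = 1 nN/um
  K <- (4 / 3) * mpa_to_kpa(E_star_MPa) # nN/um^2
  pull_off <- 1.5 * pi * W * R_um # nN (magnitude)
  a0 <- ((R_um / K) * 2 * (3 * pi * W * R_um))^(1 / 3) # contact radius at F = 0
  structure(
    list(R_um = R_um, W_nN_per_um = W, K_nN_per_um2 = K,
         pull_off_nN = pull_off, zero_load_radius_um = a0),
    class = "jkr_params"
  )
}

#' @export
#' @method print jkr_params
print.jkr_params <- function(x, ...) {
  cat(sprintf(
    "<jkr_params> R = %.0f um, W = %.3g nN/um, K = %.3g nN/um^2; pull-off %.3g uN\n",
    x$R_um, x$W_nN_per_um, x$K_nN_per_um2, x$pull_off_nN / 1e3
  ))
  invisible(x)
}

#' JKR contact radius and area under load
#'
#' Closed-form JKR solution: `a^3 = (R/K) (F + 3 pi W R + sqrt(6 pi W R F +
#' (3 pi W R)^2))`, with contact area `pi a^2`. For `W = 0` this reduces to
#' the Hertz contact `a^3 = R F / K`; for `W > 0` the contact area is finite
#' at zero load and contact is lost below the pull-off force
#' `-(3/2) pi W R`.
#'
#' @param F_mN Normal loads, mN (vectorised); must be at or above pull-off.
#' @param params A [jkr_params()].
#' @return Tibble with `load_mN`, `contact_radius_um`, `contact_area_um2`,
#'   `contact_area_mm2`.
#' @export
#' @examples
#' jkr_contact(0, jkr_params()) # finite contact at zero load
jkr_contact <- function(F_mN, params = jkr_params()) {
  stopifnot(inherits(params, "jkr_params"))
  F_nN <- mn_to_nn(F_mN)
  adh <- 3 * pi * params$W_nN_per_um * params$R_um
  if (any(F_nN < -adh / 2)) {
    abort(sprintf("load below the pull-off force (-%.3g mN): contact lost.",
                  nn_to_mn(adh / 2)))
  }
  disc <- pmax(0, 2 * adh * F_nN + adh^2)
  a3 <- (params$R_um / params$K_nN_per_um2) * (F_nN + adh + sqrt(disc))
  a <- a3^(1 / 3)
  tibble(
    load_mN = F_mN,
    contact_radius_um = a,
    contact_area_um2 = pi * a^2,
    contact_area_mm2 = um2_to_mm2(pi * a^2)
  )
}

#' Adhesion per unit contact area
#'
#' @param force_nN Adhesive force, nN.
#' @param area_um2 Contact area, um^2 (> 0).
#' @return Stress in MPa (1 nN/um^2 = 1e-3 MPa).
#' @export
#' @examples
#' adhesion_per_area(10, 0.2 * 0.2) # gecko spatula: 0.25 MPa
#' adhesion_per_area(66, 0.2)       # stick-insect acantha: 0.33 MPa
adhesion_per_area <- function(force_nN, area_um2) {
  if (any(area_um2 <= 0)) abort("`area_um2` must be > 0.")
  kpa_to_mpa(force_nN / area_um2)
}

#' Material specification for the contact-growth comparison
#'
#' @param name Material label.
#' @param law `"power_law"` (A_R = a F^k), `"linear_C"` (A_R = C F) or
#'   `"jkr"`.
#' @param tau Shear stress, MPa (carried along for mu = tau C arithmetic).
#' @param C Growth rate, mm^2/mN (`linear_C`).
#' @param a,k Prefactor (mm^2 at 1 mN) and exponent (`power_law`).
#' @param jkr A [jkr_params()] (`jkr`).
#' @return A `material_spec`.
#' @export
material_spec <- function(name, law = c("power_law", "linear_C", "jkr"),
                          tau = NA_real_, C = NA_real_, a = NA_real_,
                          k = NA_real_, jkr = NULL) {
  law <- match.arg(law)
  if (law == "power_law" && (!is.finite(a) || !is.finite(k))) {
    abort("power_law materials need `a` and `k`.")
  }
  if (law == "linear_C" && !is.finite(C)) abort("linear_C materials need `C`.")
  if (law == "jkr" && !inherits(jkr, "jkr_params")) {
    abort("jkr materials need a jkr_params object.")
  }
  structure(list(name = name, law = law, tau = tau, C = C, a = a, k = k,
                 jkr = jkr),
            class = "material_spec")
}

#' Default material set: friction pad, rigid metal, soft adhesive sphere
#'
#' The stick-insect euplantula as an empirical power law (exponent 0.802,
#' prefactor from the reference means at 1 mN), finely ground steel as a
#' linear grower with `C = 1e-6 mm^2/mN` (tau ~ 800 MPa), and a JKR soft
#' sphere (R = 180 um, W = 60 mN/m, E* = 1 MPa).
#'
#' @return List of [material_spec()] objects.
#' @export
default_materials <- function() {
  ref <- reference_contact_means()
  a1 <- um2_to_mm2(ref$A_R_um2[ref$load_mN == 1])
  list(
    material_spec("euplantula", "power_law", tau = 1, a = a1, k = 0.802),
    material_spec("steel", "linear_C", tau = 800, C = 1e-6),
    material_spec("soft sphere (JKR)", "jkr", jkr = jkr_params())
  )
}

#' Real-contact-area growth curves for a set of materials
#'
#' Evaluates each material's contact-area law over a common load grid, the
#' comparison that separates friction pads (negligible area at zero load,
#' rapid growth) from rigid materials (tiny linear growth) and soft adhesives
#' (finite area at and below zero load).
#'
#' @param materials List of [material_spec()]s (default [default_materials()]).
#' @param loads Load grid, mN.
#' @return Long tibble: `material`, `law`, `load_mN`, `A_R_mm2`.
#' @export
figure9_curves <- function(materials = default_materials(),
                           loads = seq(0, 4, by = 0.05)) {
  map(materials, function(m) {
    area <- switch(
      m$law,
      power_law = m$a * loads^m$k,
      linear_C = m$C * loads,
      jkr = jkr_contact(loads, m$jkr)$contact_area_mm2
    )
    tibble(material = m$name, law = m$law, load_mN = loads, A_R_mm2 = area)
  }) %>% list_rbind()
}
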