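p_default <- make_fibril_bed(0.1, pad_geometry(1e3), seed = 1)$params

test_that("fibril response is piecewise, continuous and saturating", {
  r0 <- fibril_response(0, p_default)
  expect_equal(r0$force, 0)
  expect_equal(r0$contact_area, 0)
  expect_equal(r0$mode, "none")

  # small overlaps: circular tip contact in the reported 0.2-0.3 um^2 range
  small <- fibril_response(c(0.02, 0.1), p_default)
  expect_true(all(small$mode == "tip"))
  expect_true(all(small$aspect_ratio == 1))
  expect_true(all(small$contact_area > 0.2 & small$contact_area < 0.3))

  # far past critical: full side contact near 4 um^2, ~17-20x the minimal tip
  deep <- fibril_response(20, p_default)
  expect_equal(deep$mode, "side")
  expect_equal(deep$contact_area, 4, tolerance = 1e-9)
  expect_equal(deep$aspect_ratio, 4.5, tolerance = 1e-9)
  ratio <- deep$contact_area / p_default$tip_area_min
  expect_gt(ratio, 17)
  expect_lt(ratio, 21)

  # continuity of force and area at the tip->side transition
  crit <- p_default$critical_side_overlap
  lo <- fibril_response(crit - 1e-9, p_default)
  hi <- fibril_response(crit + 1e-9, p_default)
  expect_equal(lo$force, hi$force, tolerance = 1e-6)
  expect_equal(lo$contact_area, hi$contact_area, tolerance = 1e-6)
  expect_equal(lo$aspect_ratio, hi$aspect_ratio, tolerance = 1e-6)

  # monotone in overlap
  ovs <- seq(0, 5, by = 0.01)
  resp <- fibril_response(ovs, p_default)
  expect_true(all(diff(resp$force) >= 0))
  expect_true(all(diff(resp$contact_area) >= -1e-12))

  expect_error(fibril_response(-0.1, p_default), ">= 0")
})

test_that("shear bias lowers the effective critical overlap", {
  crit <- p_default$critical_side_overlap
  ov <- crit * 0.8 # tip mode without shear
  expect_equal(fibril_response(ov, p_default)$mode, "tip")
  expect_equal(fibril_response(ov, p_default, shear_bias = 0.4)$mode, "side")
})

test_that("zero load gives an empty contact", {
  st <- solve_indentation(small_bed(), load = 0)
  expect_equal(st$n_contact, 0)
  expect_equal(st$delta, 0)
  expect_equal(st$A_R_um2, 0)
})

test_that("a coplanar flat bed matches the analytic spring-bank limit", {
  bed <- flat_bed(n_target = 50)
  n <- nrow(bed$fibrils)
  k <- bed$params$axial_stiffness
  F_mN <- 0.001 # all-tip regime: delta = F / (n k)
  st <- solve_indentation(bed, load = F_mN)
  expect_equal(st$delta, F_mN * 1e6 / (n * k), tolerance = 1e-5)
  expect_equal(st$n_contact, n)
  expect_true(all(st$fibrils$mode == "tip"))
})

test_that("the solver balances forces and matches a brute-force scan", {
  # oracle: fine grid over delta on small beds
  for (seed in 1:3) {
    bed <- make_fibril_bed(0.1, pad_geometry(200, 8000),
                           tip_height_sd = 0.4, seed = seed)
    expect_lte(nrow(bed$fibrils), 20)
    load <- 0.002
    st <- solve_indentation(bed, load = load)
    expect_lt(abs(st$force_residual_nN), max(1e-3, 1e-6 * load * 1e6))

    gap <- st$fibrils$gap
    p <- bed$params
    grid <- seq(0, max(gap) + 3, by = 1e-4)
    total <- vapply(grid, function(d) {
      ov <- d - gap
      sum(p$axial_stiffness * pmin(ov[ov > 0], p$critical_side_overlap)) +
        sum(p$side_stiffness_ratio * p$axial_stiffness *
              pmax(ov[ov > 0] - p$critical_side_overlap, 0))
    }, numeric(1))
    d_oracle <- grid[which.min(abs(total - load * 1e6))]
    expect_equal(st$delta, d_oracle, tolerance = 2e-4)
  }
})

test_that("indentation depth increases strictly with load", {
  bed <- small_bed()
  deltas <- vapply(c(0.005, 0.01, 0.02, 0.05, 0.1),
                   function(l) solve_indentation(bed, load = l)$delta,
                   numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("the hierarchical identity holds by construction on solved states", {
  st <- solve_indentation(small_bed(), load = 0.05)
  expect_equal(st$A_R_um2, st$A_A_um2 * st$N_A_per_um2 * st$A_Ac_um2,
               tolerance = 1e-9)
  expect_equal(st$A_R_um2, sum(st$fibrils$contact_area), tolerance = 1e-9)
})

test_that("the default calibrated bed reproduces the study-scale sweep", {
  bed <- make_fibril_bed(0.15, pad_geometry(1e5, 16000),
                         tip_height_sd = 0.3, seed = 1)
  sw <- sweep_loads(bed, loads = c(0.2, 0.5, 1, 2, 4))

  # projected area can never exceed the pad footprint ceiling
  expect_true(all(sw$A_A_mm2 <= 0.1 + 1e-12))

  # all three scaling exponents strictly between 0 and 1
  slopes <- vapply(c("A_A_mm2", "N_A_per_um2", "A_Ac_um2"), function(col) {
    unname(coef(lm(log10(sw[[col]]) ~ log10(sw$load_mN)))[2])
  }, numeric(1))
  expect_true(all(slopes > 0 & slopes < 1))

  # an order of magnitude of real-contact-area growth over the load range
  expect_gte(sw$A_R_um2[5] / sw$A_R_um2[1], 10)

  # monotone loading: every observable non-decreasing
  for (col in c("A_A_mm2", "N_A_per_um2", "A_Ac_um2", "A_R_um2")) {
    expect_true(all(diff(sw[[col]]) >= 0), info = col)
  }
})

test_that("loading is reversible: descending sweep retraces ascending states", {
  bed <- small_bed()
  up <- sweep_loads(bed, loads = c(0.01, 0.02, 0.05))
  down <- sweep_loads(bed, loads = c(0.01, 0.02, 0.05))[3:1, ]
  expect_equal(up$A_R_um2, rev(down$A_R_um2))
  expect_equal(up$delta_um, rev(down$delta_um))
})

test_that("shear promotes side contact without losing contact area", {
  bed <- small_bed(density = 0.15, footprint = 2e3, seed = 9)
  st <- solve_indentation(bed, load = 0.1)
  expect_identical(apply_shear(st, bed, F_S = 0), st)

  sheared <- apply_shear(st, bed, F_S = 2, direction = pi / 4)
  n_side <- function(s) sum(s$fibrils$mode == "side")
  expect_gte(n_side(sheared), n_side(st))
  expect_gte(sheared$A_R_um2, st$A_R_um2)

  # reversing the direction flips orientations, leaves areas untouched
  reversed <- apply_shear(st, bed, F_S = 2, direction = pi / 4 + pi)
  side <- sheared$fibrils$mode == "side"
  expect_equal(sheared$fibrils$contact_area, reversed$fibrils$contact_area)
  expect_equal(reversed$fibrils$orientation[side],
               sheared$fibrils$orientation[side] + pi)
})

test_that("contact states tidy into one-row aggregate summaries", {
  st <- solve_indentation(small_bed(), load = 0.05)
  td <- generics::tidy(st)
  expect_equal(nrow(td), 1)
  expect_named(td, c("load_mN", "delta_um", "n_contact", "A_A_mm2",
                     "N_A_per_um2", "A_Ac_um2", "A_R_um2", "saturated"))
  expect_equal(td$n_contact, st$n_contact)
})
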