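#' Per-fibril contact response
#'
#' Piecewise constitutive law of a single conical fibril pressed by `overlap`
#' (reduction of its free length, um). Up to the critical overlap the fibril is
#' in tip mode: a linear axial spring with a circular contact patch growing
#' from the minimal tip area to the fully compressed tip cap. Past the critical
#' overlap it bends into side mode: the patch elongates (minor axis fixed at
#' the tip-cap diameter) with its length linear in the post-critical overlap,
#' the aspect ratio rising continuously from 1 toward 4.5 and the area
#' saturating at the full-side maximum (~4 um^2, roughly 20x the minimal tip
#' contact); the tangent stiffness drops to `side_stiffness_ratio` of the
#' axial one. Force and area are continuous at the transition; the tapered
#' cone geometry is taken to preclude sudden Euler buckling, so there is no
#' instability anywhere. A positive `shear_bias` lowers the effective critical
#' overlap, biasing fibrils toward side contact.
#'
#' @param overlap Non-negative overlaps, um (vectorised).
#' @param params Fibril parameter block (see [make_fibril_bed()]).
#' @param shear_bias Dimensionless in \[0, 1); fraction by which the critical
#'   overlap is reduced.
#' @return Tibble with `force` (nN), `contact_area` (um^2), `aspect_ratio`,
#'   `mode` (`"none"`, `"tip"` or `"side"`).
#' @export
#' @examples
#' p <- make_fibril_bed(0.1, pad_geometry(1e3), seed = 1)$params
#' fibril_response(c(0, 0.1, 2), p)
fibril_response <- function(overlap, params, shear_bias = 0) {
  if (any(overlap < 0)) abort("`overlap` must be >= 0.")
  if (shear_bias < 0 || shear_bias >= 1) abort("`shear_bias` must be in [0, 1).")
  crit <- params$critical_side_overlap * (1 - shear_bias)
  geom <- fibril_patch_geometry(overlap, params, crit)
  tibble(
    force = fibril_force(overlap, params, crit),
    contact_area = geom$area,
    aspect_ratio = geom$aspect,
    mode = geom$mode
  )
}

# Fast numeric force law used inside the indentation solver.
fibril_force <- function(ov, p, crit) {
  k <- p$axial_stiffness
  ifelse(ov <= crit, k * ov, k * crit + p$side_stiffness_ratio * k * (ov - crit))
}

fibril_patch_geometry <- function(ov, p, crit) {
  tip <- ov > 0 & ov <= crit
  side <- ov > crit
  area <- numeric(length(ov))
  aspect <- rep(1, length(ov))
  area[tip] <- p$tip_area_min +
    (p$tip_cap_area - p$tip_area_min) * ov[tip] / crit
  excess <- (ov[side] - crit) / p$side_span
  area[side] <- pmin(p$tip_cap_area +
                       (p$side_area_max - p$tip_cap_area) * excess,
                     p$side_area_max)
  aspect[side] <- pmin(1 + (p$aspect_max - 1) * excess, p$aspect_max)
  mode <- rep("none", length(ov))
  mode[tip] <- "tip"
  mode[side] <- "side"
  list(area = area, aspect = aspect, mode = mode)
}

#' Solve the indentation of a fibril bed under normal load
#'
#' Greenwood-Williamson-style solve: the rigid convex pad envelope descends by
#' delta; a fibril engages once the descent exceeds its local envelope gap
#' (parabolic dome sag at its radius plus its tip-height offset), and the
#' per-fibril forces follow [fibril_response()]. delta is found by monotone
#' bisection until the summed fibril force balances the applied normal load
#' (relative tolerance 1e-6 or 1e-3 nN absolute). Fibrils whose gap equals the
#' descent within 1e-12 um count as contacting.
#'
#' @param bed A `fibril_bed`.
#' @param pad A [pad_geometry()]; defaults to the bed's own pad.
#' @param load Normal load, mN (>= 0). Alternatively a list with elements
#'   `F_N`, `F_S`, `shear_direction` (a load step).
#' @param shear_bias Dimensionless side-contact bias (see [fibril_response()]).
#' @param shear_direction Radians; orientation imposed on side-contact patches
#'   when a shear bias is applied. Without shear, side patches orient radially
#'   (bending away from the pad apex).
#' @return A `contact_state`: per-fibril tibble (mode, contact area, aspect
#'   ratio, orientation, normal force) plus the aggregates `A_A` (projected
#'   area, convex hull of patch footprints), `N_A` (contacting density),
#'   `A_Ac` (mean per-fibril area), `A_R = A_A * N_A * A_Ac`, the indentation
#'   `delta` and a saturation flag (projected area at the footprint ceiling).
#' @export
solve_indentation <- function(bed, pad = bed$pad, load,
                              shear_bias = 0, shear_direction = NULL) {
  stopifnot(inherits(bed, "fibril_bed"), inherits(pad, "pad_geometry"))
  if (is.list(load)) {
    step <- load
    load <- step$F_N
    shear_direction <- shear_direction %||% step$shear_direction
  }
  if (!is.numeric(load) || length(load) != 1 || load < 0) {
    abort("`load` must be a single non-negative normal load in mN.")
  }
  p <- bed$params
  crit <- p$critical_side_overlap * (1 - shear_bias)
  f <- bed$fibrils
  r2 <- (f$x - pad$apex[1])^2 + (f$y - pad$apex[2])^2
  gap <- r2 / (2 * pad$dome_radius) + f$tip_offset

  target <- mn_to_nn(load)
  tol <- max(1e-3, 1e-6 * target)
  total_force <- function(delta) {
    ov <- delta - gap
    sum(fibril_force(ov[ov > 0], p, crit))
  }

  if (target == 0) {
    delta <- 0
  } else {
    lo <- 0
    hi <- min(gap) + target / (p$axial_stiffness * p$side_stiffness_ratio) + 1
    while (total_force(hi) < target) hi <- hi * 2
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      fm <- total_force(mid)
      if (abs(fm - target) <= tol) break
      if (fm < target) lo <- mid else hi <- mid
    }
    delta <- mid
  }

  ov <- pmax(0, delta - gap)
  contact <- (delta - gap) >= -1e-12 & delta > 0
  ov[!contact] <- 0
  geom <- fibril_patch_geometry(ov, p, crit)
  orientation <- atan2(f$y - pad$apex[2], f$x - pad$apex[1])
  orientation[!is.finite(orientation)] <- 0
  if (!is.null(shear_direction)) {
    orientation[geom$mode == "side"] <- shear_direction
  }
  orientation[geom$mode != "side"] <- 0

  fib <- tibble(
    x = f$x, y = f$y, tip_offset = f$tip_offset, gap = gap, overlap = ov,
    mode = geom$mode, contact_area = geom$area, aspect_ratio = geom$aspect,
    orientation = orientation,
    normal_force = fibril_force(ov, p, crit) * (ov > 0)
  )
  new_contact_state(fib, bed, pad, delta, load,
                   shear_bias = shear_bias,
                   force_residual = sum(fib$normal_force) - target)
}

new_contact_state <- function(fib, bed, pad, delta, load, shear_bias = 0,
                              force_residual = 0) {
  touching <- filter(fib, .data$mode != "none")
  n_c <- nrow(touching)
  A_A <- hull_area_patches(touching)
  N_A <- if (A_A > 0) n_c / A_A else 0
  A_Ac <- if (n_c > 0) mean(touching$contact_area) else 0
  state <- structure(
    list(
      fibrils = fib, delta = delta, load_mN = load, shear_bias = shear_bias,
      n_contact = n_c,
      A_A_um2 = A_A, A_A_mm2 = um2_to_mm2(A_A),
      N_A_per_um2 = N_A, A_Ac_um2 = A_Ac,
      A_R_um2 = A_A * N_A * A_Ac,
      saturated = A_A >= 0.98 * pad$footprint_area,
      force_residual_nN = force_residual,
      pad = pad
    ),
    class = "contact_state"
  )
  state
}

# Convex hull area (um^2) over the footprints of contact patches: each
# elliptical patch contributes its centre displaced to the four axis
# extremes, so the hull encloses the patches, not just their centres.
hull_area_patches <- function(touching) {
  if (nrow(touching) < 3) return(0)
  a <- sqrt(touching$contact_area * touching$aspect_ratio / pi)
  b <- sqrt(touching$contact_area / (pi * touching$aspect_ratio))
  ct <- cos(touching$orientation); st <- sin(touching$orientation)
  px <- c(touching$x + a * ct, touching$x - a * ct,
          touching$x - b * st, touching$x + b * st)
  py <- c(touching$y + a * st, touching$y - a * st,
          touching$y + b * ct, touching$y - b * ct)
  h <- grDevices::chull(px, py)
  polygon_area(px[h], py[h])
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @export
#' @method print contact_state
print.contact_state <- function(x, ...) {
  cat(sprintf(
    paste0("<contact_state> F_N = %.3g mN, delta = %.3g um: %d contacts, ",
           "A_A = %.3g mm^2, N_A = %.3g /um^2, A_Ac = %.3g um^2, A_R = %.3g um^2%s\n"),
    x$load_mN, x$delta, x$n_contact, x$A_A_mm2, x$N_A_per_um2, x$A_Ac_um2,
    x$A_R_um2, if (x$saturated) " [saturated]" else ""
  ))
  invisible(x)
}

#' @export
as_tibble.contact_state <- function(x, ...) x$fibrils

#' @export
tidy.contact_state <- function(x, ...) {
  tibble(
    load_mN = x$load_mN, delta_um = x$delta, n_contact = x$n_contact,
    A_A_mm2 = x$A_A_mm2, N_A_per_um2 = x$N_A_per_um2, A_Ac_um2 = x$A_Ac_um2,
    A_R_um2 = x$A_R_um2, saturated = x$saturated
  )
}

#' Apply a shear force to a solved contact state
#'
#' Shear increases the compliance of the fibrils and their tendency to make
#' side contact; it is modelled as a bias that lowers the effective tip-to-side
#' critical overlap, after which the indentation is re-solved at the same
#' normal load. Side-contact patches align with the shear direction; reversing
#' the direction rotates the patch orientations by pi without changing any
#' area. The real contact area is non-decreasing in the shear magnitude.
#'
#' @param state A `contact_state` from [solve_indentation()].
#' @param bed The `fibril_bed` the state was solved on.
#' @param F_S Shear force magnitude, mN (>= 0).
#' @param direction Shear direction, radians.
#' @param coupling Bias per mN of shear (dimensionless/mN); the bias is capped
#'   at 0.8.
#' @return A new `contact_state`.
#' @export
apply_shear <- function(state, bed, F_S, direction = 0, coupling = 0.1) {
  stopifnot(inherits(state, "contact_state"))
  if (F_S < 0) abort("`F_S` must be >= 0 (mN).")
  if (F_S == 0) return(state)
  bias <- min(coupling * F_S, 0.8)
  solve_indentation(bed, state$pad, state$load_mN,
                    shear_bias = bias, shear_direction = direction)
}

#' Sweep a fibril bed over a series of normal loads
#'
#' Solves the indentation independently at each load (the model is elastic and
#' reversible: unloading retraces the same states) and returns one observation
#' row per load in the shared observation schema.
#'
#' @param bed A `fibril_bed`.
#' @param pad A [pad_geometry()]; defaults to the bed's own.
#' @param loads Sorted ascending normal loads, mN.
#' @param shear_bias Optional side-contact bias applied at every load.
#' @return Tibble with columns `load_mN`, `A_A_mm2`, `N_A_per_um2`, `A_Ac_um2`,
#'   `A_R_um2`, `delta_um`, `n_contact`, `saturated`.
#' @export
sweep_loads <- function(bed, pad = bed$pad, loads = c(0.2, 0.5, 1, 2, 4),
                        shear_bias = 0) {
  if (is.unsorted(loads)) abort("`loads` must be sorted ascending.")
  map(loads, function(l) {
    tidy(solve_indentation(bed, pad, l, shear_bias = shear_bias))
  }) %>%
    list_rbind() %>%
    select("load_mN", "A_A_mm2", "N_A_per_um2", "A_Ac_um2", "A_R_um2",
           delta_um = "delta_um", "n_contact", "saturated")
}

#' Simulate a full population sweep into an observation table
#'
#' Runs [sweep_loads()] on every bed of a [make_population()] draw and attaches
#' synthetic friction (constant shear stress plus noise), yielding the shared
#' per-individual, per-load observation schema consumed by the statistics
#' modules.
#'
#' @param params A [synth_params()].
#' @return Tibble of pad observations; the population's ground-truth
#'   per-individual multipliers are attached as attribute `"individuals"`.
#' @export
simulate_pad_observations <- function(params = synth_params()) {
  pop <- make_population(params)
  obs <- imap(pop$beds, function(bed, i) {
    sweep_loads(bed, loads = params$loads) %>%
      mutate(individual_id = pop$individuals$individual_id[i], .before = 1)
  }) %>% list_rbind()
  obs <- obs %>%
    mutate(friction_mN = synth_friction(
      .data$A_R_um2, tau = params$tau_true,
      noise_sd = params$friction_noise_sd, seed = params$seed + 500L
    ))
  attr(obs, "individuals") <- pop$individuals
  obs
}
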