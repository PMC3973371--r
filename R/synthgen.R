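#' Pad envelope geometry
#'
#' The pad is modelled as a rigid convex spherical-cap envelope over the
#' fibril bed. Its curvature drives the growth of projected contact area
#' with load; its footprint caps the projected area a sweep can reach
#' (around 0.1 mm^2 for a pair of euplantulae).
#'
#' @param footprint_area Pad surface (footprint) area in square micrometres;
#'   must be positive and, by default, at most `1e5` (0.1 mm^2).
#' @param dome_radius Radius of curvature of the pad envelope, micrometres.
#' @param apex Numeric length-2, (x, y) position of the pad apex, micrometres.
#' @param footprint_ceiling Upper bound enforced on `footprint_area`.
#' @return A `pad_geometry` object.
#' @export
#' @examples
#' pad_geometry(footprint_area = 1e5, dome_radius = 16000)
pad_geometry <- function(footprint_area = 1e5,
                         dome_radius = 16000,
                         apex = c(0, 0),
                         footprint_ceiling = 1e5) {
  if (!is.numeric(footprint_area) || footprint_area <= 0) {
    abort("`footprint_area` must be a positive number (um^2).")
  }
  if (footprint_area > footprint_ceiling) {
    abort(sprintf(
      "`footprint_area` (%.3g um^2) exceeds the pad surface ceiling of %.3g um^2.",
      footprint_area, footprint_ceiling
    ))
  }
  if (!is.numeric(dome_radius) || dome_radius <= 0) {
    abort("`dome_radius` must be positive (um).")
  }
  structure(
    list(
      footprint_area = footprint_area,
      dome_radius = dome_radius,
      apex = as.numeric(apex),
      footprint_radius = sqrt(footprint_area / pi)
    ),
    class = "pad_geometry"
  )
}

#' @export
#' @method print pad_geometry
print.pad_geometry <- function(x, ...) {
  cat(sprintf(
    "<pad_geometry> footprint %.3g um^2 (radius %.1f um), dome radius %.0f um\n",
    x$footprint_area, x$footprint_radius, x$dome_radius
  ))
  invisible(x)
}

# Mechanical and geometric defaults of a single conical acantha.
# Tapered cone of aspect ratio ~5 (length / basal diameter); the rounded
# tip gives a minimal circular contact of ~0.21 um^2, full tip-cap
# compression reaches side_area_max / aspect_max (so that the elongating
# side patch, minor axis fixed at the tip-cap diameter, saturates at
# 4 um^2 exactly when the aspect ratio reaches 4.5).
default_fibril_params <- function() {
  list(
    fibril_length = 5,            # um
    base_radius = 0.5,            # um -> length/(2*base_radius) = 5
    tip_radius = 0.255,           # um
    tip_area_min = pi * 0.255^2,  # ~0.204 um^2: full side contact is ~20x this
    side_area_max = 4,            # um^2, full-length side contact
    aspect_max = 4.5,             # patch major/minor axis ceiling
    tip_cap_area = 4 / 4.5,       # um^2, fully compressed tip cap
    axial_stiffness = 700,        # nN/um, tip-mode spring constant
    side_stiffness_ratio = 0.3,   # tangent stiffness ratio past the transition
    critical_side_overlap = 0.75, # um, tip->side transition overlap
    side_span = 2                 # um of post-critical overlap to full side contact
  )
}

#' Generate a fibril bed under a curved pad
#'
#' Places conical fibrils (acanthae) on a jittered hexagonal lattice inside
#' the pad footprint and draws per-fibril tip-height offsets from a
#' zero-truncated (half-) normal distribution, emulating the non-coplanar
#' acantha tips of the euplantula. The hexagonal lattice is the maximum-density
#' packing consistent with the SEM areal-density ceiling of 0.19 per um^2;
#' pure Poisson placement is available but can produce unphysical overlaps.
#'
#' Exactly `round(density * footprint_area)` sites are kept (those closest to
#' the apex), so the realised density matches the request up to rounding; the
#' outermost sites may overhang the nominal footprint disc by up to one
#' lattice spacing.
#'
#' @param density Areal fibril density, per square micrometre; must lie in
#'   (0, 0.19], the ceiling measured from SEM images.
#' @param pad A [pad_geometry()].
#' @param tip_height_sd Standard deviation (um) of the parent normal behind the
#'   zero-truncated tip-height offsets. `0` gives a coplanar bed.
#' @param seed Integer seed; the bed is a pure function of it.
#' @param jitter Positional jitter as a fraction of the lattice spacing
#'   (uniform in a square), default 0.35.
#' @param placement `"hex"` (default) or `"poisson"` (uniform random).
#' @param fibril_params Optional overrides of the per-fibril mechanical
#'   parameters (see `default_fibril_params` internals).
#' @return A `fibril_bed` object: tibble of positions and tip offsets plus the
#'   fibril parameter block and the pad.
#' @export
#' @examples
#' bed <- make_fibril_bed(0.1, pad_geometry(2e3), tip_height_sd = 0.3, seed = 1)
#' nrow(bed$fibrils)
make_fibril_bed <- function(density, pad, tip_height_sd = 0.3, seed = 1,
                            jitter = 0.35,
                            placement = c("hex", "poisson"),
                            fibril_params = list()) {
  placement <- match.arg(placement)
  if (!inherits(pad, "pad_geometry")) abort("`pad` must be a pad_geometry object.")
  if (!is.numeric(density) || density <= 0) abort("`density` must be positive.")
  if (density > 0.19) {
    abort(sprintf(
      "`density` = %.3g per um^2 exceeds the SEM ceiling of 0.19 per um^2.",
      density
    ))
  }
  if (tip_height_sd < 0) abort("`tip_height_sd` must be >= 0.")
  params <- modifyList(default_fibril_params(), fibril_params)

  n_target <- max(1L, round(density * pad$footprint_area))

  pos <- local_seed(seed, {
    if (placement == "hex") {
      # lattice spacing for the requested density: site area s^2 * sqrt(3)/2
      s <- sqrt(2 / (sqrt(3) * density))
      half_extent <- pad$footprint_radius + 3 * s
      i <- seq(-ceiling(half_extent / s), ceiling(half_extent / s))
      j <- seq(-ceiling(half_extent / (s * sqrt(3) / 2)),
               ceiling(half_extent / (s * sqrt(3) / 2)))
      grid <- expand.grid(i = i, j = j)
      x <- grid$i * s + (grid$j %% 2) * s / 2
      y <- grid$j * s * sqrt(3) / 2
      r2 <- x^2 + y^2
      keep <- order(r2)[seq_len(n_target)]
      x <- x[keep] + runif(n_target, -jitter * s / 2, jitter * s / 2)
      y <- y[keep] + runif(n_target, -jitter * s / 2, jitter * s / 2)
      tibble(x = x + pad$apex[1], y = y + pad$apex[2])
    } else {
      r <- pad$footprint_radius * sqrt(runif(n_target))
      th <- runif(n_target, 0, 2 * pi)
      tibble(x = pad$apex[1] + r * cos(th), y = pad$apex[2] + r * sin(th))
    }
  })

  offsets <- local_seed(seed + 1L, {
    if (tip_height_sd == 0) rep(0, n_target) else abs(rnorm(n_target, 0, tip_height_sd))
  })

  bed <- structure(
    list(
      fibrils = mutate(pos, tip_offset = offsets),
      params = params,
      pad = pad,
      density = density,
      tip_height_sd = tip_height_sd,
      seed = seed,
      placement = placement
    ),
    class = "fibril_bed"
  )
  validate_fibril_bed(bed)
  bed
}

validate_fibril_bed <- function(bed) {
  f <- bed$fibrils
  if (any(!is.finite(f$tip_offset)) || any(f$tip_offset < 0)) {
    abort("tip offsets must be finite and >= 0.")
  }
  realised <- nrow(f) / bed$pad$footprint_area
  if (realised > 0.19 * 1.02) {
    abort("realised fibril density exceeds the 0.19 per um^2 ceiling.")
  }
  aspect <- bed$params$fibril_length / (2 * bed$params$base_radius)
  if (abs(aspect - 5) > 2) {
    warn(sprintf("fibril aspect ratio %.1f far from the conical ~5 of acanthae.", aspect))
  }
  s <- sqrt(2 / (sqrt(3) * bed$density))
  r_max <- sqrt(max((f$x - bed$pad$apex[1])^2 + (f$y - bed$pad$apex[2])^2))
  if (r_max > bed$pad$footprint_radius + s + 1e-9) {
    abort("fibril positions fall outside the pad footprint.")
  }
  invisible(bed)
}

#' @export
#' @method print fibril_bed
print.fibril_bed <- function(x, ...) {
  cat(sprintf(
    "<fibril_bed> %d fibrils, density %.3f /um^2, tip-height sd %.2f um (%s placement)\n",
    nrow(x$fibrils), x$density, x$tip_height_sd, x$placement
  ))
  invisible(x)
}

#' Synthesis parameters for a study-like population
#'
#' Defaults emulate the study design: 10 individuals, normal loads of
#' 0.2, 0.5, 1, 2 and 4 mN, a shear stress of 1 MPa behind the friction
#' traces, and multiplicative (log-normal) between-individual variation.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param loads Strictly positive, sorted normal loads, mN.
#' @param density Mean areal fibril density, per um^2.
#' @param tip_height_sd Mean tip-height sd, um.
#' @param dome_radius Mean pad dome radius, um.
#' @param footprint_area Pad footprint, um^2.
#' @param tau_true Ground-truth shear stress, MPa.
#' @param friction_noise_sd Additive friction noise, mN.
#' @param individual_jitter Fractional (log-normal) sd applied to per-individual
#'   bed parameters.
#' @param seed Integer seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_individuals = 10,
                         loads = c(0.2, 0.5, 1, 2, 4),
                         density = 0.15,
                         tip_height_sd = 0.3,
                         dome_radius = 16000,
                         footprint_area = 1e5,
                         tau_true = 1,
                         friction_noise_sd = 0.5,
                         individual_jitter = 0.15,
                         seed = 1) {
  if (n_individuals < 1) abort("`n_individuals` must be >= 1.")
  if (any(loads <= 0)) abort("`loads` must be strictly positive (mN).")
  if (is.unsorted(loads, strictly = TRUE)) abort("`loads` must be sorted ascending.")
  if (tip_height_sd < 0 || friction_noise_sd < 0 || individual_jitter < 0) {
    abort("standard deviations must be >= 0.")
  }
  if (tau_true < 0) abort("`tau_true` must be >= 0.")
  structure(
    list(
      n_individuals = as.integer(n_individuals), loads = loads,
      density = density, tip_height_sd = tip_height_sd,
      dome_radius = dome_radius, footprint_area = footprint_area,
      tau_true = tau_true, friction_noise_sd = friction_noise_sd,
      individual_jitter = individual_jitter, seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

#' Generate a population of fibril beds with repeated-measures structure
#'
#' Draws one bed per individual, with bed parameters varied multiplicatively
#' (log-normal) around the shared means by `individual_jitter`. The
#' per-individual multipliers are returned as ground truth so that mixed-model
#' recovery (random-intercept variance) can be tested against the generator.
#'
#' @param params A [synth_params()] object.
#' @return A list with `beds` (list of `fibril_bed`) and `individuals`
#'   (tibble of per-individual parameter multipliers and realised values).
#' @export
make_population <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n_individuals
  mult <- local_seed(params$seed, {
    tibble(
      individual_id = sprintf("ind%02d", seq_len(n)),
      density_mult = exp(rnorm(n, 0, params$individual_jitter)),
      height_mult = exp(rnorm(n, 0, params$individual_jitter)),
      dome_mult = exp(rnorm(n, 0, params$individual_jitter)),
      stiffness_mult = exp(rnorm(n, 0, params$individual_jitter))
    )
  })
  beds <- map(seq_len(n), function(i) {
    dens <- min(params$density * mult$density_mult[i], 0.19)
    make_fibril_bed(
      density = dens,
      pad = pad_geometry(params$footprint_area,
                         params$dome_radius * mult$dome_mult[i]),
      tip_height_sd = params$tip_height_sd * mult$height_mult[i],
      seed = params$seed + 100L + i,
      fibril_params = list(
        axial_stiffness = default_fibril_params()$axial_stiffness *
          mult$stiffness_mult[i]
      )
    )
  })
  mult$density <- map_dbl(beds, "density")
  mult$tip_height_sd <- map_dbl(beds, "tip_height_sd")
  list(beds = beds, individuals = mult)
}

#' Render a synthetic contact image from a contact state
#'
#' Draws each contacting fibril as a bright filled ellipse (area, aspect ratio
#' and orientation taken from the state) on a dark background, with a Gaussian
#' edge blur standing in for the finite optical resolution, plus optional
#' Gaussian intensity noise. Emulates reflected-light contact images, with
#' ground truth known exactly.
#'
#' @param state A `contact_state` (from [solve_indentation()]) or a tibble of
#'   patches with columns `x`, `y` (um), `contact_area` (um^2), `aspect_ratio`,
#'   `orientation` (radians).
#' @param pixel_scale Micrometres per pixel; default 0.05 resolves the smallest
#'   reported contacts (~3 px per optical resolution element).
#' @param noise_sd Intensity noise sd (image intensities are in \[0, 1\]).
#' @param seed Seed for the noise.
#' @param pad_px Margin around the patch bounding box, px.
#' @param blur_sigma Edge blur sd in px (default 1, a ~2 px soft edge).
#' @return A `contact_image`: intensity matrix, `pixel_scale`, origin and
#'   run metadata (including a warning flag when a patch covers < 4 px).
#' @export
render_contact_image <- function(state, pixel_scale = 0.05, noise_sd = 0,
                                 seed = 1, pad_px = 8, blur_sigma = 1) {
  if (pixel_scale <= 0) abort("`pixel_scale` must be positive (um/px).")
  patches <- if (inherits(state, "contact_state")) {
    filter(state$fibrils, .data$mode != "none")
  } else {
    as_tibble(state)
  }
  meta <- list(pixel_scale = pixel_scale, noise_sd = noise_sd, seed = seed,
               n_patches = nrow(patches), warnings = character())

  if (nrow(patches) == 0) {
    img <- matrix(0, nrow = 64, ncol = 64)
    return(structure(list(intensity = img, pixel_scale = pixel_scale,
                          origin = c(0, 0), metadata = meta),
                     class = "contact_image"))
  }
  need <- c("x", "y", "contact_area", "aspect_ratio", "orientation")
  if (!all(need %in% names(patches))) {
    abort(paste("patch table needs columns:", paste(need, collapse = ", ")))
  }
  a <- sqrt(patches$contact_area * patches$aspect_ratio / pi) # major semi-axis, um
  b <- sqrt(patches$contact_area / (pi * patches$aspect_ratio))
  if (any(patches$contact_area / pixel_scale^2 < 4)) {
    meta$warnings <- c(meta$warnings,
                       "some patches cover fewer than 4 px at this pixel_scale")
  }
  x0 <- min(patches$x - a) - pad_px * pixel_scale
  y0 <- min(patches$y - a) - pad_px * pixel_scale
  nx <- ceiling((max(patches$x + a) - x0) / pixel_scale) + pad_px
  ny <- ceiling((max(patches$y + a) - y0) / pixel_scale) + pad_px
  img <- matrix(0, nrow = nx, ncol = ny) # row ~ x, col ~ y

  px_x <- (seq_len(nx) - 0.5) * pixel_scale + x0
  px_y <- (seq_len(ny) - 0.5) * pixel_scale + y0
  for (k in seq_len(nrow(patches))) {
    ix <- which(abs(px_x - patches$x[k]) <= a[k] + pixel_scale)
    iy <- which(abs(px_y - patches$y[k]) <= a[k] + pixel_scale)
    if (!length(ix) || !length(iy)) next
    dx <- outer(px_x[ix] - patches$x[k], rep(1, length(iy)))
    dy <- outer(rep(1, length(ix)), px_y[iy] - patches$y[k])
    ct <- cos(patches$orientation[k]); st <- sin(patches$orientation[k])
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    inside <- (u / a[k])^2 + (v / b[k])^2 <= 1
    img[ix, iy][inside] <- 1
  }
  if (blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  }
  if (noise_sd > 0) {
    img <- img + local_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                         nrow = nrow(img)))
  }
  img <- pmin(pmax(img, 0), 1)
  structure(
    list(intensity = img, pixel_scale = pixel_scale, origin = c(x0, y0),
         metadata = meta),
    class = "contact_image"
  )
}

#' @export
#' @method print contact_image
print.contact_image <- function(x, ...) {
  cat(sprintf("<contact_image> %d x %d px at %.3g um/px (%d patches)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_scale,
              x$metadata$n_patches))
  invisible(x)
}

#' Synthesize friction forces from real contact areas
#'
#' Constant-shear-stress model: `F_F = tau * A_R` plus optional Gaussian noise,
#' with the unit convention 1 MPa x 1 um^2 = 1e3 nN (so F_F in mN is
#' `tau * A_R * 1e-3`).
#'
#' @param a_r_um2 Real contact areas, um^2 (>= 0).
#' @param tau Shear stress, MPa (>= 0).
#' @param noise_sd Additive noise sd, mN.
#' @param seed Seed for the noise.
#' @return Friction forces, mN.
#' @export
#' @examples
#' synth_friction(6.15e3, tau = 1, noise_sd = 0) # 6.15 mN
synth_friction <- function(a_r_um2, tau = 1, noise_sd = 0, seed = 1) {
  if (tau < 0) abort("`tau` must be >= 0 (MPa).")
  if (any(a_r_um2 < 0)) abort("real contact areas must be >= 0.")
  f <- nn_to_mn(mpa_to_kpa(tau) * a_r_um2)
  if (noise_sd > 0) {
    f <- f + local_seed(seed, rnorm(length(f), 0, noise_sd))
  }
  f
}

#' Generate a power-law benchmark observation table
#'
#' Phenomenological counterpart of the mechanistic simulator: each contact-area
#' response is generated as `prefactor * F_N^k * 10^(b_i + e)` with a
#' per-individual log10 offset `b_i ~ N(0, individual_sd)` and log10 noise
#' `e ~ N(0, noise_sd)`, so the generating exponents and variance components
#' are known exactly. `A_R` is composed from the three levels via the
#' hierarchical identity and friction is added with [synth_friction()].
#'
#' Default prefactors and exponents reproduce study-like conditions (projected
#' area in mm^2, density per um^2, per-acantha area in um^2 near the printed
#' 1 mN values; exponents 0.362 / 0.214 / 0.226).
#'
#' @param k Named or positional numeric length-3: exponents for `A_A`, `N_A`,
#'   `A_Ac`.
#' @param prefactors Length-3: response values at 1 mN, units mm^2, per-um^2,
#'   um^2.
#' @param individual_sd Between-individual sd on log10 scale.
#' @param noise_sd Residual sd on log10 scale.
#' @param params A [synth_params()] (supplies individuals, loads, tau, friction
#'   noise, seed).
#' @return A tibble of pad observations with attribute `"ground_truth"`
#'   (exponents, prefactors, variance components, per-individual offsets).
#' @export
make_powerlaw_dataset <- function(k = c(A_A = 0.362, N_A = 0.214, A_Ac = 0.226),
                                  prefactors = c(A_A = 0.08, N_A = 0.107, A_Ac = 0.326),
                                  individual_sd = 0.12,
                                  noise_sd = 0.03,
                                  params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  if (length(params$loads) == 0) abort("`params$loads` must be non-empty.")
  if (any(!is.finite(k))) abort("exponents must be finite.")
  if (individual_sd < 0 || noise_sd < 0) abort("sds must be >= 0.")
  n <- params$n_individuals
  loads <- params$loads
  ids <- sprintf("ind%02d", seq_len(n))

  gen <- local_seed(params$seed, {
    offs <- matrix(rnorm(3 * n, 0, individual_sd), nrow = n,
                   dimnames = list(ids, c("A_A", "N_A", "A_Ac")))
    grid <- tidyr::expand_grid(individual_id = ids, load_mN = loads)
    draw <- function(resp, j) {
      prefactors[[j]] * grid$load_mN^k[[j]] *
        10^(offs[grid$individual_id, resp] +
              rnorm(nrow(grid), 0, noise_sd))
    }
    grid$A_A_mm2 <- draw("A_A", 1)
    grid$N_A_per_um2 <- draw("N_A", 2)
    grid$A_Ac_um2 <- draw("A_Ac", 3)
    list(grid = grid, offsets = offs)
  })
  obs <- gen$grid %>%
    mutate(
      A_R_um2 = real_contact_area(.data$A_A_mm2, .data$N_A_per_um2, .data$A_Ac_um2),
      friction_mN = synth_friction(.data$A_R_um2, tau = params$tau_true,
                                   noise_sd = params$friction_noise_sd,
                                   seed = params$seed + 7L)
    )
  attr(obs, "ground_truth") <- list(
    k = k, prefactors = prefactors, individual_sd = individual_sd,
    noise_sd = noise_sd, tau = params$tau_true,
    offsets = gen$offsets
  )
  obs
}

#' Write a contact image and its pixel-scale sidecar
#'
#' Writes the intensity grid as 16-bit grayscale TIFF (or PNG) with the pixel
#' scale, seed and provenance recorded in a JSON sidecar next to it.
#'
#' @param image A `contact_image`.
#' @param path Output path ending in `.tiff`/`.tif` or `.png`.
#' @return `path`, invisibly.
#' @export
write_contact_image <- function(image, path) {
  stopifnot(inherits(image, "contact_image"))
  m <- t(image$intensity) # writers expect row = y
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("package 'tiff' is required to write TIFF images.")
    }
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("package 'png' is required to write PNG images.")
    }
    png::writePNG(m, path)
  } else {
    abort("`path` must end in .tiff, .tif or .png.")
  }
  sidecar <- sub("\\.[A-Za-z]+$", ".json", path)
  jsonlite::write_json(
    c(image$metadata, list(origin_um = image$origin)),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a contact image written by [write_contact_image()]
#'
#' @param path TIFF or PNG path; a JSON sidecar with `pixel_scale` is read if
#'   present, otherwise `pixel_scale` must be given.
#' @param pixel_scale Micrometres per pixel (overrides the sidecar).
#' @return A `contact_image`.
#' @export
read_contact_image <- function(path, pixel_scale = NULL) {
  m <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("package 'tiff' is required to read TIFF images.")
    }
    tiff::readTIFF(path)
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("package 'png' is required to read PNG images.")
    }
    png::readPNG(path)
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  sidecar <- sub("\\.[A-Za-z]+$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  ps <- pixel_scale %||% meta$pixel_scale
  if (is.null(ps)) abort("pixel scale not found; pass `pixel_scale`.")
  structure(
    list(intensity = t(m), pixel_scale = as.numeric(ps),
         origin = as.numeric(unlist(meta$origin_um %||% c(0, 0))),
         metadata = meta),
    class = "contact_image"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
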