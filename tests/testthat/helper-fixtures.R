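# Shared fixtures and independent oracles built in code.

# Small calibrated bed: same mechanics as the default, tiny footprint.
small_bed <- function(density = 0.12, footprint = 700, dome = 16000,
                      tip_height_sd = 0.3, seed = 42, ...) {
  make_fibril_bed(density, pad_geometry(footprint, dome),
                  tip_height_sd = tip_height_sd, seed = seed, ...)
}

# Flat coplanar bed: analytic spring-bank limit (all-tip regime).
flat_bed <- function(n_target = 50, seed = 7) {
  make_fibril_bed(0.1, pad_geometry(n_target / 0.1, dome_radius = Inf),
                  tip_height_sd = 0, seed = seed)
}

# Independent Friedman statistic: within-row mid-ranks and the tie-corrected
# classical formula, written from the definition (not via stats::friedman.test).
friedman_by_hand <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  Rj <- colSums(ranks)
  # tie correction: per row, sum over tie groups of (t^3 - t)
  ties <- sum(apply(mat, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - ties / (k - 1)
  num / den
}

# Draw a dispersed synthetic spot scene (non-overlapping circular-to-elongated
# patches on a jittered grid) with exact ground truth.
toy_scene <- function(n_side = 16, spacing = 3, area_range = c(0.2, 0.5),
                      aspect = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  tibble::tibble(
    x = g$ix * spacing + runif(nrow(g), -0.5, 0.5),
    y = g$iy * spacing + runif(nrow(g), -0.5, 0.5),
    contact_area = runif(nrow(g), area_range[1], area_range[2]),
    aspect_ratio = if (length(aspect) == 1) rep(aspect, nrow(g)) else
      runif(nrow(g), aspect[1], aspect[2]),
    orientation = runif(nrow(g), 0, pi)
  )
}

# Reference per-load group means used in the worked arithmetic.
ref_means <- function() reference_contact_means()

# Shoelace polygon area (independent of the package's internal version).
poly_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}
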