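#' Segment a contact image into a binary mask
#'
#' Binary conversion of a grayscale contact image: Otsu's threshold by default
#' (bright patches on dark background) or a fixed threshold. Idempotent on
#' already-binary input; a constant image yields an empty mask with a warning.
#'
#' @param image A `contact_image` or a numeric intensity matrix in \[0, 1\].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @param pixel_scale Micrometres per pixel when `image` is a bare matrix.
#' @return A `contact_mask`: logical matrix carrying `pixel_scale` and origin.
#' @export
segment <- function(image, method = c("otsu", "fixed"), threshold = 0.5,
                    pixel_scale = NULL) {
  method <- match.arg(method)
  if (inherits(image, "contact_mask")) return(image)
  if (inherits(image, "contact_image")) {
    m <- image$intensity
    ps <- image$pixel_scale
    origin <- image$origin
  } else {
    m <- as.matrix(image)
    ps <- pixel_scale %||% 1
    origin <- c(0, 0)
  }
  if (length(m) == 0) abort("image grid is empty.")
  u <- unique(as.vector(m))
  if (length(u) == 1) {
    warn("constant image: returning an empty mask.")
    mask <- matrix(FALSE, nrow(m), ncol(m))
  } else if (all(u %in% c(0, 1))) {
    mask <- m > 0.5 # already binary
  } else {
    thr <- if (method == "otsu") {
      EBImage::otsu(EBImage::Image(m), range = range(m))
    } else {
      threshold
    }
    mask <- m > thr
  }
  new_contact_mask(mask, ps, origin)
}

new_contact_mask <- function(mask, pixel_scale, origin = c(0, 0)) {
  structure(mask, pixel_scale = pixel_scale, origin = origin,
            class = c("contact_mask", class(mask)))
}

#' @export
#' @method print contact_mask
print.contact_mask <- function(x, ...) {
  cat(sprintf("<contact_mask> %d x %d px at %.3g um/px, %d foreground px\n",
              nrow(x), ncol(x), attr(x, "pixel_scale"), sum(x)))
  invisible(x)
}

# Connected-component labelling. EBImage::bwlabel is 4-connected; the
# 8-connected default (matching ImageJ's particle analyzer) merges
# 4-components that touch diagonally via union-find on the label graph.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (connectivity == 8 && max(lab) > 1) {
    pairs <- rbind(
      diagonal_pairs(lab, 1L, 1L),
      diagonal_pairs(lab, 1L, -1L)
    )
    if (nrow(pairs) > 0) {
      parent <- seq_len(max(lab))
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      relab <- match(roots, sort(unique(roots)))
      lab[lab > 0] <- relab[lab[lab > 0]]
    }
  }
  lab
}

diagonal_pairs <- function(lab, di, dj) {
  nr <- nrow(lab); nc <- ncol(lab)
  i1 <- if (di > 0) 1:(nr - 1) else 2:nr
  i2 <- i1 + di
  j1 <- if (dj > 0) 1:(nc - 1) else 2:nc
  j2 <- j1 + dj
  a <- lab[i1, j1, drop = FALSE]
  b <- lab[i2, j2, drop = FALSE]
  keep <- a > 0 & b > 0 & a != b
  cbind(a[keep], b[keep])
}

#' Particle analysis of a binary contact mask
#'
#' ImageJ-style particle metrics: connected components (8-connectivity by
#' default) give per-spot pixel-count areas; axes and orientation come from
#' the second central moments (moment-equivalent ellipse, with the 1/12 px^2
#' pixel-extent correction), and the aspect ratio is the major axis divided
#' by the minor axis. Spots smaller than 9 px are flagged
#' `unreliable_aspect` rather than dropped, since moment axes are noisy at
#' that size.
#'
#' @param mask A `contact_mask` (or logical matrix).
#' @param pixel_scale Micrometres per pixel (taken from the mask if present).
#' @param connectivity 8 (default) or 4.
#' @return A particle tibble: `label`, centroid `x`/`y` (um), `area_um2`,
#'   `major_um`, `minor_um`, `aspect_ratio`, `orientation` (radians),
#'   `n_px`, `unreliable_aspect`.
#' @export
particle_analysis <- function(mask, pixel_scale = NULL, connectivity = 8) {
  ps <- pixel_scale %||% attr(mask, "pixel_scale") %||% 1
  origin <- attr(mask, "origin") %||% c(0, 0)
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  m <- unclass(mask)
  if (!any(m)) {
    return(tibble(
      label = integer(), x = double(), y = double(), area_um2 = double(),
      major_um = double(), minor_um = double(), aspect_ratio = double(),
      orientation = double(), n_px = integer(), unreliable_aspect = logical()
    ))
  }
  lab <- label_components(m, connectivity)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  px <- (idx[, 1] - 0.5) * ps + origin[1]
  py <- (idx[, 2] - 0.5) * ps + origin[2]

  counts <- table(l)
  labs <- as.integer(names(counts))
  n_px <- as.integer(counts)
  cx <- tapply(px, l, mean)
  cy <- tapply(py, l, mean)
  dx <- px - cx[as.character(l)]
  dy <- py - cy[as.character(l)]
  pxvar <- ps^2 / 12 # second moment of a unit pixel about its centre
  mxx <- tapply(dx * dx, l, mean) + pxvar
  myy <- tapply(dy * dy, l, mean) + pxvar
  mxy <- tapply(dx * dy, l, mean)

  # eigenvalues of the 2x2 moment matrix
  tr <- mxx + myy
  l1 <- tr / 2 + sqrt(pmax(0, (mxx - myy)^2 / 4 + mxy^2))
  l2 <- tr / 2 - sqrt(pmax(0, (mxx - myy)^2 / 4 + mxy^2))
  l2 <- pmax(l2, 1e-300)

  tibble(
    label = labs,
    x = as.numeric(cx), y = as.numeric(cy),
    area_um2 = n_px * ps^2,
    major_um = as.numeric(4 * sqrt(l1)), # full axes of the moment ellipse
    minor_um = as.numeric(4 * sqrt(l2)),
    aspect_ratio = as.numeric(sqrt(l1 / l2)),
    orientation = as.numeric(0.5 * atan2(2 * mxy, mxx - myy)),
    n_px = n_px,
    unreliable_aspect = n_px < 9
  ) %>% arrange(.data$label)
}

#' Projected contact area of a mask or particle table
#'
#' The projected (apparent) contact area is the area of the smallest convex
#' polygon containing all contact: the convex hull of the foreground pixels
#' (for a mask) or of the spot centroids extended by their ellipse axes (for a
#' particle table), converted to mm^2.
#'
#' @param x A `contact_mask` or a particle tibble from [particle_analysis()].
#' @param pixel_scale Micrometres per pixel (masks only; taken from the mask
#'   attribute when present).
#' @return Projected area, mm^2 (0 for empty input).
#' @export
projected_area <- function(x, pixel_scale = NULL) {
  um2_to_mm2(polygon_area_xy(hull_polygon(x, pixel_scale)))
}

#' Convex-hull polygon of the contact footprint
#'
#' @inheritParams projected_area
#' @return Tibble of hull vertices `x`, `y` in um (zero rows if degenerate).
#' @export
hull_polygon <- function(x, pixel_scale = NULL) {
  if (inherits(x, "contact_mask") || is.logical(x)) {
    ps <- pixel_scale %||% attr(x, "pixel_scale") %||% 1
    origin <- attr(x, "origin") %||% c(0, 0)
    idx <- which(unclass(x), arr.ind = TRUE)
    if (nrow(idx) < 3) return(tibble(x = double(), y = double()))
    px <- (idx[, 1] - 0.5) * ps + origin[1]
    py <- (idx[, 2] - 0.5) * ps + origin[2]
  } else {
    tab <- as_tibble(x)
    if (nrow(tab) == 0) return(tibble(x = double(), y = double()))
    a <- (tab$major_um %||% rep(0, nrow(tab))) / 2
    b <- (tab$minor_um %||% rep(0, nrow(tab))) / 2
    th <- tab$orientation %||% rep(0, nrow(tab))
    px <- c(tab$x + a * cos(th), tab$x - a * cos(th),
            tab$x - b * sin(th), tab$x + b * sin(th))
    py <- c(tab$y + a * sin(th), tab$y - a * sin(th),
            tab$y + b * cos(th), tab$y - b * cos(th))
  }
  h <- grDevices::chull(px, py)
  tibble(x = px[h], y = py[h])
}

polygon_area_xy <- function(poly) {
  if (nrow(poly) < 3) return(0)
  polygon_area(poly$x, poly$y)
}

#' Acantha density from sampled windows
#'
#' Emulates the sampling protocol used for contact images: spots are counted
#' in axis-aligned square windows rejection-sampled inside the projected-area
#' hull, with the windows totalling `sample_fraction` of the hull area
#' (default 0.25, the fraction analysed per animal in the original protocol).
#' With `sample_fraction = 1` the estimate is the exact count over the hull
#' area.
#'
#' @param table Particle tibble from [particle_analysis()].
#' @param hull Hull polygon from [hull_polygon()].
#' @param sample_fraction Fraction of the hull area to sample, in (0, 1].
#' @param n_windows Number of windows the sampled area is split into.
#' @param seed Seed for window placement.
#' @return Density, per square micrometre.
#' @export
density_estimate <- function(table, hull, sample_fraction = 0.25,
                             n_windows = 5, seed = 1) {
  if (sample_fraction <= 0 || sample_fraction > 1) {
    abort("`sample_fraction` must be in (0, 1].")
  }
  hull_area <- polygon_area_xy(hull)
  if (hull_area <= 0) abort("hull area is zero; cannot estimate density.")
  if (nrow(table) == 0) return(0)
  if (sample_fraction == 1) {
    return(nrow(table) / hull_area)
  }
  side <- sqrt(hull_area * sample_fraction / n_windows)
  bx <- range(hull$x); by <- range(hull$y)
  local_seed(seed, {
    centres <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centres) < n_windows && tries < 5000) {
      cx <- runif(1, bx[1] + side / 2, bx[2] - side / 2)
      cy <- runif(1, by[1] + side / 2, by[2] - side / 2)
      corners <- cbind(cx + c(-1, -1, 1, 1) * side / 2,
                       cy + c(-1, 1, -1, 1) * side / 2)
      if (all(mgcv::in.out(as.matrix(hull[, c("x", "y")]), corners))) {
        centres <- rbind(centres, c(cx, cy))
      }
      tries <- tries + 1
    }
    if (nrow(centres) == 0) {
      warn("no window fitted inside the hull; falling back to exact density.")
      return(nrow(table) / hull_area)
    }
    counted <- sum(vapply(seq_len(nrow(centres)), function(i) {
      sum(abs(table$x - centres[i, 1]) <= side / 2 &
            abs(table$y - centres[i, 2]) <= side / 2)
    }, numeric(1)))
    counted / (nrow(centres) * side^2)
  })
}

#' Optical boundary error of a measured contact area
#'
#' The finite resolution of the light microscope (about +/- 150 nm) blurs the
#' patch boundary, so the area error scales with the perimeter: relative error
#' = perimeter x (resolution / 2) / area. By default the perimeter of the
#' area-equivalent circle is used (for a circle this reduces to resolution /
#' radius); a true perimeter can be supplied for elongated patches, which
#' always increases the error at fixed area.
#'
#' @param area Contact area, um^2 (> 0, vectorised).
#' @param resolution Optical resolution, um (default 0.15).
#' @param perimeter Optional true perimeter, um.
#' @return Relative area error (0.75 means 75%).
#' @export
#' @examples
#' boundary_error(0.12) # ~0.75 for the smallest measured contact
boundary_error <- function(area, resolution = 0.15, perimeter = NULL) {
  if (any(area <= 0)) abort("`area` must be > 0.")
  if (resolution <= 0) abort("`resolution` must be > 0.")
  per <- perimeter %||% (2 * sqrt(pi * area))
  per * (resolution / 2) / area
}

#' Quantify a contact image end to end
#'
#' Segmentation, particle analysis, convex-hull projected area and sampled
#' density in one call; the per-image summary row mirrors the per-individual
#' measures used in the scaling analysis.
#'
#' @param image A `contact_image`.
#' @param connectivity Connectivity for [particle_analysis()].
#' @param sample_fraction Window fraction for [density_estimate()].
#' @param seed Seed for the density windows.
#' @return A list with `particles` (tibble), `hull` (tibble) and `summary`
#'   (one-row tibble: `A_A_mm2`, `N_A_per_um2`, `A_Ac_um2`, `n_spots`).
#' @export
quantify_contact_image <- function(image, connectivity = 8,
                                   sample_fraction = 0.25, seed = 1) {
  mask <- segment(image)
  parts <- particle_analysis(mask, connectivity = connectivity)
  hull <- hull_polygon(mask)
  A_A <- um2_to_mm2(polygon_area_xy(hull))
  N_A <- if (nrow(parts) > 0 && A_A > 0) {
    density_estimate(parts, hull, sample_fraction, seed = seed)
  } else {
    0
  }
  list(
    particles = parts,
    hull = hull,
    summary = tibble(
      A_A_mm2 = A_A,
      N_A_per_um2 = N_A,
      A_Ac_um2 = if (nrow(parts) > 0) mean(parts$area_um2) else 0,
      n_spots = nrow(parts)
    )
  )
}
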