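#' @export
autoplot.contact_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    i = seq_len(nrow(object$intensity)),
    j = seq_len(ncol(object$intensity))
  )
  df$x <- (df$i - 0.5) * object$pixel_scale + object$origin[1]
  df$y <- (df$j - 0.5) * object$pixel_scale + object$origin[2]
  df$intensity <- as.vector(object$intensity)
  ggplot(df, aes(.data$x, .data$y, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", fill = "I") +
    theme_minimal()
}

#' @export
autoplot.contact_state <- function(object, ...) {
  touching <- filter(object$fibrils, .data$mode != "none")
  ggplot(touching, aes(.data$x, .data$y)) +
    geom_point(aes(size = .data$contact_area, colour = .data$mode),
               alpha = 0.7) +
    scale_size_area(max_size = 3) +
    coord_equal() +
    labs(
      title = sprintf("F_N = %.2g mN: %d contacts, A_R = %.3g µm²",
                      object$load_mN, object$n_contact, object$A_R_um2),
      x = "x (µm)", y = "y (µm)",
      size = "area (µm²)"
    ) +
    theme_minimal()
}

#' Log-log load sweep of the three contact measures
#'
#' @param data Observation tibble (shared schema).
#' @return A ggplot: the three hierarchical measures and their product over
#'   load, log-log, one panel per measure.
#' @export
plot_load_sweep <- function(data) {
  long <- data %>%
    select(any_of(c("individual_id", "load_mN", "A_A_mm2", "N_A_per_um2",
                    "A_Ac_um2", "A_R_um2"))) %>%
    tidyr::pivot_longer(-any_of(c("individual_id", "load_mN")),
                        names_to = "measure", values_to = "value")
  p <- ggplot(long, aes(.data$load_mN, .data$value))
  if ("individual_id" %in% names(data)) {
    p <- p + geom_line(aes(group = .data$individual_id), alpha = 0.3)
  }
  p +
    geom_point(alpha = 0.6) +
    facet_wrap(~measure, scales = "free_y") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "normal load (mN)", y = NULL) +
    theme_minimal()
}

#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  grid <- tibble(lx = seq(log10(0.1), log10(5), length.out = 50))
  grid$ly <- object$intercept + object$slope * grid$lx
  ggplot(grid, aes(10^.data$lx, 10^.data$ly)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(
      title = sprintf("%s ~ load^%.3f (cond. R² %.3f, marg. %.3f)",
                      object$response, object$slope,
                      object$r2_conditional, object$r2_marginal),
      x = "normal load (mN)", y = object$response
    ) +
    theme_minimal()
}

#' Contact-growth comparison across materials
#'
#' @param curves Output of [figure9_curves()].
#' @return A ggplot of real contact area over load per material.
#' @export
plot_material_curves <- function(curves = figure9_curves()) {
  ggplot(curves, aes(.data$load_mN, .data$A_R_mm2,
                     colour = .data$material, linetype = .data$law)) +
    geom_line(linewidth = 0.8) +
    scale_y_log10() +
    labs(x = "normal load (mN)", y = expression(A[R] ~ (mm^2))) +
    theme_minimal()
}

#' Aspect ratio versus contact area of individual patches
#'
#' The tip-to-side transition signature: circular patches (aspect ~ 1) at
#' small areas, elongating continuously toward aspect 4.5 as the contact
#' grows.
#'
#' @param particles Particle tibble ([particle_analysis()]) or a
#'   `contact_state`.
#' @return A ggplot.
#' @export
plot_aspect_area <- function(particles) {
  d <- if (inherits(particles, "contact_state")) {
    filter(particles$fibrils, .data$mode != "none") %>%
      rename(area_um2 = "contact_area")
  } else {
    as_tibble(particles)
  }
  ggplot(d, aes(.data$area_um2, .data$aspect_ratio)) +
    geom_point(alpha = 0.5) +
    labs(x = "contact area (µm²)", y = "aspect ratio") +
    theme_minimal()
}
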