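#' Real contact area from the three hierarchical levels
#'
#' The real contact area of the pad is the product of the projected (apparent)
#' contact area, the density of contacting acanthae and the mean contact area
#' per acantha: `A_R = (A_A x 1e6) x N_A x A_Ac` in um^2 (the 1e6 converts
#' `A_A` from mm^2 to um^2).
#'
#' @param A_A_mm2 Projected contact area, mm^2 (>= 0, vectorised).
#' @param N_A_per_um2 Density of contacting acanthae, per um^2.
#' @param A_Ac_um2 Mean per-acantha contact area, um^2.
#' @return Real contact area, um^2.
#' @export
#' @examples
#' real_contact_area(0.101, 0.132, 0.461) # ~6.15e3 um^2
real_contact_area <- function(A_A_mm2, N_A_per_um2, A_Ac_um2) {
  if (any(A_A_mm2 < 0) || any(N_A_per_um2 < 0) || any(A_Ac_um2 < 0)) {
    abort("all contact measures must be >= 0.")
  }
  mm2_to_um2(A_A_mm2) * N_A_per_um2 * A_Ac_um2
}

#' Random-intercept power-law fit on log-log data
#'
#' Fits `log10(response) ~ log10(load)` with a random intercept per individual
#' by REML, the repeated-measures analogue of a power-law regression: the
#' slope is the scaling coefficient `k` in `response ~ a * F_N^k`. Goodness of
#' fit is reported as marginal R^2 (variance explained by the fixed effect
#' alone) and conditional R^2 (fixed plus random), following the
#' Nakagawa-Schielzeth variance decomposition.
#'
#' A perfect within-individual fit (zero residual variance, e.g. noiseless
#' synthetic data) is detected and returned via a closed-form within-group
#' path, since REML cannot estimate a zero residual variance. A singular fit
#' (zero between-individual variance) falls back to pooled OLS with a note.
#'
#' @param data Observation tibble.
#' @param response Column name (string or bare) of the response; must be
#'   strictly positive.
#' @param load,group Column names of the load (mN) and individual id.
#' @return A `powerlaw_fit`: intercept and slope (log10 scale) with standard
#'   errors, conditional and marginal R^2, variance components and counts.
#'   Methods: [tidy()], [glance()], `print()`.
#' @export
fit_powerlaw_mixed <- function(data, response, load = "load_mN",
                               group = "individual_id") {
  response <- as_response_name(rlang::enquo(response), data)
  d <- tibble(
    y = data[[response]],
    lx = log10(data[[load]]),
    g = factor(data[[group]])
  )
  bad <- which(!is.finite(d$y) | d$y <= 0)
  if (length(bad)) {
    abort(sprintf("response '%s' must be > 0; offending rows: %s",
                  response, paste(head(bad, 10), collapse = ", ")))
  }
  per_group <- table(d$g)
  if (nlevels(d$g) < 2 || any(per_group < 2)) {
    abort("need >= 2 individuals with >= 2 loads each.")
  }
  d$ly <- log10(d$y)

  # Degenerate path: exact line with per-individual offsets.
  fe <- lm(ly ~ lx + g, data = d)
  if (sqrt(mean(stats::residuals(fe)^2)) < 1e-8) {
    slope <- unname(coef(fe)[["lx"]])
    offs <- c(0, coef(fe)[grep("^g", names(coef(fe)))])
    intercepts <- coef(fe)[["(Intercept)"]] + offs
    vf <- var(slope * d$lx)
    vr <- var(as.numeric(intercepts)) * (length(intercepts) - 1) / length(intercepts)
    res <- new_powerlaw_fit(
      intercept = mean(intercepts), intercept_se = sd(intercepts) / sqrt(length(intercepts)),
      slope = slope, slope_se = 0,
      var_fixed = vf, var_random = vr, var_residual = 0,
      r2_marginal = if (vf + vr > 0) vf / (vf + vr) else 1,
      r2_conditional = 1,
      n_individuals = nlevels(d$g), n_obs = nrow(d),
      response = response, method = "exact", model = fe
    )
    return(res)
  }

  fit <- suppressMessages(
    lme4::lmer(ly ~ lx + (1 | g), data = d, REML = TRUE)
  )
  if (lme4::isSingular(fit, tol = 1e-5)) {
    rlang::inform(sprintf(
      "fit_powerlaw_mixed('%s'): zero between-individual variance; falling back to pooled OLS.",
      response
    ))
    ols <- lm(ly ~ lx, data = d)
    sm <- summary(ols)
    vf <- var(stats::fitted(ols))
    ve <- sm$sigma^2
    return(new_powerlaw_fit(
      intercept = coef(ols)[[1]], intercept_se = sm$coefficients[1, 2],
      slope = coef(ols)[[2]], slope_se = sm$coefficients[2, 2],
      var_fixed = vf, var_random = 0, var_residual = ve,
      r2_marginal = vf / (vf + ve), r2_conditional = vf / (vf + ve),
      n_individuals = nlevels(d$g), n_obs = nrow(d),
      response = response, method = "ols", model = ols
    ))
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- vc$vcov[vc$grp == "g"]
  ve <- vc$vcov[vc$grp == "Residual"]
  vf <- var(as.numeric(stats::model.matrix(fit) %*% beta))
  tot <- vf + vr + ve
  new_powerlaw_fit(
    intercept = beta[[1]], intercept_se = se[[1]],
    slope = beta[[2]], slope_se = se[[2]],
    var_fixed = vf, var_random = vr, var_residual = ve,
    r2_marginal = vf / tot, r2_conditional = (vf + vr) / tot,
    n_individuals = nlevels(d$g), n_obs = nrow(d),
    response = response, method = "reml", model = fit
  )
}

# Accept either a bare column name or a character scalar (possibly held in a
# variable) for the response argument.
as_response_name <- function(q, data) {
  e <- rlang::quo_get_expr(q)
  if (is.symbol(e) && as.character(e) %in% names(data)) return(as.character(e))
  v <- rlang::eval_tidy(q)
  if (is.character(v) && length(v) == 1) return(v)
  abort("`response` must name a column of `data`.")
}

new_powerlaw_fit <- function(...) {
  structure(list(...), class = "powerlaw_fit")
}

#' @export
#' @method print powerlaw_fit
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> %s: intercept %.3f +/- %.3f, scaling coefficient %.3f +/- %.3f\n  conditional R^2 = %.3f, marginal R^2 = %.3f (%d individuals, %d obs, %s)\n",
    x$response, x$intercept, x$intercept_se, x$slope, x$slope_se,
    x$r2_conditional, x$r2_marginal, x$n_individuals, x$n_obs, x$method
  ))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(
    response = x$response,
    intercept = x$intercept, intercept_se = x$intercept_se,
    slope = x$slope, slope_se = x$slope_se,
    r2_conditional = x$r2_conditional, r2_marginal = x$r2_marginal,
    n_individuals = x$n_individuals, n_obs = x$n_obs, method = x$method
  )
}

#' Fit the scaling of all contact measures over load
#'
#' Runs [fit_powerlaw_mixed()] for projected contact area, acantha density,
#' per-acantha contact area and real contact area, returning the fit-summary
#' table (intercept +/- SE, scaling coefficient +/- SE, conditional and
#' marginal R^2 per row).
#'
#' @param data Observation tibble with the shared schema.
#' @return A list with `fits` (named list of `powerlaw_fit`) and `table`
#'   (tibble, one row per measure).
#' @export
fit_all_powerlaws <- function(data) {
  responses <- c(
    projected_contact_area = "A_A_mm2",
    acantha_density = "N_A_per_um2",
    acantha_contact_area = "A_Ac_um2",
    real_contact_area = "A_R_um2"
  )
  responses <- responses[responses %in% names(data)]
  fits <- map(responses, function(r) fit_powerlaw_mixed(data, r))
  tab <- imap(fits, function(f, nm) mutate(glance(f), parameter = nm, .before = 1)) %>%
    list_rbind()
  list(fits = fits, table = tab)
}

#' Compose component scaling exponents into the real-contact-area exponent
#'
#' Under power-law scaling of the three hierarchical levels, the real contact
#' area scales as `A_R ~ F_N^(k_AA + k_NA + k_AAc)`: the composed exponent is
#' the sum of the component exponents and the composed prefactor the product
#' of the component prefactors (with the mm^2 -> um^2 conversion folded in).
#' An exponent sum within 0.2 of 1 is flagged near-linear.
#'
#' @param fit_aa,fit_na,fit_aac `powerlaw_fit` objects, or bare exponents
#'   (numbers), for projected area, density and per-acantha area.
#' @return An `exponent_composition` list: `k_sum`, `k_sum_se`, `prefactor_um2`
#'   (NA when bare exponents were given), `near_linear`, components.
#' @export
#' @examples
#' exponent_composition(0.362, 0.214, 0.226)$k_sum # 0.802
exponent_composition <- function(fit_aa, fit_na, fit_aac) {
  comp <- function(f) {
    if (inherits(f, "powerlaw_fit")) {
      c(k = f$slope, se = f$slope_se, b = f$intercept)
    } else {
      c(k = as.numeric(f), se = NA_real_, b = NA_real_)
    }
  }
  m <- rbind(comp(fit_aa), comp(fit_na), comp(fit_aac))
  k_sum <- sum(m[, "k"])
  se <- if (all(is.finite(m[, "se"]))) sqrt(sum(m[, "se"]^2)) else NA_real_
  pref <- if (all(is.finite(m[, "b"]))) 10^sum(m[, "b"]) * UM2_PER_MM2 else NA_real_
  structure(
    list(
      k_sum = k_sum, k_sum_se = se, prefactor_um2 = pref,
      near_linear = abs(k_sum - 1) <= 0.2,
      components = tibble(
        component = c("A_A", "N_A", "A_Ac"),
        k = m[, "k"], se = m[, "se"], intercept = m[, "b"]
      )
    ),
    class = "exponent_composition"
  )
}

#' @export
#' @method print exponent_composition
print.exponent_composition <- function(x, ...) {
  cat(sprintf("<exponent_composition> k_sum = %.3f%s%s\n",
              x$k_sum,
              if (is.finite(x$k_sum_se)) sprintf(" +/- %.3f", x$k_sum_se) else "",
              if (x$near_linear) " (near-linear)" else ""))
  invisible(x)
}

#' @export
tidy.exponent_composition <- function(x, ...) x$components

#' Friedman rank test for repeated measures
#'
#' Repeated-measures ANOVA on ranks: rows are individuals, columns the
#' (load) conditions; within-row mid-ranks with tie correction give the
#' chi-squared statistic with `k - 1` degrees of freedom. All-identical
#' columns give a zero statistic and p = 1.
#'
#' @param mat Numeric matrix (or data frame), n individuals x k conditions,
#'   no missing cells.
#' @return Tibble with `statistic`, `df`, `p_value`, `n`, `k`.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) abort("missing cells are not allowed (no imputation).")
  if (nrow(mat) < 2 || ncol(mat) < 2) abort("need n >= 2 rows and k >= 2 columns.")
  ranks <- t(apply(mat, 1, rank)) # mid-ranks for ties
  if (all(apply(ranks, 1, function(r) length(unique(r)) == 1))) {
    stat <- 0
  } else {
    ft <- friedman.test(mat)
    stat <- unname(ft$statistic)
    if (!is.finite(stat)) stat <- 0
  }
  df <- ncol(mat) - 1
  tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE),
    n = nrow(mat), k = ncol(mat)
  )
}

#' Repeated-measures effect size of load on a response
#'
#' Repeated-measures ANCOVA with the individual as blocking factor and load as
#' the continuous covariate; the effect size eta^2 = SS_load / SS_total is the
#' fraction of variance accounted for by the normal force. Its confidence
#' interval is obtained by a seeded percentile bootstrap over individuals.
#'
#' @param data Balanced observation tibble (every individual measured at every
#'   load).
#' @param response Column name of the response.
#' @param covariate,group Column names of load and individual id.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param level Confidence level.
#' @param seed Bootstrap seed.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p_value`, `eta_sq`,
#'   `ci_lower`, `ci_upper`.
#' @export
rm_effect_size <- function(data, response, covariate = "load_mN",
                           group = "individual_id", n_boot = 2000,
                           level = 0.95, seed = 1) {
  response <- as_response_name(rlang::enquo(response), data)
  d <- tibble(
    y = data[[response]],
    x = data[[covariate]],
    g = factor(data[[group]])
  )
  layout <- table(d$g, d$x)
  if (any(layout != 1)) {
    abort("unbalanced design: every individual must be measured once per load.")
  }
  eta <- function(dd) {
    a <- anova(lm(y ~ x + g, data = dd))
    ss <- a[["Sum Sq"]]
    ss[rownames(a) == "x"] / sum(ss)
  }
  a <- anova(lm(y ~ x + g, data = d))
  f_stat <- a["x", "F value"]
  df1 <- a["x", "Df"]
  df2 <- a["Residuals", "Df"]
  p <- a["x", "Pr(>F)"]
  eta_sq <- eta(d)

  ids <- levels(d$g)
  boots <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      dd <- map(seq_along(take), function(i) {
        rows <- d[d$g == take[i], ]
        rows$g <- factor(i)
        rows
      }) %>% list_rbind()
      eta(dd)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
  tibble(
    statistic = f_stat, df1 = df1, df2 = df2, p_value = p,
    eta_sq = eta_sq, ci_lower = ci[[1]], ci_upper = ci[[2]]
  )
}

#' Mean with a t-distribution margin of error
#'
#' The margin of error is half the confidence interval:
#' `t_{1-(1-level)/2, n-1} * sd / sqrt(n)`.
#'
#' @param values Numeric vector, n >= 2.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `mean`, `margin`, `lower`, `upper`, `n`.
#' @export
mean_t_ci <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) abort("need at least 2 values.")
  m <- mean(values)
  margin <- qt(1 - (1 - level) / 2, n - 1) * sd(values) / sqrt(n)
  tibble(mean = m, margin = margin, lower = m - margin, upper = m + margin, n = n)
}

#' Median and raw median absolute deviation
#'
#' The MAD is reported unscaled (no 1.4826 normal-consistency factor):
#' `median(|x - median(x)|)`.
#'
#' @param values Non-empty numeric vector.
#' @return Tibble with `median` and `mad`.
#' @export
#' @examples
#' median_mad(c(1, 2, 3, 4, 100)) # median 3, mad 1
median_mad <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("`values` must be non-empty.")
  med <- median(values)
  tibble(median = med, mad = median(abs(values - med)))
}

#' Per-load summary of an observation table
#'
#' Mean and t-based margin of error per load for each contact measure: the
#' per-individual summary convention of the study design.
#'
#' @param data Observation tibble.
#' @param level Confidence level for the margins.
#' @return Tibble, one row per load.
#' @export
summarise_observations <- function(data, level = 0.95) {
  measures <- intersect(c("A_A_mm2", "N_A_per_um2", "A_Ac_um2", "A_R_um2",
                          "friction_mN"), names(data))
  data %>%
    group_by(.data$load_mN) %>%
    summarise(
      n = dplyr::n(),
      across(all_of(measures),
             list(mean = mean,
                  margin = function(v) mean_t_ci(v, level)$margin)),
      .groups = "drop"
    )
}
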