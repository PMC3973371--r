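#' Default pipeline configuration
#'
#' One global seed fans out to per-stage child seeds (simulate: seed,
#' render/quantify: seed + 1000, stats bootstrap: seed + 2000) so that stages
#' can be rerun independently yet reproducibly. Every defaulted field is
#' echoed into the run metadata.
#'
#' @param seed Global seed.
#' @param ... Overrides of the default fields (unknown names error).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = c("simulate", "quantify", "fit", "friction"),
    synth = list(
      n_individuals = 10, loads = c(0.2, 0.5, 1, 2, 4),
      density = 0.15, tip_height_sd = 0.3, dome_radius = 16000,
      footprint_area = 1e5, tau_true = 1, friction_noise_sd = 0.5,
      individual_jitter = 0.15
    ),
    quantify = list(
      pixel_scale = 0.05, connectivity = 8, sample_fraction = 0.25,
      window_um = 40 # side of the rendered demo window
    ),
    stats = list(n_boot = 500, level = 0.95)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> render/quantify -> fit -> friction on synthetic
#' data with known ground truth, writing CSV tables and a JSON metadata file
#' into `output_dir`. Stage selection allows partial runs (e.g. stats-only on
#' an existing observation CSV via `observations`).
#'
#' Outputs (per stage): `observations.csv` (shared schema), `summary_by_load.csv`
#' (mean +/- t margin per load), `powerlaw_fits.csv` (intercept/slope +/- SE,
#' conditional and marginal R^2), `image_summary.csv` (quantified demo window),
#' `friction_fit.csv`, `shear_stress.csv`, `material_curves.csv`, and
#' `run_metadata.json` (package version, config echo, per-stage timings).
#'
#' @param config A [run_config()].
#' @param output_dir Directory to create/write into.
#' @param observations Optional observation tibble or CSV path; skips the
#'   simulate stage.
#' @return Invisibly, a list with the in-memory results (`observations`,
#'   `fits`, `composition`, `friction`, `curves`, `image`, `metadata`).
#' @export
run_pipeline <- function(config = run_config(), output_dir = tempfile("padrun"),
                         observations = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  results <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  stages <- config$stages

  obs <- NULL
  if (!is.null(observations)) {
    obs <- if (is.character(observations)) {
      as_tibble(read.csv(observations))
    } else {
      as_tibble(observations)
    }
    rep <- validate_observations(obs)
    if (nrow(rep) > 0) {
      abort(paste0("invalid observations: ", rep$message[1],
                   " (row ", rep$row[1], ", column ", rep$column[1], ")"))
    }
  } else if ("simulate" %in% stages) {
    obs <- clock("simulate", {
      params <- do.call(synth_params, c(config$synth, list(seed = config$seed)))
      simulate_pad_observations(params)
    })
  }
  if (!is.null(obs)) {
    write.csv(obs, file.path(output_dir, "observations.csv"), row.names = FALSE)
    results$observations <- obs
  }

  if ("quantify" %in% stages) {
    results$image <- clock("quantify", {
      q <- config$quantify
      # small rendered window with ground truth: a jittered patch scene
      bed <- make_fibril_bed(
        density = config$synth$density,
        pad = pad_geometry(footprint_area = (q$window_um * 1.2)^2 * pi / 4,
                           dome_radius = config$synth$dome_radius),
        tip_height_sd = config$synth$tip_height_sd,
        seed = config$seed + 1000L
      )
      state <- solve_indentation(bed, load = 0.05)
      img <- render_contact_image(state, pixel_scale = q$pixel_scale,
                                  noise_sd = 0.02, seed = config$seed + 1001L)
      quant <- quantify_contact_image(img, connectivity = q$connectivity,
                                      sample_fraction = q$sample_fraction,
                                      seed = config$seed + 1002L)
      write.csv(quant$particles, file.path(output_dir, "particles.csv"),
                row.names = FALSE)
      write.csv(quant$summary, file.path(output_dir, "image_summary.csv"),
                row.names = FALSE)
      list(state = state, image = img, quant = quant)
    })
  }

  if ("fit" %in% stages && !is.null(obs)) {
    results <- c(results, clock("fit", {
      summ <- summarise_observations(obs, level = config$stats$level)
      write.csv(summ, file.path(output_dir, "summary_by_load.csv"),
                row.names = FALSE)
      all_fits <- fit_all_powerlaws(obs)
      write.csv(all_fits$table, file.path(output_dir, "powerlaw_fits.csv"),
                row.names = FALSE)
      compo <- exponent_composition(all_fits$fits$projected_contact_area,
                                    all_fits$fits$acantha_density,
                                    all_fits$fits$acantha_contact_area)
      list(summary = summ, fits = all_fits, composition = compo)
    }))
  }

  if ("friction" %in% stages && !is.null(obs) && "friction_mN" %in% names(obs)) {
    results <- c(results, clock("friction", {
      am <- fit_amonton_extended(obs)
      tau <- shear_stress_series(obs)
      curves <- figure9_curves()
      write.csv(glance(am), file.path(output_dir, "friction_fit.csv"),
                row.names = FALSE)
      write.csv(tau$tau, file.path(output_dir, "shear_stress.csv"),
                row.names = FALSE)
      write.csv(curves, file.path(output_dir, "material_curves.csv"),
                row.names = FALSE)
      list(friction = list(amonton = am, shear = tau), curves = curves)
    }))
  }

  meta <- list(
    package = "frictionpads",
    version = as.character(utils::packageVersion("frictionpads")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    timings_s = timings,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, file.path(output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$metadata <- meta
  results$output_dir <- output_dir
  invisible(results)
}

#' Validate an observation table against the shared schema
#'
#' Checks column presence, positivity of loads, non-negativity of areas and
#' densities, and — where an `A_R_um2` column is present — consistency with
#' the hierarchical identity `A_R = A_A x N_A x A_Ac` to within 1e-6 relative.
#'
#' @param data Observation tibble or CSV path.
#' @return Tibble of violations (`row`, `column`, `message`); zero rows when
#'   valid.
#' @export
validate_observations <- function(data) {
  d <- if (is.character(data)) {
    if (!file.exists(data)) abort(sprintf("file not found: %s", data))
    as_tibble(read.csv(data))
  } else {
    as_tibble(data)
  }
  v <- list()
  note <- function(row, column, message) {
    v[[length(v) + 1]] <<- tibble(row = row, column = column, message = message)
  }
  required <- c("individual_id", "load_mN", "A_A_mm2", "N_A_per_um2", "A_Ac_um2")
  for (col in setdiff(required, names(d))) {
    note(NA_integer_, col, "required column missing")
  }
  if ("load_mN" %in% names(d)) {
    for (r in which(!is.finite(d$load_mN) | d$load_mN <= 0)) {
      note(r, "load_mN", "load must be positive")
    }
  }
  for (col in intersect(c("A_A_mm2", "N_A_per_um2", "A_Ac_um2", "A_R_um2"),
                        names(d))) {
    for (r in which(!is.finite(d[[col]]) | d[[col]] < 0)) {
      note(r, col, "must be finite and >= 0")
    }
  }
  if (all(c("A_R_um2", "A_A_mm2", "N_A_per_um2", "A_Ac_um2") %in% names(d))) {
    expected <- real_contact_area(pmax(d$A_A_mm2, 0), pmax(d$N_A_per_um2, 0),
                                  pmax(d$A_Ac_um2, 0))
    rel <- abs(d$A_R_um2 - expected) / pmax(abs(expected), 1e-12)
    for (r in which(is.finite(rel) & rel > 1e-6 & expected > 0)) {
      note(r, "A_R_um2", "inconsistent with A_A x N_A x A_Ac beyond 1e-6 relative")
    }
  }
  if (length(v) == 0) {
    tibble(row = integer(), column = character(), message = character())
  } else {
    list_rbind(v)
  }
}
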