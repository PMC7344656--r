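#' Configure an end-to-end study run
#'
#' In `simulate` mode the study region (areas, providers, persons, outcomes)
#' is generated from `region` and `params`; in `load` mode the area, provider
#' and (optionally) person tables are read from CSV/GeoJSON paths. Either
#' way the run proceeds access -> cohort -> per-risk-factor model ladders.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param region A [region_config()] (simulate mode).
#' @param params Outcome model parameters: NULL for the per-risk-factor
#'   defaults ([default_outcome_params()]), a single [outcome_params()], or a
#'   named list keyed by risk factor.
#' @param areas_path,providers_path,persons_path Input paths (load mode);
#'   `persons_path` may be NULL to run the access stage only.
#' @param cmrfs Risk factors to analyse (subset of [cmrf_types()]).
#' @param buffer_km 2SFCA radial buffer distance (km).
#' @param radii Buffer radii for the coverage sensitivity report.
#' @param window Study window for most-recent-test selection.
#' @param sampling_fraction Fraction of each area's adults tested (simulate).
#' @param repeat_rate Repeat-test rate per person and risk factor (simulate).
#' @param quad_order Quadrature order for all model fits.
#' @param se Compute Wald standard errors in the ladder fits.
#' @param seed Integer master seed; all randomness derives from it.
#' @param out_dir Output directory; NULL returns results without writing.
#' @return A list of class `run_config`.
#' @export
study_config <- function(mode = c("simulate", "load"),
                         region = region_config(),
                         params = NULL,
                         areas_path = NULL,
                         providers_path = NULL,
                         persons_path = NULL,
                         cmrfs = cmrf_types(),
                         buffer_km = 30,
                         radii = c(1, 16, 30),
                         window = c("2012-01-01", "2017-12-31"),
                         sampling_fraction = 0.25,
                         repeat_rate = 0.10,
                         quad_order = 15,
                         se = TRUE,
                         seed = 1L,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (length(cmrfs) == 0) stop_field("cmrfs", "must be non-empty")
  cmrfs <- match.arg(cmrfs, cmrf_types(), several.ok = TRUE)
  if (mode == "simulate") {
    if (!inherits(region, "region_config")) {
      stop_field("region", "must be a region_config() in simulate mode")
    }
    if (!is.null(areas_path) || !is.null(providers_path) ||
        !is.null(persons_path)) {
      stop("Input paths belong to load mode; exactly one mode's inputs may be set.",
           call. = FALSE)
    }
  } else {
    if (is.null(areas_path) || is.null(providers_path)) {
      stop("Load mode needs `areas_path` and `providers_path`.", call. = FALSE)
    }
  }
  if (buffer_km <= 0) stop_field("buffer_km", "must be > 0")
  structure(
    list(mode = mode, region = region, params = params,
         areas_path = areas_path, providers_path = providers_path,
         persons_path = persons_path, cmrfs = cmrfs, buffer_km = buffer_km,
         radii = radii, window = as.character(window),
         sampling_fraction = sampling_fraction, repeat_rate = repeat_rate,
         quad_order = quad_order, se = se, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full study pipeline
#'
#' Executes simulate-or-load, the 2SFCA access stage with its coverage
#' sensitivity report, the cohort stage (most-recent-test selection and
#' listwise exclusion), and one nested model ladder per risk factor. When
#' `out_dir` is set, writes all tables (CSV), the point layers (GeoJSON), the
#' fit results (JSON) and a manifest recording the seed, package version,
#' standardisation constants and the full configuration, so the run can be
#' reproduced bit-for-bit with [study_config_from_manifest()].
#'
#' @param config A [study_config()].
#' @return A list bundle: `areas`, `providers`, `coverage`, `records`,
#'   `risk_summary`, `ladders` (named by risk factor), `constants`,
#'   `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  window <- as.Date(config$window)

  if (config$mode == "simulate") {
    region <- config$region
    region$seed <- config$seed
    areas <- generate_areas(region)
    providers <- generate_providers(region, areas)
    areas <- compute_access(areas, providers, config$buffer_km)
    coverage <- coverage_sensitivity(areas, providers, config$radii)
    persons <- generate_persons(
      areas, window = window,
      sampling_fraction = config$sampling_fraction,
      repeat_rate = config$repeat_rate,
      cmrfs = config$cmrfs, seed = config$seed + 1L
    )
    constants <- standardization_constants(areas)
    params <- config$params
    if (is.null(params)) {
      params <- setNames(lapply(config$cmrfs, default_outcome_params),
                         config$cmrfs)
    }
    persons <- simulate_outcomes(persons, areas, params,
                                 seed = config$seed + 2L,
                                 constants = constants,
                                 on_missing_irsd = "exclude")
  } else {
    areas <- read_point_table(config$areas_path)
    assert_columns(areas, c("area_id", "adult_pop"), "areas")
    providers <- read_point_table(config$providers_path)
    assert_columns(providers, c("site_id", "gp_count"), "providers")
    areas <- compute_access(areas, providers, config$buffer_km)
    coverage <- coverage_sensitivity(areas, providers, config$radii)
    if (!"irsd" %in% names(areas)) areas$irsd <- NA_real_
    constants <- if (sum(!is.na(areas$irsd)) >= 2) {
      standardization_constants(areas)
    } else {
      NULL
    }
    persons <- NULL
    if (!is.null(config$persons_path)) {
      persons <- read_point_table(config$persons_path)
      persons$test_date <- as.Date(persons$test_date)
      persons <- classify_records(persons)
    }
  }

  records <- NULL
  summary_tbl <- NULL
  ladders <- list()
  if (!is.null(persons)) {
    records <- select_most_recent(persons, window = window)
    records <- exclude_incomplete(records, areas)
    summary_tbl <- risk_summary(records)
    ladders <- lapply(
      setNames(config$cmrfs, config$cmrfs),
      function(risk) {
        sub <- dplyr::filter(records, .data$cmrf == risk)
        if (nrow(sub) == 0) return(NULL)
        run_ladder(sub, areas, quad_order = config$quad_order,
                   se = config$se, constants = constants)
      }
    )
  }

  manifest <- list(
    package = "careaccess",
    version = as.character(utils::packageVersion("careaccess")),
    seed = config$seed,
    constants = if (!is.null(constants)) unclass(constants),
    config = serialize_config(config)
  )
  bundle <- list(
    areas = areas, providers = providers, coverage = coverage,
    records = records, risk_summary = summary_tbl, ladders = ladders,
    constants = constants, manifest = manifest
  )
  if (!is.null(config$out_dir)) {
    write_study_outputs(bundle, config$out_dir)
  }
  invisible(bundle)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$region <- unclass(out$region)
  if (!is.null(out$params)) {
    if (inherits(out$params, "outcome_params")) {
      out$params <- list(shared = unclass(out$params))
    } else {
      out$params <- lapply(out$params, unclass)
    }
  }
  out
}

write_study_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_csv(bundle$areas, p("areas.csv"))
  readr::write_csv(bundle$providers, p("providers.csv"))
  write_region_geojson(bundle$areas, p("areas.geojson"))
  if (nrow(bundle$providers) > 0) {
    write_region_geojson(bundle$providers, p("providers.geojson"))
  }
  readr::write_csv(
    dplyr::select(bundle$areas, "area_id",
                  access_raw = "access", "access_per_1000"),
    p("access.csv")
  )
  readr::write_csv(bundle$coverage, p("coverage.csv"))
  if (!is.null(bundle$records)) {
    readr::write_csv(bundle$records, p("cohort.csv"))
    readr::write_csv(bundle$risk_summary, p("risk_summary.csv"))
    lad <- bundle$ladders[!vapply(bundle$ladders, is.null, logical(1))]
    if (length(lad) > 0) {
      summaries <- purrr::imap_dfr(lad, function(l, nm) {
        dplyr::mutate(l$summary, cmrf = nm, .before = 1)
      })
      readr::write_csv(summaries, p("ladder_summary.csv"))
      ors <- purrr::imap_dfr(lad, function(l, nm) {
        purrr::imap_dfr(l$or_tables, function(tbl, model) {
          dplyr::mutate(tbl, cmrf = nm, model = model, .before = 1)
        })
      })
      readr::write_csv(ors, p("odds_ratios.csv"))
      lrts <- purrr::imap_dfr(lad, function(l, nm) {
        dplyr::mutate(l$lrt, cmrf = nm, .before = 1)
      })
      readr::write_csv(lrts, p("lrt.csv"))
      fits_json <- purrr::map(lad, function(l) {
        purrr::map(l$fits[!vapply(l$fits, is.null, logical(1))], function(f) {
          list(beta = as.list(f$beta), se = as.list(f$se), tau2 = f$tau2,
               loglik = f$loglik, aic = f$aic, n_obs = f$n_obs,
               n_groups = f$n_groups, n_params = f$n_params,
               converged = f$converged, boundary = f$boundary,
               quad_order = f$quad_order)
        })
      })
      jsonlite::write_json(fits_json, p("fits.json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Rebuild a run configuration from a manifest
#'
#' Reads the `manifest.json` written by [run_study()] and reconstructs the
#' [study_config()] it was run with, so the run can be reproduced exactly.
#'
#' @param path Path to a `manifest.json`.
#' @return A `run_config`.
#' @export
study_config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  region <- do.call(region_config, cfg$region[names(cfg$region) != "seed"] |>
                      c(list(seed = cfg$region$seed)))
  params <- NULL
  if (!is.null(cfg$params)) {
    rebuild <- function(x) do.call(outcome_params, x)
    params <- if (identical(names(cfg$params), "shared")) {
      rebuild(cfg$params$shared)
    } else {
      lapply(cfg$params, rebuild)
    }
  }
  study_config(
    mode = cfg$mode, region = region, params = params,
    areas_path = cfg$areas_path, providers_path = cfg$providers_path,
    persons_path = cfg$persons_path, cmrfs = cfg$cmrfs,
    buffer_km = cfg$buffer_km, radii = cfg$radii, window = cfg$window,
    sampling_fraction = cfg$sampling_fraction, repeat_rate = cfg$repeat_rate,
    quad_order = cfg$quad_order, se = cfg$se, seed = cfg$seed,
    out_dir = cfg$out_dir
  )
}
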