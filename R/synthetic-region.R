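#' Configure a synthetic study region
#'
#' Bundles the parameters of the synthetic small-area frame: the number of
#' areas and their adult population range, the planar extent of the region in
#' kilometres, the provider network size, and the distribution of the
#' area-level socioeconomic disadvantage score (IRSD; higher = less
#' disadvantaged). Defaults emulate a coastal region of 980 small areas
#' (200-800 adults each, about 5600 km^2) served by 165 primary care sites
#' with 611 general practitioners, and IRSD ~ Normal(976.7, 98.6^2).
#'
#' @param n_areas Number of small areas.
#' @param pop_range Length-2 integer range of adults per area (min, max).
#' @param region_extent Length-2 planar frame (width_km, height_km).
#' @param n_provider_sites Number of primary care service locations.
#' @param gp_total Total general practitioners distributed over the sites.
#' @param irsd_mean,irsd_sd Mean and SD of the disadvantage score.
#' @param irsd_missing Fraction of areas whose IRSD is set missing
#'   (missing-completely-at-random).
#' @param seed Integer seed; every generator derived from this config is
#'   deterministic given the seed.
#' @return A list of class `region_config`.
#' @export
#' @examples
#' cfg <- region_config(n_areas = 50, n_provider_sites = 5, gp_total = 20)
#' areas <- generate_areas(cfg)
region_config <- function(n_areas = 980,
                          pop_range = c(200L, 800L),
                          region_extent = c(40, 140),
                          n_provider_sites = 165,
                          gp_total = 611,
                          irsd_mean = 976.7,
                          irsd_sd = 98.6,
                          irsd_missing = 0.02,
                          seed = 1L) {
  if (!is.numeric(n_areas) || length(n_areas) != 1 || n_areas < 1) {
    stop_field("n_areas", "must be a single count >= 1")
  }
  if (length(pop_range) != 2 || pop_range[1] < 1 || pop_range[1] > pop_range[2]) {
    stop_field("pop_range", "must be (min, max) with 1 <= min <= max")
  }
  if (length(region_extent) != 2 || any(region_extent <= 0)) {
    stop_field("region_extent", "must be positive (width_km, height_km)")
  }
  if (n_provider_sites < 0) {
    stop_field("n_provider_sites", "must be >= 0")
  }
  if (gp_total < n_provider_sites) {
    stop_field("gp_total", "must be >= n_provider_sites (every site has >= 1 GP)")
  }
  if (!is.numeric(irsd_sd) || irsd_sd <= 0) {
    stop_field("irsd_sd", "must be > 0")
  }
  if (irsd_missing < 0 || irsd_missing >= 1) {
    stop_field("irsd_missing", "must be in [0, 1)")
  }
  structure(
    list(
      n_areas = as.integer(n_areas),
      pop_range = as.integer(pop_range),
      region_extent = as.numeric(region_extent),
      n_provider_sites = as.integer(n_provider_sites),
      gp_total = as.integer(gp_total),
      irsd_mean = irsd_mean,
      irsd_sd = irsd_sd,
      irsd_missing = irsd_missing,
      seed = as.integer(seed)
    ),
    class = "region_config"
  )
}

#' Generate synthetic small areas
#'
#' Draws `n_areas` areas with centroids uniform over the planar frame, adult
#' populations uniform-integer over `pop_range`, and IRSD scores from
#' Normal(`irsd_mean`, `irsd_sd`^2) with a configured fraction set missing.
#'
#' @param config A [region_config()].
#' @return A tibble with columns `area_id`, `x_km`, `y_km`, `adult_pop`,
#'   `irsd`.
#' @export
generate_areas <- function(config) {
  stopifnot(inherits(config, "region_config"))
  with_seed(config$seed, {
    n <- config$n_areas
    areas <- tibble::tibble(
      area_id = sprintf("A%05d", seq_len(n)),
      x_km = runif(n, 0, config$region_extent[1]),
      y_km = runif(n, 0, config$region_extent[2]),
      adult_pop = config$pop_range[1] +
        sample.int(config$pop_range[2] - config$pop_range[1] + 1L, n,
                   replace = TRUE) - 1L,
      irsd = rnorm(n, config$irsd_mean, config$irsd_sd)
    )
    if (config$irsd_missing > 0) {
      drop <- runif(n) < config$irsd_missing
      areas$irsd[drop] <- NA_real_
    }
    areas
  })
}

#' Generate synthetic provider sites
#'
#' Places `n_provider_sites` service locations near area centroids sampled
#' with probability proportional to adult population (provider supply tracks
#' population density), then distributes `gp_total` practitioners over the
#' sites with every site receiving at least one.
#'
#' @param config A [region_config()].
#' @param areas Area tibble from [generate_areas()].
#' @return A tibble with columns `site_id`, `x_km`, `y_km`, `gp_count`.
#' @export
generate_providers <- function(config, areas) {
  stopifnot(inherits(config, "region_config"))
  n_sites <- config$n_provider_sites
  if (n_sites == 0L) {
    return(tibble::tibble(
      site_id = character(), x_km = numeric(), y_km = numeric(),
      gp_count = integer()
    ))
  }
  if (nrow(areas) == 0L) {
    stop("`areas` must be non-empty when n_provider_sites > 0.", call. = FALSE)
  }
  if (config$gp_total < n_sites) {
    stop_field("gp_total", "must be >= n_provider_sites")
  }
  assert_columns(areas, c("x_km", "y_km", "adult_pop"), "areas")
  with_seed(config$seed + 1L, {
    host <- sample.int(nrow(areas), n_sites, replace = TRUE,
                       prob = areas$adult_pop)
    # jitter within ~2 km of the host centroid so sites are not exactly on it
    sites <- tibble::tibble(
      site_id = sprintf("S%04d", seq_len(n_sites)),
      x_km = areas$x_km[host] + runif(n_sites, -2, 2),
      y_km = areas$y_km[host] + runif(n_sites, -2, 2),
      gp_count = 1L
    )
    extra <- config$gp_total - n_sites
    if (extra > 0) {
      add <- tabulate(sample.int(n_sites, extra, replace = TRUE),
                      nbins = n_sites)
      sites$gp_count <- sites$gp_count + as.integer(add)
    }
    sites
  })
}

#' Generate a synthetic person-level test table
#'
#' Samples a fraction of each area's adult population as tested persons and
#' emits one test record per person per risk factor, with an optional rate of
#' repeat (earlier) tests so most-recent-test selection has work to do. Test
#' values are left unset; outcomes are attached later by
#' [simulate_outcomes()] (simulation) or classified from measured values
#' (real data).
#'
#' @param areas Area tibble from [generate_areas()].
#' @param window Length-2 study window as `Date` or "YYYY-MM-DD" strings.
#' @param sampling_fraction Fraction of each area's adults who are tested.
#' @param male_share Bernoulli probability of male sex.
#' @param age_probs Length-7 probabilities over the age bands
#'   `r paste(age_bands(), collapse = ", ")`.
#' @param repeat_rate Probability that a person-by-risk-factor pair has one
#'   additional, earlier test record.
#' @param cmrfs Character vector of risk-factor tags (see [cmrf_types()]).
#' @param seed Integer seed.
#' @return A tibble with columns `record_id`, `person_id`, `area_id`, `sex`,
#'   `age_group`, `cmrf`, `test_value` (NA), `test_date`.
#' @export
generate_persons <- function(areas,
                             window = c("2012-01-01", "2017-12-31"),
                             sampling_fraction = 0.25,
                             male_share = 0.48,
                             age_probs = c(0.16, 0.15, 0.16, 0.17, 0.16, 0.12, 0.08),
                             repeat_rate = 0.10,
                             cmrfs = cmrf_types(),
                             seed = 1L) {
  if (nrow(areas) == 0L) stop("`areas` must be non-empty.", call. = FALSE)
  assert_columns(areas, c("area_id", "adult_pop"), "areas")
  window <- as.Date(window)
  if (length(window) != 2 || any(is.na(window)) || window[1] > window[2]) {
    stop_field("window", "must be two ordered dates")
  }
  if (length(age_probs) != 7 || any(age_probs < 0) || sum(age_probs) <= 0) {
    stop_field("age_probs", "must be 7 non-negative weights")
  }
  cmrfs <- match.arg(cmrfs, cmrf_types(), several.ok = TRUE)
  with_seed(seed, {
    n_per_area <- round(sampling_fraction * areas$adult_pop)
    n_persons <- sum(n_per_area)
    persons <- tibble::tibble(
      person_id = sprintf("P%07d", seq_len(n_persons)),
      area_id = rep(areas$area_id, n_per_area),
      sex = ifelse(runif(n_persons) < male_share, "male", "female"),
      age_group = sample(age_bands(), n_persons, replace = TRUE,
                         prob = age_probs / sum(age_probs))
    )
    records <- tidyr::crossing(persons, cmrf = cmrfs)
    n_days <- as.integer(window[2] - window[1]) + 1L
    records$test_date <- window[1] +
      sample.int(n_days, nrow(records), replace = TRUE) - 1L
    # repeat tests: an extra record strictly before (or on) the kept date
    is_rep <- runif(nrow(records)) < repeat_rate
    if (any(is_rep)) {
      reps <- records[is_rep, ]
      offset <- as.integer(reps$test_date - window[1])
      reps$test_date <- window[1] +
        floor(runif(nrow(reps)) * (offset + 1L))
      records <- dplyr::bind_rows(records, reps)
    }
    records$test_value <- NA_real_
    records <- dplyr::arrange(records, .data$person_id, .data$cmrf,
                              .data$test_date)
    records$record_id <- sprintf("R%08d", seq_len(nrow(records)))
    dplyr::select(records, "record_id", "person_id", "area_id", "sex",
                  "age_group", "cmrf", "test_value", "test_date")
  })
}

#' Age bands used by the risk models
#'
#' @return The seven age-band labels; "18-29" is the reference category.
#' @export
age_bands <- function() {
  c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
}

#' Parameters of the generative outcome model
#'
#' The generative analogue of the fully adjusted risk model: a two-level
#' logistic model with fixed effects for sex, age band, standardised area
#' disadvantage and standardised access, plus an area random intercept with
#' variance `tau2`.
#'
#' @param intercept Log-odds at the reference covariate pattern (female,
#'   18-29, mean IRSD, mean access).
#' @param beta_male Log-odds for male vs female.
#' @param beta_age Length-6 log-odds for the non-reference age bands
#'   (30-39 ... 80+).
#' @param beta_irsd Log-odds per SD of area IRSD.
#' @param beta_access Log-odds per SD of area access.
#' @param tau2 Area random-intercept variance (>= 0).
#' @return A list of class `outcome_params`.
#' @export
outcome_params <- function(intercept = logit(0.1),
                           beta_male = 0,
                           beta_age = rep(0, 6),
                           beta_irsd = 0,
                           beta_access = 0,
                           tau2 = 0.1) {
  if (length(beta_age) != 6) {
    stop_field("beta_age", "must have exactly 6 entries (non-reference bands)")
  }
  if (!is.numeric(tau2) || length(tau2) != 1 || tau2 < 0) {
    stop_field("tau2", "must be a single value >= 0")
  }
  structure(
    list(intercept = intercept, beta_male = beta_male,
         beta_age = as.numeric(beta_age), beta_irsd = beta_irsd,
         beta_access = beta_access, tau2 = tau2),
    class = "outcome_params"
  )
}

#' Default generative parameters per risk factor
#'
#' Per-risk-factor parameter sets whose prevalences (4-34%), covariate
#' effects and area-level variances match the magnitudes the fully adjusted
#' risk models report for an Australian regional cohort; used by
#' [run_study()] in simulate mode.
#'
#' @param cmrf One of [cmrf_types()].
#' @return An [outcome_params()] object.
#' @export
default_outcome_params <- function(cmrf = cmrf_types()) {
  cmrf <- match.arg(cmrf)
  p <- switch(cmrf,
    FBSL = list(prev = 0.084, male = 1.63,
                age = c(1.65, 3.57, 6.80, 11.05, 13.8, 12.1),
                irsd = 0.79, access = 0.98, tau2 = 0.039),
    HbA1c = list(prev = 0.107, male = 1.39,
                 age = c(0.81, 1.26, 1.57, 1.64, 1.63, 1.62),
                 irsd = 0.79, access = 1.00, tau2 = 0.047),
    TC = list(prev = 0.326, male = 0.69,
              age = c(2.01, 3.00, 4.07, 2.95, 1.61, 1.14),
              irsd = 1.06, access = 1.00, tau2 = 0.017),
    HDL = list(prev = 0.117, male = 3.98,
               age = c(1.12, 1.00, 0.88, 0.82, 0.85, 0.91),
               irsd = 0.82, access = 0.95, tau2 = 0.029),
    ACR = list(prev = 0.040, male = 1.75,
               age = c(1.00, 0.70, 0.77, 0.96, 1.54, 2.70),
               irsd = 0.82, access = 0.97, tau2 = 0.025),
    eGFR = list(prev = 0.112, male = 0.98,
                age = c(1.65, 4.30, 12.28, 41.83, 149.6, 503.0),
                irsd = 0.90, access = 1.00, tau2 = 0.013),
    BMI = list(prev = 0.337, male = 0.99,
               age = c(1.64, 2.20, 2.44, 2.72, 2.42, 1.45),
               irsd = 0.82, access = 0.93, tau2 = 0.062)
  )
  par <- outcome_params(
    intercept = 0,
    beta_male = log(p$male),
    beta_age = log(p$age),
    beta_irsd = log(p$irsd),
    beta_access = log(p$access),
    tau2 = p$tau2
  )
  par$intercept <- calibrate_intercept(p$prev, par)
  par
}

# Solve for the intercept making the marginal prevalence equal `prev` under
# the default covariate mix: sex/age enumerated with their sampling weights,
# and the Gaussian part (irsd, access effects and the area intercept)
# integrated by Gauss-Hermite quadrature of the combined normal
# N(0, beta_irsd^2 + beta_access^2 + tau2).
calibrate_intercept <- function(prev, params,
                                male_share = 0.48,
                                age_probs = c(0.16, 0.15, 0.16, 0.17, 0.16, 0.12, 0.08)) {
  age_probs <- age_probs / sum(age_probs)
  cell_eta <- outer(c(0, params$beta_male), c(0, params$beta_age), "+")
  cell_w <- outer(c(1 - male_share, male_share), age_probs)
  s2 <- params$beta_irsd^2 + params$beta_access^2 + params$tau2
  gh <- pracma::gaussHermite(21)
  z <- sqrt(2 * s2) * gh$x
  wz <- gh$w / sqrt(pi)
  marg <- function(b0) {
    pr <- vapply(seq_along(z), function(k) {
      sum(cell_w * expit(b0 + cell_eta + z[k]))
    }, numeric(1))
    sum(wz * pr) - prev
  }
  stats::uniroot(marg, interval = c(-20, 10), tol = 1e-10)$root
}

#' Simulate higher-risk outcomes for person records
#'
#' Draws one random intercept per area (per risk factor) from
#' Normal(0, tau2), forms the linear predictor from the person's sex and age
#' band and the area's standardised IRSD and access, and samples the binary
#' higher-risk outcome from the implied Bernoulli probability.
#'
#' @param persons Person record tibble from [generate_persons()].
#' @param areas Area tibble carrying `irsd` and `access` columns.
#' @param params An [outcome_params()] object, or a named list of them keyed
#'   by risk factor to give each risk factor its own generative model.
#' @param seed Integer seed.
#' @param constants Standardisation constants from
#'   [standardization_constants()]; computed from `areas` when NULL. Record
#'   them in the run manifest so model fitting uses the identical constants.
#' @param on_missing_irsd `"error"` (default) stops listing areas whose IRSD
#'   is missing; `"exclude"` drops those persons with a message, mirroring
#'   downstream listwise exclusion.
#' @return `persons` with a `higher_risk` integer column (0/1).
#' @export
simulate_outcomes <- function(persons, areas, params, seed = 1L,
                              constants = NULL,
                              on_missing_irsd = c("error", "exclude")) {
  on_missing_irsd <- match.arg(on_missing_irsd)
  assert_columns(areas, c("area_id", "irsd", "access"), "areas")
  assert_columns(persons, c("person_id", "area_id", "sex", "age_group", "cmrf"),
                 "persons")
  used <- unique(persons$area_id)
  bad <- used[used %in% areas$area_id[is.na(areas$irsd)]]
  if (length(bad) > 0L) {
    if (on_missing_irsd == "error") {
      stop(sprintf(
        "Areas with missing IRSD and no missing-data policy: %s%s",
        paste(head(bad, 10), collapse = ", "),
        if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else ""
      ), call. = FALSE)
    }
    n0 <- nrow(persons)
    persons <- dplyr::filter(persons, !(.data$area_id %in% bad))
    message(sprintf("simulate_outcomes: excluded %d records in %d areas with missing IRSD.",
                    n0 - nrow(persons), length(bad)))
  }
  if (is.null(constants)) constants <- standardization_constants(areas)
  if (inherits(params, "outcome_params")) {
    params <- setNames(
      lapply(unique(persons$cmrf), function(x) params),
      unique(persons$cmrf)
    )
  }
  missing_par <- setdiff(unique(persons$cmrf), names(params))
  if (length(missing_par) > 0L) {
    stop(sprintf("No outcome parameters supplied for: %s",
                 paste(missing_par, collapse = ", ")), call. = FALSE)
  }

  areas_z <- dplyr::mutate(
    areas,
    irsd_z = (.data$irsd - constants$irsd_mean) / constants$irsd_sd,
    access_z = (.data$access - constants$access_mean) / constants$access_sd
  )
  persons <- dplyr::left_join(
    persons,
    dplyr::select(areas_z, "area_id", "irsd_z", "access_z"),
    by = "area_id"
  )

  with_seed(seed, {
    out <- lapply(split(persons, persons$cmrf), function(chunk) {
      par <- params[[chunk$cmrf[1]]]
      area_ids <- sort(unique(chunk$area_id))
      u <- rnorm(length(area_ids), 0, sqrt(par$tau2))
      names(u) <- area_ids
      age_eff <- c(0, par$beta_age)
      names(age_eff) <- age_bands()
      eta <- par$intercept +
        par$beta_male * (chunk$sex == "male") +
        age_eff[chunk$age_group] +
        par$beta_irsd * chunk$irsd_z +
        par$beta_access * chunk$access_z +
        u[chunk$area_id]
      chunk$higher_risk <- rbinom(nrow(chunk), 1L, expit(unname(eta)))
      chunk
    })
    persons <- dplyr::arrange(dplyr::bind_rows(out), .data$record_id)
  })
  dplyr::select(persons, -"irsd_z", -"access_z")
}
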