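# Shared fixtures, built in code.

# Worked 2SFCA example: three collinear areas, two provider sites, d0 = 30.
# Hand enumeration: R1 = 3/(100+200) = 0.01, R2 = 2/(200+300) = 0.004;
# A = (0.010, 0.014, 0.004).
toy_areas <- function() {
  tibble::tibble(
    area_id = c("A1", "A2", "A3"),
    x_km = c(0, 10, 40), y_km = c(0, 0, 0),
    adult_pop = c(100, 200, 300),
    irsd = c(950, 1000, 1050)
  )
}

toy_providers <- function() {
  tibble::tibble(
    site_id = c("S1", "S2"),
    x_km = c(5, 35), y_km = c(0, 0),
    gp_count = c(3L, 2L)
  )
}

# A small simulated region with access computed, for model tests.
small_region <- function(n_areas = 60, pop = c(40, 80), seed = 42,
                         n_sites = 8, gp_total = 30) {
  cfg <- region_config(
    n_areas = n_areas, pop_range = pop, region_extent = c(40, 60),
    n_provider_sites = n_sites, gp_total = gp_total,
    irsd_missing = 0, seed = seed
  )
  areas <- generate_areas(cfg)
  providers <- generate_providers(cfg, areas)
  areas <- compute_access(areas, providers, 30)
  list(config = cfg, areas = areas, providers = providers)
}

# Persons with simulated outcomes for one risk factor over a region.
sim_cohort <- function(region, params, cmrf = "FBSL",
                       sampling_fraction = 1, seed = 7) {
  persons <- generate_persons(
    region$areas, sampling_fraction = sampling_fraction,
    repeat_rate = 0, cmrfs = cmrf, seed = seed
  )
  persons <- simulate_outcomes(persons, region$areas, params, seed = seed + 1)
  dplyr::left_join(
    persons,
    dplyr::select(region$areas, "area_id", "irsd", "access"),
    by = "area_id"
  )
}

# Independent dense-grid oracle for the marginal log-likelihood: for each
# area, trapezoid integration of prod_i Bernoulli(y_i | plogis(eta_i + s z))
# phi(z) over z in [-8, 8].
trapezoid_loglik <- function(design, beta, sigma, n_grid = 20001) {
  z <- seq(-8, 8, length.out = n_grid)
  dz <- z[2] - z[1]
  eta <- drop(design$X %*% beta)
  total <- 0
  for (g in levels(design$group)) {
    idx <- design$group == g
    vals <- vapply(z, function(zk) {
      p <- stats::plogis(eta[idx] + sigma * zk)
      exp(sum(stats::dbinom(design$y[idx], 1, p, log = TRUE))) *
        stats::dnorm(zk)
    }, numeric(1))
    w <- rep(dz, n_grid); w[c(1, n_grid)] <- dz / 2
    total <- total + log(sum(w * vals))
  }
  total
}

# Minimal hand-built fit object for testing closed-form derivations that
# only need estimates and standard errors.
fake_fit <- function(beta, se, terms = character(), loglik = -100,
                     n_obs = 100, n_groups = 10) {
  structure(
    list(
      beta = beta, se = se, tau2 = 0.05, sigma = sqrt(0.05),
      loglik = loglik, aic = -2 * loglik + 2 * (length(beta) + 1),
      n_obs = n_obs, n_groups = n_groups, n_params = length(beta) + 1L,
      converged = TRUE, boundary = FALSE, quad_order = 15L,
      terms = terms, constants = NULL
    ),
    class = "area_glmm"
  )
}
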