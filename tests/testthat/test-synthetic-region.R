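test_that("generate_areas honours counts, ranges and the seed", {
  cfg <- region_config(n_areas = 980, pop_range = c(200, 800), seed = 7)
  areas <- generate_areas(cfg)
  expect_equal(nrow(areas), 980)
  expect_true(all(areas$adult_pop >= 200 & areas$adult_pop <= 800))
  expect_true(all(areas$x_km >= 0 & areas$x_km <= cfg$region_extent[1]))
  expect_true(all(areas$y_km >= 0 & areas$y_km <= cfg$region_extent[2]))
  expect_identical(areas, generate_areas(cfg))

  one <- generate_areas(region_config(n_areas = 1, pop_range = c(400, 400),
                                      irsd_missing = 0))
  expect_equal(one$adult_pop, 400L)
})

test_that("area IRSD follows the configured distribution with MCAR missingness", {
  cfg <- region_config(n_areas = 2000, irsd_mean = 976.7, irsd_sd = 98.6,
                       irsd_missing = 0.05, seed = 3)
  areas <- generate_areas(cfg)
  frac_na <- mean(is.na(areas$irsd))
  expect_lt(abs(frac_na - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  obs <- areas$irsd[!is.na(areas$irsd)]
  expect_lt(abs(mean(obs) - 976.7), 3 * 98.6 / sqrt(length(obs)))
  expect_lt(abs(sd(obs) - 98.6), 10)
})

test_that("invalid region configuration errors name the offending field", {
  expect_error(region_config(n_areas = 0), "n_areas")
  expect_error(region_config(pop_range = c(500, 100)), "pop_range")
  expect_error(region_config(irsd_sd = 0), "irsd_sd")
  expect_error(region_config(n_provider_sites = 10, gp_total = 5), "gp_total")
})

test_that("generate_providers distributes practitioners over sites", {
  cfg <- region_config(n_provider_sites = 165, gp_total = 611, seed = 1)
  areas <- generate_areas(cfg)
  sites <- generate_providers(cfg, areas)
  expect_equal(nrow(sites), 165)
  expect_equal(sum(sites$gp_count), 611)
  expect_true(all(sites$gp_count >= 1))
  expect_identical(sites, generate_providers(cfg, areas))

  none <- region_config(n_provider_sites = 0, gp_total = 0)
  expect_equal(nrow(generate_providers(none, areas)), 0)

  two <- region_config(n_provider_sites = 2, gp_total = 2)
  expect_equal(generate_providers(two, areas)$gp_count, c(1L, 1L))
})

test_that("provider placement tracks population density", {
  cfg <- region_config(n_areas = 400, pop_range = c(10, 1000),
                       n_provider_sites = 120, gp_total = 400,
                       irsd_missing = 0, seed = 5)
  areas <- generate_areas(cfg)
  sites <- generate_providers(cfg, areas)
  # nearest-area population of provider sites should exceed the region mean
  d2 <- outer(sites$x_km, areas$x_km, "-")^2 + outer(sites$y_km, areas$y_km, "-")^2
  host_pop <- areas$adult_pop[apply(d2, 1, which.min)]
  expect_gt(mean(host_pop), mean(areas$adult_pop))
})

test_that("generate_persons respects the sampling fraction, window and repeat rate", {
  areas <- tibble::tibble(
    area_id = c("A1", "A2"), x_km = c(0, 1), y_km = 0,
    adult_pop = c(400L, 600L), irsd = c(900, 1000)
  )
  recs <- generate_persons(areas, sampling_fraction = 1, repeat_rate = 0,
                           cmrfs = "FBSL", seed = 2)
  expect_equal(dplyr::n_distinct(recs$person_id), 1000)
  expect_equal(nrow(recs), 1000)  # one record per person per risk factor

  day <- generate_persons(areas, window = c("2015-06-01", "2015-06-01"),
                          sampling_fraction = 0.1, cmrfs = "TC", seed = 2)
  expect_true(all(day$test_date == as.Date("2015-06-01")))

  reps <- generate_persons(areas, sampling_fraction = 1, repeat_rate = 0.5,
                           cmrfs = c("FBSL", "BMI"), seed = 3)
  expect_gt(nrow(reps), 2000)
  expect_true(all(reps$test_date >= as.Date("2012-01-01") &
                  reps$test_date <= as.Date("2017-12-31")))

  expect_error(
    generate_persons(areas, window = c("2017-01-01", "2012-01-01")),
    "window"
  )
})

test_that("simulated prevalence matches the inverse-logit intercept", {
  areas <- tibble::tibble(
    area_id = sprintf("A%03d", 1:10), x_km = runif(10), y_km = runif(10),
    adult_pop = 1000L, irsd = rnorm(10, 977, 98), access = runif(10, 1, 3) / 1000
  )
  base <- generate_persons(areas, sampling_fraction = 1, repeat_rate = 0,
                           cmrfs = "FBSL", seed = 11)
  # null everything: prevalence -> 0.5
  p0 <- outcome_params(intercept = 0, beta_male = 0, beta_age = rep(0, 6),
                       beta_irsd = 0, beta_access = 0, tau2 = 0)
  out0 <- simulate_outcomes(base, areas, p0, seed = 12)
  expect_lt(abs(mean(out0$higher_risk) - 0.5),
            3 * sqrt(0.25 / nrow(out0)))

  # intercept at the high fasting-glucose prevalence, 8.4%
  areas5 <- dplyr::mutate(areas, adult_pop = 5000L)
  big <- generate_persons(areas5, sampling_fraction = 1, repeat_rate = 0,
                          cmrfs = "FBSL", seed = 13)
  p84 <- outcome_params(intercept = qlogis(0.084), beta_male = 0,
                        beta_age = rep(0, 6), beta_irsd = 0,
                        beta_access = 0, tau2 = 0)
  out84 <- simulate_outcomes(big, areas5, p84, seed = 14)
  expect_gte(nrow(out84), 50000)
  expect_lt(abs(mean(out84$higher_risk) - 0.084),
            3 * sqrt(0.084 * 0.916 / nrow(out84)))
})

test_that("area intercepts are drawn once per area, not per person", {
  areas <- tibble::tibble(
    area_id = sprintf("A%03d", 1:50), x_km = 0, y_km = 0,
    adult_pop = 200L, irsd = rnorm(50, 977, 98), access = runif(50, 0.001, 0.003)
  )
  persons <- generate_persons(areas, sampling_fraction = 1, repeat_rate = 0,
                              cmrfs = "BMI", seed = 21)
  huge <- outcome_params(intercept = 0, tau2 = 25)
  out <- simulate_outcomes(persons, areas, huge, seed = 22)
  prev <- tapply(out$higher_risk, out$area_id, mean)
  # a shared area intercept with tau2 = 25 pushes area prevalences to the
  # extremes; per-person draws would leave them all near 0.5
  expect_gt(sd(prev), 0.3)
  expect_lt(abs(mean(prev) - 0.5), 0.25)
})

test_that("between-area variance of outcomes matches the generative tau2", {
  # oracle: replicate simulations; the variance of area-level empirical
  # logit-prevalences estimates tau2 plus a binomial inflation term
  # ~ E[1/(n p(1-p))], which is subtracted. Tolerance: 3 SEs of the
  # replicate mean plus 0.01 for the remaining delta-method bias.
  areas <- tibble::tibble(
    area_id = sprintf("A%03d", 1:300), x_km = 0, y_km = 0,
    adult_pop = 200L, irsd = rnorm(300, 977, 98), access = runif(300, 0.001, 0.003)
  )
  persons <- generate_persons(areas, sampling_fraction = 1, repeat_rate = 0,
                              cmrfs = "BMI", seed = 31)
  pars <- outcome_params(intercept = 0, tau2 = 0.1)
  stats_rep <- vapply(1:20, function(r) {
    out <- simulate_outcomes(persons, areas, pars, seed = 1000 + r)
    k <- tapply(out$higher_risk, out$area_id, sum)
    n <- tapply(out$higher_risk, out$area_id, length)
    p <- (k + 0.5) / (n + 1)
    var(qlogis(p)) - mean(1 / (n * p * (1 - p)))
  }, numeric(1))
  se <- sd(stats_rep) / sqrt(length(stats_rep))
  expect_lt(abs(mean(stats_rep) - 0.1), 3 * se + 0.01)
})

test_that("default generative parameters hit their target prevalences", {
  reg <- small_region(n_areas = 80, pop = c(150, 250), seed = 8)
  for (risk in c("FBSL", "BMI")) {
    pars <- default_outcome_params(risk)
    target <- c(FBSL = 0.084, BMI = 0.337)[[risk]]
    cohort <- sim_cohort(reg, pars, cmrf = risk, seed = 9)
    # tau2 and area effects add noise beyond binomial; allow 2 percentage pts
    expect_lt(abs(mean(cohort$higher_risk) - target), 0.02)
  }
})
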