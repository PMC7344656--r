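const_test <- function() {
  structure(list(irsd_mean = 977, irsd_sd = 98, access_mean = 0.002,
                 access_sd = 0.0008, n_areas = 10), class = "std_constants")
}

records_grid <- function(n = 10) {
  tibble::tibble(
    higher_risk = rep(c(0L, 1L), length.out = n),
    area_id = rep(c("A1", "A2"), length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    age_group = rep(age_bands(), length.out = n),
    irsd = 977, access = 0.002
  )
}

test_that("the design uses reference coding and supplied centring constants", {
  cons <- const_test()
  ref <- tibble::tibble(
    higher_risk = 0L, area_id = "A1", sex = "female", age_group = "18-29",
    irsd = 977, access = 0.002
  )
  d <- build_design(ref, c("sex", "age", "irsd", "access"), cons)
  expect_equal(ncol(d$X), 10)  # intercept + male + 6 ages + 2 continuous
  expect_equal(unname(d$X[1, ]), c(1, rep(0, 9)))

  row <- dplyr::mutate(ref, sex = "male", age_group = "80+",
                       irsd = 977 - 98)
  d2 <- build_design(row, c("sex", "age", "irsd", "access"), cons)
  expect_equal(unname(d2$X[1, "sexmale"]), 1)
  expect_equal(unname(d2$X[1, "age80+"]), 1)
  expect_equal(unname(d2$X[1, "irsd_z"]), -1)

  d3 <- build_design(records_grid(10), c("sex", "age"))
  expect_equal(ncol(d3$X), 8)  # intercept + sex + 6 age indicators

  bad <- dplyr::mutate(ref, age_group = "17-18")
  expect_error(build_design(bad, c("age")), "age-band")
  cons0 <- const_test(); cons0$irsd_sd <- 0
  expect_error(build_design(ref, "irsd", cons0), "SD")
  expect_error(build_design(ref, "irsd"), "constants")
})

test_that("sigma = 0 reduces to the ordinary logistic log-likelihood", {
  set.seed(4)
  recs <- records_grid(40)
  recs$higher_risk <- rbinom(40, 1, 0.4)
  d <- build_design(recs, c("sex", "age"))
  beta <- rnorm(ncol(d$X), 0, 0.5)
  eta <- drop(d$X %*% beta)
  plain <- sum(stats::dbinom(d$y, 1, plogis(eta), log = TRUE))
  expect_equal(glmm_loglik(d, beta, sigma = 0), plain, tolerance = 1e-12)
})

test_that("adaptive quadrature matches dense-grid integration to 1e-6", {
  set.seed(5)
  recs <- tibble::tibble(
    higher_risk = rbinom(12, 1, 0.5),
    area_id = rep(c("A1", "A2", "A3"), each = 4),
    sex = sample(c("female", "male"), 12, replace = TRUE),
    age_group = "18-29", irsd = 977, access = 0.002
  )
  d <- build_design(recs, "sex")
  for (r in 1:3) {
    beta <- rnorm(2, 0, 0.8)
    sigma <- runif(1, 0.1, 1.2)
    expect_equal(glmm_loglik(d, beta, sigma, order = 15),
                 trapezoid_loglik(d, beta, sigma),
                 tolerance = 1e-6)
  }
})

test_that("duplicating every area doubles the log-likelihood exactly", {
  set.seed(6)
  recs <- records_grid(30)
  recs$higher_risk <- rbinom(30, 1, 0.5)
  twice <- dplyr::bind_rows(recs, dplyr::mutate(recs, area_id = paste0(area_id, "_copy")))
  d1 <- build_design(recs, "sex")
  d2 <- build_design(twice, "sex")
  beta <- c(-0.3, 0.4)
  expect_equal(glmm_loglik(d2, beta, 0.6), 2 * glmm_loglik(d1, beta, 0.6),
               tolerance = 1e-10)
})

test_that("the log-likelihood is invariant to area relabelling and row order", {
  set.seed(7)
  reg <- small_region(n_areas = 25, seed = 77)
  pars <- outcome_params(intercept = -1, beta_male = 0.4, tau2 = 0.2)
  recs <- sim_cohort(reg, pars, seed = 78)
  d <- build_design(recs, "sex")
  beta <- c(-1, 0.4)
  base <- glmm_loglik(d, beta, 0.5)

  perm <- recs[sample(nrow(recs)), ]
  expect_equal(glmm_loglik(build_design(perm, "sex"), beta, 0.5), base,
               tolerance = 1e-9)
  relab <- dplyr::mutate(recs, area_id = paste0("zone-", area_id))
  expect_equal(glmm_loglik(build_design(relab, "sex"), beta, 0.5), base,
               tolerance = 1e-9)
})

test_that("increasing the quadrature order converges on fixtures", {
  reg <- small_region(n_areas = 30, seed = 12)
  pars <- outcome_params(intercept = -1.2, beta_male = 0.5, tau2 = 0.15)
  recs <- sim_cohort(reg, pars, seed = 13)
  cons <- standardization_constants(reg$areas)
  f7 <- fit_area_glmm(recs, c("sex", "irsd"), cons, quad_order = 7, se = FALSE)
  f21 <- fit_area_glmm(recs, c("sex", "irsd"), cons, quad_order = 21, se = FALSE)
  expect_lt(abs(f7$loglik - f21$loglik), 1e-4)

  d <- build_design(recs, "sex")
  beta <- c(-1.2, 0.5)
  dense <- trapezoid_loglik(d, beta, 0.4, n_grid = 20001)
  errs <- vapply(c(3, 7, 15), function(k)
    abs(glmm_loglik(d, beta, 0.4, order = k) - dense), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))  # error shrinks with order
})

test_that("the ML fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  reg <- small_region(n_areas = 40, pop = c(40, 60), seed = 19)
  pars <- outcome_params(intercept = -1, beta_male = 0.4,
                         beta_age = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                         beta_irsd = -0.2, beta_access = -0.1, tau2 = 0.1)
  recs <- sim_cohort(reg, pars, seed = 20)
  cons <- standardization_constants(reg$areas)
  fit <- fit_area_glmm(recs, c("sex", "age", "irsd", "access"), cons,
                       quad_order = 15)
  dat <- dplyr::mutate(
    recs,
    irsd_z = (irsd - cons$irsd_mean) / cons$irsd_sd,
    access_z = (access - cons$access_mean) / cons$access_sd
  )
  ref <- lme4::glmer(
    higher_risk ~ sex + age_group + irsd_z + access_z + (1 | area_id),
    data = dat, family = binomial, nAGQ = 15
  )
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$tau2, unname(lme4::VarCorr(ref)$area_id[1]),
               tolerance = 1e-3)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(as.matrix(stats::vcov(ref))))),
               tolerance = 0.02)
})

test_that("null-variance data are recovered at the boundary", {
  reg <- small_region(n_areas = 100, pop = c(150, 250), seed = 23)
  pars <- outcome_params(intercept = -1.5, beta_male = 0.5, tau2 = 0)
  recs <- sim_cohort(reg, pars, seed = 24)
  fit <- fit_area_glmm(recs, "sex", quad_order = 15)
  expect_lt(fit$tau2, 0.01)
  expect_lt(abs(fit$beta[["sexmale"]] - 0.5), 3 * fit$se[["sexmale"]])
  expect_lt(abs(fit$beta[["(Intercept)"]] + 1.5), 3 * fit$se[["(Intercept)"]])
  expect_true(fit$converged)
})

test_that("the AIC identity holds and single-class outcomes error", {
  reg <- small_region(n_areas = 20, seed = 31)
  pars <- outcome_params(intercept = -1, tau2 = 0.1)
  recs <- sim_cohort(reg, pars, seed = 32)
  fit <- fit_area_glmm(recs, character(), se = FALSE)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$n_params, length(fit$beta) + 1L)

  allzero <- dplyr::mutate(recs, higher_risk = 0L)
  expect_error(fit_area_glmm(allzero, character()), "single class")
  expect_error(fit_area_glmm(recs[recs$area_id == recs$area_id[1], ],
                             character()), "2 areas")
})

test_that("odds ratios exponentiate the coefficients with Wald intervals", {
  # the low-HDL access estimate: beta = -0.062, se = 0.014
  fit <- fake_fit(
    beta = c("(Intercept)" = -2, "access_z" = -0.062, "x" = log(2)),
    se = c(0.05, 0.014, 0.1)
  )
  tab <- odds_ratios(fit)
  expect_equal(round(tab$or[tab$term == "access_z"], 2), 0.94)
  expect_equal(round(tab$or_low[tab$term == "access_z"], 2), 0.91)
  expect_equal(round(tab$or_high[tab$term == "access_z"], 2), 0.97)
  expect_equal(tab$or[tab$term == "x"], 2)

  null_fit <- fake_fit(beta = c(a = 0), se = c(a = 0.1))
  tab0 <- odds_ratios(null_fit)
  expect_equal(tab0$or, 1)
  expect_true(tab0$or_low < 1 && tab0$or_high > 1)
  expect_equal(tab0$p_value, 1)
})

test_that("likelihood-ratio tests compare nested fits on the chi-square scale", {
  f1 <- fake_fit(beta = c(a = 0.1), se = c(a = 0.1), terms = character(),
                 loglik = -500)
  f2 <- fake_fit(beta = c(a = 0.1, b = 0.2), se = c(0.1, 0.1),
                 terms = "access", loglik = -500)
  same <- lr_test(f1, f2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  f3 <- fake_fit(beta = c(a = 0.1, b = 0.2), se = c(0.1, 0.1),
                 terms = "access", loglik = -500 + 3.841 / 2)
  crit <- lr_test(f1, f3)
  expect_equal(crit$df, 1)
  expect_equal(crit$p_value, 0.05, tolerance = 1e-3)

  f4 <- fake_fit(beta = c(a = 1), se = c(a = 1), terms = "irsd", loglik = -499)
  expect_error(lr_test(f2, f4), "nested")
  f5 <- fake_fit(beta = c(a = 1), se = c(a = 1), n_obs = 50, loglik = -499)
  expect_error(lr_test(f5, f2), "observations")
})

test_that("tidy and glance expose broom-style summaries", {
  reg <- small_region(n_areas = 25, seed = 41)
  pars <- outcome_params(intercept = -1, beta_male = 0.3, tau2 = 0.1)
  recs <- sim_cohort(reg, pars, seed = 42)
  fit <- fit_area_glmm(recs, "sex")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n_obs, fit$n_obs)
  expect_equal(gl$AIC, fit$aic)
  expect_equal(gl$icc, icc_latent(fit$tau2))
})
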