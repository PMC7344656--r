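# Contextual-effect statistics derived from the area-level variance of a
# two-level logistic model. All are closed forms in tau2.

#' Latent-variable intraclass correlation
#'
#' Share of total outcome variance attributable to areas under the logistic
#' threshold model: `ICC = tau2 / (tau2 + pi^2/3)`, where pi^2/3 (~3.289868)
#' is the variance of the standard logistic distribution.
#'
#' @param tau2 Area-level random-intercept variance(s), >= 0.
#' @return ICC as a proportion in [0, 1).
#' @export
#' @examples
#' icc_latent(0.101)  # ~0.030
icc_latent <- function(tau2) {
  if (any(!is.finite(tau2)) || any(tau2 < 0)) {
    stop_field("tau2", "must be finite and >= 0")
  }
  tau2 / (tau2 + pi^2 / 3)
}

#' Median odds ratio
#'
#' The median of the odds ratios comparing two identical persons from a
#' randomly drawn higher- vs lower-risk area:
#' `MOR = exp(sqrt(2 tau2) * qnorm(0.75))`. Equals 1 when there is no area
#' effect and increases with tau2.
#'
#' @param tau2 Area-level random-intercept variance(s), >= 0.
#' @return MOR, always >= 1.
#' @export
#' @examples
#' median_odds_ratio(0.189)  # ~1.51
median_odds_ratio <- function(tau2) {
  if (any(!is.finite(tau2)) || any(tau2 < 0)) {
    stop_field("tau2", "must be finite and >= 0")
  }
  exp(sqrt(2 * tau2) * qnorm(0.75))
}

#' Proportional change in variance
#'
#' Signed percent change of the area-level variance relative to a reference
#' (usually null) model: `100 * (tau2_model - tau2_ref) / tau2_ref`.
#' Negative values mean variance explained by the added terms; positive
#' values mean inflation.
#'
#' @param tau2_ref Reference-model variance (> 0).
#' @param tau2_model Comparison-model variance (>= 0).
#' @return Signed percent.
#' @export
pcv <- function(tau2_ref, tau2_model) {
  if (any(!is.finite(tau2_ref)) || any(tau2_ref <= 0)) {
    stop_field("tau2_ref", "must be > 0")
  }
  if (any(!is.finite(tau2_model)) || any(tau2_model < 0)) {
    stop_field("tau2_model", "must be >= 0")
  }
  100 * (tau2_model - tau2_ref) / tau2_ref
}

#' Area-level variance explained by access
#'
#' The unique contribution of the access term: the signed percent change in
#' area-level variance from the covariate-adjusted model (M4) to the model
#' adding access (M5). Negative values mean access explains additional
#' variance beyond the other covariates.
#'
#' @param tau2_m4 Variance of the sex + age + disadvantage model (> 0).
#' @param tau2_m5 Variance after adding access (>= 0).
#' @return Signed percent.
#' @export
access_explained <- function(tau2_m4, tau2_m5) {
  pcv(tau2_m4, tau2_m5)
}

#' Model-ladder summary table
#'
#' One row per fitted model with AIC, area-level variance, latent ICC (as a
#' percent), MOR, and PCV against the first (reference) model. Values are
#' unrounded; round only for display.
#'
#' @param fits A named list of `area_glmm` fits in nesting order; the first
#'   entry is the PCV reference (the null model).
#' @return A tibble with columns `model`, `aic`, `tau2`, `icc_pct`, `mor`,
#'   `pcv_pct` (NA for the reference row).
#' @export
ladder_summary <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "area_glmm")))
  if (is.null(names(fits))) names(fits) <- paste0("M", seq_along(fits))
  tau2 <- vapply(fits, `[[`, numeric(1), "tau2")
  ref <- tau2[[1]]
  tibble::tibble(
    model = names(fits),
    aic = unname(vapply(fits, `[[`, numeric(1), "aic")),
    loglik = unname(vapply(fits, `[[`, numeric(1), "loglik")),
    tau2 = unname(tau2),
    icc_pct = 100 * icc_latent(unname(tau2)),
    mor = median_odds_ratio(unname(tau2)),
    pcv_pct = c(NA_real_, if (length(tau2) > 1) {
      if (ref > 0) pcv(ref, unname(tau2[-1])) else rep(NA_real_, length(tau2) - 1)
    })
  )
}
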