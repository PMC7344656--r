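#' Area-level standardisation constants
#'
#' Unweighted mean and SD of IRSD and access over areas (areas with missing
#' IRSD are dropped first). Continuous model terms are mean-centred and
#' scaled by these constants, so their odds ratios are per SD of the
#' area-level distribution. Compute the constants once per analysis dataset
#' and share them across all nested models (and with the outcome simulator).
#'
#' @param areas Area tibble with `irsd` and `access` columns.
#' @return A list of class `std_constants` with `irsd_mean`, `irsd_sd`,
#'   `access_mean`, `access_sd`, `n_areas`.
#' @export
standardization_constants <- function(areas) {
  assert_columns(areas, c("irsd", "access"), "areas")
  ok <- !is.na(areas$irsd)
  if (sum(ok) < 2) {
    stop("Need at least two areas with non-missing IRSD to standardise.",
         call. = FALSE)
  }
  out <- list(
    irsd_mean = mean(areas$irsd[ok]),
    irsd_sd = sd(areas$irsd[ok]),
    access_mean = mean(areas$access[ok]),
    access_sd = sd(areas$access[ok]),
    n_areas = sum(ok)
  )
  if (out$irsd_sd <= 0 || out$access_sd <= 0) {
    stop("Standardisation SD is zero; IRSD and access must vary across areas.",
         call. = FALSE)
  }
  structure(out, class = "std_constants")
}

#' Build the fixed-effects design for a risk model
#'
#' Encodes the response and design matrix of a two-level risk model: an
#' intercept always; a male indicator (female reference); six age-band
#' indicators (18-29 reference); and standardised IRSD and access columns
#' `(x - mean)/SD` using the supplied area-level constants.
#'
#' @param records Dichotomised person records with `higher_risk`, `area_id`,
#'   and whichever of `sex`, `age_group`, `irsd`, `access` the terms need.
#' @param terms Character subset of `c("access", "sex", "age", "irsd")`; the
#'   intercept is always included. `character(0)` gives the null model.
#' @param constants [standardization_constants()] for the continuous terms.
#' @return A list of class `glmm_design` with elements `y` (0/1 response),
#'   `X` (design matrix), `group` (area factor), `terms`, `constants`.
#' @export
build_design <- function(records, terms = character(),
                         constants = NULL) {
  allowed <- c("access", "sex", "age", "irsd")
  bad <- setdiff(terms, allowed)
  if (length(bad) > 0L) {
    stop(sprintf("Unknown model term(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  assert_columns(records, c("higher_risk", "area_id"), "records")
  y <- as.integer(records$higher_risk)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop("`higher_risk` must be 0/1 with no missing values.", call. = FALSE)
  }
  n <- length(y)
  cols <- list("(Intercept)" = rep(1, n))
  if ("sex" %in% terms) {
    assert_columns(records, "sex", "records")
    cols[["sexmale"]] <- as.numeric(records$sex == "male")
  }
  if ("age" %in% terms) {
    assert_columns(records, "age_group", "records")
    unseen <- setdiff(unique(records$age_group), age_bands())
    if (length(unseen) > 0L) {
      stop(sprintf("Unseen age-band label(s): %s",
                   paste(unseen, collapse = ", ")), call. = FALSE)
    }
    for (band in age_bands()[-1]) {
      cols[[paste0("age", band)]] <- as.numeric(records$age_group == band)
    }
  }
  if (any(c("irsd", "access") %in% terms) && is.null(constants)) {
    stop("Continuous terms need `constants`; see standardization_constants().",
         call. = FALSE)
  }
  if ("irsd" %in% terms) {
    assert_columns(records, "irsd", "records")
    if (constants$irsd_sd <= 0) stop("IRSD SD must be > 0.", call. = FALSE)
    cols[["irsd_z"]] <- (records$irsd - constants$irsd_mean) / constants$irsd_sd
  }
  if ("access" %in% terms) {
    assert_columns(records, "access", "records")
    if (constants$access_sd <= 0) stop("Access SD must be > 0.", call. = FALSE)
    cols[["access_z"]] <-
      (records$access - constants$access_mean) / constants$access_sd
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (any(!is.finite(X))) {
    stop("Design matrix contains missing or non-finite values.", call. = FALSE)
  }
  structure(
    list(
      y = y,
      X = X,
      group = factor(records$area_id),
      terms = terms,
      constants = constants
    ),
    class = "glmm_design"
  )
}
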