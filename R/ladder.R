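#' Fixed-effect terms of the five nested risk models
#'
#' M1 is the null (intercept-only) model; M2 adds access; M3 adds sex and
#' age to the null model; M4 adds area disadvantage to M3; M5 adds access to
#' M4. M2 is nested in M1's successors only through M5, so likelihood-ratio
#' tests follow the nesting arrows M1->M2, M1->M3, M3->M4, M4->M5.
#'
#' @return A named list of term vectors.
#' @export
ladder_terms <- function() {
  list(
    M1 = character(0),
    M2 = "access",
    M3 = c("sex", "age"),
    M4 = c("sex", "age", "irsd"),
    M5 = c("sex", "age", "irsd", "access")
  )
}

#' Fit the nested model ladder for one risk factor
#'
#' Joins area-level covariates onto the dichotomised records, computes one
#' set of area-level standardisation constants shared by every model, fits
#' the five nested random-intercept logistic models, and derives the
#' odds-ratio tables, variance-ladder summary (AIC, tau2, ICC, MOR, PCV),
#' successive likelihood-ratio tests, and the variance uniquely explained by
#' access (M4 vs M5).
#'
#' @param records Dichotomised records for a single risk factor:
#'   `higher_risk`, `area_id`, `sex`, `age_group`.
#' @param areas Area tibble with `area_id`, `irsd`, `access`.
#' @param quad_order Gauss-Hermite node count for every fit.
#' @param se Compute Wald standard errors (skip in simulation studies).
#' @param models Named list of term vectors; defaults to [ladder_terms()].
#' @param constants Standardisation constants; computed from `areas` when
#'   NULL.
#' @return An object of class `cmrf_ladder`: `fits` (named list, NULL where
#'   a fit failed), `summary` ([ladder_summary()] tibble), `or_tables`,
#'   `lrt`, `access_explained_pct`, `failures`, `constants`.
#' @export
run_ladder <- function(records, areas, quad_order = 15, se = TRUE,
                       models = ladder_terms(), constants = NULL) {
  assert_columns(records, c("higher_risk", "area_id"), "records")
  assert_columns(areas, c("area_id", "irsd", "access"), "areas")
  if (is.null(constants)) constants <- standardization_constants(areas)
  cmrf <- if ("cmrf" %in% names(records)) unique(records$cmrf) else NA_character_
  if (length(cmrf) > 1) {
    stop("`records` mixes several risk factors; fit one ladder per factor.",
         call. = FALSE)
  }
  data <- dplyr::left_join(
    records,
    dplyr::select(areas, "area_id", "irsd", "access"),
    by = "area_id"
  )
  fits <- vector("list", length(models))
  names(fits) <- names(models)
  failures <- character(0)
  for (m in names(models)) {
    fits[[m]] <- tryCatch(
      fit_area_glmm(data, terms = models[[m]], constants = constants,
                    quad_order = quad_order, se = se),
      error = function(e) {
        failures[[m]] <<- conditionMessage(e)
        NULL
      }
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  summary <- if (any(ok)) ladder_summary(fits[ok]) else NULL

  # LRTs along the actual nesting arrows, asserted via lr_test()
  arrows <- list(c("M1", "M2"), c("M1", "M3"), c("M3", "M4"), c("M4", "M5"))
  lrt <- purrr::map_dfr(arrows, function(a) {
    if (!all(a %in% names(fits)) || is.null(fits[[a[1]]]) ||
        is.null(fits[[a[2]]])) {
      return(tibble::tibble())
    }
    stopifnot(all(fits[[a[1]]]$terms %in% fits[[a[2]]]$terms))
    dplyr::bind_cols(
      tibble::tibble(nested = a[1], full = a[2]),
      lr_test(fits[[a[1]]], fits[[a[2]]])
    )
  })
  access_pct <- if (!is.null(fits$M4) && !is.null(fits$M5) &&
                    fits$M4$tau2 > 0) {
    access_explained(fits$M4$tau2, fits$M5$tau2)
  } else {
    NA_real_
  }
  structure(
    list(
      cmrf = cmrf,
      fits = fits,
      summary = summary,
      or_tables = purrr::map(fits[ok], odds_ratios),
      lrt = lrt,
      access_explained_pct = access_pct,
      failures = failures,
      constants = constants
    ),
    class = "cmrf_ladder"
  )
}

#' @export
print.cmrf_ladder <- function(x, ...) {
  cat(sprintf("Nested risk-model ladder%s\n",
              if (!is.na(x$cmrf)) paste0(" for ", x$cmrf) else ""))
  if (length(x$failures) > 0) {
    cat("Failed fits:", paste(names(x$failures), collapse = ", "), "\n")
  }
  print(x$summary, ...)
  if (is.finite(x$access_explained_pct)) {
    cat(sprintf("Proportional variance explained by access (M4 -> M5): %+.2f%%\n",
                x$access_explained_pct))
  }
  invisible(x)
}

#' @rdname run_ladder
#' @param x A `cmrf_ladder` object.
#' @param ... Unused.
#' @export
tidy.cmrf_ladder <- function(x, ...) {
  x$summary
}

#' @rdname run_ladder
#' @export
glance.cmrf_ladder <- function(x, ...) {
  tibble::tibble(
    cmrf = x$cmrf,
    n_models = sum(!vapply(x$fits, is.null, logical(1))),
    tau2_null = if (!is.null(x$fits$M1)) x$fits$M1$tau2 else NA_real_,
    tau2_full = if (!is.null(x$fits$M5)) x$fits$M5$tau2 else NA_real_,
    access_explained_pct = x$access_explained_pct
  )
}
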