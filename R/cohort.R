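#' Cardiometabolic risk factor tags
#'
#' @return The seven risk-factor tags: fasting blood sugar level, glycated
#'   haemoglobin, total cholesterol, high density lipoprotein, urinary
#'   albumin-creatinine ratio, estimated glomerular filtration rate, and body
#'   mass index.
#' @export
cmrf_types <- function() {
  c("FBSL", "HbA1c", "TC", "HDL", "ACR", "eGFR", "BMI")
}

#' Risk dichotomisation rules
#'
#' Guideline cut-points classifying each test as higher risk:
#' FBSL >= 7.0 mmol/L, HbA1c > 7.5%, TC >= 5.5 mmol/L, HDL < 1 mmol/L,
#' ACR >= 30 mg/mmol-scale, eGFR < 60 mL/min/1.73m^2, BMI >= 30 kg/m^2.
#' Boundary semantics follow the printed inequalities: a value exactly at a
#' ">=" or "<" threshold is classified by that operator (7.0 is high FBSL;
#' HbA1c 7.5 is not high; HDL 1.0 is not low).
#'
#' @return A tibble with columns `cmrf`, `direction` (one of ">=", ">", "<"),
#'   `threshold`, `unit`, `label`.
#' @export
risk_thresholds <- function() {
  tibble::tribble(
    ~cmrf,   ~direction, ~threshold, ~unit,                ~label,
    "FBSL",  ">=",       7.0,        "mmol/L",             "High FBSL",
    "HbA1c", ">",        7.5,        "%",                  "High HbA1c",
    "TC",    ">=",       5.5,        "mmol/L",             "High TC",
    "HDL",   "<",        1.0,        "mmol/L",             "Low HDL",
    "ACR",   ">=",       30,         "mcg/L to mg/L",      "High ACR",
    "eGFR",  "<",        60,         "mL/min/1.73 m^2",    "Low eGFR",
    "BMI",   ">=",       30,         "kg/m^2",             "Obesity"
  )
}

#' Classify a test value as higher risk
#'
#' Applies the dichotomisation rule for the given risk factor. Vectorised
#' over `cmrf` and `value`.
#'
#' @param cmrf Risk-factor tag(s), see [cmrf_types()].
#' @param value Test value(s) in the rule's units.
#' @return Logical vector: TRUE when the test is in the higher-risk class.
#' @export
#' @examples
#' classify_risk("FBSL", 7.0)   # TRUE, boundary inclusive for >=
#' classify_risk("HbA1c", 7.5)  # FALSE, strict >
classify_risk <- function(cmrf, value) {
  rules <- risk_thresholds()
  unknown <- setdiff(unique(cmrf), rules$cmrf)
  if (length(unknown) > 0L) {
    stop(sprintf("Unknown CMRF tag(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  idx <- match(cmrf, rules$cmrf)
  dir <- rules$direction[idx]
  thr <- rules$threshold[idx]
  out <- rep(NA, length(value))
  out[dir == ">="] <- value[dir == ">="] >= thr[dir == ">="]
  out[dir == ">"] <- value[dir == ">"] > thr[dir == ">"]
  out[dir == "<"] <- value[dir == "<"] < thr[dir == "<"]
  out
}

#' Add a higher-risk flag to test records
#'
#' Dichotomises `test_value` per record using [classify_risk()].
#'
#' @param records Tibble with `cmrf` and `test_value` columns.
#' @return `records` with a `higher_risk` integer column (0/1).
#' @export
classify_records <- function(records) {
  assert_columns(records, c("cmrf", "test_value"), "records")
  records$higher_risk <- as.integer(classify_risk(records$cmrf,
                                                  records$test_value))
  records
}

#' Keep the most recent test per person and risk factor
#'
#' Restricts records to the study window, then keeps for each
#' (person, risk factor) pair the record with the latest test date. Ties on
#' the date are broken deterministically by the highest `record_id`. Counts
#' of dropped records are attached as the `"dropped"` attribute
#' (out_of_window, superseded).
#'
#' @param records Tibble with `person_id`, `cmrf`, `test_date`, `record_id`.
#' @param window Length-2 study window (Date or "YYYY-MM-DD"); records
#'   outside it are dropped first. NULL keeps all dates.
#' @return One record per (person, cmrf) pair.
#' @export
select_most_recent <- function(records, window = NULL) {
  assert_columns(records, c("person_id", "cmrf", "test_date", "record_id"),
                 "records")
  n0 <- nrow(records)
  if (!is.null(window)) {
    window <- as.Date(window)
    records <- dplyr::filter(records, .data$test_date >= window[1],
                             .data$test_date <= window[2])
  }
  n_window <- n0 - nrow(records)
  kept <- records |>
    dplyr::arrange(.data$person_id, .data$cmrf, dplyr::desc(.data$test_date),
                   dplyr::desc(.data$record_id)) |>
    dplyr::distinct(.data$person_id, .data$cmrf, .keep_all = TRUE)
  attr(kept, "dropped") <- c(out_of_window = n_window,
                             superseded = nrow(records) - nrow(kept))
  kept
}

#' Exclude records with incomplete details
#'
#' Drops records missing sex, age group, test outcome (a measured
#' `test_value`, or `higher_risk` when values were simulated), an area link,
#' or whose linked area lacks an IRSD score (listwise exclusion). The
#' exclusion log is attached as the `"exclusions"` attribute, a tibble of
#' per-reason counts readable with [exclusion_log()].
#'
#' @param records Person-level test records.
#' @param areas Area tibble with `area_id` and `irsd`.
#' @return The retained records.
#' @export
exclude_incomplete <- function(records, areas) {
  assert_columns(records, c("person_id", "area_id", "sex", "age_group"),
                 "records")
  assert_columns(areas, c("area_id", "irsd"), "areas")
  value_col <- if ("higher_risk" %in% names(records) &&
                   !all(is.na(records$higher_risk))) "higher_risk" else "test_value"
  irsd_missing_areas <- areas$area_id[is.na(areas$irsd)]
  reasons <- list(
    sex = is.na(records$sex),
    age_group = is.na(records$age_group) |
      !(records$age_group %in% age_bands()),
    area_link = is.na(records$area_id) | !(records$area_id %in% areas$area_id),
    test_value = is.na(records[[value_col]]),
    area_irsd = records$area_id %in% irsd_missing_areas
  )
  # first matching reason wins, in the order above
  reason_idx <- rep(0L, nrow(records))
  for (k in seq_along(reasons)) {
    hit <- reasons[[k]] & reason_idx == 0L
    reason_idx[hit] <- k
  }
  log <- tibble::tibble(
    reason = names(reasons),
    n_excluded = vapply(seq_along(reasons),
                        function(k) sum(reason_idx == k), integer(1))
  )
  retained <- records[reason_idx == 0L, , drop = FALSE]
  attr(retained, "exclusions") <- log
  if (sum(log$n_excluded) > 0) {
    message(sprintf("exclude_incomplete: dropped %d of %d records (%s).",
                    sum(log$n_excluded), nrow(records),
                    paste(sprintf("%s: %d", log$reason, log$n_excluded),
                          collapse = ", ")))
  }
  retained
}

#' Read the exclusion log of a filtered record set
#'
#' @param records Output of [exclude_incomplete()].
#' @return A tibble of per-reason exclusion counts.
#' @export
exclusion_log <- function(records) {
  log <- attr(records, "exclusions")
  if (is.null(log)) {
    stop("No exclusion log found; was this produced by exclude_incomplete()?",
         call. = FALSE)
  }
  log
}

#' Risk-proportion summary by risk factor and sex
#'
#' One row per risk factor with the number of tests, the higher-risk count
#' and percentage, and the male/female higher-risk counts and percentages.
#' All percentages use that risk factor's test count as denominator and are
#' reported to one decimal place.
#'
#' @param records Dichotomised records with `cmrf`, `higher_risk`, `sex`.
#' @return A tibble with columns `cmrf`, `n_tests`, `n_higher_risk`,
#'   `pct_higher_risk`, `n_male_higher`, `pct_male`, `n_female_higher`,
#'   `pct_female`.
#' @export
risk_summary <- function(records) {
  assert_columns(records, c("cmrf", "higher_risk", "sex"), "records")
  records |>
    dplyr::group_by(.data$cmrf) |>
    dplyr::summarise(
      n_tests = dplyr::n(),
      n_higher_risk = sum(.data$higher_risk == 1),
      n_male_higher = sum(.data$higher_risk == 1 & .data$sex == "male"),
      n_female_higher = sum(.data$higher_risk == 1 & .data$sex == "female"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_higher_risk = pct_of(.data$n_higher_risk, .data$n_tests),
      pct_male = pct_of(.data$n_male_higher, .data$n_tests),
      pct_female = pct_of(.data$n_female_higher, .data$n_tests)
    ) |>
    dplyr::select("cmrf", "n_tests", "n_higher_risk", "pct_higher_risk",
                  "n_male_higher", "pct_male", "n_female_higher", "pct_female")
}
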