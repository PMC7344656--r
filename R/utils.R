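# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Percentage n/d * 100 rounded to one decimal, the convention used for the
# risk-proportion tables; NA when the denominator is zero.
pct_of <- function(n, d, digits = 1) {
  ifelse(d > 0, round(100 * n / d, digits), NA_real_)
}

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

stop_field <- function(field, msg) {
  stop(sprintf("Invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

assert_finite_coords <- function(df, what) {
  assert_columns(df, c("x_km", "y_km"), what)
  if (!all(is.finite(df$x_km)) || !all(is.finite(df$y_km))) {
    stop(sprintf("`%s` has missing or non-finite coordinates.", what),
         call. = FALSE)
  }
  invisible(df)
}
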