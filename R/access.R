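#' Catchment membership within a radial buffer
#'
#' For each centre, finds the points whose straight-line (Euclidean, planar)
#' distance is within the buffer radius `d0`. The boundary is inclusive: a
#' point exactly `d0` away is a member.
#'
#' @param centres,points Data frames with `x_km`, `y_km` columns.
#' @param d0 Buffer radius in km (> 0).
#' @return A list, one integer vector of point indices per centre.
#' @export
#' @examples
#' centres <- tibble::tibble(x_km = 0, y_km = 0)
#' points <- tibble::tibble(x_km = c(5, 35), y_km = 0)
#' catchment_members(centres, points, d0 = 30)
catchment_members <- function(centres, points, d0) {
  if (!is.numeric(d0) || length(d0) != 1 || !is.finite(d0) || d0 <= 0) {
    stop_field("d0", "must be a single positive distance in km")
  }
  assert_finite_coords(centres, "centres")
  assert_finite_coords(points, "points")
  if (nrow(points) == 0L) {
    return(rep(list(integer()), nrow(centres)))
  }
  d2 <- outer(centres$x_km, points$x_km, "-")^2 +
    outer(centres$y_km, points$y_km, "-")^2
  within <- d2 <= d0^2
  lapply(seq_len(nrow(centres)), function(i) which(within[i, ]))
}

#' 2SFCA step 1: provider-to-population ratios
#'
#' For each provider site j, computes R_j = S_j / sum(p_i) where S_j is the
#' site's GP count and the sum runs over the adult populations of areas whose
#' centroids lie within `buffer_km` of the site. Sites whose catchment is
#' empty or has zero total population get `ratio = NA` (undefined) and are
#' excluded from step 2 with a warning.
#'
#' @param providers Provider tibble with `x_km`, `y_km`, `gp_count`.
#' @param areas Area tibble with `x_km`, `y_km`, `adult_pop`.
#' @param buffer_km Radial buffer distance d0 in km.
#' @return `providers` with a `ratio` column; the buffer used is recorded in
#'   the `buffer_km` attribute so step 2 can verify both steps share it.
#' @export
provider_ratios <- function(providers, areas, buffer_km = 30) {
  assert_columns(providers, c("x_km", "y_km", "gp_count"), "providers")
  assert_columns(areas, c("x_km", "y_km", "adult_pop"), "areas")
  members <- catchment_members(providers, areas, buffer_km)
  pop <- vapply(members, function(idx) sum(areas$adult_pop[idx]), numeric(1))
  ratio <- ifelse(pop > 0, providers$gp_count / pop, NA_real_)
  n_undef <- sum(is.na(ratio))
  if (n_undef > 0) {
    warning(sprintf(
      "%d provider site(s) have an empty or zero-population catchment at d0 = %g km; their ratios are undefined and excluded from the access index.",
      n_undef, buffer_km
    ), call. = FALSE)
  }
  providers$ratio <- ratio
  attr(providers, "buffer_km") <- buffer_km
  providers
}

#' 2SFCA step 2: per-area access index
#'
#' For each area i, sums the provider ratios R_j of sites within `buffer_km`
#' of the area centroid: A_i = sum_j R_j, in practitioners per capita. Areas
#' reaching no site (or only sites with undefined ratios) get A_i = 0. Both
#' steps must use the same buffer; a mismatch is an error.
#'
#' @param areas Area tibble with `x_km`, `y_km`.
#' @param providers Output of [provider_ratios()] (carries the step-1 buffer).
#' @param buffer_km Radial buffer distance d0 in km.
#' @return `areas` with `access` (per capita) and `access_per_1000` columns.
#' @export
access_index <- function(areas, providers, buffer_km = 30) {
  assert_columns(providers, "ratio", "providers")
  step1_d0 <- attr(providers, "buffer_km")
  if (is.null(step1_d0)) {
    stop("`providers` does not carry a step-1 buffer; run provider_ratios() first.",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(step1_d0, buffer_km))) {
    stop(sprintf(
      "Buffer mismatch: provider ratios used d0 = %g km but access_index was asked for d0 = %g km; both 2SFCA steps must share one buffer.",
      step1_d0, buffer_km
    ), call. = FALSE)
  }
  usable <- providers[!is.na(providers$ratio), , drop = FALSE]
  if (nrow(usable) == 0L) {
    areas$access <- 0
  } else {
    members <- catchment_members(areas, usable, buffer_km)
    areas$access <- vapply(members, function(idx) sum(usable$ratio[idx]),
                           numeric(1))
  }
  areas$access_per_1000 <- 1000 * areas$access
  attr(areas, "buffer_km") <- buffer_km
  areas
}

#' Compute the 2SFCA access index in one call
#'
#' Convenience wrapper running [provider_ratios()] then [access_index()] with
#' a shared buffer.
#'
#' @inheritParams access_index
#' @inheritParams provider_ratios
#' @return `areas` with `access` and `access_per_1000` columns.
#' @export
compute_access <- function(areas, providers, buffer_km = 30) {
  access_index(areas, provider_ratios(providers, areas, buffer_km), buffer_km)
}

#' Buffer-radius coverage sensitivity
#'
#' For each candidate radius, counts the area centroids lying within that
#' distance of at least one provider site; used to choose a buffer that
#' covers (nearly) all areas.
#'
#' @param areas Area tibble with `x_km`, `y_km`.
#' @param providers Provider tibble with `x_km`, `y_km`.
#' @param radii Positive radii in km (default 1, 16 and 30 km).
#' @return A tibble with one row per radius: `buffer_km`, `n_covered`,
#'   `n_total`, `fraction`.
#' @export
coverage_sensitivity <- function(areas, providers, radii = c(1, 16, 30)) {
  if (any(radii <= 0)) stop_field("radii", "must all be positive")
  purrr::map_dfr(radii, function(d0) {
    members <- catchment_members(areas, providers, d0)
    covered <- vapply(members, function(idx) length(idx) > 0, logical(1))
    tibble::tibble(
      buffer_km = d0,
      n_covered = sum(covered),
      n_total = nrow(areas),
      fraction = if (nrow(areas) > 0) sum(covered) / nrow(areas) else NA_real_
    )
  })
}
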