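# Readers and writers for the point tables. GeoJSON files hold Point
# features whose coordinates are the projected planar kilometres used
# throughout (not longitude/latitude); all other columns become properties.

#' Write a point table as GeoJSON
#'
#' @param df Tibble with `x_km`, `y_km` and any property columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(df, path) {
  assert_finite_coords(df, "df")
  props <- df[setdiff(names(df), c("x_km", "y_km"))]
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(df$x_km[i], df$y_km[i])
      ),
      properties = as.list(props[i, , drop = FALSE])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a GeoJSON point table
#'
#' @param path A GeoJSON file written by [write_region_geojson()] (or any
#'   FeatureCollection of Point features with planar coordinates).
#' @return A tibble with `x_km`, `y_km` and the feature properties.
#' @export
read_region_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop(sprintf("`%s` is not a GeoJSON FeatureCollection.", path),
         call. = FALSE)
  }
  rows <- purrr::map_dfr(fc$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      stop(sprintf("`%s` contains non-Point geometry.", path), call. = FALSE)
    }
    props <- purrr::map(f$properties, function(v) if (is.null(v)) NA else v)
    tibble::as_tibble(c(
      list(x_km = f$geometry$coordinates[[1]],
           y_km = f$geometry$coordinates[[2]]),
      props
    ))
  })
  dplyr::relocate(rows, dplyr::any_of(c("area_id", "site_id")))
}

#' Read an area or provider point table from CSV or GeoJSON
#'
#' @param path File ending in `.csv`, `.geojson` or `.json`.
#' @return A tibble.
#' @export
read_point_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("Input file not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    read_region_geojson(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
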