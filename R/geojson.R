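#' Attach per-area values to GeoJSON polygons
#'
#' Adds one numeric property per feature (e.g. the SMR or the posterior
#' mean relative risk) so any GIS tool can render the choropleth.
#' Geometries are passed through untouched.
#'
#' @param polygons path to a GeoJSON file or a parsed FeatureCollection
#'   list.
#' @param values named numeric vector (names = area ids), or a data.frame
#'   whose first column is the area id and second the value.
#' @param property_name name of the property to write.
#' @param path optional output file; when given, the collection is
#'   written there as JSON.
#' @param allow_missing if `TRUE`, features without a value get a `null`
#'   property and a warning; otherwise they are an error. A value whose
#'   id matches no feature is always an error.
#' @param id_property feature property holding the area id.
#' @return the amended FeatureCollection list, invisibly if `path` is
#'   given.
#' @export
write_choropleth_geojson <- function(polygons, values, property_name,
                                     path = NULL, allow_missing = FALSE,
                                     id_property = "id") {
  gj <- parse_geojson(polygons)
  if (is.data.frame(values)) {
    values <- stats::setNames(as.numeric(values[[2]]), as.character(values[[1]]))
  }
  ids <- vapply(gj$features, function(f) {
    as.character(f$properties[[id_property]] %||% f$id)
  }, character(1))
  unknown <- setdiff(names(values), ids)
  if (length(unknown)) {
    stop("value supplied for unknown area id: ", unknown[1])
  }
  n_missing <- 0L
  for (k in seq_along(gj$features)) {
    if (ids[k] %in% names(values)) {
      gj$features[[k]]$properties[[property_name]] <-
        unname(values[[ids[k]]])
    } else if (allow_missing) {
      gj$features[[k]]$properties[property_name] <- list(NULL)
      n_missing <- n_missing + 1L
    } else {
      stop("no value for area ", ids[k],
           " (use allow_missing = TRUE to write null)")
    }
  }
  if (n_missing) {
    warning(n_missing, " feature(s) without a value written as null")
  }
  if (!is.null(path)) {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(gj))
  }
  gj
}

#' Read the id-to-value map back from a choropleth GeoJSON
#' @param x path or parsed FeatureCollection.
#' @param property_name property to extract.
#' @param id_property feature property holding the area id.
#' @return named numeric vector (NA for null properties).
#' @export
read_choropleth_values <- function(x, property_name, id_property = "id") {
  gj <- parse_geojson(x)
  vals <- vapply(gj$features, function(f) {
    v <- f$properties[[property_name]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  ids <- vapply(gj$features, function(f) {
    as.character(f$properties[[id_property]] %||% f$id)
  }, character(1))
  stats::setNames(vals, ids)
}
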