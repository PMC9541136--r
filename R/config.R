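# Plain-text configuration: target-population declarations (YAML, with
# bounding-box or GeoJSON-polygon extents) and screening run configs.

geojson_polygon_vertices <- function(gj) {
  if (is.character(gj) && length(gj) == 1 && file.exists(gj))
    gj <- jsonlite::read_json(gj)
  geom <- if (identical(gj$type, "Feature")) gj$geometry else gj
  if (!identical(geom$type, "Polygon"))
    stop("GeoJSON extent must be a Polygon geometry", call. = FALSE)
  ring <- geom$coordinates[[1]]
  do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
}

#' Read a target-population declaration from a config file
#'
#' The config is nested key-value plain text (YAML) with keys `geo_extent`
#' (either `bbox: [min_lon, min_lat, max_lon, max_lat]` or
#' `geojson: <path or inline object>` for a polygon), `temporal_extent`
#' (`[year_start, year_end]`), `taxa`, `spatial_resolution`,
#' `temporal_resolution` and optional `env_axes`.
#'
#' @param path Config file path.
#' @return A [target_population()].
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("population config not found: ", path,
                               call. = FALSE)
  x <- yaml::read_yaml(path)
  for (key in c("geo_extent", "temporal_extent", "taxa")) {
    if (is.null(x[[key]]))
      stop("population config lacks '", key, "'", call. = FALSE)
  }
  ge <- x$geo_extent
  extent <- if (!is.null(ge$bbox)) {
    as.numeric(unlist(ge$bbox))
  } else if (!is.null(ge$geojson)) {
    gj <- ge$geojson
    if (is.character(gj)) {
      # relative paths resolve against the config file
      if (!file.exists(gj)) gj <- file.path(dirname(path), gj)
    }
    geojson_polygon_vertices(gj)
  } else if (is.numeric(unlist(ge)) && length(unlist(ge)) == 4) {
    as.numeric(unlist(ge))
  } else {
    stop("geo_extent must provide 'bbox' or 'geojson'", call. = FALSE)
  }
  target_population(
    geo_extent = extent,
    temporal_extent = as.integer(unlist(x$temporal_extent)),
    taxa = as.character(unlist(x$taxa)),
    spatial_resolution = as.numeric(x$spatial_resolution %||% 1),
    temporal_resolution = as.integer(x$temporal_resolution %||% 10),
    env_axes = if (!is.null(x$env_axes)) as.character(unlist(x$env_axes)) else NULL
  )
}

#' Write a target population to a config file
#'
#' Inverse of [read_population()] (bounding-box and polygon extents; polygon
#' extents are written as inline GeoJSON).
#'
#' @param pop A [target_population()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "target_population"))
  ge <- if (pop$geo_extent$type == "bbox") {
    list(bbox = as.numeric(pop$geo_extent$bbox))
  } else {
    v <- pop$geo_extent$vertices
    ring <- lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
    ring <- c(ring, ring[1])
    list(geojson = list(type = "Polygon", coordinates = list(ring)))
  }
  yaml::write_yaml(list(
    geo_extent = ge,
    temporal_extent = as.integer(pop$temporal_extent),
    taxa = as.list(pop$taxa),
    spatial_resolution = pop$spatial_resolution,
    temporal_resolution = pop$temporal_resolution,
    env_axes = as.list(pop$env_axes)
  ), path)
  invisible(path)
}
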