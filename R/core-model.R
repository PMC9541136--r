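# Shared domain types: occurrence tibbles, target populations, spatial grids
# and temporal bins. Everything downstream (heuristics, assessment, simulator)
# speaks these types.

#' Build an occurrence-record tibble
#'
#' Occurrence records ("biological records") are the unit of analysis: one
#' documented detection of a taxon at a place (WGS84 decimal degrees) and time
#' (calendar year). The package represents a set of records as a tibble with
#' columns `taxon`, `lon`, `lat`, `year` and optional `count`,
#' `coord_uncertainty_m`, `source`.
#'
#' @param taxon Character vector of taxon identifiers.
#' @param lon,lat Numeric, decimal degrees WGS84.
#' @param year Integer calendar years (4-digit).
#' @param count Optional non-negative integer abundance.
#' @param coord_uncertainty_m Optional non-negative coordinate uncertainty in
#'   metres.
#' @param source Optional dataset/source identifier.
#'
#' @return A tibble of validated occurrence records.
#' @export
#' @examples
#' occurrences(taxon = "sp1", lon = -78.5, lat = -1.5, year = 1995)
occurrences <- function(taxon, lon, lat, year, count = NA_integer_,
                        coord_uncertainty_m = NA_real_, source = NA_character_) {
  recs <- tibble::tibble(
    taxon = as.character(taxon),
    lon = as.numeric(lon),
    lat = as.numeric(lat),
    year = as.integer(year),
    count = as.integer(count),
    coord_uncertainty_m = as.numeric(coord_uncertainty_m),
    source = as.character(source)
  )
  validate_occurrences(recs)
}

#' Validate an occurrence tibble
#'
#' Checks column presence and the record invariants: longitude in
#' \[-180, 180\], latitude in \[-90, 90\], 4-digit year, non-negative
#' `count` and `coord_uncertainty_m` where present. Missing values are
#' permitted (cleaning rules deal with them); out-of-range non-missing values
#' are an error.
#'
#' @param records A data frame of occurrence records.
#' @return The records as a tibble, invisibly checked.
#' @export
validate_occurrences <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("taxon", "lon", "lat", "year")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("occurrence records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(c("count", "coord_uncertainty_m", "source"), names(records))) {
    records[[col]] <- if (col == "source") NA_character_ else NA_real_
  }
  bad_lon <- !is.na(records$lon) & (records$lon < -180 | records$lon > 180)
  bad_lat <- !is.na(records$lat) & (records$lat < -90 | records$lat > 90)
  if (any(bad_lon)) stop("longitude outside [-180, 180] at row(s): ",
                         paste(utils::head(which(bad_lon), 5), collapse = ", "),
                         call. = FALSE)
  if (any(bad_lat)) stop("latitude outside [-90, 90] at row(s): ",
                         paste(utils::head(which(bad_lat), 5), collapse = ", "),
                         call. = FALSE)
  bad_year <- !is.na(records$year) & (records$year < 1000 | records$year > 9999)
  if (any(bad_year)) stop("year must be a 4-digit integer; bad row(s): ",
                          paste(utils::head(which(bad_year), 5), collapse = ", "),
                          call. = FALSE)
  if (any(!is.na(records$count) & records$count < 0))
    stop("count must be non-negative", call. = FALSE)
  if (any(!is.na(records$coord_uncertainty_m) & records$coord_uncertainty_m < 0))
    stop("coord_uncertainty_m must be non-negative", call. = FALSE)
  records
}

#' Declare a statistical target population
#'
#' The target population is the full set of units (places x times x taxa, and
#' optionally environments) about which inference is desired. Declaring it is
#' the first step of a risk-of-bias assessment: bias only exists relative to a
#' stated population and inferential goal.
#'
#' @param geo_extent Either a length-4 numeric bounding box
#'   `c(min_lon, min_lat, max_lon, max_lat)` or a two-column matrix/data frame
#'   of polygon vertices (lon, lat; ring need not be closed).
#' @param temporal_extent Integer vector `c(year_start, year_end)`, inclusive.
#' @param taxa Character vector of target taxon identifiers (non-empty).
#' @param spatial_resolution Grid-cell edge in decimal degrees (> 0).
#' @param temporal_resolution Temporal bin width in whole years (>= 1).
#' @param env_axes Optional character vector naming environmental covariates
#'   (columns of a per-cell covariate table) that define an environmental
#'   domain for the assessment.
#'
#' @return An object of class `target_population`.
#' @export
#' @examples
#' target_population(
#'   geo_extent = c(-82, -5, -66, 13),
#'   temporal_extent = c(1950, 2019),
#'   taxa = c("sp1", "sp2"),
#'   spatial_resolution = 1,
#'   temporal_resolution = 10
#' )
target_population <- function(geo_extent, temporal_extent, taxa,
                              spatial_resolution = 1, temporal_resolution = 10,
                              env_axes = NULL) {
  extent <- normalize_extent(geo_extent)
  temporal_extent <- as.integer(temporal_extent)
  if (length(temporal_extent) != 2 || anyNA(temporal_extent))
    stop("temporal_extent must be c(year_start, year_end)", call. = FALSE)
  if (temporal_extent[1] > temporal_extent[2])
    stop("year_start must be <= year_end", call. = FALSE)
  taxa <- as.character(taxa)
  if (length(taxa) == 0 || anyNA(taxa))
    stop("taxa must be a non-empty character vector", call. = FALSE)
  if (!is.numeric(spatial_resolution) || spatial_resolution <= 0)
    stop("spatial_resolution must be > 0", call. = FALSE)
  temporal_resolution <- as.integer(temporal_resolution)
  if (is.na(temporal_resolution) || temporal_resolution < 1)
    stop("temporal_resolution must be >= 1 year", call. = FALSE)
  structure(
    list(
      geo_extent = extent,
      temporal_extent = temporal_extent,
      taxa = taxa,
      spatial_resolution = as.numeric(spatial_resolution),
      temporal_resolution = temporal_resolution,
      env_axes = if (is.null(env_axes)) character(0) else as.character(env_axes)
    ),
    class = "target_population"
  )
}

#' @export
print.target_population <- function(x, ...) {
  bb <- extent_bbox(x$geo_extent)
  cat("<target_population>\n")
  cat(sprintf("  geographic extent: %s [%.4g, %.4g] x [%.4g, %.4g]\n",
              x$geo_extent$type, bb[1], bb[3], bb[2], bb[4]))
  cat(sprintf("  temporal extent:   %d-%d (bins of %d yr)\n",
              x$temporal_extent[1], x$temporal_extent[2], x$temporal_resolution))
  cat(sprintf("  taxa:              %d target taxa\n", length(x$taxa)))
  cat(sprintf("  spatial grain:     %g degree cells\n", x$spatial_resolution))
  if (length(x$env_axes))
    cat("  environmental axes:", paste(x$env_axes, collapse = ", "), "\n")
  invisible(x)
}

# Internal extent representation: list(type = "bbox"|"polygon", bbox, vertices)
normalize_extent <- function(geo_extent) {
  if (is.data.frame(geo_extent)) geo_extent <- as.matrix(geo_extent)
  if (is.matrix(geo_extent)) {
    if (ncol(geo_extent) != 2 || nrow(geo_extent) < 3)
      stop("polygon extent needs a 2-column matrix with >= 3 vertices",
           call. = FALSE)
    v <- geo_extent
    # drop explicit ring closure; in.out() treats the boundary as closed
    if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    bbox <- c(min(v[, 1]), min(v[, 2]), max(v[, 1]), max(v[, 2]))
    if (bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
      stop("geo_extent has zero area", call. = FALSE)
    list(type = "polygon", bbox = bbox, vertices = unname(v))
  } else if (is.numeric(geo_extent) && length(geo_extent) == 4) {
    bbox <- as.numeric(geo_extent)
    if (bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
      stop("bounding box has zero area (need min < max on both axes)",
           call. = FALSE)
    list(type = "bbox", bbox = bbox, vertices = NULL)
  } else {
    stop("geo_extent must be c(min_lon, min_lat, max_lon, max_lat) or a ",
         "polygon vertex matrix", call. = FALSE)
  }
}

extent_bbox <- function(extent) extent$bbox

# Planar area of the extent in square degrees (polygon via the shoelace
# formula). Screening treats degrees as planar; see the methods vignette.
extent_area <- function(extent) {
  if (extent$type == "bbox") {
    bb <- extent$bbox
    (bb[3] - bb[1]) * (bb[4] - bb[2])
  } else {
    v <- extent$vertices
    n <- nrow(v)
    j <- c(2:n, 1)
    abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  }
}

# Vectorized point-in-extent test. Polygon membership via mgcv::in.out.
in_extent <- function(lon, lat, extent) {
  bb <- extent$bbox
  inside <- !is.na(lon) & !is.na(lat) &
    lon >= bb[1] & lon <= bb[3] & lat >= bb[2] & lat <= bb[4]
  if (extent$type == "polygon" && any(inside)) {
    pts <- cbind(lon[inside], lat[inside])
    inside[inside] <- mgcv::in.out(rbind(extent$vertices,
                                         extent$vertices[1, , drop = FALSE]),
                                   pts)
  }
  inside
}

#' Define a spatial grid
#'
#' Cells are half-open squares `[edge, edge + res)` on both axes, anchored at
#' a fixed origin so that cell ids are reproducible regardless of the data.
#' Cell id is the integer pair `(col, row)` counted from the origin.
#'
#' @param resolution Cell edge in decimal degrees (> 0).
#' @param origin_lon,origin_lat Grid anchor (defaults: -180, -90, the
#'   south-west corner of the coordinate domain).
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(1)           # global 1-degree grid
#' grid_spec(0.5, -80, 0) # half-degree grid anchored locally
grid_spec <- function(resolution, origin_lon = -180, origin_lat = -90) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number", call. = FALSE)
  structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         resolution = as.numeric(resolution)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g deg cells, origin (%g, %g), half-open [edge, edge+res)\n",
              x$resolution, x$origin_lon, x$origin_lat))
  invisible(x)
}

#' Assign records to grid cells
#'
#' Adds integer `cell_col` and `cell_row` columns:
#' `col = floor((lon - origin_lon) / res)`, likewise for rows. Cells are
#' half-open, so a coordinate exactly on a cell edge belongs to the cell whose
#' lower edge it equals.
#'
#' @param records Occurrence tibble (needs `lon`, `lat`).
#' @param grid A [grid_spec()].
#' @return `records` with `cell_col` and `cell_row` added.
#' @export
#' @examples
#' recs <- occurrences("sp1", lon = -78.5, lat = -1.5, year = 2000)
#' assign_cell(recs, grid_spec(1))  # cell (101, 88)
assign_cell <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  bad <- !is.finite(records$lon) | !is.finite(records$lat)
  if (any(bad)) {
    stop("non-finite coordinates at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(records),
    cell_col = as.integer(floor((.data$lon - grid$origin_lon) / grid$resolution)),
    cell_row = as.integer(floor((.data$lat - grid$origin_lat) / grid$resolution))
  )
}

#' Define temporal bins
#'
#' Partitions `[start_year, end_year]` into consecutive bins of `width` years;
#' the last bin may be truncated by `end_year`. Bins are labelled `p1`, `p2`,
#' ... in order, e.g. decades p1 = 1950-1959, p2 = 1960-1969 for a 1950 start
#' and width 10.
#'
#' @param start_year,end_year Inclusive extent (integers).
#' @param width Bin width in whole years (>= 1).
#' @return An object of class `period_spec`.
#' @export
#' @examples
#' periods <- period_spec(1950, 2019, 10)
#' n_periods(periods)  # 7
period_spec <- function(start_year, end_year, width = 10) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  width <- as.integer(width)
  if (is.na(start_year) || is.na(end_year) || start_year > end_year)
    stop("need start_year <= end_year", call. = FALSE)
  if (is.na(width) || width < 1) stop("width must be >= 1 year", call. = FALSE)
  structure(
    list(start_year = start_year, end_year = end_year, width = width),
    class = "period_spec"
  )
}

#' @export
print.period_spec <- function(x, ...) {
  cat(sprintf("<period_spec> %d-%d in %d bin(s) of %d yr\n",
              x$start_year, x$end_year, n_periods(x), x$width))
  invisible(x)
}

#' Number of temporal bins
#'
#' `ceiling((end_year - start_year + 1) / width)`; e.g. 1950-2019 with decadal
#' bins gives 7.
#'
#' @param periods A [period_spec()].
#' @return Integer count of bins.
#' @export
n_periods <- function(periods) {
  stopifnot(inherits(periods, "period_spec"))
  as.integer(ceiling((periods$end_year - periods$start_year + 1) / periods$width))
}

#' Table of period ids and year ranges
#'
#' @param periods A [period_spec()].
#' @return Tibble with `period`, `start_year`, `end_year` (one row per bin).
#' @export
period_table <- function(periods) {
  k <- n_periods(periods)
  idx <- seq_len(k)
  start <- periods$start_year + (idx - 1L) * periods$width
  end <- pmin(start + periods$width - 1L, periods$end_year)
  tibble::tibble(period = paste0("p", idx), start_year = start, end_year = end)
}

#' Assign years to periods
#'
#' Period index is `1 + floor((year - start_year) / width)`. Years outside the
#' temporal extent map to `NA` (callers tally these as out-of-population, they
#' are not an error).
#'
#' @param year Integer vector of years.
#' @param periods A [period_spec()].
#' @return Character vector of period ids (`"p1"`, `"p2"`, ...) with `NA` for
#'   out-of-extent years.
#' @export
#' @examples
#' assign_period(c(1950, 1969, 2019), period_spec(1950, 2019, 10))
assign_period <- function(year, periods) {
  stopifnot(inherits(periods, "period_spec"))
  idx <- 1L + floor((as.numeric(year) - periods$start_year) / periods$width)
  idx[is.na(year) | year < periods$start_year | year > periods$end_year] <- NA
  ifelse(is.na(idx), NA_character_, paste0("p", as.integer(idx)))
}

#' Add cell and period columns to records
#'
#' Convenience wrapper: [assign_cell()] then [assign_period()], producing the
#' binned tibble that all heuristics consume.
#'
#' @param records Occurrence tibble.
#' @param grid A [grid_spec()].
#' @param periods A [period_spec()].
#' @return `records` with `cell_col`, `cell_row`, `period` columns.
#' @export
bin_occurrences <- function(records, grid, periods) {
  records <- assign_cell(records, grid)
  dplyr::mutate(records, period = assign_period(.data$year, periods))
}

#' Restrict records to the declared target population
#'
#' Drops records outside the geographic extent, temporal extent or target
#' taxon list, tallying exclusions by reason. A record failing several checks
#' is counted once, under the first failing reason in the fixed order
#' geographic, temporal, taxonomic (deterministic tallies).
#'
#' @param records Occurrence tibble.
#' @param pop A [target_population()].
#' @return List with `records` (retained tibble) and `exclusions` (tibble
#'   `reason`, `n` with reasons `geo`, `time`, `taxon`). Warns (does not fail)
#'   if nothing is retained, so an assessment can still report "no coverage".
#' @export
filter_to_population <- function(records, pop) {
  stopifnot(inherits(pop, "target_population"))
  records <- validate_occurrences(records)
  ok_geo <- in_extent(records$lon, records$lat, pop$geo_extent)
  ok_time <- !is.na(records$year) &
    records$year >= pop$temporal_extent[1] &
    records$year <= pop$temporal_extent[2]
  ok_taxon <- !is.na(records$taxon) & records$taxon %in% pop$taxa
  reason <- dplyr::case_when(
    !ok_geo ~ "geo",
    !ok_time ~ "time",
    !ok_taxon ~ "taxon",
    TRUE ~ NA_character_
  )
  retained <- records[is.na(reason), , drop = FALSE]
  tally <- tibble::tibble(reason = c("geo", "time", "taxon")) |>
    dplyr::left_join(
      dplyr::count(tibble::tibble(reason = reason[!is.na(reason)]), .data$reason),
      by = "reason"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  if (nrow(retained) == 0)
    warning("no records fall inside the target population", call. = FALSE)
  list(records = retained, exclusions = tally)
}
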