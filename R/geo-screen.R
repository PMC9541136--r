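# Geographic/temporal screening heuristics: the nearest-neighbour index per
# period against a simulated complete-spatial-randomness (CSR) reference with
# bootstrap uncertainty, the periods-sampled map, per-cell density
# trajectories and between-period coverage overlap.
#
# Distances are Euclidean in decimal degrees by default (screening convention
# at regional extents); haversine kilometres behind metric = "haversine".
# Simulation (not the closed form) defines the CSR reference so that polygon
# domains and edge effects are handled implicitly; the closed-form
# Clark-Evans ratio is retained as an independent cross-check.

# Per-point nearest-neighbour distances. Duplicate coordinates are
# legitimate in aggregated data: a duplicated point has NN distance 0.
nn_dists <- function(lon, lat, metric = "euclidean") {
  n <- length(lon)
  stopifnot(n >= 2)
  if (metric == "haversine") {
    d <- geosphere::distm(cbind(lon, lat)) / 1000
  } else {
    d <- as.matrix(stats::dist(cbind(lon, lat)))
  }
  diag(d) <- Inf
  d[cbind(seq_len(n), max.col(-d, ties.method = "first"))]
}

mean_nn_dist <- function(lon, lat, metric = "euclidean") {
  mean(nn_dists(lon, lat, metric))
}

# n uniform points over an extent; rejection sampling inside polygons.
runif_extent <- function(n, extent) {
  bb <- extent_bbox(extent)
  if (extent$type == "bbox") {
    return(cbind(lon = stats::runif(n, bb[1], bb[3]),
                 lat = stats::runif(n, bb[2], bb[4])))
  }
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, bb[1], bb[3]), stats::runif(m, bb[2], bb[4]))
    keep <- in_extent(cand[, 1], cand[, 2], extent)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  colnames(out) <- c("lon", "lat")
  out[seq_len(n), , drop = FALSE]
}

# CSR reference: mean over n_ref_sims simulated uniform datasets (same n,
# same domain) of the mean NN distance.
csr_reference_stat <- function(n_points, extent, n_ref_sims, metric = "euclidean") {
  mean(vapply(seq_len(n_ref_sims), function(i) {
    pts <- runif_extent(n_points, extent)
    mean_nn_dist(pts[, 1], pts[, 2], metric)
  }, numeric(1)))
}

#' Nearest-neighbour index against a simulated CSR reference
#'
#' The index is the observed mean nearest-neighbour distance divided by the
#' mean of the same statistic over `n_ref_sims` datasets of equally many
#' points placed uniformly at random over the domain (complete spatial
#' randomness). Values near 1 indicate a spatially random pattern; values
#' below 1 indicate clustering (a common signature of preferential sampling)
#' and values above 1 a more regular-than-random pattern. The further from 1,
#' the greater the departure from randomness.
#'
#' @param records Occurrence tibble (or any data frame with `lon`, `lat`).
#' @param domain Geographic domain: a [target_population()], a length-4
#'   bounding box, or a polygon vertex matrix.
#' @param n_ref_sims Number of CSR reference simulations (default 99).
#' @param seed Integer seed governing the reference simulations.
#' @param metric `"euclidean"` (degrees, default) or `"haversine"` (km).
#' @return One-row tibble with `n_points`, `observed` (mean NN distance),
#'   `reference` (CSR mean), `index`, `n_ref_sims`, `seed`. With fewer than
#'   two points the index is undefined: `index` is `NA` and `note` says why
#'   (undefined results are reported, never dropped).
#' @export
#' @examples
#' set.seed(1)
#' pts <- tibble::tibble(lon = runif(100), lat = runif(100))
#' nearest_neighbour_index(pts, c(0, 0, 1, 1), n_ref_sims = 19, seed = 1)
nearest_neighbour_index <- function(records, domain, n_ref_sims = 99,
                                    seed = 1L, metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  extent <- as_extent(domain)
  if (extent_area(extent) <= 0) stop("domain has zero area", call. = FALSE)
  n <- nrow(records)
  if (n < 2) {
    return(tibble::tibble(
      n_points = n, observed = NA_real_, reference = NA_real_,
      index = NA_real_, n_ref_sims = as.integer(n_ref_sims),
      seed = as.integer(seed),
      note = "undefined: fewer than 2 points"
    ))
  }
  observed <- mean_nn_dist(records$lon, records$lat, metric)
  reference <- withr::with_seed(as.integer(seed),
    csr_reference_stat(n, extent, n_ref_sims, metric))
  tibble::tibble(
    n_points = as.integer(n), observed = observed, reference = reference,
    index = observed / reference, n_ref_sims = as.integer(n_ref_sims),
    seed = as.integer(seed), note = NA_character_
  )
}

as_extent <- function(domain) {
  if (inherits(domain, "target_population")) domain$geo_extent
  else if (is.list(domain) && !is.null(domain$type) && !is.data.frame(domain)) domain
  else normalize_extent(domain)
}

#' Closed-form Clark-Evans ratio
#'
#' The analytic counterpart of the simulation-referenced nearest-neighbour
#' index: `R = 2 * dbar * sqrt(n / A)`, where `dbar` is the observed mean
#' nearest-neighbour distance and `1 / (2 * sqrt(n / A))` the expected mean
#' under CSR at intensity `n / A` in a domain of area `A`. No edge
#' correction. Used as an independent oracle for the simulation route on
#' rectangular domains; the simulation route is the one the screening
#' pipeline uses because it handles polygons and edge effects implicitly.
#'
#' @param records Data frame with `lon`, `lat` (n >= 2).
#' @param area Domain area in squared coordinate units (> 0).
#' @return The dimensionless ratio.
#' @export
#' @examples
#' corners <- tibble::tibble(lon = c(0, 0, 1, 1), lat = c(0, 1, 0, 1))
#' clark_evans_analytic(corners, area = 1)  # dbar = 1, R = 4
clark_evans_analytic <- function(records, area) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (!is.numeric(area) || area <= 0) stop("area must be > 0", call. = FALSE)
  dbar <- mean_nn_dist(records$lon, records$lat)
  2 * dbar * sqrt(n / area)
}

#' Nearest-neighbour index per period with bootstrap uncertainty
#'
#' Computes the CSR-referenced nearest-neighbour index separately for each
#' temporal bin, with a nonparametric percentile bootstrap interval: records
#' within the period are resampled with replacement `n_boot` times, the index
#' recomputed each time against the period's fixed CSR reference, and the
#' interval taken at the stated level. Periods with fewer than two records
#' yield an undefined (NA) index with a note — thin periods are reported, not
#' skipped.
#'
#' @param records Binned occurrence tibble (see [bin_occurrences()]) or an
#'   unbinned one (then `periods` is used to bin on the fly).
#' @param domain Geographic domain (see [nearest_neighbour_index()]).
#' @param periods A [period_spec()].
#' @param n_ref_sims CSR reference simulations per period (default 99).
#' @param n_boot Bootstrap resamples per period (default 199).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed; per-period streams are derived from it, so a
#'   fixed seed gives bit-identical results.
#' @param metric Distance convention, as in [nearest_neighbour_index()].
#' @return An object of class `nni_screen`: a tibble with one row per period
#'   (`period`, `n_points`, `observed`, `reference`, `index`, `lower`,
#'   `upper`, `note`), with the call parameters stored as attributes.
#' @export
nni_by_period <- function(records, domain, periods, n_ref_sims = 99,
                          n_boot = 199, level = 0.95, seed = 1L,
                          metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(periods, "period_spec"))
  extent <- as_extent(domain)
  if (!"period" %in% names(records))
    records <- dplyr::mutate(records, period = assign_period(.data$year, periods))
  ptab <- period_table(periods)
  alpha <- (1 - level) / 2
  rows <- purrr::map(seq_len(nrow(ptab)), function(i) {
    pid <- ptab$period[i]
    pts <- dplyr::filter(records, .data$period == pid)
    pseed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    if (nrow(pts) < 2) {
      return(tibble::tibble(
        period = pid, n_points = nrow(pts), observed = NA_real_,
        reference = NA_real_, index = NA_real_,
        lower = NA_real_, upper = NA_real_,
        note = "undefined: fewer than 2 records"
      ))
    }
    withr::with_seed(pseed, {
      reference <- csr_reference_stat(nrow(pts), extent, n_ref_sims, metric)
      # bootstrap unit = record: resample each record's NN distance (computed
      # on the full pattern) rather than recomputing distances on the
      # resampled set, where artificial exact duplicates would drag the mean
      # NN distance toward zero and the interval away from the estimate
      dists <- nn_dists(pts$lon, pts$lat, metric)
      observed <- mean(dists)
      boot <- vapply(seq_len(n_boot), function(b) {
        mean(sample(dists, replace = TRUE)) / reference
      }, numeric(1))
      qs <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
      tibble::tibble(
        period = pid, n_points = nrow(pts), observed = observed,
        reference = reference, index = observed / reference,
        lower = qs[1], upper = qs[2], note = NA_character_
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("nni_screen", class(out)),
            n_ref_sims = as.integer(n_ref_sims), n_boot = as.integer(n_boot),
            level = level, seed = as.integer(seed), metric = metric)
}

#' Tidy a per-period nearest-neighbour screen
#'
#' @param x An `nni_screen`.
#' @param ... Unused.
#' @return A plain tibble, one row per period.
#' @exportS3Method generics::tidy
tidy.nni_screen <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a nearest-neighbour screen
#'
#' @param x An `nni_screen`.
#' @param ... Unused.
#' @return Tibble with period counts, mean defined index and the simulation
#'   parameters.
#' @exportS3Method generics::glance
glance.nni_screen <- function(x, ...) {
  tibble::tibble(
    n_periods = nrow(x),
    n_defined = sum(!is.na(x$index)),
    mean_index = mean(x$index, na.rm = TRUE),
    n_ref_sims = attr(x, "n_ref_sims"),
    n_boot = attr(x, "n_boot"),
    level = attr(x, "level"),
    seed = attr(x, "seed")
  )
}

#' Periods-sampled map
#'
#' For each grid cell, the number of distinct temporal bins containing at
#' least one record — a simple measure of how the spatial distribution of
#' sampling has changed over time. Cells never sampled are absent (they would
#' carry 0).
#'
#' @param records Binned occurrence tibble ([bin_occurrences()]).
#' @param grid A [grid_spec()] (used only to validate binning presence).
#' @param periods A [period_spec()].
#' @return Tibble `cell_col`, `cell_row`, `n_periods_sampled`; every value
#'   lies in `[1, n_periods(periods)]`.
#' @export
periods_sampled_map <- function(records, grid, periods) {
  records <- require_binned(records, grid, periods)
  records |>
    dplyr::filter(!is.na(.data$period)) |>
    dplyr::distinct(.data$cell_col, .data$cell_row, .data$period) |>
    dplyr::count(.data$cell_col, .data$cell_row, name = "n_periods_sampled") |>
    dplyr::arrange(.data$cell_col, .data$cell_row)
}

#' Record-density surface per cell and period
#'
#' Integer record counts per grid cell per temporal bin, with a log10 display
#' transform for mapping (defined for counts >= 1; zero-count cells are
#' absent rather than -Inf). Counts over cells and periods sum to the number
#' of in-extent records.
#'
#' @inheritParams periods_sampled_map
#' @return Tibble `cell_col`, `cell_row`, `period`, `n`, `log10_n`.
#' @export
density_surface <- function(records, grid, periods) {
  records <- require_binned(records, grid, periods)
  records |>
    dplyr::filter(!is.na(.data$period)) |>
    dplyr::count(.data$cell_col, .data$cell_row, .data$period, name = "n") |>
    dplyr::mutate(log10_n = log10(.data$n)) |>
    dplyr::arrange(.data$period, .data$cell_col, .data$cell_row)
}

require_binned <- function(records, grid, periods) {
  if (!all(c("cell_col", "cell_row", "period") %in% names(records))) {
    records <- bin_occurrences(records, grid, periods)
  }
  records
}

# Single source of truth for Jaccard similarity of two finite sets, shared by
# geographic coverage overlap and taxonomic sampling turnover.
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

#' Coverage overlap of sampled cells between two periods
#'
#' Jaccard similarity of the sets of grid cells holding at least one record
#' in each of two periods. 1 means the same portion of space was sampled in
#' both; 0 means disjoint coverage — the space-time confounding signature
#' where apparent temporal change may only reflect shifted sampling.
#'
#' @inheritParams periods_sampled_map
#' @param period_a,period_b Period ids (e.g. `"p1"`, `"p7"`).
#' @return A number in `[0, 1]`, or `NA` when both periods are empty
#'   (undefined).
#' @export
coverage_overlap <- function(records, grid, periods, period_a, period_b) {
  records <- require_binned(records, grid, periods)
  valid <- period_table(periods)$period
  if (!period_a %in% valid || !period_b %in% valid)
    stop("period ids must be among: ", paste(valid, collapse = ", "),
         call. = FALSE)
  cells_in <- function(p) {
    sub <- dplyr::filter(records, .data$period == p)
    unique(paste(sub$cell_col, sub$cell_row, sep = ":"))
  }
  jaccard(cells_in(period_a), cells_in(period_b))
}
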