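# Taxonomic and environmental coverage heuristics: per-period coverage of the
# declared taxon list, record-share evenness, between-period taxon turnover,
# and occupancy of environmental space summarized at the grid-cell level.

#' Per-period coverage of the target taxon list
#'
#' For each temporal bin: the fraction of target taxa with at least one
#' record, the per-taxon record shares, and a Pielou-type evenness of those
#' shares (`H' / ln S` over recorded target taxa; 1 when all recorded taxa
#' have equal record counts, approaching 0 as one taxon dominates; undefined
#' with fewer than two recorded taxa). Records for taxa outside the target
#' list are tallied separately, never silently dropped.
#'
#' @param records Occurrence tibble with a `period` column (or `periods`
#'   supplied to bin on the fly).
#' @param taxa Character vector of target taxon identifiers, or a
#'   [target_population()] (its `taxa` is used).
#' @param periods A [period_spec()].
#' @return List of class `taxon_coverage` with elements `by_period` (tibble
#'   `period`, `n_taxa_recorded`, `frac_taxa`, `evenness`, `n_records` — one
#'   row per period, empty periods included with 0 coverage), `shares`
#'   (tibble `period`, `taxon`, `n`, `share`; shares sum to 1 within each
#'   period over recorded target taxa) and `off_target` (tibble `taxon`, `n`
#'   of records outside the target list).
#' @export
taxon_coverage <- function(records, taxa, periods) {
  if (inherits(taxa, "target_population")) taxa <- taxa$taxa
  taxa <- as.character(taxa)
  if (length(taxa) == 0) stop("target taxon list is empty", call. = FALSE)
  if (!"period" %in% names(records))
    records <- dplyr::mutate(records, period = assign_period(.data$year, periods))
  records <- dplyr::filter(records, !is.na(.data$period))
  off_target <- records |>
    dplyr::filter(!.data$taxon %in% taxa) |>
    dplyr::count(.data$taxon, name = "n")
  on_target <- dplyr::filter(records, .data$taxon %in% taxa)
  shares <- on_target |>
    dplyr::count(.data$period, .data$taxon, name = "n") |>
    dplyr::group_by(.data$period) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$period, .data$taxon)
  pielou <- function(p) {
    # evenness of record shares: Shannon H' over shares / ln(richness)
    if (length(p) < 2) return(NA_real_)
    -sum(p * log(p)) / log(length(p))
  }
  by_period <- period_table(periods) |>
    dplyr::select("period") |>
    dplyr::left_join(
      shares |>
        dplyr::group_by(.data$period) |>
        dplyr::summarise(n_taxa_recorded = dplyr::n(),
                         evenness = pielou(.data$share),
                         n_records = sum(.data$n)),
      by = "period"
    ) |>
    dplyr::mutate(
      n_taxa_recorded = dplyr::coalesce(.data$n_taxa_recorded, 0L),
      n_records = dplyr::coalesce(.data$n_records, 0L),
      frac_taxa = .data$n_taxa_recorded / length(taxa)
    ) |>
    dplyr::select("period", "n_taxa_recorded", "frac_taxa", "evenness",
                  "n_records")
  structure(
    list(by_period = by_period, shares = shares, off_target = off_target,
         n_target_taxa = length(taxa)),
    class = "taxon_coverage"
  )
}

#' @export
print.taxon_coverage <- function(x, ...) {
  cat(sprintf("<taxon_coverage> %d target taxa\n", x$n_target_taxa))
  print(x$by_period)
  if (nrow(x$off_target) > 0)
    cat(sprintf("  (%d record(s) for %d off-target taxa tallied separately)\n",
                sum(x$off_target$n), nrow(x$off_target)))
  invisible(x)
}

#' Tidy a taxon-coverage result
#'
#' @param x A `taxon_coverage`.
#' @param ... Unused.
#' @return The per-period coverage tibble.
#' @exportS3Method generics::tidy
tidy.taxon_coverage <- function(x, ...) x$by_period

#' Taxon sampling turnover between two periods
#'
#' Jaccard similarity of the sets of taxa recorded in two periods: 1 when the
#' same taxa were recorded in both, 0 when disjoint. Low turnover similarity
#' warns that apparent taxonomic trends may reflect which taxa were looked
#' for, not which occurred.
#'
#' @param records Occurrence tibble with (or to be given) a `period` column.
#' @param periods A [period_spec()].
#' @param period_a,period_b Period ids.
#' @return A number in `[0, 1]`, `NA` when both periods recorded no taxa.
#' @export
taxon_sampling_turnover <- function(records, periods, period_a, period_b) {
  if (!"period" %in% names(records))
    records <- dplyr::mutate(records, period = assign_period(.data$year, periods))
  valid <- period_table(periods)$period
  if (!period_a %in% valid || !period_b %in% valid)
    stop("period ids must be among: ", paste(valid, collapse = ", "),
         call. = FALSE)
  taxa_in <- function(p) unique(records$taxon[records$period %in% p])
  jaccard(taxa_in(period_a), taxa_in(period_b))
}

# Joint environmental bin labels for a cell table. Equal-width bins per axis
# over the range realized by the domain's cells (quantile bins optionally).
env_bin_labels <- function(cell_env, axes, bins_per_axis, scheme, ref_env = NULL) {
  if (is.null(ref_env)) ref_env <- cell_env
  per_axis <- lapply(axes, function(ax) {
    x <- cell_env[[ax]]
    r <- ref_env[[ax]]
    if (scheme == "quantile") {
      br <- unique(stats::quantile(r, probs = seq(0, 1, length.out = bins_per_axis + 1),
                                   na.rm = TRUE, type = 7))
    } else {
      br <- seq(min(r, na.rm = TRUE), max(r, na.rm = TRUE),
                length.out = bins_per_axis + 1)
    }
    if (length(br) < 2) br <- c(br, br + 1e-9)
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  })
  lab <- do.call(paste, c(per_axis, sep = "|"))
  lab[Reduce(`|`, lapply(per_axis, is.na))] <- NA_character_
  lab
}

#' Per-period coverage of environmental space
#'
#' Environmental space is summarized at the grid-cell level: each cell
#' carries one covariate vector, each axis is divided into equal-width bins
#' over the domain's realized range (default 5 per axis; quantile bins behind
#' `scheme = "quantile"`), and a joint bin is the combination of per-axis
#' bins. The reference set is the joint bins realized by the full domain cell
#' table — unrealizable covariate combinations do not count as uncovered.
#' Per-period coverage is the fraction of reference bins occupied by at least
#' one record. Records falling in cells absent from the covariate table are
#' tallied as unassessable, never silently dropped.
#'
#' @param records Binned occurrence tibble (`cell_col`, `cell_row`,
#'   `period`).
#' @param cell_env Data frame with `cell_col`, `cell_row` and one numeric
#'   column per covariate, one row per domain cell.
#' @param periods A [period_spec()].
#' @param bins_per_axis Bins per covariate axis (>= 2, default 5).
#' @param axes Covariate column names (default: all non-cell columns).
#' @param scheme `"width"` (equal-width, default) or `"quantile"`.
#' @return List of class `env_coverage`: `by_period` (tibble `period`,
#'   `n_bins_occupied`, `frac_bins`, `n_records`, `n_unassessable`),
#'   `n_reference_bins`, and the binning parameters.
#' @export
env_coverage <- function(records, cell_env, periods, bins_per_axis = 5,
                         axes = NULL, scheme = c("width", "quantile")) {
  scheme <- match.arg(scheme)
  if (bins_per_axis < 2) stop("bins_per_axis must be >= 2", call. = FALSE)
  cell_env <- tibble::as_tibble(cell_env)
  if (!all(c("cell_col", "cell_row") %in% names(cell_env)))
    stop("cell_env needs cell_col and cell_row columns", call. = FALSE)
  if (is.null(axes)) axes <- setdiff(names(cell_env), c("cell_col", "cell_row"))
  if (length(axes) == 0) stop("cell_env has no covariate columns", call. = FALSE)
  cell_env$env_bin <- env_bin_labels(cell_env, axes, bins_per_axis, scheme)
  reference_bins <- unique(stats::na.omit(cell_env$env_bin))
  if (!"period" %in% names(records))
    stop("records must carry a period column (see bin_occurrences())",
         call. = FALSE)
  joined <- records |>
    dplyr::filter(!is.na(.data$period)) |>
    dplyr::left_join(cell_env[, c("cell_col", "cell_row", "env_bin")],
                     by = c("cell_col", "cell_row"))
  by_period <- period_table(periods) |>
    dplyr::select("period") |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(.data$period) |>
        dplyr::summarise(
          n_bins_occupied = dplyr::n_distinct(.data$env_bin[!is.na(.data$env_bin)]),
          n_records = dplyr::n(),
          n_unassessable = sum(is.na(.data$env_bin))
        ),
      by = "period"
    ) |>
    dplyr::mutate(
      dplyr::across(c("n_bins_occupied", "n_records", "n_unassessable"),
                    \(x) dplyr::coalesce(x, 0L)),
      frac_bins = .data$n_bins_occupied / length(reference_bins)
    ) |>
    dplyr::select("period", "n_bins_occupied", "frac_bins", "n_records",
                  "n_unassessable")
  structure(
    list(by_period = by_period, n_reference_bins = length(reference_bins),
         bins_per_axis = as.integer(bins_per_axis), axes = axes,
         scheme = scheme),
    class = "env_coverage"
  )
}

#' @export
print.env_coverage <- function(x, ...) {
  cat(sprintf("<env_coverage> %d joint reference bin(s); %d bin(s)/axis (%s) over %s\n",
              x$n_reference_bins, x$bins_per_axis, x$scheme,
              paste(x$axes, collapse = ", ")))
  print(x$by_period)
  invisible(x)
}

#' Tidy an environmental-coverage result
#'
#' @param x An `env_coverage`.
#' @param ... Unused.
#' @return The per-period coverage tibble.
#' @exportS3Method generics::tidy
tidy.env_coverage <- function(x, ...) x$by_period
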