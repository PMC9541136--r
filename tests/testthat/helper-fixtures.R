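# Shared fixtures built in code: toy occurrence sets, a standard decadal
# population, and a tiny per-cell covariate table.

toy_population <- function(bbox = c(0, 0, 10, 10), years = c(1950, 2019),
                           taxa = c("sp1", "sp2"), res = 1, width = 10) {
  target_population(bbox, years, taxa, res, width)
}

toy_periods <- function() period_spec(1950, 2019, 10)

# deterministic uniform points in the unit square
unit_square_points <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(lon = runif(n), lat = runif(n)))
}

toy_records <- function() {
  occurrences(
    taxon = c("sp1", "sp1", "sp2", "sp2", "sp1"),
    lon = c(0.5, 1.5, 2.5, 2.5, 8.5),
    lat = c(0.5, 1.5, 2.5, 2.5, 8.5),
    year = c(1951, 1955, 1972, 1972, 2015)
  )
}

toy_cell_env <- function() {
  # 4x4 cell block with two gradients
  grid <- expand.grid(cell_col = 0:3, cell_row = 0:3)
  tibble::tibble(
    cell_col = grid$cell_col, cell_row = grid$cell_row,
    temperature = 10 + grid$cell_col * 2 + grid$cell_row * 0.5,
    rainfall = 100 - grid$cell_row * 10
  )
}

write_toy_csv <- function(path, rows) {
  readr::write_csv(rows, path, na = "", progress = FALSE)
  path
}
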