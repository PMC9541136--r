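test_that("simulation is reproducible from scenario + seed", {
  sc <- bias_scenario(c(0, 0, 10, 10), toy_periods(), taxa = c(a = 0.5, b = 0.5),
                      n_per_period = 60, seed = 9)
  r1 <- simulate_occurrences(sc)
  r2 <- simulate_occurrences(sc)
  expect_identical(r1, r2)
  sc2 <- bias_scenario(c(0, 0, 10, 10), toy_periods(), taxa = c(a = 0.5, b = 0.5),
                       n_per_period = 60, seed = 10)
  expect_false(identical(r1, simulate_occurrences(sc2)))
})

test_that("realized per-period counts stay within Poisson tolerance", {
  sc <- bias_scenario(c(0, 0, 10, 10), toy_periods(), n_per_period = 400,
                      seed = 3)
  recs <- simulate_occurrences(sc)
  counts <- table(assign_period(recs$year, toy_periods()))
  expect_identical(length(counts), 7L)
  # each count within ~4 sd of the Poisson mean
  expect_true(all(abs(counts - 400) < 4 * sqrt(400)))
  # years stay inside their period
  expect_true(all(recs$year >= 1950 & recs$year <= 2019))
})

test_that("effort multipliers scale expected counts per period", {
  sc <- bias_scenario(c(0, 0, 10, 10), period_spec(2000, 2019, 10),
                      n_per_period = 300, effort = c(1, 3), seed = 5)
  recs <- simulate_occurrences(sc)
  counts <- table(assign_period(recs$year, sc$periods))
  expect_true(abs(counts[["p1"]] - 300) < 4 * sqrt(300))
  expect_true(abs(counts[["p2"]] - 900) < 4 * sqrt(900))
})

test_that("taxon preference weights drive record shares", {
  sc <- bias_scenario(c(0, 0, 1, 1), period_spec(2000, 2009, 10),
                      taxa = c(common = 0.9, rare = 0.1),
                      n_per_period = 10000, seed = 17)
  recs <- simulate_occurrences(sc)
  share <- mean(recs$taxon == "common")
  expect_lt(abs(share - 0.9), 0.02)
})

test_that("clustered mode stays in the domain with exact n and clusters tightly", {
  sc <- bias_scenario(c(0, 0, 1, 1), period_spec(2000, 2009, 10),
                      n_per_period = 300,
                      spatial = list(mode = "clustered", parent_rate = 8,
                                     sd = 0.01),
                      seed = 23)
  recs <- simulate_occurrences(sc)
  expect_true(all(recs$lon >= 0 & recs$lon <= 1))
  expect_true(all(recs$lat >= 0 & recs$lat <= 1))
  idx <- nearest_neighbour_index(recs, c(0, 0, 1, 1), n_ref_sims = 49, seed = 1)
  expect_lt(idx$index, 1)
})

test_that("drifting windows honour the schedule and warn when clamped", {
  p <- period_spec(2000, 2069, 10)  # 7 periods
  sc <- bias_scenario(c(0, 0, 10, 10), p, n_per_period = 80,
                      spatial = list(mode = "drifting_window", frac = 0.09,
                                     drift = c(1.1, 1.1)),
                      seed = 31)
  recs <- simulate_occurrences(sc)
  recs$period <- assign_period(recs$year, p)
  # each period's points lie inside its scheduled 3x3 window
  for (i in 1:7) {
    win <- occbias:::drift_window(sc, i)$bbox
    sub <- recs[recs$period == paste0("p", i), ]
    expect_true(all(sub$lon >= win[1] & sub$lon <= win[3]))
    expect_true(all(sub$lat >= win[2] & sub$lat <= win[4]))
  }
  # endpoint windows are disjoint -> coverage overlap 0
  expect_identical(coverage_overlap(recs, grid_spec(1), p, "p1", "p7"), 0)

  # a drift that exits the domain clamps with a warning
  sc_bad <- bias_scenario(c(0, 0, 10, 10), p, n_per_period = 20,
                          spatial = list(mode = "drifting_window", frac = 0.25,
                                         drift = c(3, 0)),
                          seed = 1)
  w <- capture_warnings(simulate_occurrences(sc_bad))
  expect_true(any(grepl("clamped", w)))
})

test_that("scenario expectations state the right qualitative signatures", {
  base <- list(domain = c(0, 0, 1, 1), periods = period_spec(2000, 2019, 10))
  csr <- bias_scenario(base$domain, base$periods, seed = 1)
  clus <- bias_scenario(base$domain, base$periods,
                        spatial = list(mode = "clustered"), seed = 1)
  drift <- bias_scenario(base$domain, base$periods,
                         spatial = list(mode = "drifting_window", frac = 0.2,
                                        drift = c(0.3, 0)), seed = 1)
  get <- function(sc, h) {
    e <- scenario_expectations(sc)
    e$expectation[e$heuristic == h]
  }
  expect_identical(get(csr, "nearest_neighbour_index"), "~1")
  expect_identical(get(clus, "nearest_neighbour_index"), "<1")
  expect_identical(get(drift, "periods_sampled"), "low")
  expect_identical(get(drift, "coverage_overlap"), "decreasing")
})

test_that("scenario configs round-trip through the YAML reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    domain = c(0, 0, 10, 10),
    periods = list(start_year = 1950, end_year = 2019, width = 10),
    taxa = list(a = 0.7, b = 0.3),
    n_per_period = 50,
    spatial = list(mode = "drifting_window", frac = 0.25, drift = c(0.8, 0)),
    seed = 12
  ), path)
  sc <- read_scenario(path)
  expect_identical(sc$spatial$mode, "drifting_window")
  expect_identical(sc$seed, 12L)
  expect_equal(unname(sc$taxa), c(0.7, 0.3))
  recs <- simulate_occurrences(sc)
  expect_identical(recs, simulate_occurrences(read_scenario(path)))
  expect_error(read_scenario(withr::local_tempfile()), "not found")
})
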