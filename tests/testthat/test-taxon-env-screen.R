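test_that("taxon coverage is the fraction of target taxa recorded per period", {
  taxa <- paste0("t", 1:10)
  p <- toy_periods()
  recs <- occurrences(
    taxon = c("t1", "t2", "t3", "t4", "t1", "zz"),
    lon = 1:6, lat = 1:6,
    year = c(1951, 1952, 1953, 1954, 1961, 1951)
  )
  tc <- taxon_coverage(recs, taxa, p)
  bp <- tc$by_period
  expect_equal(bp$frac_taxa[bp$period == "p1"], 0.4)
  expect_equal(bp$frac_taxa[bp$period == "p2"], 0.1)
  expect_equal(bp$frac_taxa[bp$period == "p3"], 0)   # no records at all
  # off-target taxon is tallied, not dropped
  expect_identical(tc$off_target$taxon, "zz")
  expect_identical(tc$off_target$n, 1L)
  # shares sum to 1 over recorded taxa within each period
  sums <- dplyr::summarise(dplyr::group_by(tc$shares, period),
                           s = sum(share))$s
  expect_true(all(abs(sums - 1) < 1e-12))

  # all taxa recorded in every period -> coverage 1 everywhere
  full <- tidyr::expand_grid(taxon = taxa,
                             year = period_table(p)$start_year)
  full <- occurrences(full$taxon, lon = 1, lat = 1, year = full$year)
  expect_true(all(taxon_coverage(full, taxa, p)$by_period$frac_taxa == 1))
})

test_that("evenness is 1 for equal shares and falls toward 0 under dominance", {
  p <- period_spec(2000, 2009, 10)
  equal <- occurrences(rep(c("a", "b", "c"), each = 5), lon = 1, lat = 1,
                       year = 2001)
  tc <- taxon_coverage(equal, c("a", "b", "c"), p)
  expect_equal(tc$by_period$evenness[1], 1)

  skewed <- occurrences(c(rep("a", 998), "b", "c"), lon = 1, lat = 1,
                        year = 2001)
  tc2 <- taxon_coverage(skewed, c("a", "b", "c"), p)
  expect_lt(tc2$by_period$evenness[1], 0.05)

  # evenness undefined with a single recorded taxon
  solo <- occurrences(rep("a", 5), lon = 1, lat = 1, year = 2001)
  expect_true(is.na(taxon_coverage(solo, c("a", "b"), p)$by_period$evenness[1]))
})

test_that("evenness agrees with an independent diversity implementation", {
  counts <- c(a = 17, b = 5, c = 41, d = 2)
  recs <- occurrences(rep(names(counts), counts), lon = 1, lat = 1, year = 2001)
  tc <- taxon_coverage(recs, names(counts), period_spec(2000, 2009, 10))
  expected <- vegan::diversity(counts) / log(length(counts))
  expect_equal(tc$by_period$evenness[1], unname(expected), tolerance = 1e-12)
})

test_that("taxon turnover between periods is Jaccard on recorded taxon sets", {
  p <- toy_periods()
  recs <- occurrences(
    taxon = c("t1", "t2", "t2", "t3"),
    lon = 1:4, lat = 1:4,
    year = c(1951, 1955, 1965, 1962)
  )
  expect_equal(taxon_sampling_turnover(recs, p, "p1", "p2"), 1 / 3)
  expect_equal(taxon_sampling_turnover(recs, p, "p1", "p1"), 1)
  expect_identical(taxon_sampling_turnover(recs, p, "p3", "p4"), NA_real_)
})

test_that("environmental coverage counts occupied joint bins against the domain reference", {
  env <- toy_cell_env()
  p <- period_spec(2000, 2019, 10)
  g <- grid_spec(1, 0, 0)
  # records in 4 distinct cells in p1, 1 cell in p2
  recs <- occurrences(
    taxon = "sp1",
    lon = c(0.5, 1.5, 2.5, 3.5, 0.5),
    lat = c(0.5, 1.5, 2.5, 3.5, 0.5),
    year = c(2001, 2002, 2003, 2004, 2011)
  )
  binned <- bin_occurrences(recs, g, p)
  ec <- env_coverage(binned, env, p, bins_per_axis = 2)
  expect_identical(ec$by_period$n_records, c(4L, 1L))
  expect_true(all(ec$by_period$frac_bins >= 0 & ec$by_period$frac_bins <= 1))
  # every domain cell sampled -> full coverage of the realized bin set
  all_cells <- occurrences("sp1",
                           lon = env$cell_col + 0.5, lat = env$cell_row + 0.5,
                           year = 2001)
  ec_full <- env_coverage(bin_occurrences(all_cells, g, p), env, p, 2)
  expect_equal(ec_full$by_period$frac_bins[1], 1)

  # a record in a cell with no covariates is tallied as unassessable
  off <- occurrences("sp1", lon = 9.5, lat = 9.5, year = 2001)
  ec_off <- env_coverage(bin_occurrences(off, g, p), env, p, 2)
  expect_identical(ec_off$by_period$n_unassessable[1], 1L)
})

test_that("refining the environmental bins never raises coverage on the toy table", {
  env <- toy_cell_env()
  p <- period_spec(2000, 2019, 10)
  g <- grid_spec(1, 0, 0)
  recs <- occurrences("sp1",
                      lon = c(0.5, 1.5, 2.5), lat = c(0.5, 0.5, 1.5),
                      year = c(2001, 2002, 2003))
  binned <- bin_occurrences(recs, g, p)
  fracs <- vapply(c(2, 4, 8), function(k) {
    env_coverage(binned, env, p, bins_per_axis = k)$by_period$frac_bins[1]
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("coverage fractions are monotone under adding records", {
  env <- toy_cell_env()
  p <- period_spec(2000, 2019, 10)
  g <- grid_spec(1, 0, 0)
  taxa <- paste0("t", 1:6)
  withr::with_seed(13, {
    base <- occurrences(sample(taxa, 10, TRUE),
                        lon = runif(10, 0, 4), lat = runif(10, 0, 4),
                        year = sample(2000:2019, 10, TRUE))
    extra <- occurrences(sample(taxa, 10, TRUE),
                         lon = runif(10, 0, 4), lat = runif(10, 0, 4),
                         year = sample(2000:2019, 10, TRUE))
  })
  both <- dplyr::bind_rows(base, extra)
  tc1 <- taxon_coverage(base, taxa, p)$by_period$frac_taxa
  tc2 <- taxon_coverage(both, taxa, p)$by_period$frac_taxa
  expect_true(all(tc2 >= tc1))
  ec1 <- env_coverage(bin_occurrences(base, g, p), env, p, 3)$by_period$frac_bins
  ec2 <- env_coverage(bin_occurrences(both, g, p), env, p, 3)$by_period$frac_bins
  expect_true(all(ec2 >= ec1))
})

test_that("quantile binning is available and respects the bin budget", {
  env <- toy_cell_env()
  p <- period_spec(2000, 2019, 10)
  g <- grid_spec(1, 0, 0)
  recs <- occurrences("sp1", lon = c(0.5, 3.5), lat = c(0.5, 3.5),
                      year = c(2001, 2002))
  ec <- env_coverage(bin_occurrences(recs, g, p), env, p, 3,
                     scheme = "quantile")
  expect_lte(ec$n_reference_bins, 9L)
  expect_error(env_coverage(bin_occurrences(recs, g, p), env, p, 1), "bins_per_axis")
})
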