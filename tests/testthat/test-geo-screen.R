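test_that("nearest-neighbour index is ~1 for uniform points and <1 for clusters", {
  pts <- unit_square_points(500, seed = 10)
  res <- nearest_neighbour_index(pts, c(0, 0, 1, 1), n_ref_sims = 99, seed = 1)
  expect_true(abs(res$index - 1) < 0.1)

  # tight cluster: all points within 1% of the domain edge length
  cl <- withr::with_seed(11, tibble::tibble(lon = runif(100, 0.5, 0.51),
                                            lat = runif(100, 0.5, 0.51)))
  res_cl <- nearest_neighbour_index(cl, c(0, 0, 1, 1), n_ref_sims = 49, seed = 2)
  expect_lt(res_cl$index, 1)

  # coincident points: zero numerator, index exactly 0
  co <- tibble::tibble(lon = c(0.5, 0.5), lat = c(0.5, 0.5))
  expect_identical(nearest_neighbour_index(co, c(0, 0, 1, 1), 19, 1)$index, 0)
})

test_that("undefined results carry a reason instead of being dropped", {
  one <- tibble::tibble(lon = 0.5, lat = 0.5)
  res <- nearest_neighbour_index(one, c(0, 0, 1, 1), 19, 1)
  expect_true(is.na(res$index))
  expect_match(res$note, "fewer than 2")
  expect_error(nearest_neighbour_index(one, c(0, 0, 0, 1), 19, 1), "area")
})

test_that("Clark-Evans analytic ratio matches hand computation", {
  corners <- tibble::tibble(lon = c(0, 0, 1, 1), lat = c(0, 1, 0, 1))
  # each corner's nearest neighbour is 1 away: R = 2 * 1 * sqrt(4/1) = 4
  expect_equal(clark_evans_analytic(corners, area = 1), 4)
  expect_error(clark_evans_analytic(corners[1, ], 1), "at least 2")
  expect_error(clark_evans_analytic(corners, 0), "area")
})

test_that("simulation-referenced index agrees with the analytic ratio on CSR data", {
  pts <- unit_square_points(1000, seed = 21)
  sim <- nearest_neighbour_index(pts, c(0, 0, 1, 1), n_ref_sims = 99, seed = 3)
  analytic <- clark_evans_analytic(pts, area = 1)
  expect_lt(abs(sim$index - analytic), 0.05)
})

test_that("the index is scale invariant under coordinate rescaling", {
  pts <- unit_square_points(300, seed = 31)
  a <- nearest_neighbour_index(pts, c(0, 0, 1, 1), n_ref_sims = 49, seed = 4)
  b <- nearest_neighbour_index(
    dplyr::mutate(pts, lon = lon * 7, lat = lat * 7),
    c(0, 0, 7, 7), n_ref_sims = 49, seed = 4)
  # same seed drives the same uniform draws, scaled; indices agree closely
  expect_lt(abs(a$index - b$index), 0.05)
})

test_that("per-period screen is deterministic and reports thin periods", {
  pop <- toy_population()
  recs <- withr::with_seed(41, occurrences(
    taxon = "sp1",
    lon = runif(120, 0, 10), lat = runif(120, 0, 10),
    year = sample(1950:2009, 120, replace = TRUE)  # p7 left empty
  ))
  recs <- dplyr::bind_rows(recs, occurrences("sp1", 5, 5, 2015))  # p7: 1 record
  r1 <- nni_by_period(recs, pop, toy_periods(), n_ref_sims = 19, n_boot = 49,
                      seed = 5)
  r2 <- nni_by_period(recs, pop, toy_periods(), n_ref_sims = 19, n_boot = 49,
                      seed = 5)
  expect_identical(tidy(r1), tidy(r2))  # bit-identical under a fixed seed
  expect_identical(nrow(tidy(r1)), 7L)
  expect_identical(sum(is.na(r1$index)), 1L)
  expect_match(r1$note[r1$period == "p7"], "fewer than 2")
  expect_true(all(r1$lower <= r1$upper, na.rm = TRUE))
})

test_that("bootstrap intervals on CSR data usually cover 1", {
  pop <- target_population(c(0, 0, 1, 1), c(2000, 2009), "sp1", 0.1, 10)
  covered <- vapply(1:8, function(s) {
    recs <- withr::with_seed(100 + s, occurrences(
      "sp1", runif(150), runif(150), sample(2000:2009, 150, TRUE)))
    r <- nni_by_period(recs, pop, period_spec(2000, 2009, 10),
                       n_ref_sims = 49, n_boot = 199, seed = s)
    r$lower[1] <= 1 && 1 <= r$upper[1]
  }, logical(1))
  expect_gte(mean(covered), 0.75)
})

test_that("periods-sampled map counts distinct periods per cell", {
  g <- grid_spec(1, 0, 0)
  p <- toy_periods()
  recs <- occurrences(
    taxon = "sp1",
    lon = c(0.5, 0.2, 0.5, 3.5, 3.5, 3.6),
    lat = c(0.5, 0.8, 0.5, 2.5, 2.5, 2.5),
    year = c(1951, 1975, 1975, 1992, 1993, 1994)  # cell(0,0): p1,p3; cell(3,2): p5 only
  )
  psm <- periods_sampled_map(recs, g, p)
  expect_identical(psm$n_periods_sampled[psm$cell_col == 0], 2L)
  expect_identical(psm$n_periods_sampled[psm$cell_col == 3], 1L)
  expect_true(all(psm$n_periods_sampled <= n_periods(p)))
})

test_that("density surface counts records with a log10 display layer", {
  g <- grid_spec(1, 0, 0)
  p <- toy_periods()
  recs <- occurrences(
    taxon = "sp1",
    lon = c(0.5, 0.6, 0.7, 5.5), lat = c(0.5, 0.6, 0.7, 5.5),
    year = c(1951, 1952, 1953, 2015)
  )
  dens <- density_surface(recs, g, p)
  three <- dens[dens$cell_col == 0, ]
  expect_identical(three$n, 3L)
  expect_equal(three$log10_n, 0.4771213, tolerance = 1e-6)
  one <- dens[dens$cell_col == 5, ]
  expect_identical(one$log10_n, 0)     # log10(1)
  expect_identical(sum(dens$n), nrow(recs))  # conservation
  expect_false(any(is.infinite(dens$log10_n)))
})

test_that("coverage overlap is the Jaccard similarity of sampled cell sets", {
  g <- grid_spec(1, 0, 0)
  p <- toy_periods()
  # p1 cells {A=(0,0), B=(1,1)}; p2 cells {B, C=(2,2)}
  recs <- occurrences(
    taxon = "sp1",
    lon = c(0.5, 1.5, 1.6, 2.5), lat = c(0.5, 1.5, 1.5, 2.5),
    year = c(1951, 1955, 1965, 1962)
  )
  expect_equal(coverage_overlap(recs, g, p, "p1", "p2"), 1 / 3)
  expect_equal(coverage_overlap(recs, g, p, "p1", "p1"), 1)
  # sampled-vs-empty gives 0; empty-vs-empty is undefined
  expect_identical(coverage_overlap(recs, g, p, "p1", "p5"), 0)
  expect_identical(coverage_overlap(recs, g, p, "p3", "p4"), NA_real_)
  expect_error(coverage_overlap(recs, g, p, "p1", "p99"), "period ids")
})

test_that("jaccard matches a brute-force set-arithmetic oracle on random sets", {
  brute <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0) return(NA_real_)
    sum(vapply(u, function(x) x %in% a && x %in% b, logical(1))) / length(u)
  }
  withr::with_seed(7, {
    for (i in 1:25) {
      a <- sample(letters, sample(0:10, 1))
      b <- sample(letters, sample(0:10, 1))
      expect_identical(occbias:::jaccard(a, b), brute(a, b))
    }
  })
})
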