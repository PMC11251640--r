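test_that("count summaries use the sample SD and flag single observers", {
  s <- summarize_counts(c(10, 10))
  expect_equal(s$mean_count, 10)
  expect_equal(s$sd_count, 0)
  expect_equal(s$cv, 0)
  s2 <- summarize_counts(c(8, 12))
  expect_equal(s2$mean_count, 10)
  expect_equal(s2$sd_count, sqrt(8), tolerance = 1e-12)  # n-1 denominator
  expect_equal(s2$cv, 100 * sqrt(8) / 10, tolerance = 1e-12)
  s3 <- summarize_counts(7)
  expect_equal(s3$mean_count, 7)
  expect_true(is.na(s3$sd_count) && is.na(s3$cv))
  # zero mean with zero spread: CV undefined, not infinite
  expect_true(is.na(summarize_counts(c(0, 0))$cv))
  expect_error(summarize_counts(c(3, -1)), "non-negative")
})

test_that("CV is invariant to count scale", {
  x <- c(8, 12, 9)
  expect_equal(summarize_counts(x * 17)$cv, summarize_counts(x)$cv,
               tolerance = 1e-12)
})

test_that("polygon density is count over area", {
  expect_equal(polygon_density(387, 387.3), 387 / 387.3)
  expect_equal(polygon_density(0, 10), 0)
  expect_error(polygon_density(5, 0), "positive")
})

test_that("area-weighted mean density satisfies the ratio identity", {
  expect_equal(weighted_mean_density(1.0, 10)$mean, 1.0)
  expect_equal(weighted_mean_density(c(0.5, 2.0), c(10, 10))$mean, 1.25)
  # ratio-estimator identity on arbitrary synthetic fixtures
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    a <- runif(n, 50, 400)
    counts <- rpois(n, 0.7 * a)
    d <- counts / a
    wd <- weighted_mean_density(d, a)
    expect_equal(wd$mean, sum(counts) / sum(a), tolerance = 1e-12)
  }
})

test_that("pooled synthetic densities recover the generating density", {
  o <- make_outline("rectangle", 20000, aspect = 2)
  cells <- generate_grid(o)
  areas <- vapply(cells, `[[`, 0, "area")
  means <- vapply(1:200, function(k) {
    counts <- simulate_cell_counts(cells, 0.76, 8.979,
                                              seed = 5000 + k)
    weighted_mean_density(counts / areas, areas)$mean
  }, 0)
  mu <- 0.76 * areas
  se <- sqrt(sum(mu + mu^2 / 8.979) / sum(areas)^2 / 200)
  expect_lt(abs(mean(means) - 0.76), 3 * se)
})

test_that("QC-excluded polygons are dropped from every summary", {
  o <- make_outline("rectangle", 6 * 19.68^2, aspect = 6)
  cells <- generate_grid(o)
  true <- stats::setNames(c(100, 120, 80, 90, 110, 105),
                          vapply(cells, `[[`, "", "polygon_id"))
  obs <- simulate_observer_counts(true, 0.05, 2, seed = 9)
  full <- summarize_polygon_counts(obs, cells)
  cells[[2]]$qc_excluded <- TRUE
  reduced <- summarize_polygon_counts(obs, cells)
  expect_equal(nrow(reduced), nrow(full) - 1L)
  expect_false(cells[[2]]$polygon_id %in% reduced$polygon_id)
  expect_false(isTRUE(all.equal(weighted_mean_density(full)$mean,
                                weighted_mean_density(reduced)$mean)))
  # unknown polygon ids are a linkage error naming the id
  bad <- rbind(obs, data.frame(polygon_id = "ghost", observer_id = "obs_01",
                               count = 5L))
  expect_error(summarize_polygon_counts(bad, cells), "ghost")
})

test_that("agreement report summarises multi-observer CVs", {
  o <- make_outline("rectangle", 4 * 19.68^2, aspect = 4)
  cells <- generate_grid(o)
  ids <- vapply(cells, `[[`, "", "polygon_id")
  # identical observers everywhere: mean CV 0
  obs0 <- simulate_observer_counts(stats::setNames(c(50, 60, 70, 80), ids),
                                   0, 3, seed = 1)
  rep0 <- agreement_report(summarize_polygon_counts(obs0, cells))
  expect_equal(rep0$mean_cv, 0)
  expect_equal(rep0$n_multi_observer, 4L)
  # one multi-observer polygon: SD of CV unavailable
  obs1 <- rbind(
    data.frame(polygon_id = ids[1], observer_id = c("a", "b"),
               count = c(10L, 12L)),
    data.frame(polygon_id = ids[2], observer_id = "a", count = 20L)
  )
  rep1 <- agreement_report(summarize_polygon_counts(obs1, cells))
  expect_equal(rep1$n_multi_observer, 1L)
  expect_equal(rep1$n_single_observer, 1L)
  expect_true(is.na(rep1$sd_cv))
})

test_that("synthetic observer noise lands near the calibrated mean CV", {
  o <- make_outline("rectangle", 50 * 19.68^2, aspect = 2)
  cells <- generate_grid(o)
  counts <- simulate_cell_counts(cells, 0.76, 8.979, seed = 21)
  names(counts) <- vapply(cells, `[[`, "", "polygon_id")
  keep <- counts > 0
  obs <- simulate_observer_counts(counts[keep], 0.058, 2, seed = 22)
  rep_ <- agreement_report(
    summarize_polygon_counts(obs, cells[keep]))
  expect_gt(rep_$mean_cv, 4)
  expect_lt(rep_$mean_cv, 8)
})
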