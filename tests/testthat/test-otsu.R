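test_that("histograms conserve counts and respect the top-edge rule", {
  h <- build_histogram(c(0, 0, 1, 1), bins = 2)
  expect_equal(h$counts, c(2L, 2L))
  expect_equal(h$probs, c(0.5, 0.5))
  expect_equal(h$n, 4L)

  set.seed(1)
  x <- runif(100)
  h2 <- build_histogram(x, bins = 10)
  expect_equal(sum(h2$counts), 100L)
  expect_equal(sum(h2$probs), 1)
  expect_true(all(diff(h2$edges) > 0))
  # max value sits exactly on the top edge and lands in the last bin
  expect_gte(h2$counts[10], 1L)

  expect_error(build_histogram(rep(0.3, 10), bins = 8), "degenerate input")
  expect_error(build_histogram(grid_of(matrix(1, 3, 3)), bins = 4),
               "degenerate input")
})

test_that("class probabilities and means satisfy the defining identities at every split", {
  set.seed(42)
  for (rep in 1:25) {
    h <- random_histogram(sample(8:64, 1))
    res <- otsu_threshold(h)
    cand <- attr(res, "candidates")
    ok <- !is.na(cand$mu0)
    expect_equal(cand$omega1[ok], 1 - cand$omega0[ok], tolerance = 1e-12)
    mu_T <- sum(h$probs * h$mids)
    expect_equal(cand$omega0[ok] * cand$mu0[ok] + cand$omega1[ok] * cand$mu1[ok],
                 rep(mu_T, sum(ok)), tolerance = 1e-10)
    expect_gte(res$sigma_b2, 0)
  }
})

test_that("the selected split attains the brute-force maximum between-class variance", {
  set.seed(7)
  for (rep in 1:200) {
    h <- random_histogram(sample(4:64, 1))
    res <- otsu_threshold(h)
    oracle <- oracle_otsu(h$probs, h$mids)
    expect_equal(res$sigma_b2, oracle$sigma_b2, tolerance = 1e-10)
    expect_equal(res$threshold_bin, oracle$t)
  }
})

test_that("ties between equal-variance splits resolve to the smallest split", {
  # symmetric two-spike histogram: every split between the spikes ties
  counts <- c(5L, 0L, 0L, 0L, 5L)
  edges <- seq(0, 1, length.out = 6L)
  h <- structure(list(edges = edges, mids = (edges[-1] + edges[-6]) / 2,
                      counts = counts, n = 10L, probs = counts / 10),
                 class = "otsu_histogram")
  res <- otsu_threshold(h)
  expect_equal(res$threshold_bin, oracle_otsu(h$probs, h$mids)$t)
  expect_equal(res$threshold_bin, 1L)
})

test_that("a two-spike histogram gives the closed-form variance 0.25 (mu0 - mu1)^2", {
  counts <- integer(10); counts[c(2, 9)] <- 50L
  edges <- seq(0, 1, length.out = 11L)
  h <- structure(list(edges = edges, mids = (edges[-1] + edges[-11]) / 2,
                      counts = counts, n = 100L, probs = counts / 100),
                 class = "otsu_histogram")
  res <- otsu_threshold(h)
  expect_equal(res$omega0, 0.5)
  expect_gte(res$threshold_bin, 2L)
  expect_lt(res$threshold_bin, 9L)
  expect_equal(res$sigma_b2, 0.25 * (res$mu0 - res$mu1)^2, tolerance = 1e-12)
})

test_that("a balanced two-normal mixture thresholds inside the valley", {
  set.seed(123)
  truth <- rep(c(0, 1), each = 5e4)
  x <- c(rnorm(5e4, 0.05, 0.03), rnorm(5e4, 0.45, 0.03))
  h <- build_histogram(x, bins = 256)
  res <- otsu_threshold(h)
  # between-class variance is flat across the empty valley, so the exact
  # split is tie-broken; any valley split separates the components cleanly
  expect_gt(res$threshold_value, 0.05 + 3 * 0.03)
  expect_lt(res$threshold_value, 0.45 - 3 * 0.03)
  expect_lt(mean((x >= res$threshold_value) != truth), 1e-3)
  expect_equal(res$sigma_b2, 0.25 * (res$mu0 - res$mu1)^2, tolerance = 1e-3)
  # direct scan on the realized sample agrees
  expect_equal(res$threshold_bin, oracle_otsu(h$probs, h$mids)$t)
})

test_that("the threshold is invariant under positive affine rescaling", {
  set.seed(9)
  x <- c(rnorm(400, 0.1, 0.05), rnorm(200, 0.6, 0.08))
  a <- 3; b <- 7
  r1 <- otsu_threshold(build_histogram(x, bins = 64))
  r2 <- otsu_threshold(build_histogram(a * x + b, bins = 64))
  expect_equal(r2$threshold_bin, r1$threshold_bin)
  expect_equal(r2$threshold_value, a * r1$threshold_value + b, tolerance = 1e-9)
  expect_equal(r2$omega0, r1$omega0)
})

test_that("raster thresholding honours masks and degenerate domains", {
  set.seed(13)
  v <- matrix(c(rnorm(50, 0.1, 0.01), rnorm(50, 0.6, 0.01)), 10, 10)
  g <- raster_grid(v)
  full <- otsu_on_raster(g, bins = 64)
  all_true <- otsu_on_raster(g, bins = 64, domain_mask = matrix(TRUE, 10, 10))
  expect_identical(full$threshold_value, all_true$threshold_value)
  # planted two-cluster raster: threshold separates the clusters exactly
  labels <- v >= full$threshold_value
  expect_identical(labels, v > 0.35)
  # masking away one cluster leaves (near-)degenerate data but still two
  # distinct values; masking to a constant region errors
  const_mask <- matrix(FALSE, 10, 10); const_mask[1, 1:2] <- TRUE
  g2 <- raster_grid(matrix(0.5, 10, 10))
  expect_error(otsu_on_raster(g2, domain_mask = const_mask), "degenerate input")
  expect_error(otsu_on_raster(g, domain_mask = matrix(FALSE, 10, 10)),
               "degenerate input")
})

test_that("otsu results serialize to JSON with their diagnostics", {
  set.seed(2)
  res <- otsu_threshold(build_histogram(runif(500), bins = 32))
  parsed <- jsonlite::fromJSON(otsu_to_json(res))
  expect_equal(parsed$threshold_value, res$threshold_value)
  expect_equal(parsed$omega0 + parsed$omega1, 1, tolerance = 1e-12)
})
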