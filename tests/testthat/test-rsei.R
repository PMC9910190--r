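rank1_stack <- function(n = 40, seed = 101, noise = 0) {
  set.seed(seed)
  e <- matrix(runif(n * n), n, n)
  mk <- function(v) raster_grid(v + matrix(rnorm(n * n, 0, noise), n, n))
  list(stack = indicator_stack(wet = mk(e), ndvi = mk(e),
                               lst = mk(1 - e), si = mk(1 - e)),
       e = e)
}

test_that("min-max normalization attains [0, 1] and absorbs affine rescaling", {
  g <- grid_of(c(2, 4, 6))
  expect_equal(as.numeric(normalize_indicator(g)$values), c(0, 0.5, 1))
  set.seed(4)
  r <- raster_grid(matrix(rnorm(100, 300, 15), 10, 10))
  nr <- normalize_indicator(r)
  expect_equal(min(valid_values(nr)), 0)
  expect_equal(max(valid_values(nr)), 1)
  rescaled <- raster_grid(3 * r$values + 7)
  expect_equal(normalize_indicator(rescaled)$values, nr$values, tolerance = 1e-12)
  expect_error(normalize_indicator(grid_of(matrix(5, 3, 3))), "degenerate input")
})

test_that("a rank-one indicator stack puts all variance on an oriented PC1", {
  rs <- rank1_stack()
  prod <- compute_rsei(rs$stack)
  expect_equal(prod$variance_share[1], 100, tolerance = 1e-6)
  l1 <- prod$loadings[, 1]
  expect_true(l1[["wet"]] > 0 && l1[["ndvi"]] > 0 &&
              l1[["lst"]] < 0 && l1[["si"]] < 0)
  expect_true(all(diff(prod$variance_share) <= 1e-9))
  expect_equal(sum(prod$variance_share), 100)
  expect_equal(sqrt(colSums(prod$loadings^2)), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  v <- valid_values(prod$rsei)
  expect_equal(range(v), c(0, 1))
  # with this construction RSEI recovers the min-max scaled latent field
  e_scaled <- (rs$e - min(rs$e)) / (max(rs$e) - min(rs$e))
  expect_equal(prod$rsei$values[rs$stack$valid], as.numeric(e_scaled),
               tolerance = 1e-9)
})

test_that("orientation makes RSEI invariant to the sign of the raw PC1", {
  rs <- rank1_stack(seed = 55, noise = 0.02)
  prod <- compute_rsei(rs$stack)
  # negate all indicators: PCA's PC1 flips, orientation must restore it
  neg <- indicator_stack(
    wet = raster_grid(-rs$stack$grids$wet$values),
    ndvi = raster_grid(-rs$stack$grids$ndvi$values),
    lst = raster_grid(-rs$stack$grids$lst$values),
    si = raster_grid(-rs$stack$grids$si$values))
  prod_neg <- compute_rsei(neg)
  expect_equal(prod_neg$loadings["ndvi", 1] > 0, TRUE)
  expect_equal(cor(prod$rsei$values[rs$stack$valid],
                   prod_neg$rsei$values[rs$stack$valid]), -1, tolerance = 1e-9)
})

test_that("RSEI is invariant to per-indicator affine rescaling of raw inputs", {
  rs <- rank1_stack(seed = 77, noise = 0.05)
  prod <- compute_rsei(rs$stack)
  g <- rs$stack$grids
  rescaled <- indicator_stack(
    wet = raster_grid(10 * g$wet$values - 3),
    ndvi = raster_grid(0.5 * g$ndvi$values + 0.2),
    lst = raster_grid(40 * g$lst$values + 270),
    si = raster_grid(2 * g$si$values - 1))
  prod2 <- compute_rsei(rescaled)
  expect_equal(prod2$rsei$values, prod$rsei$values, tolerance = 1e-9)
})

test_that("water and nodata are excluded from normalization and PCA", {
  rs <- rank1_stack(seed = 12, noise = 0.01)
  water <- matrix(FALSE, 40, 40); water[1:4, ] <- TRUE
  g <- rs$stack$grids
  st <- indicator_stack(wet = g$wet, ndvi = g$ndvi, lst = g$lst, si = g$si,
                        water = water)
  prod <- compute_rsei(st)
  expect_true(all(is.na(prod$rsei$values[water])))
  expect_true(all(is.na(prod$levels$values[water])))
  expect_error(compute_rsei(indicator_stack(
    wet = grid_of(matrix(1, 3, 3)), ndvi = grid_of(matrix(1, 3, 3)),
    lst = grid_of(matrix(1, 3, 3)), si = grid_of(matrix(1, 3, 3)),
    water = matrix(TRUE, 3, 3))), "degenerate input")
})

test_that("level classing follows the 0.2 intervals with the stated boundaries", {
  g <- grid_of(c(0, 0.1999, 0.2, 0.4, 0.59999, 0.6, 0.8, 1.0))
  expect_equal(as.numeric(classify_levels(g)$values),
               c(1, 1, 2, 3, 3, 4, 5, 5))
  expect_error(classify_levels(grid_of(c(0.5, 1.2))), "domain error")
  expect_error(classify_levels(grid_of(c(-0.01, 0.5))), "domain error")
  set.seed(66)
  u <- raster_grid(matrix(runif(1e5), 250, 400))
  shares <- tabulate(classify_levels(u)$values, nbins = 5) / 1e5
  expect_true(all(abs(shares - 0.2) < 0.01))
})

test_that("change maps bin the pre-post difference as published", {
  pre <- grid_of(rep(0.5, 6))
  post <- grid_of(c(0.5, 0.8, 0.58, 0.47, 0.42, 0.2))
  # d = pre - post: 0, -0.3, -0.08, 0.03, 0.08, 0.3
  cm <- change_map(pre, post)
  expect_equal(as.numeric(cm$values), c(3, 1, 2, 3, 4, 5))
  same <- change_map(pre, pre)
  expect_true(all(same$values == 3))
  expect_error(change_map(pre, grid_of(rep(0.5, 4))), "alignment error")
})

test_that("zonal means average valid zone pixels only", {
  r <- grid_of(matrix(0.5, 4, 4))
  expect_equal(zonal_mean(r, matrix(TRUE, 4, 4)), 0.5)
  single <- matrix(FALSE, 4, 4); single[2, 3] <- TRUE
  r2 <- raster_grid(matrix(seq(0, 1, length.out = 16), 4, 4))
  expect_equal(zonal_mean(r2, single), r2$values[2, 3])
  expect_error(zonal_mean(r, matrix(FALSE, 4, 4)), "empty zone")
})

test_that("transfer matrices conserve area and compute the change margin", {
  pairs <- data.frame(pre = c(3, 4, 4, 5), post = c(3, 3, 4, 4),
                      n = c(802, 3426, 3453, 72))
  lv <- levels_from_counts(pairs, pixel_m = 10)
  tm <- transfer_matrix(lv$pre, lv$post)
  expect_equal(tm$areas["moderate", "moderate"], 8.02)
  expect_equal(tm$areas["moderate", "good"], 34.26)
  expect_equal(tm$row_totals[["moderate"]], 42.28)
  expect_equal(tm$row_totals[["good"]], 35.25)
  expect_equal(tm$change[["good"]], 34.26)  # good column minus its diagonal
  expect_equal(tm$total_hm2, sum(pairs$n) * 0.01)

  set.seed(14)
  pre <- raster_grid(matrix(sample(1:5, 900, TRUE), 30, 30), pixel_m = 30)
  post <- raster_grid(matrix(sample(1:5, 900, TRUE), 30, 30), pixel_m = 30)
  zone <- matrix(runif(900) < 0.4, 30, 30)
  tm2 <- transfer_matrix(pre, post, zone = zone)
  expect_equal(tm2$total_hm2, sum(zone) * 0.09)
  expect_equal(tm2$col_totals, colSums(tm2$areas))
  expect_equal(tm2$row_totals, rowSums(tm2$areas))
  for (k in 1:5) {
    pre_area <- sum(zone & pre$values == k) * 0.09
    expect_equal(unname(tm2$col_totals[k]), pre_area)
  }
})

test_that("transfer matrices export in the published table layout", {
  pairs <- data.frame(pre = c(1, 2), post = c(2, 2), n = c(3, 4))
  lv <- levels_from_counts(pairs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transfer_csv(transfer_matrix(lv$pre, lv$post), path)
  back <- read.csv(path)
  expect_equal(nrow(back), 7L)  # 5 levels + Total + Change rows
  expect_equal(back$post[6:7], c("Total", "Change"))
  expect_equal(back$Total[2], 0.07)
})
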