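test_that("IDW honours exact hits, symmetry and the hand-computed case", {
  # sources on a 2-cell coarse grid
  src <- chs_grid(matrix(c(7.3, NA), 1, 2), 0, 0, 1000)  # center (500, 500)
  tgt <- chs_grid(matrix(0, 1, 1), 0, 0, 1000)
  expect_equal(interp_bin_idw(src, tgt)$values[1, 1], 7.3)
  # two sources 4 and 8, target equidistant -> 6
  v <- idw_interp(c(0, 10), c(0, 0), c(4, 8), 5, 0, power = 2, k = 8)
  expect_equal(v, 6)
  # d = {1, 2}, v = {10, 20}, power 2 -> 12
  v2 <- idw_interp(c(1, 2), c(0, 0), c(10, 20), 0, 0, power = 2, k = 8)
  expect_equal(v2, 12)
  # no valid sources errors
  empty <- chs_grid(matrix(NA_real_, 2, 2), 0, 0, 1000)
  expect_error(interp_bin_idw(empty, tgt), "valid source")
})

test_that("extrusion assigns the nearest level with ties shallower and clamps", {
  levels <- c(0, 50, 100, 200)
  vals <- c(10, 8, 6, 5)
  field <- flat_climatology(levels, function(z) vals[match(z, levels)],
                            nr = 3, nc = 3, cellsize = 4000)
  bathy <- chs_grid(matrix(c(100, 130, 9000, 75,
                             0.1, 160, NA, 24, 51), 3, 3), 0, 0, 500)
  out <- extrude_to_seafloor(field, bathy)
  v <- out$grid$values
  expect_equal(v[1, 1], 6)    # exact level match 100
  expect_equal(v[2, 1], 6)    # 130 -> nearest level 100
  expect_equal(v[3, 1], 5)    # 9000 clamps to deepest bin
  expect_equal(v[1, 2], 8)    # 75 is the 50/100 midpoint -> shallower bin
  expect_true(is.na(v[1, 3])) # no-data follows bathymetry
  # provenance is a partition of the valid cells
  prov <- out$provenance$values
  expect_equal(sum(!is.na(prov)), sum(!is.na(bathy$values)))
  expect_equal(sum(table(prov)), sum(!is.na(bathy$values)))
})

test_that("depth-only climatologies are reproduced exactly (piecewise oracle)", {
  profile <- function(z) 2 + 8 * exp(-z / 300)
  levels <- seq(0, 3000, by = 150)
  field <- flat_climatology(levels, profile, nr = 5, nc = 5, cellsize = 8000)
  sc <- tiny_seascape()
  out <- extrude_to_seafloor(field, sc$bathymetry)
  d <- sc$bathymetry$values
  nearest <- levels[sapply(as.vector(d), function(z) which.min(abs(levels - z)))]
  expected <- matrix(profile(nearest), nrow(d), ncol(d))
  ok <- !is.na(d)
  expect_equal(out$grid$values[ok], expected[ok], tolerance = 1e-12)
})

test_that("bottle validation filters and correlates as specified", {
  bathy <- chs_grid(matrix(100, 2, 2), 0, 0, 500)
  layer <- chs_grid(matrix(c(1, 2, 3, 4), 2, 2), 0, 0, 500)
  casts <- data.frame(
    x = c(100, 100, 600, 600, 100, 100),
    y = c(100, 600, 100, 600, 100, 100),
    sample_depth = c(98, 94, 99, 100, 98, 98),
    year = c(2005, 2005, 2001, 2005, 2005, 2005),
    bottom_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    value = c(1, 3, 2, 4, 1, NA))
  rep <- validate_with_bottles(layer, casts, bathy)
  # cast 2 is 6% off depth; cast 3 pre-2002; cast 4 lacks the flag;
  # cast 6 has no value; casts 1 and 5 survive
  expect_equal(rep$excluded[["depth_mismatch"]], 1L)
  expect_equal(rep$excluded[["pre_cutoff_year"]], 1L)
  expect_equal(rep$excluded[["no_bottom_flag"]], 1L)
  expect_equal(rep$excluded[["missing_value"]], 1L)
  expect_equal(rep$n, 2L)
  expect_true(is.na(rep$r))  # < 3 survivors: correlation unavailable
  # perfect agreement gives r = r2 = 1
  casts2 <- data.frame(x = c(100, 600, 100, 600),
                       y = c(100, 100, 600, 600),
                       sample_depth = rep(100, 4), year = rep(2010, 4),
                       bottom_flag = TRUE, value = c(1, 3, 2, 4))
  rep2 <- validate_with_bottles(layer, casts2, bathy)
  expect_equal(rep2$n, 4L)
  expect_equal(rep2$r, 1)
  expect_equal(rep2$r2, 1)
})

test_that("synthetic bottle casts validate the truth layers at r2 >= 0.95", {
  sc <- tiny_seascape()
  layer <- list(grid = sc$true_layers$temperature, variable = "temperature")
  class(layer) <- "chs_seafloor_layer"
  casts <- sc$bottle_casts
  casts$value <- casts$temperature
  rep <- validate_with_bottles(layer, casts, sc$bathymetry)
  expect_gte(rep$n, 10L)
  expect_gte(rep$r2, 0.95)
})

test_that("correlation pruning drops the right member of each hot pair", {
  set.seed(3)
  n <- 200
  a <- stats::rnorm(n)
  b <- a + stats::rnorm(n, 0, 0.3)          # corr(A,B) ~ 0.95
  c_ <- stats::rnorm(n)
  samples <- data.frame(A = a, B = b, C = c_)
  out <- correlation_prune(samples, threshold = 0.7)
  expect_setequal(out$retained, c("A", "C"))  # later-listed B dropped
  expect_equal(out$dropped$variable, "B")
  # both protected: pair exempt, both retained
  out2 <- correlation_prune(samples, threshold = 0.7, keep_list = c("A", "B"))
  expect_setequal(out2$retained, c("A", "B", "C"))
  # keep_list protects one side
  out3 <- correlation_prune(samples, threshold = 0.7, keep_list = "B")
  expect_setequal(out3$retained, c("B", "C"))
  # correlation-free set: all retained
  set.seed(4)
  ind <- data.frame(x = stats::rnorm(50), y = stats::rnorm(50),
                    z = stats::rnorm(50))
  expect_setequal(correlation_prune(ind)$retained, c("x", "y", "z"))
  expect_error(correlation_prune(samples, keep_list = "nope"), "unknown")
})
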