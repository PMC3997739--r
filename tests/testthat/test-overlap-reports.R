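test_that("zonal areas follow cell-center membership and both unit systems", {
  cons <- chs_grid(matrix(2, 4, 4), 0, 0, 500)
  attr(cons, "K") <- 4L
  poly <- list(box = data.frame(x = c(0, 1000, 1000, 0),
                                y = c(0, 0, 1000, 1000)))
  rep <- zonal_area(cons, poly)
  # 4 cell centers inside, all class 2, cell 0.25 km^2
  expect_equal(rep$by_class$area_km2[rep$by_class$class == 2], 1.0)
  expect_equal(rep$summary$suitable_pct, 100)
  expect_equal(rep$summary$suitable_nm2, 1.0 / 3.429904)
  # all-zero consensus: suitable percentage 0
  cons0 <- chs_grid(matrix(0, 4, 4), 0, 0, 500)
  attr(cons0, "K") <- 4L
  expect_equal(zonal_area(cons0, poly)$summary$suitable_pct, 0)
  # polygon fully outside gives a zero-area row with a warning
  far <- list(out = data.frame(x = c(1e5, 2e5, 2e5), y = c(1e5, 1e5, 2e5)))
  expect_warning(rep2 <- zonal_area(cons, far), "no valid cells")
  expect_equal(rep2$summary$total_km2, 0)
})

test_that("zonal accounting matches a brute-force oracle on random grids", {
  set.seed(40)
  for (rep in 1:10) {
    cons <- chs_grid(matrix(sample(c(0:4, NA), 100, TRUE), 10, 10), 0, 0, 500)
    attr(cons, "K") <- 4L
    x0 <- stats::runif(1, 0, 2000); y0 <- stats::runif(1, 0, 2000)
    poly <- list(r = data.frame(x = c(x0, x0 + 2600, x0 + 2600, x0),
                                y = c(y0, y0, y0 + 1800, y0 + 1800)))
    out <- zonal_area(cons, poly)
    # oracle: explicit per-cell loop
    cc <- grid_coords(cons)
    inside <- cc$x >= x0 & cc$x <= x0 + 2600 & cc$y >= y0 & cc$y <= y0 + 1800
    for (k in 0:4) {
      expect_equal(out$by_class$n_cells[out$by_class$class == k],
                   sum(inside & !is.na(cc$value) & cc$value == k))
    }
    # conservation: class areas sum to polygon-covered valid area
    expect_equal(sum(out$by_class$area_km2), out$summary$total_km2)
  }
})

test_that("substrate cross-tab percentages are exact and sum to 100", {
  cons <- chs_grid(matrix(c(0, 0, 1, 1, 1, 0), 2, 3), 0, 0, 500)
  attr(cons, "K") <- 1L
  sub <- chs_grid(matrix(c(1, 2, 1, 1, 3, 3), 2, 3), 0, 0, 500)
  ct <- substrate_cross_tab(cons, sub)
  # class 0 cells: substrate {1, 2, 3}; class 1 cells: {1, 1, 3}
  expect_equal(ct$hard_pct[ct$class == 0], 100 / 3)
  expect_equal(ct$hard_pct[ct$class == 1], 200 / 3)
  expect_equal(ct$soft_pct[ct$class == 1], 100 / 3)
  sums <- rowSums(ct[, c("hard_pct", "mixed_pct", "soft_pct")])
  expect_true(all(abs(sums - 100) < 0.1))
  # uniform hard substrate: every class 100% hard
  hard <- chs_grid(matrix(1, 2, 3), 0, 0, 500)
  ct2 <- substrate_cross_tab(cons, hard)
  expect_true(all(ct2$hard_pct == 100))
  # absent class yields an NA row
  cons2 <- chs_grid(matrix(1, 2, 3), 0, 0, 500)
  attr(cons2, "K") <- 2L
  ct3 <- substrate_cross_tab(cons2, hard)
  expect_true(is.na(ct3$hard_pct[ct3$class == 0]))
})

test_that("hard substrate is enriched on steep ground in the generator", {
  sc <- tiny_seascape()
  cons_geom <- sc$bathymetry
  sub <- grid_majority_resample(sc$substrate, cons_geom,
                                tie_order = SUBSTRATE_CLASSES)
  slope <- sc$true_layers$slope$values
  ok <- !is.na(slope) & !is.na(sub$values)
  steep <- slope >= stats::quantile(slope[ok], 0.9)
  hard_steep <- mean(sub$values[ok & steep] == 1)
  hard_all <- mean(sub$values[ok] == 1)
  expect_gt(hard_steep, hard_all)
  # substrate classes partition the valid cells
  f <- table(sc$substrate$values)
  expect_equal(sum(f) , sum(!is.na(sc$substrate$values)))
})

test_that("trawl density matches the analytic chord and privacy mask", {
  spec <- chs_grid(matrix(0, 21, 21), 0, 0, 500)
  # a long straight line through the center cell's center (5250, 5250)
  mkline <- function(v) data.frame(x0 = -1e5, y0 = 5250, x1 = 1e5, y1 = 5250,
                                   vessel_id = v)
  one <- trawl_line_density(mkline("V1"), spec, radius = 3000,
                            privacy = FALSE)
  expect_equal(one$values[11, 11], 6 / (9 * pi), tolerance = 1e-9)
  # fewer than three vessels: masked under the privacy rule
  two <- trawl_line_density(rbind(mkline("V1"), mkline("V2")), spec,
                            radius = 3000)
  expect_true(is.na(two$values[11, 11]))
  three <- trawl_line_density(rbind(mkline("V1"), mkline("V2"), mkline("V3")),
                              spec, radius = 3000)
  expect_equal(three$values[11, 11], 3 * 6 / (9 * pi), tolerance = 1e-9)
  # no lines: all zeros when privacy disabled
  none <- trawl_line_density(mkline("V1")[0, ], spec, privacy = FALSE)
  expect_true(all(none$values == 0))
  # zero-length segments are ignored
  degenerate <- data.frame(x0 = 5250, y0 = 5250, x1 = 5250, y1 = 5250,
                           vessel_id = "V9")
  expect_true(all(trawl_line_density(degenerate, spec,
                                     privacy = FALSE)$values == 0))
  expect_error(trawl_line_density(mkline("V1"), spec, radius = -1),
               "positive")
})

test_that("trawl density is translation invariant up to cell quantization", {
  spec <- chs_grid(matrix(0, 15, 15), 0, 0, 500)
  lines <- data.frame(x0 = c(1000, 2000), y0 = c(1000, 4000),
                      x1 = c(6000, 6500), y1 = c(3000, 4200),
                      vessel_id = c("a", "b"))
  d1 <- trawl_line_density(lines, spec, privacy = FALSE)
  shift <- 1500  # 3 whole cells
  lines2 <- transform(lines, x0 = x0 + shift, x1 = x1 + shift)
  spec2 <- chs_grid(matrix(0, 15, 15), shift, 0, 500)
  d2 <- trawl_line_density(lines2, spec2, privacy = FALSE)
  expect_equal(d2$values, d1$values, tolerance = 1e-9)
})

test_that("intensity histogram conserves cells and concentrates zeros", {
  cons <- chs_grid(matrix(sample(0:2, 36, TRUE), 6, 6), 0, 0, 500)
  attr(cons, "K") <- 2L
  zero <- chs_grid(matrix(0, 6, 6), 0, 0, 500)
  h <- intensity_by_class(cons, zero)
  expect_equal(h$n, 36L)
  expect_equal(unname(h$bin_totals[1]), 36L)
  expect_true(all(h$counts[, -1] == 0))
  # constructed 6-cell toy with hand-counted joint table
  cons2 <- chs_grid(matrix(c(0, 0, 1, 1, 2, 2), 1, 6), 0, 0, 500)
  attr(cons2, "K") <- 2L
  inten <- chs_grid(matrix(c(0, 3, 0.2, 6, NA, 1), 1, 6), 0, 0, 500)
  h2 <- intensity_by_class(cons2, inten, bins = c(0, 1, 5, Inf))
  expect_equal(h2$n, 5L)  # one masked cell excluded
  expect_equal(unname(h2$counts["0", ]), c(1L, 1L, 0L))
  expect_equal(unname(h2$counts["1", ]), c(1L, 0L, 1L))
  expect_equal(unname(h2$counts["2", ]), c(0L, 1L, 0L))
})

test_that("niche summaries report ranges, fractions and densities", {
  env <- data.frame(omega = c(0.5, 1.5, 1.8, 2.5), t = c(4, 5, 6, NA))
  ns <- niche_summary(env, ranges = list(omega = c(1, 2)))
  expect_equal(ns$fractions$fraction_pct, 50)  # {1.5, 1.8} of 4
  srow <- ns$summary[ns$summary$variable == "omega", ]
  expect_equal(srow$min, 0.5); expect_equal(srow$max, 2.5)
  expect_equal(ns$n_no_data[["t"]], 1L)
  expect_true(all(c("x", "y") %in% names(ns$density$omega)))
  # all values inside the range -> 100%
  ns2 <- niche_summary(data.frame(v = c(1.1, 1.9)),
                       ranges = list(v = c(1, 2)))
  expect_equal(ns2$fractions$fraction_pct, 100)
})

test_that("hard-substrate share rises with suitability on the default seascape", {
  sc <- tiny_seascape()
  cons <- tiny_pipeline()$cv$consensus[["0.5"]]
  ct <- substrate_cross_tab(cons, sc$substrate)
  hard <- ct$hard_pct[!is.na(ct$hard_pct)]
  # qualitative Table-6-style pattern: monotone trend, judged by the
  # class-0 vs top-class contrast
  expect_gt(hard[length(hard)], hard[1])
})
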