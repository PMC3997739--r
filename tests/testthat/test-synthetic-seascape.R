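test_that("config validation rejects impossible worlds", {
  expect_error(seascape_config(cell_size = 0), "positive")
  expect_error(seascape_config(depth_levels = c(0, 50, 50)), "increasing")
  expect_error(seascape_config(contaminant_rates = c(trawl = 1.2)), "0, 1")
  expect_error(seascape_config(coverage_fraction = 0), "coverage")
  expect_error(make_bathymetry(seascape_config(grid_extent = c(40, 80))),
               "50 x 50")
})

test_that("a fixed seed reproduces every generated artifact exactly", {
  cfg <- seascape_config(seed = 77, grid_extent = c(50, 60), n_presences = 60,
                         n_bottle_casts = 30)
  a <- simulate_seascape(cfg)
  b <- simulate_seascape(cfg)
  expect_identical(a$bathymetry$values, b$bathymetry$values)
  expect_identical(a$soundings, b$soundings)
  expect_identical(a$presences, b$presences)
  expect_identical(a$substrate$values, b$substrate$values)
  expect_identical(a$trawl_lines, b$trawl_lines)
  expect_identical(
    a$climatology$temperature$grids[[5]]$values,
    b$climatology$temperature$grids[[5]]$values)
})

test_that("a featureless config degenerates to a planar ramp", {
  cfg <- seascape_config(seed = 3, grid_extent = c(50, 60),
                         canyon_amp = 0, seamount_amp = 0, noise_sd = 0,
                         coverage_fraction = 0.2)
  b <- make_bathymetry(cfg)
  sl <- horn_slope(b$bathymetry, 500)
  interior <- sl$values[2:49, 2:59]
  expect_lt(diff(range(interior)), 1e-9)  # constant slope on the ramp
  expect_gt(interior[1, 1], 0)
})

test_that("survey tracks hit the requested coverage fraction", {
  sc <- tiny_seascape()
  idx <- grid_cell_at(sc$soundings$x, sc$soundings$y, sc$bathymetry)
  frac <- length(unique(paste(idx$row, idx$col))) /
    length(sc$bathymetry$values)
  expect_lt(abs(frac - sc$config$coverage_fraction), 0.05)
})

test_that("climatology respects profiles, monotonicity and degenerate configs", {
  pr <- default_profiles()
  expect_equal(pr$temperature(0), 10)
  expect_equal(pr$temperature(1e9), 2, tolerance = 1e-6)
  # temperature profile monotone decreasing, salinity monotone increasing
  z <- seq(0, 5000, 50)
  expect_true(all(diff(pr$temperature(z)) < 0))
  expect_true(all(diff(pr$salinity(z)) > 0))
  # oxygen has an interior minimum (oxygen minimum zone)
  ox <- pr$oxygen(z)
  expect_gt(which.min(ox), 1)
  expect_lt(which.min(ox), length(z))
  # zero noise and gradient: every cell of a bin equals profile(level)
  cfg <- seascape_config(seed = 5, grid_extent = c(50, 60))
  clim <- make_climatology(cfg, gradients = c(temperature = 0),
                           noise_sd = c(temperature = 0))
  k <- 7
  want <- pr$temperature(cfg$depth_levels[k])
  expect_true(all(clim$temperature$grids[[k]]$values == want))
  # undefined profile errors
  expect_error(
    suppressWarnings(
      make_climatology(cfg, profiles = list(bad = function(z) sqrt(z - 1e6)))),
    "undefined")
})

test_that("presence sampling follows suitability, bias polygon and rates", {
  # suitability zero outside a polygon: every clean record falls inside
  suit <- chs_grid(matrix(0, 20, 20), 0, 0, 500)
  suit$values[5:10, 5:10] <- 0.8
  truth <- list(true_suitability = suit,
                bathymetry = chs_grid(matrix(500, 20, 20), 0, 0, 500))
  cfg <- seascape_config(seed = 9, n_presences = 100,
                         contaminant_rates = c(trawl = 0))
  pres <- sample_presences(truth, cfg)
  expect_true(all(pres$truth == "clean"))
  expect_true(all(grid_value_at(pres$x, pres$y, suit) > 0))
  # large gamma concentrates sampling in better habitat than background
  sc <- tiny_seascape()
  cfg8 <- seascape_config(seed = 11, n_presences = 150,
                          suitability_exponent = 8,
                          contaminant_rates = c(trawl = 0))
  p8 <- sample_presences(sc, cfg8)
  s_at <- grid_value_at(p8$x, p8$y, sc$true_suitability)
  expect_gt(mean(s_at, na.rm = TRUE),
            mean(sc$true_suitability$values, na.rm = TRUE))
  expect_error(sample_presences(sc, seascape_config(n_presences = 0)),
               "positive")
})

test_that("contaminant records carry their stated defects", {
  sc <- tiny_seascape()
  p <- sc$presences
  expect_true(all(p$gear[p$truth == "contaminant_trawl"] == "trawl"))
  expect_true(all(p$depth[p$truth == "contaminant_shallow"] < 50))
  expect_true(all(p$family[p$truth == "contaminant_unknown_family"] ==
                    "unknown"))
  dups <- p[p$truth == "contaminant_duplicate", ]
  clean <- p[p$truth == "clean", ]
  # every duplicate shares taxon and analysis cell with a clean record
  g <- sc$bathymetry
  dcell <- grid_cell_at(dups$x, dups$y, g)
  ccell <- grid_cell_at(clean$x, clean$y, g)
  dkey <- paste(taxon_label(dups), dcell$row, dcell$col)
  ckey <- paste(taxon_label(clean), ccell$row, ccell$col)
  expect_true(all(dkey %in% ckey))
  # expected contaminant counts follow the configured rates
  rates <- sc$config$contaminant_rates
  expect_equal(sum(p$truth == "contaminant_trawl"),
               round(rates[["trawl"]] * sc$config$n_presences))
})

test_that("overlays partition substrate and honour the trawl-line count", {
  sc <- tiny_seascape()
  tab <- table(factor(sc$substrate$values, levels = SUBSTRATE_CLASSES))
  expect_equal(sum(tab) / sum(!is.na(sc$substrate$values)), 1)
  expect_equal(length(unique(sc$trawl_lines$vessel_id)) <=
                 sc$config$n_vessels, TRUE)
  # zero trawl segments requested: empty set
  cfg0 <- seascape_config(seed = 12, grid_extent = c(50, 60),
                          n_trawl_lines = 0)
  ov <- make_overlays(cfg0, simulate_seascape(
    seascape_config(seed = 12, grid_extent = c(50, 60), n_trawl_lines = 0)))
  expect_equal(nrow(ov$trawl_lines), 0L)
  # polygons stay within the extent
  for (ring in sc$polygons) {
    expect_true(all(ring$x >= 0 & ring$x <= 80 * 500))
    expect_true(all(ring$y >= 0 & ring$y <= 60 * 500))
  }
})

test_that("seascape writes and re-reads through text formats", {
  sc <- tiny_seascape()
  dir <- withr::local_tempdir()
  write_seascape(sc, dir)
  b <- read_ascii_grid(file.path(dir, "bathymetry.asc"))
  expect_equal(b$values, sc$bathymetry$values, tolerance = 1e-6)
  snd <- read_xyz(file.path(dir, "soundings.xyz"))
  expect_equal(nrow(snd), nrow(sc$soundings))
  pres <- utils::read.csv(file.path(dir, "presences.csv"))
  expect_equal(nrow(pres), nrow(sc$presences))
  polys <- read_polygons_geojson(file.path(dir, "polygons.geojson"))
  expect_equal(length(polys), length(sc$polygons))
})
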