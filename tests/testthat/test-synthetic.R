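test_that("species pool optima span the requested range and cover it", {
  rng <- list(mat = c(2, 12), map = c(400, 1200))
  pool <- make_species_pool(6, rng, seed = 31)
  expect_equal(nrow(pool), 6)
  # optima approximately evenly spaced across the range
  spacing <- diff(sort(pool$opt_mat))
  expect_true(all(abs(spacing - 2) < 0.5))
  expect_true(min(pool$opt_mat) < 3 && max(pool$opt_mat) > 11)

  # exhaustive grid along the gradient line: some species viable everywhere
  t_grid <- seq(0, 1, length.out = 201)
  for (t in t_grid) {
    cl <- c(mat = 2 + 10 * t, map = 1200 - 800 * t)
    expect_gte(max(viability(pool, pool$code, cl)), 0.5)
  }

  # same seed -> identical pool; generators are bit-reproducible
  expect_identical(make_species_pool(6, rng, seed = 31), pool)
  expect_error(make_species_pool(1, rng), "n_species",
               class = "standclim_validation_error")
})

test_that("landscape plots follow the elevation-climate gradient", {
  land <- make_landscape(100, seed = 11, reserved_frac = 0.34)
  inv <- land$inventory
  expect_length(inv$plots, 100)
  elev <- vapply(inv$plots, `[[`, numeric(1), "elevation")
  expect_true(all(elev >= 500 & elev <= 2000))

  # normals = base climate + gradient x (elevation - reference)
  expect_equal(land$normals[, "mat"],
               land$base_climate[["mat"]] +
                 land$gradient[["mat"]] * (elev - land$ref_elevation),
               ignore_attr = TRUE)
  expect_equal(land$normals[, "map"],
               land$base_climate[["map"]] +
                 land$gradient[["map"]] * (elev - land$ref_elevation),
               ignore_attr = TRUE)

  # every initial cohort is viable at its plot's normals
  for (i in seq_along(inv$plots)) {
    co <- inv$plots[[i]]$cohorts
    v <- viability(inv$species_pool, co$species, land$normals[i, ])
    expect_true(all(v >= 0.5))
  }

  # reserved fraction close to the requested 0.34 (3 binomial SE)
  n_res <- sum(vapply(inv$plots, `[[`, logical(1), "reserved"))
  expect_lt(abs(n_res / 100 - 0.34), 3 * sqrt(0.34 * 0.66 / 100))

  expect_identical(make_landscape(100, seed = 11, reserved_frac = 0.34)$normals,
                   land$normals)
  expect_error(make_landscape(10, elevation_range = c(1000, 1000)),
               "elevation range", class = "standclim_validation_error")
})

test_that("remeasurement generator reproduces its ground truth", {
  # all-zero probabilities: every record is class none
  none <- make_remeasurement_data(true_probs = c(harvest = 0, fire = 0,
                                                 stress = 0),
                                  n_plots = 50, seed = 2)
  expect_true(all(none$class == "none"))
  expect_true(all(none$prop_ba_killed == 0))

  # empirical fire proportion within 3 binomial SE of the truth
  p_fire <- 0.144
  big <- make_remeasurement_data(true_probs = c(harvest = 0.02,
                                                fire = p_fire,
                                                stress = 0.078),
                                 n_plots = 1e4, seed = 3)
  n_fire <- length(unique(big$plot_id[big$class == "fire"]))
  se <- sqrt(p_fire * (1 - p_fire) / 1e4)
  expect_lt(abs(n_fire / 1e4 - p_fire), 3 * se)

  # a harvest always removes trees: strictly positive magnitudes
  expect_true(all(big$prop_ba_killed[big$class == "harvest"] > 0))
  # fire and stress events can kill nothing
  expect_true(any(big$prop_ba_killed[big$class == "stress"] == 0))

  expect_identical(make_remeasurement_data(n_plots = 100, seed = 9),
                   make_remeasurement_data(n_plots = 100, seed = 9))
})

test_that("climate scenarios have the documented shapes", {
  land <- small_landscape(5)
  const <- make_climate_scenario(land$normals, shape = "constant")
  for (y in const$years) {
    expect_identical(climate_at(const, y), land$normals)
  }

  lin <- make_climate_scenario(land$normals, delta = c(mat = 3, map = 0),
                               shape = "linear")
  mid <- climate_at(lin, 2066)  # year 50 of 100
  expect_equal(mid[, "mat"], land$normals[, "mat"] + 1.5)
  expect_equal(climate_at(lin, 2116)[, "mat"], land$normals[, "mat"] + 3)

  logi <- make_climate_scenario(land$normals, delta = c(mat = 3, map = 0),
                                shape = "logistic")
  expect_equal(climate_at(logi, 2016), land$normals, ignore_attr = TRUE)
  expect_equal(climate_at(logi, 2116)[, "mat"], land$normals[, "mat"] + 3)
  # monotone in time for the warming metric
  path <- logi$values[1, , match("mat", logi$metrics)]
  expect_true(all(diff(path) >= 0))

  expect_error(make_climate_scenario(land$normals, shape = "quadratic"),
               "shape", class = "standclim_validation_error")
})
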