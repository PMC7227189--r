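test_that("viability follows the Gaussian niche form", {
  pool <- manual_pool()
  expect_equal(viability(pool, "AA", clim(5, 900)), 1)
  # one breadth from the optimum in one metric
  expect_equal(viability(pool, "AA", clim(5 + 1.5, 900)), exp(-0.5))
  expect_equal(viability(pool, "AA", clim(5, 900 + 300)), exp(-0.5))
  # symmetric about the optimum
  expect_equal(viability(pool, "AA", clim(5 - 2, 900)),
               viability(pool, "AA", clim(5 + 2, 900)))
  # product over metrics
  expect_equal(viability(pool, "AA", clim(6.5, 1200)), exp(-0.5) * exp(-0.5))
  expect_error(viability(pool, "AA", c(mat = 5)), "metric",
               class = "standclim_validation_error")
  expect_error(viability(pool, "ZZ", clim(5)), "unknown species",
               class = "standclim_validation_error")
})

test_that("envelope survival ramps linearly below the threshold", {
  expect_equal(envelope_survival_multiplier(0.8), 1)
  expect_equal(envelope_survival_multiplier(0), 0)
  expect_equal(envelope_survival_multiplier(0.25), 0.5)
  # nondecreasing in score, exactly 1 on [threshold, 1]
  s <- seq(0, 1, by = 0.01)
  m <- envelope_survival_multiplier(s)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m[s >= 0.5] == 1))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("effective carrying capacity is the BA-weighted viability share of base SDI", {
  pool <- manual_pool()          # both species base max SDI 800
  # climate at AA's optimum; BB placed so its viability is exactly 0.4
  z <- sqrt(-2 * log(0.4))
  pool$opt_mat[2] <- 5 + z * pool$br_mat[2]
  pool$opt_map[2] <- 900
  p <- fixture_plot(c("AA", "BB"),
                    c(density_for_ba(10, 30), density_for_ba(20, 30)),
                    c(30, 30), pool = pool)
  # weighted viability (10*1 + 20*0.4)/30 = 0.6
  expect_equal(effective_max_sdi(p, clim(5), pool), 0.6 * 800)

  # all viabilities 1 -> base; all ~0 -> floor x base
  pAA <- fixture_plot("AA", 300, 25, pool = pool)
  expect_equal(effective_max_sdi(pAA, clim(5), pool), 800)
  expect_equal(effective_max_sdi(pAA, clim(50), pool), 0.2 * 800)

  # bounds hold for arbitrary climates, including the empty plot
  empty <- stand_plot("E", 1000, cohorts = new_cohorts())
  for (mat in seq(-5, 20, by = 2.5)) {
    e1 <- effective_max_sdi(p, clim(mat), pool)
    expect_gte(e1, 0.2 * 800 - 1e-12)
    expect_lte(e1, 800 + 1e-12)
    e2 <- effective_max_sdi(empty, clim(mat), pool)
    expect_gte(e2, 0.2 * 800 - 1e-12)
    expect_lte(e2, 800 + 1e-12)
  }
})

test_that("elevation-window thresholds and trigger arithmetic are exact", {
  cfgs <- lapply(c(0.5, 1, 2), function(m) {
    dclim_config(gradient = c(mat = -0.0065, map = 0.5), multiplier = m)
  })
  # tau_mat = multiplier x 0.0065 x 450 = multiplier x 2.925
  expect_equal(cfgs[[2]]$tau[["mat"]], 2.925)
  expect_equal(cfgs[[1]]$tau[["mat"]], 1.4625)
  expect_equal(cfgs[[3]]$tau[["mat"]], 5.85)

  co <- new_cohorts("AA", 300, 25, 20, 2016,
                    ec = cbind(mat = 5, map = 900))
  # deltaMAT 3.0 trips the default window, 2.9 does not
  expect_true(dclim_triggered(co, clim(8.0), cfgs[[2]]))
  expect_false(dclim_triggered(co, clim(7.9), cfgs[[2]]))
  # cooling counts the same as warming (absolute change)
  expect_true(dclim_triggered(co, clim(2.0), cfgs[[2]]))
  # constant climate never triggers at any multiplier
  for (cfg in cfgs) expect_false(dclim_triggered(co, clim(5), cfg))

  off <- dclim_config(multiplier = "off")
  expect_true(off$off)
  expect_error(dclim_triggered(co, clim(8), off), "disabled",
               class = "standclim_validation_error")

  # "all" semantics requires every metric to exceed its window
  all_cfg <- dclim_config(gradient = c(mat = -0.0065, map = 0.5),
                          multiplier = 1, semantics = "all")
  expect_false(dclim_triggered(co, clim(8.0, 900), all_cfg))
  expect_true(dclim_triggered(co, clim(8.0, 900 + 230), all_cfg))
})

test_that("first trigger time is nonincreasing in rule severity", {
  co <- new_cohorts("AA", 300, 25, 20, 2016,
                    ec = cbind(mat = 5, map = 900))
  years <- seq(10, 100, by = 10)
  first_trigger <- function(mult) {
    cfg <- dclim_config(gradient = c(mat = -0.0065, map = 0),
                        multiplier = mult)
    hit <- vapply(years, function(t) {
      dclim_triggered(co, clim(5 + 3 * t / 100), cfg)
    }, logical(1))
    if (any(hit)) years[which(hit)[1]] else Inf
  }
  t05 <- first_trigger(0.5)
  t10 <- first_trigger(1)
  t20 <- first_trigger(2)
  expect_lte(t05, t10)
  expect_lte(t10, t20)
  expect_lt(t05, Inf)
})

test_that("establishment reset restores immunity until climate drifts again", {
  cfg <- dclim_config(gradient = c(mat = -0.0065, map = 0), multiplier = 1)
  co <- new_cohorts("AA", 300, 25, 20, 2016, ec = cbind(mat = 5, map = 900))
  warm <- clim(9)                     # +4.0 degC: beyond the window
  expect_true(dclim_triggered(co, warm, cfg))

  fresh <- reset_establishment(co, warm, 2076)
  expect_equal(fresh$estab_year, 2076)
  expect_false(dclim_triggered(fresh, warm, cfg))      # immune at planting
  # a further drift beyond the window from the NEW baseline retriggers
  expect_false(dclim_triggered(fresh, clim(9 + 2.9), cfg))
  expect_true(dclim_triggered(fresh, clim(9 + 3.0), cfg))
})

test_that("the same species can re-establish after an elevation-window kill", {
  pool <- manual_pool(codes = "AA", opt_mat = 9, br_mat = 3)
  cfg <- run_config(seed = 1)
  warm <- clim(9)
  p <- fixture_plot("AA", 100, 25, pool = pool, ec_mat = 5)
  dcfg <- dclim_config(gradient = c(mat = -0.0065, map = 0), multiplier = 1)
  trig <- dclim_triggered(p$cohorts, warm, dcfg)
  expect_true(all(trig))               # the old cohort dies...
  expect_gte(viability(pool, "AA", warm), 0.5)  # ...but remains viable
  replanted <- regenerate(stand_plot("T", 1000), warm, pool, cfg, 2076)
  expect_equal(replanted$cohorts$species, "AA")
  expect_false(any(dclim_triggered(replanted$cohorts, warm, dcfg)))
})
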