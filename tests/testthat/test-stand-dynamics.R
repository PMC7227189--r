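test_that("stand density index uses the 25.4 cm reference diameter", {
  pool <- manual_pool()
  empty <- stand_plot("E", 1000, cohorts = new_cohorts())
  expect_equal(stand_sdi(empty), 0)
  p <- fixture_plot("AA", 500, 25.4, pool = pool)
  expect_equal(stand_sdi(p), 500)
  # additivity: a two-cohort plot equals the sum of singleton plots
  p2 <- fixture_plot(c("AA", "BB"), c(300, 200), c(30, 18), pool = pool)
  pa <- fixture_plot("AA", 300, 30, pool = pool)
  pb <- fixture_plot("BB", 200, 18, pool = pool)
  expect_equal(stand_sdi(p2), stand_sdi(pa) + stand_sdi(pb))
})

test_that("growth saturates at maximum diameter and respects height caps", {
  pool <- manual_pool(max_dbh = 80, max_incr = 0.5, height_cap = 35)
  at_max <- fixture_plot("AA", 100, 80, pool = pool)
  g <- grow_cohorts(at_max, pool, sdi_ratio = 0)
  expect_equal(g$cohorts$dbh, 80)            # zero increment at max DBH

  # open-grown seedling: first-year increment equals the species maximum
  seed <- fixture_plot("AA", 100, 0, pool = pool)
  g1 <- grow_cohorts(seed, pool, sdi_ratio = 0, cycle_years = 1)
  expect_equal(g1$cohorts$dbh, 0.5)

  # height never exceeds the cap however long the tree grows
  p <- fixture_plot("AA", 100, 60, pool = pool)
  for (i in 1:10) p <- grow_cohorts(p, pool, sdi_ratio = 0)
  expect_lte(p$cohorts$height, 35)
  expect_gt(p$cohorts$dbh, 60)

  # competition slows growth monotonically
  free <- grow_cohorts(fixture_plot("AA", 100, 20, pool = pool), pool, 0)
  dense <- grow_cohorts(fixture_plot("AA", 100, 20, pool = pool), pool, 1)
  jammed <- grow_cohorts(fixture_plot("AA", 100, 20, pool = pool), pool, 2)
  expect_gt(free$cohorts$dbh, dense$cohorts$dbh)
  expect_gt(dense$cohorts$dbh, jammed$cohorts$dbh)
  expect_equal(jammed$cohorts$dbh, 20)   # ratio >= 1/0.7 stops growth
})

test_that("self-thinning trims the stand to the ceiling exactly", {
  pool <- manual_pool()
  p <- fixture_plot(c("AA", "BB"), c(400, 200), c(30, 20), pool = pool)
  sdi <- stand_sdi(p)

  # below the ceiling: nothing happens
  r <- density_mortality(p, eff_max_sdi = sdi / 0.5, year = 2026)
  expect_equal(r$plot$cohorts$density, p$cohorts$density)
  expect_equal(r$ba_killed, 0)

  # SDI at twice the ceiling: densities halve, snag BA gains the difference
  eff <- sdi / (2 * 0.85)
  r2 <- density_mortality(p, eff, year = 2026)
  expect_equal(r2$plot$cohorts$density, p$cohorts$density / 2)
  expect_equal(stand_sdi(r2$plot), 0.85 * eff, tolerance = 1e-9)
  ba_before <- sum(p$cohorts$density * (pi / 4) * (p$cohorts$dbh / 100)^2)
  snag_ba <- sum(r2$plot$snags$density * (pi / 4) *
                   (r2$plot$snags$dbh / 100)^2)
  expect_equal(snag_ba, ba_before / 2, tolerance = 1e-9)
  expect_equal(r2$ba_killed, ba_before / 2, tolerance = 1e-9)
})

test_that("stocking is linear in density and zero on empty plots", {
  pool <- manual_pool()
  empty <- stand_plot("E", 1000, cohorts = new_cohorts())
  expect_equal(stocking_percent(empty, 800), 0)
  p <- fixture_plot("AA", 200, 25.4, pool = pool)
  s1 <- stocking_percent(p, 800)
  expect_equal(s1, 100 * 200 / 800)
  p2 <- fixture_plot("AA", 400, 25.4, pool = pool)
  expect_equal(stocking_percent(p2, 800), 2 * s1)
  expect_error(stocking_percent(p, 0), "max SDI",
               class = "standclim_validation_error")
})

test_that("regeneration plants the best-suited species, up to four, never unsuited ones", {
  # six species, optima fanned around the site climate
  pool <- manual_pool(codes = sprintf("S%d", 1:6),
                      opt_mat = c(5, 5.5, 6, 6.5, 7, 12),
                      br_mat = rep(1.5, 6), opt_map = rep(900, 6),
                      br_map = rep(300, 6))
  cfg <- run_config(seed = 1)
  site <- clim(6)
  v <- viability(pool, pool$code, site)
  expect_equal(sum(v >= 0.5), 5)    # S6 is far outside its envelope

  p <- regenerate(stand_plot("T", 1000), site, pool, cfg, 2026)
  expect_equal(n_cohorts(p$cohorts), 4)                 # up to 4 of the 5
  expect_equal(sum(p$cohorts$density), 1235)            # total, split equally
  expect_equal(unique(p$cohorts$density), 1235 / 4)
  expect_equal(p$cohorts$dbh, rep(0.5, 4))
  expect_equal(p$cohorts$height, rep(1.37, 4))
  # the four highest-viability species, ties broken by code
  want <- pool$code[order(-v, pool$code)][1:4]
  expect_setequal(p$cohorts$species, want)
  expect_false("S6" %in% p$cohorts$species)

  # single viable species gets the whole planting density
  lonely <- manual_pool(codes = c("AA", "BB"), opt_mat = c(6, 20))
  p1 <- regenerate(stand_plot("T", 1000), site, lonely, cfg, 2026)
  expect_equal(p1$cohorts$species, "AA")
  expect_equal(p1$cohorts$density, 1235)

  # nothing viable: nothing planted
  nothing <- manual_pool(codes = c("AA", "BB"), opt_mat = c(30, 40))
  p0 <- regenerate(stand_plot("T", 1000), site, nothing, cfg, 2026)
  expect_equal(n_cohorts(p0$cohorts), 0)

  # property: across random climates, never > 4 species, never viability < 0.5
  big <- make_species_pool(10, list(mat = c(0, 15), map = c(300, 1300)),
                           seed = 8)
  for (mat in seq(0, 15, length.out = 12)) {
    site_i <- c(mat = mat, map = 1300 - 1000 * mat / 15)
    pi_ <- regenerate(stand_plot("T", 1000), site_i, big, cfg, 2026)
    expect_lte(n_cohorts(pi_$cohorts), 4)
    if (n_cohorts(pi_$cohorts) > 0) {
      expect_true(all(viability(big, pi_$cohorts$species, site_i) >= 0.5))
    }
  }
})

test_that("snag pools decay geometrically and empty cleanly", {
  p <- fixture_plot("AA", 100, 30)
  p <- apply_event(p, "fire", 1)$plot          # everything to snags
  d0 <- sum(p$snags$density)
  expect_equal(sum(age_snags(p, 1)$snags$density), d0)
  expect_equal(n_snags(age_snags(p, 0)$snags), 0)
  two <- age_snags(age_snags(p, 0.7), 0.7)
  expect_equal(sum(two$snags$density), d0 * 0.49)
  expect_error(age_snags(p, 1.2), "retention",
               class = "standclim_validation_error")
})

test_that("undisturbed constant-climate stands never lose carbon or breach height caps", {
  land <- make_landscape(10, seed = 21)
  inv <- land$inventory
  reg <- scale_regime(base_regime(), 0)
  cfg <- run_config(climate = "none", disturbance_multiplier = 1,
                    snag_retention = 1, seed = 4)
  traj <- make_climate_scenario(land$normals, shape = "constant")
  run <- run_simulation(inv, traj, reg, cfg, replicate = 1)
  expect_true(all(diff(run$carbon$total_C_Mg) >= -1e-9))
  # global sweep: no tree taller than its species cap at the end
  pool <- inv$species_pool
  for (p in run$final_plots) {
    if (n_cohorts(p$cohorts) == 0) next
    caps <- pool$height_cap[match(p$cohorts$species, pool$code)]
    expect_true(all(p$cohorts$height <= caps + 1e-12))
  }
})
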