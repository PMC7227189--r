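make_rem_table <- function(n_plots, fire_plots, fire_mags) {
  ids <- sprintf("P%04d", seq_len(n_plots))
  fire <- data.frame(plot_id = ids[seq_len(fire_plots)], class = "fire",
                     prop_ba_killed = fire_mags, reserved = FALSE,
                     stringsAsFactors = FALSE)
  quiet <- data.frame(plot_id = ids[-seq_len(fire_plots)], class = "none",
                      prop_ba_killed = 0, reserved = FALSE,
                      stringsAsFactors = FALSE)
  rbind(fire, quiet)
}

test_that("regime estimation matches the proportion-of-plots definition", {
  tab <- make_rem_table(1000, 144, rep(c(0.2, 0.5, 0.9), 48))
  reg <- estimate_regime(tab)
  expect_equal(reg$classes$fire$p, 0.144)
  expect_equal(reg$classes$harvest$p, 0)
  expect_equal(reg$n_remeasured, 1000)

  # a class with no events: p = 0 and magnitude distribution degenerate at 0
  expect_identical(reg$classes$harvest$magnitudes, 0)
  f <- stats::ecdf(reg$classes$harvest$magnitudes)
  expect_equal(f(0), 1)

  # ECDF at each observed magnitude equals rank / n (sort-and-count oracle)
  mags <- sort(tab$prop_ba_killed[tab$class == "fire"])
  f_fire <- stats::ecdf(reg$classes$fire$magnitudes)
  for (m in unique(mags)) {
    expect_equal(f_fire(m), sum(mags <= m) / length(mags))
  }

  # invariant to record order
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(estimate_regime(shuffled)$classes$fire$magnitudes,
               reg$classes$fire$magnitudes)

  expect_error(estimate_regime(tab[0, ]), "empty",
               class = "standclim_validation_error")
})

test_that("probability scaling caps at one and leaves magnitudes alone", {
  tab <- make_rem_table(1000, 600, stats::runif(600))
  reg <- estimate_regime(tab)
  expect_equal(reg$classes$fire$p, 0.6)

  z <- scale_regime(reg, 0)
  expect_true(all(vapply(z$classes, `[[`, numeric(1), "p") == 0))
  expect_equal(scale_regime(reg, 2)$classes$fire$p, 1)      # capped
  expect_equal(scale_regime(reg, 1), reg)                    # identity
  expect_identical(scale_regime(reg, 0.5)$classes$fire$magnitudes,
                   reg$classes$fire$magnitudes)
  expect_error(scale_regime(reg, -1), "non-negative",
               class = "standclim_validation_error")
  # halving a typical harvest probability
  h <- reg; h$classes$harvest$p <- 0.132
  expect_equal(scale_regime(h, 0.5)$classes$harvest$p, 0.066)
})

test_that("cycle event sampling honours probabilities and reservation", {
  reg <- base_regime()
  open_plot <- fixture_plot("AA", 300, 25)
  reserved_plot <- fixture_plot("AA", 300, 25, reserved = TRUE)

  set.seed(1)
  ev <- replicate(1e4, any(sample_cycle_events(reg, reserved_plot)$class ==
                             "harvest"))
  expect_equal(sum(ev), 0)  # reserved: never harvested

  z <- scale_regime(reg, 0)
  set.seed(2)
  for (i in 1:50) expect_equal(nrow(sample_cycle_events(z, open_plot)), 0)

  # Bernoulli frequency check at p = 0.25
  reg25 <- reg
  reg25$classes$fire$p <- 0.25
  set.seed(3)
  hits <- vapply(seq_len(1e4), function(i) {
    "fire" %in% sample_cycle_events(reg25, open_plot)$class
  }, logical(1))
  se <- sqrt(0.25 * 0.75 / 1e4)
  expect_lt(abs(mean(hits) - 0.25), 3 * se)
})

test_that("event application conserves basal area and routes it by class", {
  pool <- manual_pool()
  # live BA exactly 30 m^2/ha in two cohorts (20 + 10)
  p <- fixture_plot(c("AA", "BB"), c(density_for_ba(20, 30),
                                     density_for_ba(10, 25)),
                    c(30, 25), pool = pool)
  expect_equal(plot_carbon(p, pool, "snag"), 0)
  ba0 <- sum(p$cohorts$density * (pi / 4) * (p$cohorts$dbh / 100)^2)
  expect_equal(ba0, 30)

  # m = 0: legal no-op for fire/stress
  r0 <- apply_event(p, "fire", 0)
  expect_equal(r0$plot$cohorts$density, p$cohorts$density)
  expect_equal(r0$ba_killed, 0)

  # m = 0.4 stress: live 18, snags gain 12
  r <- apply_event(p, "stress", 0.4)
  live_ba <- sum(r$plot$cohorts$density * (pi / 4) *
                   (r$plot$cohorts$dbh / 100)^2)
  snag_ba <- sum(r$plot$snags$density * (pi / 4) *
                   (r$plot$snags$dbh / 100)^2)
  expect_equal(live_ba, 18)
  expect_equal(snag_ba, 12)
  expect_equal(r$ba_killed, 12)

  # m = 0.4 harvest: removed, not transferred
  rh <- apply_event(p, "harvest", 0.4)
  expect_equal(n_snags(rh$plot$snags), 0)
  expect_equal(sum(rh$plot$cohorts$density * (pi / 4) *
                     (rh$plot$cohorts$dbh / 100)^2), 18)

  # m = 1 fire empties the live tree list and moves all BA to snags
  r1 <- apply_event(p, "fire", 1)
  expect_equal(n_cohorts(r1$plot$cohorts), 0)
  expect_equal(sum(r1$plot$snags$density * (pi / 4) *
                     (r1$plot$snags$dbh / 100)^2), 30)

  expect_error(apply_event(p, "fire", 1.2), "magnitude",
               class = "standclim_validation_error")
  expect_error(apply_event(p, "windthrow", 0.5), "class",
               class = "standclim_validation_error")
})

test_that("inverse-transform magnitudes reproduce the source distribution", {
  reg <- base_regime()
  mags <- reg$classes$stress$magnitudes
  set.seed(42)
  u <- stats::runif(5000)
  draws <- vapply(u, function(ui) {
    mags[pmin(length(mags), pmax(1L, ceiling(ui * length(mags))))]
  }, numeric(1))
  f_src <- stats::ecdf(mags)
  f_smp <- stats::ecdf(draws)
  support <- sort(unique(c(mags, draws)))
  ks <- max(abs(f_src(support) - f_smp(support)))
  expect_lt(ks, 0.05)
})
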