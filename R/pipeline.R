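# Scenario orchestration: the per-cycle update loop, single-cell
# simulations, the factorial sensitivity experiment, and end-of-run ratio
# summaries.

#' Advance one plot through one projection cycle
#'
#' Fixed step order: (1) the caller supplies the cycle's climate; (2)
#' elevation-window (dClim) mortality, skipped when the rule is off; (3)
#' viability-envelope mortality; (4) disturbance events are sampled and
#' applied; (5) cohorts grow against the cycle-start density ratio; (6)
#' density-dependent mortality trims the stand to the effective carrying
#' capacity; (7) regeneration if stocking fell below the threshold; (8) the
#' snag pool decays. The order is fixed (not configurable) so that results
#' are reproducible and regeneration always sees post-mortality stocking.
#'
#' Exactly six uniform draws are consumed per call (by the disturbance
#' step), keeping random-number streams aligned across scenario cells.
#'
#' @param plot a [stand_plot()].
#' @param climate_now named climate-metric vector for this cycle.
#' @param regime a (already multiplier-scaled) `disturbance_regime`.
#' @param dclim_cfg a [dclim_config()].
#' @param pool species-parameter table.
#' @param config a [run_config()].
#' @param year calendar year at the end of the cycle.
#' @param u optional vector of six uniforms (testing hook).
#' @return list: `plot` (updated) and `attribution`, a named vector of live
#'   basal area (m^2/ha) killed by cause (envelope, dclim, density, harvest,
#'   fire, stress).
#' @export
run_cycle <- function(plot, climate_now, regime, dclim_cfg, pool, config,
                      year, u = NULL) {
  att <- c(envelope = 0, dclim = 0, density = 0,
           harvest = 0, fire = 0, stress = 0)
  co <- plot$cohorts

  # (2) elevation-window mortality: triggered cohorts die whole
  if (!dclim_cfg$off && n_cohorts(co) > 0) {
    trig <- dclim_triggered(co, climate_now, dclim_cfg)
    if (any(trig)) {
      killed <- co$density * trig
      att[["dclim"]] <- sum(killed * (pi / 4) * (co$dbh / 100)^2)
      plot <- transfer_to_snags(plot, killed, year)
      plot$cohorts <- cohorts_subset(plot$cohorts, !trig)
      co <- plot$cohorts
    }
  }

  # (3) envelope mortality: linear density ramp below the viability threshold
  if (n_cohorts(co) > 0) {
    v <- viability(pool, co$species, climate_now)
    s <- envelope_survival_multiplier(v, config$viability_threshold)
    if (any(s < 1)) {
      killed <- co$density * (1 - s)
      att[["envelope"]] <- sum(killed * (pi / 4) * (co$dbh / 100)^2)
      plot <- transfer_to_snags(plot, killed, year)
      co <- plot$cohorts
      co$density <- co$density * s
      keep <- co$density > 1e-12
      if (!all(keep)) co <- cohorts_subset(co, keep)
      plot$cohorts <- co
    }
  }

  # (4) stochastic disturbance (same draw discipline as
  # sample_cycle_events, without the per-call table construction)
  if (is.null(u)) u <- stats::runif(6)
  for (i in seq_along(DISTURBANCE_CLASSES)) {
    cl <- DISTURBANCE_CLASSES[i]
    p <- regime$classes[[cl]]$p
    if (cl == "harvest" && plot$reserved) p <- 0
    if (u[2 * i - 1] < p) {
      m <- ecdf_quantile(regime$classes[[cl]]$magnitudes, u[2 * i])
      res <- apply_event(plot, cl, m, year)
      plot <- res$plot
      att[[cl]] <- att[[cl]] + res$ba_killed
    }
  }

  # carrying capacity under this cycle's climate
  eff <- effective_max_sdi(plot, climate_now, pool, config$sdi_floor)

  # (5) growth
  plot <- grow_cohorts(plot, pool, stand_sdi(plot) / eff, config$cycle_years)

  # (6) density-dependent mortality
  dm <- density_mortality(plot, eff, year, config$selfthin_fraction)
  plot <- dm$plot
  att[["density"]] <- dm$ba_killed

  # (7) regeneration
  if (stocking_percent(plot, eff) < config$stocking_threshold) {
    plot <- regenerate(plot, climate_now, pool, config, year)
  }

  # (8) snag decay
  plot <- age_snags(plot, config$snag_retention)

  list(plot = plot, attribution = att)
}

# Replicate seed scheme: master seed plus a fixed odd stride per replicate;
# with common random numbers the cell index does not enter, so every cell
# sharing a replicate index sees the same disturbance draw stream.
replicate_seed <- function(master_seed, replicate, cell_index = 0,
                           crn = TRUE) {
  s <- as.double(master_seed) + 1009 * as.double(replicate)
  if (!crn) s <- s + 1000003 * as.double(cell_index)
  as.integer(s %% 2147483647)
}

#' Run one simulation (one factorial cell, one replicate)
#'
#' Applies [run_cycle()] to every plot over the full horizon and records a
#' forest-level carbon and composition report at every cycle boundary,
#' including year 0. Initial cohorts take the plot's climate normals as
#' their establishment climate.
#'
#' @param inventory a [forest_inventory()].
#' @param trajectory a [climate_trajectory()] covering
#'   `origin_year .. origin_year + horizon`.
#' @param regime an unscaled `disturbance_regime`; the configuration's
#'   disturbance multiplier is applied here.
#' @param config a [run_config()] describing this cell.
#' @param replicate replicate index (labels the output rows).
#' @param seed RNG seed for this replicate; derived from the master seed
#'   when `NULL`.
#' @return list of data frames `carbon`, `composition`, `attribution`, plus
#'   `final_plots` (the plot list at the end of the run).
#' @export
run_simulation <- function(inventory, trajectory, regime, config,
                           replicate = 1, seed = NULL) {
  origin <- inventory$origin_year
  years <- seq(origin, origin + config$horizon, by = config$cycle_years)
  if (!all(years %in% trajectory$years)) {
    sc_stop("standclim_validation_error",
            "climate trajectory does not cover the full horizon %d..%d",
            origin, origin + config$horizon)
  }
  if (is.null(seed)) seed <- replicate_seed(config$seed, replicate)
  pool <- inventory$species_pool
  metrics <- attr(pool, "metrics")
  regime <- scale_regime(regime, config$disturbance_multiplier)
  dclim_cfg <- dclim_config(config$gradient, config$dclim_multiplier,
                            config$dclim_rise, config$dclim_drop,
                            config$dclim_semantics)

  plots <- inventory$plots
  norm_idx <- match(vapply(plots, `[[`, character(1), "id"),
                    trajectory$plot_ids)
  if (anyNA(norm_idx)) {
    sc_stop("standclim_validation_error",
            "climate trajectory lacks plots: %s",
            paste(vapply(plots, `[[`, character(1), "id")[is.na(norm_idx)],
                  collapse = ", "))
  }
  # initial cohorts: establishment climate defaults to the plot normals
  for (i in seq_along(plots)) {
    ec <- plots[[i]]$cohorts$ec
    if (anyNA(ec)) {
      nr <- trajectory$normals[norm_idx[i], metrics]
      fill <- matrix(nr, nrow(ec), length(metrics), byrow = TRUE,
                     dimnames = list(NULL, metrics))
      ec[is.na(ec)] <- fill[is.na(ec)]
      plots[[i]]$cohorts$ec <- ec
    }
  }

  set.seed(seed)
  lab <- function(df) {
    cbind(data.frame(scenario = config$climate,
                     dclim = as.character(config$dclim_multiplier),
                     disturbance = config$disturbance_multiplier,
                     replicate = replicate, stringsAsFactors = FALSE),
          df, stringsAsFactors = FALSE)
  }
  report <- function(year) {
    tot <- totals_over_plots(plots, pool, year)
    list(carbon = data.frame(year = year,
                             live_C_Mg = tot$total_live_C_Mg,
                             snag_C_Mg = tot$total_snag_C_Mg,
                             total_C_Mg = tot$total_C_Mg),
         composition = data.frame(year = year, species = pool$code,
                                  ba_m2 = as.numeric(tot$species_ba_m2),
                                  prop = as.numeric(tot$species_prop),
                                  stringsAsFactors = FALSE))
  }
  n_cycles <- config$horizon %/% config$cycle_years
  carbon <- vector("list", n_cycles + 1)
  compo <- vector("list", n_cycles + 1)
  attribution <- vector("list", n_cycles)
  r0 <- report(origin)
  carbon[[1]] <- r0$carbon
  compo[[1]] <- r0$composition
  for (cyc in seq_len(n_cycles)) {
    year <- origin + cyc * config$cycle_years
    clim <- climate_at(trajectory, year)
    att_forest <- c(envelope = 0, dclim = 0, density = 0,
                    harvest = 0, fire = 0, stress = 0)
    for (i in seq_along(plots)) {
      step <- run_cycle(plots[[i]], clim[norm_idx[i], ], regime, dclim_cfg,
                        pool, config, year)
      plots[[i]] <- step$plot
      att_forest <- att_forest + step$attribution * plots[[i]]$expansion
    }
    rr <- report(year)
    carbon[[cyc + 1]] <- rr$carbon
    compo[[cyc + 1]] <- rr$composition
    attribution[[cyc]] <- data.frame(year = year, cause = names(att_forest),
                                     ba_killed_m2 = as.numeric(att_forest),
                                     stringsAsFactors = FALSE)
  }
  list(carbon = lab(do.call(rbind, carbon)),
       composition = lab(do.call(rbind, compo)),
       attribution = lab(do.call(rbind, attribution)),
       final_plots = plots)
}

#' Run the factorial sensitivity experiment
#'
#' Crosses climate scenario (none, warming) with elevation-window-rule
#' multiplier (off, 2, 1, 0.5) and disturbance multiplier (0, 0.5, 1, 2),
#' with `n_replicates` replicates per cell: the default grid is 2 x 4 x 4 x
#' 10 = 320 simulation runs. With common random numbers (the default) every
#' cell sharing a replicate index uses the same disturbance draw stream, so
#' cells can be compared pairwise without replicate noise; set `crn = FALSE`
#' in the configuration for fully independent runs.
#'
#' @param inventory a [forest_inventory()].
#' @param normals plot-by-metric matrix of 1960-1990 climate normals with
#'   plot-id rownames (e.g. from [make_landscape()]).
#' @param regime a `disturbance_regime` at its base (unscaled) level.
#' @param config a [run_config()]; its `climate`, `dclim_multiplier` and
#'   `disturbance_multiplier` fields are overridden by the grid.
#' @param climate_levels,dclim_levels,disturbance_levels factor levels of
#'   the experiment.
#' @param verbose print a line per cell.
#' @return an object of class `scenario_result`: long data frames `carbon`,
#'   `composition`, `attribution` over all cells and replicates.
#' @export
run_factorial <- function(inventory, normals, regime, config = run_config(),
                          climate_levels = c("none", "warming"),
                          dclim_levels = list("off", 2, 1, 0.5),
                          disturbance_levels = c(0, 0.5, 1, 2),
                          verbose = FALSE) {
  origin <- inventory$origin_year
  traj <- list(
    none = make_climate_scenario(normals, origin, config$horizon,
                                 config$cycle_years, shape = "constant"),
    warming = make_climate_scenario(normals, origin, config$horizon,
                                    config$cycle_years, delta = config$delta,
                                    shape = config$warming_shape))
  carbon <- list()
  compo <- list()
  attrib <- list()
  cell <- 0
  for (cl in climate_levels) {
    for (dc in dclim_levels) {
      for (ds in disturbance_levels) {
        cell <- cell + 1
        cfg <- config
        cfg$climate <- cl
        cfg$dclim_multiplier <- dc
        cfg$disturbance_multiplier <- ds
        if (verbose) {
          message(sprintf("cell %d: climate=%s dClim=%s disturbance=x%s",
                          cell, cl, as.character(dc), as.character(ds)))
        }
        for (rep in seq_len(config$n_replicates)) {
          s <- replicate_seed(config$seed, rep, cell, config$crn)
          run <- run_simulation(inventory, traj[[cl]], regime, cfg,
                                replicate = rep, seed = s)
          key <- sprintf("%d_%d", cell, rep)
          carbon[[key]] <- run$carbon
          compo[[key]] <- run$composition
          attrib[[key]] <- run$attribution
        }
      }
    }
  }
  structure(list(carbon = do.call(rbind, c(carbon, make.row.names = FALSE)),
                 composition = do.call(rbind, c(compo, make.row.names = FALSE)),
                 attribution = do.call(rbind, c(attrib, make.row.names = FALSE)),
                 levels = list(climate = climate_levels,
                               dclim = vapply(dclim_levels, as.character,
                                              character(1)),
                               disturbance = disturbance_levels),
                 config = config),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cb <- x$carbon
  cat(sprintf(
    "scenario_result: %d runs (%d scenario cells x %d replicates), years %d..%d\n",
    nrow(unique(cb[c("scenario", "dclim", "disturbance", "replicate")])),
    nrow(unique(cb[c("scenario", "dclim", "disturbance")])),
    max(cb$replicate), min(cb$year), max(cb$year)))
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, ...) {
  cb <- object$carbon
  end <- cb[cb$year == max(cb$year), , drop = FALSE]
  agg <- stats::aggregate(total_C_Mg ~ scenario + dclim + disturbance,
                          data = end, FUN = mean)
  names(agg)[names(agg) == "total_C_Mg"] <- "mean_end_C_Mg"
  start <- cb[cb$year == min(cb$year), , drop = FALSE]
  agg$mean_start_C_Mg <- stats::aggregate(
    total_C_Mg ~ scenario + dclim + disturbance, data = start,
    FUN = mean)$total_C_Mg
  agg$change_pct <- 100 * (agg$mean_end_C_Mg / agg$mean_start_C_Mg - 1)
  agg[order(agg$scenario, agg$dclim, agg$disturbance), ]
}

#' Plot mean carbon trajectories of a scenario experiment
#'
#' One line per (scenario, dClim level) at a chosen disturbance level;
#' replicate means.
#'
#' @param x a `scenario_result`.
#' @param disturbance_level which disturbance multiplier to display.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scenario_result <- function(x, disturbance_level = 1, ...) {
  cb <- x$carbon[x$carbon$disturbance == disturbance_level, , drop = FALSE]
  agg <- stats::aggregate(total_C_Mg ~ scenario + dclim + year, data = cb,
                          FUN = mean)
  cells <- unique(agg[c("scenario", "dclim")])
  years <- sort(unique(agg$year))
  m <- sapply(seq_len(nrow(cells)), function(i) {
    sub <- agg[agg$scenario == cells$scenario[i] &
                 agg$dclim == cells$dclim[i], ]
    sub$total_C_Mg[match(years, sub$year)]
  })
  graphics::matplot(years, m / 1e6, type = "l", lty = 1 + (cells$scenario == "none"),
                    col = seq_len(nrow(cells)), xlab = "Year",
                    ylab = "Total aboveground C (Tg)", ...)
  graphics::legend("bottomleft",
                   legend = sprintf("%s, dClim %s", cells$scenario,
                                    cells$dclim),
                   col = seq_len(nrow(cells)),
                   lty = 1 + (cells$scenario == "none"), cex = 0.7,
                   bty = "n")
  invisible(x)
}

#' End-of-run carbon ratios against the default cell
#'
#' For every (scenario, dClim, disturbance) cell, the replicate-mean
#' end-of-horizon total carbon divided by the same-scenario reference cell
#' mean (default reference: dClim 1, base disturbance). The reference row
#' has ratio exactly 1.
#'
#' @param result a `scenario_result`.
#' @param reference list with elements `dclim` (character) and `disturbance`
#'   (numeric) naming the reference cell.
#' @return data frame with one row per cell and a `ratio` column.
#' @export
summarize_ratios <- function(result,
                             reference = list(dclim = "1", disturbance = 1)) {
  cb <- result$carbon
  end <- cb[cb$year == max(cb$year), , drop = FALSE]
  agg <- stats::aggregate(total_C_Mg ~ scenario + dclim + disturbance,
                          data = end, FUN = mean)
  out <- list()
  for (sc in unique(agg$scenario)) {
    sub <- agg[agg$scenario == sc, , drop = FALSE]
    ref <- sub$total_C_Mg[sub$dclim == reference$dclim &
                            sub$disturbance == reference$disturbance]
    if (length(ref) != 1) {
      sc_stop("standclim_validation_error",
              "reference cell (dClim %s, disturbance %s) missing for scenario %s",
              reference$dclim, reference$disturbance, sc)
    }
    sub$ratio <- if (ref > 0) sub$total_C_Mg / ref else
      as.numeric(sub$total_C_Mg == ref)
    out[[sc]] <- sub
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  names(res)[names(res) == "total_C_Mg"] <- "mean_end_C_Mg"
  res
}
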