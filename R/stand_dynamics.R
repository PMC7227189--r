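# Cohort growth, density-dependent mortality against the effective carrying
# capacity, regeneration of understocked plots, and snag aging.

# Basal area per cohort, m^2/ha.
cohort_ba <- function(cohorts) {
  cohorts$density * (pi / 4) * (cohorts$dbh / 100)^2
}

# Live basal area of a plot, m^2/ha.
plot_live_ba <- function(plot) sum(cohort_ba(plot$cohorts))

snag_ba <- function(plot) {
  sn <- plot$snags
  sum(sn$density * (pi / 4) * (sn$dbh / 100)^2)
}

#' Stand density index of a plot
#'
#' Summation-form Reineke SDI: `sum(density * (dbh / 25.4)^1.605)` over live
#' cohorts. A stand of 500 trees/ha at the 25.4 cm reference diameter has
#' SDI 500. SDI is linear in cohort density, so proportional thinning scales
#' it exactly.
#'
#' @param plot a [stand_plot()].
#' @return SDI in trees/ha at the reference diameter.
#' @export
stand_sdi <- function(plot) {
  co <- plot$cohorts
  sum(co$density * (co$dbh / 25.4)^1.605)
}

# Height-diameter curve: saturating toward the species height cap.
height_from_dbh <- function(dbh, hd_k, height_cap) {
  pmin(height_cap, 1.37 + (height_cap - 1.37) * (1 - exp(-hd_k * dbh)))
}

#' Grow the cohorts of a plot for one cycle
#'
#' Annual diameter increment is `max_incr * (1 - dbh / max_dbh) *
#' max(0, 1 - 0.7 * sdi_ratio)`, clipped at zero and applied `cycle_years`
#' times with the density ratio held at its cycle-start value. Height follows
#' a saturating height-diameter curve and is hard-capped at the species
#' height cap, so no simulated tree grows taller than the tallest tree
#' plausibly observed for its species.
#'
#' @param plot a [stand_plot()].
#' @param pool species-parameter table.
#' @param sdi_ratio stand SDI / effective maximum SDI at cycle start.
#' @param cycle_years years per cycle.
#' @return the plot with updated diameters and heights.
#' @export
grow_cohorts <- function(plot, pool, sdi_ratio, cycle_years = 10) {
  co <- plot$cohorts
  if (n_cohorts(co) == 0) return(plot)
  idx <- match(co$species, pool$code)
  max_incr <- pool$max_incr[idx]
  max_dbh <- pool$max_dbh[idx]
  comp <- max(0, 1 - 0.7 * sdi_ratio)
  dbh <- co$dbh
  for (y in seq_len(cycle_years)) {
    inc <- max_incr * (1 - dbh / max_dbh) * comp
    inc[inc < 0] <- 0
    dbh <- dbh + inc
  }
  co$dbh <- dbh
  co$height <- height_from_dbh(dbh, pool$hd_k[idx], pool$height_cap[idx])
  plot$cohorts <- co
  plot
}

#' Density-dependent (self-thinning) mortality
#'
#' When stand SDI exceeds `selfthin_fraction` of the effective maximum SDI,
#' every cohort's density is scaled by the single factor that brings SDI to
#' exactly that ceiling; the killed density moves to the snag pool. Because
#' SDI is linear in density the postcondition is exact.
#'
#' @param plot a [stand_plot()].
#' @param eff_max_sdi effective maximum SDI (see [effective_max_sdi()]).
#' @param year calendar year recorded on new snags.
#' @param selfthin_fraction mortality ceiling as a fraction of `eff_max_sdi`.
#' @return list with elements `plot` and `ba_killed` (m^2/ha moved to snags).
#' @export
density_mortality <- function(plot, eff_max_sdi, year,
                              selfthin_fraction = 0.85) {
  if (eff_max_sdi <= 0) {
    sc_stop("standclim_validation_error", "effective max SDI must be > 0")
  }
  sdi <- stand_sdi(plot)
  cap <- selfthin_fraction * eff_max_sdi
  if (sdi <= cap || sdi == 0) {
    return(list(plot = plot, ba_killed = 0))
  }
  f <- cap / sdi
  co <- plot$cohorts
  killed <- co$density * (1 - f)
  plot <- transfer_to_snags(plot, killed, year)
  co$density <- co$density * f
  plot$cohorts <- co
  list(plot = plot, ba_killed = sum(killed * (pi / 4) * (co$dbh / 100)^2))
}

#' Stocking percentage of a plot
#'
#' Stocking is measured as stand SDI relative to the effective maximum SDI,
#' in percent. Regeneration triggers strictly below the 40% default
#' threshold.
#'
#' @param plot a [stand_plot()].
#' @param eff_max_sdi effective maximum SDI; must be positive.
#' @return stocking in percent.
#' @export
stocking_percent <- function(plot, eff_max_sdi) {
  if (eff_max_sdi <= 0) {
    sc_stop("standclim_validation_error", "effective max SDI must be > 0")
  }
  100 * stand_sdi(plot) / eff_max_sdi
}

#' Regenerate an understocked plot
#'
#' Plants up to `max_regen_species` species with viability at or above the
#' threshold under the current climate, highest scores first (ties broken by
#' species code), splitting the total planting density equally among the
#' selected species. Seedlings take the configured planting dimensions and
#' record the current climate as their establishment climate, which makes
#' them immune to elevation-window mortality until climate drifts beyond the
#' window again. Any pool species may establish -- no seed source is
#' required, so species can migrate into a plot as climate changes. If no
#' species is viable, nothing is planted.
#'
#' @param plot a [stand_plot()].
#' @param climate_now named climate-metric vector.
#' @param pool species-parameter table.
#' @param config a [run_config()] (regeneration fields are read from it).
#' @param year planting calendar year.
#' @return the plot, possibly with new seedling cohorts.
#' @export
regenerate <- function(plot, climate_now, pool, config, year) {
  v <- viability(pool, pool$code, climate_now)
  ok <- v >= config$viability_threshold
  if (!any(ok)) return(plot)
  cand <- data.frame(code = pool$code[ok], v = v[ok],
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$v, cand$code), , drop = FALSE]
  chosen <- utils::head(cand$code, config$max_regen_species)
  per_species <- config$planting_density / length(chosen)
  metrics <- colnames(plot$cohorts$ec)
  seedlings <- new_cohorts(species = chosen,
                           density = rep(per_species, length(chosen)),
                           dbh = rep(config$seedling_dbh, length(chosen)),
                           height = rep(config$seedling_height, length(chosen)),
                           estab_year = rep(year, length(chosen)),
                           metrics = metrics)
  seedlings <- reset_establishment(seedlings, climate_now, year)
  plot$cohorts <- cohorts_bind(plot$cohorts, seedlings)
  plot
}

#' Age the snag pool for one cycle
#'
#' Standing dead trees fall over time: each snag record's density is
#' multiplied by the per-cycle retention fraction and records that reach zero
#' density are dropped. Snag dimensions never change after death.
#'
#' @param plot a [stand_plot()].
#' @param retention fraction in \[0, 1\] of snag density retained per cycle.
#' @return the plot with a decayed snag pool.
#' @export
age_snags <- function(plot, retention) {
  if (retention < 0 || retention > 1) {
    sc_stop("standclim_validation_error", "snag retention must be in [0, 1]")
  }
  sn <- plot$snags
  sn$density <- sn$density * retention
  keep <- sn$density > 1e-12
  if (!all(keep)) {
    sn <- structure(list(species = sn$species[keep],
                         density = sn$density[keep],
                         dbh = sn$dbh[keep], height = sn$height[keep],
                         death_year = sn$death_year[keep]),
                    class = "snag_table")
  }
  plot$snags <- sn
  plot
}
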