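# Aboveground carbon accounting: per tree, per plot, and expanded to forest
# totals, plus species basal-area composition.

#' Aboveground carbon of a single tree
#'
#' Stem volume from a form-factor cylinder model, `form_factor * (pi/4) *
#' (dbh/100)^2 * height` (m^3); aboveground biomass as volume times wood
#' density times a species crown expansion factor accounting for branches
#' and foliage; carbon as half of dry biomass.
#'
#' @param dbh diameter at breast height (cm), vectorised.
#' @param height total height (m).
#' @param species species code(s), recycled against `dbh`.
#' @param pool species-parameter table supplying wood density, form factor
#'   and crown expansion factor.
#' @return kg carbon per tree.
#' @export
tree_carbon <- function(dbh, height, species, pool) {
  if (any(dbh < 0) || any(height < 0)) {
    sc_stop("standclim_validation_error",
            "dbh and height must be non-negative")
  }
  idx <- match(species, pool$code)
  if (anyNA(idx)) {
    sc_stop("standclim_validation_error", "unknown species codes: %s",
            paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  vol <- pool$form_factor[idx] * (pi / 4) * (dbh / 100)^2 * height
  0.5 * vol * pool$wood_density[idx] * pool$crown_factor[idx]
}

#' Aboveground carbon of a plot
#'
#' Sums `density * tree carbon` over the requested pools. Snag carbon uses
#' each snag's dimensions at death.
#'
#' @param plot a [stand_plot()].
#' @param pool species-parameter table.
#' @param which `"live"`, `"snag"`, or `"both"`.
#' @return Mg carbon per hectare.
#' @export
plot_carbon <- function(plot, pool, which = "both") {
  if (!which %in% c("live", "snag", "both")) {
    sc_stop("standclim_validation_error",
            "carbon pool must be live, snag, or both")
  }
  total <- 0
  if (which %in% c("live", "both")) {
    co <- plot$cohorts
    if (n_cohorts(co) > 0) {
      total <- total +
        sum(co$density * tree_carbon(co$dbh, co$height, co$species, pool))
    }
  }
  if (which %in% c("snag", "both")) {
    sn <- plot$snags
    if (n_snags(sn) > 0) {
      total <- total +
        sum(sn$density * tree_carbon(sn$dbh, sn$height, sn$species, pool))
    }
  }
  total / 1000
}

# Forest totals over a plain list of plots (internal pipeline path).
totals_over_plots <- function(plots, pool, year) {
  n <- length(plots)
  live <- numeric(n)
  snag <- numeric(n)
  ids <- character(n)
  sp_ba <- numeric(nrow(pool))
  names(sp_ba) <- pool$code
  total_live <- 0
  total_snag <- 0
  for (i in seq_len(n)) {
    p <- plots[[i]]
    ids[i] <- p$id
    live[i] <- plot_carbon(p, pool, "live")
    snag[i] <- plot_carbon(p, pool, "snag")
    total_live <- total_live + live[i] * p$expansion
    total_snag <- total_snag + snag[i] * p$expansion
    co <- p$cohorts
    if (n_cohorts(co) > 0) {
      ba <- cohort_ba(co) * p$expansion
      add <- tapply(ba, factor(co$species, levels = pool$code), sum,
                    default = 0)
      sp_ba <- sp_ba + as.numeric(add)
    }
  }
  tot_ba <- sum(sp_ba)
  structure(list(year = year,
                 plot_table = data.frame(plot_id = ids, live_C_Mg_ha = live,
                                         snag_C_Mg_ha = snag,
                                         stringsAsFactors = FALSE),
                 total_live_C_Mg = total_live,
                 total_snag_C_Mg = total_snag,
                 total_C_Mg = total_live + total_snag,
                 species_ba_m2 = sp_ba,
                 species_prop = if (tot_ba > 0) sp_ba / tot_ba else sp_ba),
            class = "carbon_report")
}

#' Forest-level carbon and composition report
#'
#' Expands plot-level carbon to forest totals by the plot expansion factors
#' and computes species basal-area totals and proportions the same way.
#'
#' @param inventory a [forest_inventory()].
#' @param year calendar year to stamp on the report.
#' @return an object of class `carbon_report`: per-plot carbon densities,
#'   forest totals (Mg), species basal area (m^2) and proportions.
#' @export
forest_totals <- function(inventory, year = inventory$origin_year) {
  totals_over_plots(inventory$plots, inventory$species_pool, year)
}

#' @export
print.carbon_report <- function(x, ...) {
  cat(sprintf("carbon_report @ %s: total %.0f Mg (live %.0f, snag %.0f) over %d plots\n",
              x$year, x$total_C_Mg, x$total_live_C_Mg, x$total_snag_C_Mg,
              nrow(x$plot_table)))
  top <- sort(x$species_prop, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("  composition (BA share):",
        paste(sprintf("%s %.0f%%", names(top)[seq_len(min(4, length(top)))],
                      100 * top[seq_len(min(4, length(top)))]),
              collapse = ", "), "\n")
  }
  invisible(x)
}
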