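# Core containers: cohort tables, snag pools, plots, inventories, run
# configuration. Cohort and snag tables are column-oriented lists (not data
# frames) because the per-plot, per-cycle update loop touches them millions of
# times in a factorial experiment.

sc_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "standclim_error", "error"),
                      call = sys.call(-1)))
}

#' Create a cohort table
#'
#' A cohort is a group of identical trees on a plot: one species, one diameter,
#' one height, and a per-hectare density (the expansion of inventory tree
#' records). The establishment climate (`ec`) stores the climate-metric vector
#' at the cohort's establishment; climate-change mortality is evaluated against
#' it.
#'
#' @param species character vector of species codes.
#' @param density trees per hectare, non-negative.
#' @param dbh diameter at breast height (cm).
#' @param height total height (m).
#' @param estab_year establishment calendar year.
#' @param ec numeric matrix (one row per cohort) of climate metrics at
#'   establishment, or `NULL` for all-`NA` (filled in when a simulation
#'   starts).
#' @param metrics metric names used when `ec` is `NULL`.
#' @return an object of class `cohort_table`.
#' @export
new_cohorts <- function(species = character(), density = numeric(),
                        dbh = numeric(), height = numeric(),
                        estab_year = numeric(), ec = NULL,
                        metrics = c("mat", "map")) {
  n <- length(species)
  if (is.null(ec)) {
    ec <- matrix(NA_real_, n, length(metrics),
                 dimnames = list(NULL, metrics))
  }
  ec <- as.matrix(ec)
  if (length(density) != n || length(dbh) != n || length(height) != n ||
      length(estab_year) != n || nrow(ec) != n) {
    sc_stop("standclim_validation_error",
            "cohort fields have unequal lengths (species: %d)", n)
  }
  if (any(density < 0)) {
    sc_stop("standclim_validation_error", "cohort density must be >= 0")
  }
  if (any(dbh < 0)) {
    sc_stop("standclim_validation_error", "cohort dbh must be >= 0")
  }
  structure(list(species = as.character(species),
                 density = as.numeric(density),
                 dbh = as.numeric(dbh),
                 height = as.numeric(height),
                 estab_year = as.numeric(estab_year),
                 ec = ec),
            class = "cohort_table")
}

n_cohorts <- function(x) length(x$species)

cohorts_subset <- function(x, keep) {
  structure(list(species = x$species[keep], density = x$density[keep],
                 dbh = x$dbh[keep], height = x$height[keep],
                 estab_year = x$estab_year[keep],
                 ec = x$ec[keep, , drop = FALSE]),
            class = "cohort_table")
}

cohorts_bind <- function(a, b) {
  structure(list(species = c(a$species, b$species),
                 density = c(a$density, b$density),
                 dbh = c(a$dbh, b$dbh),
                 height = c(a$height, b$height),
                 estab_year = c(a$estab_year, b$estab_year),
                 ec = rbind(a$ec, b$ec)),
            class = "cohort_table")
}

#' Create a snag (standing dead tree) pool
#'
#' Snag records keep the dimensions the trees had at death; only their density
#' changes afterwards, through per-cycle retention decay.
#'
#' @param species,density,dbh,height as in [new_cohorts()].
#' @param death_year calendar year of death.
#' @return an object of class `snag_table`.
#' @export
new_snags <- function(species = character(), density = numeric(),
                      dbh = numeric(), height = numeric(),
                      death_year = numeric()) {
  n <- length(species)
  if (length(density) != n || length(dbh) != n || length(height) != n ||
      length(death_year) != n) {
    sc_stop("standclim_validation_error", "snag fields have unequal lengths")
  }
  structure(list(species = as.character(species),
                 density = as.numeric(density),
                 dbh = as.numeric(dbh),
                 height = as.numeric(height),
                 death_year = as.numeric(death_year)),
            class = "snag_table")
}

n_snags <- function(x) length(x$species)

snags_bind <- function(a, b) {
  structure(list(species = c(a$species, b$species),
                 density = c(a$density, b$density),
                 dbh = c(a$dbh, b$dbh),
                 height = c(a$height, b$height),
                 death_year = c(a$death_year, b$death_year)),
            class = "snag_table")
}

# Move part of the live cohorts into the snag pool. `killed` is a per-cohort
# density vector (same length as the cohort table).
transfer_to_snags <- function(plot, killed, year) {
  pos <- killed > 0
  if (any(pos)) {
    co <- plot$cohorts
    plot$snags <- snags_bind(plot$snags,
                             new_snags(co$species[pos], killed[pos],
                                       co$dbh[pos], co$height[pos],
                                       rep(year, sum(pos))))
  }
  plot
}

#' Create an inventory plot
#'
#' @param id plot identifier (scalar).
#' @param elevation elevation above sea level (m).
#' @param reserved logical; `TRUE` when the plot is excluded from harvest
#'   (wilderness and similar designations).
#' @param expansion hectares of forest the plot represents; scales plot-level
#'   values to forest totals.
#' @param cohorts a [new_cohorts()] table of live trees.
#' @param snags a [new_snags()] table, empty by default.
#' @return an object of class `stand_plot`.
#' @export
stand_plot <- function(id, elevation, reserved = FALSE, expansion = 2400,
                       cohorts = new_cohorts(), snags = new_snags()) {
  if (!is.numeric(expansion) || length(expansion) != 1 || expansion <= 0) {
    sc_stop("standclim_validation_error",
            "plot '%s': expansion factor must be a positive scalar", id)
  }
  structure(list(id = as.character(id), elevation = as.numeric(elevation),
                 reserved = isTRUE(reserved), expansion = as.numeric(expansion),
                 cohorts = cohorts, snags = snags),
            class = "stand_plot")
}

#' Create a forest inventory
#'
#' Bundles a plot network with its species-parameter pool and the calendar
#' year of the measurement the simulation starts from.
#'
#' @param plots list of [stand_plot()] objects.
#' @param species_pool a species-parameter table (see [make_species_pool()]).
#' @param origin_year calendar year of the inventory (simulation start).
#' @return an object of class `forest_inventory`.
#' @export
forest_inventory <- function(plots, species_pool, origin_year = 2016) {
  ids <- vapply(plots, function(p) p$id, character(1))
  if (anyDuplicated(ids)) {
    sc_stop("standclim_validation_error", "duplicated plot ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  used <- unique(unlist(lapply(plots, function(p) p$cohorts$species)))
  unknown <- setdiff(used, species_pool$code)
  if (length(unknown)) {
    sc_stop("standclim_validation_error",
            "cohort species codes missing from species pool: %s",
            paste(unknown, collapse = ", "))
  }
  structure(list(plots = plots, species_pool = species_pool,
                 origin_year = as.integer(origin_year)),
            class = "forest_inventory")
}

#' @export
print.forest_inventory <- function(x, ...) {
  nc <- sum(vapply(x$plots, function(p) n_cohorts(p$cohorts), integer(1)))
  cat(sprintf("forest_inventory: %d plots, %d live cohorts, %d species, origin %d\n",
              length(x$plots), nc, nrow(x$species_pool), x$origin_year))
  invisible(x)
}

#' Simulation run configuration
#'
#' Collects every scenario/engine setting for one simulation cell or a full
#' factorial experiment. Defaults reproduce the study design this package
#' implements: decadal cycles over a 100-year horizon, ten replicates,
#' regeneration planting 1235 seedlings/ha of up to four climatically suited
#' species when stocking falls below 40%.
#'
#' @param climate climate scenario label: `"none"` (constant normals) or
#'   `"warming"`.
#' @param dclim_multiplier `"off"` (rule disabled) or a positive number; the
#'   elevation-window thresholds are multiplied by it (2 = laxer, 0.5 =
#'   stricter).
#' @param disturbance_multiplier non-negative factor on the per-class decadal
#'   disturbance probabilities (capped at 1).
#' @param n_replicates replicate simulations per factorial cell.
#' @param cycle_years projection cycle length (years).
#' @param horizon total projection length (years); must be a multiple of
#'   `cycle_years`.
#' @param seed master seed; all replicate seeds derive from it.
#' @param snag_retention fraction of snag density retained per cycle.
#' @param delta named per-metric climate change reached at the end of the
#'   horizon under the warming scenario (default +3.0 degC mean annual
#'   temperature, +50 mm mean annual precipitation).
#' @param warming_shape `"linear"`, `"constant"`, or `"logistic"`.
#' @param stocking_threshold regeneration trigger: plant when stocking (%)
#'   falls strictly below this.
#' @param planting_density total seedlings planted per hectare, split equally
#'   among the selected species.
#' @param max_regen_species maximum number of species planted at once.
#' @param viability_threshold viability score below which a species is
#'   considered outside its climatic envelope.
#' @param seedling_dbh,seedling_height planting dimensions (cm, m).
#' @param selfthin_fraction density-dependent mortality trims stands to this
#'   fraction of the effective maximum stand density index.
#' @param sdi_floor lower bound on the viability multiplier applied to the
#'   maximum carrying capacity.
#' @param dclim_rise,dclim_drop elevation window (m) defining the
#'   climate-change mortality thresholds.
#' @param gradient named per-metric climate lapse with elevation (units per
#'   m); temperature negative by convention.
#' @param dclim_semantics `"any"` (a single metric exceeding its threshold
#'   triggers mortality) or `"all"`.
#' @param crn use common random numbers across factorial cells sharing a
#'   replicate index (`TRUE`) or independent streams per cell (`FALSE`).
#' @return an object of class `run_config` (a validated list).
#' @export
run_config <- function(climate = "warming",
                       dclim_multiplier = 1,
                       disturbance_multiplier = 1,
                       n_replicates = 10,
                       cycle_years = 10,
                       horizon = 100,
                       seed = 1L,
                       snag_retention = 0.7,
                       delta = c(mat = 3.0, map = 50),
                       warming_shape = "linear",
                       stocking_threshold = 40,
                       planting_density = 1235,
                       max_regen_species = 4,
                       viability_threshold = 0.5,
                       seedling_dbh = 0.5,
                       seedling_height = 1.37,
                       selfthin_fraction = 0.85,
                       sdi_floor = 0.2,
                       dclim_rise = 300,
                       dclim_drop = 150,
                       gradient = c(mat = -0.0065, map = 0.5),
                       dclim_semantics = "any",
                       crn = TRUE) {
  if (!climate %in% c("none", "warming")) {
    sc_stop("standclim_validation_error", "unknown climate scenario '%s'",
            climate)
  }
  if (!identical(dclim_multiplier, "off")) {
    if (is.character(dclim_multiplier)) {
      dclim_multiplier <- suppressWarnings(as.numeric(dclim_multiplier))
    }
    if (!is.numeric(dclim_multiplier) || is.na(dclim_multiplier) ||
        dclim_multiplier <= 0) {
      sc_stop("standclim_validation_error",
              "dclim_multiplier must be \"off\" or a positive number")
    }
  }
  if (!is.numeric(disturbance_multiplier) || disturbance_multiplier < 0) {
    sc_stop("standclim_validation_error",
            "disturbance_multiplier must be >= 0")
  }
  if (horizon %% cycle_years != 0) {
    sc_stop("standclim_validation_error",
            "horizon (%s) must be divisible by cycle length (%s)",
            horizon, cycle_years)
  }
  if (n_replicates < 1) {
    sc_stop("standclim_validation_error", "n_replicates must be >= 1")
  }
  if (snag_retention < 0 || snag_retention > 1) {
    sc_stop("standclim_validation_error", "snag_retention must be in [0, 1]")
  }
  if (stocking_threshold <= 0 || stocking_threshold >= 100) {
    sc_stop("standclim_validation_error",
            "stocking_threshold must be in (0, 100)")
  }
  structure(list(climate = climate, dclim_multiplier = dclim_multiplier,
                 disturbance_multiplier = disturbance_multiplier,
                 n_replicates = as.integer(n_replicates),
                 cycle_years = as.integer(cycle_years),
                 horizon = as.integer(horizon), seed = as.integer(seed),
                 snag_retention = snag_retention, delta = delta,
                 warming_shape = warming_shape,
                 stocking_threshold = stocking_threshold,
                 planting_density = planting_density,
                 max_regen_species = as.integer(max_regen_species),
                 viability_threshold = viability_threshold,
                 seedling_dbh = seedling_dbh,
                 seedling_height = seedling_height,
                 selfthin_fraction = selfthin_fraction,
                 sdi_floor = sdi_floor,
                 dclim_rise = dclim_rise, dclim_drop = dclim_drop,
                 gradient = gradient, dclim_semantics = dclim_semantics,
                 crn = isTRUE(crn)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run_config: climate=%s, dClim=%s, disturbance x%s, %d reps, %dy horizon (%dy cycles), seed %d\n",
    x$climate, as.character(x$dclim_multiplier),
    as.character(x$disturbance_multiplier),
    x$n_replicates, x$horizon, x$cycle_years, x$seed))
  invisible(x)
}
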