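# Climate trajectories: per-plot climate-metric paths at cycle resolution,
# anchored to 1960-1990 normals.

#' Construct a climate trajectory
#'
#' @param values numeric array `[n_plots, n_years, n_metrics]` of metric
#'   values; dimnames are plot ids, years, metric names.
#' @param years integer calendar years (cycle boundaries).
#' @param plot_ids character plot identifiers, matching the inventory.
#' @param metrics metric names (default mean annual temperature `mat` in degC
#'   and mean annual precipitation `map` in mm).
#' @param normals numeric matrix `[n_plots, n_metrics]` of 1960-1990 normals.
#' @return object of class `climate_trajectory`.
#' @export
climate_trajectory <- function(values, years, plot_ids, metrics, normals) {
  values <- array(values, dim = c(length(plot_ids), length(years),
                                  length(metrics)),
                  dimnames = list(plot_ids, years, metrics))
  normals <- matrix(normals, nrow = length(plot_ids),
                    dimnames = list(plot_ids, metrics))
  structure(list(values = values, years = as.integer(years),
                 plot_ids = as.character(plot_ids),
                 metrics = as.character(metrics), normals = normals),
            class = "climate_trajectory")
}

#' @export
print.climate_trajectory <- function(x, ...) {
  cat(sprintf("climate_trajectory: %d plots, years %d..%d, metrics: %s\n",
              length(x$plot_ids), min(x$years), max(x$years),
              paste(x$metrics, collapse = ", ")))
  invisible(x)
}

#' Climate of every plot at a given year
#'
#' @param trajectory a [climate_trajectory()].
#' @param year a year present in the trajectory.
#' @return numeric matrix `[n_plots, n_metrics]` with plot-id rownames.
#' @export
climate_at <- function(trajectory, year) {
  i <- match(year, trajectory$years)
  if (is.na(i)) {
    sc_stop("standclim_validation_error",
            "year %s not covered by the climate trajectory (%d..%d)",
            year, min(trajectory$years), max(trajectory$years))
  }
  m <- trajectory$values[, i, , drop = FALSE]
  dim(m) <- dim(trajectory$values)[c(1, 3)]
  dimnames(m) <- list(trajectory$plot_ids, trajectory$metrics)
  m
}

#' Build a climate scenario from plot normals
#'
#' Turns per-plot climate normals into a trajectory at cycle resolution.
#' `shape = "constant"` reproduces the normals at every cycle (the no-change
#' scenario). `"linear"` and `"logistic"` ramp each metric from its normal to
#' normal + `delta` at the end of the horizon; both are monotone and reach
#' the endpoints exactly (the logistic ramp is rescaled to hit 0 and 1).
#' Trajectories are deterministic; scenario-to-scenario variation enters the
#' simulations only through disturbance draws.
#'
#' @param normals matrix `[n_plots, n_metrics]` with plot-id rownames and
#'   metric colnames.
#' @param origin_year first calendar year of the projection.
#' @param horizon projection length in years.
#' @param cycle_years cycle length in years.
#' @param delta named numeric: per-metric change reached at
#'   `origin_year + horizon`. Ignored for `shape = "constant"`.
#' @param shape `"constant"`, `"linear"`, or `"logistic"`.
#' @param steepness logistic slope parameter (only for `shape = "logistic"`).
#' @return a [climate_trajectory()].
#' @export
make_climate_scenario <- function(normals, origin_year = 2016, horizon = 100,
                                  cycle_years = 10,
                                  delta = c(mat = 3.0, map = 50),
                                  shape = "linear", steepness = 8) {
  if (!shape %in% c("constant", "linear", "logistic")) {
    sc_stop("standclim_validation_error",
            "unknown scenario shape '%s' (constant, linear, logistic)", shape)
  }
  normals <- as.matrix(normals)
  metrics <- colnames(normals)
  plot_ids <- rownames(normals)
  years <- seq(origin_year, origin_year + horizon, by = cycle_years)
  frac <- (years - origin_year) / horizon
  ramp <- switch(shape,
    constant = rep(0, length(years)),
    linear = frac,
    logistic = {
      g <- function(u) 1 / (1 + exp(-steepness * (u - 0.5)))
      (g(frac) - g(0)) / (g(1) - g(0))
    })
  d <- rep(0, length(metrics))
  names(d) <- metrics
  if (shape != "constant") {
    hit <- intersect(names(delta), metrics)
    d[hit] <- delta[hit]
  }
  vals <- array(0, dim = c(nrow(normals), length(years), length(metrics)))
  for (k in seq_along(metrics)) {
    vals[, , k] <- outer(normals[, k], ramp * d[k], `+`)
  }
  climate_trajectory(vals, years, plot_ids, metrics, normals)
}
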