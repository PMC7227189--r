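# Empirical disturbance regimes: estimation from repeat inventory
# measurements, sensitivity scaling, stochastic event sampling, and event
# application to plots.

DISTURBANCE_CLASSES <- c("harvest", "fire", "stress")

#' Estimate an empirical disturbance regime
#'
#' For each disturbance class (harvest, fire, stress) the decadal disturbance
#' probability is the proportion of remeasured plots on which that class was
#' recorded, and the disturbance magnitude -- the proportion of plot basal
#' area killed -- is kept as the empirical distribution of the observed
#' magnitudes (rendered as a cumulative distribution function). A class with
#' no observed events gets probability 0 and a magnitude distribution
#' degenerate at 0.
#'
#' @param remeasurements a remeasurement table as returned by
#'   [read_remeasurements()] or [make_remeasurement_data()]: columns
#'   `plot_id`, `class` (one of harvest/fire/stress/none), `prop_ba_killed`,
#'   `reserved`.
#' @return an object of class `disturbance_regime`: per class, the
#'   probability `p`, the sorted magnitude vector, and event counts, plus the
#'   number of remeasured plots.
#' @seealso [scale_regime()], [sample_cycle_events()]
#' @export
estimate_regime <- function(remeasurements) {
  if (is.null(remeasurements) || nrow(remeasurements) == 0) {
    sc_stop("standclim_validation_error",
            "remeasurement table is empty; cannot estimate a regime")
  }
  n_plots <- length(unique(remeasurements$plot_id))
  classes <- lapply(DISTURBANCE_CLASSES, function(cl) {
    rec <- remeasurements[remeasurements$class == cl, , drop = FALSE]
    n_events <- length(unique(rec$plot_id))
    mags <- sort(rec$prop_ba_killed)
    list(p = n_events / n_plots,
         magnitudes = if (n_events > 0) mags else 0,
         n_events = n_events)
  })
  names(classes) <- DISTURBANCE_CLASSES
  structure(list(classes = classes, n_remeasured = n_plots,
                 multiplier = 1),
            class = "disturbance_regime")
}

#' @export
print.disturbance_regime <- function(x, ...) {
  cat(sprintf("disturbance_regime estimated from %d remeasured plots", x$n_remeasured))
  if (x$multiplier != 1) cat(sprintf(" (probabilities x%g)", x$multiplier))
  cat("\n  10-year disturbance probabilities:\n")
  for (cl in names(x$classes)) {
    c0 <- x$classes[[cl]]
    cat(sprintf("    %-8s p = %.3f  (%d events; median BA killed %.2f)\n",
                cl, c0$p, c0$n_events, stats::median(c0$magnitudes)))
  }
  invisible(x)
}

#' Plot the magnitude distributions of a regime
#'
#' Draws the empirical cumulative distribution function of proportion basal
#' area killed for each disturbance class. A class with no events appears as
#' a vertical line at 0.
#'
#' @param x a `disturbance_regime`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.disturbance_regime <- function(x, ...) {
  cols <- c(harvest = "#D55E00", fire = "#E69F00", stress = "#0072B2")
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Proportion basal area killed",
                 ylab = "Cumulative probability", ...)
  for (cl in names(x$classes)) {
    f <- stats::ecdf(x$classes[[cl]]$magnitudes)
    graphics::plot(f, add = TRUE, col = cols[[cl]], verticals = TRUE,
                   do.points = FALSE)
  }
  graphics::legend("bottomright", legend = names(x$classes),
                   col = cols[names(x$classes)], lty = 1, bty = "n")
  invisible(x)
}

#' Scale the disturbance probabilities of a regime
#'
#' Sensitivity-analysis helper: multiplies every per-class probability by
#' `multiplier` (capped at 1). The magnitude distributions are untouched --
#' only how often disturbances occur changes, not how severe they are.
#' Multiplier 0 turns disturbance off entirely.
#'
#' @param regime a `disturbance_regime`.
#' @param multiplier non-negative factor (study design uses 0, 0.5, 1, 2).
#' @return the scaled regime.
#' @export
scale_regime <- function(regime, multiplier) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier < 0) {
    sc_stop("standclim_validation_error",
            "disturbance multiplier must be a non-negative number")
  }
  for (cl in names(regime$classes)) {
    regime$classes[[cl]]$p <- min(1, multiplier * regime$classes[[cl]]$p)
  }
  regime$multiplier <- regime$multiplier * multiplier
  regime
}

# Type-1 inverse of the empirical CDF over a sorted magnitude vector.
ecdf_quantile <- function(sorted_mags, u) {
  n <- length(sorted_mags)
  sorted_mags[pmin(n, pmax(1L, ceiling(u * n)))]
}

#' Sample the disturbance events of one cycle for one plot
#'
#' Each class is drawn independently as a Bernoulli trial with the regime's
#' (possibly scaled) probability; harvest probability is forced to zero on
#' reserved plots. Event magnitudes come from the class's empirical magnitude
#' distribution by inverse-transform sampling. Exactly six uniforms (an
#' occurrence and a magnitude draw per class, in the order harvest, fire,
#' stress) are consumed per call whether or not events occur, so random-number
#' streams stay aligned across scenario cells that share a replicate seed.
#'
#' @param regime a `disturbance_regime`.
#' @param plot a [stand_plot()] (only its `reserved` flag is used).
#' @param u optional numeric vector of six uniforms (for testing); drawn from
#'   the current RNG stream when `NULL`.
#' @param year calendar year stamped on the events.
#' @return data frame with columns `class`, `prop_ba_killed`, `year` (zero
#'   rows when nothing occurs).
#' @export
sample_cycle_events <- function(regime, plot, u = NULL, year = NA_integer_) {
  if (is.null(u)) u <- stats::runif(6)
  cls <- character(0)
  mag <- numeric(0)
  for (i in seq_along(DISTURBANCE_CLASSES)) {
    cl <- DISTURBANCE_CLASSES[i]
    p <- regime$classes[[cl]]$p
    if (cl == "harvest" && plot$reserved) p <- 0
    u_occ <- u[2 * i - 1]
    u_mag <- u[2 * i]
    if (u_occ < p) {
      cls <- c(cls, cl)
      mag <- c(mag, ecdf_quantile(regime$classes[[cl]]$magnitudes, u_mag))
    }
  }
  data.frame(class = cls, prop_ba_killed = mag,
             year = rep(as.integer(year), length(cls)),
             stringsAsFactors = FALSE)
}

#' Apply a disturbance event to a plot
#'
#' The event's magnitude `m` is the proportion of live basal area killed.
#' Mortality is applied proportionally across cohorts (every density is
#' multiplied by `1 - m`), which reproduces the plot-level magnitude exactly.
#' Harvested trees leave the plot; fire- and stress-killed trees become
#' snags. `m = 1` empties the live tree list.
#'
#' @param plot a [stand_plot()].
#' @param class disturbance class: `"harvest"`, `"fire"`, or `"stress"`.
#' @param prop_ba_killed magnitude in \[0, 1\].
#' @param year calendar year recorded on new snags.
#' @return list with elements `plot` and `ba_killed` (m^2/ha of live basal
#'   area removed or transferred).
#' @export
apply_event <- function(plot, class, prop_ba_killed, year = NA_integer_) {
  if (!class %in% DISTURBANCE_CLASSES) {
    sc_stop("standclim_validation_error", "unknown disturbance class '%s'",
            class)
  }
  m <- prop_ba_killed
  if (is.na(m) || m < 0 || m > 1) {
    sc_stop("standclim_validation_error",
            "disturbance magnitude must be in [0, 1], got %s", m)
  }
  co <- plot$cohorts
  if (n_cohorts(co) == 0 || m == 0) {
    return(list(plot = plot, ba_killed = 0))
  }
  killed <- co$density * m
  ba_killed <- sum(killed * (pi / 4) * (co$dbh / 100)^2)
  if (class != "harvest") {
    plot <- transfer_to_snags(plot, killed, year)
    co <- plot$cohorts
  }
  co$density <- co$density * (1 - m)
  if (m == 1) co <- cohorts_subset(co, logical(n_cohorts(co)))
  plot$cohorts <- co
  list(plot = plot, ba_killed = ba_killed)
}
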