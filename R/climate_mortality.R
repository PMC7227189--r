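# The three climate-driven mortality pathways:
#   1. viability-envelope mortality  -- gradual density loss once a species'
#      climatic viability score falls below 0.5;
#   2. viability-modified carrying capacity -- the maximum stand density index
#      shrinks when climate favours species that occur at lower densities;
#   3. the elevation-window rule -- whole-cohort mortality when climate change
#      since cohort establishment exceeds the climate difference across a
#      +300 m / -150 m elevation shift (roughly one seed zone).

#' Species viability score
#'
#' Climatic suitability of each species for a climate, on \[0, 1\]. The score
#' is a product over climate metrics of Gaussian niche kernels
#' `exp(-0.5 * ((x - optimum) / breadth)^2)`: 1 at the niche optimum,
#' symmetric about it in each metric. Species are treated as rarely viable
#' where the score is below 0.5.
#'
#' @param pool species-parameter table with `opt_<metric>` / `br_<metric>`
#'   columns (see [make_species_pool()]).
#' @param species character vector of species codes.
#' @param climate either a named numeric vector of climate metrics (recycled
#'   to all species) or a matrix with one row per element of `species`.
#' @return numeric vector of scores in \[0, 1\].
#' @export
viability <- function(pool, species, climate) {
  metrics <- attr(pool, "metrics")
  idx <- match(species, pool$code)
  if (anyNA(idx)) {
    sc_stop("standclim_validation_error",
            "unknown species codes: %s",
            paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  if (is.matrix(climate)) {
    if (nrow(climate) != length(species)) {
      sc_stop("standclim_validation_error",
              "climate matrix has %d rows for %d species",
              nrow(climate), length(species))
    }
    cm <- climate[, metrics, drop = FALSE]
  } else {
    if (!all(metrics %in% names(climate))) {
      sc_stop("standclim_validation_error",
              "climate vector lacks metric(s): %s",
              paste(setdiff(metrics, names(climate)), collapse = ", "))
    }
    cm <- matrix(climate[metrics], length(species), length(metrics),
                 byrow = TRUE)
  }
  score <- rep(1, length(species))
  for (k in seq_along(metrics)) {
    opt <- pool[[paste0("opt_", metrics[k])]][idx]
    br <- pool[[paste0("br_", metrics[k])]][idx]
    z <- (cm[, k] - opt) / br
    score <- score * exp(-0.5 * z * z)
  }
  score
}

#' Per-cycle survival fraction from a viability score
#'
#' Above the viability threshold the envelope pathway removes nothing; below
#' it, survival ramps linearly from 1 (at the threshold) down to 0 (score 0),
#' so envelope mortality is gradual rather than a sudden die-off.
#'
#' @param score viability score(s) in \[0, 1\].
#' @param threshold envelope threshold (default 0.5).
#' @return survival fraction(s) in \[0, 1\], applied to cohort density once
#'   per cycle.
#' @export
envelope_survival_multiplier <- function(score, threshold = 0.5) {
  ifelse(score >= threshold, 1, score / threshold)
}

#' Effective maximum stand density index under a climate
#'
#' The carrying capacity of a plot is its basal-area-weighted mean of species
#' base maximum SDI, scaled by the basal-area-weighted mean viability of the
#' trees present (floored to avoid a zero-capacity singularity). As climate
#' favours species that occur at lower densities, the weighted viability --
#' and with it the carrying capacity -- declines, and density-dependent
#' mortality follows. Empty plots fall back to pool means.
#'
#' @param plot a [stand_plot()].
#' @param climate named climate-metric vector for the plot.
#' @param pool species-parameter table.
#' @param floor lower bound on the viability multiplier.
#' @return effective maximum SDI (trees/ha at the 25.4 cm reference
#'   diameter), always within `[floor * base, base]`.
#' @export
effective_max_sdi <- function(plot, climate, pool, floor = 0.2) {
  co <- plot$cohorts
  if (n_cohorts(co) == 0) {
    base <- mean(pool$base_max_sdi)
    v <- mean(viability(pool, pool$code, climate))
  } else {
    ba <- cohort_ba(co)
    w <- if (sum(ba) > 0) ba / sum(ba) else rep(1 / length(ba), length(ba))
    idx <- match(co$species, pool$code)
    base <- sum(w * pool$base_max_sdi[idx])
    v <- sum(w * viability(pool, co$species, climate))
  }
  base * max(floor, v)
}

#' Configure the elevation-window (dClim) mortality rule
#'
#' The rule kills a cohort when the climate change since its establishment
#' exceeds, in any metric, the climate difference associated with a +`rise` /
#' -`drop` m elevation shift: threshold `tau_k = multiplier * |gradient_k| *
#' (rise + drop)`. Halving the multiplier tightens the window (more
#' climate-related mortality); doubling relaxes it; `"off"` disables the rule.
#'
#' @param gradient named per-metric climate lapse with elevation (units per
#'   m); e.g. `c(mat = -0.0065, map = 0.5)`.
#' @param multiplier `"off"`, or a positive number scaling the thresholds.
#' @param rise,drop elevation window (m); defaults +300 / -150.
#' @param semantics `"any"`: one exceeded metric triggers; `"all"`: every
#'   metric must exceed.
#' @return object of class `dclim_config` with per-metric thresholds `tau`.
#' @export
dclim_config <- function(gradient = c(mat = -0.0065, map = 0.5),
                         multiplier = 1, rise = 300, drop = 150,
                         semantics = "any") {
  if (!semantics %in% c("any", "all")) {
    sc_stop("standclim_validation_error",
            "dclim semantics must be \"any\" or \"all\"")
  }
  off <- identical(multiplier, "off")
  if (!off && is.character(multiplier)) {
    multiplier <- suppressWarnings(as.numeric(multiplier))
  }
  if (!off && (!is.numeric(multiplier) || is.na(multiplier) ||
               multiplier <= 0)) {
    sc_stop("standclim_validation_error",
            "dclim multiplier must be \"off\" or > 0")
  }
  tau <- if (off) NULL else multiplier * abs(gradient) * (rise + drop)
  structure(list(gradient = gradient, multiplier = multiplier,
                 rise = rise, drop = drop, tau = tau, off = off,
                 semantics = semantics),
            class = "dclim_config")
}

#' Which cohorts does the elevation-window rule kill?
#'
#' Compares each cohort's establishment climate with the current climate;
#' triggered cohorts die whole (their density moves to the snag pool), the
#' sudden-die-off behaviour characteristic of this rule. The rule acts
#' independently of viability scores: a killed cohort's species may still be
#' viable and re-establish at the next regeneration opportunity.
#'
#' @param cohorts a [new_cohorts()] table.
#' @param climate_now named climate-metric vector.
#' @param config a [dclim_config()] with a numeric multiplier (callers skip
#'   the rule entirely when it is `"off"`).
#' @return logical vector, one element per cohort.
#' @export
dclim_triggered <- function(cohorts, climate_now, config) {
  if (config$off) {
    sc_stop("standclim_validation_error",
            "dclim_triggered called with the rule disabled")
  }
  metrics <- names(config$tau)
  if (!all(metrics %in% colnames(cohorts$ec)) ||
      !all(metrics %in% names(climate_now))) {
    sc_stop("standclim_validation_error",
            "climate metric mismatch between cohorts, climate and dclim config")
  }
  n <- n_cohorts(cohorts)
  if (n == 0) return(logical(0))
  exceed <- matrix(FALSE, n, length(metrics))
  for (k in seq_along(metrics)) {
    m <- metrics[k]
    exceed[, k] <- abs(climate_now[[m]] - cohorts$ec[, m]) > config$tau[[m]]
  }
  if (config$semantics == "any") {
    rowSums(exceed) > 0
  } else {
    rowSums(exceed) == length(metrics)
  }
}

#' Reset a cohort's establishment climate
#'
#' New cohorts record the climate under which they establish; they are immune
#' to elevation-window mortality until climate drifts beyond the window from
#' this new baseline.
#'
#' @param cohorts a [new_cohorts()] table.
#' @param climate_now named climate-metric vector (the establishment climate).
#' @param year establishment calendar year.
#' @return the cohort table with establishment year and climate replaced.
#' @export
reset_establishment <- function(cohorts, climate_now, year) {
  n <- n_cohorts(cohorts)
  metrics <- colnames(cohorts$ec)
  cohorts$estab_year <- rep(as.numeric(year), n)
  cohorts$ec <- matrix(climate_now[metrics], n, length(metrics), byrow = TRUE,
                       dimnames = list(NULL, metrics))
  cohorts
}
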