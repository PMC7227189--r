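# Synthetic study systems: species pools with unimodal climatic niches,
# plot networks along an elevation/climate gradient, and remeasurement
# records drawn from known disturbance probabilities. Everything is
# reproducible from a seed, and the ground truth is recorded so estimators
# can be checked against it.

#' Generate a species pool with climatic niches along a gradient
#'
#' Species niche optima are spread (approximately evenly, with a small
#' jitter) across the supplied climate range so that every climate in the
#' range is suitable (viability >= 0.5) for at least one species. The two
#' default metrics are paired as on a montane gradient: optima ascend in
#' temperature while descending in precipitation (warm-dry lowlands to
#' cool-wet highlands). Niche breadths scale with the optimum spacing;
#' precipitation breadths have a generous floor, reflecting that temperature
#' is the dominant control on montane species distributions.
#'
#' Growth, allometry, and density parameters are drawn from fixed realistic
#' ranges: maximum diameter 60-120 cm, maximum annual increment
#' 0.25-0.55 cm/y, height caps 28-48 m, wood density 380-550 kg/m^3, base
#' maximum stand density index 600-1000.
#'
#' @param n_species number of species (>= 2).
#' @param climate_range named list of per-metric `c(lo, hi)` ranges, e.g.
#'   `list(mat = c(2, 12), map = c(400, 1200))`.
#' @param seed RNG seed.
#' @param breadth_factor niche breadth as a fraction of optimum spacing.
#' @param min_breadth named per-metric lower bounds on breadth.
#' @param jitter_frac jitter on optima as a fraction of spacing.
#' @return a `species_pool` data frame with attribute `metrics`.
#' @export
make_species_pool <- function(n_species,
                              climate_range = list(mat = c(2, 12),
                                                   map = c(400, 1200)),
                              seed = 1,
                              breadth_factor = 0.8,
                              min_breadth = c(mat = 0, map = 300),
                              jitter_frac = 0.05) {
  if (n_species < 2) {
    sc_stop("standclim_validation_error", "n_species must be >= 2")
  }
  set.seed(seed)
  metrics <- names(climate_range)
  pool <- data.frame(code = sprintf("SP%02d", seq_len(n_species)),
                     stringsAsFactors = FALSE)
  for (k in seq_along(metrics)) {
    m <- metrics[k]
    rng <- climate_range[[m]]
    opt <- seq(rng[1], rng[2], length.out = n_species)
    if (k %% 2 == 0) opt <- rev(opt)  # pair warm with dry, cool with wet
    spacing <- abs(diff(range(rng))) / (n_species - 1)
    opt <- opt + stats::runif(n_species, -1, 1) * jitter_frac * spacing
    br <- max(breadth_factor * spacing,
              if (m %in% names(min_breadth)) min_breadth[[m]] else 0)
    pool[[paste0("opt_", m)]] <- opt
    pool[[paste0("br_", m)]] <- rep(br, n_species)
  }
  pool$max_dbh <- stats::runif(n_species, 60, 120)
  pool$max_incr <- stats::runif(n_species, 0.25, 0.55)
  pool$hd_k <- stats::runif(n_species, 0.03, 0.06)
  pool$height_cap <- stats::runif(n_species, 28, 48)
  pool$wood_density <- stats::runif(n_species, 380, 550)
  pool$crown_factor <- stats::runif(n_species, 1.15, 1.35)
  pool$base_max_sdi <- stats::runif(n_species, 600, 1000)
  pool$form_factor <- rep(0.42, n_species)
  attr(pool, "metrics") <- metrics
  class(pool) <- c("species_pool", "data.frame")
  pool
}

# Climate normals implied by the elevation gradient.
normals_from_elevation <- function(elevation, base_climate, gradient,
                                   ref_elevation) {
  metrics <- names(gradient)
  out <- vapply(metrics, function(m) {
    base_climate[[m]] + gradient[[m]] * (elevation - ref_elevation)
  }, numeric(length(elevation)))
  matrix(out, nrow = length(elevation), dimnames = list(NULL, metrics))
}

#' Generate a synthetic inventory landscape
#'
#' Places plots uniformly along an elevation range; each plot's 1960-1990
#' climate normals follow the elevation gradient from a regional base
#' climate at the reference elevation. Initial cohorts are drawn only from
#' species viable (score >= 0.5) under the plot's normals, with random
#' diameters and densities targeting moderate stocking. A configurable
#' fraction of plots is flagged reserved (excluded from harvest), and every
#' plot carries a fixed expansion factor of 2400 ha, the national inventory
#' sampling intensity.
#'
#' @param n_plots number of plots (>= 1).
#' @param elevation_range `c(lo, hi)` in m; must be non-degenerate.
#' @param gradient named per-metric climate lapse with elevation (units/m).
#' @param seed RNG seed.
#' @param base_climate regional climate at the reference elevation.
#' @param ref_elevation elevation (m) at which the base climate applies.
#' @param reserved_frac probability that a plot is reserved (default 0.34,
#'   the reserved share of a large wilderness-dominated forest).
#' @param n_species pool size when `species_pool` is generated here.
#' @param warming_headroom extra warm-end temperature range (degC) covered by
#'   the generated pool, so warming climates remain colonisable.
#' @param species_pool optional pre-built [make_species_pool()] result.
#' @param origin_year inventory calendar year.
#' @param expansion per-plot expansion factor (ha).
#' @param stocking_range initial relative density range (fraction of mean
#'   base maximum SDI).
#' @return a list of class `sc_landscape`: `inventory`
#'   ([forest_inventory()]), `normals` (plot-by-metric matrix), `gradient`.
#' @export
make_landscape <- function(n_plots,
                           elevation_range = c(500, 2000),
                           gradient = c(mat = -0.0065, map = 0.5),
                           seed = 1,
                           base_climate = c(mat = 6.0, map = 800),
                           ref_elevation = mean(elevation_range),
                           reserved_frac = 0.34,
                           n_species = 8,
                           warming_headroom = 3,
                           species_pool = NULL,
                           origin_year = 2016,
                           expansion = 2400,
                           stocking_range = c(0.45, 0.75)) {
  if (n_plots < 1) {
    sc_stop("standclim_validation_error", "n_plots must be >= 1")
  }
  if (diff(range(elevation_range)) <= 0) {
    sc_stop("standclim_validation_error", "elevation range is empty")
  }
  metrics <- names(gradient)
  if (is.null(species_pool)) {
    # pool spans the landscape's normals plus warm-end headroom, with the
    # second metric paired along the same elevation line
    elev_for <- function(mat) {
      ref_elevation + (mat - base_climate[["mat"]]) / gradient[["mat"]]
    }
    mat_lo <- base_climate[["mat"]] +
      gradient[["mat"]] * (max(elevation_range) - ref_elevation)
    mat_hi <- base_climate[["mat"]] +
      gradient[["mat"]] * (min(elevation_range) - ref_elevation) +
      warming_headroom
    map_at <- function(mat) {
      base_climate[["map"]] + gradient[["map"]] * (elev_for(mat) - ref_elevation)
    }
    species_pool <- make_species_pool(
      n_species,
      climate_range = list(mat = c(mat_lo, mat_hi),
                           map = sort(c(map_at(mat_lo), map_at(mat_hi)))),
      seed = seed)
  }
  set.seed(seed + 1L)
  elevation <- stats::runif(n_plots, elevation_range[1], elevation_range[2])
  normals <- normals_from_elevation(elevation, base_climate, gradient,
                                    ref_elevation)
  ids <- sprintf("P%04d", seq_len(n_plots))
  rownames(normals) <- ids
  reserved <- stats::runif(n_plots) < reserved_frac
  plots <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    clim <- normals[i, ]
    v <- viability(species_pool, species_pool$code, clim)
    viable <- which(v >= 0.5)
    n_coh <- min(sample(2:4, 1), length(viable))
    pick <- if (length(viable) == 1) viable else {
      sample(viable, n_coh, prob = v[viable])
    }
    dbh <- stats::runif(n_coh, 15, 45)
    idx <- pick
    height <- height_from_dbh(dbh, species_pool$hd_k[idx],
                              species_pool$height_cap[idx])
    target <- stats::runif(1, stocking_range[1], stocking_range[2]) *
      mean(species_pool$base_max_sdi[idx])
    w <- stats::runif(n_coh, 0.5, 1.5)
    sdi_per_tree <- (dbh / 25.4)^1.605
    density <- (w / sum(w)) * target / sdi_per_tree
    cohorts <- new_cohorts(species = species_pool$code[idx],
                           density = density, dbh = dbh, height = height,
                           estab_year = rep(origin_year, n_coh),
                           metrics = metrics)
    plots[[i]] <- stand_plot(ids[i], elevation[i], reserved[i], expansion,
                             cohorts)
  }
  inv <- forest_inventory(plots, species_pool, origin_year)
  structure(list(inventory = inv, normals = normals, gradient = gradient,
                 base_climate = base_climate, ref_elevation = ref_elevation),
            class = "sc_landscape")
}

#' @export
print.sc_landscape <- function(x, ...) {
  print(x$inventory)
  cat(sprintf("  elevations %.0f..%.0f m; normals MAT %.1f..%.1f degC\n",
              min(vapply(x$inventory$plots, `[[`, numeric(1), "elevation")),
              max(vapply(x$inventory$plots, `[[`, numeric(1), "elevation")),
              min(x$normals[, "mat"]), max(x$normals[, "mat"])))
  invisible(x)
}

#' Default disturbance magnitude distributions
#'
#' Sampling functions for proportion basal area killed, per class. Harvest
#' magnitudes are strictly positive (a harvest always removes trees) with a
#' small atom at 1 (occasional complete removal). Fire and stress are
#' zero-inflated -- such events do not always kill trees; the stress
#' zero-probability default (0.40) matches a dry-forest inventory where 40%
#' of stress events killed nothing.
#'
#' @param fire_zero,stress_zero probability of a zero-magnitude event.
#' @param harvest_clearcut probability that a harvest removes everything.
#' @return named list of functions `n -> n draws in [0, 1]`.
#' @export
default_magnitude_dists <- function(fire_zero = 0.25, stress_zero = 0.40,
                                    harvest_clearcut = 0.02) {
  list(
    harvest = function(n) {
      x <- pmax(stats::rbeta(n, 2, 1.5), 1e-3)
      x[stats::runif(n) < harvest_clearcut] <- 1
      x
    },
    fire = function(n) {
      ifelse(stats::runif(n) < fire_zero, 0, stats::rbeta(n, 1.2, 2))
    },
    stress = function(n) {
      ifelse(stats::runif(n) < stress_zero, 0, stats::rbeta(n, 1.2, 4))
    })
}

#' Generate synthetic remeasurement records with known truth
#'
#' Each plot is independently disturbed by each class with its true decadal
#' probability; disturbed plots get one record per class with a magnitude
#' draw from that class's distribution, and undisturbed plots get a single
#' `"none"` record with magnitude 0. The true probabilities are stored in
#' the attribute `true_probs` so estimator recovery can be verified.
#'
#' @param true_probs named per-class 10-year disturbance probabilities;
#'   defaults are the dry-mixed-conifer inventory values
#'   (harvest 0.132, fire 0.093, stress 0.335).
#' @param magnitude_dists named list of magnitude samplers, see
#'   [default_magnitude_dists()].
#' @param n_plots number of remeasured plots.
#' @param seed RNG seed.
#' @param reserved_frac fraction of plots flagged reserved in the output.
#' @return a remeasurement data frame (`plot_id`, `class`, `prop_ba_killed`,
#'   `reserved`).
#' @export
make_remeasurement_data <- function(true_probs = c(harvest = 0.132,
                                                   fire = 0.093,
                                                   stress = 0.335),
                                    magnitude_dists = default_magnitude_dists(),
                                    n_plots = 343, seed = 1,
                                    reserved_frac = 0) {
  if (any(true_probs < 0 | true_probs > 1)) {
    sc_stop("standclim_validation_error",
            "true probabilities must be in [0, 1]")
  }
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_plots))
  reserved <- stats::runif(n_plots) < reserved_frac
  rows <- list()
  for (cl in DISTURBANCE_CLASSES) {
    p <- if (cl %in% names(true_probs)) true_probs[[cl]] else 0
    hit <- stats::runif(n_plots) < p
    n_hit <- sum(hit)
    if (n_hit > 0) {
      mags <- magnitude_dists[[cl]](n_hit)
      rows[[cl]] <- data.frame(plot_id = ids[hit], class = cl,
                               prop_ba_killed = mags,
                               reserved = reserved[hit],
                               stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  disturbed <- if (is.null(tab)) character(0) else unique(tab$plot_id)
  quiet <- setdiff(ids, disturbed)
  if (length(quiet)) {
    tab <- rbind(tab, data.frame(plot_id = quiet, class = "none",
                                 prop_ba_killed = 0,
                                 reserved = reserved[match(quiet, ids)],
                                 stringsAsFactors = FALSE))
  }
  tab <- tab[order(tab$plot_id, tab$class), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "true_probs") <- true_probs
  tab
}
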