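# Fixtures are built in code: nothing on disk, everything seeded.

# A hand-specified species pool with known parameters, for exact oracles.
manual_pool <- function(codes = c("AA", "BB"),
                        opt_mat = c(5, 9), br_mat = c(1.5, 1.5),
                        opt_map = c(900, 700), br_map = c(300, 300),
                        wood_density = 450, form_factor = 0.42,
                        crown_factor = 1.2, base_max_sdi = 800,
                        max_dbh = 100, max_incr = 0.4, hd_k = 0.045,
                        height_cap = 40) {
  n <- length(codes)
  rep_n <- function(x) rep_len(x, n)
  pool <- data.frame(code = codes, opt_mat = rep_n(opt_mat),
                     br_mat = rep_n(br_mat), opt_map = rep_n(opt_map),
                     br_map = rep_n(br_map), max_dbh = rep_n(max_dbh),
                     max_incr = rep_n(max_incr), hd_k = rep_n(hd_k),
                     height_cap = rep_n(height_cap),
                     wood_density = rep_n(wood_density),
                     crown_factor = rep_n(crown_factor),
                     base_max_sdi = rep_n(base_max_sdi),
                     form_factor = rep_n(form_factor),
                     stringsAsFactors = FALSE)
  attr(pool, "metrics") <- c("mat", "map")
  class(pool) <- c("species_pool", "data.frame")
  pool
}

# One plot with explicit cohorts (establishment climate filled in).
fixture_plot <- function(species, density, dbh, height = NULL,
                         pool = manual_pool(), reserved = FALSE,
                         expansion = 2400, ec_mat = 5, ec_map = 900,
                         id = "T1") {
  n <- length(species)
  if (is.null(height)) height <- rep(20, n)
  ec <- cbind(mat = rep(ec_mat, n), map = rep(ec_map, n))
  stand_plot(id, 1000, reserved, expansion,
             new_cohorts(species, density, dbh, height,
                         rep(2016, n), ec = ec))
}

# Density giving a target basal area (m^2/ha) at a given dbh (cm).
density_for_ba <- function(ba, dbh) ba / ((pi / 4) * (dbh / 100)^2)

# A cohort-free single-metric climate vector.
clim <- function(mat, map = 900) c(mat = mat, map = map)

# Small landscape shared by several tests.
small_landscape <- function(n_plots = 20, seed = 7) {
  make_landscape(n_plots, seed = seed)
}

base_regime <- function(seed = 5, n_plots = 343) {
  estimate_regime(make_remeasurement_data(n_plots = n_plots, seed = seed))
}
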