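# CSV table schemas and configuration I/O. Comma-separated, UTF-8, header
# row mandatory, "." decimal. Units are fixed at the interface: DBH cm,
# height m, density trees/ha, area ha, carbon Mg. Numbers are written with
# 17 significant digits so that write -> read round-trips bit-exactly.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  out
}

write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) {
                    sc_stop("standclim_io_error", "cannot write '%s': %s",
                            path, conditionMessage(e))
                  })
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    sc_stop("standclim_schema_error", "%s: missing required column(s): %s",
            path, paste(miss, collapse = ", "))
  }
}

read_csv_file <- function(path) {
  if (!file.exists(path)) {
    sc_stop("standclim_io_error", "file not found: %s", path)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Read a species-parameter table
#'
#' Expected columns: `code`, one `opt_<metric>`/`br_<metric>` pair per
#' climate metric, `max_dbh`, `max_incr`, `hd_k`, `height_cap`,
#' `wood_density`, `crown_factor`, `base_max_sdi`, `form_factor`. The metric
#' set is inferred from the `opt_*` columns.
#'
#' @param path species.csv path.
#' @return a `species_pool` data frame.
#' @export
read_species <- function(path) {
  df <- read_csv_file(path)
  require_columns(df, c("code", "max_dbh", "max_incr", "hd_k", "height_cap",
                        "wood_density", "crown_factor", "base_max_sdi",
                        "form_factor"), path)
  metrics <- sub("^opt_", "", grep("^opt_", names(df), value = TRUE))
  if (!length(metrics)) {
    sc_stop("standclim_schema_error",
            "%s: no opt_<metric> niche columns found", path)
  }
  for (m in metrics) {
    require_columns(df, paste0("br_", m), path)
    if (any(df[[paste0("br_", m)]] <= 0)) {
      sc_stop("standclim_validation_error",
              "%s: column br_%s must be positive", path, m)
    }
  }
  if (any(df$height_cap <= 1.37)) {
    sc_stop("standclim_validation_error",
            "%s: height_cap must exceed breast height (1.37 m)", path)
  }
  attr(df, "metrics") <- metrics
  class(df) <- c("species_pool", "data.frame")
  df
}

#' @rdname read_species
#' @param pool a `species_pool` table.
#' @export
write_species <- function(pool, path) {
  write_csv_exact(as.data.frame(pool), path)
}

#' Read an inventory from plot, tree, and species tables
#'
#' `plots.csv`: `plot_id`, `elevation_m`, `reserved` (TRUE/FALSE),
#' `expansion_ha`. `trees.csv`: `plot_id`, `species`, `dbh_cm`, `height_m`,
#' `tph` and optionally `estab_year`; each tree row becomes one cohort on
#' its plot. All referential problems (tree rows pointing at absent plots,
#' species codes absent from the pool) raise validation errors naming the
#' offending values.
#'
#' @param plot_path,tree_path,species_path CSV file paths.
#' @param origin_year calendar year of the inventory.
#' @return a [forest_inventory()].
#' @export
read_inventory <- function(plot_path, tree_path, species_path,
                           origin_year = 2016) {
  pool <- read_species(species_path)
  metrics <- attr(pool, "metrics")
  pl <- read_csv_file(plot_path)
  require_columns(pl, c("plot_id", "elevation_m", "reserved", "expansion_ha"),
                  plot_path)
  tr <- read_csv_file(tree_path)
  require_columns(tr, c("plot_id", "species", "dbh_cm", "height_m", "tph"),
                  tree_path)
  pl$plot_id <- as.character(pl$plot_id)
  tr$plot_id <- as.character(tr$plot_id)
  orphan <- setdiff(tr$plot_id, pl$plot_id)
  if (length(orphan)) {
    sc_stop("standclim_validation_error",
            "%s: tree rows reference absent plot id(s): %s", tree_path,
            paste(orphan, collapse = ", "))
  }
  unknown <- setdiff(tr$species, pool$code)
  if (length(unknown)) {
    sc_stop("standclim_validation_error",
            "%s: unknown species code(s): %s", tree_path,
            paste(unknown, collapse = ", "))
  }
  if (!"estab_year" %in% names(tr)) tr$estab_year <- origin_year
  plots <- lapply(seq_len(nrow(pl)), function(i) {
    rows <- tr[tr$plot_id == pl$plot_id[i], , drop = FALSE]
    cohorts <- new_cohorts(species = rows$species, density = rows$tph,
                           dbh = rows$dbh_cm, height = rows$height_m,
                           estab_year = rows$estab_year, metrics = metrics)
    stand_plot(pl$plot_id[i], pl$elevation_m[i],
               isTRUE(as.logical(pl$reserved[i])), pl$expansion_ha[i],
               cohorts)
  })
  forest_inventory(plots, pool, origin_year)
}

#' @rdname read_inventory
#' @param inventory a [forest_inventory()].
#' @export
write_inventory <- function(inventory, plot_path, tree_path, species_path) {
  pl <- data.frame(
    plot_id = vapply(inventory$plots, `[[`, character(1), "id"),
    elevation_m = vapply(inventory$plots, `[[`, numeric(1), "elevation"),
    reserved = vapply(inventory$plots, `[[`, logical(1), "reserved"),
    expansion_ha = vapply(inventory$plots, `[[`, numeric(1), "expansion"),
    stringsAsFactors = FALSE)
  tr <- do.call(rbind, lapply(inventory$plots, function(p) {
    co <- p$cohorts
    if (n_cohorts(co) == 0) return(NULL)
    data.frame(plot_id = p$id, species = co$species, dbh_cm = co$dbh,
               height_m = co$height, tph = co$density,
               estab_year = co$estab_year, stringsAsFactors = FALSE)
  }))
  if (is.null(tr)) {
    tr <- data.frame(plot_id = character(), species = character(),
                     dbh_cm = numeric(), height_m = numeric(),
                     tph = numeric(), estab_year = numeric())
  }
  write_csv_exact(pl, plot_path)
  write_csv_exact(tr, tree_path)
  write_species(inventory$species_pool, species_path)
  invisible(inventory)
}

#' Read a remeasurement table
#'
#' Expected columns: `plot_id`, `class`, `prop_ba_killed`, and optionally
#' `reserved`. Class labels are case-folded to lower case (the only
#' documented coercion); anything other than harvest/fire/stress/none is an
#' error, as is a proportion outside \[0, 1\] (values are refused, never
#' clipped) or a `"none"` record with a nonzero proportion.
#'
#' @param path remeasure.csv path.
#' @return validated remeasurement data frame.
#' @export
read_remeasurements <- function(path) {
  df <- read_csv_file(path)
  require_columns(df, c("plot_id", "class", "prop_ba_killed"), path)
  df$plot_id <- as.character(df$plot_id)
  df$class <- tolower(trimws(df$class))
  bad <- setdiff(unique(df$class), c(DISTURBANCE_CLASSES, "none"))
  if (length(bad)) {
    sc_stop("standclim_validation_error",
            "%s: column class: unknown label(s): %s", path,
            paste(bad, collapse = ", "))
  }
  out_of_range <- which(is.na(df$prop_ba_killed) | df$prop_ba_killed < 0 |
                          df$prop_ba_killed > 1)
  if (length(out_of_range)) {
    sc_stop("standclim_validation_error",
            "%s: column prop_ba_killed outside [0, 1] at row(s): %s", path,
            paste(out_of_range, collapse = ", "))
  }
  nz_none <- which(df$class == "none" & df$prop_ba_killed != 0)
  if (length(nz_none)) {
    sc_stop("standclim_validation_error",
            "%s: class \"none\" with nonzero prop_ba_killed at row(s): %s",
            path, paste(nz_none, collapse = ", "))
  }
  if (!"reserved" %in% names(df)) df$reserved <- FALSE
  df$reserved <- as.logical(df$reserved)
  df
}

#' @rdname read_remeasurements
#' @param remeasurements a remeasurement data frame.
#' @export
write_remeasurements <- function(remeasurements, path) {
  cols <- c("plot_id", "class", "prop_ba_killed", "reserved")
  write_csv_exact(remeasurements[intersect(cols, names(remeasurements))],
                  path)
}

#' Read or write per-plot climate tables
#'
#' Long CSV with columns `plot_id`, `year`, and one column per climate
#' metric. Rows with `year = "normal"` carry the 1960-1990 normals; all
#' other rows are trajectory values at cycle boundaries.
#'
#' @param path climate.csv path.
#' @return a [climate_trajectory()].
#' @export
read_climate <- function(path) {
  df <- read_csv_file(path)
  require_columns(df, c("plot_id", "year"), path)
  metrics <- setdiff(names(df), c("plot_id", "year"))
  if (!length(metrics)) {
    sc_stop("standclim_schema_error", "%s: no climate metric columns", path)
  }
  df$plot_id <- as.character(df$plot_id)
  is_norm <- df$year == "normal"
  norm <- df[is_norm, , drop = FALSE]
  tra <- df[!is_norm, , drop = FALSE]
  tra$year <- as.integer(tra$year)
  plot_ids <- unique(df$plot_id)
  years <- sort(unique(tra$year))
  vals <- array(NA_real_, c(length(plot_ids), length(years), length(metrics)))
  pi_ <- match(tra$plot_id, plot_ids)
  yi <- match(tra$year, years)
  for (k in seq_along(metrics)) {
    vals[cbind(pi_, yi, k)] <- tra[[metrics[k]]]
  }
  normals <- matrix(NA_real_, length(plot_ids), length(metrics))
  ni <- match(norm$plot_id, plot_ids)
  for (k in seq_along(metrics)) normals[ni, k] <- norm[[metrics[k]]]
  climate_trajectory(vals, years, plot_ids, metrics, normals)
}

#' @rdname read_climate
#' @param trajectory a [climate_trajectory()].
#' @export
write_climate <- function(trajectory, path) {
  metrics <- trajectory$metrics
  norm <- data.frame(plot_id = trajectory$plot_ids, year = "normal",
                     stringsAsFactors = FALSE)
  for (k in seq_along(metrics)) norm[[metrics[k]]] <- trajectory$normals[, k]
  rows <- list(norm)
  for (j in seq_along(trajectory$years)) {
    d <- data.frame(plot_id = trajectory$plot_ids,
                    year = as.character(trajectory$years[j]),
                    stringsAsFactors = FALSE)
    for (k in seq_along(metrics)) {
      d[[metrics[k]]] <- trajectory$values[, j, k]
    }
    rows[[j + 1]] <- d
  }
  write_csv_exact(do.call(rbind, rows), path)
}

#' Write or read a scenario result table
#'
#' One long CSV holding both response variables: forest-level carbon rows
#' (`plot_id = "ALL"`, empty `species`) and species basal-area rows. Columns:
#' `year`, `scenario`, `dclim_level`, `disturbance_level`, `replicate`,
#' `plot_id`, `live_C_Mg`, `snag_C_Mg`, `species`, `ba_m2`. An empty result
#' produces a header-only file. Numbers round-trip bit-exactly.
#'
#' @param result a `scenario_result` (or a list with `carbon` and
#'   `composition` data frames in the same layout).
#' @param path results.csv path.
#' @export
write_results <- function(result, path) {
  cb <- result$carbon
  cp <- result$composition
  empty <- data.frame(year = integer(), scenario = character(),
                      dclim_level = character(),
                      disturbance_level = numeric(), replicate = integer(),
                      plot_id = character(), live_C_Mg = numeric(),
                      snag_C_Mg = numeric(), species = character(),
                      ba_m2 = numeric(), stringsAsFactors = FALSE)
  rows <- list(empty)
  if (!is.null(cb) && nrow(cb)) {
    rows$carbon <- data.frame(year = cb$year, scenario = cb$scenario,
                              dclim_level = cb$dclim,
                              disturbance_level = cb$disturbance,
                              replicate = cb$replicate, plot_id = "ALL",
                              live_C_Mg = cb$live_C_Mg,
                              snag_C_Mg = cb$snag_C_Mg, species = "",
                              ba_m2 = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(cp) && nrow(cp)) {
    rows$composition <- data.frame(year = cp$year, scenario = cp$scenario,
                                   dclim_level = cp$dclim,
                                   disturbance_level = cp$disturbance,
                                   replicate = cp$replicate, plot_id = "ALL",
                                   live_C_Mg = NA_real_,
                                   snag_C_Mg = NA_real_,
                                   species = cp$species, ba_m2 = cp$ba_m2,
                                   stringsAsFactors = FALSE)
  }
  write_csv_exact(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}

#' @rdname write_results
#' @return `read_results()` returns a list with `carbon` and `composition`
#'   data frames.
#' @export
read_results <- function(path) {
  df <- read_csv_file(path)
  require_columns(df, c("year", "scenario", "dclim_level",
                        "disturbance_level", "replicate", "plot_id",
                        "live_C_Mg", "snag_C_Mg", "species", "ba_m2"), path)
  df$species[is.na(df$species)] <- ""
  is_carbon <- df$species == ""
  cb <- df[is_carbon, , drop = FALSE]
  cp <- df[!is_carbon, , drop = FALSE]
  list(
    carbon = data.frame(scenario = cb$scenario, dclim = as.character(cb$dclim_level),
                        disturbance = cb$disturbance_level,
                        replicate = cb$replicate, year = cb$year,
                        live_C_Mg = cb$live_C_Mg, snag_C_Mg = cb$snag_C_Mg,
                        total_C_Mg = cb$live_C_Mg + cb$snag_C_Mg,
                        stringsAsFactors = FALSE),
    composition = data.frame(scenario = cp$scenario,
                             dclim = as.character(cp$dclim_level),
                             disturbance = cp$disturbance_level,
                             replicate = cp$replicate, year = cp$year,
                             species = cp$species, ba_m2 = cp$ba_m2,
                             stringsAsFactors = FALSE))
}

#' Read or write a run configuration
#'
#' The configuration lives in a YAML file whose keys mirror the arguments
#' of [run_config()]; `delta` and `gradient` are nested metric-keyed maps.
#'
#' @param path run.yml path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    sc_stop("standclim_io_error", "file not found: %s", path)
  }
  vals <- yaml::read_yaml(path)
  for (f in c("delta", "gradient")) {
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    sc_stop("standclim_schema_error", "%s: unknown config key(s): %s", path,
            paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  vals$delta <- as.list(vals$delta)
  vals$gradient <- as.list(vals$gradient)
  yaml::write_yaml(vals, path)
  invisible(config)
}
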