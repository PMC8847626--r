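# Plain-text IO: CSV for tables, a directory of CSV layers plus a JSON
# header (coordinates, units, provenance) for grid stacks, JSON for model
# ledgers and pipeline reports.

site_table_columns <- function() {
  c("site_id", "biome", "form", candidate_predictors(),
    "rec_plant", "rec_wood_share", "rec_org", "rec_min", "loss")
}

#' Read / write the site table
#'
#' @param sites Site table data frame ([make_site_table()] format).
#' @param path CSV path.
#' @return `read_site_csv` returns the validated data frame.
#' @export
write_site_csv <- function(sites, path) {
  utils::write.csv(sites[, site_table_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_csv
#' @export
read_site_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(site_table_columns(), names(d))
  if (length(miss))
    stop("site CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- c("rec_plant", "rec_org", "rec_min", "loss")
  for (col in bad)
    if (any(d[[col]] < 0 | d[[col]] > 100, na.rm = TRUE))
      stop("site CSV: ", col, " outside [0, 100]", call. = FALSE)
  d
}

#' Write / read a grid stack as a self-described directory
#'
#' Each layer becomes `<name>.csv` (one row per latitude band) and
#' `header.json` records layer names, units, cell-edge coordinates, and any
#' provenance fields passed in, so a stack round-trips without side
#' knowledge.
#'
#' @param grid A [grid_stack()].
#' @param dir Output directory (created if needed).
#' @param provenance Optional named list stored in the header (e.g. seed,
#'   package version).
#' @return `read_grid_stack` returns the reconstructed [grid_stack()].
#' @export
write_grid_stack <- function(grid, dir, provenance = list()) {
  stopifnot(inherits(grid, "grid_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(layers = names(grid$layers),
                 units = as.list(grid$units),
                 lat_bounds = grid$lat_bounds,
                 lon_bounds = grid$lon_bounds,
                 provenance = provenance)
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(grid$layers))
    utils::write.table(grid$layers[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_grid_stack
#' @export
read_grid_stack <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  layers <- lapply(header$layers, function(nm)
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")),
                                sep = ",")))
  layers <- lapply(layers, unname)
  names(layers) <- header$layers
  grid_stack(layers, header$lat_bounds, header$lon_bounds,
             units = unlist(header$units))
}

#' Convert retention maps to a grid stack for writing
#'
#' @param maps A `retention_maps` object.
#' @param grid The [grid_stack()] the maps were computed on (for
#'   coordinates).
#' @return A [grid_stack()] with layers `fracPlant`, `fracWood`, `fracOrg`,
#'   `fracMin`, `fracLoss` (units "%") plus `extrapolation` (0/1).
#' @export
retention_maps_as_stack <- function(maps, grid) {
  stopifnot(inherits(maps, "retention_maps"))
  layers <- list(fracPlant = maps$frac_plant, fracWood = maps$frac_wood,
                 fracOrg = maps$frac_org, fracMin = maps$frac_min,
                 fracLoss = maps$frac_loss)
  units <- stats::setNames(rep("%", 5), names(layers))
  ex <- attr(maps, "extrapolation")
  if (!is.null(ex)) {
    layers$extrapolation <- ex * 1
    units <- c(units, extrapolation = "0/1")
  }
  grid_stack(layers, grid$lat_bounds, grid$lon_bounds, units)
}

#' Write the ranked model ledger of a selection to JSON
#'
#' @param models Model list from [fit_retention_models()], or a single
#'   `retention_fit` from [select_best()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_model_ledger <- function(models, path) {
  if (inherits(models, "retention_fit")) models <- list(models)
  out <- lapply(models, function(fit) {
    list(response = fit$response,
         predictors = fit$predictors,
         coefficients = as.list(fit$coefficients),
         aicc = fit$aicc, r2 = fit$r2,
         vif = as.list(fit$vif), n = fit$n,
         ledger = attr(fit, "ledger"))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Headline pipeline report
#'
#' Collects the run's headline quantities (global and biome sinks,
#' per-form efficiencies, deposition totals, member count) together with the
#' recomputed consistency identities of [consistency_report()], plus seed
#' and package-version provenance.
#'
#' @param csink A `csink_result` from [aggregate_csink()] (point estimate
#'   run).
#' @param ensemble Optional `ensemble_result` from [run_ensemble()].
#' @param seed Seed used for the run (recorded as provenance).
#' @return Named list; serialize with [write_report_json()].
#' @export
pipeline_report <- function(csink, ensemble = NULL, seed = NA_integer_) {
  stopifnot(inherits(csink, "csink_result"))
  rep <- list(
    global_sink_pg = csink$global_total_pg,
    sink_by_form_pg = as.list(csink$global_pg),
    sink_by_biome_pg = as.list(csink$biome_pg),
    efficiency_kgc_per_kgn = as.list(csink$efficiency),
    deposition_tg = as.list(csink$deposition_tg),
    deposition_by_biome_tg = as.list(csink$deposition_biome_tg),
    forest_area_mkm2 = csink$forest_area_mkm2,
    consistency = consistency_report(),
    provenance = list(seed = seed,
                      package_version =
                        as.character(utils::packageVersion("ndepsink"))))
  if (!is.null(ensemble)) {
    rep$ensemble <- list(
      n_members = ensemble$n_members,
      n_draws_completed = ensemble$n_draws_completed,
      n_draws_skipped = ensemble$n_draws_skipped,
      global_total_pg = ensemble$summary$global_total_pg,
      global_NHx_pg = ensemble$summary$global_NHx_pg,
      global_NOy_pg = ensemble$summary$global_NOy_pg)
  }
  rep
}

#' @rdname pipeline_report
#' @param report A report list from [pipeline_report()].
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
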