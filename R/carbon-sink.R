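# Stoichiometric conversion of retained deposition N into an annual C sink:
# N entering wood and soil organic matter is multiplied by the compartment
# C/N ratio, with a flexible wood stoichiometry factor f that decays as N
# deposition saturates tree growth, and a fixed fraction of soil-retained N
# counted as immobilized in persistent soil organic matter.

#' Stoichiometry set for the C-sink calculation
#'
#' @param cn_wood Wood C/N ratio (scalar or matrix).
#' @param cn_org Organic-soil-layer C/N ratio (scalar or matrix).
#' @param cn_min Mineral-soil C/N ratio (scalar or matrix).
#' @param soil_immobilization Fraction of soil-retained N immobilized in
#'   persistent soil organic matter (default 0.8); applied to both the
#'   organic-layer and mineral-soil terms.
#' @param f_breakpoints Data frame `n_dep`, `f` anchoring the flexible wood
#'   stoichiometry: default `f = 1` up to 15, 0.5 at 30, 0 at and beyond
#'   100 kg N ha^-1 yr^-1, linear in between.
#' @return A `stoichiometry_set`.
#' @export
stoichiometry_set <- function(cn_wood, cn_org, cn_min,
                              soil_immobilization = 0.8,
                              f_breakpoints = data.frame(
                                n_dep = c(15, 30, 100), f = c(1, 0.5, 0))) {
  if (any(cn_wood <= 0) || any(cn_org <= 0) || any(cn_min <= 0))
    stop("config error: C/N ratios must be positive", call. = FALSE)
  if (soil_immobilization < 0 || soil_immobilization > 1)
    stop("config error: soil_immobilization must lie in [0, 1]",
         call. = FALSE)
  bp <- f_breakpoints
  if (!all(c("n_dep", "f") %in% names(bp)) || nrow(bp) < 2 ||
      any(diff(bp$n_dep) <= 0) || any(diff(bp$f) > 0) ||
      any(bp$f < 0 | bp$f > 1))
    stop("config error: malformed f breakpoints", call. = FALSE)
  structure(list(cn_wood = cn_wood, cn_org = cn_org, cn_min = cn_min,
                 soil_immobilization = soil_immobilization,
                 f_breakpoints = bp),
            class = "stoichiometry_set")
}

#' Flexible wood stoichiometry factor
#'
#' Piecewise-linear, continuous and non-increasing response of effective wood
#' C/N to N load: `f = 1` at and below the first breakpoint (growth fully
#' N-responsive), declining to 0 at the last (no further growth response).
#'
#' @param n_dep N deposition, kg N ha^-1 yr^-1 (vector or matrix, >= 0).
#' @param breakpoints Data frame `n_dep`, `f` (default as in
#'   [stoichiometry_set()]).
#' @return Factor in `[0, 1]`, same shape as `n_dep`.
#' @examples
#' f_wood(c(10, 22.5, 30, 100)) # 1, 0.75, 0.5, 0
#' @export
f_wood <- function(n_dep, breakpoints = data.frame(n_dep = c(15, 30, 100),
                                                   f = c(1, 0.5, 0))) {
  if (any(n_dep < 0, na.rm = TRUE))
    stop("domain error: n_dep must be >= 0", call. = FALSE)
  if (nrow(breakpoints) < 2 || any(diff(breakpoints$n_dep) <= 0) ||
      any(diff(breakpoints$f) > 0))
    stop("config error: malformed breakpoints", call. = FALSE)
  out <- stats::approx(breakpoints$n_dep, breakpoints$f, xout = as.numeric(n_dep),
                       rule = 2)$y
  if (is.matrix(n_dep)) matrix(out, nrow(n_dep), ncol(n_dep)) else out
}

#' Per-cell N-induced C sink
#'
#' \deqn{C_{sink} = N_{dep} (N^R_{org} \tfrac{C}{N}_{org} s
#'   + N^R_{min} \tfrac{C}{N}_{min} s
#'   + N^R_{wood} \tfrac{C}{N}_{wood} f)}
#' where the retention fractions are percent of the form's deposition, `s` is
#' the soil-immobilization fraction and `f` the flexible wood factor.
#' Non-woody plant retention (foliage, fine tissue) contributes no persistent
#' C and enters with weight zero.
#'
#' @param n_dep Deposition of the form being converted, kg N ha^-1 yr^-1.
#' @param frac_wood,frac_org,frac_min Retention fractions, percent.
#' @param stoich A [stoichiometry_set()].
#' @param n_dep_total Deposition used to evaluate `f` (defaults to `n_dep`;
#'   pass total NHx + NOy deposition so growth saturation responds to the
#'   whole N load even for a single form's sink).
#' @return C sink in kg C ha^-1 yr^-1, same shape as `n_dep`.
#' @examples
#' s <- stoichiometry_set(cn_wood = 300, cn_org = 30, cn_min = 15)
#' csink_cell(10, frac_wood = 10, frac_org = 30, frac_min = 20, stoich = s)
#' # 300 + 72 + 24 = 396
#' @export
csink_cell <- function(n_dep, frac_wood, frac_org, frac_min, stoich,
                       n_dep_total = n_dep) {
  stopifnot(inherits(stoich, "stoichiometry_set"))
  if (any(n_dep < 0, na.rm = TRUE))
    stop("domain error: n_dep must be >= 0", call. = FALSE)
  s <- stoich$soil_immobilization
  f <- f_wood(n_dep_total, stoich$f_breakpoints)
  n_dep * (frac_org / 100 * stoich$cn_org * s +
             frac_min / 100 * stoich$cn_min * s +
             frac_wood / 100 * stoich$cn_wood * f)
}

#' Per-form C-sink maps from retention maps and a deposition map
#'
#' @param maps Named list `NHx`/`NOy` of `retention_maps` (see
#'   [upscale_retention()]).
#' @param deposition One deposition map: `list(nhx, noy)` matrices,
#'   kg N ha^-1 yr^-1.
#' @param stoich A [stoichiometry_set()].
#' @param f_from_total If `TRUE` (default) the wood factor `f` is evaluated
#'   from total NHx + NOy deposition; otherwise from each form alone.
#' @return List of matrices `NHx`, `NOy`, `total` (kg C ha^-1 yr^-1).
#' @export
csink_map <- function(maps, deposition, stoich, f_from_total = TRUE) {
  tot_dep <- deposition$nhx + deposition$noy
  one <- function(form, dep) {
    m <- maps[[form]]
    csink_cell(dep, m$frac_wood, m$frac_org, m$frac_min, stoich,
               n_dep_total = if (f_from_total) tot_dep else dep)
  }
  nhx <- one("NHx", deposition$nhx)
  noy <- one("NOy", deposition$noy)
  list(NHx = nhx, NOy = noy, total = nhx + noy)
}

#' Aggregate a C-sink map to biome and global totals
#'
#' Weights each cell's per-hectare sink by its spherical area and forest
#' cover, sums over latitude-band biomes ([biome_bands()]) and globally, and
#' derives C-gain efficiencies (kg C per kg N deposited) per form and
#' overall. Biome totals sum to the global total by construction.
#'
#' @param sink Output of [csink_map()].
#' @param grid The [grid_stack()] (for areas, latitudes and forest cover).
#' @param deposition The deposition map used for the sink (for efficiency
#'   denominators).
#' @param mask Logical forest mask (default [forest_mask()] at 0.2).
#' @return A `csink_result`: `global_total_pg` (Pg C yr^-1), `global_pg` per
#'   form, `biome_pg` (named vector), `efficiency` (kg C kg^-1 N per form and
#'   overall), `deposition_tg` per form/biome/global (Tg N yr^-1),
#'   `forest_area_mkm2`, and the per-cell `cell_sink` maps.
#' @export
aggregate_csink <- function(sink, grid, deposition,
                            mask = forest_mask(grid)) {
  stopifnot(inherits(grid, "grid_stack"))
  area <- cell_area_ha(grid)
  w <- area * grid$layers$forest_cover * mask # forested ha per cell
  biome <- biome_bands(grid$lat)
  tot_kg <- function(x) sum(x * w) # per-ha rate -> kg yr^-1
  by_biome <- function(x) {
    rs <- rowSums(x * w)
    tapply(rs, biome, sum, default = 0)
  }
  dep_kg <- c(NHx = tot_kg(deposition$nhx), NOy = tot_kg(deposition$noy))
  sink_kg <- c(NHx = tot_kg(sink$NHx), NOy = tot_kg(sink$NOy))
  eff <- c(sink_kg / dep_kg, overall = sum(sink_kg) / sum(dep_kg))
  dep_tot <- deposition$nhx + deposition$noy
  structure(list(
    global_total_pg = sum(sink_kg) / 1e12,
    global_pg = sink_kg / 1e12,
    biome_pg = by_biome(sink$total) / 1e12,
    efficiency = eff,
    deposition_tg = c(dep_kg / 1e9, total = sum(dep_kg) / 1e9),
    deposition_biome_tg = by_biome(dep_tot) / 1e9,
    forest_area_mkm2 = sum(w) / 1e8, # ha -> million km^2
    cell_sink = sink),
    class = "csink_result")
}

#' @export
print.csink_result <- function(x, ...) {
  cat(sprintf("N-induced forest C sink: %.3f Pg C yr-1 (NHx %.3f, NOy %.3f)\n",
              x$global_total_pg, x$global_pg[["NHx"]], x$global_pg[["NOy"]]))
  cat(sprintf("  biomes (Pg C yr-1): %s\n",
              paste(sprintf("%s %.3f", names(x$biome_pg), x$biome_pg),
                    collapse = ", ")))
  cat(sprintf("  efficiency (kg C kg-1 N): NHx %.1f, NOy %.1f, overall %.1f\n",
              x$efficiency[["NHx"]], x$efficiency[["NOy"]],
              x$efficiency[["overall"]]))
  cat(sprintf("  forest deposition: %.2f Tg N yr-1 on %.1f Mkm2\n",
              x$deposition_tg[["total"]], x$forest_area_mkm2))
  invisible(x)
}
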