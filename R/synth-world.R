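# Gridded-world generator and the grid-stack container. Real-data analogues
# (1-km NPP, soil and deposition products) are out of scope: worlds here are
# smooth random fields on a coarse lat/lon grid spanning the site-table
# predictor ranges, which is all the downstream formulas need.

#' Co-registered stack of raster layers
#'
#' A minimal container for 2-D fields on a regular latitude/longitude grid.
#' Layers are `ny x nx` matrices (row 1 = southernmost band); cell-edge
#' coordinates are stored so per-cell spherical areas are exact.
#'
#' @param layers Named list of `ny x nx` numeric matrices.
#' @param lat_bounds Strictly increasing vector of `ny + 1` cell-edge
#'   latitudes, degrees.
#' @param lon_bounds Strictly increasing vector of `nx + 1` cell-edge
#'   longitudes, degrees.
#' @param units Named character vector of layer units.
#' @return An object of class `grid_stack` with `lat`/`lon` cell centres.
#' @export
grid_stack <- function(layers, lat_bounds, lon_bounds, units = character()) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  ny <- length(lat_bounds) - 1L
  nx <- length(lon_bounds) - 1L
  if (any(diff(lat_bounds) <= 0) || any(diff(lon_bounds) <= 0))
    stop("coordinates must be strictly monotone", call. = FALSE)
  for (nm in names(layers)) {
    d <- dim(layers[[nm]])
    if (is.null(d) || d[1] != ny || d[2] != nx)
      stop("layer ", nm, " is not co-registered (expected ", ny, "x", nx, ")",
           call. = FALSE)
  }
  if ("forest_cover" %in% names(layers)) {
    fc <- layers$forest_cover
    if (any(fc < 0 | fc > 1, na.rm = TRUE))
      stop("forest_cover must lie in [0, 1]", call. = FALSE)
  }
  structure(list(layers = layers,
                 lat = (lat_bounds[-1] + lat_bounds[-(ny + 1)]) / 2,
                 lon = (lon_bounds[-1] + lon_bounds[-(nx + 1)]) / 2,
                 lat_bounds = lat_bounds, lon_bounds = lon_bounds,
                 units = units),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("grid_stack: %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              length(x$lat), length(x$lon), min(x$lat_bounds),
              max(x$lat_bounds), min(x$lon_bounds), max(x$lon_bounds)))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell area on the sphere
#'
#' Exact spherical-zone area of each grid cell,
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}, in hectares
#' (Earth radius 6371.0088 km).
#'
#' @param grid A [grid_stack()].
#' @return `ny x nx` matrix of areas in ha.
#' @export
cell_area_ha <- function(grid) {
  stopifnot(inherits(grid, "grid_stack"))
  r_km <- 6371.0088
  dlam <- diff(grid$lon_bounds) * pi / 180
  dsin <- diff(sin(grid$lat_bounds * pi / 180))
  outer(dsin, dlam) * r_km^2 * 100 # km^2 -> ha
}

#' Biome band of each grid row
#'
#' Latitude-band classification used for aggregate reporting: tropical for
#' `|lat| < 23.5`, boreal for `|lat| > 50`, temperate in between.
#'
#' @param lat Vector of cell-centre latitudes, degrees.
#' @return Factor with levels tropical, temperate, boreal.
#' @export
biome_bands <- function(lat) {
  a <- abs(lat)
  factor(ifelse(a < 23.5, "tropical", ifelse(a > 50, "boreal", "temperate")),
         levels = c("tropical", "temperate", "boreal"))
}

#' Configuration for the synthetic gridded world
#'
#' @param nx,ny Grid size (>= 4 each).
#' @param lat_span,lon_span Domain edges in degrees.
#' @param n_deposition_maps Number of alternative N-deposition maps
#'   (default 4, mirroring a four-model deposition ensemble).
#' @param wood_cn_sets Numeric vector of wood C/N ratios (default six values
#'   spanning typical stemwood stoichiometry).
#' @param n_dep_range Total N deposition range, kg N ha^-1 yr^-1.
#' @param smooth_passes Number of 3x3 smoothing passes applied to the white
#'   noise underlying every field (controls spatial autocorrelation length).
#' @param seed Integer seed.
#' @return A `world_generator_config` list.
#' @export
world_generator_config <- function(nx = 72, ny = 36,
                                   lat_span = c(-56, 76),
                                   lon_span = c(-180, 180),
                                   n_deposition_maps = 4,
                                   wood_cn_sets = c(150, 200, 250, 300, 350, 400),
                                   n_dep_range = c(6, 54),
                                   smooth_passes = 6,
                                   seed = 1L) {
  if (nx < 4 || ny < 4)
    stop("config error: nx and ny must be >= 4", call. = FALSE)
  if (n_deposition_maps < 1 || length(wood_cn_sets) < 1)
    stop("config error: need at least one deposition map and wood C/N set",
         call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 lat_span = lat_span, lon_span = lon_span,
                 n_deposition_maps = as.integer(n_deposition_maps),
                 wood_cn_sets = wood_cn_sets, n_dep_range = n_dep_range,
                 smooth_passes = as.integer(smooth_passes),
                 seed = as.integer(seed)),
            class = "world_generator_config")
}

# One pass of 3x3 mean smoothing with replicated edges.
smooth_pass <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  up <- m[c(1, seq_len(ny - 1)), , drop = FALSE]
  dn <- m[c(seq_len(ny - 1) + 1, ny), , drop = FALSE]
  lf <- m[, c(1, seq_len(nx - 1)), drop = FALSE]
  rt <- m[, c(seq_len(nx - 1) + 1, nx), drop = FALSE]
  (m + up + dn + lf + rt) / 5
}

# Smooth standard-normal-ish field rescaled linearly onto [lo, hi].
smooth_field <- function(ny, nx, passes, lo, hi, trend = NULL) {
  m <- matrix(stats::rnorm(ny * nx), ny, nx)
  for (i in seq_len(passes)) m <- smooth_pass(m)
  m <- m / stats::sd(m)
  if (!is.null(trend)) m <- m + trend
  rng <- range(m)
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Generate a synthetic gridded world
#'
#' Builds spatially autocorrelated predictor layers within the site-table
#' ranges (MAT and NPP additionally carry a poleward-cooling latitudinal
#' trend), a forest-cover fraction in `[0, 1]`, stoichiometric C/N layers for
#' the organic and mineral soil, and an ensemble of total-N-deposition maps
#' split into NHx and NOy by a smooth reduced-fraction field.
#'
#' @param cfg A [world_generator_config()].
#' @param ranges Predictor ranges (defaults to those of
#'   [site_generator_config()]).
#' @return List with `grid` (a [grid_stack()] whose layers include the nine
#'   predictors and `forest_cover`), `deposition` (list of length
#'   `n_deposition_maps`, each `list(nhx, noy)` matrices, kg N ha^-1 yr^-1),
#'   `cn_org`, `cn_min` (matrices), and `wood_cn_sets`.
#' @export
make_world <- function(cfg = world_generator_config(),
                       ranges = site_generator_config()$ranges) {
  stopifnot(inherits(cfg, "world_generator_config"))
  with_seed(cfg$seed, {
    ny <- cfg$ny; nx <- cfg$nx; sp <- cfg$smooth_passes
    lat_bounds <- seq(cfg$lat_span[1], cfg$lat_span[2], length.out = ny + 1)
    lon_bounds <- seq(cfg$lon_span[1], cfg$lon_span[2], length.out = nx + 1)
    lat <- (lat_bounds[-1] + lat_bounds[-(ny + 1)]) / 2
    # poleward cooling trend shared by MAT and NPP, in sd units of the noise
    trend <- matrix(rep(2 * (1 - abs(lat) / 90), nx), ny, nx)
    mk <- function(nm, tr = NULL)
      smooth_field(ny, nx, sp, ranges[[nm]][1], ranges[[nm]][2], tr)
    layers <- list(
      mat = mk("mat", trend), map = mk("map"), soil_cn = mk("soil_cn"),
      clay = mk("clay"), leaf_cn = mk("leaf_cn"),
      n_dep = mk("n_dep"), org_mass = mk("org_mass"),
      wood_biomass = mk("wood_biomass"), npp = mk("npp", trend),
      forest_cover = smooth_field(ny, nx, sp, 0, 1))
    units <- c(mat = "degC", map = "mm yr-1", soil_cn = "ratio", clay = "%",
               leaf_cn = "ratio", n_dep = "kg N ha-1 yr-1",
               org_mass = "Mg ha-1", wood_biomass = "Mg ha-1",
               npp = "g C m-2 yr-1", forest_cover = "fraction")
    base <- smooth_field(ny, nx, sp, cfg$n_dep_range[1], cfg$n_dep_range[2])
    deposition <- lapply(seq_len(cfg$n_deposition_maps), function(k) {
      tot <- smooth_field(ny, nx, sp, cfg$n_dep_range[1], cfg$n_dep_range[2])
      tot <- (base + tot) / 2 # maps share a common pattern plus model spread
      frac_nhx <- smooth_field(ny, nx, sp, 0.35, 0.75)
      list(nhx = tot * frac_nhx, noy = tot * (1 - frac_nhx))
    })
    list(grid = grid_stack(layers, lat_bounds, lon_bounds, units),
         deposition = deposition,
         cn_org = smooth_field(ny, nx, sp, 20, 45),
         cn_min = smooth_field(ny, nx, sp, 8, 20),
         wood_cn_sets = cfg$wood_cn_sets)
  })
}
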