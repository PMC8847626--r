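# Monte Carlo uncertainty propagation: resample sites, refit and re-upscale
# the retention relations, and cross every retention draw with every
# deposition map and wood C/N set when converting to the C sink, summarizing
# the member ensemble with percentile confidence intervals.

#' Ensemble configuration
#'
#' @param n_retention_draws Number of site-resampling draws (the full-scale
#'   analysis uses 1000; the desk default is 50).
#' @param n_sites_per_draw Sites drawn without replacement per draw
#'   (default 10 of the 13).
#' @param ci_level Two-sided confidence level (default 0.95).
#' @param seed Master seed; per-draw substreams are spawned from it so each
#'   draw is individually reproducible.
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(n_retention_draws = 50, n_sites_per_draw = 10,
                            ci_level = 0.95, seed = 1L) {
  if (n_retention_draws < 1 || n_sites_per_draw < 1)
    stop("config error: counts must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("config error: ci_level must lie in (0, 1)", call. = FALSE)
  structure(list(n_retention_draws = as.integer(n_retention_draws),
                 n_sites_per_draw = as.integer(n_sites_per_draw),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Summarize an ensemble of scalar members
#'
#' Mean, standard deviation and empirical percentile bounds at
#' `(1 - ci_level)/2` and `(1 + ci_level)/2`. Deterministic given the
#' members and invariant to their order.
#'
#' @param members Numeric vector (>= 2 values).
#' @param ci_level Two-sided confidence level.
#' @return List `mean`, `sd`, `lower`, `upper`, `n`.
#' @export
summarize_ensemble <- function(members, ci_level = 0.95) {
  members <- members[!is.na(members)]
  if (length(members) < 2)
    stop("summary error: need at least 2 members", call. = FALSE)
  q <- stats::quantile(members, probs = c((1 - ci_level) / 2,
                                          (1 + ci_level) / 2),
                       names = FALSE)
  list(mean = mean(members), sd = stats::sd(members),
       lower = q[1], upper = q[2], n = length(members))
}

#' Run the site-resampling x deposition x wood-C/N ensemble
#'
#' For each retention draw, subsamples `n_sites_per_draw` sites without
#' replacement (the same subset for both tracer forms), refits the retention
#' models and re-upscales. Each retention draw is then crossed with every
#' deposition map and every wood C/N set to produce one C-sink member, so
#' the member count is `draws x maps x wood sets`. Draws whose model
#' selection fails (every subset excluded by the VIF cutoff) are skipped and
#' logged, never imputed.
#'
#' @param sites Site table.
#' @param world Output of [make_world()] (grid, deposition maps, C/N layers,
#'   wood C/N sets).
#' @param cfg An [ensemble_config()].
#' @param mode,selection,candidates,vif_cutoff Passed to
#'   [upscale_retention()].
#' @param soil_immobilization,f_breakpoints Stoichiometry settings shared by
#'   all members.
#' @param forest_threshold Forest-cover cutoff for the mask.
#' @return An `ensemble_result`: `summary` (per-quantity ensemble summaries
#'   for the global sink, per-form sinks and biome sinks, in Pg C yr^-1),
#'   `members` (data frame ledger: draw, deposition map, wood C/N, selected
#'   predictors, global sinks), `cell_sd` (per-form per-cell ensemble SD of
#'   the loss fraction across retention draws), `n_draws_completed`,
#'   `n_draws_skipped`.
#' @export
run_ensemble <- function(sites, world, cfg = ensemble_config(),
                         mode = c("chained", "regression"),
                         selection = c("subset", "fixed"),
                         candidates = candidate_predictors(),
                         vif_cutoff = 3,
                         soil_immobilization = 0.8,
                         f_breakpoints = data.frame(n_dep = c(15, 30, 100),
                                                    f = c(1, 0.5, 0)),
                         forest_threshold = 0.2) {
  mode <- match.arg(mode); selection <- match.arg(selection)
  stopifnot(inherits(cfg, "ensemble_config"))
  site_ids <- unique(sites$site_id)
  if (cfg$n_sites_per_draw > length(site_ids))
    stop("config error: n_sites_per_draw exceeds available sites",
         call. = FALSE)
  grid <- world$grid
  mask <- forest_mask(grid, forest_threshold)
  draw_seeds <- with_seed(cfg$seed,
                          sample.int(.Machine$integer.max - 1L,
                                     cfg$n_retention_draws))
  members <- list(); biome_members <- list()
  # loss-map moments accumulated relative to the first completed draw to
  # avoid catastrophic cancellation when draws are (near-)identical
  acc <- list(NHx = list(s = 0, s2 = 0, ref = NULL),
              NOy = list(s = 0, s2 = 0, ref = NULL))
  skipped <- 0L; completed <- 0L
  for (d in seq_len(cfg$n_retention_draws)) {
    sub_ids <- with_seed(draw_seeds[d],
                         sample(site_ids, cfg$n_sites_per_draw))
    sub <- sites[sites$site_id %in% sub_ids, , drop = FALSE]
    maps <- tryCatch(
      suppressWarnings(upscale_retention(sub, grid, mode = mode,
                                         selection = selection,
                                         candidates = candidates,
                                         vif_cutoff = vif_cutoff)),
      error = function(e) e)
    if (inherits(maps, "error")) {
      skipped <- skipped + 1L
      members[[length(members) + 1L]] <- data.frame(
        draw = d, dep_map = NA_integer_, wood_cn = NA_real_,
        status = "skipped", note = conditionMessage(maps),
        predictors_NHx = NA_character_, predictors_NOy = NA_character_,
        sink_NHx_pg = NA_real_, sink_NOy_pg = NA_real_,
        sink_total_pg = NA_real_)
      next
    }
    completed <- completed + 1L
    for (f in c("NHx", "NOy")) {
      if (is.null(acc[[f]]$ref)) acc[[f]]$ref <- maps[[f]]$frac_loss
      dev <- maps[[f]]$frac_loss - acc[[f]]$ref
      acc[[f]]$s <- acc[[f]]$s + dev
      acc[[f]]$s2 <- acc[[f]]$s2 + dev^2
    }
    mods <- attr(maps, "models")
    pred_str <- vapply(c("NHx", "NOy"), function(f)
      paste(vapply(mods[[f]], function(m)
        paste(m$predictors, collapse = "+"), character(1)),
        collapse = "; "), character(1))
    for (k in seq_along(world$deposition)) {
      dep <- world$deposition[[k]]
      for (w in world$wood_cn_sets) {
        stoich <- stoichiometry_set(
          cn_wood = w, cn_org = world$cn_org, cn_min = world$cn_min,
          soil_immobilization = soil_immobilization,
          f_breakpoints = f_breakpoints)
        sink <- csink_map(maps, dep, stoich)
        res <- aggregate_csink(sink, grid, dep, mask)
        members[[length(members) + 1L]] <- data.frame(
          draw = d, dep_map = k, wood_cn = w, status = "ok", note = "",
          predictors_NHx = pred_str[["NHx"]],
          predictors_NOy = pred_str[["NOy"]],
          sink_NHx_pg = res$global_pg[["NHx"]],
          sink_NOy_pg = res$global_pg[["NOy"]],
          sink_total_pg = res$global_total_pg)
        biome_members[[length(biome_members) + 1L]] <- res$biome_pg
      }
    }
  }
  ledger <- do.call(rbind, members)
  ok <- ledger[ledger$status == "ok", , drop = FALSE]
  if (nrow(ok) >= 2) {
    biome_mat <- do.call(rbind, biome_members)
    summ <- list(
      global_total_pg = summarize_ensemble(ok$sink_total_pg, cfg$ci_level),
      global_NHx_pg = summarize_ensemble(ok$sink_NHx_pg, cfg$ci_level),
      global_NOy_pg = summarize_ensemble(ok$sink_NOy_pg, cfg$ci_level))
    for (b in colnames(biome_mat))
      summ[[paste0("biome_", b, "_pg")]] <-
        summarize_ensemble(biome_mat[, b], cfg$ci_level)
  } else {
    summ <- NULL
  }
  nd <- completed
  cell_sd <- lapply(acc, function(a) {
    if (nd < 2) return(NULL)
    v <- (a$s2 - a$s^2 / nd) / (nd - 1)
    sqrt(pmax(v, 0))
  })
  structure(list(summary = summ, members = ledger, cell_sd = cell_sd,
                 n_draws_completed = completed, n_draws_skipped = skipped,
                 n_members = nrow(ok), ci_level = cfg$ci_level),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  g <- x$summary$global_total_pg
  cat(sprintf(
    "ensemble_result: %d members (%d draws completed, %d skipped)\n",
    x$n_members, x$n_draws_completed, x$n_draws_skipped))
  cat(sprintf("  global sink: %.3f Pg C yr-1 (%.0f%% CI %.3f-%.3f)\n",
              g$mean, 100 * x$ci_level, g$lower, g$upper))
  invisible(x)
}
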