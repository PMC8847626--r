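# Upscaling fitted retention relations over gridded predictors into per-form
# maps of the deposited-N fate: plant (with its woody share), organic layer,
# mineral soil and loss, summing to 100 % of deposition at every forest cell.

#' Forest mask from the cover layer
#'
#' @param grid A [grid_stack()] with a `forest_cover` layer.
#' @param threshold Cover fraction above which a cell counts as forest
#'   (default 0.2; 0.1 is the common alternative cutoff).
#' @return Logical matrix; masked-out cells are excluded from aggregation.
#' @export
forest_mask <- function(grid, threshold = 0.2) {
  stopifnot(inherits(grid, "grid_stack"))
  if (is.null(grid$layers$forest_cover))
    stop("schema error: no forest_cover layer", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("config error: threshold must lie in [0, 1]", call. = FALSE)
  grid$layers$forest_cover > threshold
}

clip01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

#' Chained allocation of the non-lost, non-organic tracer
#'
#' Given the loss fraction and organic-layer retention (percent of deposited
#' N) plus the plant:(plant+mineral) ratio and the woody share of plant N
#' (both fractions in `[0, 1]`), allocates the remaining
#' `available = 100 - loss - org` between plant and mineral soil and splits
#' out the woody sub-share. If `loss + org` exceeds 100 the available pool is
#' clipped to 0 with a warning.
#'
#' @param loss_pct,org_pct Percent of deposited N (vectors or matrices).
#' @param plant_ratio,wood_share Fractions in `[0, 1]`.
#' @return List of `plant`, `min`, `wood` (percent of deposited N);
#'   `loss + org + plant + min = 100` wherever `loss + org <= 100`.
#' @examples
#' chained_allocation(30, 25, 0.4, 0.5) # plant 18, min 27, wood 9
#' @export
chained_allocation <- function(loss_pct, org_pct, plant_ratio, wood_share) {
  stopifnot(all(plant_ratio >= 0 & plant_ratio <= 1, na.rm = TRUE),
            all(wood_share >= 0 & wood_share <= 1, na.rm = TRUE))
  over <- loss_pct + org_pct > 100
  if (any(over, na.rm = TRUE))
    warning(sum(over, na.rm = TRUE),
            " cell(s) with loss + organic > 100; available pool set to 0",
            call. = FALSE)
  avail <- pmax(100 - loss_pct - org_pct, 0)
  plant <- plant_ratio * avail
  list(plant = plant, min = (1 - plant_ratio) * avail,
       wood = wood_share * plant)
}

new_retention_maps <- function(form, plant, wood, org, min, loss,
                               extrapolation = NULL) {
  structure(list(form = form, frac_plant = plant, frac_wood = wood,
                 frac_org = org, frac_min = min, frac_loss = loss),
            extrapolation = extrapolation, class = "retention_maps")
}

#' @export
print.retention_maps <- function(x, ...) {
  cat(sprintf("retention_maps (%s): %d x %d cells\n", x$form,
              nrow(x$frac_loss), ncol(x$frac_loss)))
  for (nm in c("frac_plant", "frac_wood", "frac_org", "frac_min", "frac_loss"))
    cat(sprintf("  %-10s mean %6.2f %%\n", sub("frac_", "", nm),
                mean(x[[nm]])))
  invisible(x)
}

# Cells where any predictor used by any model leaves its training range.
extrapolation_mask <- function(models, grid) {
  out <- NULL
  for (fit in models) {
    for (p in fit$predictors) {
      lay <- grid$layers[[p]]
      bad <- lay < fit$ranges[1, p] | lay > fit$ranges[2, p]
      out <- if (is.null(out)) bad else out | bad
    }
  }
  out
}

#' Per-pool regression upscaling
#'
#' Evaluates the selected per-pool regressions at every cell, clips each
#' prediction to `[0, 100]`, then rescales plant, organic, mineral and loss
#' proportionally so they sum to exactly 100 (cells where all four predict 0
#' are assigned full loss). The woody fraction is the predicted woody share
#' applied to the normalized plant fraction, capped at the plant fraction.
#'
#' @param models Model list from
#'   `fit_retention_models(..., mode = "regression")`: elements `plant`,
#'   `org`, `min`, `loss`, `wood_share`.
#' @param grid A [grid_stack()] carrying every predictor layer the models use.
#' @param form Form label stored on the result (`"NHx"` or `"NOy"`).
#' @return A `retention_maps` object with an `extrapolation` attribute
#'   (logical matrix flagging cells outside the training predictor hull).
#' @export
predict_fractions_regression <- function(models, grid, form = "NHx") {
  need <- c("plant", "org", "min", "loss", "wood_share")
  miss <- setdiff(need, names(models))
  if (length(miss))
    stop("model list lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  pr <- lapply(models[need], predict, newdata = grid$layers)
  plant <- clip01(pr$plant); org <- clip01(pr$org)
  mins <- clip01(pr$min);   loss <- clip01(pr$loss)
  total <- plant + org + mins + loss
  zero <- total <= 0
  total[zero] <- 100
  loss[zero] <- 100
  scale <- 100 / total
  plant <- plant * scale; org <- org * scale
  mins <- mins * scale;  loss <- loss * scale
  share <- clip01(pr$wood_share) / 100
  wood <- pmin(share * plant, plant)
  new_retention_maps(form, plant, wood, org, mins, loss,
                     extrapolation_mask(models[need], grid))
}

#' Chained (allocation-cascade) upscaling
#'
#' Predicts the loss fraction and organic-layer retention from their
#' regressions (clipped to `[0, 100]`, organic additionally to `100 - loss`),
#' then allocates the remainder between plant and mineral soil by the
#' predicted plant:(plant+mineral) ratio and splits out the woody share
#' (ratio and share clipped to `[0, 1]`). Fractions sum to 100 identically.
#'
#' @param models Model list from
#'   `fit_retention_models(..., mode = "chained")`: elements `loss`, `org`,
#'   `plant_ratio`, `wood_share`.
#' @inheritParams predict_fractions_regression
#' @return A `retention_maps` object with an `extrapolation` attribute.
#' @export
predict_fractions_chained <- function(models, grid, form = "NHx") {
  need <- c("loss", "org", "plant_ratio", "wood_share")
  miss <- setdiff(need, names(models))
  if (length(miss))
    stop("model list lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  loss <- clip01(predict(models$loss, grid$layers))
  org <- clip01(predict(models$org, grid$layers))
  org <- pmin(org, 100 - loss)
  ratio <- clip01(predict(models$plant_ratio, grid$layers), 0, 1)
  share <- clip01(predict(models$wood_share, grid$layers)) / 100
  parts <- chained_allocation(loss, org, ratio, share)
  new_retention_maps(form, parts$plant, parts$wood, org, parts$min, loss,
                     extrapolation_mask(models[need], grid))
}

#' Upscale retention fractions for both deposition forms
#'
#' @param sites Site table ([make_site_table()] format).
#' @param grid A [grid_stack()] with all predictor layers.
#' @param mode `"chained"` (default) or `"regression"`; see
#'   [predict_fractions_chained()] and [predict_fractions_regression()].
#' @param selection,candidates,vif_cutoff Passed to
#'   [fit_retention_models()].
#' @return Named list `NHx`/`NOy` of `retention_maps`, with the fitted model
#'   lists attached as attribute `models`.
#' @export
upscale_retention <- function(sites, grid, mode = c("chained", "regression"),
                              selection = c("subset", "fixed"),
                              candidates = candidate_predictors(),
                              vif_cutoff = 3) {
  mode <- match.arg(mode); selection <- match.arg(selection)
  fun <- if (mode == "chained") predict_fractions_chained
         else predict_fractions_regression
  models <- lapply(c(NHx = "NHx", NOy = "NOy"), fit_retention_models,
                   sites = sites, mode = mode, selection = selection,
                   candidates = candidates, vif_cutoff = vif_cutoff)
  maps <- lapply(c(NHx = "NHx", NOy = "NOy"), function(f)
    fun(models[[f]], grid, form = f))
  attr(maps, "models") <- models
  maps
}
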