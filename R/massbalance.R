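#' Pool measurement for isotopic mass balance
#'
#' Bundles the nitrogen pool size and \eqn{^{15}}N abundance of one ecosystem
#' compartment before and about one year after tracer addition. Pool sizes are
#' in kg N ha\eqn{^{-1}}; isotopic abundance is atom % \eqn{^{15}}N
#' (natural abundance is about 0.3663%).
#'
#' @param pool_name Compartment label, e.g. `"plant"`, `"organic"`, `"mineral"`,
#'   `"wood"`, `"understory"`.
#' @param n_pool_before N pool before labelling (kg N ha^-1), non-negative.
#' @param atom_pct_before Atom % 15N before labelling, in (0, 100).
#' @param atom_pct_after Atom % 15N after labelling, non-negative and < 100.
#' @param n_pool_after Optional N pool after labelling (kg N ha^-1). Needed only
#'   for the full two-inventory balance; the constant-pool recovery uses the
#'   before pool alone.
#' @return An object of class `pool_measurement`.
#' @seealso [recovery_percent()], [full_balance_recovery()]
#' @export
pool_measurement <- function(pool_name, n_pool_before, atom_pct_before,
                             atom_pct_after, n_pool_after = NA_real_) {
  stopifnot(is.character(pool_name), length(pool_name) == 1L)
  if (!is.finite(n_pool_before) || n_pool_before < 0)
    stop("invalid-pool: n_pool_before must be finite and >= 0", call. = FALSE)
  if (!is.na(n_pool_after) && n_pool_after < 0)
    stop("invalid-pool: n_pool_after must be >= 0", call. = FALSE)
  if (!is.finite(atom_pct_before) || atom_pct_before <= 0 || atom_pct_before >= 100)
    stop("invalid-pool: atom_pct_before must lie in (0, 100)", call. = FALSE)
  if (!is.finite(atom_pct_after) || atom_pct_after < 0 || atom_pct_after >= 100)
    stop("invalid-pool: atom_pct_after must lie in [0, 100)", call. = FALSE)
  structure(
    list(pool_name = pool_name,
         n_pool_before = n_pool_before,
         n_pool_after = n_pool_after,
         atom_pct_before = atom_pct_before,
         atom_pct_after = atom_pct_after),
    class = "pool_measurement")
}

#' Tracer application
#'
#' The mass of \eqn{^{15}}N added to a plot, by chemical form. Multi-year
#' additions are represented by their cumulative added mass, so the recovery
#' denominator is the total tracer ever applied.
#'
#' @param form `"ammonium"` or `"nitrate"`.
#' @param n15_added Added 15N mass (kg 15N ha^-1), strictly positive.
#' @return An object of class `tracer_application`.
#' @export
tracer_application <- function(form = c("ammonium", "nitrate"), n15_added) {
  form <- match.arg(form)
  if (!is.finite(n15_added) || n15_added <= 0)
    stop("invalid-tracer: n15_added must be finite and > 0", call. = FALSE)
  structure(list(form = form, n15_added = n15_added),
            class = "tracer_application")
}

#' Percent recovery of added tracer under the constant-pool assumption
#'
#' Recovery of the added \eqn{^{15}}N in one compartment from the rise in its
#' isotopic abundance, assuming the N pool itself did not change over the
#' experiment:
#' \deqn{rec = 100 \times \frac{N_{pool,before} \times (A_{after} - A_{before})/100}{^{15}N_{added}}}
#' where \eqn{A} is atom % \eqn{^{15}}N. This is the standard estimator when
#' pool change over ~1 year is too small to detect by inventory.
#'
#' @param pool A [pool_measurement()].
#' @param tracer A [tracer_application()].
#' @return Recovery as percent of the added 15N (may be negative if the
#'   measured abundance fell; see [floor_recoveries()] for the flooring policy).
#' @examples
#' p <- pool_measurement("mineral", 1000, 0.3663, 0.3763)
#' recovery_percent(p, tracer_application("ammonium", 0.1)) # 100
#' @export
recovery_percent <- function(pool, tracer) {
  stopifnot(inherits(pool, "pool_measurement"),
            inherits(tracer, "tracer_application"))
  100 * pool$n_pool_before *
    (pool$atom_pct_after - pool$atom_pct_before) / 100 / tracer$n15_added
}

#' Percent recovery from the full two-inventory mass balance
#'
#' Uses both the before and after pool inventories:
#' \deqn{rec = 100 \times \frac{(N_{after} A_{after} - N_{before} A_{before})/100}{^{15}N_{added}}}
#' It reduces exactly to [recovery_percent()] when the pool is unchanged.
#' Apparent pool growth at unchanged abundance inflates this estimator (the
#' inventory picks up unlabelled N), which is why the constant-pool form is
#' preferred for noisy one-year inventories.
#'
#' @inheritParams recovery_percent
#' @return Recovery as percent of the added 15N.
#' @export
full_balance_recovery <- function(pool, tracer) {
  stopifnot(inherits(pool, "pool_measurement"),
            inherits(tracer, "tracer_application"))
  if (is.na(pool$n_pool_after))
    stop("missing-data: n_pool_after is required for the full balance",
         call. = FALSE)
  100 * (pool$n_pool_after * pool$atom_pct_after -
           pool$n_pool_before * pool$atom_pct_before) / 100 / tracer$n15_added
}

#' Floor negative pool recoveries at zero
#'
#' Enrichment noise can push a single-pool recovery slightly below zero;
#' negative mass recovery is unphysical, so values below zero are set to zero.
#' The number of floored values is attached as attribute `n_floored` and
#' reported via a warning so data problems are not silently absorbed.
#'
#' @param recovery_pct Numeric vector of recoveries (percent of added 15N).
#' @return The vector with negatives set to 0 and attribute `n_floored`.
#' @export
floor_recoveries <- function(recovery_pct) {
  neg <- !is.na(recovery_pct) & recovery_pct < 0
  if (any(neg)) {
    warning(sprintf("%d negative pool recover%s floored at 0", sum(neg),
                    if (sum(neg) == 1L) "y" else "ies"), call. = FALSE)
    recovery_pct[neg] <- 0
  }
  structure(recovery_pct, n_floored = sum(neg))
}

#' Whole-ecosystem recovery and loss fraction
#'
#' Sums the recoveries of the non-overlapping compartments (plant including
#' understory, organic soil layer, mineral soil) and attributes the remainder
#' of the added tracer to leaching and gaseous (denitrification) losses.
#' Woody tissue is a sub-share of the plant pool and must not be passed here.
#'
#' @param recoveries Named numeric vector or list of pool recoveries in
#'   percent, with unique names among `"plant"`, `"organic"`, `"mineral"`.
#' @return A list with `ecosystem_pct`, `loss_pct`
#'   (`ecosystem_pct + loss_pct == 100` exactly) and logical `flag_over100`,
#'   raised when summed recoveries exceed 100 so that the loss is negative.
#'   Over-recovery is flagged, not clipped, at this stage.
#' @examples
#' ecosystem_recovery(c(plant = 12, organic = 33, mineral = 24))
#' @export
ecosystem_recovery <- function(recoveries) {
  recoveries <- unlist(recoveries)
  nm <- names(recoveries)
  allowed <- c("plant", "organic", "mineral")
  if (is.null(nm) || !all(nm %in% allowed))
    stop("aggregation error: recoveries must be named among ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (anyDuplicated(nm))
    stop("aggregation error: duplicate pool names", call. = FALSE)
  eco <- sum(recoveries)
  list(ecosystem_pct = eco,
       loss_pct = 100 - eco,
       flag_over100 = eco > 100)
}

#' Plot-level recoveries from a measurement table
#'
#' Applies the constant-pool mass balance to every row of a plot-level
#' measurement table and returns a tidy recovery table. Negative recoveries
#' are floored at zero (see [floor_recoveries()]).
#'
#' @param measurements Data frame with columns `site`, `plot`, `form`, `pool`,
#'   `n_pool_before`, `n_pool_after`, `atom_pct_before`, `atom_pct_after`,
#'   `n15_added`.
#' @return Data frame `site, plot, form, pool, recovery_pct`.
#' @export
plot_recoveries <- function(measurements) {
  req <- c("site", "plot", "form", "pool", "n_pool_before",
           "atom_pct_before", "atom_pct_after", "n15_added")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec <- vapply(seq_len(nrow(measurements)), function(i) {
    row <- measurements[i, ]
    recovery_percent(
      pool_measurement(as.character(row$pool), row$n_pool_before,
                       row$atom_pct_before, row$atom_pct_after),
      tracer_application(as.character(row$form), row$n15_added))
  }, numeric(1))
  rec <- suppressWarnings(floor_recoveries(rec))
  data.frame(site = measurements$site, plot = measurements$plot,
             form = measurements$form, pool = measurements$pool,
             recovery_pct = as.numeric(rec))
}

#' Site-mean recoveries with standard errors
#'
#' Averages plot-level recoveries to one value per site, form and pool, with
#' the standard error over plots (`NA` when a site has a single plot). Paired
#' ammonium/nitrate comparisons are then site-wise on these means.
#'
#' @param plot_table Output of [plot_recoveries()].
#' @return Data frame `site, form, pool, recovery_pct, se, n_plots`.
#' @export
site_mean_recoveries <- function(plot_table) {
  key <- interaction(plot_table$site, plot_table$form, plot_table$pool,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(plot_table, key), function(d) {
    data.frame(site = d$site[1], form = d$form[1], pool = d$pool[1],
               recovery_pct = mean(d$recovery_pct),
               se = stats::sd(d$recovery_pct) / sqrt(nrow(d)),
               n_plots = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$site, out$form, out$pool), , drop = FALSE]
}
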