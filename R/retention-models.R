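# All-subset OLS with small-sample AIC ranking and variance-inflation-factor
# screening: the cross-site retention/loss fractions are regressed on up to
# nine candidate predictors and the minimum-AICc model without collinearity
# (max VIF <= cutoff) is kept per response.

#' Candidate predictors for retention regressions
#'
#' The nine site covariates considered: climate (`mat`, `map`), N status and
#' soil fertility (`soil_cn`, `clay`, `leaf_cn`, `n_dep`), pool sizes
#' (`org_mass`, `wood_biomass`) and productivity (`npp`).
#' @return Character vector of column names.
#' @export
candidate_predictors <- function() {
  c("mat", "map", "soil_cn", "clay", "leaf_cn", "n_dep",
    "org_mass", "wood_biomass", "npp")
}

#' Small-sample corrected AIC from a residual sum of squares
#'
#' Gaussian constant-dropped form
#' \deqn{AICc = n \ln(RSS/n) + 2k' + \frac{2k'(k'+1)}{n - k' - 1}}
#' with \eqn{k' = p + 2} counting the intercept and the error variance.
#' Returns `Inf` when the correction denominator is not positive (model too
#' large for the sample), so such models can never be selected.
#'
#' @param rss Residual sum of squares.
#' @param n Sample size.
#' @param n_predictors Number of slope parameters `p`.
#' @return AICc value.
#' @export
aicc_from_rss <- function(rss, n, n_predictors) {
  kp <- n_predictors + 2
  if (n - kp - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * kp + 2 * kp * (kp + 1) / (n - kp - 1)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} comes from regressing
#' predictor `j` on the remaining predictors (with intercept). A single
#' predictor has `VIF = 1` by convention; perfect collinearity is reported as
#' `Inf`, not raised as an error, so screening can act on it.
#'
#' @param table Data frame holding the predictor columns.
#' @param predictors Character vector of column names.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(table, predictors) {
  X <- as.matrix(table[, predictors, drop = FALSE])
  p <- ncol(X)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("vif: constant predictor column", call. = FALSE)
  if (p == 1L) return(stats::setNames(1, predictors))
  out <- vapply(seq_len(p), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(pmax(out, 1), predictors)
}

#' Fit one ordinary-least-squares subset model
#'
#' @param table Data frame with the response and predictor columns; rows with
#'   missing values in used columns are not allowed.
#' @param response Response column name (fractions fitted on the percent
#'   scale, untransformed).
#' @param predictors Character vector of predictor column names.
#' @return A `retention_fit`: response, predictors, named coefficients
#'   (intercept first), `aicc`, `r2`, per-predictor `vif`, `n`, and the
#'   training ranges of the used predictors (for extrapolation flagging).
#' @export
fit_subset <- function(table, response, predictors) {
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- table[, cols, drop = FALSE]
  if (anyNA(d)) stop("missing values in used columns", call. = FALSE)
  n <- nrow(d); k <- length(predictors)
  if (n <= k + 2)
    stop("sample-size error: need n > k + 2 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  y <- d[[response]]
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, predictors, drop = FALSE]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("singular-fit error: rank-deficient design", call. = FALSE)
  coefs <- qr.coef(qrx, y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  rng <- vapply(predictors, function(p) range(d[[p]]), numeric(2))
  structure(
    list(response = response, predictors = predictors,
         coefficients = coefs,
         aicc = aicc_from_rss(rss, n, k),
         r2 = if (tss > 0) 1 - rss / tss else 0,
         vif = vif(d, predictors),
         n = n, rss = rss,
         ranges = rng),
    class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("retention_fit: %s ~ %s\n  n = %d, R2 = %.3f, AICc = %.2f, max VIF = %.2f\n",
              x$response, paste(x$predictors, collapse = " + "),
              x$n, x$r2, x$aicc, max(x$vif)))
  invisible(x)
}

#' Predict from a retention fit
#'
#' Evaluates the linear predictor on new data (a data frame or a named list
#' of co-registered matrices, in which case a matrix is returned).
#'
#' @param object A `retention_fit`.
#' @param newdata Data frame or named list of matrices with the predictor
#'   variables.
#' @param ... Unused.
#' @return Numeric vector or matrix of linear predictions (no clipping).
#' @export
predict.retention_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss))
    stop("schema error: missing layer(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- object$coefficients[["(Intercept)"]]
  for (p in object$predictors)
    out <- out + object$coefficients[[p]] * newdata[[p]]
  if (is.matrix(newdata[[object$predictors[1]]]) ||
      length(object$predictors) == 0) out else as.numeric(out)
}

#' Exhaustive best-subset selection under an AICc criterion and VIF cutoff
#'
#' Enumerates all `2^p - 1` non-empty predictor subsets, drops every subset
#' whose maximum VIF exceeds `vif_cutoff`, and returns the surviving model
#' with minimum AICc. Ties within `1e-9` AICc are broken toward fewer
#' predictors, then by alphabetical predictor set, so selection is invariant
#' to candidate order. The complete ranked ledger is attached for audit.
#'
#' @param table Site table (one tracer form).
#' @param response Response column name.
#' @param candidates Candidate predictor names
#'   (default [candidate_predictors()]).
#' @param vif_cutoff Collinearity cutoff; subsets with max VIF above it are
#'   excluded (default 3).
#' @return The winning `retention_fit`, with attribute `ledger`: a data frame
#'   of all evaluated subsets (`predictors`, `k`, `aicc`, `r2`, `max_vif`,
#'   `excluded`) sorted by AICc.
#' @export
select_best <- function(table, response, candidates = candidate_predictors(),
                        vif_cutoff = 3) {
  if (length(candidates) == 0)
    stop("candidate set is empty", call. = FALSE)
  p <- length(candidates)
  d <- table[, c(response, candidates), drop = FALSE]
  if (anyNA(d)) stop("missing values in used columns", call. = FALSE)
  n <- nrow(d)
  y <- d[[response]]
  X <- as.matrix(d[, candidates, drop = FALSE])
  tss <- sum((y - mean(y))^2)
  # VIF of a subset via the correlation-matrix inverse (diagonal of R^-1),
  # algebraically identical to the 1/(1 - R2_j) regressions in vif()
  Cmat <- stats::cor(X)
  vif_sub <- function(idx) {
    if (length(idx) == 1L) return(1)
    tryCatch(pmax(diag(solve(Cmat[idx, idx])), 1),
             error = function(e) rep(Inf, length(idx)))
  }
  masks <- seq_len(2^p - 1)
  rows <- vector("list", length(masks))
  for (m in masks) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    k <- length(idx)
    if (n <= k + 2) {
      rows[[m]] <- data.frame(predictors = paste(sort(candidates[idx]),
                                                 collapse = "+"),
                              k = k, aicc = Inf, r2 = NA_real_,
                              max_vif = NA_real_, excluded = TRUE)
      next
    }
    Z <- cbind(1, X[, idx, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    singular <- fit$rank < ncol(Z)
    rss <- sum(fit$residuals^2)
    v <- if (singular) Inf else max(vif_sub(idx))
    rows[[m]] <- data.frame(
      predictors = paste(sort(candidates[idx]), collapse = "+"),
      k = k,
      aicc = if (singular) Inf else aicc_from_rss(rss, n, k),
      r2 = if (tss > 0) 1 - rss / tss else 0,
      max_vif = v,
      excluded = singular || v > vif_cutoff)
  }
  ledger <- do.call(rbind, rows)
  ledger <- ledger[order(ledger$aicc, ledger$k, ledger$predictors), ,
                   drop = FALSE]
  rownames(ledger) <- NULL
  ok <- ledger[!ledger$excluded & is.finite(ledger$aicc), , drop = FALSE]
  if (nrow(ok) == 0)
    stop("selection-failure: every subset excluded at VIF cutoff ",
         vif_cutoff, call. = FALSE)
  near <- ok[ok$aicc <= ok$aicc[1] + 1e-9, , drop = FALSE]
  near <- near[order(near$k, near$predictors), , drop = FALSE]
  chosen <- strsplit(near$predictors[1], "+", fixed = TRUE)[[1]]
  # preserve the caller's candidate order in the refit
  chosen <- candidates[candidates %in% chosen]
  best <- fit_subset(table, response, chosen)
  attr(best, "ledger") <- ledger
  best
}

#' Fit the retention model set for one tracer form
#'
#' Fits the models needed by an upscaling mode for one form's rows of the
#' site table. Chained mode models the loss fraction, organic-layer
#' retention, plant:(plant+mineral) ratio and woody share; regression mode
#' models each pool fraction directly plus the woody share.
#'
#' @param sites Site table from [make_site_table()] (or equivalent).
#' @param form `"NHx"` or `"NOy"`.
#' @param mode `"chained"` or `"regression"`.
#' @param selection `"subset"` for exhaustive AICc selection over
#'   `candidates`, or `"fixed"` for the canonical single-predictor relations
#'   (loss ~ soil_cn, organic ~ org_mass, ratio ~ npp, woody share ~
#'   wood_biomass).
#' @param candidates Candidate predictors for `"subset"` selection.
#' @param vif_cutoff Passed to [select_best()].
#' @return Named list of `retention_fit` objects; names depend on mode
#'   (chained: `loss`, `org`, `plant_ratio`, `wood_share`; regression:
#'   `plant`, `org`, `min`, `loss`, `wood_share`).
#' @export
fit_retention_models <- function(sites, form = c("NHx", "NOy"),
                                 mode = c("chained", "regression"),
                                 selection = c("subset", "fixed"),
                                 candidates = candidate_predictors(),
                                 vif_cutoff = 3) {
  form <- match.arg(form); mode <- match.arg(mode)
  selection <- match.arg(selection)
  d <- sites[sites$form == form, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for form ", form, call. = FALSE)
  # a site that retains nothing outside loss+organic is uninformative for
  # the plant:(plant+mineral) split; such rows are dropped from that fit
  d$plant_ratio <- ifelse(d$rec_plant + d$rec_min > 0,
                          d$rec_plant / (d$rec_plant + d$rec_min), NA)
  responses <- if (mode == "chained")
    c(loss = "loss", org = "rec_org", plant_ratio = "plant_ratio",
      wood_share = "rec_wood_share")
  else
    c(plant = "rec_plant", org = "rec_org", min = "rec_min", loss = "loss",
      wood_share = "rec_wood_share")
  fixed_pred <- c(loss = "soil_cn", org = "org_mass", plant_ratio = "npp",
                  wood_share = "wood_biomass", plant = "npp", min = "npp")
  out <- lapply(names(responses), function(nm) {
    di <- d[is.finite(d[[responses[[nm]]]]), , drop = FALSE]
    if (selection == "subset")
      select_best(di, responses[[nm]], candidates, vif_cutoff)
    else
      fit_subset(di, responses[[nm]], fixed_pred[[nm]])
  })
  names(out) <- names(responses)
  structure(out, form = form, mode = mode)
}
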