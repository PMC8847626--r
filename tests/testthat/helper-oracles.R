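# Independent oracles used by the unit and acceptance tests. These deliberately
# re-derive results from first principles (hand-coded formulas, lm(), car::vif,
# exhaustive enumeration over combn) rather than calling the package internals
# they check.

# Hand-evaluated constant-pool mass balance, straight from its definition.
oracle_recovery <- function(n_pool, atom_before, atom_after, added) {
  n15_before <- n_pool * atom_before / 100
  n15_after <- n_pool * atom_after / 100
  (n15_after - n15_before) / added * 100
}

# Hand-coded small-sample AIC with k' = p + 2 (intercept, slopes, variance).
oracle_aicc <- function(fit_lm) {
  n <- length(stats::residuals(fit_lm))
  rss <- sum(stats::residuals(fit_lm)^2)
  kp <- length(stats::coef(fit_lm)) + 1
  n * log(rss / n) + 2 * kp + 2 * kp * (kp + 1) / (n - kp - 1)
}

# Brute-force best-subset selection: enumerate every non-empty subset with
# combn + lm, screen on VIF computed by its defining regressions, and return
# the sorted predictor set of the minimum-AICc survivor (ties: fewer
# predictors, then alphabetical).
oracle_select <- function(data, response, candidates, vif_cutoff = 3) {
  n <- nrow(data)
  best <- NULL
  for (k in seq_along(candidates)) {
    if (n <= k + 2 || n - (k + 2) - 1 <= 0) next
    sets <- utils::combn(candidates, k, simplify = FALSE)
    for (s in sets) {
      f <- stats::as.formula(paste(response, "~",
                                   paste(s, collapse = "+")))
      fit <- stats::lm(f, data = data)
      if (k >= 2) {
        vifs <- vapply(s, function(p) {
          r2 <- summary(stats::lm(
            stats::as.formula(paste(p, "~", paste(setdiff(s, p),
                                                  collapse = "+"))),
            data = data))$r.squared
          1 / (1 - r2)
        }, numeric(1))
        if (max(vifs) > vif_cutoff) next
      }
      a <- oracle_aicc(fit)
      key <- list(aicc = a, k = k, set = paste(sort(s), collapse = "+"))
      if (is.null(best) || a < best$aicc - 1e-9 ||
          (abs(a - best$aicc) <= 1e-9 &&
           (k < best$k || (k == best$k && key$set < best$set))))
        best <- key
    }
  }
  if (is.null(best)) return(NULL)
  sort(strsplit(best$set, "+", fixed = TRUE)[[1]])
}

# Two vectors with an exact given sample correlation, built from orthogonal
# residual components.
correlated_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  u <- stats::rnorm(n); v <- stats::rnorm(n)
  u <- (u - mean(u)) / stats::sd(u)
  v <- stats::residuals(stats::lm(v ~ u))
  v <- (v - mean(v)) / stats::sd(v)
  list(x1 = u, x2 = rho * u + sqrt(1 - rho^2) * v)
}

# Small default worlds/sites shared by tests (kept tiny for speed).
tiny_world <- function(seed = 7, nx = 24, ny = 12)
  make_world(world_generator_config(nx = nx, ny = ny, seed = seed))

default_sites <- function(seed = 42)
  make_site_table(site_generator_config(seed = seed))
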