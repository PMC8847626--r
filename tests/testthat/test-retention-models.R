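test_that("AICc matches the hand-coded formula on lm fits", {
  set.seed(8)
  d <- data.frame(x1 = runif(13, 0, 10), x2 = runif(13), x3 = rnorm(13))
  d$y <- 2 * d$x1 + rnorm(13, 0, 0.1)
  for (preds in list("x1", c("x1", "x2"), c("x1", "x2", "x3"))) {
    fit <- fit_subset(d, "y", preds)
    lmfit <- stats::lm(stats::reformulate(preds, "y"), data = d)
    expect_equal(fit$aicc, oracle_aicc(lmfit), tolerance = 1e-8)
    expect_equal(unname(fit$coefficients), unname(stats::coef(lmfit)),
                 tolerance = 1e-10)
  }
  fit <- fit_subset(d, "y", "x1")
  expect_true(fit$coefficients[["x1"]] > 1.9 && fit$coefficients[["x1"]] < 2.1)
})

test_that("exact linear responses and intercept-only behaviour", {
  d <- data.frame(x = 1:13)
  d$y <- 3 + 2 * d$x
  f <- fit_subset(d, "y", "x")
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(unname(f$coefficients), c(3, 2), tolerance = 1e-10)
  # noise orthogonal to any predictor: R2 of the true model dominates
  expect_error(fit_subset(d[1:3, ], "y", "x"), "sample-size")
  dup <- data.frame(x1 = 1:13, x2 = 1:13, y = rnorm(13))
  expect_error(fit_subset(dup, "y", c("x1", "x2")), "singular-fit")
})

test_that("VIF equals the closed form for exactly correlated pairs", {
  for (rho in c(0, 0.5, 0.8, 0.99)) {
    pr <- correlated_pair(13, rho, seed = 3)
    d <- data.frame(x1 = pr$x1, x2 = pr$x2)
    v <- vif(d, c("x1", "x2"))
    expect_equal(unname(v), rep(1 / (1 - rho^2), 2), tolerance = 1e-8)
  }
  # orthogonal predictors -> all VIFs 1
  pr <- correlated_pair(20, 0, seed = 5)
  expect_equal(unname(vif(data.frame(a = pr$x1, b = pr$x2), c("a", "b"))),
               c(1, 1), tolerance = 1e-10)
  # agreement with car::vif as an independent implementation
  skip_if_not_installed("car")
  set.seed(10)
  d <- data.frame(x1 = rnorm(15), x2 = rnorm(15), x3 = rnorm(15))
  d$y <- rnorm(15)
  ours <- vif(d, c("x1", "x2", "x3"))
  theirs <- car::vif(stats::lm(y ~ x1 + x2 + x3, data = d))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-8)
})

test_that("perfect collinearity yields an Inf sentinel, not an error", {
  d <- data.frame(x1 = 1:10, x2 = 2 * (1:10) + 1, x3 = rnorm(10))
  v <- vif(d, c("x1", "x2", "x3"))
  expect_true(all(is.infinite(v[c("x1", "x2")])))
})

test_that("select_best enumerates every subset and agrees with brute force", {
  d <- default_sites(6)
  d <- d[d$form == "NHx", ]
  cands <- c("soil_cn", "org_mass", "npp", "mat", "n_dep")
  best <- select_best(d, "loss", cands)
  ledger <- attr(best, "ledger")
  expect_equal(nrow(ledger), 2^length(cands) - 1)
  expect_identical(sort(best$predictors), oracle_select(d, "loss", cands))
  # full nine-candidate agreement across the chained responses
  d$plant_ratio <- d$rec_plant / (d$rec_plant + d$rec_min)
  for (resp in c("loss", "rec_org", "plant_ratio", "rec_wood_share")) {
    got <- select_best(d, resp)
    expect_identical(sort(got$predictors),
                     oracle_select(d, resp, candidate_predictors()),
                     info = resp)
  }
})

test_that("selection is invariant to candidate order and affine rescaling", {
  d <- default_sites(12)
  d <- d[d$form == "NOy", ]
  cands <- c("soil_cn", "org_mass", "npp", "mat")
  a <- select_best(d, "loss", cands)
  b <- select_best(d, "loss", rev(cands))
  expect_setequal(a$predictors, b$predictors)
  expect_equal(a$aicc, b$aicc, tolerance = 1e-10)
  # rescale a predictor: same subset, slope transforms accordingly
  d2 <- d
  d2$soil_cn <- d2$soil_cn * 10 + 5
  c2 <- select_best(d2, "loss", cands)
  expect_setequal(gsub("soil_cn", "soil_cn", c2$predictors), a$predictors)
  if ("soil_cn" %in% a$predictors)
    expect_equal(c2$coefficients[["soil_cn"]] * 10,
                 a$coefficients[["soil_cn"]], tolerance = 1e-8)
})

test_that("a larger nested model never wins on equal RSS", {
  # AICc penalty strictly increases with k at fixed RSS
  for (k in 1:8)
    expect_lt(aicc_from_rss(10, 13, k), aicc_from_rss(10, 13, k + 1))
  expect_equal(aicc_from_rss(10, 13, 10), Inf) # n - k' - 1 hits 0
  expect_lt(aicc_from_rss(10, 13, 9), Inf)
})

test_that("duplicated predictors are excluded by the VIF screen", {
  set.seed(21)
  d <- data.frame(xt = runif(13, 0, 10))
  d$xa <- d$xt + rnorm(13, 0, 1e-8)
  d$xb <- d$xt + rnorm(13, 0, 1e-8)
  d$y <- 5 - 2 * d$xt + rnorm(13, 0, 0.5)
  best <- select_best(d, "y", c("xt", "xa", "xb"))
  expect_lt(sum(c("xa", "xb") %in% best$predictors), 2)
  ledger <- attr(best, "ledger")
  both <- grepl("xa", ledger$predictors) & grepl("xb", ledger$predictors)
  expect_true(all(ledger$excluded[both]))
})

test_that("single-candidate selection returns that model; empty set errors", {
  d <- default_sites(2)
  d <- d[d$form == "NHx", ]
  one <- select_best(d, "loss", "soil_cn")
  expect_identical(one$predictors, "soil_cn")
  expect_error(select_best(d, "loss", character(0)), "empty")
})

test_that("selection failure under an impossible VIF cutoff is reported", {
  set.seed(2)
  d <- data.frame(x1 = rnorm(13), x2 = rnorm(13))
  d$y <- d$x1 + rnorm(13)
  expect_error(select_best(d, "y", c("x1", "x2"), vif_cutoff = 0.5),
               "selection-failure")
})

test_that("fit_retention_models returns the mode-appropriate model sets", {
  sites <- default_sites(1)
  ch <- fit_retention_models(sites, "NHx", mode = "chained",
                             selection = "fixed")
  expect_named(ch, c("loss", "org", "plant_ratio", "wood_share"))
  expect_identical(ch$loss$predictors, "soil_cn")
  rg <- fit_retention_models(sites, "NOy", mode = "regression",
                             selection = "fixed")
  expect_named(rg, c("plant", "org", "min", "loss", "wood_share"))
})
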