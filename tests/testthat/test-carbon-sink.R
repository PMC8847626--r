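test_that("flexible wood stoichiometry hits its anchors and is continuous", {
  expect_identical(f_wood(10), 1)
  expect_identical(f_wood(15), 1)
  expect_identical(f_wood(30), 0.5)
  expect_identical(f_wood(100), 0)
  expect_identical(f_wood(120), 0)
  expect_equal(f_wood(22.5), 0.75)
  grid <- seq(0, 120, by = 0.25)
  f <- f_wood(grid)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) <= 0))
  # continuity: no jump larger than the local linear increment
  expect_lt(max(abs(diff(f))), 0.5 / 15 * 0.25 + 1e-12)
  expect_error(f_wood(-1), "domain error")
  expect_error(f_wood(10, data.frame(n_dep = c(30, 15), f = c(0, 1))),
               "config error")
})

test_that("per-cell sink reproduces the hand-worked stoichiometric case", {
  s <- stoichiometry_set(cn_wood = 300, cn_org = 30, cn_min = 15)
  expect_equal(csink_cell(10, frac_wood = 10, frac_org = 30, frac_min = 20,
                          stoich = s), 396)
  expect_equal(csink_cell(0, 10, 30, 20, s), 0)
  # past saturation the wood term vanishes and soil terms scale linearly
  expect_equal(csink_cell(100, 10, 30, 20, s), 10 * (72 + 24))
  expect_error(csink_cell(-5, 10, 30, 20, s), "domain error")
})

test_that("rigid stoichiometry is recovered as the s = 1, f = 1 limit", {
  rigid <- stoichiometry_set(cn_wood = 300, cn_org = 30, cn_min = 15,
                             soil_immobilization = 1,
                             f_breakpoints = data.frame(n_dep = c(0, 1e6),
                                                        f = c(1, 1)))
  got <- csink_cell(40, 10, 30, 20, rigid)
  expect_equal(got, 40 * (0.3 * 30 + 0.2 * 15 + 0.1 * 300))
})

test_that("sink is monotone in fractions and C/N ratios", {
  s <- stoichiometry_set(300, 30, 15)
  base <- csink_cell(20, 10, 30, 20, s)
  expect_gt(csink_cell(20, 12, 30, 20, s), base)
  expect_gt(csink_cell(20, 10, 35, 20, s), base)
  s2 <- stoichiometry_set(350, 30, 15)
  expect_gt(csink_cell(20, 10, 30, 20, s2), base)
})

test_that("aggregation integrates area exactly and conserves biome totals", {
  w <- tiny_world(9)
  grid <- w$grid
  ones <- matrix(1, length(grid$lat), length(grid$lon))
  # uniform 100 kg C ha-1 yr-1 over full cover, no mask
  grid$layers$forest_cover <- ones
  sink <- list(NHx = 60 * ones, NOy = 40 * ones, total = 100 * ones)
  dep <- list(nhx = 6 * ones, noy = 4 * ones)
  res <- aggregate_csink(sink, grid, dep, mask = ones > 0)
  area_ha <- sum(cell_area_ha(grid))
  expect_equal(res$global_total_pg, 100 * area_ha / 1e12, tolerance = 1e-12)
  expect_equal(sum(res$biome_pg), res$global_total_pg, tolerance = 1e-12)
  # efficiency: 100 kg C per 10 kg N everywhere
  expect_equal(unname(res$efficiency["overall"]), 10, tolerance = 1e-12)
  expect_equal(unname(res$efficiency["NHx"]), 10, tolerance = 1e-12)
  # no forest, no sink
  grid0 <- grid
  grid0$layers$forest_cover <- 0 * ones
  res0 <- aggregate_csink(sink, grid0, dep, mask = ones > 0)
  expect_equal(res0$global_total_pg, 0)
})

test_that("per-form efficiencies recombine exactly into the overall efficiency", {
  sites <- default_sites(42)
  w <- tiny_world(7)
  maps <- upscale_retention(sites, w$grid, selection = "fixed")
  stoich <- stoichiometry_set(300, w$cn_org, w$cn_min)
  sink <- csink_map(maps, w$deposition[[1]], stoich)
  res <- aggregate_csink(sink, w$grid, w$deposition[[1]])
  dep <- res$deposition_tg
  recombined <- (res$efficiency[["NHx"]] * dep[["NHx"]] +
                   res$efficiency[["NOy"]] * dep[["NOy"]]) / dep[["total"]]
  expect_equal(recombined, res$efficiency[["overall"]], tolerance = 1e-12)
  expect_equal(sum(res$biome_pg), res$global_total_pg, tolerance = 1e-12)
  expect_true(all(unlist(res$biome_pg) >= 0))
})

test_that("zero forest cover in the world zeroes the downstream global sink", {
  w <- tiny_world(5)
  w$grid$layers$forest_cover[] <- 0
  sites <- default_sites(1)
  maps <- upscale_retention(sites, w$grid, selection = "fixed")
  stoich <- stoichiometry_set(300, w$cn_org, w$cn_min)
  sink <- csink_map(maps, w$deposition[[1]], stoich)
  res <- aggregate_csink(sink, w$grid, w$deposition[[1]],
                         mask = forest_mask(w$grid, 0))
  expect_equal(res$global_total_pg, 0)
})

test_that("stoichiometry validation rejects malformed inputs", {
  expect_error(stoichiometry_set(-1, 30, 15), "config error")
  expect_error(stoichiometry_set(300, 30, 15, soil_immobilization = 1.2),
               "config error")
  expect_error(stoichiometry_set(300, 30, 15,
                                 f_breakpoints = data.frame(
                                   n_dep = c(15, 30), f = c(0.5, 1))),
               "config error")
})
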