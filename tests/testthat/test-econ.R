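test_that("a static stand yields a constant trajectory without harvests", {
  trees <- tibble::tibble(species = "beech", dbh = c(30, 40),
    stems_ha = c(100, 50), age = 80)
  growth <- default_growth_params()
  growth$increment[] <- 0
  mgmt <- default_management(thinning = 0)
  mgmt$target_diameter[] <- 999
  tr <- simulate_trajectory(trees, growth, mgmt)
  expect_equal(length(unique(tr$year)), 7)
  expect_true(all(tr$v_harvested == 0))
  expect_equal(length(unique(round(tr$v_standing, 9))), 1)
})

test_that("trees above target diameter are harvested in the first interval", {
  trees <- tibble::tibble(species = "douglas", dbh = c(70, 30),
    stems_ha = c(50, 100), age = 80)
  tr <- simulate_trajectory(trees, management = default_management(0))
  h5 <- tr$v_harvested[tr$year == 5]
  expect_gt(sum(h5), 0)
  # the harvested cohort's volume at its harvest dbh
  g <- default_growth_params()
  expect_equal(sum(h5), forestmf:::tree_volume_(70, "douglas", g) * 50)
})

test_that("standing plus cumulative harvested volume never decreases", {
  d <- generate_design(1, seed = 4)
  inv <- generate_stand_inventory(d[d$forest_type == "beech_douglas", ][1, ],
    seed = 5)
  tr <- simulate_trajectory(inv)
  totals <- tr |>
    dplyr::group_by(year) |>
    dplyr::summarise(s = sum(v_standing), h = sum(v_harvested)) |>
    dplyr::mutate(total = s + cumsum(h))
  expect_true(all(diff(totals$total) >= -1e-9))
})

test_that("conifers in mixtures are harvested before beech", {
  trees <- tibble::tibble(
    species = c("beech", "douglas"),
    dbh = c(35, 50), stems_ha = c(200, 120), age = 80
  )
  tr <- simulate_trajectory(trees, management = default_management(0))
  final <- tr[tr$year == 30, ]
  expect_equal(final$v_standing[final$species == "douglas"], 0)
  expect_gt(final$v_standing[final$species == "beech"], 0)
  expect_error(
    simulate_trajectory(trees, horizon = 20),
    "7 time points"
  )
  expect_error(simulate_trajectory(trees[0, ]), "empty")
})

test_that("stumpage value is the net-revenue-weighted standing volume", {
  v <- flat_valuation(price = 60, cost = 10)
  st <- tibble::tibble(species = "beech", volume = 100, qmd = 40)
  expect_equal(stumpage_value(st, v), 5000)
  expect_equal(stumpage_value(st[0, ], v), 0)
  two <- tibble::tibble(species = c("beech", "spruce"), volume = c(100, 50),
    qmd = c(40, 35))
  expect_equal(
    stumpage_value(two, v),
    stumpage_value(two[1, ], v) + stumpage_value(two[2, ], v)
  )
  # unknown species rejected by a parameterised valuation
  expect_error(
    stumpage_value(tibble::tibble(species = "larch", volume = 10, qmd = 30),
      build_valuation()),
    "larch"
  )
})

test_that("npv discounts harvests and the standing-value change", {
  v1 <- flat_valuation(price = 1, cost = 0) # value = volume
  # single harvest worth 1000 at t = 5, no standing value
  tr <- toy_trajectory(v_standing = 0,
    v_harvested = c(0, 1000, 0, 0, 0, 0, 0))
  got <- npv(tr, v1, i = 0.015)
  expect_equal(got, 1000 * 1.015^-5, tolerance = 1e-12)
  expect_equal(round(got, 2), 928.26)
  # independent present-value loop over the valued trajectory
  val <- value_trajectory(tr, v1)
  loop <- sum(val$harvest_value / (1 + 0.015)^val$year)
  expect_equal(got, loop, tolerance = 1e-12)

  # standing value growing exactly at rate i, no harvests -> npv = 0
  tr2 <- toy_trajectory(v_standing = 500 * 1.015^seq(0, 30, 5))
  expect_lt(abs(npv(tr2, v1, i = 0.015)), 1e-9)

  # i = 0: undiscounted sum plus value change
  tr3 <- toy_trajectory(v_standing = c(400, rep(300, 6)),
    v_harvested = c(0, 120, 0, 80, 0, 0, 0))
  expect_equal(npv(tr3, v1, i = 0), 120 + 80 + 300 - 400)
})

test_that("the annuity amortizes the npv exactly", {
  a <- annuity(10000, 0.015, 30)
  expect_equal(round(a, 2), 416.39)
  expect_equal(sum(a / 1.015^(1:30)), 10000, tolerance = 1e-8)
  expect_equal(annuity(0, 0.015, 30), 0)
  expect_equal(annuity(5000, 0.02, 1), 5000 * 1.02)
  expect_error(annuity(1000, 0), "i = 0")
})

test_that("annuity/npv duality holds across random rates and horizons", {
  withr::with_seed(21, {
    for (rep in 1:50) {
      npv0 <- runif(1, -5e4, 5e4)
      i <- runif(1, 0.001, 0.1)
      t_max <- sample(c(10, 30, 50), 1)
      a <- annuity(npv0, i, t_max)
      expect_equal(sum(a / (1 + i)^(1:t_max)), npv0,
        tolerance = 1e-8)
    }
  })
})

test_that("planting costs compound at the configured rate", {
  got <- compound_planting_costs(2000, 80, 0.015)
  expect_equal(round(got, 1), 6581.3)
  iter <- 2000
  for (y in 1:80) iter <- iter * 1.015
  expect_equal(got, iter, tolerance = 1e-12)
  expect_equal(compound_planting_costs(2000, 0), 2000)
  expect_error(compound_planting_costs(-1, 10), ">= 0")
  expect_error(compound_planting_costs(10, -1), ">= 0")
  expect_equal(corrected_profit(10000, 2000, 0, 0.015), 8000)
})

test_that("sawn-timber share is the volume-weighted assortment fraction", {
  tr_all <- toy_trajectory(v_harvested = c(0, 50, 0, 0, 0, 0, 50))
  expect_equal(sawn_timber_share(tr_all, flat_valuation(sawn = 1)), 100)
  expect_equal(sawn_timber_share(tr_all, flat_valuation(sawn = 0)), 0)
  # 50 m3 at share 0.8 and 50 m3 at share 0.4 -> 60%
  v_mix <- structure(
    list(
      price = function(s, q) rep_len(50, length(q)),
      harvest_cost = function(s, q) rep_len(10, length(q)),
      sawn_share = function(s, q) ifelse(q > 40, 0.8, 0.4),
      params = list()
    ),
    class = "mf_valuation"
  )
  tr_mix <- toy_trajectory(v_harvested = c(0, 50, 0, 0, 0, 0, 50),
    qmd = c(50, 50, 50, 50, 50, 50, 30))
  expect_equal(sawn_timber_share(tr_mix, v_mix), 60)
  expect_warning(
    s0 <- sawn_timber_share(toy_trajectory(v_harvested = 0),
      flat_valuation()),
    "no harvest"
  )
  expect_equal(s0, 0)
})

test_that("the six economic indicators compose their sub-operations", {
  d <- generate_design(1, seed = 8)
  plot <- d[d$forest_type == "douglas", ][1, ]
  inv <- generate_stand_inventory(plot, seed = 9)
  tr <- simulate_trajectory(inv)
  v <- build_valuation()
  ind <- compute_econ_indicators(plot, tr)
  expect_equal(nrow(ind), 1)
  expect_equal(ind$future_wood_volume,
    sum(tr$v_standing[tr$year == 30]))
  expect_equal(ind$sawn_timber_share, sawn_timber_share(tr, v))
  expect_equal(ind$annuity, annuity(npv(tr, v, 0.015), 0.015, 30))
  start <- tr[tr$year == 0, ]
  expect_equal(ind$immediate_profit, stumpage_value(
    tibble::tibble(species = start$species, volume = start$v_standing,
      qmd = start$qmd), v))
  expect_true(ind$survival_30yr > 0 && ind$survival_30yr <= 1)
  expect_true(ind$sawn_timber_share >= 0 && ind$sawn_timber_share <= 100)
})
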