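test_that("zero-variance continuous indicators collapse to the baseline", {
  d <- generate_design(4, seed = 1)
  m <- indicator_model("flat", "ecosystem", baseline = 7.5)
  tab <- generate_indicators(d, m, seed = 2)
  expect_true(all(tab$flat == 7.5))
})

test_that("the latent factor induces the model-implied correlation", {
  d <- generate_design(200, seed = 5) # 1000 plots
  l1 <- 0.8
  l2 <- 0.6
  s1 <- 1
  s2 <- 1.5
  m <- dplyr::bind_rows(
    indicator_model("a", "ecosystem", baseline = 10, resid_sd = s1,
      loading = l1),
    indicator_model("b", "ecosystem", baseline = 10, resid_sd = s2,
      loading = l2)
  )
  tab <- generate_indicators(d, m, seed = 6)
  r_model <- l1 * l2 / sqrt((l1^2 + s1^2) * (l2^2 + s2^2))
  r_hat <- cor(tab$a, tab$b)
  expect_gt(r_hat, 0)
  # Fisher-z comparison at 3 standard errors
  expect_lt(abs(atanh(r_hat) - atanh(r_model)), 3 / sqrt(nrow(tab) - 3))
})

test_that("forest-type effects are recovered from group means", {
  d <- generate_design(200, seed = 11)
  eff <- setNames(c(0, 2, -1, 0.5, 1), forestmf:::forest_types())
  m <- indicator_model("y", "ecosystem", baseline = 10, effects = eff,
    resid_sd = 1, quintet_sd = 0.5, loading = 0.3)
  tab <- generate_indicators(d, m, seed = 12)
  for (ft in forestmf:::forest_types()) {
    y <- tab$y[tab$forest_type == ft]
    se <- sd(y) / sqrt(length(y))
    expect_lt(abs(mean(y) - (10 + eff[[ft]])), 3 * se)
  }
})

test_that("count indicators are non-negative integers on the log-link scale", {
  d <- generate_design(20, seed = 3)
  m <- dplyr::bind_rows(
    indicator_model("pois", "biodiversity", "count", baseline = 12),
    indicator_model("nb", "biodiversity", "count", baseline = 30,
      dispersion = 5)
  )
  tab <- generate_indicators(d, m, seed = 4)
  expect_true(all(tab$pois >= 0 & tab$pois == floor(tab$pois)))
  expect_true(all(tab$nb >= 0 & tab$nb == floor(tab$nb)))
  # Poisson mean close to baseline at zero effects
  expect_lt(abs(mean(tab$pois) - 12), 3 * sqrt(12 / nrow(tab)))
})

test_that("missingness rules reproduce the configured patterns exactly", {
  cfg <- paper_like_preset()
  d <- generate_design(cfg$design$n_quintets, seed = 1,
    exclusions = cfg$design$exclusions)
  tab <- generate_indicators(d, cfg$indicators, seed = 2)
  inc <- included_plots(tab)
  expect_equal(sum(is.na(inc$litter_decomposition)), 6)
  expect_true(all(is.na(tab$canopy_arthropods[!tab$quintet %in%
    sprintf("q%02d", 1:3)])))
  expect_true(all(!is.na(tab$canopy_arthropods[tab$quintet %in%
    sprintf("q%02d", 1:3)])))
  expect_true(all(is.na(tab$birds[tab$quintet %in% c("q07", "q08")])))
  expect_true(all(is.na(tab$fine_root_biomass[!tab$quintet %in%
    sprintf("q%02d", 1:4)])))
})

test_that("invalid models are rejected", {
  d <- generate_design(2, seed = 1)
  expect_error(
    indicator_model("x", "ecosystem", resid_sd = -1),
    "standard deviations"
  )
  m <- indicator_model("x", "ecosystem")
  m$resid_sd <- -0.5 # bypass the constructor
  expect_error(generate_indicators(d, m, seed = 1), "standard deviations")
  expect_error(indicator_model("x", "nowhere"), "dimension")
})

test_that("indicator tables are deterministic and carry their metadata", {
  cfg <- paper_like_preset()
  d <- generate_design(8, seed = 9, exclusions = cfg$design$exclusions)
  t1 <- generate_indicators(d, cfg$indicators, seed = 10)
  t2 <- generate_indicators(d, cfg$indicators, seed = 10)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  meta <- indicator_meta(t1)
  expect_equal(sum(meta$dimension == "biodiversity"), 9)
  expect_equal(sum(meta$dimension == "ecosystem"), 9)
  expect_equal(sum(meta$dimension == "economic"), 6)
})
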