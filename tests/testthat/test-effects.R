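test_that("net diversity effects match hand-computed cases", {
  expect_equal(net_diversity_effect(10, 8, 12, .5, .5), 0)
  expect_equal(net_diversity_effect(12, 8, 12, .5, .5), 0.2)
  expect_equal(net_diversity_effect(10, 10, 10, .4, .4), 0)
  expect_error(net_diversity_effect(10, 0, 0, .5, .5), "Et_ij")
  expect_error(net_diversity_effect(10, 8, 12, .6, .6), "\\(0, 1\\]")
  expect_error(net_diversity_effect(10, 8, 12, -.1, .5), ">= 0")
})

test_that("the net diversity effect is scale invariant", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      Ot <- runif(1, 1, 20)
      Ei <- runif(1, 1, 20)
      Ej <- runif(1, 1, 20)
      pi_ <- runif(1, .2, .6)
      pj <- runif(1, .2, 1 - pi_)
      c0 <- runif(1, .01, 100)
      expect_equal(
        net_diversity_effect(Ot, Ei, Ej, pi_, pj),
        net_diversity_effect(c0 * Ot, c0 * Ei, c0 * Ej, pi_, pj),
        tolerance = 1e-12
      )
    }
  })
})

test_that("proportional deviation is anchored at the baseline mean", {
  expect_equal(proportional_deviation(3, c(2, 2)), 0.5)
  expect_equal(proportional_deviation(2, c(1, 2, 3)), 0)
  expect_equal(proportional_deviation(1, c(1, 2, 3)), -0.5)
  b <- c(1.3, 2.7, 4.1)
  expect_equal(proportional_deviation(mean(b), b), 0)
  expect_error(proportional_deviation(1, numeric(0)), "empty")
  expect_error(proportional_deviation(1, c(-1, 1)), "zero")
})

test_that("dimension correlations match the covariance formula", {
  x <- tibble::tibble(multidiversity = 1:10,
    ecosystem_mf = 2 * (1:10),
    economic_mf = -(1:10))
  out <- dimension_correlations(x)
  expect_equal(out$r[out$dim_x == "multidiversity" &
    out$dim_y == "ecosystem_mf"], 1)
  expect_equal(out$r[out$dim_x == "multidiversity" &
    out$dim_y == "economic_mf"], -1)
  withr::with_seed(4, {
    y <- tibble::tibble(multidiversity = rnorm(10),
      ecosystem_mf = rnorm(10), economic_mf = rnorm(10))
    out2 <- dimension_correlations(y)
    manual <- function(a, b) {
      sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    }
    expect_equal(out2$r[1], manual(y$multidiversity, y$ecosystem_mf),
      tolerance = 1e-12)
    expect_equal(out2$r[3], manual(y$ecosystem_mf, y$economic_mf),
      tolerance = 1e-12)
  })
  # listwise deletion reported in n
  y2 <- tibble::tibble(multidiversity = c(1, 2, 3, 4, NA),
    ecosystem_mf = c(2, 1, 4, 3, 5), economic_mf = c(5, 4, 3, 2, 1))
  expect_equal(unique(dimension_correlations(y2)$n), 4)
  expect_error(
    dimension_correlations(tibble::tibble(multidiversity = c(1, 1, 1),
      ecosystem_mf = 1:3, economic_mf = 3:1)),
    "zero variance"
  )
})

test_that("species overlap percentages follow the union accounting", {
  same <- species_overlap(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(unique(same$shared_pct), 100)
  expect_equal(same$unique_pct, c(0, 0))
  disj <- species_overlap(list(a = "x", b = "y"))
  expect_equal(unique(disj$shared_pct), 0)
  expect_equal(disj$unique_pct, c(50, 50))
  part <- species_overlap(list(a = c("x", "y"), b = c("x", "z")))
  expect_equal(unique(part$shared_pct), 100 / 3, tolerance = 1e-12)
  expect_equal(part$unique_pct, c(100 / 3, 100 / 3), tolerance = 1e-12)
  expect_error(species_overlap(list(a = character(), b = character())),
    "non-empty")
})
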