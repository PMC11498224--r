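test_that("rarefied richness matches closed-form and enumeration values", {
  expect_equal(rarefy_richness(c(5, 5), 1), 1.0)
  expect_equal(rarefy_richness(c(5, 5), 10), 2.0)
  # brute-force average over all C(10,2) = 45 pairs
  expect_equal(rarefy_richness(c(9, 1), 2), 1.2, tolerance = 1e-12)
  expect_equal(rarefy_richness(c(9, 1), 2), rarefy_enumerate(c(9, 1), 2),
    tolerance = 1e-12)
  expect_equal(rarefy_richness(c(3, 2, 1), 3), rarefy_enumerate(c(3, 2, 1), 3),
    tolerance = 1e-12)
})

test_that("rarefaction is monotone in n and exact at the boundaries", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      counts <- rpois(6, 8) + 1
      N <- sum(counts)
      es <- vapply(1:N, function(n) rarefy_richness(counts, n), numeric(1))
      expect_true(all(diff(es) >= -1e-10))
      expect_equal(es[1], 1.0)
      expect_equal(es[N], length(counts))
    }
  })
  expect_error(rarefy_richness(c(5, 5), 11), "exceeds")
  expect_error(rarefy_richness(c(-1, 5), 2), "non-negative")
})

test_that("group-median imputation fills only the missing cells", {
  t <- tibble::tibble(
    forest_type = rep(c("a", "b"), each = 3),
    y = c(1, 2, NA, 10, NA, 30)
  )
  out <- impute_median_by_group(t, "y", "forest_type")
  expect_identical(out$y, c(1, 2, 1.5, 10, 20, 30))
  log <- attr(out, "imputation_log")
  expect_equal(sum(log$n_imputed), 2)

  # the median example: {1, 2, NA, 4} in one group
  t2 <- tibble::tibble(g = "x", y = c(1, 2, NA, 4))
  expect_equal(impute_median_by_group(t2, "y", "g")$y[3], 2)

  # untouched when nothing is missing (bitwise)
  t3 <- tibble::tibble(g = c("x", "x"), y = c(0.1 + 0.2, 0.3))
  expect_identical(impute_median_by_group(t3, "y", "g")$y, t3$y)

  expect_error(
    impute_median_by_group(
      tibble::tibble(g = c("x", "x"), y = c(NA_real_, NA_real_)), "y", "g"
    ),
    "'x'"
  )
})

test_that("min-max normalization rescales to [0, 1] with recorded bounds", {
  t <- tibble::tibble(plot_id = letters[1:3], a = c(2, 4, 6),
    b = c(10, 30, 20))
  out <- minmax_normalize(t, c("a", "b"))
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 1, 0.5))
  sc <- attr(out, "scaling")
  expect_equal(sc$min, c(2, 10))
  expect_equal(sc$max, c(6, 30))
  # idempotent on columns already spanning {0, 1}
  expect_equal(minmax_normalize(out, "a")$a, out$a)
  # invariant to positive affine transforms of the raw column
  t2 <- t
  t2$a <- 3 * t$a + 7
  expect_equal(minmax_normalize(t2, "a")$a, out$a)
  # a "less is better" flag reflects the scale
  expect_equal(minmax_normalize(t, "a", c(a = "less"))$a, c(1, 0.5, 0))
  expect_error(
    minmax_normalize(tibble::tibble(a = c(1, 1, 1)), "a"),
    "constant"
  )
})

test_that("microbial biomass is 38 times the respiration response", {
  expect_equal(microbial_biomass_from_mirr(1), 38)
  expect_equal(microbial_biomass_from_mirr(0), 0)
  expect_equal(microbial_biomass_from_mirr(2.5), 95)
  expect_error(microbial_biomass_from_mirr(-0.1), "non-negative")
})
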