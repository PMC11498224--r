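test_that("correlation distances hit the redundancy and distinctness limits", {
  x <- tibble::tibble(a = c(0, .5, 1, .2), b = c(0, .5, 1, .2))
  expect_equal(function_distance(x)["a", "b"], 0)
  y <- tibble::tibble(a = c(0, .5, 1), b = c(1, .5, 0))
  expect_equal(function_distance(y)["a", "b"], 1)
  # exactly uncorrelated pair -> d = 0.5
  z <- tibble::tibble(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(function_distance(z)["a", "b"], 0.5)
  D <- function_distance(tibble::tibble(a = runif(10), b = runif(10),
    c = runif(10)))
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  expect_error(
    function_distance(tibble::tibble(a = c(1, 1, 1), b = c(0, 1, 2))),
    "constant|undefined"
  )
})

test_that("the corrected multifunctionality hits its closed-form cases", {
  D2 <- function(d) matrix(c(0, d, d, 0), 2)
  expect_equal(hill_chao_mf_at_tau(c(1, 1), D2(1), tau = 1), 2)
  # perfectly redundant pair at level 0.5 counts once
  expect_equal(hill_chao_mf_at_tau(c(.5, .5), D2(0), tau = .7), 0.5)
  # zero-level function contributes nothing
  expect_equal(hill_chao_mf_at_tau(c(1, 0), D2(.3), tau = .5), 1)
  expect_error(hill_chao_mf_at_tau(c(1, 1), D2(1), tau = 0), "tau")
  expect_error(hill_chao_mf_at_tau(c(2, 1), D2(1), tau = .5), "\\[0, 1\\]")
})

test_that("profiles are monotone in tau and bounded", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      k <- sample(2:8, 1)
      f <- runif(k)
      D <- random_distance(k)
      taus <- sort(runif(12, 0.01, 1))
      vals <- vapply(taus, function(t) hill_chao_mf_at_tau(f, D, t),
        numeric(1))
      expect_true(all(diff(vals) <= 1e-12))
      expect_true(all(vals <= sum(f) + 1e-12))
      if (sum(f) > 0) {
        expect_true(all(vals >= sum(f^2) / sum(f) - 1e-12))
      }
      # no correction below the smallest distance
      d_off <- D[upper.tri(D)]
      expect_equal(hill_chao_mf_at_tau(f, D, min(d_off[d_off > 0]) / 2),
        sum(f))
    }
  })
})

test_that("the tau-profile AUC reduces correctly in degenerate geometries", {
  # single positive distance -> flat profile, auc equals the point value
  D <- matrix(c(0, .6, .6, 0), 2)
  pr <- mf_effective_number(c(1, 1), D)
  expect_equal(pr$auc, 2)
  # all pairwise distances equal at the grid maximum -> auc = sum(f)
  D3 <- matrix(.8, 3, 3)
  diag(D3) <- 0
  expect_equal(mf_effective_number(c(1, 1, 0), D3)$auc, 2)
  # full redundancy -> common level, with a warning
  D0 <- matrix(0, 3, 3)
  expect_warning(pr0 <- mf_effective_number(c(.4, .4, .4), D0), "degenerate")
  expect_equal(pr0$auc, 0.4)
  # auc lies between the profile extremes (mean-value property)
  withr::with_seed(3, {
    f <- runif(5)
    D <- random_distance(5)
    pr <- mf_effective_number(f, D)
    expect_gte(pr$auc, min(pr$values) - 1e-12)
    expect_lte(pr$auc, max(pr$values) + 1e-12)
  })
})

test_that("threshold counts match a brute-force per-cell oracle", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(4:10, 1)
      k <- sample(3:7, 1)
      tab <- tibble::as_tibble(
        setNames(as.data.frame(matrix(runif(n * k, 0.1, 1), n)),
          paste0("f", 1:k))
      )
      tab$plot_id <- paste0("p", 1:n)
      th <- threshold_mf(tab, paste0("f", 1:k), thresholds = c(1, 25, 50, 99))
      maxima <- vapply(tab[paste0("f", 1:k)], max, numeric(1))
      for (t in c(1, 25, 50, 99)) {
        manual <- vapply(seq_len(n), function(i) {
          sum(unlist(tab[i, paste0("f", 1:k)]) >= t / 100 * maxima)
        }, numeric(1))
        expect_identical(th$count[th$threshold == t], manual)
      }
      wide <- tidyr::pivot_wider(th, names_from = "threshold",
        values_from = "count")
      expect_true(all(apply(wide[, -1], 1, function(r) all(diff(r) <= 0))))
    }
  })
  expect_error(threshold_mf(tibble::tibble(plot_id = "a", f = 1), "f",
    thresholds = 0), "\\(0, 100\\]")
})

test_that("a plot holding every maximum reaches K at the 100% threshold", {
  tab <- tibble::tibble(plot_id = c("top", "low"), f1 = c(1, .2),
    f2 = c(2, 1), f3 = c(5, .5))
  th <- threshold_mf(tab, c("f1", "f2", "f3"), thresholds = 100)
  expect_equal(th$count[th$plot_id == "top"], 3)
})

test_that("dimension indices respect block bounds and separation", {
  cfg <- paper_like_preset()
  d <- generate_design(8, seed = 2, exclusions = cfg$design$exclusions)
  tab <- generate_indicators(d, cfg$indicators, seed = 3)
  tab <- included_plots(tab)
  tab <- impute_median_by_group(tab, "litter_decomposition", "forest_type")
  idx <- compute_dimension_indices(tab, cfg$indicators)
  expect_equal(nrow(idx), 38)
  expect_true(all(idx$economic_mf <= 6 + 1e-9))
  expect_true(all(idx$ecosystem_mf <= 8 + 1e-9))
  expect_true(all(idx$multidiversity <= 7 + 1e-9))
  expect_true(all(idx$multidiversity >= 0))
  # block separation: perturbing a biodiversity column leaves the other
  # two dimensions untouched
  tab2 <- tab
  tab2$collembola <- rev(tab2$collembola)
  idx2 <- compute_dimension_indices(tab2, cfg$indicators)
  expect_identical(idx$ecosystem_mf, idx2$ecosystem_mf)
  expect_identical(idx$economic_mf, idx2$economic_mf)
  expect_false(identical(idx$multidiversity, idx2$multidiversity))
  # a dimension with fewer than two members is rejected
  meta_bad <- cfg$indicators
  meta_bad$index_member[meta_bad$dimension == "economic"] <- FALSE
  meta_bad$index_member[meta_bad$indicator == "immediate_profit"] <- TRUE
  expect_error(compute_dimension_indices(tab, meta_bad), "fewer than 2")
})
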