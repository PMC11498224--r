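# Shared fixtures, all generated in code.

# A valuation model with flat curves, for hand-checkable monetary arithmetic.
flat_valuation <- function(price = 60, cost = 10, sawn = 1) {
  structure(
    list(
      price = function(species, qmd) rep_len(price, length(qmd)),
      harvest_cost = function(species, qmd) rep_len(cost, length(qmd)),
      sawn_share = function(species, qmd) rep_len(sawn, length(qmd)),
      params = list()
    ),
    class = "mf_valuation"
  )
}

# Minimal hand-built trajectory: one species, standing volumes by year and
# harvest volumes booked at given years.
toy_trajectory <- function(years = seq(0, 30, 5), v_standing = 0,
                           v_harvested = 0, qmd = 40, species = "beech") {
  tibble::tibble(
    year = years,
    species = species,
    v_standing = rep_len(v_standing, length(years)),
    v_harvested = rep_len(v_harvested, length(years)),
    qmd = qmd,
    qmd_harvested = qmd,
    age = 80 + years
  )
}

# Random symmetric distance matrix with zero diagonal, entries in [0, 1].
random_distance <- function(k) {
  d <- matrix(0, k, k)
  d[upper.tri(d)] <- runif(k * (k - 1) / 2)
  d + t(d)
}

# Brute-force expected rarefied richness by full enumeration of subsets
# (tiny N only).
rarefy_enumerate <- function(counts, n) {
  ids <- rep.int(seq_along(counts), counts)
  combos <- utils::combn(length(ids), n)
  mean(apply(combos, 2, function(ix) length(unique(ids[ix]))))
}

# Indices table with a built-in group shift, for transformation tests.
shifted_indices <- function(n = 8, shift = c(spruce = 2), base_mean = 4,
                            sd = 0.3, seed = 42) {
  withr::with_seed(seed, {
    types <- c("beech", names(shift))
    purrr::map(types, function(ft) {
      mu <- base_mean + if (ft == "beech") 0 else shift[[ft]]
      tibble::tibble(
        plot_id = paste0(ft, "_", seq_len(n)),
        forest_type = ft,
        multidiversity = rnorm(n, mu, sd),
        ecosystem_mf = rnorm(n, mu, sd),
        economic_mf = rnorm(n, mu, sd)
      )
    }) |> dplyr::bind_rows()
  })
}
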