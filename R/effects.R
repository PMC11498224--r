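#' Net diversity effect of a two-species mixture
#'
#' Proportional deviation of the observed provision level of a mixture
#' from its monoculture-weighted expectation:
#' `Dt = (Ot * p_ij - Et_ij) / Et_ij` with
#' `Et_ij = Et_i * p_i + Et_j * p_j` and `p_ij = p_i + p_j`,
#' where `Ot` is the observed level in the mixture, `Et_i`/`Et_j` the
#' mean levels of the pure stands of the two focal species, and
#' `p_i`/`p_j` the focal species' basal-area proportions. `Dt = 0` under
#' exact additivity; positive values are overperformance (e.g. +0.2 is a
#' 20% excess). Scale-invariant: rescaling `Ot`, `Et_i`, `Et_j` by a
#' common positive factor leaves `Dt` unchanged. When the mixture holds
#' only the two focal species (`p_ij = 1`) this is the classical
#' proportional-deviation form.
#'
#' @param Ot Observed level in the mixture.
#' @param Et_i,Et_j Expected (pure-stand mean) levels of the two species.
#' @param p_i,p_j Basal-area proportions of the two species in the
#'   mixture (`p_i + p_j` in (0, 1\]).
#' @return `Dt`, vectorized over its arguments.
#' @examples
#' net_diversity_effect(12, 8, 12, 0.5, 0.5) # 0.2
#' @export
net_diversity_effect <- function(Ot, Et_i, Et_j, p_i, p_j) {
  if (any(p_i < 0) || any(p_j < 0)) {
    stop_forestmf("proportions must be >= 0")
  }
  p_ij <- p_i + p_j
  if (any(p_ij <= 0) || any(p_ij > 1 + 1e-8)) {
    stop_forestmf("p_i + p_j must lie in (0, 1]")
  }
  Et_ij <- Et_i * p_i + Et_j * p_j
  if (any(Et_ij <= 0)) {
    stop_forestmf("expected mixture level Et_ij must be > 0; the net diversity effect is undefined")
  }
  (Ot * p_ij - Et_ij) / Et_ij
}

#' Proportional deviation from the beech baseline
#'
#' `(value - mean(baseline)) / mean(baseline)`: -1 is a 100% decrease,
#' +1 a 100% increase relative to the average of the pure beech stands.
#'
#' @param value Value(s) observed under a forest-type transformation.
#' @param beech_values Baseline values (pure beech stands).
#' @return Proportional deviation(s).
#' @export
proportional_deviation <- function(value, beech_values) {
  beech_values <- beech_values[!is.na(beech_values)]
  if (length(beech_values) == 0) {
    stop_forestmf("empty baseline")
  }
  m <- mean(beech_values)
  if (m == 0) {
    stop_forestmf("baseline mean is zero; proportional deviation undefined")
  }
  (value - m) / m
}

#' Pearson correlations among the three dimensions
#'
#' Pairwise Pearson correlations (with two-sided t-based p-values) among
#' multidiversity, ecosystem multifunctionality and economic
#' multifunctionality across plots, after listwise deletion of incomplete
#' plots.
#'
#' @param indices Tibble of per-plot indices, e.g. from
#'   [compute_dimension_indices()].
#' @param dims Names of the dimension columns.
#' @return Tibble with `dim_x`, `dim_y`, `r`, `p_value` and the number of
#'   complete plots `n` used.
#' @export
dimension_correlations <- function(indices,
                                   dims = c("multidiversity", "ecosystem_mf",
                                     "economic_mf")) {
  x <- indices[, dims, drop = FALSE]
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 3) {
    stop_forestmf("at least 3 complete plots are required")
  }
  if (any(vapply(x, sd, numeric(1)) == 0)) {
    stop_forestmf("a dimension has zero variance; correlation undefined")
  }
  pairs <- utils::combn(dims, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    ct <- cor.test(x[[p[1]]], x[[p[2]]], method = "pearson")
    tibble(
      dim_x = p[1], dim_y = p[2],
      r = unname(ct$estimate), p_value = ct$p.value, n = nrow(x)
    )
  }) %>% bind_rows()
}

#' Species overlap among forest types
#'
#' Percentage of the pooled species list shared among all forest types,
#' and the percentage found in exactly one type.
#'
#' @param sets Named list of per-forest-type species vectors (at least two
#'   non-empty sets).
#' @return Tibble with one row per set: `set`, `n_species`, `unique_pct`,
#'   and the overall `shared_pct` (identical in every row).
#' @examples
#' species_overlap(list(a = c("x", "y"), b = c("x", "z")))
#' @export
species_overlap <- function(sets) {
  sets <- purrr::map(sets, unique)
  if (sum(lengths(sets) > 0) < 2) {
    stop_forestmf("at least two non-empty species sets are required")
  }
  pool <- unique(unlist(sets))
  shared <- Reduce(intersect, sets)
  shared_pct <- 100 * length(shared) / length(pool)
  counts <- table(unlist(sets))
  purrr::imap(sets, function(s, nm) {
    uniq <- sum(counts[s] == 1)
    tibble(
      set = nm, n_species = length(s),
      unique_pct = 100 * uniq / length(pool),
      shared_pct = shared_pct
    )
  }) %>% bind_rows()
}
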