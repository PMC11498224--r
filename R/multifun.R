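#' Pairwise distance among indicators from their correlation across plots
#'
#' The correlation-corrected effective number of functions needs a notion
#' of distinctiveness among indicators. Here the distance between
#' indicators k and j is derived from their Pearson correlation across
#' plots: `d_kj = (1 - r_kj) / 2` (perfectly correlated pairs are
#' redundant, d = 0; perfectly anti-correlated pairs maximally distinct,
#' d = 1). An absolute-value variant `d = 1 - |r|` treats negative
#' correlation as redundancy instead.
#'
#' @param normalized A plots x indicators numeric matrix or a tibble of
#'   normalized indicator columns (any non-numeric metadata columns are
#'   dropped). Needs at least 3 plots and 2 indicators, with no
#'   undefined correlations (no missing cells, no constant columns).
#' @param metric `"neg_half"` (default) for `(1 - r)/2`, `"abs"` for
#'   `1 - |r|`.
#' @return A K x K symmetric distance matrix with zero diagonal, entries
#'   in \[0, 1\].
#' @export
function_distance <- function(normalized, metric = c("neg_half", "abs")) {
  metric <- match.arg(metric)
  x <- as.matrix(dplyr::select(as_tibble(normalized), dplyr::where(is.numeric)))
  if (nrow(x) < 3) {
    stop_forestmf("at least 3 plots are needed to estimate correlations")
  }
  if (ncol(x) < 2) {
    stop_forestmf("at least 2 indicators are needed")
  }
  r <- suppressWarnings(cor(x, use = "everything"))
  if (any(!is.finite(r))) {
    stop_forestmf(paste0(
      "undefined correlation among indicators (missing values or a ",
      "constant column); normalize and impute before computing distances"
    ))
  }
  d <- if (metric == "neg_half") (1 - r) / 2 else 1 - abs(r)
  d <- pmin(pmax(d, 0), 1)
  diag(d) <- 0
  d
}

#' Correlation-corrected multifunctionality at one distinctiveness level
#'
#' The effective number of functions of one plot at threshold `tau`:
#' indicator pairs closer than `tau` are treated as partially redundant.
#' With truncated distances `d_kj(tau) = min(d_kj, tau)` and the
#' redundancy-adjusted level `a_k = sum_j (1 - d_kj(tau)/tau) * f_j`, the
#' order-0 value is `sum_k f_k^2 / a_k` (0/0 terms count as 0). When all
#' off-diagonal distances are at least `tau` this is the plain sum of the
#' normalized levels; K identical perfectly correlated functions at level
#' f collapse to f.
#'
#' @param f Numeric vector of normalized function levels in \[0, 1\].
#' @param D Distance matrix from [function_distance()].
#' @param tau Distinctiveness threshold, `0 < tau <= 1`.
#' @param q Diversity order; only `q = 0` (the tested surface) is
#'   implemented.
#' @return The multifunctionality value at `tau` (a single number).
#' @examples
#' D <- matrix(c(0, 1, 1, 0), 2)
#' hill_chao_mf_at_tau(c(1, 1), D, tau = 1) # 2
#' @export
hill_chao_mf_at_tau <- function(f, D, tau, q = 0) {
  if (!identical(q, 0) && !isTRUE(all.equal(q, 0))) {
    stop_forestmf("only q = 0 is implemented")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop_forestmf("`tau` must be a single positive number")
  }
  if (any(f < -1e-8) || any(f > 1 + 1e-8)) {
    stop_forestmf("`f` must lie in [0, 1]")
  }
  f <- pmin(pmax(f, 0), 1)
  w <- 1 - pmin(D, tau) / tau
  a <- as.numeric(w %*% f)
  ifelse_sum_(f, a)
}

# sum of f^2 / a with 0/0 := 0 (a_k = 0 implies f_k = 0 since diag weight 1)
ifelse_sum_ <- function(f, a) {
  term <- rep(0, length(f))
  pos <- a > 0
  term[pos] <- f[pos]^2 / a[pos]
  sum(term)
}

#' Effective number of functions via the tau-profile AUC
#'
#' Evaluates the corrected multifunctionality of one plot on a uniform
#' grid of `tau` values spanning the positive pairwise distances, and
#' summarises the profile by its range-normalized area under the curve
#' (trapezoidal rule). Degenerate cases: if all positive distances are
#' equal the single profile value is returned as the AUC; if every
#' distance is zero (full redundancy) the common-level value is returned
#' with a warning.
#'
#' @inheritParams hill_chao_mf_at_tau
#' @param grid_size Number of tau grid points (>= 2; default 100).
#' @return A `mf_tau_profile` object: list with `q`, `taus`, `values`,
#'   `auc` and `k` (number of indicators). `tidy()` gives the profile as
#'   a tibble, `glance()` the AUC, `autoplot()` the tau-curve.
#' @export
mf_effective_number <- function(f, D, q = 0, grid_size = 100) {
  check_number(grid_size, "grid_size", lower = 2)
  d_off <- D[upper.tri(D)]
  pos <- d_off[d_off > 0]
  if (length(pos) == 0) {
    warn("all pairwise distances are zero: tau-profile degenerate, returning the full-redundancy value")
    val <- hill_chao_mf_at_tau(f, D, tau = 1, q = q)
    return(new_tau_profile(q, taus = 1, values = val, auc = val, k = length(f)))
  }
  dmin <- min(pos)
  dmax <- max(d_off)
  if (isTRUE(all.equal(dmin, dmax))) {
    val <- hill_chao_mf_at_tau(f, D, tau = dmax, q = q)
    return(new_tau_profile(q, taus = dmax, values = val, auc = val,
      k = length(f)))
  }
  taus <- seq(dmin, dmax, length.out = grid_size)
  values <- vapply(taus, function(t) hill_chao_mf_at_tau(f, D, t, q = q),
    numeric(1))
  auc <- trapz_(taus, values) / (dmax - dmin)
  new_tau_profile(q, taus, values, auc, k = length(f))
}

new_tau_profile <- function(q, taus, values, auc, k) {
  structure(
    list(q = q, taus = taus, values = values, auc = auc, k = k),
    class = "mf_tau_profile"
  )
}

#' @export
print.mf_tau_profile <- function(x, ...) {
  cat("Tau profile (q = ", x$q, ", K = ", x$k, " indicators)\n", sep = "")
  cat("  tau range: [", format(min(x$taus), digits = 4), ", ",
    format(max(x$taus), digits = 4), "], ", length(x$taus),
    " grid points\n", sep = "")
  cat("  effective number (AUC): ", format(x$auc, digits = 6), "\n", sep = "")
  invisible(x)
}

# Vectorized per-plot AUC over a normalized plots x indicators matrix,
# sharing one distance matrix and tau grid across plots.
mf_auc_matrix_ <- function(F_mat, D, grid_size = 100) {
  d_off <- D[upper.tri(D)]
  pos <- d_off[d_off > 0]
  one_tau <- function(tau) {
    w <- 1 - pmin(D, tau) / tau
    A <- F_mat %*% w # plots x K redundancy-adjusted levels
    num <- F_mat^2
    vals <- num / A
    vals[A <= 0] <- 0
    rowSums(vals)
  }
  if (length(pos) == 0) {
    warn("all pairwise distances are zero: tau-profile degenerate, returning the full-redundancy value")
    return(one_tau(1))
  }
  dmin <- min(pos)
  dmax <- max(d_off)
  if (isTRUE(all.equal(dmin, dmax))) {
    return(one_tau(dmax))
  }
  taus <- seq(dmin, dmax, length.out = grid_size)
  profile <- vapply(taus, one_tau, numeric(nrow(F_mat)))
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  apply(profile, 1, function(v) trapz_(taus, v)) / (dmax - dmin)
}

#' Threshold-approach multifunctionality counts
#'
#' For each plot and each threshold t, counts how many indicators reach at
#' least t% of that indicator's maximum observed value across the plots of
#' the table (ties at the boundary count as meeting the threshold).
#'
#' @param table A plot-level tibble (raw or normalized values; the counts
#'   are invariant to per-indicator affine rescaling with positive slope).
#' @param indicator_set Indicator columns to count over.
#' @param thresholds Numeric thresholds in percent, each in (0, 100\];
#'   default `1:99`.
#' @param id_col Plot identifier column, default `"plot_id"`.
#' @return A long tibble (class `mf_threshold`): `plot_id`, `threshold`,
#'   `count`. Counts are non-increasing in the threshold.
#' @export
threshold_mf <- function(table, indicator_set, thresholds = 1:99,
                         id_col = "plot_id") {
  if (any(thresholds <= 0 | thresholds > 100)) {
    stop_forestmf("thresholds must lie in (0, 100]")
  }
  x <- as.matrix(table[, indicator_set, drop = FALSE])
  maxima <- apply(x, 2, max, na.rm = TRUE)
  if (any(maxima <= 0)) {
    stop_forestmf("per-indicator maxima must be positive for the threshold approach")
  }
  rows <- purrr::map(thresholds, function(t) {
    meets <- sweep(x, 2, t / 100 * maxima, FUN = ">=")
    tibble(
      plot_id = table[[id_col]],
      threshold = t,
      count = rowSums(meets, na.rm = TRUE)
    )
  })
  out <- bind_rows(rows)
  structure(out, class = c("mf_threshold", class(out)))
}

#' Per-plot effective numbers for the three management dimensions
#'
#' Wrapper producing the three integrative indices: for each dimension
#' block (biodiversity, ecosystem, economic), the member indicators are
#' min-max normalized within the block over the included plots, a
#' correlation-based distance matrix is computed, and each plot's
#' effective number of taxa/functions is the tau-profile AUC at q = 0.
#'
#' @param table A plot-by-indicator tibble (e.g. from
#'   [generate_indicators()], after imputation); only non-excluded plots
#'   are used.
#' @param meta Indicator metadata (tibble with `indicator`, `dimension`,
#'   `index_member`, `direction` columns); defaults to the metadata
#'   attached to `table`.
#' @param grid_size Tau-grid size passed to the profile computation.
#' @param metric Distance metric, see [function_distance()].
#' @return A tibble with the plot metadata and columns `multidiversity`,
#'   `ecosystem_mf`, `economic_mf`.
#' @export
compute_dimension_indices <- function(table, meta = NULL, grid_size = 100,
                                      metric = "neg_half") {
  meta <- meta %||% attr(table, "meta")
  if (is.null(meta)) {
    stop_forestmf("indicator metadata (dimension tags) required")
  }
  tab <- included_plots(table)
  dims <- c(
    biodiversity = "multidiversity",
    ecosystem = "ecosystem_mf",
    economic = "economic_mf"
  )
  id_cols <- intersect(
    c("plot_id", "quintet", "region", "forest_type"), names(tab)
  )
  out <- tab[, id_cols, drop = FALSE]
  for (d in names(dims)) {
    members <- meta$indicator[meta$dimension == d & meta$index_member]
    if (length(members) < 2) {
      stop_forestmf(paste0(
        "dimension '", d, "' has fewer than 2 member indicators"
      ))
    }
    dirs <- setNames(meta$direction[match(members, meta$indicator)], members)
    norm <- minmax_normalize(tab, members, dirs)
    f_mat <- as.matrix(norm[, members, drop = FALSE])
    if (any(is.na(f_mat))) {
      stop_forestmf(paste0(
        "dimension '", d, "' has missing member values; impute or exclude ",
        "the affected indicator first"
      ))
    }
    D <- function_distance(f_mat, metric = metric)
    out[[dims[[d]]]] <- mf_auc_matrix_(f_mat, D, grid_size = grid_size)
  }
  as_tibble(out)
}
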