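#' Expected rarefied species richness
#'
#' Expected number of species (or OTUs) in a random subsample of `n`
#' individuals drawn without replacement from an observed count vector —
#' the hypergeometric expectation
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`.
#' Computation is delegated to [vegan::rarefy()], which evaluates the
#' binomial ratios on the log scale and is stable for large totals.
#'
#' @param counts Non-negative integer vector of per-species counts.
#' @param n Subsample size, `0 <= n <= sum(counts)`.
#' @return Expected richness (a single number).
#' @examples
#' rarefy_richness(c(9, 1), 2) # 1.2
#' @export
rarefy_richness <- function(counts, n) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_forestmf("`counts` must be non-negative integers")
  }
  check_number(n, "n", lower = 0)
  total <- sum(counts)
  if (n > total) {
    stop_forestmf(paste0(
      "subsample size n = ", n, " exceeds the total count N = ", total
    ))
  }
  if (n == 0) {
    return(0)
  }
  # muffle vegan's advisory aimed at raw community matrices; a pooled
  # count vector legitimately has a smallest count > 1
  withCallingHandlers(
    as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = n)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Impute missing values by within-group median
#'
#' Replaces missing cells of one indicator column by the median of the
#' non-missing values in the same group (e.g. the median litter
#' decomposition per forest type). Non-missing cells are never touched.
#'
#' @param table A plot-level tibble.
#' @param indicator Name of the column to impute.
#' @param group_column Name of the grouping column (e.g. `"forest_type"`).
#' @return The table with missing cells filled; an imputation log (tibble
#'   of group, number imputed and median used) is attached as attribute
#'   `"imputation_log"`.
#' @export
impute_median_by_group <- function(table, indicator,
                                   group_column = "forest_type") {
  if (!group_column %in% names(table)) {
    stop_forestmf(paste0("group column '", group_column, "' not found"))
  }
  if (!indicator %in% names(table)) {
    stop_forestmf(paste0("indicator '", indicator, "' not found"))
  }
  x <- table[[indicator]]
  g <- table[[group_column]]
  log <- list()
  for (grp in unique(g[is.na(x)])) {
    vals <- x[g == grp & !is.na(x)]
    if (length(vals) == 0) {
      stop_forestmf(paste0(
        "group '", grp, "' has no observed values of '", indicator,
        "' to impute from"
      ))
    }
    med <- median(vals)
    idx <- which(g == grp & is.na(x))
    x[idx] <- med
    log[[grp]] <- tibble(group = grp, n_imputed = length(idx), median = med)
  }
  table[[indicator]] <- x
  attr(table, "imputation_log") <- bind_rows(log)
  table
}

#' Min-max normalization of an indicator block
#'
#' Rescales each selected indicator to \[0, 1\] over the plots of the
#' table: `x' = (x - min) / (max - min)`, so the highest observed value
#' maps to 1 and the lowest to 0. Indicators flagged `"less"` (smaller is
#' better) are reflected, `x' = (max - x) / (max - min)`. The dimension
#' blocks of a multifunctionality analysis are normalized separately by
#' calling this once per block.
#'
#' @param table A plot-level tibble.
#' @param indicator_set Character vector of indicator columns to scale.
#' @param direction_flags Optional named character vector (`"more"` /
#'   `"less"`) per indicator; default all `"more"`.
#' @return A tibble with the plot metadata columns and the normalized
#'   indicators (class `mf_normalized`); the min/max and direction used
#'   per indicator are recorded in attribute `"scaling"`.
#' @examples
#' t <- tibble::tibble(plot_id = letters[1:3], x = c(2, 4, 6))
#' minmax_normalize(t, "x")$x # 0 0.5 1
#' @export
minmax_normalize <- function(table, indicator_set, direction_flags = NULL) {
  missing_cols <- setdiff(indicator_set, names(table))
  if (length(missing_cols) > 0) {
    stop_forestmf(paste0(
      "indicator(s) not found: ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (is.null(direction_flags)) {
    direction_flags <- setNames(rep("more", length(indicator_set)),
      indicator_set)
  }
  out <- table
  scaling <- list()
  for (ind in indicator_set) {
    x <- table[[ind]]
    rng <- range(x, na.rm = TRUE)
    if (!all(is.finite(rng)) || rng[1] == rng[2]) {
      stop_forestmf(paste0(
        "indicator '", ind, "' is constant (or all missing): min-max ",
        "scaling is undefined and the indicator carries no information"
      ))
    }
    z <- (x - rng[1]) / (rng[2] - rng[1])
    if (identical(direction_flags[[ind]], "less")) {
      z <- 1 - z
    }
    out[[ind]] <- z
    scaling[[ind]] <- tibble(
      indicator = ind, min = rng[1], max = rng[2],
      direction = direction_flags[[ind]]
    )
  }
  structure(out,
    scaling = bind_rows(scaling),
    class = c("mf_normalized", class(as_tibble(out)))
  )
}

#' Microbial biomass from substrate-induced respiration
#'
#' Converts the maximum initial respiration response (MIRR, O2 consumption
#' rate) of a glucose-amended litter sample into microbial biomass
#' (ug C_mic per g) via the standard calibration factor 38.
#'
#' @param mirr Non-negative O2-consumption rate(s).
#' @return `38 * mirr`.
#' @export
microbial_biomass_from_mirr <- function(mirr) {
  if (any(mirr < 0, na.rm = TRUE)) {
    stop_forestmf("`mirr` must be non-negative")
  }
  38 * mirr
}
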