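#' Forest-type transformation analysis with bootstrap inference
#'
#' Quantifies the effect of transforming pure beech stands into each of
#' the other forest types (enrichment mixtures or pure conifer stands):
#' for every transformation x dimension cell it computes the proportional
#' deviation of the transformed stands' mean index from the beech mean,
#' with a BCa bootstrap confidence interval, and labels the cell `"win"`
#' (CI entirely above zero), `"lose"` (entirely below) or `"neutral"`
#' (spanning zero).
#'
#' By default both groups are resampled (plots within each forest type
#' independently), so the uncertainty of the beech baseline is
#' propagated; `fixed_baseline = TRUE` conditions on the observed beech
#' mean and resamples the transformed plots only.
#'
#' @param indices Per-plot dimension indices with a `forest_type` column,
#'   e.g. from [compute_dimension_indices()].
#' @param dims Dimension columns to analyse.
#' @param baseline Baseline forest type, default `"beech"`.
#' @param B Bootstrap replicates per cell, default 10000.
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed; each cell uses a deterministic child seed.
#' @param method Interval method, `"bca"` or `"percentile"`.
#' @param fixed_baseline Condition on the observed beech mean instead of
#'   resampling it.
#' @return Tibble (class `mf_transformation`) with one row per
#'   transformation x dimension: `forest_type`, `dimension`, `estimate`,
#'   `ci_low`, `ci_high`, `label`, `n_boot`, `ci_method`, `level`,
#'   `seed`. `autoplot()` draws the effect panels; `glance()` tallies the
#'   labels.
#' @export
transformation_analysis <- function(indices,
                                    dims = c("multidiversity",
                                      "ecosystem_mf", "economic_mf"),
                                    baseline = "beech", B = 10000,
                                    level = 0.95, seed = 1,
                                    method = "bca",
                                    fixed_baseline = FALSE) {
  if (!baseline %in% indices$forest_type) {
    stop_forestmf(paste0("no '", baseline, "' plots present"))
  }
  types <- setdiff(unique(indices$forest_type), baseline)
  cells <- tidyr::expand_grid(forest_type = types, dimension = dims)
  rows <- purrr::pmap(cells, function(forest_type, dimension) {
    xb <- indices[[dimension]][indices$forest_type == baseline]
    xt <- indices[[dimension]][indices$forest_type == forest_type]
    xb <- xb[!is.na(xb)]
    xt <- xt[!is.na(xt)]
    if (length(xt) < 2 || length(xb) < 2) {
      stop_forestmf(paste0(
        "fewer than 2 plots for '", forest_type, "' or the baseline"
      ))
    }
    cell_seed <- child_seed(seed,
      match(forest_type, types) * 101 + match(dimension, dims))
    if (fixed_baseline) {
      mb <- mean(xb)
      res <- bootstrap_ci(xt, function(x) (mean(x) - mb) / mb,
        B = B, level = level, method = method, seed = cell_seed
      )
    } else {
      df <- tibble(
        value = c(xb, xt),
        grp = rep(c("baseline", "transform"), c(length(xb), length(xt)))
      )
      stat <- function(d) {
        mb <- mean(d$value[d$grp == "baseline"])
        (mean(d$value[d$grp == "transform"]) - mb) / mb
      }
      res <- bootstrap_ci(df, stat,
        B = B, level = level, method = method, seed = cell_seed,
        groups = df$grp
      )
    }
    res %>%
      mutate(
        forest_type = forest_type, dimension = dimension,
        label = dplyr::case_when(
          ci_low > 0 ~ "win",
          ci_high < 0 ~ "lose",
          TRUE ~ "neutral"
        ),
        .before = 1
      )
  })
  out <- bind_rows(rows) %>%
    select(
      "forest_type", "dimension", "estimate", "ci_low", "ci_high",
      "label", "n_boot", "ci_method", "level", "seed"
    )
  structure(out, class = c("mf_transformation", class(tibble())))
}
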