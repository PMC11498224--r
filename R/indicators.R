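#' Specify the generative model for one indicator
#'
#' Each indicator is simulated from a linear predictor
#' `baseline (+ log link for counts) + forest-type effect + quintet random
#' effect + loading x latent plot factor`, plus residual noise. The shared
#' latent plot factor (standard normal, one value per plot) induces the
#' inter-indicator correlation that the correlation-corrected effective
#' numbers act on.
#'
#' @param indicator Indicator name.
#' @param dimension One of `"biodiversity"`, `"ecosystem"`, `"economic"`.
#' @param family `"gaussian"` for continuous indicators or `"count"` for a
#'   log-link (possibly over-dispersed) count family.
#' @param baseline Baseline level (mean for gaussian; mean count for count
#'   indicators, the forest-type effects then act on the log scale).
#' @param effects Named numeric vector of forest-type effects covering all
#'   five forest types.
#' @param quintet_sd,resid_sd,loading Random-effect SD per quintet,
#'   residual SD (gaussian only), and loading on the latent plot factor.
#' @param dispersion Negative-binomial size parameter for count indicators;
#'   `Inf` gives Poisson.
#' @param direction `"more"` if larger raw values are better, `"less"`
#'   otherwise (all indicators of the default preset use `"more"`).
#' @param index_member Logical: does this indicator enter its dimension's
#'   integrative index?
#' @param missing_rule A list describing missingness: `list(type = "none")`,
#'   `list(type = "quintets", quintets = <ids>)` (measured only on those
#'   quintets), or `list(type = "mar_k", k = <n>)` (k cells missing at
#'   random among included plots).
#' @return A one-row tibble usable as a building block of the `models`
#'   argument of [generate_indicators()].
#' @export
indicator_model <- function(indicator, dimension, family = "gaussian",
                            baseline = 1, effects = NULL,
                            quintet_sd = 0, resid_sd = 0, loading = 0,
                            dispersion = Inf, direction = "more",
                            index_member = TRUE,
                            missing_rule = list(type = "none")) {
  if (!dimension %in% c("biodiversity", "ecosystem", "economic")) {
    stop_forestmf(paste0("unknown dimension '", dimension, "'"))
  }
  if (!family %in% c("gaussian", "count")) {
    stop_forestmf(paste0("unknown family '", family, "'"))
  }
  if (is.null(effects)) {
    effects <- setNames(rep(0, 5), forest_types())
  }
  if (!all(forest_types() %in% names(effects))) {
    stop_forestmf(paste0(
      "`effects` for indicator '", indicator,
      "' must name every forest type"
    ))
  }
  for (s in c(quintet_sd, resid_sd)) {
    if (s < 0) {
      stop_forestmf("standard deviations must be >= 0")
    }
  }
  tibble(
    indicator = indicator, dimension = dimension, family = family,
    baseline = baseline, effects = list(effects[forest_types()]),
    quintet_sd = quintet_sd, resid_sd = resid_sd, loading = loading,
    dispersion = dispersion, direction = direction,
    index_member = index_member, missing_rule = list(missing_rule)
  )
}

#' Simulate a plot-by-indicator table over a study design
#'
#' Draws every indicator of `models` for every plot of `design` from the
#' one-factor generative model described in [indicator_model()], applies
#' each indicator's missingness rule, and returns the design columns plus
#' one column per indicator. Missing-at-random cells are drawn among
#' non-excluded plots so the post-exclusion table reproduces the configured
#' missingness count exactly.
#'
#' @param design A design from [generate_design()].
#' @param models A tibble of stacked [indicator_model()] rows.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @return A tibble (class `mf_indicators`) of plots x indicators with the
#'   design metadata columns; the `models` table is attached as attribute
#'   `"meta"` and retrievable with [indicator_meta()].
#' @examples
#' d <- generate_design(2, seed = 1)
#' m <- indicator_model("soil_c", "ecosystem", baseline = 60, resid_sd = 5)
#' generate_indicators(d, m, seed = 2)
#' @export
generate_indicators <- function(design, models, seed = 1) {
  stopifnot(is.data.frame(design), is.data.frame(models))
  check_number(seed, "seed")
  if (any(models$quintet_sd < 0) || any(models$resid_sd < 0)) {
    stop_forestmf("standard deviations must be >= 0")
  }
  for (eff in models$effects) {
    if (!all(forest_types() %in% names(eff))) {
      stop_forestmf("every effect vector must name all five forest types")
    }
  }

  n_plot <- nrow(design)
  quintets <- unique(design$quintet)
  out <- design

  with_seed_(seed, {
    latent <- rnorm(n_plot)
    for (i in seq_len(nrow(models))) {
      m <- models[i, ]
      eff <- m$effects[[1]][design$forest_type]
      qre <- rnorm(length(quintets), 0, m$quintet_sd)[
        match(design$quintet, quintets)
      ]
      shift <- eff + qre + m$loading * latent
      y <- if (m$family == "gaussian") {
        m$baseline + shift + rnorm(n_plot, 0, m$resid_sd)
      } else {
        mu <- exp(log(m$baseline) + shift)
        if (is.infinite(m$dispersion)) {
          rpois(n_plot, mu)
        } else {
          rnbinom(n_plot, size = m$dispersion, mu = mu)
        }
      }
      y <- apply_missing_(y, m$missing_rule[[1]], design)
      out[[m$indicator]] <- y
    }
  })

  structure(as_tibble(out),
    meta = models, seed = seed,
    class = c("mf_indicators", class(as_tibble(out)))
  )
}

apply_missing_ <- function(y, rule, design) {
  type <- rule$type %||% "none"
  if (type == "none") {
    return(y)
  }
  if (type == "quintets") {
    y[!design$quintet %in% rule$quintets] <- NA
    return(y)
  }
  if (type == "mar_k") {
    eligible <- which(!design$excluded)
    k <- rule$k
    if (k > length(eligible)) {
      stop_forestmf("missingness k exceeds the number of included plots")
    }
    y[sample(eligible, k)] <- NA
    return(y)
  }
  stop_forestmf(paste0("unknown missingness rule '", type, "'"))
}

#' Indicator metadata of a simulated table
#'
#' @param x A table from [generate_indicators()].
#' @return The `models` tibble used to generate it (one row per indicator,
#'   with dimension tags, directions and index membership).
#' @export
indicator_meta <- function(x) {
  meta <- attr(x, "meta")
  if (is.null(meta)) {
    stop_forestmf("`x` carries no indicator metadata")
  }
  meta
}
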