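#' Run the full analysis pipeline on a configuration
#'
#' Chains the five stages — simulate (design + indicator table +
#' per-plot stand inventories), preprocess (median imputation), mf
#' (per-plot effective numbers of taxa/functions), econ (six economic
#' indicators from simulated stand trajectories) and effects
#' (transformation analysis and dimension correlations) — under a single
#' seed. Every stage draws its randomness from a child seed derived
#' deterministically from `seed`, so outputs are a pure function of
#' (config, seed) and a stage rerun from persisted intermediates equals
#' the monolithic run.
#'
#' @param config A configuration, e.g. [paper_like_preset()].
#' @param seed Integer master seed.
#' @param out_dir Optional output directory; if given, all tables are
#'   written as CSV plus a JSON run manifest (seed, config hash, package
#'   version).
#' @param B,level Bootstrap replicates and confidence level for the
#'   effects stage; default from `config$analysis`.
#' @return A list with `design`, `indicators`, `table` (imputed),
#'   `indices`, `econ`, `transformation`, `correlations`, `manifest`.
#' @export
run_pipeline <- function(config = paper_like_preset(), seed = 1,
                         out_dir = NULL,
                         B = config$analysis$B,
                         level = config$analysis$level) {
  sim <- stage_simulate(config, seed)
  prep <- stage_preprocess(config, sim)
  mf <- stage_mf(config, prep)
  econ <- stage_econ(config, seed, sim)
  eff <- stage_effects(config, seed, mf, B = B, level = level)

  manifest <- list(
    package = "forestmf",
    version = as.character(utils::packageVersion("forestmf")),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    created = format(Sys.time(), tz = "UTC")
  )
  out <- list(
    design = sim$design, indicators = sim$indicators, table = prep$table,
    indices = mf$indices, econ = econ$econ,
    transformation = eff$transformation, correlations = eff$correlations,
    manifest = manifest
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      utils::write.csv(as.data.frame(x), file.path(out_dir, name),
        row.names = FALSE)
    }
    wr(sim$design, "design.csv")
    wr(flatten_indicators_(sim$indicators), "indicators.csv")
    wr(mf$indices, "indices.csv")
    wr(econ$econ, "econ_indicators.csv")
    wr(eff$transformation, "transformation_effects.csv")
    wr(eff$correlations, "correlations.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE)
  }
  out
}

flatten_indicators_ <- function(x) {
  as_tibble(x)
}

stage_simulate <- function(config, seed) {
  d <- config$design
  design <- generate_design(
    n_quintets = d$n_quintets, seed = child_seed(seed, 1),
    exclusions = d$exclusions %||% character(),
    mean_age = d$mean_age %||% 80, age_sd = d$age_sd %||% 4
  )
  indicators <- generate_indicators(design, config$indicators,
    seed = child_seed(seed, 2))
  list(design = design, indicators = indicators)
}

stage_preprocess <- function(config, inputs) {
  if (is.null(inputs$indicators)) {
    stop_forestmf("preprocess stage needs `indicators`",
      class = "forestmf_error_input")
  }
  meta <- config$indicators
  table <- included_plots(inputs$indicators)
  logs <- list()
  members <- meta$indicator[meta$index_member]
  for (ind in members) {
    if (any(is.na(table[[ind]]))) {
      table <- impute_median_by_group(table, ind, "forest_type")
      logs[[ind]] <- attr(table, "imputation_log")
    }
  }
  list(table = table, imputation_log = bind_rows(logs))
}

stage_mf <- function(config, inputs) {
  if (is.null(inputs$table)) {
    stop_forestmf("mf stage needs the preprocessed `table`",
      class = "forestmf_error_input")
  }
  indices <- compute_dimension_indices(
    inputs$table,
    meta = config$indicators,
    grid_size = config$analysis$tau_grid %||% 100,
    metric = config$analysis$distance_metric %||% "neg_half"
  )
  list(indices = indices)
}

stage_econ <- function(config, seed, inputs) {
  if (is.null(inputs$design)) {
    stop_forestmf("econ stage needs the `design`",
      class = "forestmf_error_input")
  }
  plots <- included_plots(inputs$design)
  valuation <- build_valuation(config$econ$valuation)
  rows <- purrr::map(seq_len(nrow(plots)), function(r) {
    plot <- plots[r, ]
    inv <- generate_stand_inventory(plot, config$econ$stand %||% list(),
      seed = child_seed(seed, 1000 + r))
    traj <- simulate_trajectory(inv)
    compute_econ_indicators(plot, traj,
      valuation = valuation,
      survival_model = config$econ$survival,
      planting = config$econ$planting,
      i = config$econ$interest_rate, t_max = config$econ$t_max
    )
  })
  list(econ = bind_rows(rows))
}

stage_effects <- function(config, seed, inputs, B = config$analysis$B,
                          level = config$analysis$level) {
  if (is.null(inputs$indices)) {
    stop_forestmf("effects stage needs the `indices`",
      class = "forestmf_error_input")
  }
  list(
    transformation = transformation_analysis(inputs$indices,
      B = B, level = level, seed = child_seed(seed, 3)),
    correlations = dimension_correlations(inputs$indices)
  )
}

#' Run a single pipeline stage
#'
#' @param stage One of `"simulate"`, `"preprocess"`, `"mf"`, `"econ"`,
#'   `"effects"`, `"run-all"`.
#' @param config A configuration, e.g. [paper_like_preset()].
#' @param seed Integer master seed (stages derive child seeds, so a stage
#'   rerun from persisted inputs matches the monolithic run).
#' @param inputs Outputs of the prerequisite stage(s); if `NULL` the
#'   prerequisites are computed on the fly.
#' @param ... Passed on to the stage (e.g. `B`, `level`, `out_dir` for
#'   `"run-all"`).
#' @return The stage's output list. Unknown stages signal a
#'   `forestmf_error_stage` condition; missing inputs a
#'   `forestmf_error_input` condition.
#' @export
run_stage <- function(stage, config = paper_like_preset(), seed = 1,
                      inputs = NULL, ...) {
  stages <- c("simulate", "preprocess", "mf", "econ", "effects", "run-all")
  if (!is.character(stage) || length(stage) != 1 || !stage %in% stages) {
    abort(
      paste0(
        "unknown stage '", paste(stage, collapse = ","), "'; must be one of ",
        paste(stages, collapse = ", ")
      ),
      class = c("forestmf_error_stage", "forestmf_error")
    )
  }
  switch(stage,
    "run-all" = run_pipeline(config, seed, ...),
    "simulate" = stage_simulate(config, seed),
    "preprocess" = stage_preprocess(config,
      inputs %||% stage_simulate(config, seed)),
    "mf" = stage_mf(config,
      inputs %||% stage_preprocess(config, stage_simulate(config, seed))),
    "econ" = stage_econ(config, seed,
      inputs %||% stage_simulate(config, seed)),
    "effects" = stage_effects(config, seed,
      inputs %||% stage_mf(config,
        stage_preprocess(config, stage_simulate(config, seed))), ...)
  )
}

#' Validate a configuration
#'
#' Range and sanity checks on a configuration: interest rate (the annuity
#' requires `i > 0`), bootstrap replicates (`B >= 100`), confidence level
#' in (0, 1), non-negative variance components, and reminders that the
#' valuation, survival and planting coefficients of the preset are
#' synthetic placeholders.
#'
#' @param config A configuration list.
#' @return A tibble of findings (`level` in error/warning/note, `field`,
#'   `message`); no condition is signalled.
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(level, field, message) {
    f[[length(f) + 1]] <<- tibble(level = level, field = field,
      message = message)
  }
  i <- config$econ$interest_rate
  if (!is.null(i) && i <= 0) {
    add("error", "econ.interest_rate",
      "interest rate must be > 0 (annuity precondition: the amortization factor is undefined at i = 0)")
  }
  B <- config$analysis$B
  if (!is.null(B) && B < 100) {
    add("error", "analysis.B",
      paste0("B = ", B, " is below the minimum of 100 bootstrap replicates"))
  }
  lv <- config$analysis$level
  if (!is.null(lv) && (lv <= 0 || lv >= 1)) {
    add("error", "analysis.level", "confidence level must lie in (0, 1)")
  }
  nq <- config$design$n_quintets
  if (!is.null(nq) && nq < 1) {
    add("error", "design.n_quintets", "at least one quintet is required")
  }
  if (!is.null(config$indicators)) {
    if (any(config$indicators$quintet_sd < 0) ||
      any(config$indicators$resid_sd < 0)) {
      add("error", "indicators", "standard deviations must be >= 0")
    }
  }
  add("warning", "econ.valuation",
    "valuation coefficients are synthetic placeholders, not market data")
  add("warning", "econ.survival",
    "survival-model coefficients are synthetic placeholders, not fitted to monitoring data")
  add("warning", "econ.planting",
    "planting costs are synthetic placeholders")
  add("note", "defaults",
    paste0("i = ", i %||% 0.015, ", t_max = ", config$econ$t_max %||% 30,
      ", B = ", B %||% 10000, ", level = ", lv %||% 0.95))
  bind_rows(f)
}

#' Write / read a configuration as YAML
#'
#' Configurations are pure data (parameter lists and the indicator-model
#' table), so they round-trip losslessly through YAML.
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   configuration (class `mf_config`).
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$indicators <- purrr::map(seq_len(nrow(config$indicators)), function(r) {
    m <- config$indicators[r, ]
    list(
      indicator = m$indicator, dimension = m$dimension, family = m$family,
      baseline = m$baseline, effects = as.list(m$effects[[1]]),
      quintet_sd = m$quintet_sd, resid_sd = m$resid_sd,
      loading = m$loading, dispersion = m$dispersion,
      direction = m$direction, index_member = m$index_member,
      missing_rule = m$missing_rule[[1]]
    )
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_forestmf(paste0("config file not found: ", path),
      class = "forestmf_error_input")
  }
  lst <- yaml::read_yaml(path)
  lst$indicators <- purrr::map(lst$indicators, function(m) {
    indicator_model(
      indicator = m$indicator, dimension = m$dimension, family = m$family,
      baseline = m$baseline, effects = unlist(m$effects),
      quintet_sd = m$quintet_sd, resid_sd = m$resid_sd,
      loading = m$loading, dispersion = m$dispersion,
      direction = m$direction, index_member = m$index_member,
      missing_rule = m$missing_rule
    )
  }) %>% bind_rows()
  structure(lst, class = "mf_config")
}
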