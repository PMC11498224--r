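#' Study-like preset configuration
#'
#' Frozen configuration emulating the structure of the quintet study the
#' package is designed around: 8 quintets in 2 regions x 5 forest types
#' (40 plots, the spruce plots of two quintets excluded, leaving 38), nine
#' biodiversity indicators (seven entering multidiversity), nine ecosystem
#' functions (eight entering ecosystem multifunctionality) and six
#' economic indicators (all entering economic multifunctionality), with
#' the qualitative effect pattern built in: enrichment of beech with
#' Douglas-fir raises all three dimensions, enrichment with spruce raises
#' multidiversity but lowers economic multifunctionality.
#'
#' Missingness mirrors the study structure: canopy-arthropod richness only
#' on a 3-quintet subset, birds on a 6-quintet subset, fine-root biomass
#' on 4 of 8 quintets (these three are flagged as non-members of the
#' integrative indices), and six litter-decomposition cells missing at
#' random (to be imputed by forest-type medians).
#'
#' All variance components are synthetic placeholders: the study the
#' design emulates reports no within-plot sampling variances, so SDs were
#' chosen once to give realistic signal-to-noise and are not calibrated to
#' any field data.
#'
#' @return A config list (class `mf_config`) with elements `design`,
#'   `indicators` (a models tibble for [generate_indicators()]), `econ`
#'   (valuation/survival/planting parameter lists) and `analysis`
#'   (tau-grid size, bootstrap replicates `B = 10000`, `level = 0.95`,
#'   interest rate `i = 0.015`, horizon `t_max = 30`).
#' @export
paper_like_preset <- function() {
  ft <- forest_types()
  eff <- function(...) setNames(c(...), ft)

  biodiversity <- bind_rows(
    indicator_model("collembola", "biodiversity", "count",
      baseline = 25, effects = eff(0, .35, .05, .30, .30), dispersion = 30,
      quintet_sd = .08, loading = .05
    ),
    indicator_model("oribatida", "biodiversity", "count",
      baseline = 30, effects = eff(0, .30, .05, .25, .30), dispersion = 30,
      quintet_sd = .08, loading = .05
    ),
    indicator_model("soil_fungi", "biodiversity", "gaussian",
      baseline = 220, effects = eff(0, 45, 30, 35, 30), quintet_sd = 10,
      resid_sd = 18, loading = 8
    ),
    indicator_model("root_fungi", "biodiversity", "gaussian",
      baseline = 150, effects = eff(0, 35, 25, 28, 25), quintet_sd = 8,
      resid_sd = 15, loading = 6
    ),
    indicator_model("small_mammals", "biodiversity", "count",
      baseline = 6, effects = eff(0, .20, .10, .25, .30),
      quintet_sd = .10, loading = .05
    ),
    indicator_model("tree_diversity", "biodiversity", "count",
      baseline = 8, effects = eff(0, .10, .30, .25, .45),
      quintet_sd = .10, loading = .05
    ),
    indicator_model("canopy_beetles", "biodiversity", "count",
      baseline = 60, effects = eff(0, .05, -.35, .10, .15), dispersion = 40,
      quintet_sd = .08, loading = .05
    ),
    indicator_model("canopy_arthropods", "biodiversity", "count",
      baseline = 120, effects = eff(0, 0, -.25, .05, .10), dispersion = 20,
      quintet_sd = .08, loading = .05, index_member = FALSE,
      missing_rule = list(type = "quintets", quintets = sprintf("q%02d", 1:3))
    ),
    indicator_model("birds", "biodiversity", "count",
      baseline = 12, effects = eff(0, .05, -.10, .10, .15),
      quintet_sd = .08, loading = .05, index_member = FALSE,
      missing_rule = list(type = "quintets", quintets = sprintf("q%02d", 1:6))
    )
  )

  ecosystem <- bind_rows(
    indicator_model("soil_c", "ecosystem",
      baseline = 60, effects = eff(0, 8, 6, 3, 6),
      quintet_sd = 3, resid_sd = 6, loading = 2
    ),
    indicator_model("soil_n", "ecosystem",
      baseline = 2.8, effects = eff(0, .20, .30, .10, .35),
      quintet_sd = .10, resid_sd = .30, loading = .08
    ),
    indicator_model("n_c_ratio", "ecosystem",
      baseline = .045, effects = eff(0, .001, .006, 0, .007),
      quintet_sd = .001, resid_sd = .004, loading = .001
    ),
    indicator_model("microbial_biomass", "ecosystem",
      baseline = 900, effects = eff(0, 140, 160, 80, 170),
      quintet_sd = 40, resid_sd = 90, loading = 30
    ),
    indicator_model("aboveground_biomass", "ecosystem",
      baseline = 320, effects = eff(0, 20, 60, 30, 90),
      quintet_sd = 15, resid_sd = 30, loading = 10
    ),
    indicator_model("lai", "ecosystem",
      baseline = 6, effects = eff(0, .30, .60, .40, .90),
      quintet_sd = .20, resid_sd = .50, loading = .15
    ),
    indicator_model("litter_decomposition", "ecosystem",
      baseline = 45, effects = eff(0, 1, 2, 4, 7),
      quintet_sd = 1.5, resid_sd = 4, loading = 1,
      missing_rule = list(type = "mar_k", k = 6)
    ),
    indicator_model("tree_density", "ecosystem", "count",
      baseline = 1500, effects = eff(0, .05, .15, .20, .35), dispersion = 15,
      quintet_sd = .08, loading = .05
    ),
    indicator_model("fine_root_biomass", "ecosystem",
      baseline = 350, effects = eff(0, 30, -40, 20, -20),
      quintet_sd = 15, resid_sd = 35, loading = 10, index_member = FALSE,
      missing_rule = list(type = "quintets", quintets = sprintf("q%02d", 1:4))
    )
  )

  economic <- bind_rows(
    indicator_model("future_wood_volume", "economic",
      baseline = 450, effects = eff(0, -120, -10, -70, -10),
      quintet_sd = 20, resid_sd = 40, loading = 10
    ),
    indicator_model("future_timber_production", "economic",
      baseline = 40, effects = eff(0, 3, 25, 0, 15),
      quintet_sd = 3, resid_sd = 6, loading = 2
    ),
    indicator_model("medium_term_income", "economic",
      baseline = 250, effects = eff(0, -120, 280, -90, 180),
      quintet_sd = 30, resid_sd = 60, loading = 20
    ),
    indicator_model("immediate_profit", "economic",
      baseline = 9000, effects = eff(0, -2500, 9000, -1800, 5500),
      quintet_sd = 800, resid_sd = 1500, loading = 500
    ),
    indicator_model("investment_corrected_profit", "economic",
      baseline = 8000, effects = eff(0, -2600, 8600, -1900, 5200),
      quintet_sd = 800, resid_sd = 1600, loading = 500
    ),
    indicator_model("resistance_disturbances", "economic",
      baseline = .80, effects = eff(0, -.25, -.02, -.05, -.03),
      quintet_sd = .02, resid_sd = .04, loading = .01
    )
  )

  cfg <- list(
    design = list(
      n_quintets = 8,
      exclusions = c("q07_spruce", "q08_spruce"),
      mean_age = 80, age_sd = 4
    ),
    indicators = bind_rows(biodiversity, ecosystem, economic),
    econ = list(
      interest_rate = 0.015,
      t_max = 30,
      valuation = default_valuation_params(),
      survival = default_survival_params(),
      planting = default_planting_params(),
      stand = list(total_basal_area = 35, n_cohorts = 8)
    ),
    analysis = list(
      tau_grid = 100,
      B = 10000,
      level = 0.95,
      distance_metric = "neg_half"
    ),
    version = "1.0"
  )
  structure(cfg, class = "mf_config")
}
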