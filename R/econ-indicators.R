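#' Compute the six economic indicators for one plot
#'
#' Derives from a stand trajectory and the pluggable valuation, survival
#' and planting-cost models the six economic functions:
#' \describe{
#'   \item{future_wood_volume}{standing volume (m3/ha) at the end of the
#'     30-year projection;}
#'   \item{sawn_timber_share}{percentage of the 30-year harvested volume
#'     that is sawn-timber assortment;}
#'   \item{annuity}{annualized net present value of the projection period
#'     (EUR/ha/yr), the medium-term income;}
#'   \item{immediate_profit}{stumpage value of the current stand
#'     (EUR/ha);}
#'   \item{investment_corrected_profit}{stumpage value minus planting
#'     costs compounded from stand establishment (EUR/ha);}
#'   \item{survival_30yr}{conditional stand-level probability of
#'     surviving the projection window.}
#' }
#'
#' @param plot One plot row (with `share_*` columns and `stand_age`).
#' @param trajectory Trajectory from [simulate_trajectory()].
#' @param valuation Valuation model from [build_valuation()].
#' @param survival_model Survival parameters, see
#'   [default_survival_params()].
#' @param planting Named per-species planting costs (EUR/ha), see
#'   [default_planting_params()].
#' @param i Annual interest rate, default 0.015.
#' @param t_max Projection horizon in years, default 30.
#' @return One-row tibble with `plot_id` (if present) and the six
#'   indicator columns.
#' @export
compute_econ_indicators <- function(plot, trajectory,
                                    valuation = build_valuation(),
                                    survival_model = default_survival_params(),
                                    planting = default_planting_params(),
                                    i = 0.015, t_max = 30) {
  final <- trajectory[trajectory$year == max(trajectory$year), , drop = FALSE]
  start <- trajectory[trajectory$year == 0, , drop = FALSE]

  shares <- c(
    beech = plot$share_beech, spruce = plot$share_spruce,
    douglas = plot$share_douglas, other = plot$share_other
  )
  shares <- shares[!is.na(shares)]

  stump <- stumpage_value(
    tibble(species = start$species, volume = start$v_standing,
      qmd = start$qmd),
    valuation
  )
  plant_cost <- sum(shares * planting[names(shares)], na.rm = TRUE)

  tibble(
    plot_id = plot$plot_id %||% NA_character_,
    future_wood_volume = sum(final$v_standing),
    sawn_timber_share = sawn_timber_share(trajectory, valuation),
    annuity = annuity(npv(trajectory, valuation, i), i, t_max),
    immediate_profit = stump,
    investment_corrected_profit = corrected_profit(
      stump, plant_cost, plot$stand_age, i
    ),
    survival_30yr = stand_survival(shares, plot$stand_age,
      model = survival_model, window = t_max)
  )
}
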