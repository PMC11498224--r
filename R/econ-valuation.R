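#' Default valuation parameters (synthetic placeholders)
#'
#' Parametric price, harvest-cost and sawn-assortment curves by species
#' and quadratic mean diameter (QMD). The shapes are conventional —
#' saturating timber price, exponentially decreasing harvest cost, and a
#' logistic sawn-timber share in QMD — but the coefficients are synthetic
#' placeholders, not published market data; swap in your own via
#' [build_valuation()].
#'
#' @return A nested parameter list (per species where species-specific).
#' @export
default_valuation_params <- function() {
  list(
    price = list(
      max = c(beech = 90, spruce = 95, douglas = 110, other = 70),
      qmd_half = 30, steepness = 3
    ),
    harvest_cost = list(min = 18, max = 60, scale = 25),
    sawn_share = list(
      max = c(beech = 0.50, spruce = 0.85, douglas = 0.90, other = 0.40),
      midpoint = 35, slope = 8
    )
  )
}

#' Build a valuation model from parameters
#'
#' @param params Parameter list as in [default_valuation_params()].
#' @return A list of vectorized functions `price(species, qmd)`,
#'   `harvest_cost(species, qmd)`, `sawn_share(species, qmd)` (EUR/m3,
#'   EUR/m3, fraction), class `mf_valuation`. Each errors on species
#'   absent from the parameterisation. Net revenue `price - harvest_cost`
#'   may be negative for small diameters.
#' @export
build_valuation <- function(params = default_valuation_params()) {
  species_of <- function(sp, known) {
    bad <- setdiff(unique(sp), known)
    if (length(bad) > 0) {
      stop_forestmf(paste0(
        "no valuation parameters for species: ", paste(bad, collapse = ", ")
      ), class = "forestmf_error_input")
    }
    sp
  }
  price <- function(species, qmd) {
    species <- species_of(species, names(params$price$max))
    pm <- params$price$max[species]
    cc <- params$price$steepness
    unname(pm * qmd^cc / (qmd^cc + params$price$qmd_half^cc))
  }
  harvest_cost <- function(species, qmd) {
    species_of(species, names(params$price$max))
    p <- params$harvest_cost
    rep_len(p$min + (p$max - p$min) * exp(-qmd / p$scale),
      length.out = max(length(species), length(qmd)))
  }
  sawn_share <- function(species, qmd) {
    species <- species_of(species, names(params$sawn_share$max))
    sm <- params$sawn_share$max[species]
    p <- params$sawn_share
    unname(sm / (1 + exp(-(qmd - p$midpoint) / p$slope)))
  }
  structure(
    list(
      price = price, harvest_cost = harvest_cost, sawn_share = sawn_share,
      params = params
    ),
    class = "mf_valuation"
  )
}

#' Stumpage value of a standing stock
#'
#' Net revenue from hypothetically harvesting the entire standing stock
#' immediately: the sum over species of standing volume times net price
#' (price minus harvest cost at the species' QMD).
#'
#' @param state A tibble with columns `species`, `volume` (m3/ha; the
#'   column `v_standing` of a trajectory is also accepted) and `qmd` (cm).
#' @param valuation A valuation model from [build_valuation()].
#' @return Stumpage value in EUR/ha (may be negative for small timber).
#' @export
stumpage_value <- function(state, valuation = build_valuation()) {
  vol <- state[["volume"]] %||% state[["v_standing"]]
  if (is.null(vol)) {
    stop_forestmf("`state` needs a `volume` (or `v_standing`) column")
  }
  if (nrow(state) == 0 || sum(vol) == 0) {
    return(0)
  }
  keep <- vol > 0
  net <- valuation$price(state$species[keep], state$qmd[keep]) -
    valuation$harvest_cost(state$species[keep], state$qmd[keep])
  sum(vol[keep] * net)
}

#' Net present value of a 30-year stand trajectory
#'
#' Discounted sum of the net revenues of all harvests within the
#' projection period plus the discounted change in the stumpage value of
#' the standing trees:
#' `npv = sum_t Vh_t (1+i)^-t + [Vs_tmax (1+i)^-tmax - Vs_0]`,
#' where `Vh_t` is the monetary value of the volume harvested in the
#' interval ending at year t (cash flows booked at interval end) and
#' `Vs_t` the stumpage value of the standing stock at year t.
#'
#' @param trajectory A trajectory from [simulate_trajectory()].
#' @param valuation A valuation model from [build_valuation()].
#' @param i Annual interest rate (> -1), default 0.015.
#' @return NPV in EUR/ha.
#' @export
npv <- function(trajectory, valuation = build_valuation(), i = 0.015) {
  check_number(i, "i", lower = -1 + 1e-12)
  val <- value_trajectory(trajectory, valuation)
  t_max <- max(val$year)
  harvest_pv <- sum(val$harvest_value * (1 + i)^(-val$year))
  vs0 <- val$standing_value[val$year == 0]
  vsT <- val$standing_value[val$year == t_max]
  harvest_pv + vsT * (1 + i)^(-t_max) - vs0
}

#' Monetary valuation of a trajectory per time step
#'
#' @inheritParams npv
#' @return Tibble with `year`, `harvest_value` (EUR/ha of the volume
#'   harvested in the interval ending at `year`) and `standing_value`
#'   (stumpage value of the standing stock at `year`).
#' @export
value_trajectory <- function(trajectory, valuation = build_valuation()) {
  per_year <- function(df) {
    h <- df$v_harvested > 0
    harvest_value <- if (any(h)) {
      sum(df$v_harvested[h] *
        (valuation$price(df$species[h], df$qmd_harvested[h]) -
          valuation$harvest_cost(df$species[h], df$qmd_harvested[h])))
    } else {
      0
    }
    tibble(
      year = df$year[1],
      harvest_value = harvest_value,
      standing_value = stumpage_value(
        tibble(species = df$species, volume = df$v_standing, qmd = df$qmd),
        valuation
      )
    )
  }
  split(as_tibble(trajectory), trajectory$year) %>%
    purrr::map(per_year) %>%
    bind_rows() %>%
    arrange(.data$year)
}

#' Annuity of a net present value
#'
#' The constant annual payment over `t_max` years whose present value at
#' interest rate `i` equals `npv_value`:
#' `a = npv * i (1+i)^t_max / ((1+i)^t_max - 1)` (EUR/ha/yr), the annual
#' average monetary success of management over the period.
#'
#' @param npv_value NPV in EUR/ha.
#' @param i Annual interest rate, must be > 0 (for `i = 0` the limit is
#'   `npv / t_max`, which this function refuses to silently take).
#' @param t_max Period length in years (>= 1), default 30.
#' @return Annuity in EUR/ha/yr.
#' @examples
#' annuity(10000, 0.015, 30) # about 416.39
#' @export
annuity <- function(npv_value, i = 0.015, t_max = 30) {
  if (!is.numeric(i) || length(i) != 1 || i <= 0) {
    stop_forestmf(paste0(
      "`i` must be > 0; for i = 0 the annuity degenerates to npv / t_max ",
      "(undiscounted average), which you can compute directly"
    ))
  }
  check_number(t_max, "t_max", lower = 1)
  npv_value * i * (1 + i)^t_max / ((1 + i)^t_max - 1)
}

#' Compound past planting costs to the present
#'
#' @param cost Planting cost at establishment (EUR/ha, >= 0).
#' @param years_since_planting Years elapsed since planting (>= 0).
#' @param i Annual interest rate, default 0.015.
#' @return `cost * (1 + i)^years` in EUR/ha.
#' @examples
#' compound_planting_costs(2000, 80) # about 6581.2
#' @export
compound_planting_costs <- function(cost, years_since_planting, i = 0.015) {
  if (any(cost < 0)) {
    stop_forestmf("`cost` must be >= 0")
  }
  if (any(years_since_planting < 0)) {
    stop_forestmf("`years_since_planting` must be >= 0")
  }
  cost * (1 + i)^years_since_planting
}

#' Investment-corrected immediate profit
#'
#' Stumpage value minus planting costs compounded to the present.
#'
#' @param stumpage Stumpage value (EUR/ha).
#' @inheritParams compound_planting_costs
#' @return EUR/ha.
#' @export
corrected_profit <- function(stumpage, cost, years_since_planting,
                             i = 0.015) {
  stumpage - compound_planting_costs(cost, years_since_planting, i)
}

#' Sawn-timber share of the harvested volume
#'
#' Volume-weighted percentage of the 30-year harvest that is sawn-timber
#' assortment, using the valuation model's `sawn_share(species, qmd)`
#' curve at the QMD of each harvest.
#'
#' @inheritParams npv
#' @return Percentage in \[0, 100\]; 0 with a warning if nothing is
#'   harvested.
#' @export
sawn_timber_share <- function(trajectory, valuation = build_valuation()) {
  h <- trajectory[trajectory$v_harvested > 0, , drop = FALSE]
  total <- sum(h$v_harvested)
  if (total == 0) {
    warn("no harvest in the trajectory; sawn-timber share is 0")
    return(0)
  }
  100 * sum(h$v_harvested *
    valuation$sawn_share(h$species, h$qmd_harvested)) / total
}

#' Default planting costs (synthetic placeholders)
#'
#' Per-species full-stand planting costs in EUR/ha. Placeholder values
#' chosen for plausibility (beech plantations cost several times a
#' conifer planting); replace with your own cost records for any real
#' valuation.
#'
#' @return Named numeric vector.
#' @export
default_planting_params <- function() {
  c(beech = 8000, spruce = 3000, douglas = 4000, other = 3000)
}
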