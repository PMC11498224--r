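#' Default growth parameters for the fixture trajectory simulator
#'
#' Species-specific annual diameter-increment curves
#' `inc(dbh) = a_sp * exp(-dbh / 100)` (cm/yr) and height curves
#' `h(dbh) = 1.3 + hmax_sp * (1 - exp(-0.04 dbh))` (m). Deterministic
#' stand-ins for an external single-tree growth simulator; coefficients
#' are synthetic but ordered realistically (Douglas-fir fastest, beech
#' slowest).
#'
#' @return Parameter list with `increment` (cm/yr at small dbh, per
#'   species), `inc_scale`, `hmax` (m), `h_k`, `form_factor`.
#' @export
default_growth_params <- function() {
  list(
    increment = c(beech = 0.30, spruce = 0.40, douglas = 0.50, other = 0.30),
    inc_scale = 100,
    hmax = c(beech = 32, spruce = 33, douglas = 38, other = 28),
    h_k = 0.04,
    form_factor = 0.45
  )
}

#' Default management rules
#'
#' @param thinning Fraction of remaining stems removed as thinning in each
#'   5-year interval (default 0.05).
#' @return List with species target diameters (cm) and the thinning
#'   fraction. Conifers have lower targets than beech, so conifers in
#'   mixtures are harvested first, leaving beech-dominated stands.
#' @export
default_management <- function(thinning = 0.05) {
  list(
    target_diameter = c(beech = 65, spruce = 45, douglas = 55, other = 55),
    thinning = thinning
  )
}

tree_volume_ <- function(dbh, species, growth) {
  g <- pi / 4 * (dbh / 100)^2
  h <- 1.3 + growth$hmax[species] * (1 - exp(-growth$h_k * dbh))
  unname(growth$form_factor * g * h)
}

#' Simulate a 30-year stand trajectory in 5-year steps
#'
#' Deterministic fixture projection of a tree list: in each 5-year
#' interval, cohorts at or above their species' target diameter are
#' harvested (their volume booked to the harvest of that interval), a
#' thinning fraction of the remaining stems is removed, and the remaining
#' cohorts grow along the species increment curve. No mortality is
#' simulated, so standing plus cumulative harvested volume never
#' decreases.
#'
#' @param trees A tree list (`species`, `dbh`, `stems_ha`, `age`), e.g.
#'   from [generate_stand_inventory()].
#' @param growth Growth parameters, see [default_growth_params()].
#' @param management Management rules, see [default_management()].
#' @param horizon,step Projection horizon and step length in years; must
#'   describe the canonical 7-step grid 0, 5, ..., 30.
#' @return A tidy trajectory tibble (class `mf_trajectory`): `year`,
#'   `species`, `v_standing` (m3/ha), `v_harvested` (m3/ha, harvested in
#'   the interval ending at `year`), `qmd` (cm), `qmd_harvested`, `age`.
#' @export
simulate_trajectory <- function(trees, growth = default_growth_params(),
                                management = default_management(),
                                horizon = 30, step = 5) {
  if (nrow(trees) == 0) {
    stop_forestmf("tree list is empty", class = "forestmf_error_input")
  }
  n_steps <- horizon / step + 1
  if (!isTRUE(all.equal(n_steps, 7))) {
    stop_forestmf("the projection grid must be 0 to 30 years in 5-year steps (7 time points)")
  }
  miss <- setdiff(unique(trees$species), names(growth$increment))
  if (length(miss) > 0) {
    stop_forestmf(paste0(
      "no growth parameters for species: ", paste(miss, collapse = ", ")
    ), class = "forestmf_error_input")
  }

  state <- trees
  species_set <- sort(unique(trees$species))
  snapshot <- function(st, year, harvested) {
    purrr::map(species_set, function(sp) {
      s <- st[st$species == sp, , drop = FALSE]
      h <- harvested[harvested$species == sp, , drop = FALSE]
      tibble(
        year = year,
        species = sp,
        v_standing = sum(tree_volume_(s$dbh, s$species, growth) * s$stems_ha),
        v_harvested = sum(tree_volume_(h$dbh, h$species, growth) *
          h$stems_ha),
        qmd = if (nrow(s) > 0 && sum(s$stems_ha) > 0) {
          sqrt(sum(s$stems_ha * s$dbh^2) / sum(s$stems_ha))
        } else {
          NA_real_
        },
        qmd_harvested = if (nrow(h) > 0 && sum(h$stems_ha) > 0) {
          sqrt(sum(h$stems_ha * h$dbh^2) / sum(h$stems_ha))
        } else {
          NA_real_
        },
        age = if (nrow(s) > 0) {
          sum(s$age * s$stems_ha) / sum(s$stems_ha)
        } else if (nrow(h) > 0) {
          sum(h$age * h$stems_ha) / sum(h$stems_ha)
        } else {
          NA_real_
        }
      )
    }) %>% bind_rows()
  }

  empty_harvest <- trees[0, , drop = FALSE]
  rows <- list(snapshot(state, 0, empty_harvest))
  for (s in seq_len(horizon / step)) {
    at_target <- state$dbh >= management$target_diameter[state$species]
    harvested <- state[at_target, , drop = FALSE]
    state <- state[!at_target, , drop = FALSE]
    if (management$thinning > 0 && nrow(state) > 0) {
      thinned <- state
      thinned$stems_ha <- state$stems_ha * management$thinning
      state$stems_ha <- state$stems_ha * (1 - management$thinning)
      harvested <- bind_rows(harvested, thinned)
    }
    if (nrow(state) > 0) {
      inc <- growth$increment[state$species] *
        exp(-state$dbh / growth$inc_scale)
      state$dbh <- state$dbh + step * unname(inc)
      state$age <- state$age + step
    }
    rows[[s + 1]] <- snapshot(state, s * step, harvested)
  }
  out <- bind_rows(rows)
  structure(out, class = c("mf_trajectory", class(out)))
}
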