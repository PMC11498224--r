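#' Generate a stand inventory tree list for one plot
#'
#' Stand-in for a field inventory: draws diameter cohorts per species
#' (dbh at breast height, truncated at the 7 cm calliper threshold) and
#' allocates stems per hectare so that the species' basal-area fractions
#' match the plot's configured shares exactly.
#'
#' @param plot One plot row of a design from [generate_design()] (or a list
#'   with `share_*` columns and `stand_age`).
#' @param stand_params List overriding any of: `total_basal_area` (m2/ha,
#'   default 35), `n_cohorts` per species (default 8), `mean_dbh` named by
#'   species (cm), `dbh_sd` (cm), `age_jitter` (years, sd of cohort age
#'   around stand age).
#' @param seed Integer seed.
#' @return A tibble tree list: `species`, `dbh` (cm), `stems_ha`, `age`.
#' @export
generate_stand_inventory <- function(plot, stand_params = list(), seed = 1) {
  check_number(seed, "seed")
  p <- list(
    total_basal_area = 35, n_cohorts = 8,
    mean_dbh = c(beech = 35, spruce = 40, douglas = 48, other = 30),
    dbh_sd = 8, age_jitter = 2
  )
  p <- modifyList(p, stand_params)
  shares <- c(
    beech = plot$share_beech, spruce = plot$share_spruce,
    douglas = plot$share_douglas, other = plot$share_other
  )
  shares <- shares[shares > 0]
  if (length(shares) == 0 || all(is.na(shares))) {
    stop_forestmf("plot has an empty species share map",
      class = "forestmf_error_input"
    )
  }
  with_seed_(seed, {
    rows <- purrr::imap(shares, function(s, sp) {
      dbh <- pmax(rnorm(p$n_cohorts, p$mean_dbh[[sp]], p$dbh_sd), 7)
      g <- pi / 4 * (dbh / 100)^2 # basal area per tree, m2
      w <- runif(p$n_cohorts, 0.5, 1.5)
      w <- w / sum(w)
      target <- s * p$total_basal_area
      tibble(
        species = sp, dbh = dbh,
        stems_ha = target * w / g,
        age = round(plot$stand_age + rnorm(p$n_cohorts, 0, p$age_jitter))
      )
    })
    bind_rows(rows)
  })
}

#' Basal-area fractions of a tree list
#'
#' @param trees A tree list as from [generate_stand_inventory()].
#' @return Named numeric vector of per-species basal-area fractions.
#' @export
basal_area_shares <- function(trees) {
  g <- pi / 4 * (trees$dbh / 100)^2 * trees$stems_ha
  tapply(g, trees$species, sum) / sum(g)
}
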