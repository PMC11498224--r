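#' Generate a blocked quintet study design
#'
#' Lays out `n_quintets` blocks ("quintets") of five co-located plots, one
#' per forest type: pure beech, pure Norway spruce, pure Douglas-fir, and
#' the two beech-conifer mixtures. Half of the quintets are assigned to a
#' southern upland region and half to a northern lowland region. Basal-area
#' shares of the focal species are drawn subject to the establishment
#' rules: each focal species contributes at least 20% of the basal area in
#' mixtures and at least 80% in pure stands, with a small residual share of
#' other species (uniform on \[0, 0.1\]).
#'
#' Exclusions (e.g. plots lost to bark-beetle outbreaks) are applied after
#' generation: excluded plots stay in the table flagged `excluded = TRUE`,
#' so sensitivity analyses can toggle them.
#'
#' @param n_quintets Number of quintets (blocks); default 8 gives the
#'   classic 40-plot layout.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param exclusions Character vector of plot ids to flag as excluded.
#' @param mean_age,age_sd Mean and standard deviation of stand age (years)
#'   drawn per plot.
#' @return A tibble with one row per plot (class `mf_design`): `plot_id`,
#'   `quintet`, `region`, `forest_type`, basal-area shares
#'   `share_beech`, `share_spruce`, `share_douglas`, `share_other`,
#'   `stand_age`, and `excluded`.
#' @examples
#' d <- generate_design(n_quintets = 8, seed = 1)
#' nrow(d) # 40 plots
#' @export
generate_design <- function(n_quintets = 8, seed = 1,
                            exclusions = character(),
                            mean_age = 80, age_sd = 4) {
  check_number(n_quintets, "n_quintets", lower = 1)
  check_number(seed, "seed")
  quintets <- sprintf("q%02d", seq_len(n_quintets))
  region <- ifelse(seq_len(n_quintets) <= ceiling(n_quintets / 2),
    "south", "north"
  )
  grid <- tidyr::expand_grid(
    quintet = quintets,
    forest_type = forest_types()
  )
  grid$region <- region[match(grid$quintet, quintets)]
  grid$plot_id <- paste(grid$quintet, grid$forest_type, sep = "_")

  bad <- setdiff(exclusions, grid$plot_id)
  if (length(bad) > 0) {
    stop_forestmf(
      paste0(
        "unknown plot id(s) in `exclusions`: ",
        paste(bad, collapse = ", ")
      ),
      class = "forestmf_error_input"
    )
  }

  plots <- with_seed_(seed, {
    shares <- purrr::map(grid$forest_type, draw_shares_)
    grid %>%
      mutate(
        share_beech = map_dbl(shares, "beech"),
        share_spruce = map_dbl(shares, "spruce"),
        share_douglas = map_dbl(shares, "douglas"),
        share_other = map_dbl(shares, "other"),
        stand_age = round(pmax(rnorm(dplyr::n(), mean_age, age_sd), 40))
      )
  })

  plots <- plots %>%
    mutate(excluded = .data$plot_id %in% exclusions) %>%
    select(
      "plot_id", "quintet", "region", "forest_type",
      dplyr::starts_with("share_"), "stand_age", "excluded"
    )
  structure(as_tibble(plots),
    n_quintets = n_quintets, seed = seed,
    class = c("mf_design", class(as_tibble(plots)))
  )
}

# Draw basal-area shares for one plot. Pure stands: focal = 1 - other with
# other ~ U(0, 0.1), so focal >= 0.9 > 0.8. Mixtures: the non-other share is
# split by u ~ U(0.3, 0.7), guaranteeing each focal species >= 0.27 > 0.2.
draw_shares_ <- function(type) {
  other <- runif(1, 0, 0.1)
  shares <- c(beech = 0, spruce = 0, douglas = 0, other = other)
  focal <- focal_species(type)
  if (length(focal) == 1L) {
    shares[focal] <- 1 - other
  } else {
    u <- runif(1, 0.3, 0.7)
    shares[focal[1]] <- u * (1 - other)
    shares[focal[2]] <- (1 - u) * (1 - other)
  }
  shares
}

#' Drop excluded plots from a design or plot-level table
#'
#' @param x A tibble with an `excluded` column (as returned by
#'   [generate_design()] or [generate_indicators()]).
#' @return The table restricted to included plots.
#' @export
included_plots <- function(x) {
  if (!"excluded" %in% names(x)) {
    return(x)
  }
  dplyr::filter(x, !.data$excluded)
}
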