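#' Generate a sparse plot-by-OTU count matrix
#'
#' Fixture generator for the rarefaction step: each plot receives counts
#' for at most `richness` operational taxonomic units (OTUs) drawn from a
#' larger pool, with lognormal relative abundances and a multinomial fill
#' to an exact per-plot total.
#'
#' @param design A design from [generate_design()] (or any tibble with a
#'   `plot_id` column).
#' @param richness Target number of OTUs present per plot (upper bound on
#'   the realised richness, since rare OTUs may receive zero counts).
#' @param total_count Per-plot total read count: a single number or a
#'   length-2 range sampled uniformly per plot.
#' @param pool_size Size of the OTU pool (number of columns).
#' @param abundance_sdlog Lognormal sd of the relative abundances.
#' @param seed Integer seed.
#' @return Integer matrix (plots x OTUs) with row names `plot_id` and
#'   row sums equal to the drawn totals.
#' @export
generate_otu_matrix <- function(design, richness = 50, total_count = 1e4,
                                pool_size = 5 * richness,
                                abundance_sdlog = 1.5, seed = 1) {
  check_number(richness, "richness", lower = 1)
  check_number(pool_size, "pool_size", lower = richness)
  check_number(seed, "seed")
  if (!all(total_count > 0)) {
    stop_forestmf("`total_count` must be positive")
  }
  plots <- design$plot_id
  mat <- matrix(0L, length(plots), pool_size,
    dimnames = list(plots, sprintf("otu_%04d", seq_len(pool_size)))
  )
  with_seed_(seed, {
    for (p in seq_along(plots)) {
      present <- sample.int(pool_size, richness)
      ab <- rlnorm(richness, sdlog = abundance_sdlog)
      total <- if (length(total_count) == 2L) {
        sample(seq(total_count[1], total_count[2]), 1)
      } else {
        total_count
      }
      mat[p, present] <- as.integer(
        stats::rmultinom(1, size = total, prob = ab / sum(ab))
      )
    }
  })
  mat
}
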