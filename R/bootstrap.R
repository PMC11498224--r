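#' Nonparametric bootstrap confidence interval (BCa or percentile)
#'
#' Ordinary nonparametric bootstrap of an arbitrary statistic with
#' bias-corrected and accelerated (BCa, "adjusted percentile") or plain
#' percentile intervals. Resampling is with replacement; if `groups` is
#' supplied, rows are resampled independently within each group (the
#' resampling unit is the observation/plot). The bias correction `z0` is
#' estimated from the bootstrap distribution and the acceleration from
#' the jackknife (leave-one-out) influence values.
#'
#' @param data Numeric vector or data frame of observations.
#' @param statistic Function mapping a resampled `data` object to a
#'   single number.
#' @param B Number of bootstrap replicates (>= 100), default 10000.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param method `"bca"` (default) or `"percentile"`.
#' @param seed Optional integer seed; intervals are deterministic given
#'   the seed.
#' @param groups Optional vector (length = observations) of group labels
#'   for within-group resampling.
#' @param ... Metadata columns (e.g. a label) added to the result row.
#' @return One-row tibble (class `mf_effect`): `estimate`, `ci_low`,
#'   `ci_high`, `n_boot`, `ci_method`, `level`, `seed`, plus any `...`
#'   metadata. If all replicates are identical the point value is
#'   returned as both bounds, with a warning.
#' @examples
#' bootstrap_ci(rnorm(30), mean, B = 500, seed = 1)
#' @export
bootstrap_ci <- function(data, statistic, B = 10000, level = 0.95,
                         method = c("bca", "percentile"), seed = NULL,
                         groups = NULL, ...) {
  method <- match.arg(method)
  check_number(B, "B", lower = 100)
  if (level <= 0 || level >= 1) {
    stop_forestmf("`level` must lie in (0, 1)")
  }
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- function(idx) {
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }
  if (!is.null(groups)) {
    if (length(groups) != n) {
      stop_forestmf("`groups` must match the number of observations")
    }
    idx_by_group <- split(seq_len(n), groups)
    if (any(lengths(idx_by_group) < 2)) {
      stop_forestmf("each resampled group needs at least 2 observations")
    }
  } else if (n < 2) {
    stop_forestmf("at least 2 observations are required")
  }

  t0 <- statistic(data)
  resample_idx <- function() {
    if (is.null(groups)) {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(lapply(idx_by_group, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
    }
  }
  tb <- with_seed_(seed, {
    vapply(seq_len(B), function(b) statistic(take(resample_idx())),
      numeric(1))
  })

  result <- function(lo, hi, used_method) {
    tibble(
      ...,
      estimate = t0, ci_low = lo, ci_high = hi,
      n_boot = B, ci_method = used_method, level = level,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ) %>%
      structure(class = c("mf_effect", class(tibble())))
  }

  if (diff(range(tb)) < .Machine$double.eps * 4) {
    warn("degenerate bootstrap distribution (all replicates identical); returning the point value as both bounds")
    return(result(tb[1], tb[1], method))
  }

  alpha <- (1 - level) / 2
  if (method == "percentile") {
    ci <- quantile(tb, c(alpha, 1 - alpha), names = FALSE, type = 7)
    return(result(ci[1], ci[2], "percentile"))
  }

  frac <- (sum(tb < t0) + 0.5 * sum(tb == t0)) / B
  if (frac <= 0 || frac >= 1) {
    warn("extreme bias correction (statistic outside the bootstrap distribution); falling back to the percentile interval")
    ci <- quantile(tb, c(alpha, 1 - alpha), names = FALSE, type = 7)
    return(result(ci[1], ci[2], "percentile"))
  }
  z0 <- qnorm(frac)

  loo <- vapply(seq_len(n), function(j) statistic(take(-j)), numeric(1))
  d <- mean(loo) - loo
  accel <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)

  adj <- function(z_alpha) {
    pnorm(z0 + (z0 + z_alpha) / (1 - accel * (z0 + z_alpha)))
  }
  a1 <- adj(qnorm(alpha))
  a2 <- adj(qnorm(1 - alpha))
  ci <- quantile(tb, c(a1, a2), names = FALSE, type = 7)
  result(ci[1], ci[2], "bca")
}
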