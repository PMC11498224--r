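# broom-style tidiers for the package's result objects

#' Tidy a tau-profile into a tibble
#'
#' @param x A `mf_tau_profile`.
#' @param ... Unused.
#' @return Tibble with `tau` and `value` columns.
#' @export
tidy.mf_tau_profile <- function(x, ...) {
  tibble(tau = x$taus, value = x$values)
}

#' One-row summary of a tau-profile
#'
#' @param x A `mf_tau_profile`.
#' @param ... Unused.
#' @return Tibble with `q`, `k`, `n_grid` and the effective number `auc`.
#' @export
glance.mf_tau_profile <- function(x, ...) {
  tibble(q = x$q, k = x$k, n_grid = length(x$taus), auc = x$auc)
}

#' Tidy a bootstrap effect result
#'
#' @param x A `mf_effect` row from [bootstrap_ci()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.mf_effect <- function(x, ...) {
  as_tibble(unclass_tbl_(x))
}

#' Tidy a transformation analysis
#'
#' @param x A `mf_transformation` from [transformation_analysis()].
#' @param ... Unused.
#' @return The underlying tibble (one row per transformation x
#'   dimension).
#' @export
tidy.mf_transformation <- function(x, ...) {
  as_tibble(unclass_tbl_(x))
}

#' One-row summary of a transformation analysis
#'
#' @param x A `mf_transformation`.
#' @param ... Unused.
#' @return Tibble tallying win/lose/neutral cells plus `n_boot` and
#'   `level`.
#' @export
glance.mf_transformation <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_win = sum(x$label == "win"),
    n_lose = sum(x$label == "lose"),
    n_neutral = sum(x$label == "neutral"),
    n_boot = x$n_boot[1],
    level = x$level[1]
  )
}

unclass_tbl_ <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
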