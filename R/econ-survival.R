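#' Default Weibull survival parameters (synthetic placeholders)
#'
#' Per-species two-parameter Weibull survival-time models in the
#' accelerated-failure-time style: survival `S(t) = exp(-(t/lambda)^k)`
#' with the scale acting multiplicatively,
#' `lambda = scale0 * exp(stabilization * (1 - share) + beta . z)`,
#' where `share` is the species' basal-area share in the stand. A
#' positive stabilization coefficient means admixture (lower conspecific
#' share) increases the survival scale — the stabilizing effect of
#' species mixture for the storm- and beetle-prone conifers. Climate or
#' site covariates enter as an opaque vector `z` with linear effect
#' `beta` on the log scale. Coefficients are synthetic placeholders, not
#' fitted to monitoring data.
#'
#' @return Named list per species with `shape`, `scale0`,
#'   `stabilization`, `beta`.
#' @export
default_survival_params <- function() {
  list(
    beech = list(shape = 2.3, scale0 = 220, stabilization = 0, beta = numeric(0)),
    spruce = list(shape = 1.8, scale0 = 130, stabilization = 0.5, beta = numeric(0)),
    douglas = list(shape = 2.0, scale0 = 170, stabilization = 0.35, beta = numeric(0)),
    other = list(shape = 2.0, scale0 = 160, stabilization = 0, beta = numeric(0))
  )
}

weibull_scale_ <- function(m, share, covariates) {
  z <- covariates %||% numeric(0)
  beta <- m$beta %||% numeric(0)
  if (length(z) != length(beta)) {
    if (length(beta) == 0 && length(z) > 0) {
      stop_forestmf("covariates supplied but the model has no `beta`")
    }
    if (length(beta) > 0 && length(z) == 0) {
      z <- rep(0, length(beta))
    }
  }
  m$scale0 * exp((m$stabilization %||% 0) * (1 - share) + sum(beta * z))
}

#' Conditional probability of surviving the 30-year projection window
#'
#' Probability that a stand of the given species, alive at `age`,
#' survives the next `window` years:
#' `S(age + window) / S(age) = exp(-((age+w)/lambda)^k + (age/lambda)^k)`
#' under the Weibull survival-time model. For shape `k = 1` this is
#' age-independent (memoryless exponential case).
#'
#' @param species Species name (must be in `model`).
#' @param age Current stand age in years (>= 0).
#' @param share Basal-area share of the species in the stand, in
#'   \[0, 1\]; enters the scale via the stabilization term.
#' @param model Survival parameters, see [default_survival_params()].
#' @param window Projection window in years, default 30.
#' @param covariates Optional covariate vector matching the model's
#'   `beta`.
#' @return Conditional survival probability in (0, 1\].
#' @examples
#' # exponential case: independent of age
#' m <- list(x = list(shape = 1, scale0 = 100, stabilization = 0))
#' survival_conditional_30("x", age = 50, model = m) # exp(-0.3)
#' @export
survival_conditional_30 <- function(species, age, share = 1,
                                    model = default_survival_params(),
                                    window = 30, covariates = NULL) {
  if (!species %in% names(model)) {
    stop_forestmf(paste0("no survival model for species '", species, "'"),
      class = "forestmf_error_input"
    )
  }
  check_number(age, "age", lower = 0)
  m <- model[[species]]
  lambda <- weibull_scale_(m, share, covariates)
  if (!isTRUE(m$shape > 0) || !isTRUE(lambda > 0)) {
    stop_forestmf("Weibull shape and scale must be > 0")
  }
  exp(-((age + window) / lambda)^m$shape + (age / lambda)^m$shape)
}

#' Stand-level conditional survival probability
#'
#' Basal-area-share-weighted mean of the species' conditional survival
#' probabilities (shares renormalized over the modeled species present).
#' Because each species' scale depends on its own share, mixtures inherit
#' the stabilization effect of admixture. The weighted mean treats stand
#' survival ("maintaining crown cover") as a graded outcome; a
#' `aggregation = "product"` variant treats it as joint survival of all
#' components.
#'
#' @param shares Named numeric vector of basal-area shares.
#' @param ages Stand age (single number) or named vector per species.
#' @param model Survival parameters, see [default_survival_params()].
#' @param window Projection window in years.
#' @param aggregation `"weighted_mean"` (default) or `"product"`.
#' @return Stand survival probability in (0, 1\].
#' @export
stand_survival <- function(shares, ages,
                           model = default_survival_params(),
                           window = 30,
                           aggregation = c("weighted_mean", "product")) {
  aggregation <- match.arg(aggregation)
  shares <- shares[!is.na(shares) & shares > 0]
  modeled <- intersect(names(shares), names(model))
  if (length(modeled) == 0) {
    stop_forestmf("no modeled species present in the stand",
      class = "forestmf_error_input"
    )
  }
  w <- shares[modeled] / sum(shares[modeled])
  s <- vapply(modeled, function(sp) {
    a <- if (length(ages) == 1) ages else ages[[sp]]
    survival_conditional_30(sp, a, share = shares[[sp]], model = model,
      window = window)
  }, numeric(1))
  if (aggregation == "weighted_mean") {
    sum(w * s)
  } else {
    prod(s^w) # share-weighted geometric form of the joint-survival variant
  }
}
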