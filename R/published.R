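#' Published Swiss coefficient estimates and AIC measures
#'
#' Reference values from the national Swiss geographic correlation study of
#' canine cancer incidence (3,611 registry cases in 2008 across 2,350
#' municipalities) whose design this package re-implements: the coefficient
#' table of the zero-inflated negative binomial incidence model on both
#' enumeration supports, and the AIC measures of the four model families.
#' These are inputs for effect-size conversion and model-comparison
#' arithmetic — the underlying registry microdata are not public, so the
#' fits themselves cannot be recomputed here.
#'
#' @return `published_estimates()`: data frame with `component`
#'   (`"count"`/`"zero_inflation"`), `covariate`, `support`, `estimate`,
#'   `se`, `deviance_reduction_pct`.
#' @export
published_estimates <- function() {
  path <- system.file("extdata", "swiss_published_estimates.csv",
                      package = "dasycan", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname published_estimates
#' @return `published_aic()`: data frame with `family`, `municipal`,
#'   `refined` AIC values.
#' @export
published_aic <- function() {
  path <- system.file("extdata", "swiss_published_aic.csv",
                      package = "dasycan", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
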