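#' Population preference parameters for choice simulation
#'
#' Describes the random-coefficients logit data-generating process: each
#' respondent's preference-weight vector is
#' \eqn{\beta_i = \mu + \sigma \odot z_i} with \eqn{z_i} independent standard
#' normal. A zero entry in `sigma` makes that coefficient fixed across
#' respondents (the alternative-specific constant is fixed in the study
#' fixture).
#'
#' @param mu Numeric mean preference-weight vector (utility units).
#' @param sigma Non-negative heterogeneity SD vector, same length as `mu`.
#' @param labels Coefficient names; default `names(mu)`.
#' @return An object of class `dce_population`.
#' @examples
#' study_population()
#' @export
population_preferences <- function(mu, sigma, labels = names(mu)) {
  mu <- as.numeric(mu)
  sigma <- as.numeric(sigma)
  if (length(mu) != length(sigma))
    stop("'mu' and 'sigma' must have the same length")
  if (any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop("'mu' and 'sigma' must be finite")
  if (any(sigma < 0)) stop("'sigma' must be non-negative")
  if (is.null(labels) || length(labels) != length(mu) || anyDuplicated(labels))
    stop("'labels' must be unique names, one per coefficient")
  structure(list(mu = stats::setNames(mu, labels),
                 sigma = stats::setNames(sigma, labels),
                 labels = labels),
            class = "dce_population")
}

#' @export
print.dce_population <- function(x, ...) {
  cat("Population preferences (random-coefficients logit):\n")
  print(round(rbind(mu = x$mu, sigma = x$sigma), 4))
  invisible(x)
}

#' Estimated preference weights of the community-based DOT study
#'
#' The study's mixed-logit coefficient means and heterogeneity SDs (reported
#' to two decimals), shipped as a plain-text fixture and used as the default
#' generating process of the synthetic-data module.
#'
#' @return A `dce_population` with labels
#'   `asc, c_chw, c_expert, l_home, s_phcall, s_tvouch`.
#' @export
study_population <- function() {
  path <- system.file("extdata", "study_population.yaml", package = "dcemixl")
  y <- yaml::read_yaml(path)
  population_preferences(y$mu, y$sigma, labels = y$labels)
}

#' Respondent covariate marginals of the community-based DOT study
#'
#' Marginal frequencies of the study's 103 respondents: 43/103 female, 42/103
#' aged 20-34 years, 40/103 HIV positive, and 31/102 on MDR-TB treatment for
#' under six months (one respondent's treatment duration is missing).
#'
#' @return Named list of proportions: `female`, `age_20_34`, `hiv_positive`,
#'   `months_lt6`, and `missing_months` (the expected share of respondents
#'   with a missing treatment-duration value).
#' @export
study_marginals <- function() {
  list(female = 43 / 103,
       age_20_34 = 42 / 103,
       hiv_positive = 40 / 103,
       months_lt6 = 31 / 102,
       missing_months = 1 / 103)
}

#' Read an attribute scheme from a YAML file
#'
#' @param path YAML file with fields `attributes` (named lists of levels,
#'   reference first) and optional `columns`.
#' @return A `dce_scheme`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  y <- yaml::read_yaml(path)
  attrs <- lapply(y$attributes, as.character)
  cols <- if (!is.null(y$columns)) lapply(y$columns, as.character) else NULL
  attribute_scheme(attrs, cols)
}
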