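#' Range-method relative importance of attributes
#'
#' For each attribute, the range is the difference between its largest and
#' smallest level coefficients (the reference level contributing 0), and the
#' relative importance is the attribute's range as a percentage of the sum of
#' ranges. Importance is translation-invariant within an attribute and sums
#' to 100% across attributes.
#'
#' @param object A `mixlogit` fit, or a named numeric vector of level
#'   coefficients (indicator-column names; an `asc` entry is ignored).
#' @param scheme The attribute scheme mapping indicator columns to
#'   attributes.
#' @param ... Unused.
#' @return A `dce_importance` data frame with columns `attribute`, `range`
#'   and `importance` (percent).
#' @examples
#' relative_importance(c(c_chw = 1.13, c_expert = 0.89, l_home = 1.25,
#'                       s_phcall = 0.70, s_tvouch = 1.35))
#' @export
relative_importance <- function(object, ...) UseMethod("relative_importance")

#' @rdname relative_importance
#' @export
relative_importance.mixlogit <- function(object, scheme = cbdot_scheme(),
                                         ...) {
  relative_importance(coef(object), scheme = scheme)
}

#' @rdname relative_importance
#' @export
relative_importance.numeric <- function(object, scheme = cbdot_scheme(),
                                        ...) {
  coding <- scheme$coding
  missing_col <- setdiff(coding$column, names(object))
  if (length(missing_col))
    stop("missing coefficient(s): ", paste(missing_col, collapse = ", "))
  rng <- vapply(names(scheme$attributes), function(a) {
    coefs <- c(0, unname(object[coding$column[coding$attribute == a]]))
    max(coefs) - min(coefs)
  }, 0)
  if (all(rng == 0))
    stop("all attribute ranges are zero: relative importance undefined")
  out <- data.frame(attribute = names(scheme$attributes),
                    range = unname(rng),
                    importance = unname(100 * rng / sum(rng)),
                    stringsAsFactors = FALSE)
  class(out) <- c("dce_importance", "data.frame")
  out
}

#' @rdname relative_importance
#' @details The list method takes one numeric vector of level coefficients
#'   per attribute (reference included, conventionally 0) and needs no
#'   scheme; it makes the translation invariance of the range explicit.
#' @export
relative_importance.list <- function(object, ...) {
  if (is.null(names(object))) stop("attribute list must be named")
  rng <- vapply(object, function(coefs) max(coefs) - min(coefs), 0)
  if (all(rng == 0))
    stop("all attribute ranges are zero: relative importance undefined")
  out <- data.frame(attribute = names(object), range = unname(rng),
                    importance = unname(100 * rng / sum(rng)),
                    stringsAsFactors = FALSE)
  class(out) <- c("dce_importance", "data.frame")
  out
}

#' @export
print.dce_importance <- function(x, ...) {
  cat("Range-method relative importance:\n")
  df <- data.frame(attribute = x$attribute,
                   range = round(x$range, 2),
                   importance = sprintf("%.1f%%", round(x$importance, 1)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Utility equation of a care-model profile
#'
#' Bundles a constant (the alternative-specific constant) and the dummy-coded
#' level coefficients into the linear utility scorer
#' \eqn{V = \mathrm{constant} + \sum_k x_k \beta_k}.
#'
#' @param object A `mixlogit` fit (the `asc` coefficient becomes the
#'   constant), or a numeric constant when building an equation by hand.
#' @param coefficients Named level coefficients (used with a numeric
#'   `object`).
#' @param ... Unused.
#' @return An object of class `utility_equation`.
#' @examples
#' eq <- utility_equation(0.52, c(c_chw = 1.13, c_expert = 0.89,
#'                                l_home = 1.25, s_phcall = 0.70,
#'                                s_tvouch = 1.35))
#' @export
utility_equation <- function(object, ...) UseMethod("utility_equation")

#' @rdname utility_equation
#' @export
utility_equation.mixlogit <- function(object, ...) {
  est <- coef(object)
  if (!"asc" %in% names(est))
    stop("fit has no 'asc' coefficient to use as the constant")
  utility_equation(unname(est["asc"]), est[setdiff(names(est), "asc")])
}

#' @rdname utility_equation
#' @export
utility_equation.numeric <- function(object, coefficients, ...) {
  stopifnot(length(object) == 1L, is.numeric(coefficients),
            !is.null(names(coefficients)))
  if (any(!is.finite(c(object, coefficients))))
    stop("equation terms must be finite")
  structure(list(constant = unname(object), coefficients = coefficients),
            class = "utility_equation")
}

#' @export
print.utility_equation <- function(x, digits = 4, ...) {
  cat("V =", round(x$constant, digits),
      paste0("+ ", round(x$coefficients, digits), " (",
             names(x$coefficients), ")", collapse = " "), "\n")
  invisible(x)
}

#' The published utility equation of the community-based DOT study
#'
#' Full-precision mixed-logit estimates used to score and rank the 18
#' hypothetical care models.
#'
#' @return A `utility_equation`.
#' @export
study_equation <- function() {
  utility_equation(0.5230616,
                   c(c_chw = 1.132371, c_expert = 0.8881919,
                     l_home = 1.250887, s_phcall = 0.7014401,
                     s_tvouch = 1.346391))
}

#' Utility score of care-model profiles
#'
#' Substitutes a profile's dummy-coded indicators into the utility equation:
#' \eqn{V = \mathrm{constant} + \sum_k x_k \beta_k}. The all-reference
#' profile scores the constant alone.
#'
#' @param profile Named character vector (one level per attribute) or a data
#'   frame of profiles.
#' @param equation A [utility_equation()].
#' @param scheme The attribute scheme.
#' @return Numeric utility score(s), full precision.
#' @examples
#' utility_score(c(provider = "CHW", location = "Home",
#'                 support = "Travel vouchers"), study_equation())
#' @export
utility_score <- function(profile, equation, scheme = cbdot_scheme()) {
  stopifnot(inherits(equation, "utility_equation"))
  ind <- encode_profiles(profile, scheme)
  missing_col <- setdiff(colnames(ind), names(equation$coefficients))
  if (length(missing_col))
    stop("equation lacks coefficient(s): ",
         paste(missing_col, collapse = ", "))
  drop(equation$constant +
         ind %*% equation$coefficients[colnames(ind)])
}

#' Rank all care-model profiles by utility score
#'
#' Enumerates the full factorial of profiles, scores each with the utility
#' equation, and sorts descending. Ranks are dense (tied scores share a
#' rank); ties are listed in lexicographic profile order.
#'
#' @param equation A [utility_equation()].
#' @param scheme The attribute scheme.
#' @return A `dce_ranking` data frame: one column per attribute, `profile`
#'   (slash-separated label), `utility` and `rank`, covering every profile
#'   exactly once.
#' @examples
#' head(rank_profiles(study_equation()), 3)
#' @export
rank_profiles <- function(equation, scheme = cbdot_scheme()) {
  ff <- full_factorial(scheme)
  v <- utility_score(ff, equation, scheme)
  o <- order(-v, seq_len(nrow(ff)))
  out <- ff[o, , drop = FALSE]
  out$profile <- profile_label(out, scheme)
  out$utility <- v[o]
  out$rank <- cumsum(!duplicated(out$utility))
  rownames(out) <- NULL
  class(out) <- c("dce_ranking", "data.frame")
  out
}

#' @export
print.dce_ranking <- function(x, digits = 2, ...) {
  df <- data.frame(profile = x$profile, utility = round(x$utility, digits),
                   rank = x$rank)
  print(df, row.names = FALSE)
  invisible(x)
}
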