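#' Draw synthetic respondents from covariate marginals
#'
#' Generates respondent covariate profiles (gender, age group, HIV status,
#' months on MDR-TB treatment) from marginal frequencies. With
#' `exact = TRUE` (default) category counts are fixed at `round(n * p)` and
#' assigned to respondents by a seeded permutation, so a cohort of 103
#' reproduces the study's stratum sizes exactly; with `exact = FALSE` each
#' respondent's categories are independent Bernoulli draws. Covariates are
#' drawn independently of each other and of preferences.
#'
#' @param n Number of respondents (>= 1).
#' @param marginals Named list of proportions as returned by
#'   [study_marginals()].
#' @param seed Integer seed.
#' @param exact Fix category counts at their rounded expectations?
#' @return Data frame with columns `respondent_id`, `gender`, `age_group`,
#'   `hiv_status`, `months_group` (NA where treatment duration is missing).
#' @examples
#' table(draw_respondents(103, seed = 1)$hiv_status)
#' @export
draw_respondents <- function(n, marginals = study_marginals(), seed = 1L,
                             exact = TRUE) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  p <- marginals
  need <- c("female", "age_20_34", "hiv_positive", "months_lt6")
  if (!all(need %in% names(p)))
    stop("'marginals' must contain: ", paste(need, collapse = ", "))
  pm <- p$missing_months %||% 0
  vals <- c(unlist(p[need]), pm)
  if (any(vals < 0 | vals > 1)) stop("marginal proportions must be in [0, 1]")
  with_seed(seed, {
    pick2 <- function(prob, yes, no) {
      if (exact) {
        k <- round(n * prob)
        out <- rep(no, n)
        out[sample.int(n, k)] <- yes
        out
      } else ifelse(rbinom(n, 1L, prob) == 1L, yes, no)
    }
    gender <- pick2(p$female, "female", "male")
    age_group <- pick2(p$age_20_34, "20-34", ">=35")
    hiv_status <- pick2(p$hiv_positive, "positive", "negative")
    months_group <- if (exact) {
      k_miss <- round(n * pm)
      out <- rep(NA_character_, n)
      obs <- sample.int(n, n - k_miss)
      k_lt6 <- round(length(obs) * p$months_lt6)
      out[obs] <- ">=6"
      out[obs[seq_len(k_lt6)]] <- "<6"
      out
    } else {
      miss <- rbinom(n, 1L, pm) == 1L
      out <- ifelse(rbinom(n, 1L, p$months_lt6) == 1L, "<6", ">=6")
      out[miss] <- NA_character_
      out
    }
    data.frame(respondent_id = seq_len(n), gender = gender,
               age_group = age_group, hiv_status = hiv_status,
               months_group = months_group, stringsAsFactors = FALSE)
  })
}

#' Draw respondent-level preference coefficients
#'
#' Realises each respondent's coefficient vector
#' \eqn{\beta_i = \mu + \sigma \odot z_i}, \eqn{z_i \sim N(0, I)}.
#' Coefficients with `sigma = 0` (the ASC in the study fixture) are constant
#' across respondents.
#'
#' @param pop A [population_preferences()] object.
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @return Numeric matrix (`n` rows) with the population's labels as columns.
#' @export
draw_coefficients <- function(pop, n, seed = 1L) {
  stopifnot(inherits(pop, "dce_population"), n >= 1)
  n <- as.integer(n)
  with_seed(seed, {
    P <- length(pop$mu)
    z <- matrix(rnorm(n * P), n, P)
    beta <- matrix(pop$mu, n, P, byrow = TRUE) +
      z * matrix(pop$sigma, n, P, byrow = TRUE)
    colnames(beta) <- pop$labels
    beta
  })
}

#' Simulate panel choices under the random-utility model
#'
#' For each respondent and task, the utility of alternative `j` is
#' \eqn{U_j = x_j'\beta_i} (the opt-out has \eqn{x = 0}, hence utility 0) and
#' the chosen alternative is sampled with the multinomial-logit probability
#' \eqn{\exp(U_j)/\sum_k \exp(U_k)} — equivalently, the utility-maximising
#' alternative under independent Gumbel noise. Exactly one alternative is
#' chosen per task. The random stream is keyed by task id, so choices in a
#' task depend only on that task's alternatives.
#'
#' @param design A `dce_design`.
#' @param coefficients Matrix of per-respondent coefficients whose column
#'   names match the design-matrix columns (`asc` plus indicators), e.g. from
#'   [draw_coefficients()].
#' @param respondents Optional respondent covariate table
#'   ([draw_respondents()]); its columns are carried into the output.
#' @param seed Integer seed.
#' @param shift Optional preference-shift hook: `function(respondents)`
#'   returning a matrix (same shape as `coefficients`, or a subset of its
#'   columns) added to the coefficients — used to induce subgroup preference
#'   differences.
#' @return Long-format data frame: `respondent_id`, `task_id`, `alt_id`,
#'   `chosen`, `asc`, the indicator columns, then any covariates. One row per
#'   respondent x task x alternative (including the opt-out).
#' @examples
#' beta <- draw_coefficients(study_population(), 5, seed = 2)
#' ch <- simulate_choices(study_design(), beta, seed = 3)
#' nrow(ch)  # 5 * 8 * 3
#' @export
simulate_choices <- function(design, coefficients, respondents = NULL,
                             seed = 1L, shift = NULL) {
  stopifnot(inherits(design, "dce_design"), is.matrix(coefficients))
  X <- design_matrix(design)
  if (!identical(colnames(coefficients), colnames(X)))
    stop("coefficient labels must match design columns: ",
         paste(colnames(X), collapse = ", "))
  n <- nrow(coefficients)
  if (!is.null(respondents)) {
    stopifnot(is.data.frame(respondents), nrow(respondents) == n)
  }
  if (!is.null(shift)) {
    if (is.null(respondents))
      stop("'shift' requires a 'respondents' table")
    delta <- shift(respondents)
    if (is.null(colnames(delta)) ||
        !all(colnames(delta) %in% colnames(coefficients)))
      stop("'shift' must return columns named after coefficients")
    coefficients[, colnames(delta)] <- coefficients[, colnames(delta)] + delta
  }
  task_of_row <- attr(X, "task_id")
  alt_of_row <- attr(X, "alt_id")
  task_ids <- unique(task_of_row)
  t_n <- length(task_ids)
  J <- design$n_alts + 1L
  U <- X %*% t(coefficients)  # (t*J) x n
  ch <- matrix(NA_integer_, t_n, n)
  with_seed(seed, {
    for (pos in order(task_ids)) {    # random stream keyed by task id
      rows <- which(task_of_row == task_ids[pos])
      Ut <- U[rows, , drop = FALSE]
      E <- exp(sweep(Ut, 2L, apply(Ut, 2L, max)))
      cumE <- apply(E, 2L, cumsum)
      u <- runif(n) * cumE[J, ]
      ch[pos, ] <- colSums(cumE < rep(u, each = J)) + 1L
    }
  })
  ids <- if (is.null(respondents)) seq_len(n) else respondents$respondent_id
  n_row <- t_n * J
  out <- data.frame(
    respondent_id = rep(ids, each = n_row),
    task_id = rep(task_of_row, n),
    alt_id = rep(alt_of_row, n),
    chosen = as.integer(rep(alt_of_row, n) ==
                          as.vector(ch[rep(seq_len(t_n), each = J), ])),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X[rep(seq_len(n_row), n), , drop = FALSE]))
  if (!is.null(respondents)) {
    cov_cols <- setdiff(names(respondents), "respondent_id")
    out <- cbind(out, respondents[rep(seq_len(n), each = n_row), cov_cols,
                                  drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Simulate a full study cohort
#'
#' Convenience wrapper emulating the study's structure end to end: draws
#' respondent covariates, realises random preference coefficients from the
#' population, and simulates every respondent's choices over the design. With
#' all defaults (103 respondents, the study's eight tasks, the study's
#' preference weights) the result has 103 x 8 x 3 = 2472 rows.
#'
#' @param n Number of respondents (default 103, the study cohort).
#' @param design Choice-set design (default [study_design()]).
#' @param pop Generating preferences (default [study_population()]).
#' @param marginals Covariate marginals (default [study_marginals()]).
#' @param seed Root seed; stage seeds are derived from it.
#' @param shift Optional preference-shift hook, see [simulate_choices()].
#' @param exact Passed to [draw_respondents()].
#' @return Long-format choice data frame with covariates.
#' @export
simulate_study <- function(n = 103L, design = study_design(),
                           pop = study_population(),
                           marginals = study_marginals(), seed = 1L,
                           shift = NULL, exact = TRUE) {
  resp <- draw_respondents(n, marginals, seed = stage_seed(seed, 1L),
                           exact = exact)
  beta <- draw_coefficients(pop, n, seed = stage_seed(seed, 2L))
  simulate_choices(design, beta, respondents = resp,
                   seed = stage_seed(seed, 3L), shift = shift)
}
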