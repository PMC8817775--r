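# Prepare long-format choice data for estimation: model matrix, task/choice
# indexing, and per-respondent grouping. Rows are re-ordered respondent-major,
# task-minor; alternative order within a task is preserved.
prep_choices <- function(formula, data, id = "respondent_id",
                         task = "task_id") {
  stopifnot(is.data.frame(data))
  for (col in c(id, task)) {
    if (!col %in% names(data)) stop("column '", col, "' not found in data")
  }
  tt <- stats::terms(formula, data = data)
  attr(tt, "intercept") <- 0L
  mf <- model.frame(tt, data)
  y <- model.response(mf)
  if (is.null(y) || !all(y %in% c(0, 1)))
    stop("the response must be a 0/1 chosen indicator")
  X <- model.matrix(tt, mf)
  o <- order(data[[id]], data[[task]], seq_len(nrow(data)))
  X <- X[o, , drop = FALSE]
  y <- y[o]
  rid <- data[[id]][o]
  tid <- data[[task]][o]
  n <- length(y)
  new_task <- c(TRUE, rid[-1L] != rid[-n] | tid[-1L] != tid[-n])
  task_start <- c(which(new_task) - 1L, n)        # 0-based row offsets
  n_tasks <- length(task_start) - 1L
  chosen <- which(y == 1)
  task_of_chosen <- findInterval(chosen, task_start + 1L)
  if (length(chosen) != n_tasks || anyDuplicated(task_of_chosen))
    stop("each (respondent, task) group must have exactly one chosen row")
  first_rows <- task_start[-length(task_start)] + 1L
  new_resp <- c(TRUE, rid[first_rows][-1L] != rid[first_rows][-n_tasks])
  resp_start <- c(which(new_resp) - 1L, n_tasks)  # 0-based task offsets
  # columns constant within every task carry no choice information
  Jt <- diff(task_start)
  keep <- vapply(seq_len(ncol(X)), function(j) {
    any(X[, j] != rep.int(X[first_rows, j], Jt))
  }, NA)
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    warning("dropping column(s) constant within every task: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  list(X = X, Xt = t(X), y = y, task_start = as.integer(task_start),
       chosen_row = as.integer(chosen - 1L),
       resp_start = as.integer(resp_start),
       resp_ids = rid[first_rows][new_resp],
       n_obs = n, n_resp = sum(new_resp), n_tasks = n_tasks,
       dropped = dropped)
}

# Single call into the compiled core.
sll_core <- function(theta, pr, Z, rand_cols, want_grad = FALSE) {
  P <- ncol(pr$X)
  mu <- theta[seq_len(P)]
  sigma_full <- numeric(P)
  sigma_full[rand_cols] <- theta[-seq_len(P)]
  R <- if (length(rand_cols)) dim(Z)[1L] else 1L
  mixl_sll(mu, sigma_full, pr$Xt %||% t(pr$X), pr$task_start, pr$chosen_row,
           pr$resp_start, Z, as.integer(rand_cols - 1L),
           as.integer(R), want_grad)
}

# Central-difference Hessian of an analytic gradient function.
numeric_hessian <- function(grad_fn, theta, h = 1e-4) {
  P <- length(theta)
  H <- matrix(0, P, P)
  for (j in seq_len(P)) {
    hj <- h * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + hj
    dn <- theta; dn[j] <- dn[j] - hj
    H[, j] <- (grad_fn(up) - grad_fn(dn)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Simulated log-likelihood of the panel mixed logit
#'
#' Evaluates \eqn{\sum_i \log\left[\frac{1}{R}\sum_r \prod_t
#' P_{it}(\mathrm{chosen} \mid \beta_{ir})\right]} with
#' \eqn{\beta_{ir} = \mu + \sigma \odot z_{ir}}, where the per-task choice
#' probabilities are multinomial logit over the task's alternatives (the
#' opt-out row has all-zero covariates, so its utility is 0). Probabilities
#' are computed with log-sum-exp stabilisation; with `sigma` empty or zero the
#' value equals the conditional-logit log-likelihood at `mu`.
#'
#' @param mu Named coefficient means; names select design-matrix columns.
#' @param sigma Named heterogeneity SDs for the random coefficients (a subset
#'   of `names(mu)`); may be `NULL` for a fixed-coefficient model.
#' @param data Long-format choice data frame.
#' @param draws Either a draw count (Halton draws are generated) or a
#'   pre-built array of dimension `c(R, length(sigma), n_respondents)`.
#' @param id,task Column names identifying respondents and tasks.
#' @param burn_in Halton burn-in when `draws` is a count.
#' @return The simulated log-likelihood (a finite scalar).
#' @export
simulated_loglik <- function(mu, sigma = NULL, data, draws = 1000,
                             id = "respondent_id", task = "task_id",
                             burn_in = 10) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma %||% 0)))
    stop("parameters must be finite")
  if (is.null(names(mu))) stop("'mu' must be named after design columns")
  rand <- names(sigma) %||% character(0)
  if (length(rand) && !all(rand %in% names(mu)))
    stop("names(sigma) must be a subset of names(mu)")
  fml <- stats::reformulate(names(mu), response = "chosen")
  pr <- prep_choices(fml, data, id, task)
  if (!identical(colnames(pr$X), names(mu)))
    stop("design columns do not match 'mu' labels")
  rand_cols <- match(rand, colnames(pr$X))
  Z <- if (!length(rand)) numeric(0)
  else if (is.array(draws) && length(dim(draws)) == 3L) {
    if (dim(draws)[2L] != length(rand) || dim(draws)[3L] != pr$n_resp)
      stop("draw array must be (R, ", length(rand), ", ", pr$n_resp, ")")
    draws
  } else halton_normal_draws(pr$n_resp, length(rand), n_draws = draws,
                             burn_in = burn_in)
  res <- sll_core(c(mu, unname(sigma[rand])), pr, Z, rand_cols)
  res$loglik
}
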