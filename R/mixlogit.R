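#' Fit a mixed (random-parameters) logit model by maximum simulated likelihood
#'
#' Estimates choice models of the form \eqn{U_{ijt} = x_{ijt}'\beta_i +
#' \epsilon_{ijt}} with iid Gumbel errors, where the coefficients named in
#' `random` vary across respondents as independent normals
#' \eqn{\beta_{ik} \sim N(\mu_k, \sigma_k^2)} and the remaining coefficients
#' (the alternative-specific constant in the default specification) are fixed.
#' The mixing integral is simulated with Halton draws mapped through the
#' normal inverse CDF, one contiguous block of draws per respondent, and the
#' simulated log-likelihood is maximised by BFGS with the analytic simulated
#' score. Starting values are the conditional-logit estimates (obtained first,
#' by the same maximiser with no random coefficients) with all SDs started at
#' `start_sigma`. With `random = NULL` the fit is the conditional logit
#' itself.
#'
#' Standard errors come from the inverse of the numeric Hessian of the
#' simulated log-likelihood; heterogeneity SDs are reported as absolute
#' values (the likelihood is invariant to their sign); 95% confidence
#' intervals are estimate +/- 1.96 SE and p-values use the standard normal
#' approximation (SD rows test sigma = 0).
#'
#' @param formula Model formula, `chosen ~ asc + <indicator columns>`; no
#'   intercept is added (the opt-out is normalised to zero utility).
#' @param data Long-format choice data (one row per respondent x task x
#'   alternative), e.g. from [simulate_study()] or [read_choices()].
#' @param id,task Names of the respondent and task id columns.
#' @param random Coefficient names given normal mixing; `NULL` for a
#'   fixed-coefficient conditional logit.
#' @param draws Number of Halton draws per respondent (default 1000), or a
#'   pre-built array `c(R, length(random), n_respondents)`.
#' @param burn_in Initial Halton elements discarded (default 10).
#' @param primes Optional prime bases for the Halton dimensions.
#' @param start Optional full start vector `c(mu, sigma[random])`.
#' @param start_sigma Starting value for each heterogeneity SD (default 0.1).
#' @param maxit,reltol BFGS iteration budget and relative tolerance.
#' @param gtol Gradient tolerance (scaled by 1 + |logLik|) used for the
#'   convergence flag.
#' @return An object of class `mixlogit`: coefficient means, heterogeneity
#'   SDs, standard errors, the full variance matrix, the simulated
#'   log-likelihood, counts (`n_obs`, `n_resp`, `n_tasks`), and a
#'   convergence flag with diagnostic message.
#' @seealso [summary.mixlogit()], [relative_importance()],
#'   [subgroup_analysis()]
#' @examples
#' dat <- simulate_study(n = 40, seed = 7)
#' fit <- mixlogit(data = dat, draws = 50)
#' coef(fit)
#' @export
mixlogit <- function(formula = chosen ~ asc + c_chw + c_expert + l_home +
                       s_phcall + s_tvouch,
                     data, id = "respondent_id", task = "task_id",
                     random = c("c_chw", "c_expert", "l_home", "s_phcall",
                                "s_tvouch"),
                     draws = 1000, burn_in = 10, primes = NULL, start = NULL,
                     start_sigma = 0.1, maxit = 500, gtol = 1e-5,
                     reltol = 1e-10) {
  cl <- match.call()
  pr <- prep_choices(formula, data, id, task)
  cols <- colnames(pr$X)
  P <- length(cols)
  random <- intersect(random %||% character(0), cols)
  Kr <- length(random)
  rand_cols <- match(random, cols)

  # conditional-logit stage: fixed coefficients, also the MIXL start
  obj0 <- function(th) -sll_core(th, pr, numeric(0), integer(0))$loglik
  grd0 <- function(th)
    -sll_core(th, pr, numeric(0), integer(0), want_grad = TRUE)$grad_mu
  opt0 <- optim(numeric(P), obj0, grd0, method = "BFGS",
                control = list(maxit = maxit, reltol = reltol))
  mu0 <- opt0$par

  if (Kr == 0L) {
    theta <- mu0
    value <- -opt0$value
    grad_fn <- function(th) sll_core(th, pr, numeric(0), integer(0),
                                     want_grad = TRUE)$grad_mu
    Z <- numeric(0)
    n_draws <- 0L
    conv_code <- opt0$convergence
  } else {
    if (is.array(draws) && length(dim(draws)) == 3L) {
      Z <- draws
      if (dim(Z)[2L] != Kr || dim(Z)[3L] != pr$n_resp)
        stop("draw array must have dimension (R, ", Kr, ", ", pr$n_resp, ")")
    } else {
      Z <- halton_normal_draws(pr$n_resp, Kr, n_draws = draws,
                               burn_in = burn_in, primes = primes)
    }
    n_draws <- dim(Z)[1L]
    theta0 <- start %||% c(mu0, rep(start_sigma, Kr))
    if (length(theta0) != P + Kr)
      stop("'start' must have length ", P + Kr)
    obj <- function(th) -sll_core(th, pr, Z, rand_cols)$loglik
    grd <- function(th) {
      g <- sll_core(th, pr, Z, rand_cols, want_grad = TRUE)
      -c(g$grad_mu, g$grad_sigma)
    }
    opt <- optim(theta0, obj, grd, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))
    theta <- opt$par
    value <- -opt$value
    grad_fn <- function(th) {
      g <- sll_core(th, pr, Z, rand_cols, want_grad = TRUE)
      c(g$grad_mu, g$grad_sigma)
    }
    conv_code <- opt$convergence
  }

  g_final <- grad_fn(theta)
  gnorm <- max(abs(g_final))
  message <- character(0)
  converged <- conv_code == 0L && gnorm <= gtol * (1 + abs(value))
  if (conv_code != 0L)
    message <- c(message, paste("optimizer did not converge (code",
                                conv_code, ")"))
  if (max(abs(theta[seq_len(P)])) > 15) {
    converged <- FALSE
    message <- c(message,
                 "coefficient diverging: possible separation in the data")
  }

  H <- numeric_hessian(grad_fn, theta)
  vc <- tryCatch(solve(-H), error = function(e) NULL)
  se_ok <- !is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)
  if (!se_ok) {
    vc <- matrix(NA_real_, length(theta), length(theta))
    message <- c(message, "singular Hessian: standard errors unavailable")
  }
  par_names <- c(cols, if (Kr) paste0("sd.", random))
  dimnames(vc) <- list(par_names, par_names)

  mu_hat <- stats::setNames(theta[seq_len(P)], cols)
  sigma_hat <- if (Kr) stats::setNames(abs(theta[-seq_len(P)]), random)
               else NULL
  se <- stats::setNames(sqrt(diag(vc)), par_names)

  structure(list(
    call = cl, formula = formula, id = id, task = task,
    coefficients = mu_hat, sigma = sigma_hat, se = se, vcov = vc,
    loglik = value, loglik_clogit = -opt0$value,
    n_obs = pr$n_obs, n_resp = pr$n_resp, n_tasks = pr$n_tasks,
    n_draws = n_draws, burn_in = burn_in, random = random,
    converged = converged, message = message, gradient_norm = gnorm,
    index = pr, draws_array = if (Kr) Z else NULL,
    dropped = pr$dropped), class = "mixlogit")
}

#' @export
print.mixlogit <- function(x, digits = 4, ...) {
  cat(if (length(x$random)) "Mixed logit (maximum simulated likelihood)"
      else "Conditional logit", "\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Coefficient means:\n")
  print(round(x$coefficients, digits))
  if (length(x$random)) {
    cat("\nHeterogeneity SDs (|sigma|):\n")
    print(round(x$sigma, digits))
    cat("\nSimulated log-likelihood:", format(x$loglik, digits = 8),
        "(", x$n_draws, "Halton draws )\n")
  } else {
    cat("\nLog-likelihood:", format(x$loglik, digits = 8), "\n")
  }
  cat("Observations:", x$n_obs, "(", x$n_resp, "respondents )\n")
  if (!x$converged) cat("WARNING:", paste(x$message, collapse = "; "), "\n")
  invisible(x)
}

#' Summarise a mixed logit fit
#'
#' @param object A `mixlogit` fit.
#' @param ... Unused.
#' @return A `summary.mixlogit` object holding per-parameter tables
#'   (estimate, SE, z, p, 95% CI) for the coefficient means and the
#'   heterogeneity SDs.
#' @export
summary.mixlogit <- function(object, ...) {
  mk <- function(est, se) {
    z <- est / se
    data.frame(estimate = est, se = se, z = z,
               p = 2 * pnorm(-abs(z)),
               ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se)
  }
  P <- length(object$coefficients)
  mean_tab <- mk(object$coefficients, object$se[seq_len(P)])
  sd_tab <- if (length(object$random))
    mk(object$sigma, object$se[-seq_len(P)]) else NULL
  structure(list(call = object$call, mean_table = mean_tab, sd_table = sd_tab,
                 loglik = object$loglik, n_obs = object$n_obs,
                 n_resp = object$n_resp, n_draws = object$n_draws,
                 converged = object$converged, message = object$message),
            class = "summary.mixlogit")
}

#' @export
print.summary.mixlogit <- function(x, digits = 4, ...) {
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Coefficient means:\n")
  print(round(x$mean_table, digits))
  if (!is.null(x$sd_table)) {
    cat("\nHeterogeneity SDs (tested against 0):\n")
    print(round(x$sd_table, digits))
  }
  cat("\nLog-likelihood:", format(x$loglik, digits = 8),
      "  Observations:", x$n_obs, "  Respondents:", x$n_resp, "\n")
  if (x$n_draws > 0) cat("Halton draws per respondent:", x$n_draws, "\n")
  if (!x$converged) cat("WARNING:", paste(x$message, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.mixlogit <- function(object, component = c("mean", "sd", "all"), ...) {
  component <- match.arg(component)
  switch(component,
         mean = object$coefficients,
         sd = object$sigma,
         all = c(object$coefficients,
                 if (length(object$random))
                   stats::setNames(object$sigma,
                                   paste0("sd.", object$random))))
}

#' @export
vcov.mixlogit <- function(object, ...) object$vcov

#' @export
logLik.mixlogit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + length(object$random),
            nobs = object$n_obs, class = "logLik")
}

#' @export
nobs.mixlogit <- function(object, ...) object$n_obs

# Multinomial-logit probabilities within contiguous task blocks
# (task_of_row must be ascending 1..T).
softmax_by_task <- function(u, task_of_row) {
  Jt <- tabulate(task_of_row)
  m <- rep.int(unname(tapply(u, task_of_row, max)), Jt)
  e <- exp(u - m)
  s <- rep.int(rowsum(e, task_of_row, reorder = FALSE)[, 1L], Jt)
  e / s
}

# Row structure helpers for a prepared dataset.
row_structure <- function(pr) {
  Jt <- diff(pr$task_start)
  task_of_row <- rep.int(seq_len(pr$n_tasks), Jt)
  resp_of_task <- rep.int(seq_len(pr$n_resp), diff(pr$resp_start))
  list(Jt = Jt, task_of_row = task_of_row,
       resp_of_row = resp_of_task[task_of_row])
}

# Simulated per-row choice probabilities (averaged over the mixing draws).
mixl_fitted <- function(object) {
  pr <- object$index
  rs <- row_structure(pr)
  P <- ncol(pr$X)
  mu <- object$coefficients
  if (!length(object$random)) {
    u <- drop(pr$X %*% mu)
    return(softmax_by_task(u, rs$task_of_row))
  }
  Z <- object$draws_array
  R <- dim(Z)[1L]
  rand_cols <- match(object$random, colnames(pr$X))
  sig <- object$sigma
  acc <- numeric(pr$n_obs)
  for (r in seq_len(R)) {
    zr <- matrix(Z[r, , ], nrow = length(rand_cols))  # Kr x n_resp
    B <- matrix(mu, pr$n_resp, P, byrow = TRUE)
    B[, rand_cols] <- B[, rand_cols] +
      sweep(t(zr), 2L, sig, "*")
    u <- rowSums(pr$X * B[rs$resp_of_row, , drop = FALSE])
    acc <- acc + softmax_by_task(u, rs$task_of_row)
  }
  acc / R
}

#' @export
#' @rdname mixlogit
#' @param object,x A `mixlogit` fit.
#' @param ... Passed on / unused.
fitted.mixlogit <- function(object, ...) mixl_fitted(object)

#' Predicted choice probabilities
#'
#' Returns the simulated choice probability of every row of the estimation
#' data (or of `newdata` in the same long format), averaging the
#' multinomial-logit probabilities over the estimated mixing distribution.
#'
#' @param object A `mixlogit` fit.
#' @param newdata Optional long-format data frame.
#' @param ... Unused.
#' @return Numeric vector of probabilities, one per row, summing to one
#'   within each (respondent, task).
#' @export
predict.mixlogit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(mixl_fitted(object))
  refit <- object
  refit$index <- prep_choices(object$formula, newdata, object$id, object$task)
  if (length(object$random)) {
    refit$draws_array <- halton_normal_draws(
      refit$index$n_resp, length(object$random),
      n_draws = max(object$n_draws, 1L), burn_in = object$burn_in)
  }
  mixl_fitted(refit)
}

#' @export
residuals.mixlogit <- function(object, ...) {
  pr <- object$index
  pr$y - mixl_fitted(object)
}

#' Simulate choices from a fitted model
#'
#' Draws new respondent coefficient vectors from the estimated mixing
#' distribution and resamples every task's chosen alternative, reusing the
#' estimation data's alternatives.
#'
#' @param object A `mixlogit` fit.
#' @param nsim Number of simulated choice replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame of 0/1 chosen indicators (`sim_1`, ..., `sim_nsim`),
#'   one row per row of the estimation data.
#' @export
simulate.mixlogit <- function(object, nsim = 1, seed = NULL, ...) {
  pr <- object$index
  rs <- row_structure(pr)
  P <- ncol(pr$X)
  rand_cols <- match(object$random, colnames(pr$X))
  with_seed(seed, {
    out <- vector("list", nsim)
    for (s in seq_len(nsim)) {
      B <- matrix(object$coefficients, pr$n_resp, P, byrow = TRUE)
      if (length(rand_cols))
        B[, rand_cols] <- B[, rand_cols] +
          matrix(rnorm(pr$n_resp * length(rand_cols)), pr$n_resp) *
          matrix(object$sigma, pr$n_resp, length(rand_cols), byrow = TRUE)
      u <- rowSums(pr$X * B[rs$resp_of_row, , drop = FALSE])
      p <- softmax_by_task(u, rs$task_of_row)
      cs <- cumsum(p)
      prior <- c(0, cs)[pr$task_start[seq_len(pr$n_tasks)] + 1L]
      cum <- cs - rep.int(prior, rs$Jt)
      thresh <- rep.int(runif(pr$n_tasks), rs$Jt)
      first_lt <- rowsum(as.numeric(cum < thresh), rs$task_of_row,
                         reorder = FALSE)[, 1L]
      first_lt <- pmin(first_lt, rs$Jt - 1L)
      pick_row <- pr$task_start[seq_len(pr$n_tasks)] + first_lt + 1L
      chosen <- integer(pr$n_obs)
      chosen[pick_row] <- 1L
      out[[s]] <- chosen
    }
    names(out) <- paste0("sim_", seq_len(nsim))
    as.data.frame(out)
  })
}

#' Plot coefficient means with confidence intervals
#'
#' Dot-and-whisker display of the estimated coefficient means and their 95%
#' confidence intervals; heterogeneity SDs are drawn as hollow points when
#' present.
#'
#' @param x A `mixlogit` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mixlogit <- function(x, ...) {
  est <- x$coefficients
  P <- length(est)
  se <- x$se[seq_len(P)]
  ypos <- rev(seq_len(P))
  lo <- est - 1.96 * se
  hi <- est + 1.96 * se
  graphics::plot(est, ypos, xlim = range(c(lo, hi, 0), na.rm = TRUE),
                 yaxt = "n", ylab = "", xlab = "coefficient (utility units)",
                 pch = 16, ...)
  axis(2, at = ypos, labels = names(est), las = 1)
  segments(lo, ypos, hi, ypos)
  abline(v = 0, lty = 3)
  if (length(x$random)) {
    ysd <- ypos[match(x$random, names(est))]
    points(x$sigma, ysd - 0.2, pch = 1)
  }
  invisible(x)
}
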