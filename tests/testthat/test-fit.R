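test_that("conditional logit matches an independent implementation", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  dat <- simulate_study(n = 300, pop = fixed_population(), seed = 9)
  fit <- mixlogit(data = dat, random = NULL)
  ref <- survival::clogit(
    chosen ~ asc + c_chw + c_expert + l_home + s_phcall + s_tvouch +
      strata(interaction(respondent_id, task_id)),
    data = dat)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(unname(fit$se[1:6]), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(nobs(fit), 300L * 24L)
})

test_that("null data yields estimates within sampling error of zero", {
  pop0 <- population_preferences(rep(0, 6), rep(0, 6), labels = study_labels)
  dat <- simulate_study(n = 400, pop = pop0, seed = 13)
  fit <- mixlogit(data = dat, random = NULL)
  expect_true(all(abs(coef(fit)) < 3 * fit$se[1:6]))
})

test_that("conditional logit recovers generating coefficients (99% CI coverage)", {
  truth <- c(0.52, 1.13, 0.89, 1.25, 0.70, 1.35)
  hits <- 0L
  for (rep in 1:10) {
    dat <- simulate_study(n = 500, pop = fixed_population(truth),
                          seed = 5000 + rep)
    fit <- mixlogit(data = dat, random = NULL)
    ci_lo <- coef(fit) - 2.576 * fit$se[1:6]
    ci_hi <- coef(fit) + 2.576 * fit$se[1:6]
    hits <- hits + sum(truth >= ci_lo & truth <= ci_hi)
  }
  expect_gte(hits / 60, 0.93)
})

test_that("a study-sized dataset reports the published observation count", {
  dat <- simulate_study(n = 103, seed = 1)
  fit <- mixlogit(data = dat, random = NULL)
  expect_equal(fit$n_obs, 2472L)
  expect_equal(fit$n_resp, 103L)
})

test_that("one zero-valued draw reduces the mixed logit to conditional logit", {
  dat <- simulate_study(n = 60, seed = 17)
  clg <- mixlogit(data = dat, random = NULL)
  # a single mixing draw at the uniform midpoint maps to z = 0 exactly
  Z0 <- array(qnorm(0.5), c(1, 5, 60))
  mx <- mixlogit(data = dat, draws = Z0)
  expect_equal(coef(mx), coef(clg), tolerance = 1e-4)
  expect_equal(mx$loglik, clg$loglik, tolerance = 1e-6)
})

test_that("data generated without heterogeneity collapses the SDs", {
  dat <- simulate_study(n = 300, pop = fixed_population(), seed = 23)
  clg <- mixlogit(data = dat, random = NULL)
  mx <- mixlogit(data = dat, draws = 50)
  small <- mx$sigma < 2 * mx$se[-(1:6)]
  expect_gte(sum(small), 4L)
  # the SD parameters sit on the boundary: the log-likelihood gain over the
  # nested fixed-coefficient model behaves like a (half-)chi-square on 5 df
  expect_lt(mx$loglik - clg$loglik, qchisq(0.999, 5) / 2)
  expect_gte(mx$loglik, clg$loglik - 0.01)  # mixture nests the fixed model
})

test_that("fitted means are stable in the number of Halton draws", {
  dat <- simulate_study(n = 250, seed = 29)
  f100 <- mixlogit(data = dat, draws = 100)
  f1000 <- mixlogit(data = dat, draws = 1000)
  expect_lt(max(abs(coef(f100) - coef(f1000))), 0.05)
})

test_that("columns without within-task variation are dropped with a warning", {
  dat <- simulate_study(n = 30, seed = 33)
  dat$dead <- 1
  expect_warning(
    fit <- mixlogit(chosen ~ asc + c_chw + c_expert + l_home + s_phcall +
                      s_tvouch + dead,
                    data = dat, random = NULL),
    "constant within every task")
  expect_false("dead" %in% names(coef(fit)))
})

test_that("model methods are coherent", {
  dat <- simulate_study(n = 40, seed = 37)
  fit <- mixlogit(data = dat, draws = 50)
  s <- summary(fit)
  expect_s3_class(s, "summary.mixlogit")
  expect_equal(s$mean_table$ci_hi - s$mean_table$estimate,
               1.96 * s$mean_table$se, tolerance = 1e-12)
  expect_true(all(s$mean_table$p >= 0 & s$mean_table$p <= 1))
  expect_equal(unname(coef(fit, "all")),
               unname(c(coef(fit), fit$sigma)))
  expect_equal(dim(vcov(fit)), c(11L, 11L))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  # probabilities sum to one within each task and match residuals
  p <- predict(fit)
  expect_equal(unname(tapply(p, paste(dat$respondent_id, dat$task_id), sum)),
               rep(1, 40 * 8), tolerance = 1e-10, ignore_attr = TRUE)
  r <- residuals(fit)
  expect_equal(sort(unique(round(r + p, 10))), c(0, 1))
  sim <- simulate(fit, nsim = 2, seed = 3)
  expect_equal(dim(sim), c(nrow(dat), 2L))
  expect_true(all(tapply(sim$sim_1, paste(dat$respondent_id, dat$task_id),
                         sum) == 1))
  # plot method draws without error
  tmp <- tempfile(fileext = ".pdf")
  grDevices::pdf(tmp)
  expect_no_error(plot(fit))
  grDevices::dev.off()
})
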