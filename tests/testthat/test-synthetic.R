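test_that("respondent draws honour the cohort marginals", {
  expect_error(draw_respondents(0), ">= 1")
  r <- draw_respondents(103, seed = 1)
  expect_equal(nrow(r), 103L)
  expect_equal(anyDuplicated(r$respondent_id), 0L)
  # exact mode pins the category counts at rounded expectations
  expect_equal(sum(r$hiv_status == "positive"), 40L)
  expect_equal(sum(r$gender == "female"), 43L)
  expect_equal(sum(r$age_group == "20-34"), 42L)
  expect_equal(sum(is.na(r$months_group)), 1L)
  expect_equal(sum(r$months_group == "<6", na.rm = TRUE), 31L)
  # iid mode: binomial CLT bound at a known marginal
  marg <- study_marginals()
  marg$female <- 0.5
  big <- draw_respondents(10000, marg, seed = 2, exact = FALSE)
  expect_lt(abs(mean(big$gender == "female") - 0.5), 3 * sqrt(0.25 / 10000))
  # determinism
  expect_identical(draw_respondents(50, seed = 9), draw_respondents(50, seed = 9))
})

test_that("individual coefficients follow beta_i = mu + sigma * z", {
  pop0 <- fixed_population()
  b <- draw_coefficients(pop0, 20, seed = 1)
  expect_true(all(abs(sweep(b, 2, pop0$mu)) == 0))  # sigma = 0 collapses to mu
  pop <- study_population()
  b <- draw_coefficients(pop, 50000, seed = 3)
  expect_equal(unname(colnames(b)), study_labels)
  expect_true(all(b[, "asc"] == pop$mu["asc"]))     # fixed ASC
  expect_lt(abs(sd(b[, "c_chw"]) / 1.85 - 1), 0.02)
  expect_lt(abs(mean(b[, "l_home"]) - 1.25), 0.02)
  expect_identical(draw_coefficients(pop, 10, seed = 5),
                   draw_coefficients(pop, 10, seed = 5))
})

test_that("simulated choices follow the logit probabilities", {
  d <- study_design()
  # all-zero coefficients: uniform choice over the three alternatives
  beta0 <- matrix(0, 400, 6, dimnames = list(NULL, study_labels))
  ch <- simulate_choices(d, beta0, seed = 11)
  n_choices <- 400 * 8
  share <- tapply(ch$chosen, ch$alt_id, sum) / n_choices
  expect_true(all(abs(share - 1 / 3) < 3 * sqrt(2 / 9 / n_choices)))
  # saturating coefficient: a lone voucher alternative is always taken
  beta_sat <- matrix(0, 200, 6, dimnames = list(NULL, study_labels))
  beta_sat[, "s_tvouch"] <- 20
  ch <- simulate_choices(d, beta_sat, seed = 12)
  voucher_tasks <- c(1, 2, 5, 6, 8)  # tasks with exactly one voucher option
  picked <- ch[ch$task_id %in% voucher_tasks & ch$chosen == 1, ]
  hit <- picked$s_tvouch == 1
  expect_gt(mean(hit), 0.999)
})

test_that("a study-sized cohort yields the published observation count", {
  dat <- simulate_study(n = 103, seed = 1)
  expect_equal(nrow(dat), 2472L)
  dims <- choice_dims(dat)
  expect_equal(dims$n_respondents, 103L)
  expect_equal(dims$n_tasks, 8L)
  expect_equal(dims$n_alts, 3L)
  # grouping contract: one chosen row per task
  expect_true(all(tapply(dat$chosen, paste(dat$respondent_id, dat$task_id),
                         sum) == 1))
  # stratum row counts are stratum size x 24
  expect_equal(unname(table(dat$hiv_status)[c("negative", "positive")]),
               c(63L, 40L) * 24L, ignore_attr = TRUE)
})

test_that("choices depend only on each task's own alternatives", {
  d <- study_design()
  beta <- draw_coefficients(study_population(), 30, seed = 4)
  a <- simulate_choices(d, beta, seed = 5)
  shuffled <- d$tasks[sample(nrow(d$tasks)), ]  # row order scrambled
  d2 <- choice_design(shuffled, cbdot_scheme())
  b <- simulate_choices(d2, beta, seed = 5)
  expect_identical(a, b)
})

test_that("the preference-shift hook changes only the targeted stratum", {
  resp <- draw_respondents(200, seed = 6)
  beta <- draw_coefficients(fixed_population(), 200, seed = 6)
  shift <- function(r) {
    m <- matrix(0, nrow(r), 1, dimnames = list(NULL, "l_home"))
    m[r$hiv_status == "positive", 1] <- 5
    m
  }
  ch <- simulate_choices(study_design(), beta, respondents = resp,
                         seed = 7, shift = shift)
  home_rate <- function(status) {
    sub <- ch[ch$hiv_status == status & ch$chosen == 1, ]
    mean(sub$l_home)
  }
  expect_gt(home_rate("positive"), home_rate("negative"))
})

test_that("choice CSV round-trips and the reader enforces the contract", {
  dat <- simulate_study(n = 10, seed = 3)
  tmp <- tempfile(fileext = ".csv")
  write_choices(dat, tmp)
  back <- read_choices(tmp)
  expect_equal(back, dat)
  # two chosen rows in one task
  bad <- dat
  bad$chosen[bad$respondent_id == 1 & bad$task_id == 1] <- c(1, 1, 0)
  write_choices(bad, tmp)
  expect_error(read_choices(tmp), "exactly one chosen")
  # indicator outside {0, 1}
  bad <- dat
  bad$c_chw[5] <- 2
  v <- validate_choices(bad)
  expect_true(any(v$check == "domain"))
  # dropping an opt-out row breaks the grouping contract
  bad <- dat[!(dat$respondent_id == 2 & dat$task_id == 3 & dat$alt_id == 3), ]
  v <- validate_choices(bad)
  expect_true(any(grepl("opt-out", v$message)))
})
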