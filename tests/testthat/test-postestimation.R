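study_coefs <- c(c_chw = 1.13, c_expert = 0.89, l_home = 1.25,
                 s_phcall = 0.70, s_tvouch = 1.35)

test_that("range-method importance reproduces the study shares", {
  imp <- relative_importance(study_coefs)
  shares <- stats::setNames(round(imp$importance, 1), imp$attribute)
  expect_equal(shares[["support"]], 36.2)
  expect_equal(shares[["location"]], 33.5)
  expect_equal(shares[["provider"]], 30.3)
  expect_equal(sum(round(imp$importance, 1)), 100, tolerance = 0.1)
})

test_that("importance normalises and is translation-invariant per attribute", {
  one <- attribute_scheme(list(a = c("x", "y")))
  expect_equal(relative_importance(c(a_y = 2), scheme = one)$importance, 100)
  two <- attribute_scheme(list(a = c("x", "y"), b = c("u", "v")))
  imp <- relative_importance(c(a_y = 0.7, b_v = -0.7), scheme = two)
  expect_equal(imp$importance, c(50, 50))
  # ranges are unchanged by shifting every level of one attribute
  levels_list <- list(provider = c(0, 1.13, 0.89), location = c(0, 1.25),
                      support = c(0, 0.70, 1.35))
  base <- relative_importance(levels_list)
  shifted <- levels_list
  shifted$support <- shifted$support + 2.5
  expect_equal(relative_importance(shifted)$importance, base$importance)
  expect_equal(base$importance, relative_importance(study_coefs)$importance)
  expect_error(relative_importance(c(a_y = 0, b_v = 0), scheme = two),
               "undefined")
})

test_that("utility scores match the published equation", {
  eq <- study_equation()
  expect_equal(round(utility_score(c(provider = "CHW", location = "Home",
                                     support = "Travel vouchers"), eq), 2),
               4.25)
  expect_equal(round(utility_score(c(provider = "Expert client",
                                     location = "Home",
                                     support = "Travel vouchers"), eq), 2),
               4.01)
  expect_equal(round(utility_score(c(provider = "CHW", location = "Home",
                                     support = "Call reminders"), eq), 2),
               3.61)
  expect_equal(round(utility_score(c(provider = "CHW", location = "Work",
                                     support = "Travel vouchers"), eq), 2),
               3.00)
  # the all-reference profile scores the constant alone
  expect_equal(round(utility_score(c(provider = "Family member",
                                     location = "Work",
                                     support = "SMS reminders"), eq), 2),
               0.52)
  expect_error(utility_score(c(provider = "Nurse", location = "Work",
                               support = "SMS reminders"), eq),
               "unknown level")
})

test_that("profile ranking covers the factorial and orders by utility", {
  eq <- study_equation()
  rk <- rank_profiles(eq)
  expect_equal(nrow(rk), 18L)
  expect_equal(anyDuplicated(rk$profile), 0L)
  expect_equal(rk$profile[1], "CHW/Home/Travel vouchers")
  expect_equal(rk$rank[1], 1L)
  expect_equal(round(rk$utility[rk$rank == 3], 2), 3.61)
  expect_true(all(diff(rk$utility) <= 0))
  # hand recomputation of every score
  ff <- rk[, c("provider", "location", "support")]
  hand <- eq$constant +
    (ff$provider == "CHW") * eq$coefficients["c_chw"] +
    (ff$provider == "Expert client") * eq$coefficients["c_expert"] +
    (ff$location == "Home") * eq$coefficients["l_home"] +
    (ff$support == "Call reminders") * eq$coefficients["s_phcall"] +
    (ff$support == "Travel vouchers") * eq$coefficients["s_tvouch"]
  expect_equal(rk$utility, unname(hand), tolerance = 1e-12)
  # adding a constant shifts scores but not the ranking
  eq2 <- utility_equation(eq$constant + 5, eq$coefficients)
  rk2 <- rank_profiles(eq2)
  expect_equal(rk2$profile, rk$profile)
  expect_equal(rk2$rank, rk$rank)
  expect_equal(rk2$utility, rk$utility + 5, tolerance = 1e-12)
})

test_that("utility equation can be extracted from a fitted model", {
  dat <- simulate_study(n = 50, seed = 41)
  fit <- mixlogit(data = dat, random = NULL)
  eq <- utility_equation(fit)
  expect_equal(eq$constant, unname(coef(fit)["asc"]))
  expect_equal(utility_score(c(provider = "Family member", location = "Work",
                               support = "SMS reminders"), eq),
               eq$constant)
})

test_that("subgroup split reproduces stratum counts and excludes missing", {
  dat <- simulate_study(n = 103, seed = 1)
  sg <- subgroup_analysis(dat, "hiv_status", draws = 100)
  expect_equal(unname(sg$n_obs), c(1512L, 960L))
  expect_equal(sg$strata, c("negative", "positive"))
  sgm <- subgroup_analysis(dat, "months_group", draws = 50)
  expect_equal(sum(sgm$n_obs), 2448L)
  expect_equal(sgm$n_excluded_rows, 24L)
  expect_error(subgroup_analysis(dat, "nope"), "not found")
})

test_that("the Wald difference statistic is antisymmetric in stratum order", {
  dat <- simulate_study(n = 60, seed = 43)
  sg <- subgroup_analysis(dat, "gender", draws = 50)
  flipped <- dat
  flipped$gender <- factor(flipped$gender, levels = c("male", "female"))
  sg2 <- subgroup_analysis(flipped, "gender", draws = 50)
  expect_equal(sg$tests$z, -sg2$tests$z, tolerance = 1e-8)
  expect_equal(sg$tests$p, sg2$tests$p, tolerance = 1e-8)
})
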