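test_that("attribute scheme enforces reference levels and unique columns", {
  sch <- cbdot_scheme()
  expect_s3_class(sch, "dce_scheme")
  expect_equal(nrow(sch$coding), 5L)
  expect_equal(sch$coding$column,
               c("c_chw", "c_expert", "l_home", "s_phcall", "s_tvouch"))
  expect_error(attribute_scheme(list(a = "one")), "2 distinct")
  expect_error(attribute_scheme(list(a = c("x", "y"), b = c("x", "z")),
                                columns = list(a = "dup", b = "dup")),
               "unique")
})

test_that("full factorial enumerates every profile once, lexicographically", {
  ff <- full_factorial(cbdot_scheme())
  expect_equal(nrow(ff), 18L)
  expect_equal(anyDuplicated(profile_label <- apply(ff, 1, paste, collapse = "/")),
               0L)
  # the study's top-ranked profile is present
  expect_true(any(ff$provider == "CHW" & ff$location == "Home" &
                    ff$support == "Travel vouchers"))
  # first attribute most significant: first 6 rows are all Family member
  expect_equal(unique(ff$provider[1:6]), "Family member")
  expect_equal(nrow(full_factorial(attribute_scheme(list(a = c("x", "y"))))),
               2L)
})

test_that("orme sample size reproduces the study bound and is monotone", {
  expect_identical(orme_sample_size(3, 8, 2, nonresponse = 0.10), 104L)
  expect_identical(orme_sample_size(3, 8, 2), 94L)
  expect_identical(orme_sample_size(2, 10, 2), 50L)
  expect_error(orme_sample_size(3, 0, 2), "t >= 1")
  expect_error(orme_sample_size(3, 8, 2, nonresponse = 1), "nonresponse")
  # non-increasing in t and a, non-decreasing in c and nonresponse
  grid <- expand.grid(c = 2:4, t = c(4, 8), a = 1:2, nr = c(0, 0.1))
  n <- mapply(orme_sample_size, grid$c, grid$t, grid$a, grid$nr)
  for (i in seq_len(nrow(grid))) {
    expect_gte(n[i], orme_sample_size(grid$c[i], grid$t[i] + 1, grid$a[i], grid$nr[i]))
    expect_gte(n[i], orme_sample_size(grid$c[i], grid$t[i], grid$a[i] + 1, grid$nr[i]))
    expect_lte(n[i], orme_sample_size(grid$c[i] + 1, grid$t[i], grid$a[i], grid$nr[i]))
    expect_lte(n[i], orme_sample_size(grid$c[i], grid$t[i], grid$a[i], grid$nr[i] + 0.2))
  }
})

test_that("design matrix encodes tasks with ASC and all-zero opt-out rows", {
  d <- study_design()
  X <- design_matrix(d)
  expect_equal(dim(X), c(24L, 6L))
  expect_equal(colnames(X),
               c("asc", "c_chw", "c_expert", "l_home", "s_phcall", "s_tvouch"))
  alt <- attr(X, "alt_id")
  expect_true(all(X[alt == 3, ] == 0))              # opt-out rows
  expect_true(all(X[alt != 3, "asc"] == 1))
  # task 8, alternative II: CHW delivering at home with travel vouchers
  row <- which(attr(X, "task_id") == 8 & alt == 2)
  expect_equal(unname(X[row, ]), c(1, 1, 0, 1, 0, 1))
})

test_that("design CSV round-trips the study fixture unchanged", {
  d <- study_design()
  tmp <- tempfile(fileext = ".csv")
  write_design(d, tmp)
  d2 <- read_design(tmp, cbdot_scheme())
  expect_identical(d$tasks, d2$tasks)
  expect_identical(d$n_tasks, 8L)
  # fixture content matches the shipped file byte-for-byte (modulo header)
  shipped <- readLines(system.file("extdata", "study_design.csv",
                                   package = "dcemixl"))
  expect_identical(readLines(tmp), shipped)
})

test_that("duplicate alternatives within a task are rejected", {
  tasks <- data.frame(task_id = c(1, 1), alt_id = c(1, 2),
                      provider = "CHW", location = "Home",
                      support = "SMS reminders")
  expect_error(choice_design(tasks, cbdot_scheme()), "repeats")
})

test_that("information matrix matches the brute-force summation oracle", {
  for (seed in c(3, 11)) {
    d <- search_design(cbdot_scheme(), 8, 2, iterations = 50, seed = seed)
    info <- dcemixl:::mnl_information(d)
    expect_lt(max(abs(info - oracle_information(d))), 1e-12)
  }
  d <- study_design()
  expect_lt(max(abs(dcemixl:::mnl_information(d) - oracle_information(d))),
            1e-12)
})

test_that("D-efficiency matches a direct-determinant oracle and normalises", {
  d <- study_design()
  m <- design_metrics(d)
  oracle <- det(oracle_information(d) / d$n_tasks)^(1 / 5)
  expect_equal(m$d_criterion, oracle, tolerance = 1e-10)
  expect_equal(m$d_error, 1 / oracle, tolerance = 1e-10)
  expect_gt(m$d_efficiency, 0)
  expect_lte(m$d_efficiency, 1)
  expect_equal(m$k_params, 5L)
  # self-normalisation
  expect_equal(design_metrics(d, reference = d)$d_efficiency, 1)
  # balance counts sum to t * a per attribute
  for (b in m$level_balance) expect_equal(sum(b), 16L)
})

test_that("degenerate designs give a singular-matrix error", {
  # every task pairs a CHW and an expert client, both at Home: the home
  # indicator equals c_chw + c_expert in every task, a linear dependence
  tasks <- study_design()$tasks
  tasks$location <- "Home"
  tasks$provider <- rep(c("CHW", "Expert client"), 8)
  d <- choice_design(tasks, cbdot_scheme())
  expect_error(design_metrics(d), "singular")
})

test_that("D-efficiency is invariant to task permutation and alt swap", {
  d <- study_design()
  base <- design_metrics(d)$d_efficiency
  perm <- d$tasks
  perm$task_id <- 9L - perm$task_id          # reverse task labels
  expect_equal(design_metrics(choice_design(perm, cbdot_scheme()))$d_efficiency,
               base, tolerance = 1e-12)
  swap <- d$tasks
  swap$alt_id <- ifelse(swap$alt_id == 1L, 2L, 1L)
  expect_equal(design_metrics(choice_design(swap, cbdot_scheme()))$d_efficiency,
               base, tolerance = 1e-12)
})

test_that("coordinate-exchange search is deterministic and beats random search", {
  s1 <- search_design(cbdot_scheme(), 8, 2, iterations = 400, seed = 7)
  s2 <- search_design(cbdot_scheme(), 8, 2, iterations = 400, seed = 7)
  expect_identical(s1$tasks, s2$tasks)
  best <- design_metrics(s1)$d_efficiency
  # Monte-Carlo comparison against pure random designs
  rand_best <- max(vapply(1:200, function(s) {
    d <- search_design(cbdot_scheme(), 8, 2, iterations = 0, seed = 1000 + s)
    tryCatch(design_metrics(d)$d_efficiency, error = function(e) 0)
  }, 0))
  expect_gte(best, rand_best)
})

test_that("search fails cleanly when parameters cannot be identified", {
  expect_error(search_design(cbdot_scheme(), 1, 2, iterations = 30, seed = 2),
               "nonsingular|identify")
})
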