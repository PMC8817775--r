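#' Construct a choice-set design
#'
#' A design is an ordered list of choice tasks, each presenting `a` designed
#' alternatives (profiles from the attribute scheme) plus an opt-out
#' ("Neither") alternative whose utility is normalised to zero. Duplicate
#' profiles within a task are rejected; the same profile may recur across
#' tasks.
#'
#' @param tasks Data frame with columns `task_id`, `alt_id` and one column per
#'   scheme attribute holding level labels; one row per designed alternative.
#' @param scheme A [attribute_scheme()].
#' @return An object of class `dce_design` with elements `tasks`, `scheme`,
#'   `n_tasks` and `n_alts`.
#' @examples
#' d <- study_design()
#' d$n_tasks
#' @export
choice_design <- function(tasks, scheme) {
  stopifnot(inherits(scheme, "dce_scheme"), is.data.frame(tasks))
  need <- c("task_id", "alt_id", names(scheme$attributes))
  missing_col <- setdiff(need, names(tasks))
  if (length(missing_col))
    stop("design lacks column(s): ", paste(missing_col, collapse = ", "))
  tasks <- tasks[order(tasks$task_id, tasks$alt_id), need, drop = FALSE]
  rownames(tasks) <- NULL
  encode_profiles(tasks, scheme)  # validates levels
  split_tasks <- split(tasks, tasks$task_id)
  n_alts <- unique(vapply(split_tasks, nrow, 0L))
  if (length(n_alts) != 1L || n_alts < 1L)
    stop("every task must present the same number of designed alternatives")
  for (tt in split_tasks) {
    key <- profile_label(tt, scheme)
    if (anyDuplicated(key))
      stop("task ", tt$task_id[1L], " repeats the same profile in two alternatives")
    if (any(tt$alt_id != seq_len(nrow(tt))))
      stop("task ", tt$task_id[1L], " must number alternatives 1..a")
  }
  structure(list(tasks = tasks, scheme = scheme,
                 n_tasks = length(split_tasks), n_alts = n_alts),
            class = "dce_design")
}

#' @export
print.dce_design <- function(x, ...) {
  cat("Choice-set design:", x$n_tasks, "tasks x", x$n_alts,
      "designed alternatives + opt-out\n")
  print(x$tasks, row.names = FALSE)
  invisible(x)
}

#' The eight choice sets of the community-based DOT study
#'
#' Loads the study's published fractional-factorial design: eight tasks, each
#' pairing two care-model profiles with an opt-out, shipped with the package
#' as a plain-text fixture.
#'
#' @return A `dce_design` over [cbdot_scheme()].
#' @export
study_design <- function() {
  path <- system.file("extdata", "study_design.csv", package = "dcemixl")
  read_design(path, cbdot_scheme())
}

#' Write / read a design CSV
#'
#' The on-disk layout has columns `task_id`, `alt_id`, then one column per
#' attribute holding the level label. The opt-out alternative is written as an
#' explicit row with `alt_id = a + 1` and empty level fields; the reader drops
#' such rows when rebuilding the design. Lines starting with `#` are ignored.
#'
#' @param design A `dce_design`.
#' @param path File path.
#' @param comment Optional comment line (without the leading `#`) written
#'   before the header, used by the pipeline to stamp seed and config hash.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `dce_design`.
#' @export
write_design <- function(design, path, comment = NULL) {
  stopifnot(inherits(design, "dce_design"))
  tasks <- design$tasks
  opt <- tasks[!duplicated(tasks$task_id), , drop = FALSE]
  opt$alt_id <- design$n_alts + 1L
  for (a in names(design$scheme$attributes)) opt[[a]] <- ""
  out <- rbind(tasks, opt)
  out <- out[order(out$task_id, out$alt_id), , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param scheme Scheme the design is read against.
#' @export
read_design <- function(path, scheme = cbdot_scheme()) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 colClasses = "character")
  df$task_id <- as.integer(df$task_id)
  df$alt_id <- as.integer(df$alt_id)
  attrs <- names(scheme$attributes)
  blank <- rowSums(df[, attrs, drop = FALSE] != "") == 0L
  choice_design(df[!blank, , drop = FALSE], scheme)
}

#' Dummy-coded design matrix in long format
#'
#' Expands a design to one row per (task, alternative) including the opt-out:
#' designed alternatives carry their profile's 0/1 indicators plus a 1 in the
#' alternative-specific-constant column `asc`; opt-out rows are all zero. Rows
#' are ordered task-major, alternative-minor, opt-out last within task.
#'
#' @param design A `dce_design`.
#' @return Numeric matrix with columns `asc` plus the scheme's indicator
#'   columns, and attributes `task_id` and `alt_id` giving each row's task and
#'   alternative.
#' @examples
#' dim(design_matrix(study_design()))  # 24 x 6
#' @export
design_matrix <- function(design) {
  stopifnot(inherits(design, "dce_design"))
  ind <- encode_profiles(design$tasks, design$scheme)
  J <- design$n_alts + 1L
  task_ids <- unique(design$tasks$task_id)
  X <- matrix(0, design$n_tasks * J, 1L + ncol(ind),
              dimnames = list(NULL, c("asc", colnames(ind))))
  row_task <- rep(task_ids, each = J)
  row_alt <- rep(seq_len(J), design$n_tasks)
  designed <- row_alt <= design$n_alts
  X[designed, "asc"] <- 1
  X[designed, -1L] <- ind
  attr(X, "task_id") <- row_task
  attr(X, "alt_id") <- row_alt
  X
}

#' Orme rule-of-thumb sample size for a choice experiment
#'
#' Computes the smallest integer respondent count N satisfying
#' \eqn{N > 500c/(t a)}, where `c` is the largest number of levels of any
#' attribute, `t` the number of choice tasks and `a` the number of designed
#' alternatives per task, then inflates it for anticipated non-response and
#' rounds up again.
#'
#' @param n_levels Largest number of levels across attributes (c >= 2).
#' @param n_tasks Number of choice tasks per respondent (t >= 1).
#' @param n_alts Designed alternatives per task, excluding the opt-out
#'   (a >= 1).
#' @param nonresponse Anticipated non-response proportion in [0, 1).
#' @return Integer sample size.
#' @examples
#' orme_sample_size(3, 8, 2, nonresponse = 0.10)  # 104
#' @export
orme_sample_size <- function(n_levels, n_tasks, n_alts, nonresponse = 0) {
  stopifnot(length(n_levels) == 1L, length(n_tasks) == 1L,
            length(n_alts) == 1L, length(nonresponse) == 1L)
  if (n_levels < 2 || n_tasks < 1 || n_alts < 1 || n_tasks * n_alts == 0)
    stop("need c >= 2, t >= 1, a >= 1")
  if (nonresponse < 0 || nonresponse >= 1)
    stop("'nonresponse' must be in [0, 1)")
  base_n <- ceiling(500 * n_levels / (n_tasks * n_alts))
  as.integer(ceiling(base_n * (1 + nonresponse)))
}

# Per-task information matrix summation for the multinomial logit at a prior
# on the indicator coefficients; opt-out (and ASC) utility held at zero.
mnl_information <- function(design, prior = NULL) {
  X <- design_matrix(design)
  K <- ncol(X) - 1L
  Xi <- X[, -1L, drop = FALSE]  # indicator columns only; ASC excluded from K
  if (is.null(prior)) prior <- rep(0, K)
  if (length(prior) != K) stop("'prior' must have length ", K)
  task <- attr(X, "task_id")
  u <- drop(Xi %*% prior)
  info <- matrix(0, K, K, dimnames = list(colnames(Xi), colnames(Xi)))
  for (tt in unique(task)) {
    rows <- which(task == tt)
    p <- exp(u[rows] - max(u[rows]))
    p <- p / sum(p)
    Xt <- Xi[rows, , drop = FALSE]
    xbar <- colSums(Xt * p)
    info <- info + t(Xt) %*% (Xt * p) - tcrossprod(xbar)
  }
  info
}

# D-criterion det(I/t)^(1/K); errors on a singular information matrix
# (relative eigenvalue tolerance, so scale does not matter).
d_criterion <- function(design, prior = NULL) {
  info <- mnl_information(design, prior)
  K <- ncol(info)
  ev <- eigen(info / design$n_tasks, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || min(ev) < 1e-10 * max(ev))
    stop("singular information matrix: the design cannot identify all ",
         K, " parameters")
  exp(mean(log(ev)))
}

# Largest attainable diagonal of the per-task information at the
# utility-neutral point: max over m of (m/J)(1 - m/J), m designed
# alternatives carrying the indicator; a Hadamard bound on det(I/t)^(1/K).
ideal_task_information <- function(n_alts) {
  J <- n_alts + 1L
  m <- seq_len(n_alts)
  max((m / J) * (1 - m / J))
}

#' Evaluate a design: D-efficiency, balance and overlap
#'
#' Computes the multinomial-logit information matrix
#' \eqn{I(\beta) = \sum_t X_t' (\mathrm{diag}(p_t) - p_t p_t') X_t} at a prior
#' coefficient vector (default zero, the utility-neutral point, where all
#' alternatives in a task are equally likely), the D-criterion
#' \eqn{\det(I/t)^{1/K}} over the K dummy-coded parameters (the ASC is
#' excluded), and a normalised D-efficiency in (0, 1]: the criterion divided
#' by that of the utility-neutral orthogonal ideal, or by the criterion of a
#' supplied reference design.
#'
#' @param design A `dce_design`.
#' @param prior Numeric length-K prior coefficient vector (default zeros).
#' @param reference Optional `dce_design` used to normalise the efficiency;
#'   a design referenced against itself scores exactly 1.
#' @return An object of class `dce_metrics`: `d_efficiency`, `d_criterion`,
#'   `d_error` (its reciprocal), `k_params`, `level_balance` (per-attribute
#'   level counts over designed alternatives) and `overlap_count` (tasks whose
#'   designed alternatives all share a level on some attribute).
#' @export
design_metrics <- function(design, prior = NULL, reference = NULL) {
  stopifnot(inherits(design, "dce_design"))
  crit <- d_criterion(design, prior)
  ref_crit <- if (is.null(reference)) ideal_task_information(design$n_alts)
              else d_criterion(reference, prior)
  balance <- lapply(names(design$scheme$attributes), function(a)
    table(factor(design$tasks[[a]], levels = design$scheme$attributes[[a]])))
  names(balance) <- names(design$scheme$attributes)
  overlap <- sum(vapply(split(design$tasks, design$tasks$task_id), function(tt)
    any(vapply(names(design$scheme$attributes),
               function(a) length(unique(tt[[a]])) == 1L, NA)), NA))
  structure(list(d_efficiency = crit / ref_crit,
                 d_criterion = crit,
                 d_error = 1 / crit,
                 k_params = nrow(design$scheme$coding),
                 level_balance = balance,
                 overlap_count = as.integer(overlap),
                 n_tasks = design$n_tasks, n_alts = design$n_alts),
            class = "dce_metrics")
}

#' @export
print.dce_metrics <- function(x, ...) {
  cat(sprintf("D-efficiency %.4f (criterion %.4f, K = %d, %d tasks x %d alts)\n",
              x$d_efficiency, x$d_criterion, x$k_params, x$n_tasks, x$n_alts))
  cat("Level balance:\n")
  for (a in names(x$level_balance)) {
    cat("  ", a, ": ", paste(names(x$level_balance[[a]]),
                             x$level_balance[[a]], sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  cat("Tasks with attribute overlap:", x$overlap_count, "\n")
  invisible(x)
}

# Draw one random task (a distinct profiles) from the scheme.
random_task <- function(scheme, n_alts) {
  repeat {
    prof <- as.data.frame(lapply(scheme$attributes, sample, size = n_alts,
                                 replace = TRUE), stringsAsFactors = FALSE)
    if (!anyDuplicated(apply(prof, 1L, paste, collapse = "\r"))) return(prof)
  }
}

#' Coordinate-exchange search for a D-efficient design
#'
#' Starts from a seeded random design and repeatedly proposes changing a
#' single attribute level of a single alternative, accepting the proposal when
#' it raises the D-criterion (and keeps the task's alternatives distinct).
#' Deterministic given `seed`; the returned design is never worse than the
#' starting design.
#'
#' @param scheme A `dce_scheme`.
#' @param n_tasks Number of tasks.
#' @param n_alts Designed alternatives per task.
#' @param iterations Number of exchange proposals.
#' @param seed Integer seed for the random start and proposal stream.
#' @param prior Prior coefficients passed to the D-criterion (default zeros).
#' @return A `dce_design`.
#' @export
search_design <- function(scheme, n_tasks, n_alts = 2L, iterations = 2000L,
                          seed = 1L, prior = NULL) {
  stopifnot(inherits(scheme, "dce_scheme"), n_tasks >= 1L, n_alts >= 1L)
  with_seed(seed, {
    tasks <- do.call(rbind, lapply(seq_len(n_tasks), function(tt) {
      prof <- random_task(scheme, n_alts)
      cbind(data.frame(task_id = tt, alt_id = seq_len(n_alts)), prof)
    }))
    cur <- choice_design(tasks, scheme)
    score <- function(d) tryCatch(d_criterion(d, prior), error = function(e) -Inf)
    cur_score <- score(cur)
    for (it in seq_len(iterations)) {
      tt <- sample.int(n_tasks, 1L)
      aa <- sample.int(n_alts, 1L)
      attr_name <- sample(names(scheme$attributes), 1L)
      levels_a <- scheme$attributes[[attr_name]]
      row <- which(cur$tasks$task_id == tt & cur$tasks$alt_id == aa)
      new_level <- sample(setdiff(levels_a, cur$tasks[[attr_name]][row]), 1L)
      cand_tasks <- cur$tasks
      cand_tasks[[attr_name]][row] <- new_level
      cand <- tryCatch(choice_design(cand_tasks, scheme),
                       error = function(e) NULL)
      if (is.null(cand)) next
      cand_score <- score(cand)
      if (cand_score > cur_score) {
        cur <- cand
        cur_score <- cand_score
      }
    }
    if (!is.finite(cur_score))
      stop("no nonsingular design found within ", iterations,
           " iterations: too few tasks to identify ",
           nrow(scheme$coding), " parameters")
    cur
  })
}
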