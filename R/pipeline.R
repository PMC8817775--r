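# Polynomial rolling hash (mod 2^31 - 1) of a character scalar, 8 hex digits.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline configuration
#'
#' @param scheme Path to a scheme YAML, or `NULL` for the built-in study
#'   scheme.
#' @param design Path to a design CSV, `NULL` for the built-in study design,
#'   or the string `"search"` to run the coordinate-exchange search.
#' @param population Path to a population YAML (labels/mu/sigma), or `NULL`
#'   for the study estimates.
#' @param n_respondents Cohort size (default 103).
#' @param draws,burn_in Halton settings for estimation.
#' @param search_tasks,search_alts,search_iterations Design-search settings
#'   (used when `design = "search"`).
#' @param subgroups Covariates to run subgroup analyses on.
#' @param subgroup_draws Halton draws for the stratum fits.
#' @param seed Root seed; all stage seeds derive from it.
#' @return A list of class `dce_config`.
#' @export
pipeline_config <- function(scheme = NULL, design = NULL, population = NULL,
                            n_respondents = 103L, draws = 1000L,
                            burn_in = 10L, search_tasks = 8L,
                            search_alts = 2L, search_iterations = 2000L,
                            subgroups = "hiv_status", subgroup_draws = draws,
                            seed = 1L) {
  structure(list(scheme = scheme, design = design, population = population,
                 n_respondents = as.integer(n_respondents),
                 draws = as.integer(draws), burn_in = as.integer(burn_in),
                 search_tasks = as.integer(search_tasks),
                 search_alts = as.integer(search_alts),
                 search_iterations = as.integer(search_iterations),
                 subgroups = subgroups,
                 subgroup_draws = as.integer(subgroup_draws),
                 seed = as.integer(seed)),
            class = "dce_config")
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — design (load or search), cohort
#' simulation, mixed-logit estimation, relative importance, profile ranking,
#' subgroup analyses — writing `design.csv`, `choices.csv`, `result.json`,
#' `importance.json`, `ranking.csv`, `subgroups.json` and `run.log` to the
#' output directory. Every output is stamped with the root seed and a hash of
#' the configuration; re-running with the same configuration reproduces
#' identical outputs byte for byte (timestamps appear only in the log). A
#' stage failure stops the run with the stage name; outputs of completed
#' stages are retained.
#'
#' @param config A [pipeline_config()], or the path of a YAML file with the
#'   same fields.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a `dce_run` bundle: the config, output paths, and the
#'   stage objects (`design`, `choices`, `fit`, `importance`, `ranking`,
#'   `subgroups`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "dce_config"))
  for (f in c(config$scheme, config$population)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  if (!is.null(config$design) && !identical(config$design, "search") &&
      !file.exists(config$design))
    stop("input file not found: ", config$design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(deparse(unclass(config)))
  stamp <- paste0("seed=", config$seed, " config=", hash)
  log_lines <- c(paste("dcemixl", as.character(packageVersion("dcemixl")),
                       "| R", paste(R.version$major, R.version$minor,
                                    sep = ".")),
                 paste("config hash:", hash),
                 paste("seed:", config$seed))
  paths <- list()
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("[%s] stage %-10s done in %.2fs",
                                       format(Sys.time(), "%H:%M:%S"), name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }

  scheme <- stage("scheme", {
    if (is.null(config$scheme)) cbdot_scheme() else read_scheme(config$scheme)
  })
  design <- stage("design", {
    if (identical(config$design, "search")) {
      search_design(scheme, config$search_tasks, config$search_alts,
                    config$search_iterations,
                    seed = stage_seed(config$seed, 10L))
    } else if (is.null(config$design)) {
      if (!identical(scheme, cbdot_scheme()))
        stop("a custom scheme needs an explicit design (path or 'search')")
      study_design()
    } else read_design(config$design, scheme)
  })
  paths$design <- file.path(out_dir, "design.csv")
  write_design(design, paths$design, comment = stamp)

  choices <- stage("simulate", {
    pop <- if (is.null(config$population)) study_population() else {
      y <- yaml::read_yaml(config$population)
      population_preferences(y$mu, y$sigma, labels = y$labels)
    }
    simulate_study(n = config$n_respondents, design = design, pop = pop,
                   seed = config$seed)
  })
  paths$choices <- file.path(out_dir, "choices.csv")
  write_choices(choices, paths$choices, comment = stamp)

  fml <- stats::reformulate(indicator_cols(scheme), response = "chosen")
  fit <- stage("fit", {
    mixlogit(fml, data = choices, random = scheme$coding$column,
             draws = config$draws, burn_in = config$burn_in)
  })
  paths$result <- file.path(out_dir, "result.json")
  write_result_json(fit, paths$result, seed = config$seed, hash = hash)

  importance <- stage("importance", relative_importance(fit, scheme = scheme))
  paths$importance <- file.path(out_dir, "importance.json")
  jsonlite::write_json(
    list(seed = config$seed, config = hash,
         attributes = stats::setNames(as.list(importance$importance),
                                      importance$attribute)),
    paths$importance, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ranking <- stage("rank", rank_profiles(utility_equation(fit), scheme))
  paths$ranking <- file.path(out_dir, "ranking.csv")
  rk <- data.frame(profile = ranking$profile, v_score = ranking$utility,
                   rank = ranking$rank)
  con <- file(paths$ranking, "wt", encoding = "UTF-8")
  writeLines(paste0("# ", stamp), con)
  write.csv(rk, con, row.names = FALSE, quote = FALSE)
  close(con)

  subgroups <- stage("subgroup", {
    out <- lapply(config$subgroups, function(by)
      subgroup_analysis(choices, by, scheme = scheme, formula = fml,
                        random = scheme$coding$column,
                        draws = config$subgroup_draws,
                        burn_in = config$burn_in))
    names(out) <- config$subgroups
    out
  })
  paths$subgroups <- file.path(out_dir, "subgroups.json")
  jsonlite::write_json(
    list(seed = config$seed, config = hash,
         subgroups = lapply(subgroups, function(sg) list(
           by = sg$by, strata = sg$strata,
           n_obs = stats::setNames(as.list(sg$n_obs), sg$strata),
           excluded_rows = sg$n_excluded_rows,
           converged = sg$converged,
           tests = sg$tests))),
    paths$subgroups, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(log_lines, sprintf("total elapsed %.2fs",
                                    proc.time()[["elapsed"]] - t_all),
                 paste("outputs:", paste(basename(unlist(paths)),
                                         collapse = ", ")))
  paths$log <- file.path(out_dir, "run.log")
  writeLines(log_lines, paths$log)

  invisible(structure(list(config = config, hash = hash, paths = paths,
                           scheme = scheme, design = design,
                           choices = choices, fit = fit,
                           importance = importance, ranking = ranking,
                           subgroups = subgroups),
                      class = "dce_run"))
}

# result.json mirrors the model-table layout: per-parameter estimate, se,
# ci95, p, plus the heterogeneity-SD block, loglik and counts.
write_result_json <- function(fit, path, seed = NULL, hash = NULL) {
  s <- summary(fit)
  param <- lapply(rownames(s$mean_table), function(nm) {
    row <- s$mean_table[nm, ]
    out <- list(estimate = row$estimate, se = row$se,
                ci95 = c(row$ci_lo, row$ci_hi), p = row$p)
    if (!is.null(s$sd_table) && nm %in% rownames(s$sd_table)) {
      sdr <- s$sd_table[nm, ]
      out$sd <- list(estimate = sdr$estimate, se = sdr$se,
                     ci95 = c(sdr$ci_lo, sdr$ci_hi), p = sdr$p)
    }
    out
  })
  names(param) <- rownames(s$mean_table)
  jsonlite::write_json(
    list(seed = seed, config = hash, parameters = param,
         loglik = fit$loglik, n_obs = fit$n_obs,
         n_respondents = fit$n_resp, draws = fit$n_draws,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render report tables from a pipeline bundle
#'
#' Formats the bundle's model estimates (estimate, 95% CI, p, SD, SD p,
#' relative importance) and the profile ranking (profile, utility, rank) as
#' fixed-width text tables.
#'
#' @param bundle A `dce_run` bundle from [run_pipeline()].
#' @return Character vector of table lines.
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "dce_run"))
  if (is.null(bundle$fit) || is.null(bundle$ranking) ||
      nrow(bundle$ranking) == 0L)
    stop("incomplete bundle: fit and ranking are required")
  s <- summary(bundle$fit)
  imp <- bundle$importance
  lines <- c("Model estimates", sprintf(
    "%-12s %9s %18s %8s %9s %8s", "parameter", "estimate", "95% CI", "p",
    "SD", "SD p"))
  for (nm in rownames(s$mean_table)) {
    row <- s$mean_table[nm, ]
    has_sd <- !is.null(s$sd_table) && nm %in% rownames(s$sd_table)
    lines <- c(lines, sprintf(
      "%-12s %9.3f [%7.3f, %6.3f] %8.4f %9s %8s", nm, row$estimate,
      row$ci_lo, row$ci_hi, row$p,
      if (has_sd) sprintf("%.3f", s$sd_table[nm, "estimate"]) else "-",
      if (has_sd) sprintf("%.4f", s$sd_table[nm, "p"]) else "-"))
  }
  lines <- c(lines, "", "Relative importance (range method)")
  lines <- c(lines, sprintf("  %-12s %5.1f%%", imp$attribute,
                            round(imp$importance, 1)))
  lines <- c(lines, "", "Care-model ranking", sprintf(
    "%-55s %8s %5s", "profile", "utility", "rank"))
  lines <- c(lines, sprintf("%-55s %8.2f %5d", bundle$ranking$profile,
                            round(bundle$ranking$utility, 2),
                            bundle$ranking$rank))
  lines
}

#' Validate pipeline input files
#'
#' Checks a design CSV and/or a choices CSV against the schema, grouping and
#' domain contracts. Violations are returned as data, not raised as errors.
#'
#' @param design Optional path of a design CSV.
#' @param choices Optional path of a choices CSV.
#' @param scheme Scheme to validate against.
#' @return Data frame with columns `file`, `check`, `message`; zero rows when
#'   all inputs are valid.
#' @export
validate_inputs <- function(design = NULL, choices = NULL,
                            scheme = cbdot_scheme()) {
  out <- data.frame(file = character(), check = character(),
                    message = character(), stringsAsFactors = FALSE)
  if (!is.null(design)) {
    res <- tryCatch({ read_design(design, scheme); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(res))
      out <- rbind(out, data.frame(file = design, check = "design",
                                   message = res, stringsAsFactors = FALSE))
  }
  if (!is.null(choices)) {
    if (!file.exists(choices)) {
      out <- rbind(out, data.frame(file = choices, check = "schema",
                                   message = "file not found",
                                   stringsAsFactors = FALSE))
    } else {
      df <- tryCatch(read.csv(choices, stringsAsFactors = FALSE,
                              comment.char = "#", na.strings = ""),
                     error = function(e) NULL)
      if (is.null(df)) {
        out <- rbind(out, data.frame(file = choices, check = "schema",
                                     message = "unparseable CSV",
                                     stringsAsFactors = FALSE))
      } else {
        v <- validate_choices(df, scheme)
        if (nrow(v))
          out <- rbind(out, data.frame(file = choices, check = v$check,
                                       message = v$message,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  out
}
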