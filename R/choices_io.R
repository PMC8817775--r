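indicator_cols <- function(scheme) c("asc", scheme$coding$column)

choice_key_cols <- c("respondent_id", "task_id", "alt_id", "chosen")

covariate_levels <- list(
  gender = c("female", "male"),
  age_group = c("20-34", ">=35"),
  hiv_status = c("negative", "positive"),
  months_group = c("<6", ">=6"))

#' Validate a long-format choice dataset
#'
#' Checks the structural contract of a choice dataset: required columns,
#' 0/1 domains of `chosen` and the indicator columns, unique
#' (respondent, task, alternative) keys, exactly one chosen alternative per
#' (respondent, task), exactly one opt-out (all-zero) row per task, and
#' recognised covariate categories where covariates are present.
#'
#' @param data Data frame in the long choice format.
#' @param scheme Scheme defining the indicator columns.
#' @return Data frame of violations with columns `check` and `message`;
#'   zero rows when the dataset is valid.
#' @export
validate_choices <- function(data, scheme = cbdot_scheme()) {
  v <- list()
  add <- function(check, message)
    v[[length(v) + 1L]] <<- data.frame(check = check, message = message,
                                       stringsAsFactors = FALSE)
  ind <- indicator_cols(scheme)
  missing_col <- setdiff(c(choice_key_cols, ind), names(data))
  if (length(missing_col)) {
    add("schema", paste("missing column(s):",
                        paste(missing_col, collapse = ", ")))
    return(do.call(rbind, v))
  }
  for (col in c("chosen", ind)) {
    bad <- !data[[col]] %in% c(0, 1)
    if (any(bad))
      add("domain", paste0("column '", col, "' has ", sum(bad),
                           " value(s) outside {0, 1}"))
  }
  key <- paste(data$respondent_id, data$task_id, data$alt_id, sep = "\r")
  if (anyDuplicated(key))
    add("keys", "duplicate (respondent, task, alternative) rows")
  grp <- paste(data$respondent_id, data$task_id, sep = "\r")
  n_chosen <- tapply(data$chosen, grp, sum)
  if (any(n_chosen != 1))
    add("grouping", paste(sum(n_chosen != 1),
                          "task(s) without exactly one chosen alternative"))
  optout <- rowSums(data[, ind, drop = FALSE] != 0) == 0L
  if (any(data$asc == 0 & !optout))
    add("grouping", "rows with asc = 0 must have all-zero indicators")
  n_opt <- tapply(optout, grp, sum)
  if (any(n_opt != 1))
    add("grouping", paste(sum(n_opt != 1),
                          "task(s) without exactly one opt-out row"))
  for (col in intersect(names(covariate_levels), names(data))) {
    bad <- !is.na(data[[col]]) & !data[[col]] %in% covariate_levels[[col]]
    if (any(bad))
      add("covariates", paste0("column '", col, "' has unrecognised categories: ",
                               paste(unique(data[[col]][bad]), collapse = ", ")))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(check = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Write / read choice data CSV
#'
#' Lossless round-trip of the long choice format (`respondent_id`, `task_id`,
#' `alt_id`, `chosen`, `asc`, indicator columns, covariates). The reader
#' validates the structural contract with [validate_choices()] and fails on
#' any violation. Lines starting with `#` are ignored.
#'
#' @param data Long-format choice data frame.
#' @param path File path.
#' @param comment Optional comment line written before the header.
#' @param scheme Scheme defining the indicator columns.
#' @return `write_choices` returns `path` invisibly; `read_choices` returns
#'   the validated data frame.
#' @export
write_choices <- function(data, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(data, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path, scheme = cbdot_scheme()) {
  if (!file.exists(path)) stop("choices file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 na.strings = "")
  viol <- validate_choices(df, scheme)
  if (nrow(viol))
    stop("invalid choice data:\n",
         paste0("  [", viol$check, "] ", viol$message, collapse = "\n"))
  df
}

#' Dimensions of a choice dataset
#'
#' @param data Long-format choice data frame.
#' @return List with `n_respondents`, `n_tasks` (per respondent), `n_alts`
#'   (alternatives per task, opt-out included) and `n_rows`.
#' @examples
#' \dontrun{choice_dims(simulate_study(seed = 1))}
#' @export
choice_dims <- function(data) {
  n_resp <- length(unique(data$respondent_id))
  tasks_per <- tapply(data$task_id, data$respondent_id,
                      function(x) length(unique(x)))
  alts_per <- tapply(data$alt_id, paste(data$respondent_id, data$task_id),
                     length)
  list(n_respondents = n_resp,
       n_tasks = if (length(unique(tasks_per)) == 1L) unname(tasks_per[1L])
                 else NA_integer_,
       n_alts = if (length(unique(alts_per)) == 1L) unname(alts_per[1L])
                else NA_integer_,
       n_rows = nrow(data))
}
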