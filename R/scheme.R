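#' Define a choice-experiment attribute scheme
#'
#' An attribute scheme lists the attributes that describe a hypothetical
#' alternative, the levels each attribute can take, and the dummy-coded
#' indicator column attached to every non-reference level. The first level of
#' each attribute is its reference level: its coefficient is constrained to
#' zero and it receives no indicator column, so a scheme with levels
#' \eqn{c_1, \dots, c_A} produces \eqn{\sum_a (c_a - 1)} indicator columns.
#'
#' @param attributes Named list; each element is a character vector of at
#'   least two distinct level labels, the first being the reference level.
#' @param columns Optional named list parallel to `attributes`, giving the
#'   indicator column name for each non-reference level. Defaults to
#'   syntactic names built from the attribute and level labels.
#' @return An object of class `dce_scheme` with elements `attributes`,
#'   `columns`, and a `coding` table mapping (attribute, level) pairs to
#'   indicator columns.
#' @examples
#' sch <- attribute_scheme(list(price = c("low", "high")))
#' cbdot_scheme()
#' @export
attribute_scheme <- function(attributes, columns = NULL) {
  if (!is.list(attributes) || length(attributes) < 1L)
    stop("'attributes' must be a non-empty named list of level vectors")
  nm <- names(attributes)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("attributes must have unique non-empty names")
  for (a in nm) {
    lev <- attributes[[a]]
    if (!is.character(lev) || length(lev) < 2L || anyDuplicated(lev) ||
        any(!nzchar(lev)))
      stop("attribute '", a, "' needs at least 2 distinct non-empty levels")
  }
  if (is.null(columns)) {
    columns <- lapply(nm, function(a)
      make.names(paste(a, attributes[[a]][-1L], sep = "_")))
    names(columns) <- nm
  }
  if (!identical(sort(names(columns)), sort(nm)))
    stop("'columns' must be named like 'attributes'")
  for (a in nm) {
    if (length(columns[[a]]) != length(attributes[[a]]) - 1L)
      stop("attribute '", a, "' needs one column per non-reference level")
  }
  coding <- do.call(rbind, lapply(nm, function(a) data.frame(
    attribute = a,
    level = attributes[[a]][-1L],
    column = columns[[a]],
    stringsAsFactors = FALSE)))
  if (anyDuplicated(coding$column))
    stop("indicator column names must be unique")
  structure(list(attributes = attributes, columns = columns, coding = coding),
            class = "dce_scheme")
}

#' @export
print.dce_scheme <- function(x, ...) {
  cat("Attribute scheme:", length(x$attributes), "attributes,",
      nrow(x$coding), "dummy-coded parameters\n")
  for (a in names(x$attributes)) {
    lev <- x$attributes[[a]]
    cat("  ", a, ": ", lev[1L], " (reference), ",
        paste(lev[-1L], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Attribute scheme of the community-based DOT study
#'
#' The three-attribute scheme used throughout the package's worked example:
#' the person delivering directly observed therapy (DOT) to an MDR-TB patient
#' (family member as reference, community health worker, expert client), the
#' location of treatment delivery (workplace as reference, home), and the type
#' of additional support (SMS reminder as reference, phone-call reminder,
#' travel voucher). Dummy coding yields the five indicator columns `c_chw`,
#' `c_expert`, `l_home`, `s_phcall`, `s_tvouch`.
#'
#' @return A `dce_scheme`.
#' @export
cbdot_scheme <- function() {
  attribute_scheme(
    attributes = list(
      provider = c("Family member", "CHW", "Expert client"),
      location = c("Work", "Home"),
      support  = c("SMS reminders", "Call reminders", "Travel vouchers")),
    columns = list(
      provider = c("c_chw", "c_expert"),
      location = "l_home",
      support  = c("s_phcall", "s_tvouch")))
}

#' Enumerate the full factorial of profiles
#'
#' Lists every combination of attribute levels exactly once, in lexicographic
#' order (the first attribute is the most significant digit; levels are
#' ordered as declared in the scheme).
#'
#' @param scheme A `dce_scheme`.
#' @return A data frame with one column per attribute and one row per profile.
#' @examples
#' nrow(full_factorial(cbdot_scheme()))  # 18
#' @export
full_factorial <- function(scheme) {
  stopifnot(inherits(scheme, "dce_scheme"))
  g <- expand.grid(rev(scheme$attributes), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  rownames(g) <- NULL
  g
}

# Encode profiles (data frame with one column per attribute, or a single
# named character vector) into the scheme's 0/1 indicator matrix.
encode_profiles <- function(profiles, scheme) {
  stopifnot(inherits(scheme, "dce_scheme"))
  if (!is.data.frame(profiles)) {
    profiles <- as.list(profiles)
    profiles <- as.data.frame(profiles, stringsAsFactors = FALSE)
  }
  missing_attr <- setdiff(names(scheme$attributes), names(profiles))
  if (length(missing_attr))
    stop("profile lacks attribute(s): ", paste(missing_attr, collapse = ", "))
  for (a in names(scheme$attributes)) {
    bad <- setdiff(unique(profiles[[a]]), scheme$attributes[[a]])
    if (length(bad))
      stop("unknown level(s) for '", a, "': ", paste(bad, collapse = ", "))
  }
  out <- matrix(0L, nrow(profiles), nrow(scheme$coding),
                dimnames = list(NULL, scheme$coding$column))
  for (i in seq_len(nrow(scheme$coding))) {
    out[, i] <- as.integer(
      profiles[[scheme$coding$attribute[i]]] == scheme$coding$level[i])
  }
  out
}

# "CHW/Home/Travel vouchers"-style labels for profile rows.
profile_label <- function(profiles, scheme, sep = "/") {
  apply(profiles[, names(scheme$attributes), drop = FALSE], 1L,
        paste, collapse = sep)
}
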