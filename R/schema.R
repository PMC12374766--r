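#' Declare a categorical variable
#'
#' A variable specification names a discrete variable and fixes the order of
#' its category labels. Category order is part of the model definition: CPT
#' layouts, sampling and serialisation all follow the declared order, never
#' the order in which labels happen to appear in data.
#'
#' @param name Variable name (non-empty string).
#' @param categories Character vector of at least two unique category labels.
#' @return An object of class `bn_variable`.
#' @examples
#' variable_spec("hypertension", c("no", "yes"))
#' @export
variable_spec <- function(name, categories) {
  if (!is_string(name) || !nzchar(name)) {
    stop2("variable name must be a non-empty string")
  }
  categories <- as.character(categories)
  if (length(categories) < 2L) {
    stop2("variable '", name, "' needs at least 2 categories, got ",
          length(categories))
  }
  if (anyDuplicated(categories)) {
    stop2("variable '", name, "' has duplicated category labels: ",
          paste(unique(categories[duplicated(categories)]), collapse = ", "))
  }
  structure(list(name = name, categories = categories),
            class = "bn_variable")
}

#' Declare a cohort schema
#'
#' Collects the variable specifications of a cohort (predictors plus outcome)
#' and names the outcome variable.
#'
#' @param variables List of [variable_spec()] objects.
#' @param outcome Name of the outcome variable; must be declared in
#'   `variables`.
#' @return An object of class `bn_schema`.
#' @export
cohort_schema <- function(variables, outcome) {
  if (!length(variables)) stop2("schema needs at least one variable")
  variables <- lapply(variables, function(v) {
    if (inherits(v, "bn_variable")) v else variable_spec(v$name, v$categories)
  })
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop2("duplicated variable names in schema: ",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (!is_string(outcome) || !outcome %in% nms) {
    stop2("outcome '", outcome, "' is not a declared variable")
  }
  names(variables) <- nms
  structure(list(variables = variables, outcome = outcome),
            class = "bn_schema")
}

schema_names <- function(schema) names(schema$variables)

schema_categories <- function(schema, var) {
  v <- schema$variables[[var]]
  if (is.null(v)) stop2("unknown variable '", var, "'")
  v$categories
}

schema_cardinality <- function(schema, var) length(schema_categories(schema, var))

#' @export
print.bn_schema <- function(x, ...) {
  cat("Cohort schema:", length(x$variables), "variables, outcome =",
      x$outcome, "\n")
  for (v in x$variables) {
    cat("  ", v$name, ": ", paste(v$categories, collapse = "/"), "\n",
        sep = "")
  }
  invisible(x)
}

#' Default hereditary-angioedema cohort schema
#'
#' Nine categorical predictors describing an inpatient admission — age group,
#' race, household-income quartile, census region, primary payer, three
#' comorbidity indicators (hypertension, autoimmune disease, diabetes) and
#' APR-DRG admission severity — plus a binary mortality-risk outcome
#' (minor/moderate severity-of-risk collapsed to `low`, major/extreme to
#' `high`).
#'
#' @return A `bn_schema`.
#' @export
default_ha_schema <- function() {
  cohort_schema(
    list(
      variable_spec("age",          c("le17", "18-39", "40-64", "ge65")),
      variable_spec("race",         c("white", "black", "hispanic", "other")),
      variable_spec("income",       c("q1", "q2", "q3", "q4")),
      variable_spec("region",       c("northeast", "midwest", "south", "west")),
      variable_spec("insurance",    c("medicare", "medicaid", "private", "other")),
      variable_spec("hypertension", c("no", "yes")),
      variable_spec("autoimmune",   c("no", "yes")),
      variable_spec("diabetes",     c("no", "yes")),
      variable_spec("severity",     c("minor", "moderate", "major", "extreme")),
      variable_spec("mortality",    c("low", "high"))
    ),
    outcome = "mortality"
  )
}

#' Validate a cohort table against a schema
#'
#' Checks that every schema variable is present as a column and every cell
#' holds a declared category label. Offending cells are reported with row
#' numbers. Columns are returned as factors with levels in schema order, so
#' downstream count tables are laid out deterministically.
#'
#' @param data A data frame of category labels (character or factor columns).
#' @param schema A `bn_schema`.
#' @param require_outcome If `FALSE`, the outcome column may be absent
#'   (e.g. for prediction-only inputs).
#' @return The validated data frame with factor columns in schema order.
#' @export
validate_cohort <- function(data, schema, require_outcome = TRUE) {
  stopifnot(is.data.frame(data), inherits(schema, "bn_schema"))
  wanted <- schema_names(schema)
  if (!require_outcome) wanted <- setdiff(wanted, schema$outcome)
  missing_cols <- setdiff(wanted, names(data))
  if (length(missing_cols)) {
    stop2("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- data[wanted]
  for (var in wanted) {
    cats <- schema_categories(schema, var)
    col <- as.character(out[[var]])
    bad <- which(is.na(col) | !col %in% cats)
    if (length(bad)) {
      shown <- utils::head(bad, 5L)
      stop2("column '", var, "' has ", length(bad),
            " invalid value(s); e.g. row ", shown[1], ": '",
            col[shown[1]], "' (allowed: ", paste(cats, collapse = ", "), ")")
    }
    out[[var]] <- factor(col, levels = cats)
  }
  rownames(out) <- NULL
  out
}

#' Read a cohort CSV
#'
#' Reads a header-row CSV of category labels and validates it with
#' [validate_cohort()].
#'
#' @inheritParams validate_cohort
#' @param path CSV file path.
#' @return Validated data frame of factors.
#' @export
read_cohort_csv <- function(path, schema, require_outcome = TRUE) {
  data <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
  validate_cohort(data, schema, require_outcome = require_outcome)
}

#' Write a cohort CSV
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @export
write_cohort_csv <- function(data, path) {
  out <- data
  out[] <- lapply(out, as.character)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Integer category codes (n x p matrix) for `vars`, in schema order.
cohort_codes <- function(data, schema, vars = schema_names(schema)) {
  m <- vapply(vars, function(v) {
    col <- data[[v]]
    if (!is.factor(col) ||
        !identical(levels(col), schema_categories(schema, v))) {
      col <- factor(as.character(col), levels = schema_categories(schema, v))
    }
    unclass(col)
  }, integer(nrow(data)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(data))
  colnames(m) <- vars
  m
}
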