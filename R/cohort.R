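# Cohort tables: tibbles typed by a tier_schema; missing cells are NA.

#' Validate a cohort table against a schema
#'
#' A cohort table is an ordinary tibble whose columns are exactly the
#' schema's variables: categorical variables as factors with the schema's
#' levels, continuous variables as finite doubles. Missing cells are `NA`;
#' the missingness mask is therefore `is.na()` of the table.
#'
#' @param data A data frame.
#' @param schema A [tier_schema()].
#' @return `data` as a tibble, columns coerced to schema order and types.
#' @export
validate_cohort <- function(data, schema) {
  data <- as_tibble(data)
  missing_cols <- setdiff(schema$variables$name, names(data))
  if (length(missing_cols)) {
    abort(sprintf("data lacks schema variables: %s", paste(missing_cols, collapse = ", ")))
  }
  data <- data[schema$variables$name]
  lv <- schema_levels(schema)
  for (i in seq_len(nrow(schema$variables))) {
    nm <- schema$variables$name[i]
    if (schema$variables$kind[i] == "categorical") {
      col <- data[[nm]]
      if (!is.factor(col)) col <- factor(as.character(col), levels = lv[[nm]])
      else col <- factor(as.character(col), levels = lv[[nm]])
      bad <- !is.na(data[[nm]]) & is.na(col)
      if (any(bad)) abort(sprintf("column '%s' has values outside its levels", nm))
      data[[nm]] <- col
    } else {
      col <- as.numeric(data[[nm]])
      if (any(!is.na(col) & !is.finite(col))) {
        abort(sprintf("column '%s' has non-finite observed values", nm))
      }
      data[[nm]] <- col
    }
  }
  data
}

#' Read or write a cohort table as CSV with a sidecar schema
#'
#' Missing cells are written as empty strings; the schema file is
#' authoritative for column typing when reading back.
#'
#' @param path CSV file path.
#' @param schema A [tier_schema()] (or, for `read_cohort()`, a path to a
#'   schema file accepted by [read_schema()]).
#' @return `read_cohort()` returns a validated tibble.
#' @export
read_cohort <- function(path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  validate_cohort(raw, schema)
}

#' @rdname read_cohort
#' @param data A cohort tibble.
#' @export
write_cohort <- function(data, path) {
  out <- data
  for (nm in names(out)) out[[nm]] <- as.character(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Fraction of missing cells, overall or per column.
missing_fraction <- function(data, by_column = FALSE) {
  if (by_column) vapply(data, function(c) mean(is.na(c)), numeric(1))
  else mean(is.na(as.matrix(data)))
}
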