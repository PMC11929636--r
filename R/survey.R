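#' Construct a survey table
#'
#' A survey table is a rectangular respondent-by-variable grid of numeric
#' values with explicit missingness (`NA`) and unique respondent identifiers.
#' It is the common input container for scale scoring and for the node tables
#' handed to the correlation stage.
#'
#' @param values data frame of numeric (or `NA`) item/variable columns.
#' @param respondent_id character vector of unique respondent labels; defaults
#'   to `r001 ...` when omitted. A column named `respondent_id` inside
#'   `values` is used (and removed from the grid) when present.
#' @return An object of class `survey_table`: a data frame whose first column
#'   is `respondent_id`, followed by the numeric variables.
#' @export
survey_table <- function(values, respondent_id = NULL) {
  values <- as.data.frame(values)
  if ("respondent_id" %in% names(values)) {
    if (is.null(respondent_id)) respondent_id <- as.character(values$respondent_id)
    values$respondent_id <- NULL
  }
  if (is.null(respondent_id)) {
    respondent_id <- sprintf("r%03d", seq_len(nrow(values)))
  }
  respondent_id <- as.character(respondent_id)
  if (length(respondent_id) != nrow(values)) {
    data_error("respondent_id length does not match the number of rows")
  }
  if (anyDuplicated(respondent_id)) {
    data_error("respondent ids must be unique")
  }
  bad <- names(values)[!vapply(values, is.numeric, logical(1))]
  if (length(bad)) {
    data_error(paste0("non-numeric survey column(s): ", paste(bad, collapse = ", ")))
  }
  out <- cbind(data.frame(respondent_id = respondent_id, stringsAsFactors = FALSE), values)
  class(out) <- c("survey_table", "data.frame")
  out
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %d respondents x %d variables\n",
              nrow(x), ncol(x) - 1L))
  print(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

survey_values <- function(table) {
  stopifnot(inherits(table, "survey_table") || is.data.frame(table))
  df <- as.data.frame(table)
  df$respondent_id <- NULL
  df
}

#' Read a survey table from delimited text
#'
#' Expects a comma-separated file whose first row holds variable names. A
#' `respondent_id` column is honoured if present. Cells equal to
#' `missing_marker` (default: empty) are read as missing; any other
#' non-numeric cell is a data error naming its row and column.
#'
#' @param path file path.
#' @param missing_marker string standing for a missing cell.
#' @return A [survey_table()].
#' @export
read_survey <- function(path, missing_marker = "") {
  if (!file.exists(path)) data_error(paste0("input file not found: ", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = missing_marker)
  id <- NULL
  if ("respondent_id" %in% names(raw)) {
    id <- raw$respondent_id
    raw$respondent_id <- NULL
  }
  num <- raw
  for (cn in names(raw)) {
    v <- raw[[cn]]
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(conv))
    if (length(bad)) {
      data_error(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                         bad[1], cn, v[bad[1]]))
    }
    num[[cn]] <- conv
  }
  survey_table(num, respondent_id = id)
}

#' Write a survey table as delimited text
#'
#' @param table a [survey_table()] or data frame.
#' @param path output file path.
#' @param missing_marker string written for missing cells.
#' @export
write_survey <- function(table, path, missing_marker = "") {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   na = missing_marker, quote = FALSE)
  invisible(path)
}

#' Declare the measurement level of a variable
#'
#' Variable specifications override automatic level detection in the
#' correlation stage and document the legal range of a variable.
#'
#' @param name variable name.
#' @param level one of `"continuous"`, `"ordinal"`, `"binary"`.
#' @param allowed_range closed numeric interval `c(lo, hi)`.
#' @param n_levels number of categories (ordinal/binary only, `>= 2`).
#' @return A `variable_spec` list.
#' @export
variable_spec <- function(name, level = c("continuous", "ordinal", "binary"),
                          allowed_range = c(-Inf, Inf), n_levels = NULL) {
  level <- match.arg(level)
  if (level != "continuous") {
    if (is.null(n_levels) || n_levels < 2) {
      config_error(sprintf("ordinal/binary variable '%s' needs n_levels >= 2", name))
    }
  }
  structure(list(name = name, level = level,
                 allowed_range = as.numeric(allowed_range),
                 n_levels = n_levels),
            class = "variable_spec")
}

#' Read variable specifications from JSON
#'
#' The file holds an array of objects with fields `name`, `level`, and
#' optionally `allowed_range` and `n_levels`.
#'
#' @param path JSON file path.
#' @return Named list of [variable_spec()] objects.
#' @export
read_variable_specs <- function(path) {
  if (!file.exists(path)) config_error(paste0("variable-spec file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  specs <- lapply(raw, function(s) {
    variable_spec(s$name, s$level,
                  allowed_range = unlist(s$allowed_range) %||% c(-Inf, Inf),
                  n_levels = s$n_levels %||% NULL)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
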