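#' Declare a cohort variable
#'
#' A variable specification describes one column of a cohort table: its
#' measurement kind (binary questionnaire class or continuous assay value),
#' the tissue it was measured in, its units, and either the closed interval
#' of admissible values (continuous) or the two class labels (binary).
#'
#' @param name Variable name (unique within a schema).
#' @param kind `"binary"` or `"continuous"`.
#' @param tissue One of `"placenta"`, `"maternal_buccal"`,
#'   `"neonatal_buccal"` or `"none"` (questionnaire and other
#'   non-tissue variables).
#' @param units Free-text units, e.g. `"%"`, `"mg/kg"`, `"pg TEQ/g"` or `""`.
#' @param valid_range Length-2 numeric, the closed interval of admissible
#'   values for a continuous variable (upper bound may be `Inf`). Ignored for
#'   binary variables.
#' @param levels Character vector of the two class labels for a binary
#'   variable, e.g. `c("suboptimal", "adequate")`. Ignored for continuous
#'   variables.
#' @return An object of class `"variable_spec"`.
#' @examples
#' variable_spec("H19_placenta", "continuous", tissue = "placenta",
#'               units = "%", valid_range = c(0, 100))
#' variable_spec("stressful_events", "binary", levels = c("yes", "no"))
#' @export
variable_spec <- function(name, kind = c("continuous", "binary"),
                          tissue = c("none", "placenta", "maternal_buccal",
                                     "neonatal_buccal"),
                          units = "", valid_range = NULL, levels = NULL) {
  kind <- match.arg(kind)
  tissue <- match.arg(tissue)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    if (is.null(valid_range)) valid_range <- c(-Inf, Inf)
    valid_range <- as.numeric(valid_range)
    if (length(valid_range) != 2L || is.na(valid_range[1]) ||
        is.na(valid_range[2]) || !(valid_range[1] < valid_range[2])) {
      stop("variable '", name,
           "': valid_range must be an interval with low < high",
           call. = FALSE)
    }
    levels <- NULL
  } else {
    if (length(levels) != 2L || anyDuplicated(levels)) {
      stop("variable '", name,
           "': binary variables need exactly 2 distinct levels",
           call. = FALSE)
    }
    levels <- as.character(levels)
    valid_range <- NULL
  }
  structure(list(name = name, kind = kind, tissue = tissue, units = units,
                 valid_range = valid_range, levels = levels),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  dom <- if (x$kind == "binary") paste(x$levels, collapse = "/") else
    paste0("[", x$valid_range[1], ", ", x$valid_range[2], "]")
  cat(sprintf("<variable_spec> %s (%s, %s%s) %s\n", x$name, x$kind, x$tissue,
              if (nzchar(x$units)) paste0(", ", x$units) else "", dom))
  invisible(x)
}

#' Assemble a cohort table
#'
#' A cohort table is the raw subjects-by-variables grid of mixed-type
#' observations together with the per-variable metadata. Binary cells hold
#' one of the declared class labels, continuous cells hold a real inside the
#' variable's valid range; missing values (`NA`) are permitted and dealt with
#' downstream (see [encode_cohort()]).
#'
#' @param data A data.frame with one column per declared variable (in any
#'   order; they are reordered to schema order). Binary columns must be
#'   character, continuous columns numeric.
#' @param variables List of [variable_spec()] objects, one per column.
#' @param subjects Character vector of unique subject identifiers, one per
#'   row. Defaults to `S1, S2, ...`.
#' @return An object of class `"cohort_table"` with elements `subjects`,
#'   `variables` and `data`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
cohort_table <- function(data, variables, subjects = NULL) {
  stopifnot(is.data.frame(data), is.list(variables))
  vnames <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(vnames)) {
    stop("duplicate variable names in schema: ",
         paste(unique(vnames[duplicated(vnames)]), collapse = ", "),
         call. = FALSE)
  }
  names(variables) <- vnames
  extra <- setdiff(names(data), vnames)
  if (length(extra)) {
    stop("undeclared column(s) in table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(vnames, names(data))
  if (length(missing_cols)) {
    stop("column(s) declared in schema but absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, vnames, drop = FALSE]
  if (is.null(subjects)) {
    subjects <- if (nrow(data)) paste0("S", seq_len(nrow(data))) else
      character(0)
  }
  subjects <- as.character(subjects)
  if (length(subjects) != nrow(data)) {
    stop("length of subjects does not match number of rows", call. = FALSE)
  }
  if (anyDuplicated(subjects)) {
    stop("subject identifiers must be unique", call. = FALSE)
  }
  rownames(data) <- NULL
  x <- structure(list(subjects = subjects, variables = variables,
                      data = data),
                 class = "cohort_table")
  validate_cohort(x)
  x
}

#' Validate a cohort table against its schema
#'
#' Checks every non-missing cell: continuous values must lie inside the
#' variable's valid range, binary values must be one of the declared levels.
#' Errors name the offending subject and variable.
#'
#' @param cohort A [cohort_table()].
#' @return `cohort`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  for (v in cohort$variables) {
    col <- cohort$data[[v$name]]
    if (v$kind == "continuous") {
      if (!is.numeric(col)) {
        stop("variable '", v$name, "' must be numeric", call. = FALSE)
      }
      bad <- which(!is.na(col) &
                     (col < v$valid_range[1] | col > v$valid_range[2]))
      if (length(bad)) {
        stop(sprintf(
          "subject '%s', variable '%s': value %s outside valid range [%s, %s]",
          cohort$subjects[bad[1]], v$name, format(col[bad[1]]),
          format(v$valid_range[1]), format(v$valid_range[2])), call. = FALSE)
      }
    } else {
      col <- as.character(col)
      bad <- which(!is.na(col) & !(col %in% v$levels))
      if (length(bad)) {
        stop(sprintf(
          "subject '%s', variable '%s': unknown level '%s' (expected %s)",
          cohort$subjects[bad[1]], v$name, col[bad[1]],
          paste(v$levels, collapse = "/")), call. = FALSE)
      }
    }
  }
  invisible(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  nb <- sum(vapply(x$variables, function(v) v$kind == "binary", logical(1)))
  cat(sprintf("<cohort_table> %d subjects x %d variables (%d binary, %d continuous)\n",
              length(x$subjects), length(x$variables), nb,
              length(x$variables) - nb))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) {
  c(length(x$subjects), length(x$variables))
}

# ---- schema (YAML) I/O ------------------------------------------------------

#' Read or write a variable schema
#'
#' The schema is a YAML document with a top-level `variables` sequence, one
#' mapping per variable with keys `name`, `kind`, `tissue`, `units` and
#' either `valid_range` (continuous; `.inf` allowed for an unbounded upper
#' end) or `levels` (binary).
#'
#' @param path File path of the YAML schema.
#' @return `read_schema()` returns a list of [variable_spec()] objects.
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$variables)) {
    stop("schema file has no 'variables' entry: ", path, call. = FALSE)
  }
  lapply(doc$variables, function(e) {
    variable_spec(name = e$name, kind = e$kind,
                  tissue = if (is.null(e$tissue)) "none" else e$tissue,
                  units = if (is.null(e$units)) "" else e$units,
                  valid_range = if (is.null(e$valid_range)) NULL else
                    unlist(e$valid_range),
                  levels = if (is.null(e$levels)) NULL else unlist(e$levels))
  })
}

#' @rdname read_schema
#' @param variables List of [variable_spec()] objects (or a
#'   [cohort_table()], whose schema is used).
#' @return `write_schema()` returns `path`, invisibly.
#' @export
write_schema <- function(variables, path) {
  if (inherits(variables, "cohort_table")) variables <- variables$variables
  entries <- lapply(variables, function(v) {
    e <- list(name = v$name, kind = v$kind, tissue = v$tissue,
              units = v$units)
    if (v$kind == "continuous") e$valid_range <- v$valid_range
    else e$levels <- v$levels
    e
  })
  yaml::write_yaml(list(variables = unname(entries)), path)
  invisible(path)
}

# ---- cohort table (CSV) I/O -------------------------------------------------

#' Read a cohort table from CSV plus a schema
#'
#' The table is RFC-4180 CSV with a header row: a `subject_id` column
#' followed by one column per schema variable. Missing values are empty
#' fields. Every column must be declared in the schema and every cell is
#' validated against it.
#'
#' @param table_path CSV file with the observations.
#' @param schema_path YAML schema file (see [read_schema()]).
#' @return A validated [cohort_table()]; column order follows schema order.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_subjects = 5, seed = 1))
#' tf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".yml")
#' write_cohort(cohort, tf); write_schema(cohort, sf)
#' cohort2 <- read_cohort(tf, sf)
#' @export
read_cohort <- function(table_path, schema_path) {
  variables <- read_schema(schema_path)
  raw <- utils::read.csv(table_path, check.names = FALSE,
                         colClasses = "character", na.strings = "")
  if (!"subject_id" %in% names(raw)) {
    stop("cohort table must have a 'subject_id' column", call. = FALSE)
  }
  subjects <- raw[["subject_id"]]
  raw <- raw[, setdiff(names(raw), "subject_id"), drop = FALSE]
  vnames <- vapply(variables, function(v) v$name, character(1))
  extra <- setdiff(names(raw), vnames)
  if (length(extra)) {
    stop("undeclared column(s) in table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (v in variables) {
    if (!v$name %in% names(raw)) next
    if (v$kind == "continuous") {
      col <- raw[[v$name]]
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop(sprintf("subject '%s', variable '%s': non-numeric value '%s'",
                     subjects[bad[1]], v$name, col[bad[1]]), call. = FALSE)
      }
      raw[[v$name]] <- num
    }
  }
  cohort_table(raw, variables, subjects = subjects)
}

#' Write a cohort table to CSV
#'
#' Writes a `subject_id` column followed by the variables in schema order.
#' Missing cells become empty fields; numerics are written with enough
#' digits to round-trip exactly, so `read_cohort(write_cohort(x))`
#' reproduces `x` cell for cell.
#'
#' @param cohort A [cohort_table()].
#' @param table_path Output CSV path.
#' @return `table_path`, invisibly.
#' @export
write_cohort <- function(cohort, table_path) {
  validate_cohort(cohort)
  out <- cohort$data
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      chr <- sprintf("%.17g", out[[nm]])
      chr[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- chr
    }
  }
  out <- cbind(data.frame(subject_id = cohort$subjects,
                          stringsAsFactors = FALSE), out)
  utils::write.csv(out, table_path, row.names = FALSE, na = "")
  invisible(table_path)
}
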