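#' Binary-code a questionnaire variable
#'
#' Each class becomes an indicator node: 1 where the class is present,
#' 0 where absent. In `"both_levels"` mode both outcomes of the parameter
#' are emitted as two complementary nodes (the two columns sum to 1 in every
#' row); `"first_level_only"` emits the first level's indicator alone.
#'
#' @param x Character vector of observations.
#' @param levels The two class labels; the first is taken as the reference
#'   ("present") class.
#' @param mode `"both_levels"` (default) or `"first_level_only"`.
#' @return A numeric 0/1 matrix with one or two named columns.
#' @examples
#' encode_binary(c("suboptimal", "adequate", "suboptimal"),
#'               c("suboptimal", "adequate"))
#' @export
encode_binary <- function(x, levels,
                          mode = c("both_levels", "first_level_only")) {
  mode <- match.arg(mode)
  stopifnot(length(levels) == 2L)
  x <- as.character(x)
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    stop("unknown level '", x[bad[1]], "' (expected ",
         paste(levels, collapse = "/"), ")", call. = FALSE)
  }
  first <- as.numeric(x == levels[1])
  if (mode == "first_level_only") {
    m <- matrix(first, ncol = 1, dimnames = list(NULL, levels[1]))
  } else {
    m <- cbind(first, 1 - first)
    colnames(m) <- levels
  }
  m
}

#' Min-max scale a continuous variable onto [0, 1]
#'
#' The affine map `x -> (x - min) / (max - min)` over the observed (or
#' supplied) range, so the smallest value becomes exactly 0 and the largest
#' exactly 1. For example, a methylation column ranging from 40.7% to 76.1%
#' maps 40.7 to 0 and 76.1 to 1, with all other values scaled in proportion.
#'
#' @param x Numeric vector (no missing values).
#' @param observed_range Optional length-2 numeric `(min, max)`; defaults to
#'   `range(x)`. Values of `x` outside a supplied range are an error.
#' @return Numeric vector in `[0, 1]` with attributes `"min"` and `"max"`
#'   recording the range used.
#' @examples
#' scale_minmax(c(40.7, 58.4, 76.1))
#' @export
scale_minmax <- function(x, observed_range = NULL) {
  stopifnot(is.numeric(x), !anyNA(x))
  if (is.null(observed_range)) {
    observed_range <- range(x)
  } else {
    stopifnot(length(observed_range) == 2L)
    if (any(x < observed_range[1] | x > observed_range[2])) {
      stop("values outside the supplied observed_range", call. = FALSE)
    }
  }
  lo <- observed_range[1]; hi <- observed_range[2]
  if (hi == lo) {
    stop("constant column: max == min, cannot min-max scale", call. = FALSE)
  }
  structure((x - lo) / (hi - lo), min = lo, max = hi)
}

#' Encode a cohort table into the [0,1] matrix the Auto-CM consumes
#'
#' Binary variables are binary-coded ([encode_binary()]) and continuous
#' variables min-max scaled on their observed range ([scale_minmax()]), in
#' schema order. Constant continuous columns carry no information for the
#' map and are dropped with a warning by default (e.g. a metal never
#' detected in any placenta); binary variables whose two indicator columns
#' are constant are likewise dropped. Missing values are rejected unless the
#' median/mode imputation policy is chosen.
#'
#' @param cohort A validated [cohort_table()].
#' @param binary_mode Passed to [encode_binary()]; `"both_levels"` keeps
#'   both outcomes of each questionnaire parameter as complementary nodes,
#'   mirroring maps whose nodes name specific classes.
#' @param constant Policy for constant continuous columns: `"drop"`
#'   (default, with a warning) or `"midpoint"` (keep as a constant 0.5
#'   node).
#' @param missing Policy for missing cells: `"error"` (default) or
#'   `"impute"` (variable median for continuous, mode for binary).
#' @return An object of class `"encoded_matrix"`: list with `records`
#'   (subject ids), `nodes` (node labels; binary nodes are
#'   `"variable=level"`), `values` (records x nodes numeric matrix in
#'   `[0, 1]`), `provenance` (per-node data.frame with source variable,
#'   class level, and the observed min/max used for scaling) and `dropped`
#'   (names of dropped constant variables).
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_subjects = 28, seed = 1))
#' em <- encode_cohort(cohort)
#' range(em$values)
#' @export
encode_cohort <- function(cohort,
                          binary_mode = c("both_levels", "first_level_only"),
                          constant = c("drop", "midpoint"),
                          missing = c("error", "impute")) {
  binary_mode <- match.arg(binary_mode)
  constant <- match.arg(constant)
  missing <- match.arg(missing)
  validate_cohort(cohort)

  cols <- list()
  prov <- list()
  dropped <- character(0)
  n <- length(cohort$subjects)

  for (v in cohort$variables) {
    x <- cohort$data[[v$name]]
    if (anyNA(x)) {
      if (missing == "error") {
        stop("variable '", v$name, "' has missing values; set ",
             "missing = \"impute\" or complete the data", call. = FALSE)
      }
      if (v$kind == "continuous") {
        x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      } else {
        tab <- table(x)
        x[is.na(x)] <- names(tab)[which.max(tab)]
      }
    }
    if (v$kind == "binary") {
      m <- encode_binary(x, v$levels, mode = binary_mode)
      if (n > 0 && length(unique(m[, 1])) == 1L && constant == "drop") {
        warning("dropping constant binary variable '", v$name, "'",
                call. = FALSE)
        dropped <- c(dropped, v$name)
        next
      }
      for (j in seq_len(ncol(m))) {
        lab <- paste0(v$name, "=", colnames(m)[j])
        cols[[lab]] <- m[, j]
        prov[[lab]] <- data.frame(node = lab, variable = v$name,
                                  kind = "binary",
                                  level = colnames(m)[j],
                                  obs_min = NA_real_, obs_max = NA_real_,
                                  stringsAsFactors = FALSE)
      }
    } else {
      if (n > 0 && max(x) == min(x)) {
        if (constant == "drop") {
          warning("dropping constant continuous variable '", v$name,
                  "' (all values ", format(x[1]), ")", call. = FALSE)
          dropped <- c(dropped, v$name)
          next
        }
        s <- rep(0.5, n)
        attr(s, "min") <- x[1]; attr(s, "max") <- x[1]
      } else {
        s <- scale_minmax(x)
      }
      cols[[v$name]] <- as.numeric(s)
      prov[[v$name]] <- data.frame(node = v$name, variable = v$name,
                                   kind = "continuous", level = NA_character_,
                                   obs_min = attr(s, "min"),
                                   obs_max = attr(s, "max"),
                                   stringsAsFactors = FALSE)
    }
  }

  if (!length(cols)) stop("no nodes left after encoding", call. = FALSE)
  values <- do.call(cbind, cols)
  rownames(values) <- cohort$subjects
  structure(list(records = cohort$subjects, nodes = colnames(values),
                 values = values,
                 provenance = do.call(rbind, unname(prov)),
                 dropped = dropped),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("<encoded_matrix> %d records x %d nodes, values in [%.3g, %.3g]\n",
              length(x$records), length(x$nodes),
              min(x$values), max(x$values)))
  if (length(x$dropped)) {
    cat("  dropped constant variables:", paste(x$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write or read an encoded matrix
#'
#' The matrix is written as records x nodes CSV (first column `record`),
#' with a sidecar YAML carrying the per-node scaling provenance so a map can
#' be regenerated or back-transformed later.
#'
#' @param em An [encode_cohort()] result.
#' @param path CSV path for the values.
#' @param provenance_path YAML path for the provenance sidecar; defaults to
#'   `path` with a `.provenance.yml` suffix.
#' @return `write_encoded()` returns `path` invisibly; `read_encoded()`
#'   returns an `"encoded_matrix"`.
#' @export
write_encoded <- function(em, path,
                          provenance_path = paste0(path, ".provenance.yml")) {
  stopifnot(inherits(em, "encoded_matrix"))
  df <- data.frame(record = em$records, stringsAsFactors = FALSE)
  vals <- as.data.frame(em$values)
  names(vals) <- em$nodes
  utils::write.csv(cbind(df, vals), path, row.names = FALSE)
  prov <- lapply(seq_len(nrow(em$provenance)), function(i) {
    p <- as.list(em$provenance[i, ])
    p[!vapply(p, function(z) is.na(z), logical(1))]
  })
  yaml::write_yaml(list(dropped = as.list(em$dropped),
                        nodes = prov), provenance_path)
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path,
                         provenance_path = paste0(path, ".provenance.yml")) {
  df <- utils::read.csv(path, check.names = FALSE)
  records <- as.character(df$record)
  values <- as.matrix(df[, setdiff(names(df), "record"), drop = FALSE])
  rownames(values) <- records
  doc <- yaml::read_yaml(provenance_path)
  prov <- do.call(rbind, lapply(doc$nodes, function(p) {
    data.frame(node = p$node, variable = p$variable, kind = p$kind,
               level = if (is.null(p$level)) NA_character_ else p$level,
               obs_min = if (is.null(p$obs_min)) NA_real_ else p$obs_min,
               obs_max = if (is.null(p$obs_max)) NA_real_ else p$obs_max,
               stringsAsFactors = FALSE)
  }))
  structure(list(records = records, nodes = colnames(values), values = values,
                 provenance = prov,
                 dropped = as.character(unlist(doc$dropped))),
            class = "encoded_matrix")
}
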