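#' Build an MS-HRM standard curve
#'
#' In methylation-sensitive high-resolution melting, fully methylated and
#' unmethylated control DNA are mixed in known ratios (canonically 0, 12.5,
#' 25, 50, 75 and 100%) and each standard's melt-derived response anchors
#' an interpolation curve used to assign a methylation percentage to every
#' sample. The module is agnostic to how the response statistic is reduced
#' from the melt signal; it only requires responses strictly monotone in
#' the methylation level.
#'
#' @param levels Numeric methylation levels of the standards, in percent
#'   (`[0, 100]`), strictly increasing after sorting; at least 2 distinct
#'   levels.
#' @param responses Melt-derived response of each standard (arbitrary
#'   units), strictly monotone in level (either direction).
#' @return An object of class `"calibration_curve"` with the ordered
#'   standards and the inferred `direction` (`"increasing"` or
#'   `"decreasing"`).
#' @examples
#' cal <- calibration_curve(c(0, 12.5, 25, 50, 75, 100),
#'                          c(0.02, 0.11, 0.24, 0.52, 0.77, 0.98))
#' predict(cal, c(0.52, 0.065))
#' @export
calibration_curve <- function(levels, responses) {
  stopifnot(is.numeric(levels), is.numeric(responses),
            length(levels) == length(responses), length(levels) >= 2,
            all(is.finite(levels)), all(is.finite(responses)))
  if (anyDuplicated(levels)) {
    stop("duplicate standard levels", call. = FALSE)
  }
  ord <- order(levels)
  levels <- levels[ord]; responses <- responses[ord]
  dr <- diff(responses)
  if (all(dr > 0)) {
    direction <- "increasing"
  } else if (all(dr < 0)) {
    direction <- "decreasing"
  } else {
    stop("standard responses are not strictly monotone in level",
         call. = FALSE)
  }
  structure(list(standards = data.frame(level = levels,
                                        response = responses),
                 direction = direction),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d standards (%s response), levels %s%%\n",
              nrow(x$standards), x$direction,
              paste(x$standards$level, collapse = "/")))
  invisible(x)
}

#' Assign methylation percentages from a standard curve
#'
#' Piecewise-linear inverse interpolation between the bracketing standards;
#' a response exactly equal to a standard's response returns that
#' standard's level exactly. Responses beyond the extreme standards clamp
#' to the extreme levels (0 or 100% for the canonical curve) and are
#' flagged as out of range rather than extrapolated, since methylation is
#' bounded.
#'
#' @param object A [calibration_curve()].
#' @param response Numeric vector of melt-derived sample responses (finite).
#' @param ... Unused.
#' @return A data.frame with columns `response`, `methylation` (percent)
#'   and `out_of_range` (logical).
#' @export
predict.calibration_curve <- function(object, response, ...) {
  stopifnot(is.numeric(response))
  if (any(!is.finite(response))) {
    stop("non-finite response", call. = FALSE)
  }
  s <- object$standards
  r <- s$response; l <- s$level
  if (object$direction == "decreasing") {
    r <- rev(r); l <- rev(l)
  }
  below <- response < r[1]
  above <- response > r[length(r)]
  meth <- stats::approx(r, l, xout = pmin(pmax(response, r[1]),
                                          r[length(r)]),
                        method = "linear", ties = "ordered")$y
  # exact at the standards regardless of interpolation rounding
  hit <- match(response, s$response)
  meth[!is.na(hit)] <- s$level[hit[!is.na(hit)]]
  data.frame(response = response, methylation = meth,
             out_of_range = below | above)
}

#' Read standards from CSV and quantify samples to CSV
#'
#' Convenience I/O around [calibration_curve()] and its `predict()`
#' method: standards come in as a two-column CSV (`level`, `response`),
#' sample quantifications go out as CSV with `sample`, `response`,
#' `methylation` and `out_of_range` columns.
#'
#' @param standards_path CSV with `level` and `response` columns.
#' @return `read_standards()` returns a `"calibration_curve"`.
#' @export
read_standards <- function(standards_path) {
  df <- utils::read.csv(standards_path)
  calibration_curve(df$level, df$response)
}

#' @rdname read_standards
#' @param curve A `"calibration_curve"`.
#' @param samples Data.frame with `sample` and `response` columns (or a
#'   named numeric vector of responses).
#' @param out_path Output CSV path.
#' @return `write_quantification()` returns the quantification data.frame,
#'   invisibly.
#' @export
write_quantification <- function(curve, samples, out_path) {
  if (is.numeric(samples)) {
    samples <- data.frame(sample = names(samples) %||%
                            paste0("sample", seq_along(samples)),
                          response = as.numeric(samples))
  }
  q <- predict(curve, samples$response)
  out <- data.frame(sample = samples$sample, response = q$response,
                    methylation = q$methylation,
                    out_of_range = q$out_of_range)
  utils::write.csv(out, out_path, row.names = FALSE)
  invisible(out)
}
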