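#' Run the full connectivity-map pipeline
#'
#' Chains cohort acquisition (read from CSV + schema, or simulate), [0,1]
#' encoding, Auto-CM training and map construction, writing every stage's
#' artifact plus a run log into an output directory. Deterministic given
#' the seeds in the configuration.
#'
#' @param input Optional list with `table` and `schema` paths of an
#'   existing cohort. Exactly one of `input` / `simulate` must be given.
#' @param simulate Optional [cohort_sim_config()] to generate the cohort.
#' @param outdir Output directory (created if needed).
#' @param encode_options List of arguments for [encode_cohort()]
#'   (`binary_mode`, `constant`, `missing`).
#' @param training An [autocm_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `cohort`, `encoded`, `model`, `map` and
#'   the paths written. The run log records dropped constant nodes, the
#'   convergence epoch and the hub set.
#' @examples
#' \donttest{
#' out <- run_pipeline(simulate = cohort_sim_config(seed = 11),
#'                     outdir = tempfile())
#' out$map$hubs
#' }
#' @export
run_pipeline <- function(input = NULL, simulate = NULL,
                         outdir = "autocm_run",
                         encode_options = list(),
                         training = autocm_config(),
                         quiet = FALSE) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of 'input' or 'simulate' must be supplied",
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  if (!is.null(simulate)) {
    say("stage simulate: n_subjects = %d, seed = %d",
        simulate$n_subjects, simulate$seed)
    cohort <- simulate_cohort(simulate)
    write_cohort(cohort, file.path(outdir, "cohort.csv"))
    write_schema(cohort, file.path(outdir, "schema.yml"))
  } else {
    say("stage read: %s", input$table)
    cohort <- read_cohort(input$table, input$schema)
  }
  say("cohort: %d subjects x %d variables", length(cohort$subjects),
      length(cohort$variables))

  encoded <- withCallingHandlers(
    do.call(encode_cohort, c(list(cohort), encode_options)),
    warning = function(w) {
      say("stage encode: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  say("stage encode: %d nodes (%d constant variable(s) dropped)",
      length(encoded$nodes), length(encoded$dropped))
  write_encoded(encoded, file.path(outdir, "encoded.csv"))

  model <- autocm_train(encoded, training)
  say("stage train: %s after %d epochs (final mean |output| = %.3g)",
      if (model$converged) "converged" else "stopped", model$epochs_run,
      model$trace[length(model$trace)])
  write_autocm(model, file.path(outdir, "model"))

  map <- connectivity_map(model)
  say("stage map: %d tree edges, hubs: %s", nrow(map$edges),
      paste(map$hubs, collapse = ", "))
  export_map(map, file.path(outdir, "map_edges.csv"), format = "edge_csv")
  export_map(map, file.path(outdir, "map.graphml"), format = "graphml")
  export_map(map, file.path(outdir, "map.dot"), format = "dot")

  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(list(cohort = cohort, encoded = encoded, model = model,
                 map = map, outdir = outdir, log = log_lines))
}
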