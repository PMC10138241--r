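#' Auto-CM training configuration
#'
#' The Auto-Contractive Map (Auto-CM) is a three-layer unsupervised network
#' with a contraction constant `C`. Each node `s` has a hidden-contraction
#' weight `v[s]` and each ordered node pair `(i, s)` an output-contraction
#' weight `w[i, s]`; all weights grow monotonically from their initial value
#' toward `C` as a function of co-activation across records, and at
#' convergence the output signal vanishes.
#'
#' @param C Contraction constant: a positive real, or `"auto"` (default) for
#'   `C = N`, the number of nodes, which guarantees every contraction factor
#'   `1 - Net/C` stays in `[0, 1]` for inputs in `[0, 1]`.
#' @param alpha Learning factor (default 0.1); updates are online,
#'   record by record.
#' @param init Initial weight value as a fraction of `C` (default 0.01).
#'   It must be strictly positive: the hidden-layer update is proportional
#'   to `v` itself, so `v = 0` is an exactly absorbing state from which the
#'   hidden contraction can never engage and training cannot converge.
#' @param max_epochs Maximum number of passes over the records
#'   (default 5000).
#' @param tol Convergence tolerance on the epoch mean absolute output
#'   signal (default `1e-6`).
#' @param record_order `"dataset"` (default; bit-reproducible) or
#'   `"shuffled"` (a fresh permutation per epoch, driven by `seed`).
#' @param seed Integer seed for `record_order = "shuffled"`.
#' @return An object of class `"autocm_config"`.
#' @export
autocm_config <- function(C = "auto", alpha = 0.1, init = 0.01,
                          max_epochs = 5000, tol = 1e-6,
                          record_order = c("dataset", "shuffled"),
                          seed = NULL) {
  record_order <- match.arg(record_order)
  if (!identical(C, "auto")) {
    stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  }
  stopifnot(alpha > 0, init > 0, init < 1, max_epochs >= 1, tol > 0)
  if (record_order == "shuffled" && is.null(seed)) {
    stop("record_order = \"shuffled\" needs a seed", call. = FALSE)
  }
  structure(list(C = C, alpha = alpha, init = init,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 record_order = record_order, seed = seed),
            class = "autocm_config")
}

#' Initialise an untrained Auto-CM model
#'
#' @param n_nodes Number of nodes `N`.
#' @param config An [autocm_config()].
#' @param nodes Optional node labels.
#' @return An object of class `"autocm"` with elements `C`, `alpha`, `v`
#'   (length-`N` hidden-contraction weights), `w` (`N x N`
#'   output-contraction weights), `nodes`, `epochs_run`, `converged` and
#'   `trace`.
#' @export
autocm_init <- function(n_nodes, config = autocm_config(), nodes = NULL) {
  stopifnot(n_nodes >= 1)
  C <- if (identical(config$C, "auto")) as.numeric(n_nodes) else config$C
  w0 <- config$init * C
  structure(list(C = C, alpha = config$alpha,
                 v = rep(w0, n_nodes),
                 w = matrix(w0, n_nodes, n_nodes,
                            dimnames = list(nodes, nodes)),
                 nodes = nodes, epochs_run = 0L, converged = FALSE,
                 trace = numeric(0), config = config),
            class = "autocm")
}

#' Auto-CM forward pass
#'
#' Propagates one record through the three layers:
#' `hidden[s] = record[s] * (1 - v[s]/C)`;
#' `net[i] = sum_s hidden[s] * (1 - w[i,s]/C)`;
#' `output[i] = hidden[i] * (1 - net[i]/C)`.
#' With weights in `[0, C]` and `C >= N`, outputs satisfy
#' `0 <= output <= hidden <= record` element-wise.
#'
#' @param model An `"autocm"` model.
#' @param record Numeric vector in `[0, 1]` of length `N`.
#' @return List with `hidden`, `net` and `output`.
#' @export
autocm_forward <- function(model, record) {
  stopifnot(inherits(model, "autocm"))
  if (length(record) != length(model$v)) {
    stop("record length ", length(record), " does not match model size ",
         length(model$v), call. = FALSE)
  }
  hidden <- record * (1 - model$v / model$C)
  net <- as.vector((1 - model$w / model$C) %*% hidden)
  output <- hidden * (1 - net / model$C)
  list(hidden = hidden, net = net, output = output)
}

#' Auto-CM weight update for one record
#'
#' Applies the monotone contraction updates computed from the forward
#' quantities of `record`:
#' `v[s] <- v[s] + alpha * (record[s] - hidden[s]) * (1 - v[s]/C)` and
#' `w[i,s] <- w[i,s] + alpha * (hidden[i] - output[i]) * (1 - w[i,s]/C) * hidden[s]`.
#' For inputs in `[0, 1]` every increment is nonnegative and weights stay
#' within `[0, C]` (a floating-point guard clamps them there).
#'
#' @inheritParams autocm_forward
#' @return The model with incremented weights.
#' @export
autocm_update <- function(model, record) {
  fw <- autocm_forward(model, record)
  dv <- model$alpha * (record - fw$hidden) * (1 - model$v / model$C)
  model$v <- pmin(pmax(model$v + dv, 0), model$C)
  dw <- model$alpha * outer(fw$hidden - fw$output, fw$hidden) *
    (1 - model$w / model$C)
  model$w <- pmin(pmax(model$w + dw, 0), model$C)
  model
}

#' Train an Auto-CM on an encoded matrix
#'
#' Iterates record-wise forward + update passes over epochs until the epoch
#' mean absolute output signal falls below `tol` or `max_epochs` is
#' reached. With `record_order = "dataset"` the result is bit-reproducible.
#' The trained `w` matrix encodes pairwise association strength: node pairs
#' that are systematically co-active accumulate larger weights (see
#' [weights_to_sa()]).
#'
#' @param x An [encode_cohort()] result, or a plain numeric matrix
#'   (records x nodes) with all entries in `[0, 1]`.
#' @param config An [autocm_config()].
#' @return A trained `"autocm"` model; `trace` holds the per-epoch mean
#'   `|output|` and `converged` whether it dropped below `tol`.
#' @examples
#' m <- matrix(runif(60), 20, 3)
#' fit <- autocm_train(m, autocm_config(max_epochs = 50))
#' fit$epochs_run
#' @export
autocm_train <- function(x, config = autocm_config()) {
  if (inherits(x, "encoded_matrix")) {
    nodes <- x$nodes
    x <- x$values
  } else {
    nodes <- colnames(x)
  }
  x <- as.matrix(x)
  if (!nrow(x) || !ncol(x)) stop("empty training matrix", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    stop("training matrix must be fully observed with entries in [0, 1]",
         call. = FALSE)
  }
  model <- autocm_init(ncol(x), config, nodes = nodes)
  orders <- NULL
  if (config$record_order == "shuffled") {
    orders <- with_local_seed(config$seed, {
      vapply(seq_len(config$max_epochs),
             function(e) sample.int(nrow(x)), integer(nrow(x)))
    })
    if (is.null(dim(orders))) orders <- matrix(orders, nrow = nrow(x))
  }
  res <- autocm_train_cpp(x, model$C, config$alpha, config$init * model$C,
                          config$tol, config$max_epochs, orders)
  if (!all(is.finite(res$v)) || !all(is.finite(res$w))) {
    stop("non-finite weights during training; check that C >= N ",
         "(C = \"auto\") and alpha is moderate", call. = FALSE)
  }
  model$v <- res$v
  model$w <- matrix(res$w, ncol(x), ncol(x), dimnames = list(nodes, nodes))
  model$epochs_run <- res$epochs_run
  model$converged <- res$converged
  model$trace <- res$trace
  model
}

#' @export
print.autocm <- function(x, ...) {
  cat(sprintf("<autocm> %d nodes, C = %.4g, alpha = %.3g\n",
              length(x$v), x$C, x$alpha))
  if (x$epochs_run > 0) {
    cat(sprintf("  trained %d epochs, %s (final mean |output| = %.3g)\n",
                x$epochs_run,
                if (x$converged) "converged" else "not converged",
                x$trace[length(x$trace)]))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# ---- model bundle I/O -------------------------------------------------------

#' Save or load a trained Auto-CM as a YAML + CSV bundle
#'
#' `write_autocm()` writes `model.yml` (C, alpha, epochs, convergence,
#' trace), `v.csv` and `w.csv` into `dir`; `read_autocm()` restores the
#' model so the connectivity map can be regenerated without retraining.
#'
#' @param model A trained `"autocm"`.
#' @param dir Bundle directory (created if needed).
#' @return `write_autocm()` returns `dir` invisibly; `read_autocm()` the
#'   model.
#' @export
write_autocm <- function(model, dir) {
  stopifnot(inherits(model, "autocm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(C = model$C, alpha = model$alpha,
                        epochs_run = model$epochs_run,
                        converged = model$converged,
                        trace = as.list(model$trace)),
                   file.path(dir, "model.yml"))
  utils::write.csv(data.frame(node = model$nodes %||% seq_along(model$v),
                              v = sprintf("%.17g", model$v)),
                   file.path(dir, "v.csv"), row.names = FALSE)
  w <- matrix(sprintf("%.17g", model$w), nrow(model$w))
  colnames(w) <- model$nodes %||% paste0("n", seq_len(ncol(model$w)))
  utils::write.csv(as.data.frame(w), file.path(dir, "w.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_autocm
#' @export
read_autocm <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yml"))
  vdf <- utils::read.csv(file.path(dir, "v.csv"), check.names = FALSE,
                         colClasses = "character")
  wdf <- utils::read.csv(file.path(dir, "w.csv"), check.names = FALSE,
                         colClasses = "character")
  nodes <- vdf$node
  w <- apply(as.matrix(wdf), 2, as.numeric)
  dimnames(w) <- list(nodes, nodes)
  structure(list(C = meta$C, alpha = meta$alpha,
                 v = as.numeric(vdf$v), w = w, nodes = nodes,
                 epochs_run = as.integer(meta$epochs_run),
                 converged = isTRUE(meta$converged),
                 trace = as.numeric(unlist(meta$trace)),
                 config = NULL),
            class = "autocm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
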